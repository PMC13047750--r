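test_that("the probit transform is exact and round-trips", {
  expect_equal(probit_transform(0.5), 0)
  expect_equal(probit_transform(pnorm(1)), 1, tolerance = 1e-10)
  expect_equal(pnorm(probit_transform(0.3)), 0.3, tolerance = 1e-12)
  # vectorized round trip
  a <- seq(0.01, 0.99, by = 0.007)
  expect_equal(pnorm(probit_transform(a)), a, tolerance = 1e-10)
  # clipping keeps the endpoints finite
  expect_true(all(is.finite(probit_transform(c(0, 1)))))
  expect_error(probit_transform(1.2), "0, 1")
})

test_that("single-subject MAP recovers a strong go bias at large n", {
  pars <- orl_params(0.2, 0.2, 0, 3)
  s <- do.call(rbind, lapply(1:4, function(i)
    simulate_agent(pars, task_config(), seed = 100 + i)))
  s$trial <- seq_len(nrow(s))
  flat <- list(mean = rep(0, 4), sd = rep(10, 4))
  est <- fit_subject_map(s, flat)
  expect_true(est$converged)
  expect_lt(abs(est$beta_b - 3), 0.5)
})

test_that("a tighter prior shrinks every unconstrained coordinate toward its mean", {
  s <- simulate_agent(orl_params(0.3, 0.2, 3, 1.5), task_config(), seed = 5)
  flat <- fit_subject_map(s, list(mean = rep(0, 4), sd = rep(10, 4)))
  tight <- fit_subject_map(s, list(mean = rep(0, 4), sd = rep(0.2, 4)))
  fl <- unlist(flat[c("a_rew_z", "a_pun_z", "beta_f", "beta_b")])
  ti <- unlist(tight[c("a_rew_z", "a_pun_z", "beta_f", "beta_b")])
  expect_true(all(abs(ti) < abs(fl)))
})

test_that("an all-pass session leaves the learning rates at the prior mean", {
  allpass <- manual_session(rep(c("A", "B", "C", "D"), 30), rep("pass", 120))
  prior <- list(mean = c(-0.8, 0.4, 1, 0), sd = c(1, 1, 2, 1))
  est <- fit_subject_map(allpass, prior)
  expect_equal(est$a_rew_z, -0.8, tolerance = 1e-4)
  expect_equal(est$a_pun_z, 0.4, tolerance = 1e-4)
})

test_that("hierarchical fits are exchangeable and shrink between-subject variance", {
  smp <- simulate_sample(12, task = quick_task(), seed = 21)
  dup <- c(smp$sessions, lapply(smp$sessions, function(s) {
    s$subject_id <- paste0(s$subject_id, "dup"); s
  }))
  fit <- fit_wave(dup, quick_fit())
  est <- fit$estimates
  for (id in smp$truth$subject_id) {
    a <- est[est$subject_id == id, -1]
    b <- est[est$subject_id == paste0(id, "dup"), -1]
    rownames(a) <- rownames(b) <- NULL
    expect_equal(a, b)
  }
  # shrinkage: hierarchical spread never exceeds flat-prior MLE spread
  flat <- list(mean = rep(0, 4), sd = rep(20, 4))
  mle <- t(vapply(smp$sessions, function(s)
    unlist(fit_subject_map(s, flat)[c("a_rew_z", "a_pun_z", "beta_f", "beta_b")]),
    numeric(4)))
  hier <- as.matrix(est[match(smp$truth$subject_id, est$subject_id),
                        c("a_rew_z", "a_pun_z", "beta_f", "beta_b")])
  expect_true(all(apply(hier, 2, var) <= apply(mle, 2, var)))
  expect_error(fit_wave(smp$sessions[1], quick_fit()), ">= 2 subjects")
})

test_that("group moments track the simulated sample at study scale", {
  smp <- simulate_sample(80, seed = 31)
  fit <- fit_wave(smp$sessions)
  gm <- fit$group_posterior$mean
  sample_mean <- colMeans(smp$truth[, c("a_rew_z", "a_pun_z", "beta_f", "beta_b")])
  # MAP-EB group means carry a known small mode-vs-mean attenuation toward
  # zero; require agreement within 0.45 generating-SD units
  dist <- recovery_distributions()
  dev <- abs(gm - sample_mean) / dist$sd
  expect_true(all(dev[c("a_pun_z", "beta_f", "beta_b")] < 0.45))
  expect_true(all(fit$group_posterior$sd > 0))
})

test_that("parameter recovery refuses degenerate generators and reports scatter data", {
  bad <- recovery_distributions()
  bad$sd[2] <- 0
  expect_error(parameter_recovery(30, bad), "degenerate")
  expect_error(parameter_recovery(10), ">= 20")
  rec <- parameter_recovery(24, task = quick_task(), config = quick_fit(),
                            seed = 2)
  expect_named(rec$r, c("a_rew", "a_pun", "beta_f", "beta_b"))
  expect_equal(nrow(rec$truth), 24)
  expect_true(all(is.finite(rec$r)))
})

test_that("independently generated reward parameters stay weakly correlated after recovery", {
  rec <- parameter_recovery(100, seed = 1)
  # truth is independent by construction; estimation cross-talk introduces a
  # mild positive coupling, which must stay in the weak range
  expect_lte(abs(cor(rec$recovered$a_rew_z, rec$recovered$beta_f)), 0.4)
  expect_lt(abs(cor(rec$truth$a_rew_z, rec$truth$beta_f)), 0.2)
})

test_that("posterior predictive checks cover self-simulated data", {
  smp <- simulate_sample(15, task = quick_task(), seed = 41)
  sessions <- do.call(rbind, smp$sessions)
  est <- data.frame(subject_id = smp$truth$subject_id,
                    a_rew = pnorm(smp$truth$a_rew_z),
                    a_pun = pnorm(smp$truth$a_pun_z),
                    beta_f = smp$truth$beta_f, beta_b = smp$truth$beta_b,
                    stringsAsFactors = FALSE)
  ppc <- posterior_predictive_check(est, sessions, quick_task(), n_reps = 40,
                                    seed = 2, block_size = 10)
  ok <- ppc$observed >= ppc$lower & ppc$observed <= ppc$upper
  expect_gte(mean(ok), 0.9)
  # deterministic given the seed
  ppc2 <- posterior_predictive_check(est, sessions, quick_task(), n_reps = 1,
                                     seed = 2, block_size = 10)
  ppc3 <- posterior_predictive_check(est, sessions, quick_task(), n_reps = 1,
                                     seed = 2, block_size = 10)
  expect_identical(ppc2, ppc3)
  # all-pass observed sessions give zero observed proportions
  allpass <- manual_session(rep(c("A", "B", "C", "D"), 10), rep("pass", 40))
  allpass$subject_id <- est$subject_id[1]
  p1 <- posterior_predictive_check(est[1, ], allpass, quick_task(),
                                   n_reps = 3, seed = 1, block_size = 10)
  expect_true(all(p1$observed == 0))
  expect_error(posterior_predictive_check(est[2, ], allpass, quick_task()),
               "aligned")
})

test_that("the mcmc backend is refused explicitly", {
  expect_error(fit_config(backend = "mcmc"), "not available")
})
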