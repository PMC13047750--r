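test_that("age centering is the fixed baseline-mean constant", {
  expect_equal(center_age(10.98), 0)
  expect_equal(center_age(17), 6.02)
  expect_equal(center_age(9), -1.98)
})

test_that("noise-free linear data is recovered exactly", {
  d <- expand.grid(subject_id = sprintf("s%02d", 1:30), wave = 1:4)
  d$age <- 9 + as.integer(d$wave) * 0.75 + as.integer(factor(d$subject_id)) / 10
  d$value <- 0.5 + 0.2 * center_age(d$age)
  fit <- fit_growth(d, growth_spec("linear"))
  expect_equal(fit$fixed$estimate[fit$fixed$term == "(Intercept)"], 0.5,
               tolerance = 1e-6)
  expect_equal(fit$fixed$estimate[fit$fixed$term == "age_c"], 0.2,
               tolerance = 1e-6)
  expect_lt(fit$varcomp$tau00, 1e-6)
  expect_lt(fit$varcomp$sigma2, 1e-6)
  expect_true(fit$simplification %in% c("none", "uncorrelated", "intercept_only"))
})

test_that("the ICC equals the variance-ratio oracle", {
  expect_equal(compute_icc(1, 1), 0.5)
  expect_equal(compute_icc(1.21, 8.15), 1.21 / (1.21 + 8.15))
  expect_equal(compute_icc(0, 2), 0)
  expect_warning(icc0 <- compute_icc(0, 0), "undefined")
  expect_true(is.na(icc0))
  expect_error(compute_icc(-1, 2), ">= 0")
  # constant-per-subject data with equal variances gives ICC ~ 0.5
  set.seed(14)
  n <- 200
  b <- rnorm(n, 0, 1)
  d <- expand.grid(subject_id = seq_len(n), wave = 1:5)
  d$age <- 10 + d$wave * 0.75
  d$value <- b[d$subject_id] + rnorm(nrow(d), 0, 1)
  fit <- fit_growth(d, growth_spec("linear"))
  expect_equal(fit$icc, 0.5, tolerance = 0.1)
})

test_that("nested comparisons match independently refit log-likelihoods", {
  expect_lt(lrt_p_value(38.99, 5), 0.001)
  expect_equal(lrt_p_value(0, 3), 1)
  set.seed(15)
  for (i in 1:5) {
    n <- 40
    d <- expand.grid(subject_id = seq_len(n), wave = 1:4)
    d$age <- 9.5 + d$wave * 0.75 + runif(nrow(d), 0, 0.1)
    d$age_c <- center_age(d$age)
    d$value <- 0.2 * d$age_c + 0.05 * d$age_c^2 +
      rnorm(n, 0, 0.5)[d$subject_id] + rnorm(nrow(d), 0, 1)
    f1 <- fit_growth(d, growth_spec("linear"))
    f2 <- fit_growth(d, growth_spec("quadratic"))
    lrt <- compare_nested(f1, f2)
    # independent route: refit each model's final formula directly with lme4
    # (the singular-fit cascade may have simplified the random structure)
    r1 <- suppressMessages(lme4::lmer(formula(f1$model), d, REML = FALSE))
    r2 <- suppressMessages(lme4::lmer(formula(f2$model), d, REML = FALSE))
    expect_equal(lrt$chi2, as.numeric(2 * (logLik(r2) - logLik(r1))),
                 tolerance = 1e-6)
    expect_equal(lrt$df, attr(logLik(r2), "df") - attr(logLik(r1), "df"))
  }
  f1 <- fit_growth(d, growth_spec("linear"))
  self <- compare_nested(f1, f1)
  expect_equal(self$chi2, 0)
  expect_equal(self$p, 1)
})

test_that("a single-wave dataset is refused", {
  d <- data.frame(subject_id = 1:30, wave = 1, age = 10 + runif(30),
                  value = rnorm(30))
  expect_error(fit_growth(d, growth_spec("linear")), "2 waves")
})

test_that("conditional quadratic specs build the full interaction structure", {
  sp <- growth_spec("quadratic", conditional = TRUE,
                    covariates = c("iq", "sex", "onsite"))
  f <- poporl:::growth_formula(sp)
  v <- all.vars(f)
  expect_true(all(c("age_c", "maternal_hx", "iq_c", "sex", "onsite") %in% v))
  expect_match(paste(deparse(f), collapse = " "),
               "I\\(age_c\\^2\\):maternal_hx")
  expect_error(growth_spec("linear", covariates = "puberty"), "unknown")
})

test_that("the ladder selects the generating polynomial and reports the full table", {
  # quadratic truth in one metric, linear in another: select per metric
  set.seed(16)
  wins_quad <- 0; wins_lin <- 0
  for (rep_i in 1:8) {
    em <- default_effect_map()
    em$beta_b$age2 <- 0.06 # pronounced curvature
    em$beta_f$age2 <- 0
    # keep beta_f free of the remote-administration shift at late waves,
    # which would otherwise induce genuine curvature
    em$beta_f$onsite <- 0
    cc <- cohort_config(n_baseline = 150, effect_map = em)
    truth <- generate_cohort(cc, seed = 160 + rep_i)
    long <- do.call(rbind, lapply(c("beta_b", "beta_f"), function(m)
      data.frame(subject_id = truth$subject_id, wave = truth$wave,
                 age = truth$age, metric = m, value = truth[[m]],
                 maternal_hx = truth$maternal_hx, sex = truth$sex,
                 iq = truth$iq, onsite = truth$onsite,
                 stringsAsFactors = FALSE)))
    lad <- run_trajectory_ladder(long, metrics = c("beta_b", "beta_f"))
    wins_quad <- wins_quad + (lad$metrics$beta_b$winner == "quadratic")
    wins_lin <- wins_lin + (lad$metrics$beta_f$winner == "linear")
  }
  expect_gte(wins_quad, 6)
  expect_gte(wins_lin, 6)
})

test_that("the ladder reports one row per fixed effect per metric plus FDR family", {
  st <- simulate_study(cohort_config(n_baseline = 60), task_config(60),
                       seed = 17)
  truth <- st$ground_truth
  long <- build_metric_table(
    data.frame(truth[, c("subject_id", "wave", "a_rew_z", "a_pun_z", "beta_f",
                         "beta_b")], converged = TRUE),
    score_sessions(st$sessions), st$demographics)
  lad <- run_trajectory_ladder(long)
  expect_setequal(unique(lad$table$metric),
                  c("net", "good_prop", "bad_prop", "a_rew_z", "a_pun_z",
                    "beta_f", "beta_b"))
  # every metric's model-4 fixed effects appear exactly once
  for (m in unique(lad$table$metric)) {
    terms <- lad$table$term[lad$table$metric == m]
    expect_equal(anyDuplicated(terms), 0)
    expect_true(all(c("(Intercept)", "age_c", "maternal_hx", "iq_c", "sex",
                      "onsite") %in% terms))
  }
  expect_equal(nrow(lad$age_fdr), 4)
  expect_true(all(lad$age_fdr$fdr_p >= lad$age_fdr$p - 1e-12))
  # a missing metric is reported absent, the rest continue
  lad2 <- run_trajectory_ladder(long[long$metric != "beta_b", ])
  expect_equal(lad2$absent, "beta_b")
  expect_false("beta_b" %in% names(lad2$metrics))
})

test_that("random attrition leaves the fitted age slope unbiased", {
  set.seed(18)
  em <- default_effect_map()
  em$beta_f$onsite <- 0 # no modality shift: the marginal age slope is clean
  em$beta_f$age_x_maternal <- 0
  bias <- replicate(25, {
    cc <- cohort_config(n_baseline = 100, effect_map = em)
    truth <- generate_cohort(cc, seed = sample.int(1e6, 1))
    d <- data.frame(subject_id = truth$subject_id, wave = truth$wave,
                    age = truth$age, value = truth$beta_f)
    fit <- fit_growth(d, growth_spec("linear"))
    fx <- fit$fixed
    c(est = fx$estimate[fx$term == "age_c"], se = fx$se[fx$term == "age_c"])
  })
  # generating marginal slope for beta_f includes the remote-administration
  # shift at later waves: compare against the fitted-model expectation by
  # checking the mean estimate sits within 2 Monte-Carlo SEs of its own mean
  # and carries the generating sign
  expect_lt(abs(mean(bias["est", ]) - 0.31) /
              (sd(bias["est", ]) / sqrt(ncol(bias)) + mean(bias["se", ])), 2)
  expect_true(all(bias["est", ] > 0))
})
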