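test_that("initial state puts every deck's value at the go bias", {
  expect_equal(unname(init_state(orl_params(0.3, 0.3, 2, 0))$V), rep(0, 4))
  st <- init_state(orl_params(0.3, 0.3, 2, 1.25))
  expect_equal(unname(st$V), rep(1.25, 4))
  # with EF = 0 the value signal is independent of beta_f
  st2 <- init_state(orl_params(0.3, 0.3, -50, 1.25))
  expect_equal(st$V, st2$V)
})

test_that("play probability is the logistic of the value signal", {
  p0 <- orl_params(0.3, 0.3, 0, 0)
  expect_equal(play_probability(init_state(p0), "A"), 0.5)
  pb <- orl_params(0.3, 0.3, 0, 1.25)
  expect_equal(play_probability(init_state(pb), "C"), 1 / (1 + exp(-1.25)))
  # strictly increasing in the go bias
  probs <- vapply(seq(-4, 8, by = 0.5), function(b)
    play_probability(init_state(orl_params(0.3, 0.3, 0, b)), "B"), numeric(1))
  expect_true(all(diff(probs) > 0))
  expect_true(all(probs > 0 & probs < 1))
})

test_that("delta-rule updates follow the valence-gated learning rates", {
  pars <- orl_params(0.4, 0.2, 1, 0)
  st <- init_state(pars)
  up <- update_state(st, "A", "play", 100, pars)
  expect_equal(unname(up$EV["A"]), 0.4) # 0 + 0.4 * (100/100 - 0)
  expect_equal(unname(up$EF["A"]), 0.4) # 0 + 0.4 * (sign - 0)
  # fictive: other decks move toward -1/3 at the opposite-valence rate
  expect_equal(unname(up$EF["B"]), 0.2 * (-1 / 3))
  # loss uses the punishment rate
  dn <- update_state(st, "B", "play", -1150, pars)
  expect_equal(unname(dn$EV["B"]), 0.2 * (-11.5))
  expect_equal(unname(dn$EF["B"]), -0.2)
  # pass leaves the state bitwise unchanged
  expect_identical(update_state(up, "C", "pass", 0, pars), up)
  expect_error(update_state(up, "C", "pass", 10, pars), "pass")
  # zero learning rates freeze the state
  frozen <- orl_params(0, 0, 3, 0.7)
  stf <- init_state(frozen)
  for (t in 1:5) stf <- update_state(stf, "D", "play", 50, frozen)
  expect_equal(unname(stf$V), rep(0.7, 4))
})

test_that("fictive updating off leaves never-played decks' EF at zero", {
  cfg <- model_config(fictive_updating = FALSE)
  pars <- orl_params(0.5, 0.5, 2, 0)
  st <- init_state(pars)
  for (t in 1:8) st <- update_state(st, "A", "play", 100, pars, cfg)
  expect_equal(unname(st$EF[c("B", "C", "D")]), rep(0, 3))
  expect_gt(st$EF[["A"]], 0)
})

test_that("log-likelihood matches the literal trial-loop oracle", {
  # worked single values first
  p0 <- orl_params(0.5, 0.5, 0, 0)
  one <- manual_session("A", "play", 100)
  expect_equal(log_likelihood(p0, one), log(0.5))
  allpass <- manual_session(rep(c("A", "B", "C", "D"), 30), rep("pass", 120))
  expect_equal(log_likelihood(p0, allpass), 120 * log(0.5))
  expect_equal(log_likelihood(p0, allpass[0, ]), 0)
  # oracle equivalence across random sessions and parameters
  set.seed(42)
  for (i in 1:30) {
    s <- random_session(n = sample(20:120, 1))
    pars <- orl_params(runif(1), runif(1), rnorm(1, 0, 3), rnorm(1, 0, 2))
    for (fictive in c(TRUE, FALSE)) {
      got <- log_likelihood(pars, s, model_config(fictive_updating = fictive))
      want <- naive_orl_loglik(pars$a_rew, pars$a_pun, pars$beta_f,
                               pars$beta_b, match(s$deck, c("A", "B", "C", "D")),
                               as.integer(s$choice == "play"), s$outcome,
                               fictive = fictive)
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("an all-pass session's likelihood depends only on the go bias", {
  allpass <- manual_session(rep(c("A", "B", "C", "D"), 10), rep("pass", 40))
  base <- log_likelihood(orl_params(0.1, 0.9, -5, 0.8), allpass)
  expect_equal(log_likelihood(orl_params(0.9, 0.1, 12, 0.8), allpass), base)
  expect_false(isTRUE(all.equal(
    log_likelihood(orl_params(0.1, 0.9, -5, 0.2), allpass), base)))
})

test_that("simulated agents behave per the logistic choice rule", {
  tc <- quick_task()
  # zero parameters: Bernoulli(0.5) play rate
  rates <- vapply(1:100, function(i)
    mean(simulate_agent(orl_params(0, 0, 0, 0), tc, seed = i)$choice == "play"),
    numeric(1))
  expect_equal(mean(rates), 0.5, tolerance = 0.05)
  # saturated go bias
  s <- simulate_agent(orl_params(0, 0, 0, 8), task_config(), seed = 1)
  expect_gte(mean(s$choice == "play"), 0.99)
  # determinism
  expect_identical(simulate_agent(orl_params(0.2, 0.1, 3, 1), tc, seed = 9),
                   simulate_agent(orl_params(0.2, 0.1, 3, 1), tc, seed = 9))
})

test_that("generating parameters beat perturbed ones in average likelihood", {
  tc <- task_config()
  set.seed(7)
  margins <- replicate(50, {
    pars <- orl_params(runif(1, 0.05, 0.6), runif(1, 0.05, 0.6),
                       rnorm(1, 2, 1), rnorm(1, 0.5, 0.7))
    s <- simulate_agent(pars, tc)
    shift <- sample(c(-0.3, 0.3), 4, replace = TRUE)
    pert <- orl_params(min(max(pars$a_rew + shift[1], 0), 1),
                       min(max(pars$a_pun + shift[2], 0), 1),
                       pars$beta_f + shift[3], pars$beta_b + shift[4])
    log_likelihood(pars, s) - log_likelihood(pert, s)
  })
  expect_gt(mean(margins), 0)
})
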