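# Independent reference implementations used as oracles. These deliberately
# re-derive everything from first principles (literal loops, textbook sum
# formulas) and never call the code paths they check.

# literal trial-by-trial PoP-ORL log-likelihood: delta rules written out
# inline, probabilities through the plain logistic
naive_orl_loglik <- function(a_rew, a_pun, beta_f, beta_b, deck, choice,
                             outcome, outcome_scale = 100, fictive = TRUE,
                             fictive_att = 3) {
  EV <- EF <- rep(0, 4)
  ll <- 0
  for (t in seq_along(deck)) {
    j <- deck[t]
    V <- EV[j] + EF[j] * beta_f + beta_b
    p <- 1 / (1 + exp(-V))
    ll <- ll + if (choice[t] == 1) log(p) else log(1 - p)
    if (choice[t] == 1) {
      x <- outcome[t]
      lr <- if (x >= 0) a_rew else a_pun
      EV[j] <- EV[j] + lr * (x / outcome_scale - EV[j])
      EF[j] <- EF[j] + lr * (sign(x) - EF[j])
      if (fictive) {
        lrf <- if (x >= 0) a_pun else a_rew
        for (k in setdiff(1:4, j))
          EF[k] <- EF[k] + lrf * (-sign(x) / fictive_att - EF[k])
      }
    }
  }
  ll
}

# brute-force Benjamini-Hochberg step-up: for each p_i take the minimum of
# m * p_j / rank_j over all p_j >= p_i, straight from the definition
brute_bh <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(m), function(i) {
    cand <- which(p >= p[i] | seq_len(m) == i)
    min(1, min(m * p[cand] / r[cand]))
  }, numeric(1))
}

# textbook sum-formula Pearson correlation
pearson_sums <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

# random session log on random decks (not the fixed schedule) for likelihood
# equivalence checks
random_session <- function(n = 60, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  deck <- sample(c("A", "B", "C", "D"), n, replace = TRUE)
  choice <- sample(c("play", "pass"), n, replace = TRUE)
  outcome <- ifelse(choice == "play",
                    sample(c(-1250, -350, -150, -50, 0, 50, 100), n,
                           replace = TRUE), 0)
  data.frame(subject_id = "o1", wave = 1L, trial = seq_len(n), deck = deck,
             choice = choice, timeout = 0L, outcome = outcome,
             bank_after = 2000 + cumsum(outcome), version = 1L,
             modality = "onsite", stringsAsFactors = FALSE)
}
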