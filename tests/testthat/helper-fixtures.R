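# shared small fixtures: a short task and a quick fit configuration keep the
# unit tests fast; study-scale settings live only in the acceptance suite

quick_task <- function(n_trials = 40) task_config(n_trials = n_trials)

quick_fit <- function() fit_config(max_iterations = 6, tolerance = 0.01)

# a deterministic hand-built session: explicit decks/choices for scoring tests
manual_session <- function(deck, choice, outcome = NULL) {
  n <- length(deck)
  if (is.null(outcome)) outcome <- ifelse(choice == "play", 50, 0)
  outcome[choice == "pass"] <- 0
  data.frame(subject_id = "m1", wave = 1L, trial = seq_len(n), deck = deck,
             choice = choice, timeout = 0L, outcome = outcome,
             bank_after = 2000 + cumsum(outcome), version = 1L,
             modality = "onsite", stringsAsFactors = FALSE)
}

# simulate a small cross-sectional sample from given generator distributions
simulate_sample <- function(n, dist = recovery_distributions(),
                            task = task_config(), seed = 1) {
  set.seed(seed)
  truth <- sapply(1:4, function(i) rnorm(n, dist$mean[i], dist$sd[i]))
  colnames(truth) <- c("a_rew_z", "a_pun_z", "beta_f", "beta_b")
  ids <- sprintf("h%03d", seq_len(n))
  sessions <- lapply(seq_len(n), function(i)
    simulate_agent(orl_params(pnorm(truth[i, 1]), pnorm(truth[i, 2]),
                              truth[i, 3], truth[i, 4]),
                   task, subject_id = ids[i]))
  list(truth = data.frame(subject_id = ids, truth, stringsAsFactors = FALSE),
       sessions = sessions)
}
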