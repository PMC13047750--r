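#' PoP-ORL parameters
#'
#' The four free parameters of the play-or-pass outcome-representation
#' learning model: a reward learning rate `a_rew` and a punishment learning
#' rate `a_pun` (both in \[0,1\], the delta-rule step sizes applied to
#' non-negative vs negative outcomes), a win/loss frequency sensitivity
#' `beta_f` (weight on the expected-frequency signal, magnitude-blind), and a
#' go bias `beta_b` (constant added to the value of playing every deck).
#'
#' @param a_rew,a_pun learning rates in \[0,1\].
#' @param beta_f,beta_b real-valued sensitivities.
#' @return an `orl_params` list.
#' @export
orl_params <- function(a_rew, a_pun, beta_f, beta_b) {
  stopifnot(is.finite(a_rew), is.finite(a_pun), is.finite(beta_f), is.finite(beta_b))
  if (a_rew < 0 || a_rew > 1 || a_pun < 0 || a_pun > 1)
    stop("learning rates must lie in [0, 1]")
  structure(list(a_rew = a_rew, a_pun = a_pun, beta_f = beta_f,
                 beta_b = beta_b), class = "orl_params")
}

#' @export
print.orl_params <- function(x, ...) {
  cat(sprintf("PoP-ORL parameters: A_rew = %.3f, A_pun = %.3f, beta_f = %.3f, beta_b = %.3f\n",
              x$a_rew, x$a_pun, x$beta_f, x$beta_b))
  invisible(x)
}

#' Model configuration for under-specified update details
#'
#' Houses the update-rule conventions: the divisor applied to raw currency
#' before expected-value updates (`outcome_scale`), whether unpresented decks
#' receive fictive frequency updates, and the attenuation divisor for those
#' fictive pseudo-outcomes. Defaults: outcomes scaled by 100, fictive
#' updating on with attenuation 3 (the parent ORL model's frequency
#' mechanism).
#'
#' @param outcome_scale positive divisor for EV update targets.
#' @param fictive_updating logical; update unpresented decks' expected
#'   frequency toward `-sign(outcome) / fictive_attenuation` at the
#'   opposite-valence learning rate.
#' @param fictive_attenuation positive divisor for fictive targets.
#' @return a `model_config` list.
#' @export
model_config <- function(outcome_scale = 100, fictive_updating = TRUE,
                         fictive_attenuation = 3) {
  if (outcome_scale <= 0) stop("outcome_scale must be > 0")
  if (fictive_attenuation <= 0) stop("fictive_attenuation must be > 0")
  structure(list(outcome_scale = outcome_scale,
                 fictive_updating = fictive_updating,
                 fictive_attenuation = fictive_attenuation),
            class = "model_config")
}

#' Initial latent state
#'
#' Expected value (EV) and expected win/loss frequency (EF) start at zero for
#' every deck, so the initial value of playing any deck is the go bias
#' `beta_b` (the value of passing is held constant at 0 throughout).
#'
#' @param params an [orl_params()].
#' @return a `latent_state` list with 4-vectors `EV`, `EF`, `V`.
#' @export
init_state <- function(params) {
  z <- setNames(numeric(4), DECKS)
  structure(list(EV = z, EF = z, V = z + params$beta_b), class = "latent_state")
}

#' Probability of playing a deck
#'
#' The Bernoulli-logistic choice rule: `p = 1 / (1 + exp(-V_deck))`, where
#' `V_deck = EV + EF * beta_f + beta_b` is the deck's current value signal.
#'
#' @param state a `latent_state`.
#' @param deck deck label (A-D) or index (1-4).
#' @return play probability in (0, 1).
#' @export
play_probability <- function(state, deck) {
  j <- if (is.numeric(deck)) deck else deck_index(deck)
  plogis(unname(state$V[j]))
}

#' Delta-rule state update after one trial
#'
#' A pass leaves the state untouched. A play updates the presented deck's EV
#' toward `outcome / outcome_scale` and its EF toward `sign(outcome)`, both
#' at the reward learning rate when the outcome is non-negative and the
#' punishment learning rate otherwise. With fictive updating on, the three
#' unpresented decks' EF move toward `-sign(outcome) / fictive_attenuation`
#' at the opposite-valence learning rate. The value signal `V` is recomputed
#' for all decks.
#'
#' @param state a `latent_state`.
#' @param deck presented deck (label or index).
#' @param choice `"play"` or `"pass"`.
#' @param outcome raw currency outcome; must be 0 on a pass.
#' @param params an [orl_params()].
#' @param config a [model_config()].
#' @return the updated `latent_state`.
#' @export
update_state <- function(state, deck, choice, outcome, params,
                         config = model_config()) {
  if (!choice %in% c("play", "pass")) stop("choice must be \"play\" or \"pass\"")
  if (choice == "pass") {
    if (outcome != 0) stop("a pass trial must have outcome 0")
    return(state)
  }
  j <- if (is.numeric(deck)) deck else deck_index(deck)
  lr <- if (outcome >= 0) params$a_rew else params$a_pun
  s <- sign(outcome)
  state$EV[j] <- state$EV[j] + lr * (outcome / config$outcome_scale - state$EV[j])
  state$EF[j] <- state$EF[j] + lr * (s - state$EF[j])
  if (config$fictive_updating) {
    lrf <- if (outcome >= 0) params$a_pun else params$a_rew
    target <- -s / config$fictive_attenuation
    k <- setdiff(1:4, j)
    state$EF[k] <- state$EF[k] + lrf * (target - state$EF[k])
  }
  state$V <- state$EV + state$EF * params$beta_f + params$beta_b
  state
}

# shared column extraction / validation for likelihood and scoring
session_arrays <- function(session) {
  need <- c("deck", "choice", "outcome")
  miss <- setdiff(need, names(session))
  if (length(miss)) stop("session missing column(s): ", paste(miss, collapse = ", "))
  if (!all(session$deck %in% DECKS))
    stop("session decks must be canonical labels A-D; see recode_to_canonical()")
  list(deck = deck_index(session$deck),
       choice = as.integer(session$choice == "play"),
       outcome = as.numeric(session$outcome))
}

#' Session log-likelihood under the PoP-ORL model
#'
#' Sum over trials of the Bernoulli log-probability of the observed play/pass
#' choice, with the play probability computed from the latent state *before*
#' that trial's update (prediction precedes outcome). Timeouts enter as
#' passes. Evaluated by a compiled trial loop using a numerically stable
#' log-logistic form; an empty session has log-likelihood 0.
#'
#' @param params an [orl_params()].
#' @param session a canonical, trial-ordered session log.
#' @param config a [model_config()].
#' @return the log-likelihood (finite for finite parameters).
#' @export
log_likelihood <- function(params, session, config = model_config()) {
  if (nrow(session) == 0) return(0)
  a <- session_arrays(session)
  orl_loglik_cpp(a$deck, a$choice, a$outcome, params$a_rew, params$a_pun,
                 params$beta_f, params$beta_b, config$outcome_scale,
                 config$fictive_updating, config$fictive_attenuation)
}

#' Simulate a PoP-ORL agent on the task
#'
#' Draws play/pass choices trial-by-trial from the Bernoulli-logistic rule,
#' updating the latent state after each play, on the fixed presentation and
#' outcome schedules of `config`. Reproducible given `seed`.
#'
#' @param params an [orl_params()].
#' @param config a [task_config()].
#' @param model a [model_config()].
#' @param seed RNG seed.
#' @param subject_id,wave,modality session metadata.
#' @return a session log `data.frame` (see [run_session()]).
#' @export
simulate_agent <- function(params, config = task_config(),
                           model = model_config(), seed = NULL,
                           subject_id = "s1", wave = 1L, modality = "onsite") {
  if (config$n_trials == 0)
    return(empty_session(subject_id, wave, config$version, modality))
  if (!is.null(seed)) set.seed(seed)
  deck <- deck_index(config$presentation_order)
  sim <- orl_simulate_cpp(deck, config$outcome_schedule, params$a_rew,
                          params$a_pun, params$beta_f, params$beta_b,
                          model$outcome_scale, model$fictive_updating,
                          model$fictive_attenuation, config$timeout_prob)
  data.frame(subject_id = subject_id, wave = as.integer(wave),
             trial = seq_len(config$n_trials),
             deck = config$presentation_order,
             choice = ifelse(sim$choice == 1, "play", "pass"),
             timeout = sim$timeout, outcome = sim$outcome,
             bank_after = config$starting_bank + cumsum(sim$outcome),
             version = config$version, modality = modality,
             stringsAsFactors = FALSE)
}
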