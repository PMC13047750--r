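#' Default generating effect map for the synthetic cohort
#'
#' Per-parameter generating model on the unconstrained scale (probit for the
#' learning rates): intercept at the centering age (10.98 years), linear and
#' quadratic age slopes, maternal-history offset and age interaction,
#' covariate effects (IQ per point above 100, sex with female = 1, and
#' administration modality applied as `coef * (onsite - 1)` so fully on-site
#' sessions sit at the intercept), plus random-effect and residual SDs.
#' Fixed-effect values mirror the full conditional growth-model coefficients
#' this task typically yields in adolescence (age-related decline in reward
#' learning rate, rise in frequency sensitivity, reward-learning deficit with
#' maternal depression history). The random-effect and residual SDs are
#' true-score calibration choices set so that fitted parameter estimates show
#' poor-to-fair nine-month test-retest reliability; see the methods vignette.
#'
#' @return named list of per-parameter effect lists.
#' @export
default_effect_map <- function() {
  eff <- function(intercept, age, maternal, age_x_maternal, iq, sex, onsite,
                  re_int_sd, re_slope_sd, resid_sd, age2 = 0,
                  age2_x_maternal = 0)
    list(intercept = intercept, age = age, age2 = age2, maternal = maternal,
         age_x_maternal = age_x_maternal, age2_x_maternal = age2_x_maternal,
         iq = iq, sex = sex, onsite = onsite, re_int_sd = re_int_sd,
         re_slope_sd = re_slope_sd, resid_sd = resid_sd)
  list(
    a_rew_z = eff(-1.67, -0.04, -0.06, 0.02, 0.00, 0.00, 0.12,
                  re_int_sd = 0.25, re_slope_sd = 0.02, resid_sd = 0.16),
    a_pun_z = eff(-1.81, 0.01, -0.02, 0.02, 0.01, 0.01, 0.01,
                  re_int_sd = 0.25, re_slope_sd = 0.02, resid_sd = 0.16),
    beta_f = eff(4.42, 0.31, -0.52, 0.04, 0.05, -0.10, -2.50,
                 re_int_sd = 1.3, re_slope_sd = 0.40, resid_sd = 1.6),
    beta_b = eff(1.25, 0.03, -0.08, -0.01, 0.00, -0.06, -0.33,
                 re_int_sd = 0.30, re_slope_sd = 0.05, resid_sd = 0.25,
                 age2 = 0.01, age2_x_maternal = 0.00)
  )
}

#' Synthetic accelerated-longitudinal cohort configuration
#'
#' Study-shaped defaults: 208 youth at baseline recruited in two overlapping
#' age cohorts (9-10 and 12-13 years old), five waves spaced 0.75 years,
#' attrition to wave counts 208/157/135/98/73, 36% maternal-history
#' prevalence, 59% female, IQ ~ N(101.8, 15), task administration fully
#' on-site through wave 3 then 89% and 41% on-site at waves 4 and 5. When
#' `n_baseline` differs from 208 the retention counts scale proportionally.
#'
#' @param n_baseline subjects at wave 1.
#' @param cohort_split fraction recruited in the younger (9-10) cohort.
#' @param waves number of assessment waves.
#' @param wave_spacing years between waves.
#' @param retention per-wave retained counts (non-increasing, `waves` long).
#' @param maternal_hx_prev maternal depression-history prevalence.
#' @param female_prob,iq_mean,iq_sd covariate distributions.
#' @param onsite_prob per-wave probability of on-site administration.
#' @param effect_map generating effects, see [default_effect_map()].
#' @param dropout `"mar"` (missing at random, default) or `"covariate"`
#'   (dropout odds increase for lower-IQ subjects, for robustness studies).
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_baseline = 208, cohort_split = 0.5, waves = 5,
                          wave_spacing = 0.75, retention = NULL,
                          maternal_hx_prev = 0.36, female_prob = 0.59,
                          iq_mean = 101.8, iq_sd = 15,
                          onsite_prob = c(1, 1, 1, 0.89, 0.41),
                          effect_map = default_effect_map(),
                          dropout = c("mar", "covariate")) {
  dropout <- match.arg(dropout)
  if (is.null(retention)) {
    base <- c(208, 157, 135, 98, 73)[seq_len(waves)]
    retention <- round(base * n_baseline / 208)
    retention[1] <- n_baseline
    retention <- cummin(retention)
  }
  if (length(retention) != waves) stop("retention must have one count per wave")
  if (any(diff(retention) > 0)) stop("retention must be non-increasing")
  if (retention[1] > n_baseline) stop("retention cannot exceed n_baseline")
  if (wave_spacing <= 0) stop("wave_spacing must be > 0")
  stopifnot(maternal_hx_prev >= 0, maternal_hx_prev <= 1,
            length(onsite_prob) >= waves)
  structure(list(n_baseline = n_baseline, cohort_split = cohort_split,
                 waves = waves, wave_spacing = wave_spacing,
                 retention = retention, maternal_hx_prev = maternal_hx_prev,
                 female_prob = female_prob, iq_mean = iq_mean, iq_sd = iq_sd,
                 onsite_prob = onsite_prob[seq_len(waves)],
                 effect_map = effect_map, dropout = dropout),
            class = "cohort_config")
}

#' Generate a synthetic cohort ground-truth table
#'
#' Samples subjects (cohort band, baseline age, maternal history, sex, IQ),
#' advances ages by the wave spacing, applies attrition to match the
#' configured retention exactly (monotone dropout, missing at random by
#' default), draws subject random intercepts/slopes and wave-level noise, and
#' computes each retained subject-wave's true PoP-ORL parameters from the
#' effect map (learning rates mapped through the standard-normal CDF).
#'
#' @param config a [cohort_config()].
#' @param seed RNG seed.
#' @return ground-truth data.frame: one row per retained subject-wave with
#'   `subject_id, wave, age, age_c, cohort, maternal_hx, sex, iq, onsite,
#'   internalizing`, true `a_rew, a_pun, beta_f, beta_b` and their
#'   unconstrained-scale versions `a_rew_z, a_pun_z`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1) {
  set.seed(seed)
  n <- config$n_baseline
  ids <- sprintf("s%04d", seq_len(n))
  young <- runif(n) < config$cohort_split
  age0 <- ifelse(young, runif(n, 9, 10), runif(n, 12, 13))
  maternal <- rbinom(n, 1, config$maternal_hx_prev)
  sex <- rbinom(n, 1, config$female_prob)
  iq <- rnorm(n, config$iq_mean, config$iq_sd)
  internalizing <- 50 + 5 * maternal + rnorm(n, 0, 9)
  # monotone dropout: assign each subject a last observed wave so wave counts
  # match retention exactly
  drops <- -diff(c(config$retention, 0)) # subjects whose last wave is w
  lastv <- rep(seq_len(config$waves), times = drops)
  ord <- if (config$dropout == "mar") sample.int(n) else
    order(iq + rnorm(n, 0, config$iq_sd)) # lower-IQ families drop earlier
  last <- integer(n)
  last[ord] <- lastv
  em <- config$effect_map
  re <- lapply(em, function(e)
    cbind(int = rnorm(n, 0, e$re_int_sd), slope = rnorm(n, 0, e$re_slope_sd)))
  rows <- list()
  for (w in seq_len(config$waves)) {
    keep <- which(last >= w)
    age <- age0[keep] + (w - 1) * config$wave_spacing
    age_c <- center_age(age)
    onsite <- rbinom(length(keep), 1, config$onsite_prob[w])
    lp <- function(pname) {
      e <- em[[pname]]
      e$intercept + e$age * age_c + e$age2 * age_c^2 +
        (e$maternal + e$age_x_maternal * age_c +
           e$age2_x_maternal * age_c^2) * maternal[keep] +
        e$iq * (iq[keep] - 100) + e$sex * sex[keep] +
        e$onsite * (onsite - 1) +
        re[[pname]][keep, "int"] + re[[pname]][keep, "slope"] * age_c +
        rnorm(length(keep), 0, e$resid_sd)
    }
    a_rew_z <- lp("a_rew_z"); a_pun_z <- lp("a_pun_z")
    rows[[w]] <- data.frame(
      subject_id = ids[keep], wave = w, age = age, age_c = age_c,
      cohort = ifelse(young[keep], "younger", "older"),
      maternal_hx = maternal[keep], sex = sex[keep], iq = iq[keep],
      onsite = onsite, internalizing = internalizing[keep],
      a_rew = pnorm(a_rew_z), a_pun = pnorm(a_pun_z),
      beta_f = lp("beta_f"), beta_b = lp("beta_b"),
      a_rew_z = a_rew_z, a_pun_z = a_pun_z, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a full synthetic study
#'
#' Couples [generate_cohort()] with the PoP-ORL generative agent: one
#' simulated task session per retained subject-wave at that row's true
#' parameters, alternating task versions across administrations. Fully
#' reproducible given `seed`.
#'
#' @param config a [cohort_config()].
#' @param task a [task_config()].
#' @param model a [model_config()].
#' @param seed RNG seed.
#' @return list with `sessions` (long session log), `demographics`
#'   (one row per subject-wave) and `ground_truth` (the [generate_cohort()]
#'   table).
#' @export
simulate_study <- function(config = cohort_config(), task = task_config(),
                           model = model_config(), seed = 1) {
  truth <- generate_cohort(config, seed)
  task_v <- list(task_config(n_trials = task$n_trials,
                             starting_bank = task$starting_bank,
                             timeout_seconds = task$timeout_seconds,
                             version = 1,
                             presentation_order = task$presentation_order,
                             timeout_prob = task$timeout_prob),
                 task_config(n_trials = task$n_trials,
                             starting_bank = task$starting_bank,
                             timeout_seconds = task$timeout_seconds,
                             version = 2,
                             presentation_order = task$presentation_order,
                             timeout_prob = task$timeout_prob))
  set.seed(seed + 1L)
  sessions <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    r <- truth[i, ]
    p <- orl_params(r$a_rew, r$a_pun, r$beta_f, r$beta_b)
    v <- ((r$wave - 1L) %% 2L) + 1L # versions alternate across administrations
    sessions[[i]] <- simulate_agent(
      p, task_v[[v]], model, subject_id = r$subject_id, wave = r$wave,
      modality = if (r$onsite == 1) "onsite" else "remote")
  }
  sessions <- do.call(rbind, sessions)
  demographics <- truth[, c("subject_id", "wave", "age", "age_c", "cohort",
                            "maternal_hx", "sex", "iq", "onsite",
                            "internalizing")]
  list(sessions = sessions, demographics = demographics, ground_truth = truth)
}
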