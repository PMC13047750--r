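#' Probit (inverse standard-normal CDF) transform of a learning rate
#'
#' Maps a rate in (0, 1) to the real line via `qnorm()`, the scale on which
#' learning rates enter the multilevel growth models. Rates are clipped to
#' `[1e-6, 1 - 1e-6]` first to avoid infinities.
#'
#' @param a rate(s) in \[0, 1\].
#' @return `qnorm(a)` after clipping.
#' @export
#' @examples
#' probit_transform(0.5) # 0
probit_transform <- function(a) {
  if (any(!is.finite(a)) || any(a < 0) || any(a > 1))
    stop("rates must lie in [0, 1]")
  qnorm(pmin(pmax(a, 1e-6), 1 - 1e-6))
}

# parameter order on the unconstrained scale, used throughout the fitter
THETA_NAMES <- c("a_rew_z", "a_pun_z", "beta_f", "beta_b")

#' Fitting configuration
#'
#' Controls the per-wave hierarchical estimator. The default (and only
#' implemented) backend, `map_eb`, is penalized-likelihood empirical Bayes:
#' subject-level MAP estimates under normal priors on the unconstrained
#' scale, alternated with moment updates of the group mean and SD until the
#' group means move less than `tolerance`. Initial group means are 0 (rates
#' 0.5) and initial group SDs 1, except `beta_f` which starts at SD 2.
#'
#' @param backend `"map_eb"`. (`"mcmc"` is a recognised contract but not
#'   available in this build.)
#' @param tolerance convergence tolerance on the maximum group-mean movement.
#' @param max_iterations cap on alternation rounds.
#' @param init_mean,init_sd initial group moments, in the order
#'   `a_rew_z, a_pun_z, beta_f, beta_b`.
#' @param sd_floor lower bound kept on group SDs for numerical stability.
#' @param seed reserved for stochastic backends; `map_eb` is deterministic.
#' @return a `fit_config` list.
#' @export
fit_config <- function(backend = c("map_eb", "mcmc"), tolerance = 1e-3,
                       max_iterations = 20,
                       init_mean = c(0, 0, 0, 0), init_sd = c(1, 1, 2, 1),
                       sd_floor = 0.05, seed = NULL) {
  backend <- match.arg(backend)
  if (backend == "mcmc")
    stop("the mcmc backend is not available in this build; use backend = \"map_eb\"")
  if (tolerance <= 0) stop("tolerance must be > 0")
  stopifnot(length(init_mean) == 4, length(init_sd) == 4, all(init_sd > 0))
  structure(list(backend = backend, tolerance = tolerance,
                 max_iterations = max_iterations,
                 init_mean = setNames(init_mean, THETA_NAMES),
                 init_sd = setNames(init_sd, THETA_NAMES),
                 sd_floor = sd_floor, seed = seed),
            class = "fit_config")
}

# one penalized-likelihood MAP optimisation; multi-start quasi-Newton on the
# unconstrained scale, deterministic starts at mu and mu +/- 0.5 sd (plus any
# warm start), tie broken by best penalized likelihood.
map_optim <- function(arrays, mu, sd, model, warm_start = NULL) {
  fn <- function(th) orl_map_obj_cpp(th, arrays$deck, arrays$choice,
                                     arrays$outcome, mu, sd,
                                     model$outcome_scale,
                                     model$fictive_updating,
                                     model$fictive_attenuation)
  gr <- function(th) orl_map_grad_cpp(th, arrays$deck, arrays$choice,
                                      arrays$outcome, mu, sd,
                                      model$outcome_scale,
                                      model$fictive_updating,
                                      model$fictive_attenuation)
  starts <- if (is.null(warm_start))
    list(mu, mu + 0.5 * sd, mu - 0.5 * sd) else list(warm_start)
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      optim(s, fn, gr, method = "BFGS",
            control = list(maxit = 300, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    return(list(theta = mu, converged = FALSE, value = fn(mu),
                post_var = sd^2))
  # Laplace posterior variances from the MAP Hessian; they feed the EM-style
  # group-variance update (without them the group SD collapses toward zero,
  # the classic naive-moment empirical-Bayes failure)
  pv <- tryCatch({
    H <- stats::optimHess(best$par, fn, gr)
    v <- diag(solve(H))
    ifelse(is.finite(v) & v > 0, v, sd^2)
  }, error = function(e) sd^2)
  list(theta = setNames(best$par, THETA_NAMES),
       converged = best$convergence == 0, value = best$value, post_var = pv)
}

theta_to_estimate <- function(theta) {
  list(a_rew = pnorm(theta[["a_rew_z"]]), a_pun = pnorm(theta[["a_pun_z"]]),
       beta_f = theta[["beta_f"]], beta_b = theta[["beta_b"]],
       a_rew_z = theta[["a_rew_z"]], a_pun_z = theta[["a_pun_z"]])
}

#' MAP estimate for a single session
#'
#' Maximizes the session log-likelihood plus independent normal log priors on
#' the unconstrained scale (learning rates via the standard-normal CDF link).
#' With a flat-ish prior (large group SDs) this approaches the per-subject
#' MLE; with an informative group posterior it realises hierarchical
#' shrinkage at the single-subject level. Deterministic: starts are the prior
#' mean and the mean offset by +/- 0.5 prior SD. Nonconvergence is flagged,
#' never silent.
#'
#' @param session a nonempty canonical session log.
#' @param group_posterior list with numeric `mean` and `sd` (length 4, order
#'   `a_rew_z, a_pun_z, beta_f, beta_b`); defaults to the [fit_config()]
#'   initial moments.
#' @param config a [fit_config()].
#' @param model a [model_config()].
#' @return an `orl_estimate` list: the four parameters, the probit-scale
#'   learning rates, and a `converged` flag.
#' @export
fit_subject_map <- function(session, group_posterior = NULL,
                            config = fit_config(), model = model_config()) {
  if (nrow(session) == 0) stop("cannot fit an empty session")
  if (is.null(group_posterior))
    group_posterior <- list(mean = config$init_mean, sd = config$init_sd)
  mu <- unname(group_posterior$mean); sd <- unname(group_posterior$sd)
  stopifnot(length(mu) == 4, length(sd) == 4, all(sd > 0))
  a <- session_arrays(session)
  fit <- map_optim(a, mu, sd, model)
  structure(c(theta_to_estimate(fit$theta), list(converged = fit$converged)),
            class = "orl_estimate")
}

#' Hierarchical per-wave fit with empirical-Bayes shrinkage
#'
#' Fits every subject's session at one assessment wave under a common group
#' prior, alternating subject-level MAP estimation with moment updates of the
#' group mean and SD on the unconstrained scale, until the group means move
#' less than `config$tolerance` or `config$max_iterations` is reached.
#' Shrinkage pulls subject estimates toward the group mean, compressing
#' between-subject variation relative to flat-prior MLEs.
#'
#' @param sessions either a long session log covering >= 2 subjects at one
#'   wave, or a list of single-subject session logs.
#' @param config a [fit_config()].
#' @param model a [model_config()].
#' @return list with `estimates` (data.frame: `subject_id, wave, a_rew,
#'   a_pun, beta_f, beta_b, a_rew_z, a_pun_z, converged`) and
#'   `group_posterior` (`mean`, `sd`, `iterations`, `converged`).
#' @export
fit_wave <- function(sessions, config = fit_config(), model = model_config()) {
  if (is.data.frame(sessions)) sessions <- split_sessions(sessions)
  if (length(sessions) < 2)
    stop("hierarchical fitting needs >= 2 subjects; use fit_subject_map() for one")
  arrays <- lapply(sessions, session_arrays)
  meta <- do.call(rbind, lapply(sessions, function(s)
    data.frame(subject_id = s$subject_id[1], wave = s$wave[1],
               stringsAsFactors = FALSE)))
  n <- length(arrays)
  mu <- unname(config$init_mean); sd <- unname(config$init_sd)
  theta <- matrix(NA_real_, n, 4, dimnames = list(NULL, THETA_NAMES))
  pvar <- matrix(NA_real_, n, 4)
  conv <- logical(n)
  iterations <- 0L; converged <- FALSE
  for (it in seq_len(config$max_iterations)) {
    iterations <- it
    for (i in seq_len(n)) {
      warm <- if (it > 1) theta[i, ] else NULL
      fit <- map_optim(arrays[[i]], mu, sd, model, warm_start = warm)
      theta[i, ] <- fit$theta; pvar[i, ] <- fit$post_var
      conv[i] <- fit$converged
    }
    new_mu <- colMeans(theta)
    # EM-style variance update: squared deviations plus Laplace posterior
    # variances, so shrinkage does not collapse the group SD
    new_sd <- pmax(sqrt(colMeans(sweep(theta, 2, new_mu)^2 + pvar)),
                   config$sd_floor)
    moved <- max(abs(new_mu - mu))
    mu <- new_mu; sd <- new_sd
    if (moved < config$tolerance) { converged <- TRUE; break }
  }
  est <- data.frame(
    meta,
    a_rew = pnorm(theta[, "a_rew_z"]), a_pun = pnorm(theta[, "a_pun_z"]),
    beta_f = theta[, "beta_f"], beta_b = theta[, "beta_b"],
    a_rew_z = theta[, "a_rew_z"], a_pun_z = theta[, "a_pun_z"],
    converged = conv, stringsAsFactors = FALSE)
  rownames(est) <- NULL
  list(estimates = est,
       group_posterior = list(mean = setNames(mu, THETA_NAMES),
                              sd = setNames(sd, THETA_NAMES),
                              iterations = iterations, converged = converged))
}

#' Fit every wave of a study
#'
#' Convenience wrapper: the model is fit separately at each assessment wave
#' (each wave gets its own group prior), mirroring per-timepoint hierarchical
#' estimation. Waves with a single subject are fit with [fit_subject_map()]
#' under the initial prior.
#'
#' @inheritParams fit_wave
#' @param sessions long session log covering one or more waves.
#' @return data.frame of subject estimates for all waves, plus a
#'   `group_posteriors` attribute (one entry per wave).
#' @export
fit_study <- function(sessions, config = fit_config(), model = model_config()) {
  waves <- sort(unique(sessions$wave))
  out <- vector("list", length(waves)); gp <- list()
  for (k in seq_along(waves)) {
    sw <- sessions[sessions$wave == waves[k], , drop = FALSE]
    parts <- split_sessions(sw)
    if (length(parts) >= 2) {
      fit <- fit_wave(parts, config, model)
      out[[k]] <- fit$estimates
      gp[[as.character(waves[k])]] <- fit$group_posterior
    } else {
      e <- fit_subject_map(parts[[1]], config = config, model = model)
      out[[k]] <- data.frame(subject_id = parts[[1]]$subject_id[1],
                             wave = waves[k], a_rew = e$a_rew, a_pun = e$a_pun,
                             beta_f = e$beta_f, beta_b = e$beta_b,
                             a_rew_z = e$a_rew_z, a_pun_z = e$a_pun_z,
                             converged = e$converged, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "group_posteriors") <- gp
  res
}

#' Default generator distributions for recovery studies
#'
#' Independent normals on the unconstrained scale (probit for learning
#' rates). Means sit at plausible adolescent values for this task (reward and
#' punishment learning rates near 0.05 and 0.035 on the rate scale, strong
#' frequency sensitivity, a positive go bias); SDs span the individual
#' differences such models typically show cross-sectionally.
#'
#' @return list with `mean` and `sd`, length-4 each.
#' @export
recovery_distributions <- function() {
  list(mean = setNames(c(-1.67, -1.81, 4.42, 1.25), THETA_NAMES),
       sd = setNames(c(0.5, 0.5, 2, 0.75), THETA_NAMES))
}

#' Parameter-recovery study
#'
#' Simulates subjects with true parameters drawn from `distributions`,
#' simulates one session each, refits the whole set hierarchically, and
#' correlates true with recovered parameters. Correlations for the learning
#' rates are computed on the unconstrained (probit) scale, the scale on which
#' subjects are generated and modelled.
#'
#' @param n_subjects number of simulated subjects (>= 20).
#' @param distributions list with `mean` and `sd` on the unconstrained scale;
#'   defaults to [recovery_distributions()]. Zero-variance generators are
#'   refused (the correlation would be undefined).
#' @param task a [task_config()].
#' @param config a [fit_config()].
#' @param model a [model_config()].
#' @param seed RNG seed.
#' @return list with `r` (named Pearson correlations), and `truth` /
#'   `recovered` data.frames for scatter plots.
#' @export
parameter_recovery <- function(n_subjects = 100,
                               distributions = recovery_distributions(),
                               task = task_config(), config = fit_config(),
                               model = model_config(), seed = 1) {
  if (n_subjects < 20) stop("n_subjects must be >= 20")
  if (any(distributions$sd <= 0))
    stop("degenerate generator: zero between-subject variance makes recovery correlations undefined")
  set.seed(seed)
  truth <- sapply(1:4, function(i)
    rnorm(n_subjects, distributions$mean[i], distributions$sd[i]))
  colnames(truth) <- THETA_NAMES
  ids <- sprintf("r%03d", seq_len(n_subjects))
  sessions <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    p <- orl_params(pnorm(truth[i, 1]), pnorm(truth[i, 2]),
                    truth[i, 3], truth[i, 4])
    sessions[[i]] <- simulate_agent(p, task, model, subject_id = ids[i])
  }
  fit <- fit_wave(sessions, config, model)
  rec <- fit$estimates[match(ids, fit$estimates$subject_id), ]
  recovered <- as.matrix(rec[, THETA_NAMES])
  r <- setNames(vapply(1:4, function(i) cor(truth[, i], recovered[, i]),
                       numeric(1)),
                c("a_rew", "a_pun", "beta_f", "beta_b"))
  list(r = r,
       truth = data.frame(subject_id = ids, truth, stringsAsFactors = FALSE),
       recovered = data.frame(subject_id = ids, recovered,
                              stringsAsFactors = FALSE))
}

#' Posterior predictive check
#'
#' For each subject, simulates `n_reps` sessions at the subject's estimated
#' parameters on the same task schedule, then aggregates observed and
#' simulated play proportions per deck per 30-trial block, with a simulated
#' 95% interval across replicates.
#'
#' @param estimates data.frame of subject estimates (as from [fit_wave()]).
#' @param sessions long session log aligned with `estimates` by subject.
#' @param task a [task_config()].
#' @param model a [model_config()].
#' @param n_reps simulated sessions per subject.
#' @param seed RNG seed.
#' @param block_size trials per block.
#' @return data.frame: `deck, block, observed, simulated_mean, lower, upper`.
#' @export
posterior_predictive_check <- function(estimates, sessions,
                                       task = task_config(),
                                       model = model_config(), n_reps = 50,
                                       seed = 1, block_size = 30) {
  parts <- split_sessions(sessions)
  ids <- vapply(parts, function(s) s$subject_id[1], character(1))
  if (!all(ids %in% estimates$subject_id))
    stop("estimates and sessions are not aligned by subject")
  set.seed(seed)
  cell <- function(s) {
    blk <- ceiling(s$trial / block_size)
    tapply(s$choice == "play", list(factor(s$deck, levels = DECKS), blk), mean)
  }
  obs <- lapply(parts, cell)
  n_blocks <- ncol(obs[[1]])
  sims <- array(NA_real_, c(length(parts), n_reps, 4, n_blocks))
  for (i in seq_along(parts)) {
    e <- estimates[match(ids[i], estimates$subject_id), ]
    p <- orl_params(e$a_rew, e$a_pun, e$beta_f, e$beta_b)
    for (r in seq_len(n_reps)) sims[i, r, , ] <- cell(simulate_agent(p, task, model))
  }
  obs_arr <- array(unlist(obs), c(4, n_blocks, length(parts)))
  grid <- expand.grid(deck = DECKS, block = seq_len(n_blocks),
                      stringsAsFactors = FALSE)
  res <- do.call(rbind, lapply(seq_len(nrow(grid)), function(g) {
    j <- deck_index(grid$deck[g]); b <- grid$block[g]
    m <- matrix(sims[, , j, b], nrow = dim(sims)[1])
    rep_means <- colMeans(m, na.rm = TRUE)
    data.frame(deck = grid$deck[g], block = b,
               observed = mean(obs_arr[j, b, ], na.rm = TRUE),
               simulated_mean = mean(rep_means),
               lower = unname(quantile(rep_means, 0.025)),
               upper = unname(quantile(rep_means, 0.975)),
               stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res
}

#' Write subject estimates to CSV
#'
#' @param estimates data.frame from [fit_wave()] / [fit_study()].
#' @param path CSV file path.
#' @export
write_estimates <- function(estimates, path) {
  write.csv(estimates, path, row.names = FALSE)
  invisible(path)
}
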