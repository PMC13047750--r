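#' Center age at the average baseline age
#'
#' Age is centered at 10.98 years (the average age at the first assessment
#' wave), so model intercepts and group contrasts are "baseline effects" at
#' ~11 years old. The center is a fixed constant, never recomputed from the
#' data, for comparability across datasets.
#'
#' @param age age in years.
#' @return `age - 10.98`.
#' @export
center_age <- function(age) age - 10.98

AGE_CENTER <- 10.98

#' Growth-model specification
#'
#' One rung of the model ladder: polynomial degree of age, whether the
#' depression-risk group enters (main effect plus interactions with every age
#' term), which covariates are included, and an optional continuous moderator
#' crossed with age.
#'
#' @param polynomial `"linear"` or `"quadratic"`.
#' @param conditional include maternal-history main effect and age
#'   interactions.
#' @param covariates subset of `c("iq", "sex", "onsite")`.
#' @param moderator optional column name entered with its age interaction.
#' @return a `growth_spec` list.
#' @export
growth_spec <- function(polynomial = c("linear", "quadratic"),
                        conditional = FALSE, covariates = character(0),
                        moderator = NULL) {
  polynomial <- match.arg(polynomial)
  bad <- setdiff(covariates, c("iq", "sex", "onsite"))
  if (length(bad)) stop("unknown covariate(s): ", paste(bad, collapse = ", "))
  structure(list(polynomial = polynomial, conditional = conditional,
                 covariates = covariates, moderator = moderator),
            class = "growth_spec")
}

growth_formula <- function(spec, random = "(1 + age_c | subject_id)") {
  fx <- "age_c"
  if (spec$polynomial == "quadratic") fx <- c(fx, "I(age_c^2)")
  if (spec$conditional) {
    fx <- c(fx, "maternal_hx", "age_c:maternal_hx")
    if (spec$polynomial == "quadratic") fx <- c(fx, "I(age_c^2):maternal_hx")
  }
  if ("iq" %in% spec$covariates) fx <- c(fx, "iq_c")
  if ("sex" %in% spec$covariates) fx <- c(fx, "sex")
  if ("onsite" %in% spec$covariates) fx <- c(fx, "onsite")
  if (!is.null(spec$moderator))
    fx <- c(fx, spec$moderator, paste0("age_c:", spec$moderator))
  as.formula(paste("value ~", paste(fx, collapse = " + "), "+", random))
}

# fit with singular-fit simplification cascade: full (correlated) random
# intercept + slope -> uncorrelated -> intercept only
fit_lmm <- function(formula_fun, data) {
  cascade <- list(
    full = "(1 + age_c | subject_id)",
    uncorrelated = "(1 + age_c || subject_id)",
    intercept_only = "(1 | subject_id)")
  for (nm in names(cascade)) {
    f <- formula_fun(cascade[[nm]])
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(f, data = data, REML = FALSE)))
    if (!lme4::isSingular(fit, tol = 1e-4) || nm == "intercept_only")
      return(list(model = fit,
                  simplification = if (nm == "full") "none" else nm))
  }
}

#' Fit one multilevel growth model
#'
#' Random-intercept, random-age-slope model of one performance metric across
#' age, estimated by maximum likelihood (not REML) so nested likelihood-ratio
#' tests remain valid. If the random-effects covariance is singular the model
#' is refit without the intercept-slope correlation, then without the random
#' slope, and the simplification is recorded. Fixed-effect t tests and
#' confidence intervals use residual degrees of freedom
#' `n_obs - n_fixed_effects`. IQ is centered at 100 (`iq_c`) so the constant
#' is interpretable at average cognitive ability.
#'
#' @param data long records for one metric: columns `subject_id, value`, and
#'   `age` or `age_c`; plus `maternal_hx`, `iq`/`iq_c`, `sex`, `onsite` as the
#'   spec requires.
#' @param spec a [growth_spec()].
#' @return a `growth_fit`: `fixed` (term, estimate, se, t, df, p, ci_lo,
#'   ci_hi), `varcomp` (`sigma2`, `tau00`, `tau11`, `cov_int_slope`),
#'   `logLik`, `n_par`, `n_obs`, `n_subjects`, `icc`, `pseudo_r2_total`,
#'   `converged`, `simplification`, and the underlying `model`.
#' @export
fit_growth <- function(data, spec = growth_spec()) {
  if (!"age_c" %in% names(data)) {
    if (!"age" %in% names(data)) stop("data needs an age or age_c column")
    data$age_c <- center_age(data$age)
  }
  if ("iq" %in% spec$covariates && !"iq_c" %in% names(data))
    data$iq_c <- data$iq - 100
  data <- data[!is.na(data$value), , drop = FALSE]
  n_waves <- if ("wave" %in% names(data)) length(unique(data$wave))
             else max(table(data$subject_id))
  if (n_waves < 2 || nrow(data) < 3)
    stop("growth modelling needs observations spanning >= 2 waves")
  res <- fit_lmm(function(r) growth_formula(spec, r), data)
  fit <- res$model
  sm <- summary(fit)$coefficients
  n_obs <- nrow(data)
  df <- n_obs - nrow(sm)
  est <- sm[, "Estimate"]; se <- sm[, "Std. Error"]; t <- est / se
  crit <- qt(0.975, df)
  fixed <- data.frame(term = rownames(sm), estimate = unname(est),
                      se = unname(se), t = unname(t), df = df,
                      p = unname(2 * pt(-abs(t), df)),
                      ci_lo = unname(est - crit * se),
                      ci_hi = unname(est + crit * se),
                      stringsAsFactors = FALSE)
  rownames(fixed) <- NULL
  vc <- lme4::VarCorr(fit)$subject_id
  tau00 <- if (!is.null(vc)) unname(vc["(Intercept)", "(Intercept)"]) else {
    # uncorrelated cascade stores separate grouping terms
    v <- lme4::VarCorr(fit)
    sum(vapply(v, function(m) if ("(Intercept)" %in% rownames(m))
      m["(Intercept)", "(Intercept)"] else 0, numeric(1)))
  }
  v_all <- lme4::VarCorr(fit)
  tau11 <- sum(vapply(v_all, function(m) if ("age_c" %in% rownames(m))
    m["age_c", "age_c"] else 0, numeric(1)))
  cov_is <- if (!is.null(vc) && all(c("(Intercept)", "age_c") %in% rownames(vc)))
    unname(vc["(Intercept)", "age_c"]) else 0
  sigma2 <- unname(attr(v_all, "sc"))^2
  # unconditional-means variance partition on the same data
  mm <- suppressMessages(suppressWarnings(
    lme4::lmer(value ~ 1 + (1 | subject_id), data = data, REML = FALSE)))
  vm <- lme4::VarCorr(mm)
  icc <- compute_icc(unname(vm$subject_id["(Intercept)", "(Intercept)"]),
                     unname(attr(vm, "sc"))^2)
  conv <- length(fit@optinfo$conv$lme4$messages) == 0
  structure(list(
    fixed = fixed,
    varcomp = list(sigma2 = sigma2, tau00 = tau00, tau11 = tau11,
                   cov_int_slope = cov_is),
    logLik = as.numeric(logLik(fit)), n_par = attr(logLik(fit), "df"),
    n_obs = n_obs, n_subjects = length(unique(data$subject_id)),
    icc = icc, pseudo_r2_total = cor(data$value, fitted(fit))^2,
    converged = conv, simplification = res$simplification,
    spec = spec, model = fit), class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("Multilevel growth model (%s%s), ML fit\n", x$spec$polynomial,
              if (x$spec$conditional) ", conditional" else ""))
  cat(sprintf("  %d observations, %d subjects; logLik %.2f\n", x$n_obs,
              x$n_subjects, x$logLik))
  print(x$fixed, digits = 3)
  cat(sprintf("  sigma2 %.4f  tau00 %.4f  tau11 %.4f  ICC %.3f  pseudo-R2 %.3f\n",
              x$varcomp$sigma2, x$varcomp$tau00, x$varcomp$tau11, x$icc,
              x$pseudo_r2_total))
  if (x$simplification != "none")
    cat("  random effects simplified:", x$simplification, "\n")
  invisible(x)
}

#' Likelihood-ratio p-value
#'
#' Upper-tail chi-square probability for a likelihood-ratio statistic.
#'
#' @param chi2 the LRT statistic, `2 * (logLik_full - logLik_reduced)`.
#' @param df difference in parameter counts.
#' @return the p-value.
#' @export
#' @examples
#' lrt_p_value(38.99, 5) # < 0.001
lrt_p_value <- function(chi2, df) pchisq(chi2, df, lower.tail = FALSE)

#' Likelihood-ratio test of nested growth models
#'
#' Both fits must be ML fits of nested fixed-effect structures on the same
#' data. A negative statistic (boundary or convergence artefact) is floored
#' at zero with a warning.
#'
#' @param fit_reduced,fit_full `growth_fit` objects.
#' @return list `chi2`, `df`, `p`.
#' @export
compare_nested <- function(fit_reduced, fit_full) {
  if (fit_reduced$n_obs != fit_full$n_obs)
    stop("nested comparison requires the same data")
  chi2 <- 2 * (fit_full$logLik - fit_reduced$logLik)
  if (chi2 < 0) {
    warning("full model has lower log-likelihood than reduced (boundary or convergence issue); statistic floored at 0")
    chi2 <- 0
  }
  df <- fit_full$n_par - fit_reduced$n_par
  list(chi2 = chi2, df = df, p = if (df > 0) lrt_p_value(chi2, df) else 1)
}

#' Intraclass correlation from an unconditional means model
#'
#' Share of variance attributable to stable between-subject differences:
#' `tau00 / (tau00 + sigma2)`.
#'
#' @param tau00 between-subject intercept variance (>= 0).
#' @param sigma2 residual variance (>= 0).
#' @return the ICC in \[0, 1\]; `NA` with a warning if both variances are 0.
#' @export
#' @examples
#' compute_icc(1.21, 8.15) # ~0.129
compute_icc <- function(tau00, sigma2) {
  if (tau00 < 0 || sigma2 < 0) stop("variances must be >= 0")
  if (tau00 + sigma2 == 0) {
    warning("both variance components are zero; ICC undefined")
    return(NA_real_)
  }
  tau00 / (tau00 + sigma2)
}

LADDER_METRICS <- c("net", "good_prop", "bad_prop", "a_rew_z", "a_pun_z",
                    "beta_f", "beta_b")
PARAM_METRICS <- c("a_rew_z", "a_pun_z", "beta_f", "beta_b")

#' Developmental-trajectory model ladder
#'
#' For each metric: fits the unconditional linear (model 1) and quadratic
#' (model 2) growth models and keeps the quadratic only if it wins the
#' likelihood-ratio test at `alpha`; adds the depression-risk group with its
#' age interactions to the winner (model 3); adds the covariates IQ, sex and
#' administration modality (model 4). Age-effect p-values (linear age term of
#' model 4) for the four computational parameters are Benjamini-Hochberg
#' adjusted as one family. Because the quadratic case makes the "unconditional
#' growth model" reference ambiguous, the model-4 LRT is emitted against both
#' the winning unconditional model and model 1.
#'
#' @param data long table: `subject_id, wave, age` (or `age_c`), `metric,
#'   value, maternal_hx, sex, iq, onsite`.
#' @param metrics metrics to model; missing ones are reported absent and
#'   skipped.
#' @param alpha LRT threshold for preferring the quadratic model.
#' @return a `trajectory_ladder`: per-metric fits and tests, `age_fdr` (BH
#'   family over the computational parameters), `table` (long fixed-effects
#'   table in the standard report shape) and `summary` (variance components,
#'   ICC, pseudo-R2, model-comparison chi-square per metric).
#' @export
run_trajectory_ladder <- function(data, metrics = LADDER_METRICS,
                                  alpha = 0.05) {
  if (!"age_c" %in% names(data)) data$age_c <- center_age(data$age)
  if (!"iq_c" %in% names(data) && "iq" %in% names(data))
    data$iq_c <- data$iq - 100
  res <- list(); absent <- character(0)
  for (m in metrics) {
    dm <- data[data$metric == m & !is.na(data$value), , drop = FALSE]
    if (nrow(dm) == 0) { absent <- c(absent, m); next }
    m1 <- fit_growth(dm, growth_spec("linear"))
    m2 <- fit_growth(dm, growth_spec("quadratic"))
    lrt_quad <- compare_nested(m1, m2)
    winner <- if (lrt_quad$p < alpha) "quadratic" else "linear"
    m3 <- fit_growth(dm, growth_spec(winner, conditional = TRUE))
    m4 <- fit_growth(dm, growth_spec(winner, conditional = TRUE,
                                     covariates = c("iq", "sex", "onsite")))
    res[[m]] <- list(metric = m, winner = winner, m1 = m1, m2 = m2, m3 = m3,
                     m4 = m4, lrt_quad = lrt_quad,
                     lrt_m4_vs_winner = compare_nested(
                       if (winner == "quadratic") m2 else m1, m4),
                     lrt_m4_vs_m1 = compare_nested(m1, m4))
  }
  params_present <- intersect(PARAM_METRICS, names(res))
  age_p <- vapply(params_present, function(m) {
    fx <- res[[m]]$m4$fixed
    fx$p[fx$term == "age_c"]
  }, numeric(1))
  age_fdr <- data.frame(metric = params_present, p = unname(age_p),
                        fdr_p = bh_fdr(unname(age_p)),
                        stringsAsFactors = FALSE)
  tab <- do.call(rbind, lapply(res, function(r)
    cbind(metric = r$metric, r$m4$fixed, stringsAsFactors = FALSE)))
  summ <- do.call(rbind, lapply(res, function(r) data.frame(
    metric = r$metric, winner = r$winner,
    sigma2 = r$m4$varcomp$sigma2, tau00 = r$m4$varcomp$tau00,
    tau11 = r$m4$varcomp$tau11, icc = r$m4$icc,
    pseudo_r2_total = r$m4$pseudo_r2_total,
    chi2_vs_uncond = r$lrt_m4_vs_winner$chi2,
    df_vs_uncond = r$lrt_m4_vs_winner$df,
    p_vs_uncond = r$lrt_m4_vs_winner$p,
    chi2_vs_m1 = r$lrt_m4_vs_m1$chi2, df_vs_m1 = r$lrt_m4_vs_m1$df,
    n_obs = r$m4$n_obs, n_subjects = r$m4$n_subjects,
    simplification = r$m4$simplification, stringsAsFactors = FALSE)))
  rownames(tab) <- rownames(summ) <- NULL
  structure(list(metrics = res, absent = absent, age_fdr = age_fdr,
                 table = tab, summary = summ),
            class = "trajectory_ladder")
}

#' @export
print.trajectory_ladder <- function(x, ...) {
  cat("Developmental trajectory ladder:", length(x$metrics), "metrics\n")
  if (length(x$absent)) cat("  absent:", paste(x$absent, collapse = ", "), "\n")
  print(x$summary[, c("metric", "winner", "icc", "pseudo_r2_total",
                      "chi2_vs_uncond", "df_vs_uncond")], digits = 3)
  cat("\nBH-adjusted age effects (computational parameters):\n")
  print(x$age_fdr, digits = 3)
  invisible(x)
}

#' Assemble the long metric table for growth modelling
#'
#' Joins subject estimates, summary scores and demographics into the
#' one-row-per-subject-wave-metric table the ladder consumes.
#'
#' @param estimates data.frame from [fit_study()].
#' @param scores data.frame from [score_sessions()].
#' @param demographics data.frame with `subject_id, wave, age, maternal_hx,
#'   sex, iq, onsite`.
#' @return long data.frame with a `metric` column covering the three
#'   traditional scores and four model parameters.
#' @export
build_metric_table <- function(estimates, scores, demographics) {
  wide <- merge(merge(estimates, scores, by = c("subject_id", "wave")),
                demographics, by = c("subject_id", "wave"))
  cols <- c(net = "net", good_prop = "good_prop", bad_prop = "bad_prop",
            a_rew_z = "a_rew_z", a_pun_z = "a_pun_z", beta_f = "beta_f",
            beta_b = "beta_b")
  out <- do.call(rbind, lapply(names(cols), function(m) {
    data.frame(subject_id = wide$subject_id, wave = wide$wave,
               age = wide$age, metric = m, value = wide[[cols[m]]],
               maternal_hx = wide$maternal_hx, sex = wide$sex, iq = wide$iq,
               onsite = wide$onsite, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
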