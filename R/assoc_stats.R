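#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjusted p-values, returned in the input
#' order: `adj_i = min over {j: p_j >= p_i} of m * p_j / rank(p_j)`, capped at
#' 1. A thin, order-preserving wrapper over `stats::p.adjust(method = "BH")`.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.04, 0.03, 0.20))
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Pearson correlation with t-distribution p-value
#'
#' Pairwise-complete Pearson correlation; p from the exact t transform with
#' n - 2 degrees of freedom. Constant input is flagged (`NA` with a note)
#' rather than an error.
#'
#' @param x,y numeric vectors.
#' @return list `r`, `p`, `n`, `note`.
#' @export
cor_with_p <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]; n <- length(x)
  if (n < 3) return(list(r = NA_real_, p = NA_real_, n = n, note = "n < 3"))
  if (sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, note = "constant variable"))
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n, note = "")
}

#' Per-wave parameter-performance associations
#'
#' Pearson correlations between each of the four PoP-ORL parameters (learning
#' rates on the probit scale) and net proportion play, separately at each
#' wave. The Benjamini-Hochberg family is the four tests within a wave.
#' Optionally computed within risk groups.
#'
#' @param estimates data.frame from [fit_study()] / [fit_wave()].
#' @param scores data.frame from [score_sessions()].
#' @param by_group optional data.frame `subject_id, maternal_hx` to split by
#'   risk status.
#' @return data.frame: `wave, group, parameter, r, p, fdr_p, n, note`.
#' @export
param_performance_associations <- function(estimates, scores,
                                           by_group = NULL) {
  params <- c("a_rew_z", "a_pun_z", "beta_f", "beta_b")
  d <- merge(estimates, scores, by = c("subject_id", "wave"))
  d$group <- "all"
  if (!is.null(by_group)) {
    g <- merge(d, by_group[, c("subject_id", "maternal_hx")], by = "subject_id")
    g$group <- ifelse(g$maternal_hx == 1, "maternal_hx", "no_maternal_hx")
    d <- rbind(d[, names(g)[names(g) != "maternal_hx"]],
               g[, names(g)[names(g) != "maternal_hx"]])
  }
  out <- list()
  for (grp in unique(d$group)) for (w in sort(unique(d$wave))) {
    dw <- d[d$wave == w & d$group == grp, ]
    if (nrow(dw) < 3) next
    rows <- lapply(params, function(pm) {
      cc <- cor_with_p(dw[[pm]], dw$net)
      data.frame(wave = w, group = grp, parameter = pm, r = cc$r, p = cc$p,
                 n = cc$n, note = cc$note, stringsAsFactors = FALSE)
    })
    fam <- do.call(rbind, rows)
    fam$fdr_p <- NA_real_
    ok <- !is.na(fam$p)
    fam$fdr_p[ok] <- bh_fdr(fam$p[ok])
    out[[length(out) + 1]] <- fam
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("wave", "group", "parameter", "r", "p", "fdr_p", "n", "note")]
}

# conventional interpretive cutoffs (Cicchetti-style), reported as labels
reliability_band <- function(r) {
  ifelse(is.na(r), NA_character_,
         ifelse(r < 0.4, "poor",
                ifelse(r < 0.6, "fair", ifelse(r < 0.75, "good", "excellent"))))
}

#' Test-retest reliability across adjacent waves
#'
#' Pairwise-complete Pearson correlations of one metric between adjacent
#' wave pairs (1,2), (2,3), (3,4), (4,5). Pairs with fewer than 3 overlapping
#' subjects are reported missing. Bands use conventional cutoffs (poor < .40,
#' fair < .60, good < .75, excellent otherwise), reported as labels only.
#'
#' @param data long data.frame with columns `subject_id, wave, value`.
#' @param waves wave pairs to correlate; defaults to adjacent pairs 1-5.
#' @return data.frame: `wave_a, wave_b, r, n, band, note`.
#' @export
test_retest <- function(data, waves = 1:5) {
  stopifnot(all(c("subject_id", "wave", "value") %in% names(data)))
  if (length(waves) < 2)
    return(data.frame(wave_a = integer(0), wave_b = integer(0),
                      r = numeric(0), n = integer(0), band = character(0),
                      note = character(0), stringsAsFactors = FALSE))
  pairs <- cbind(waves[-length(waves)], waves[-1])
  out <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    a <- data[data$wave == pairs[i, 1], c("subject_id", "value")]
    b <- data[data$wave == pairs[i, 2], c("subject_id", "value")]
    m <- merge(a, b, by = "subject_id")
    cc <- cor_with_p(m$value.x, m$value.y)
    data.frame(wave_a = pairs[i, 1], wave_b = pairs[i, 2], r = cc$r, n = cc$n,
               band = reliability_band(cc$r),
               note = if (cc$n < 3) "insufficient overlap" else cc$note,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Pooled two-sample t statistic from summary statistics
#'
#' Classical equal-variance two-sample t computed from group means, SDs and
#' ns, as used for demographic group comparisons.
#'
#' @param mean1,sd1,n1 first group summary.
#' @param mean2,sd2,n2 second group summary.
#' @return list `t`, `df`, `p` (two-sided).
#' @export
pooled_t_test <- function(mean1, sd1, n1, mean2, sd2, n2) {
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}
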