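#' Traditional summary scores for one session
#'
#' Proportion of plays on the good (C, D) and bad (A, B) decks, each over the
#' number of presentations of that deck pair, and the net score
#' `good_prop - bad_prop` (a gross measure of overall good performance).
#' Timeouts count as passes: excluded from numerators, included in
#' denominators. A pair with zero presentations yields `NA` scores with a
#' `missing` flag rather than an error.
#'
#' @param session a canonical session log.
#' @return a `summary_scores` list: `good_prop`, `bad_prop`, `net`,
#'   `n_good_pres`, `n_bad_pres`, `missing`.
#' @export
compute_summary <- function(session) {
  if (!all(session$deck %in% DECKS))
    stop("session decks must be canonical labels A-D; see recode_to_canonical()")
  good <- session$deck %in% c("C", "D")
  bad <- session$deck %in% c("A", "B")
  play <- session$choice == "play"
  n_good <- sum(good); n_bad <- sum(bad)
  good_prop <- if (n_good > 0) sum(play & good) / n_good else NA_real_
  bad_prop <- if (n_bad > 0) sum(play & bad) / n_bad else NA_real_
  structure(list(good_prop = good_prop, bad_prop = bad_prop,
                 net = good_prop - bad_prop,
                 n_good_pres = n_good, n_bad_pres = n_bad,
                 missing = n_good == 0 || n_bad == 0),
            class = "summary_scores")
}

#' Score every session of a study
#'
#' Applies [compute_summary()] to each subject-wave of a long session log.
#'
#' @param sessions long session log.
#' @return data.frame: `subject_id, wave, good_prop, bad_prop, net`.
#' @export
score_sessions <- function(sessions) {
  parts <- split_sessions(sessions)
  out <- do.call(rbind, lapply(parts, function(s) {
    sc <- compute_summary(s)
    data.frame(subject_id = s$subject_id[1], wave = s$wave[1],
               good_prop = sc$good_prop, bad_prop = sc$bad_prop, net = sc$net,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$wave, out$subject_id), ]
}

#' Write summary scores to CSV
#' @param scores data.frame from [score_sessions()].
#' @param path CSV file path.
#' @export
write_scores <- function(scores, path) {
  write.csv(scores, path, row.names = FALSE)
  invisible(path)
}
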