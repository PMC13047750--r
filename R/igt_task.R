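#' Deck payout schedules for the play-or-pass Iowa Gambling Task
#'
#' Returns the four canonical deck schedules. Decks A and B are the
#' disadvantageous (net-loss) decks and decks C and D the advantageous
#' (net-gain) decks. Magnitudes follow the classic Iowa Gambling Task block
#' structure: the bad decks pay +100 per play and lose 250 net per 10-play
#' block (A through five graded losses, B through one large loss); the good
#' decks pay +50 and gain 250 net per block (C through five small losses, D
#' through one moderate loss). Loss positions within the repeating block are
#' fixed, so the outcome of the k-th play on a deck is deterministic.
#'
#' The task is administered in two versions that map physical deck positions
#' to payout structures differently (to blunt recognition across repeated
#' administrations); the canonical A-D schedules are identical in both, only
#' the position mapping recorded in the schedule attributes changes.
#'
#' @param version task version, 1 or 2.
#' @return A named list of four deck schedules (elements `deck_label`,
#'   `win_amount`, `loss_pattern`, `loss_positions`, `block_length`,
#'   `net_per_block`), with attribute `position_map` giving the physical
#'   position (P1-P4) to canonical label mapping for `version`.
#' @export
#' @examples
#' sched <- deck_schedules(1)
#' sched$A$net_per_block # -250
deck_schedules <- function(version = 1) {
  if (!version %in% c(1, 2)) stop("unknown task version: ", version)
  mk <- function(label, win, losses, positions, block = 10) {
    net <- win * block + sum(losses)
    stopifnot(length(losses) == length(positions), length(losses) <= block, win > 0)
    list(deck_label = label, win_amount = win, loss_pattern = losses,
         loss_positions = positions, block_length = block, net_per_block = net)
  }
  sched <- list(
    A = mk("A", 100, c(-150, -200, -250, -300, -350), c(3, 5, 7, 9, 10)),
    B = mk("B", 100, -1250, 9),
    C = mk("C", 50, c(-50, -50, -50, -50, -50), c(3, 5, 7, 9, 10)),
    D = mk("D", 50, -250, 10)
  )
  stopifnot(sched$A$net_per_block < 0, sched$B$net_per_block < 0,
            sched$C$net_per_block > 0, sched$D$net_per_block > 0)
  attr(sched, "position_map") <- position_map(version)
  attr(sched, "version") <- version
  sched
}

# physical position -> canonical label, per task version
position_map <- function(version) {
  if (!version %in% c(1, 2)) stop("unknown task version: ", version)
  if (version == 1) c(P1 = "A", P2 = "B", P3 = "C", P4 = "D")
  else c(P1 = "C", P2 = "D", P3 = "A", P4 = "B")
}

#' Per-deck outcome sequence
#'
#' Expands a deck schedule into the deterministic outcome (net currency
#' change) of the k-th play on that deck: the win amount every play, plus the
#' scheduled loss when the within-block play position is a loss position.
#'
#' @param schedule one element of [deck_schedules()].
#' @param n_presentations number of plays to expand.
#' @return numeric vector of length `n_presentations`.
#' @export
deck_outcomes <- function(schedule, n_presentations) {
  k <- seq_len(n_presentations)
  pos <- ((k - 1) %% schedule$block_length) + 1
  loss <- rep(0, n_presentations)
  idx <- match(pos, schedule$loss_positions)
  loss[!is.na(idx)] <- schedule$loss_pattern[idx[!is.na(idx)]]
  schedule$win_amount + loss
}

# build_seed used once to fix the shipped default presentation order
.default_build_seed <- 20240901

#' Generate a fixed deck presentation sequence
#'
#' The order in which decks are offered is fixed across participants; this
#' generates such an order (a seeded permutation with each deck appearing
#' exactly `presentations_per_deck` times). The package default order is the
#' sequence produced by `build_seed = 20240901`, generated once and also
#' stored in the shipped task configuration fixture.
#'
#' @param n_trials total trials.
#' @param presentations_per_deck presentations of each deck; must satisfy
#'   `n_trials == 4 * presentations_per_deck`.
#' @param build_seed integer seed fixing the permutation.
#' @return character vector of deck labels of length `n_trials`.
#' @export
presentation_sequence <- function(n_trials = 120,
                                  presentations_per_deck = n_trials / 4,
                                  build_seed = .default_build_seed) {
  if (n_trials != 4 * presentations_per_deck ||
      presentations_per_deck %% 1 != 0)
    stop("n_trials must equal 4 * presentations_per_deck (whole presentations)")
  with_preserved_seed({
    set.seed(build_seed)
    sample(rep(DECKS, each = presentations_per_deck))
  })
}

# run expr with the global RNG state restored afterwards
with_preserved_seed <- function(expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  expr
}

#' Task configuration
#'
#' Assembles the play-or-pass IGT environment: trial count, starting bank,
#' response window, version, the fixed presentation order, and the per-deck
#' outcome schedule matrix. Defaults: 120 trials (30 presentations per deck),
#' a starting bank of 2000, a 4-second response window, and no simulated
#' timeouts.
#'
#' @param n_trials total trials (4 x `presentations_per_deck`).
#' @param presentations_per_deck presentations per deck.
#' @param starting_bank starting bank in task currency.
#' @param timeout_seconds response window (metadata only).
#' @param version task version (1 or 2); affects only the physical-position
#'   mapping, not the canonical payout structure.
#' @param presentation_order fixed deck-label sequence; defaults to the
#'   shipped order for the requested size.
#' @param timeout_prob per-trial probability of a nonresponse in simulation;
#'   timed-out trials are recorded as passes with a timeout flag.
#' @return a `task_config` list, including `schedules` and the
#'   `outcome_schedule` matrix (`presentations_per_deck` x 4).
#' @export
task_config <- function(n_trials = 120, presentations_per_deck = n_trials / 4,
                        starting_bank = 2000, timeout_seconds = 4,
                        version = 1, presentation_order = NULL,
                        timeout_prob = 0) {
  if (n_trials != 4 * presentations_per_deck ||
      presentations_per_deck %% 1 != 0)
    stop("n_trials must equal 4 * presentations_per_deck (whole presentations)")
  if (timeout_prob < 0 || timeout_prob > 1) stop("timeout_prob must be in [0,1]")
  if (is.null(presentation_order))
    presentation_order <- presentation_sequence(n_trials, presentations_per_deck)
  if (length(presentation_order) != n_trials)
    stop("presentation_order must have length n_trials")
  counts <- table(factor(presentation_order, levels = DECKS))
  if (any(counts != presentations_per_deck))
    stop("presentation_order must contain each deck exactly presentations_per_deck times")
  sched <- deck_schedules(version)
  outcome_schedule <- vapply(DECKS, function(d)
    deck_outcomes(sched[[d]], presentations_per_deck),
    numeric(presentations_per_deck))
  structure(list(
    n_trials = n_trials, presentations_per_deck = presentations_per_deck,
    starting_bank = starting_bank, timeout_seconds = timeout_seconds,
    version = version, presentation_order = presentation_order,
    timeout_prob = timeout_prob, schedules = sched,
    outcome_schedule = outcome_schedule
  ), class = "task_config")
}

#' Read a task configuration from YAML
#'
#' Reads the external-interface YAML form of a [task_config()]. The shipped
#' default lives at `system.file("extdata", "task_default.yaml",
#' package = "poporl")`.
#'
#' @param path YAML file path.
#' @return a `task_config`.
#' @export
read_task_config <- function(path) {
  y <- yaml::read_yaml(path)
  task_config(
    n_trials = y$n_trials, presentations_per_deck = y$presentations_per_deck,
    starting_bank = y$starting_bank, timeout_seconds = y$timeout_seconds,
    version = y$version,
    presentation_order = strsplit(y$presentation_order, "")[[1]],
    timeout_prob = if (is.null(y$timeout_prob)) 0 else y$timeout_prob
  )
}

#' Run one task session under an arbitrary policy
#'
#' Hosts any play/pass policy in the task environment loop with full bank
#' accounting. The policy is called once per trial with the trial index (1
#' based), the offered deck label, and the current bank, and must return
#' `"play"` or `"pass"`. Passes leave the bank unchanged and yield outcome 0;
#' plays draw the next scheduled outcome for that deck. If
#' `config$timeout_prob > 0`, trials time out at that rate (seeded) and are
#' recorded as passes with `timeout = 1`.
#'
#' @param policy `function(trial, deck, bank) -> "play"|"pass"`.
#' @param config a [task_config()].
#' @param seed RNG seed (only consulted when timeouts are simulated).
#' @param subject_id,wave,modality session metadata stored in the log.
#' @return a session log `data.frame` with columns `subject_id, wave, trial,
#'   deck, choice, timeout, outcome, bank_after, version, modality`.
#' @export
run_session <- function(policy, config = task_config(), seed = NULL,
                        subject_id = "s1", wave = 1L, modality = "onsite") {
  n <- config$n_trials
  if (n == 0) return(empty_session(subject_id, wave, config$version, modality))
  if (!is.null(seed)) set.seed(seed)
  deck <- config$presentation_order
  choice <- character(n); timeout <- integer(n); outcome <- numeric(n)
  bank <- config$starting_bank; bank_after <- numeric(n)
  plays <- setNames(integer(4), DECKS)
  for (t in seq_len(n)) {
    d <- deck[t]
    if (config$timeout_prob > 0 && runif(1) < config$timeout_prob) {
      choice[t] <- "pass"; timeout[t] <- 1L
    } else {
      ch <- policy(t, d, bank)
      if (!is.character(ch) || length(ch) != 1 || !ch %in% c("play", "pass"))
        stop("policy must return \"play\" or \"pass\" (trial ", t, ")")
      choice[t] <- ch
    }
    if (choice[t] == "play") {
      plays[d] <- plays[d] + 1L
      outcome[t] <- config$outcome_schedule[plays[d], d]
      bank <- bank + outcome[t]
    }
    bank_after[t] <- bank
  }
  data.frame(subject_id = subject_id, wave = as.integer(wave),
             trial = seq_len(n), deck = deck, choice = choice,
             timeout = timeout, outcome = outcome, bank_after = bank_after,
             version = config$version, modality = modality,
             stringsAsFactors = FALSE)
}

empty_session <- function(subject_id, wave, version, modality) {
  data.frame(subject_id = character(0), wave = integer(0), trial = integer(0),
             deck = character(0), choice = character(0), timeout = integer(0),
             outcome = numeric(0), bank_after = numeric(0),
             version = integer(0), modality = character(0),
             stringsAsFactors = FALSE)
}

#' Recode physical deck positions to canonical labels
#'
#' Raw logs record the physical deck position (`P1`-`P4`). Analyses use
#' canonical labels where A/B are always the net-loss decks and C/D the
#' net-gain decks; the mapping depends on the task version. Already-canonical
#' logs pass through unchanged (idempotent).
#'
#' @param raw_log session log whose `deck` column holds physical positions or
#'   canonical labels.
#' @param version task version used for the session.
#' @return the log with `deck` in canonical labels.
#' @export
recode_to_canonical <- function(raw_log, version) {
  d <- raw_log$deck
  if (all(d %in% DECKS)) return(raw_log)
  map <- position_map(version)
  bad <- setdiff(unique(d), c(names(map), DECKS))
  if (length(bad)) stop("unknown deck position label(s): ", paste(bad, collapse = ", "))
  raw_log$deck <- ifelse(d %in% DECKS, d, unname(map[d]))
  raw_log
}

#' Read / write session logs
#'
#' Long-format CSV dialect: one row per trial with columns `subject_id, wave,
#' trial` (1-based), `deck` (canonical A-D), `choice` (play/pass), `timeout`
#' (0/1), `outcome`, `bank_after`, `version`, `modality`.
#'
#' @param sessions session log data.frame (one or many subject-waves).
#' @param path CSV file path.
#' @return `read_sessions` returns the data.frame; `write_sessions` returns
#'   `path` invisibly.
#' @export
write_sessions <- function(sessions, path) {
  write.csv(sessions, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sessions
#' @export
read_sessions <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "wave", "trial", "deck", "choice", "timeout",
            "outcome", "bank_after")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("session file missing column(s): ", paste(miss, collapse = ", "))
  x
}

# split a long multi-session log into a list of single subject-wave sessions
split_sessions <- function(sessions) {
  key <- interaction(sessions$subject_id, sessions$wave, drop = TRUE)
  lapply(split(sessions, key), function(s) s[order(s$trial), , drop = FALSE])
}
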