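#' Score a 10-item CES-D response
#'
#' Computes the 0--30 total for the short (10-item) CES-D form.  Items are
#' answered on a 4-point frequency scale (0 = rarely, 3 = most of the time);
#' items 5 ("hopeful about the future") and 8 ("was happy") are positively
#' worded and contribute reversed, i.e. `3 - raw`.  Up to two missing items
#' per wave are filled in with the rounded person-mean of that wave's
#' non-missing (post-reversal) item contributions; three or more missing
#' items invalidate the wave and yield `NA`.
#'
#' @param items Integer vector of length 10 (one wave), or an n x 10 matrix /
#'   data frame (one row per wave).  Entries in \{0,1,2,3\} or `NA`.
#' @return Integer total score in 0..30, or `NA_integer_` for an invalid
#'   wave (>= 3 missing items).  Vectorised over rows for matrix input.
#' @export
#' @examples
#' score_cesd(rep(0L, 10))          # reversal of items 5 and 8 forces 6
#' score_cesd(rep(3L, 10))          # 24: the two reversed items contribute 0
#' score_cesd(c(NA, NA, NA, rep(0L, 7)))  # invalid wave
score_cesd <- function(items) {
  if (is.data.frame(items)) items <- as.matrix(items)
  if (is.matrix(items)) {
    if (ncol(items) != 10L)
      stop("item matrix must have 10 columns", call. = FALSE)
    return(vapply(seq_len(nrow(items)),
                  function(i) score_cesd(items[i, ]), integer(1)))
  }
  if (length(items) != 10L)
    stop("a CES-D wave response has exactly 10 items", call. = FALSE)
  ok <- !is.na(items)
  if (any(!(items[ok] %in% 0:3)))
    stop("CES-D item values must be in {0,1,2,3}", call. = FALSE)
  if (sum(!ok) >= 3L) return(NA_integer_)
  contrib <- as.numeric(items)
  contrib[c(5L, 8L)] <- 3 - contrib[c(5L, 8L)]
  if (any(!ok)) contrib[!ok] <- round(mean(contrib[ok]))
  as.integer(sum(contrib))
}

# Deterministic wave-state machine over a symptomatic indicator.
# Start in state 1 (the cohort is symptom-free at baseline); first elevated
# wave opens an episode (2); staying elevated is persistence (3); dropping
# below the cutoff from any symptomatic state is remission (4); elevation
# after remission is relapse (5), absorbing in the observation window.
classify_indicator <- function(symptomatic) {
  n <- length(symptomatic)
  states <- integer(n)
  states[1L] <- 1L
  if (symptomatic[1L])
    stop("baseline wave is symptomatic: subject excluded by design",
         call. = FALSE)
  for (w in seq_len(n)[-1L]) {
    prev <- states[w - 1L]
    states[w] <- if (prev == 5L) 5L
    else if (symptomatic[w]) switch(prev, 2L, 3L, 3L, 5L)
    else switch(prev, 1L, 4L, 4L, 4L)
  }
  states
}

#' Classify a subject's wave scores into symptom states
#'
#' Applies the five-state rules to one subject's per-wave CES-D totals.  A
#' wave is symptomatic when its total is at or above `cutoff` (default 12,
#' the conventional 10-item CES-D threshold for elevated depressive
#' symptoms).  Subjects symptomatic at baseline are excluded upstream and
#' raise an error here.
#'
#' @param scores Numeric vector of per-wave totals, no missing values.
#' @param wave_times Numeric vector of observation times in years, same
#'   length as `scores`, strictly increasing.
#' @param subject_id Identifier carried into the result.
#' @param cutoff Symptom threshold; a wave is symptomatic iff
#'   `score >= cutoff`.
#' @return A `state_sequence`: list with `subject_id`, `wave_times`,
#'   `states` (labels in 1..5) and `events`, a data frame of
#'   (`path`, `time`) for each observed transition.
#' @export
#' @examples
#' classify_states(c(5, 14, 14, 8), c(0, 2, 4, 7))$states  # 1 2 3 4
#' classify_states(c(5, 14, 8, 14), c(0, 2, 4, 7))$states  # 1 2 4 5
classify_states <- function(scores, wave_times = seq_along(scores) - 1,
                            subject_id = NA_integer_, cutoff = 12) {
  if (anyNA(scores))
    stop("scores contain missing waves; filter invalid waves upstream",
         call. = FALSE)
  if (length(scores) < 1L) stop("need at least one valid wave", call. = FALSE)
  if (length(wave_times) != length(scores) ||
      is.unsorted(wave_times, strictly = TRUE))
    stop("wave_times must be strictly increasing and match scores",
         call. = FALSE)
  states <- classify_indicator(scores >= cutoff)
  new_state_sequence(subject_id, wave_times, states)
}

new_state_sequence <- function(subject_id, wave_times, states) {
  moved <- which(diff(states) != 0L) + 1L
  events <- data.frame(
    path = paste0(states[moved - 1L], states[moved]),
    time = wave_times[moved],
    stringsAsFactors = FALSE)
  bad <- setdiff(events$path, transition_paths())
  if (length(bad))
    stop("forbidden state transition(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(subject_id = subject_id, wave_times = wave_times,
                 states = states, events = events),
            class = "state_sequence")
}

#' @export
print.state_sequence <- function(x, ...) {
  cat("Subject", x$subject_id, "states:",
      paste(x$states, collapse = " -> "), "\n")
  if (nrow(x$events))
    cat("  events:", paste(sprintf("%s@%g", x$events$path, x$events$time),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Classify a whole panel of wave scores
#'
#' @param panel Data frame with columns `subject_id`, `wave_time` and either
#'   `cesd_total` or ten item columns `item_1`..`item_10` (items scored
#'   first; the two dialects are auto-detected).
#' @param cutoff Symptom threshold passed to [classify_states()].
#' @return List with `states` (long data frame `subject_id`, `wave_time`,
#'   `state`), `events` (`subject_id`, `path`, `time`) and `sequences`
#'   (list of `state_sequence`).  Subjects with any invalid wave (>= 3
#'   missing items) or a symptomatic baseline are dropped with a message,
#'   mirroring the cohort inclusion rules.
#' @export
classify_panel <- function(panel, cutoff = 12) {
  stopifnot(is.data.frame(panel),
            all(c("subject_id", "wave_time") %in% names(panel)))
  item_cols <- paste0("item_", 1:10)
  if (!"cesd_total" %in% names(panel)) {
    if (!all(item_cols %in% names(panel)))
      stop("panel needs either cesd_total or item_1..item_10", call. = FALSE)
    panel$cesd_total <- score_cesd(panel[item_cols])
  }
  panel <- panel[order(panel$subject_id, panel$wave_time), ]
  by_subj <- split(panel, panel$subject_id)
  dropped_missing <- dropped_baseline <- 0L
  sequences <- list()
  for (sp in by_subj) {
    if (anyNA(sp$cesd_total)) { dropped_missing <- dropped_missing + 1L; next }
    if (sp$cesd_total[1L] >= cutoff) { dropped_baseline <- dropped_baseline + 1L; next }
    sequences[[length(sequences) + 1L]] <-
      classify_states(sp$cesd_total, sp$wave_time, sp$subject_id[1L], cutoff)
  }
  if (dropped_missing + dropped_baseline > 0L)
    message("excluded ", dropped_missing, " subject(s) with invalid waves and ",
            dropped_baseline, " symptomatic at baseline")
  states <- do.call(rbind, lapply(sequences, function(s)
    data.frame(subject_id = s$subject_id, wave_time = s$wave_times,
               state = s$states)))
  events <- do.call(rbind, lapply(sequences, function(s)
    if (nrow(s$events)) cbind(subject_id = s$subject_id, s$events) else NULL))
  if (is.null(events))
    events <- data.frame(subject_id = integer(), path = character(),
                         time = numeric())
  list(states = states, events = events, sequences = sequences)
}

#' Count observed events per transition path
#'
#' @param x A list of `state_sequence` objects, the list returned by
#'   [classify_panel()], or an events data frame with a `path` column.
#' @return Named integer vector over [transition_paths()] (zero-filled).
#' @export
#' @examples
#' a <- classify_states(c(5, 14, 14, 8), c(0, 2, 4, 7))
#' b <- classify_states(c(5, 14, 8, 14), c(0, 2, 4, 7))
#' tabulate_events(list(a, b))
tabulate_events <- function(x) {
  paths <- if (is.data.frame(x)) x$path
  else if (is.list(x) && !is.null(x$events)) x$events$path
  else unlist(lapply(x, function(s) s$events$path), use.names = FALSE)
  counts <- table(factor(paths, levels = transition_paths()))
  stats::setNames(as.integer(counts), transition_paths())
}
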