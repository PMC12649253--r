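#' Build the stacked counting-process design
#'
#' Converts observed wave-level state sequences plus baseline covariates
#' into transition records: for every subject, every occupied transient
#' state h and every permissible path h->g, one interval record from the
#' time the subject entered h (delayed entry) to the earlier of the state
#' exit and the last wave, with status 1 when the h->g move was the one
#' observed.  Event times sit at the wave of first observation of the new
#' state (the right endpoint of the interval in which the true transition
#' occurred), so events are heavily tied at wave times.
#'
#' @param states Long data frame (`subject_id`, `wave_time`, `state`) from
#'   [classify_panel()] or [simulate_state_paths()]; the panel must be
#'   balanced (all subjects share the wave grid).
#' @param X Numeric model matrix, one row per subject (see
#'   [build_model_matrix()]), or a data frame of numeric columns.
#' @param structure A [transition_structure()].
#' @param subject_id Subject identifiers aligned to the rows of `X`;
#'   default: the sorted unique ids of `states`.
#' @return Object of class `stacked_design`: `records` (data frame
#'   `subject_id`, `path`, `group`, `entry`, `exit`, `status`), `X`, `n`,
#'   `p`, `structure`, and cached per-path risk-set structures.
#' @export
build_transition_records <- function(states, X,
                                     structure = transition_structure(),
                                     subject_id = NULL) {
  stopifnot(is.data.frame(states),
            all(c("subject_id", "wave_time", "state") %in% names(states)))
  if (is.data.frame(X)) X <- as.matrix(X[setdiff(names(X), "subject_id")])
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  ids <- subject_id %||% sort(unique(states$subject_id))
  n <- length(ids)
  if (nrow(X) != n)
    stop("X must have one row per subject", call. = FALSE)
  states <- states[order(match(states$subject_id, ids), states$wave_time), ]
  wt <- sort(unique(states$wave_time))
  W <- length(wt)
  if (nrow(states) != n * W)
    stop("panel must be balanced: every subject observed at every wave",
         call. = FALSE)
  S <- matrix(states$state, nrow = n, ncol = W, byrow = TRUE)
  bad <- S[, -1L, drop = FALSE] - S[, -W, drop = FALSE]
  pairs <- paste0(S[, -W, drop = FALSE][bad != 0L], S[, -1L, drop = FALSE][bad != 0L])
  if (length(pairs) && !all(pairs %in% transition_paths()))
    stop("state sequence contains a forbidden transition: ",
         paste(unique(setdiff(pairs, transition_paths())), collapse = ", "),
         call. = FALSE)
  pg <- path_group(structure)
  recs <- vector("list", 8L)
  ri <- 0L
  for (h in 1:4) {
    occ <- (S == h) + 0
    has <- rowSums(occ) > 0L
    if (!any(has)) next
    firstw <- max.col(occ, ties.method = "first")
    above <- (S > h) + 0
    hasnext <- rowSums(above) > 0L
    nextw <- max.col(above, ties.method = "first")
    entry <- wt[firstw]
    exit <- ifelse(hasnext, wt[nextw], wt[W])
    next_state <- ifelse(hasnext, S[cbind(seq_len(n), nextw)], NA_integer_)
    keep <- has & entry < exit
    for (path in .paths_from[[as.character(h)]]) {
      g <- as.integer(substr(path, 2L, 2L))
      ri <- ri + 1L
      recs[[ri]] <- data.frame(
        subject_row = which(keep),
        subject_id = ids[keep],
        path = path,
        group = pg[[path]],
        entry = entry[keep],
        exit = exit[keep],
        status = as.integer(!is.na(next_state[keep]) & next_state[keep] == g))
    }
  }
  records <- do.call(rbind, recs[seq_len(ri)])
  records <- records[order(records$path, records$subject_id), ]
  rownames(records) <- NULL
  design <- structure(list(records = records, X = X, n = n,
                           p = ncol(X), ids = ids, structure = structure),
                      class = "stacked_design")
  design$risk <- .risk_structures(design)
  design
}

#' Construct a stacked design directly from transition records
#'
#' Lower-level constructor for designs not derived from a wave panel --
#' hand-built toy examples, or records read back from the long interchange
#' format.  Validates the counting-process invariants: known paths,
#' `entry < exit`, and at most one event record per subject and path.
#'
#' @param records Data frame with columns `subject_id`, `path`, `entry`,
#'   `exit`, `status`.
#' @param X Model matrix, one row per distinct subject (rows aligned to
#'   `sort(unique(records$subject_id))`), or a data frame.
#' @param structure A [transition_structure()].
#' @return A `stacked_design`.
#' @export
stacked_design <- function(records, X, structure = transition_structure()) {
  stopifnot(is.data.frame(records),
            all(c("subject_id", "path", "entry", "exit", "status") %in%
                  names(records)))
  if (is.data.frame(X)) X <- as.matrix(X[setdiff(names(X), "subject_id")])
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (!all(records$path %in% transition_paths()))
    stop("unknown transition path in records", call. = FALSE)
  if (any(records$entry >= records$exit))
    stop("every record needs entry < exit", call. = FALSE)
  ev <- records[records$status == 1L, ]
  if (anyDuplicated(ev[c("subject_id", "path")]))
    stop("at most one event record per subject and path", call. = FALSE)
  ids <- sort(unique(records$subject_id))
  if (nrow(X) != length(ids))
    stop("X must have one row per subject", call. = FALSE)
  pg <- path_group(structure)
  records$group <- unname(pg[records$path])
  records$subject_row <- match(records$subject_id, ids)
  design <- structure(list(records = records, X = X, n = length(ids),
                           p = ncol(X), ids = ids, structure = structure),
                      class = "stacked_design")
  design$risk <- .risk_structures(design)
  design
}

#' Read a stacked design from its long interchange CSV
#'
#' Inverse of [write_stacked()]: covariates are taken from each subject's
#' first record (they are baseline-fixed by construction).
#'
#' @param file Path to a CSV written by [write_stacked()].
#' @param structure A [transition_structure()].
#' @return A `stacked_design`.
#' @export
read_stacked <- function(file, structure = transition_structure()) {
  long <- utils::read.csv(file, stringsAsFactors = FALSE,
                          colClasses = c(path = "character",
                                         group = "character"))
  meta <- c("subject_id", "path", "group", "entry", "exit", "status")
  covars <- setdiff(names(long), meta)
  ids <- sort(unique(long$subject_id))
  X <- as.matrix(long[match(ids, long$subject_id), covars, drop = FALSE])
  rownames(X) <- NULL
  stacked_design(long[setdiff(meta, "group")], X, structure)
}

# Per-path Breslow pieces: distinct event times, their multiplicities,
# event subject rows, and risk-set subject rows (entry < t <= exit).
.risk_structures <- function(design) {
  out <- list()
  for (path in unique(design$records$path)) {
    rr <- design$records[design$records$path == path, ]
    ev_times <- sort(unique(rr$exit[rr$status == 1L]))
    per_time <- lapply(ev_times, function(t) {
      risk <- rr$subject_row[rr$entry < t & t <= rr$exit]
      if (!length(risk))
        stop("empty risk set for path ", path, " at time ", t, call. = FALSE)
      evt <- rr$subject_row[rr$status == 1L & rr$exit == t]
      list(time = t, d = length(evt), events = evt, risk = risk)
    })
    out[[path]] <- per_time
  }
  out
}

#' @export
print.stacked_design <- function(x, ...) {
  ev <- tapply(x$records$status, x$records$path, sum)
  cat("Stacked design:", x$n, "subjects,", x$p, "covariates,",
      nrow(x$records), "transition records\n")
  cat("  events:", paste(names(ev), ev, sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Risk set of a transition path at a time point
#'
#' @param design A `stacked_design`.
#' @param path One of [transition_paths()].
#' @param time Time in years (>= 0).
#' @return Sorted vector of subject ids with a record for `path` whose
#'   interval satisfies `entry < time <= exit` -- i.e. subjects occupying
#'   the origin state and under observation just before `time` (a subject
#'   whose event occurs exactly at `time` is included).
#' @export
risk_set <- function(design, path, time) {
  stopifnot(inherits(design, "stacked_design"), time >= 0)
  if (!path %in% transition_paths())
    stop("unknown transition path: ", path, call. = FALSE)
  rr <- design$records[design$records$path == path, ]
  sort(rr$subject_id[rr$entry < time & time <= rr$exit])
}

#' Write the stacked design in long interchange form
#'
#' @param design A `stacked_design`.
#' @param file Output CSV path.
#' @return The written data frame (invisibly): one row per transition
#'   record with its covariate columns.
#' @export
write_stacked <- function(design, file) {
  out <- cbind(design$records[c("subject_id", "path", "group",
                                "entry", "exit", "status")],
               as.data.frame(design$X[design$records$subject_row, ,
                                      drop = FALSE]))
  utils::write.csv(out, file, row.names = FALSE)
  invisible(out)
}
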