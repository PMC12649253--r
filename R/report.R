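#' Transition rate ratio
#'
#' The multiplicative effect of a covariate on a transition intensity:
#' `exp(est)`.
#' @param est Coefficient estimate(s).
#' @return `exp(est)`.
#' @export
#' @examples
#' trr(0.4026)   # 1.4957 to 4 decimals
trr <- function(est) {
  stopifnot(all(is.finite(est)))
  exp(est)
}

#' 95% confidence limits of a transition rate ratio
#'
#' `exp(est -/+ z * se)` with `z` the exact 0.975 normal quantile
#' (about 1.959964), not 1.96 rounded.
#'
#' @param est Coefficient estimate.
#' @param se Standard error (> 0).
#' @param level Confidence level (default 0.95).
#' @return Numeric vector `c(lower, upper)`; vectorised inputs give a
#'   two-column matrix.
#' @export
#' @examples
#' trr_confidence_limits(0.4026, 0.0568)
trr_confidence_limits <- function(est, se, level = 0.95) {
  if (any(!is.finite(se)) || any(se <= 0))
    stop("standard errors must be positive", call. = FALSE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  lo <- exp(est - z * se)
  hi <- exp(est + z * se)
  if (length(est) == 1L) c(lower = lo, upper = hi)
  else cbind(lower = lo, upper = hi)
}

#' Assemble the per-transition effect table
#'
#' One row per coefficient group and design column, in the reporting style
#' of the multi-state feature-selection analysis: selected coefficients
#' carry their refit estimate, standard error, TRR, 95% confidence limits
#' and significance mark; coefficients shrunk to zero carry `est = 0` and
#' blank inference columns.
#'
#' @param fit A `penalized_fit`.
#' @param inference The matching [post_selection_inference()] result.
#' @return Data frame `block`, `term`, `est`, `se`, `trr`, `cl_low`,
#'   `cl_high`, `sig`.
#' @export
transition_effect_table <- function(fit, inference) {
  stopifnot(inherits(fit, "penalized_fit"))
  rows <- list()
  for (g in names(fit$beta)) {
    terms <- names(fit$beta[[g]])
    tab <- data.frame(block = g, term = terms, est = 0, se = NA_real_,
                      trr = NA_real_, cl_low = NA_real_, cl_high = NA_real_,
                      sig = "", stringsAsFactors = FALSE)
    inf <- inference[inference$group == g, ]
    m <- match(inf$term, tab$term)
    tab$est[m] <- inf$est
    tab$se[m] <- inf$se
    tab$trr[m] <- trr(inf$est)
    cl <- trr_confidence_limits(inf$est, inf$se)
    if (length(m) == 1L) { tab$cl_low[m] <- cl[1]; tab$cl_high[m] <- cl[2] }
    else { tab$cl_low[m] <- cl[, 1]; tab$cl_high[m] <- cl[, 2] }
    tab$sig[m] <- inf$sig
    rows[[g]] <- tab
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Round an effect table to reporting precision
#'
#' @param table Effect table from [transition_effect_table()].
#' @param digits Decimal places (default 4, the reporting convention).
#' @return The table with numeric columns rounded.
#' @export
format_effect_table <- function(table, digits = 4) {
  num <- c("est", "se", "trr", "cl_low", "cl_high")
  table[num] <- lapply(table[num], round, digits = digits)
  table
}

#' Onset-age distribution across downstream symptom states
#'
#' For subjects who experienced at least one new symptom episode, onset age
#' is baseline age plus the time of the first 1->2 event.  Subjects who
#' never became symptomatic are excluded (their onset age is undefined).
#' Ages are split into early (< 60 years) and late (>= 60) onset, and
#' cross-tabulated against the furthest symptom state the subject reached
#' in the window.
#'
#' @param states Long state data frame (`subject_id`, `wave_time`,
#'   `state`).
#' @param baseline_age Named or positionally aligned numeric vector of ages
#'   at the first wave, one per subject appearing in `states`.
#' @param threshold Early/late boundary in years (default 60; late is
#'   `>= threshold`).
#' @return List: `table` (`subject_id`, `onset_age`, `final_state`,
#'   `onset_group`), `counts` (final_state x early/late contingency
#'   table), `n_onset`.
#' @export
onset_age_summary <- function(states, baseline_age, threshold = 60) {
  ids <- sort(unique(states$subject_id))
  if (length(baseline_age) != length(ids))
    stop("baseline_age must align with the subjects in states", call. = FALSE)
  states <- states[order(states$subject_id, states$wave_time), ]
  by_subj <- split(states, states$subject_id)
  rows <- lapply(seq_along(ids), function(i) {
    sp <- by_subj[[i]]
    w <- which(sp$state == 2L)
    if (!length(w)) return(NULL)
    data.frame(subject_id = ids[i],
               onset_age = baseline_age[i] + sp$wave_time[w[1L]],
               final_state = max(sp$state))
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    return(list(table = data.frame(subject_id = integer(),
                                   onset_age = numeric(),
                                   final_state = integer(),
                                   onset_group = character()),
                counts = table(factor(integer(), levels = 2:5),
                               factor(character(), levels = c("early", "late"))),
                n_onset = 0L))
  tab$onset_group <- ifelse(tab$onset_age < threshold, "early", "late")
  counts <- table(final_state = factor(tab$final_state, levels = 2:5),
                  onset = factor(tab$onset_group, levels = c("early", "late")))
  list(table = tab, counts = counts, n_onset = nrow(tab))
}
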