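#' Min-max normalize a numeric column to [0, 1]
#'
#' @param x Numeric vector with at least two distinct finite values.
#' @return `(x - min) / (max - min)`; the minimum maps to 0, the maximum
#'   to 1.
#' @export
#' @examples
#' minmax_normalize(c(0, 5, 10))
minmax_normalize <- function(x) {
  if (!is.numeric(x) || !all(is.finite(x)))
    stop("minmax_normalize needs finite numeric input", call. = FALSE)
  r <- range(x)
  if (r[1] == r[2])
    stop("constant column cannot be min-max normalized (degenerate scale)",
         call. = FALSE)
  (x - r[1]) / (r[2] - r[1])
}

#' Flag (or winsorize) outliers by the median-absolute-deviation rule
#'
#' A value is flagged when `|x - median| > k * 1.4826 * MAD`, the usual
#' normal-consistent robust z-score rule.  When the MAD is zero on
#' non-constant data the rule is uninformative: nothing is flagged and a
#' warning is raised.
#'
#' @param x Numeric vector (>= 3 values).
#' @param k Threshold multiplier (default 3).
#' @param action `"flag"` (default) reports flags only; `"winsorize"` also
#'   clips flagged values to the rule's boundaries.
#' @return List: `flags` (logical), `values` (original or winsorized),
#'   `bounds` (the clipping interval).
#' @export
#' @examples
#' mad_outliers(c(1, 2, 1, 2, 100))$flags
mad_outliers <- function(x, k = 3, action = c("flag", "winsorize")) {
  action <- match.arg(action)
  stopifnot(is.numeric(x), length(x) >= 3L, k > 0)
  med <- stats::median(x)
  s <- stats::mad(x)  # already scaled by 1.4826
  if (s == 0) {
    if (stats::var(x) > 0)
      warning("MAD is zero on non-constant data; no outliers flagged")
    return(list(flags = rep(FALSE, length(x)), values = x,
                bounds = c(-Inf, Inf)))
  }
  bounds <- med + c(-1, 1) * k * s
  flags <- x < bounds[1] | x > bounds[2]
  values <- if (action == "winsorize") pmin(pmax(x, bounds[1]), bounds[2]) else x
  list(flags = flags, values = values, bounds = bounds)
}

#' Complete missing covariates by chained conditional models
#'
#' Single-imputation chained equations: missing entries are initialised at
#' the column mean (mode for binary), then each incomplete column is
#' repeatedly re-imputed from a conditional model on all other columns in a
#' fixed sweep order -- linear regression for continuous columns, logistic
#' regression for binary \{0,1\} columns (imputed as the more probable
#' class, so binaries stay in \{0,1\}).  Predictions are conditional means,
#' so the completion is deterministic.
#'
#' @param data Data frame of numeric columns (a `subject_id` column, if
#'   present, is carried through untouched).
#' @param max_missing_rate Columns missing more than this fraction abort
#'   with an error, mirroring the cohort exclusion rule for poorly observed
#'   risk factors (default 0.30).
#' @param n_iter Number of full sweeps (default 10).
#' @param seed Accepted for interface stability; the default conditional-
#'   mean completion does not consume randomness.
#' @return The completed data frame.
#' @export
chained_impute <- function(data, max_missing_rate = 0.30, n_iter = 10,
                           seed = NULL) {
  stopifnot(is.data.frame(data), max_missing_rate > 0, max_missing_rate <= 1)
  id <- data[["subject_id"]]
  work <- data[setdiff(names(data), "subject_id")]
  if (!all(vapply(work, is.numeric, TRUE)))
    stop("chained_impute expects numeric columns", call. = FALSE)
  miss_rate <- vapply(work, function(x) mean(is.na(x)), 0)
  if (any(miss_rate > max_missing_rate))
    stop("column(s) exceed the missing-rate cap (",
         max_missing_rate * 100, "%): ",
         paste(names(work)[miss_rate > max_missing_rate], collapse = ", "),
         call. = FALSE)
  incomplete <- names(work)[miss_rate > 0]
  if (!length(incomplete)) return(data)
  na_idx <- lapply(work, function(x) which(is.na(x)))
  is_binary <- vapply(work, function(x) all(stats::na.omit(x) %in% 0:1), TRUE)
  for (nm in incomplete)  # initialise
    work[[nm]][na_idx[[nm]]] <- if (is_binary[[nm]])
      round(mean(work[[nm]], na.rm = TRUE)) else mean(work[[nm]], na.rm = TRUE)
  for (iter in seq_len(n_iter)) {
    for (nm in incomplete) {
      obs <- seq_len(nrow(work))[-na_idx[[nm]]]
      rhs <- setdiff(names(work), nm)
      fml <- stats::as.formula(paste0("`", nm, "` ~ ",
                                      paste0("`", rhs, "`", collapse = " + ")))
      train <- work
      train[[nm]][na_idx[[nm]]] <- NA  # fit on originally observed rows only
      pred <- if (is_binary[[nm]]) {
        fit <- suppressWarnings(stats::glm(fml, data = train,
                                           family = stats::binomial()))
        as.numeric(stats::predict(fit, newdata = work[na_idx[[nm]], ],
                                  type = "response") > 0.5)
      } else {
        fit <- stats::lm(fml, data = train)
        as.numeric(stats::predict(fit, newdata = work[na_idx[[nm]], ]))
      }
      work[[nm]][na_idx[[nm]]] <- pred
    }
  }
  out <- if (is.null(id)) work else cbind(data.frame(subject_id = id), work)
  rownames(out) <- NULL
  out
}

#' Screen candidate interaction terms by marginal transition association
#'
#' Ranks candidate product terms by a marginal utility: for each candidate,
#' the interaction column (product of the normalized factors) is entered
#' alone into each transition path's partial likelihood and its score test
#' statistic at beta = 0 is computed; the utility is the maximum over
#' paths.  This is a pragmatic marginal-association screen standing behind
#' a pluggable interface -- any ranking function with the same signature
#' can replace it.
#'
#' @param candidates List of covariate-name pairs; duplicates are removed.
#' @param states Long state data frame (`subject_id`, `wave_time`,
#'   `state`).
#' @param covariates Covariate data frame (raw scale; factors named in
#'   `normalize` are normalized before the product is formed).
#' @param k Number of top candidates to retain (default: all, ranked).
#' @param normalize Columns to min-max normalize first.
#' @param structure [transition_structure()] used to build per-path
#'   records.
#' @return Data frame `term`, `var1`, `var2`, `utility`, ranked
#'   decreasingly; the top `k` rows.
#' @export
screen_interactions <- function(candidates, states, covariates,
                                k = length(candidates),
                                normalize = c("age", "income", "n_conditions"),
                                structure = transition_structure()) {
  candidates <- unique(lapply(candidates, as.character))
  cov_names <- setdiff(names(covariates), "subject_id")
  for (pr in candidates)
    if (!all(pr %in% cov_names))
      stop("unknown covariate in candidate pair: ",
           paste(pr, collapse = " x "), call. = FALSE)
  X <- build_model_matrix(covariates, normalize = normalize,
                          interactions = candidates)
  inter_names <- vapply(candidates, paste, "", collapse = "_x_")
  # singleton groups so every path is scored separately
  singleton <- transition_structure(
    coefficient_groups = as.list(stats::setNames(transition_paths(),
                                                 transition_paths())))
  utilities <- vapply(inter_names, function(nm) {
    Xi <- X[, nm, drop = FALSE]
    des <- build_transition_records(states, Xi, singleton,
                                    subject_id = covariates$subject_id)
    per_path <- vapply(transition_paths(), function(pth) {
      if (!any(des$records$path == pth & des$records$status == 1L)) return(0)
      sc <- score_test_stat(des, group = pth)
      sc
    }, 0)
    max(per_path)
  }, 0)
  out <- data.frame(term = inter_names,
                    var1 = vapply(candidates, `[`, "", 1L),
                    var2 = vapply(candidates, `[`, "", 2L),
                    utility = utilities)
  out <- out[order(-out$utility), ]
  rownames(out) <- NULL
  utils::head(out, k)
}
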