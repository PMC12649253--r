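#' Symptom states and permissible transitions
#'
#' The model distinguishes five depressive-symptom states observed at survey
#' waves: 1 = no symptom, 2 = new symptom episode, 3 = symptom persistence,
#' 4 = symptom remission, 5 = symptom relapse.  Only five directed moves are
#' possible between consecutive waves: 1->2, 2->3, 2->4, 3->4 and 4->5;
#' relapse is absorbing within the observation window.
#'
#' @return Character vector of the five permissible transition paths,
#'   encoded `"12"`, `"23"`, `"24"`, `"34"`, `"45"`.
#' @export
#' @examples
#' transition_paths()
transition_paths <- function() c("12", "23", "24", "34", "45")

#' State labels used throughout the package
#' @return Named character vector mapping state code to label.
#' @export
state_labels <- function() {
  c(`1` = "no symptom", `2` = "new symptom episode",
    `3` = "symptom persistence", `4` = "symptom remission",
    `5` = "symptom relapse")
}

# states whose occupancy implies an elevated CES-D score
.symptomatic_states <- c(2L, 3L, 5L)

# paths leaving each transient state
.paths_from <- list(`1` = "12", `2` = c("23", "24"), `3` = "34", `4` = "45")

#' Transition structure: coefficient sharing and baseline strata
#'
#' Defines how the five transition paths are grouped for estimation.  Each
#' coefficient group shares one regression coefficient vector across its
#' paths; each baseline stratum has its own (unspecified) baseline hazard.
#' The default groups follow the reporting blocks of the analysis the
#' package reproduces: onset (1->2), persistence (2->3), remission (2->4 and
#' 3->4 share one block), relapse (4->5); baselines stay stratified per path.
#'
#' @param coefficient_groups Named list partitioning [transition_paths()]
#'   into groups sharing a coefficient vector.
#' @param baseline_strata Named list partitioning the paths into baseline
#'   hazard strata.  Default: one stratum per path.
#' @return An object of class `transition_structure`.
#' @export
#' @examples
#' transition_structure()
#' # fully transition-specific coefficients:
#' transition_structure(coefficient_groups = as.list(setNames(
#'   transition_paths(), transition_paths())))
transition_structure <- function(
    coefficient_groups = list(onset = "12", persistence = "23",
                              remission = c("24", "34"), relapse = "45"),
    baseline_strata = as.list(stats::setNames(transition_paths(),
                                              transition_paths()))) {
  .check_partition(coefficient_groups, "coefficient_groups")
  .check_partition(baseline_strata, "baseline_strata")
  structure(list(paths = transition_paths(),
                 coefficient_groups = coefficient_groups,
                 baseline_strata = baseline_strata),
            class = "transition_structure")
}

.check_partition <- function(part, what) {
  if (is.null(names(part)) || any(!nzchar(names(part))))
    stop(what, " must be a named list", call. = FALSE)
  flat <- unlist(part, use.names = FALSE)
  if (anyDuplicated(flat) || !setequal(flat, transition_paths()))
    stop(what, " must partition the transition paths ",
         paste(transition_paths(), collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' @export
print.transition_structure <- function(x, ...) {
  cat("Transition structure over paths:", paste(x$paths, collapse = " "), "\n")
  for (g in names(x$coefficient_groups))
    cat("  group", g, ":", paste(x$coefficient_groups[[g]], collapse = " + "), "\n")
  invisible(x)
}

# map path -> coefficient group name
path_group <- function(structure) {
  grp <- rep(names(structure$coefficient_groups),
             lengths(structure$coefficient_groups))
  stats::setNames(grp, unlist(structure$coefficient_groups, use.names = FALSE))
}
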