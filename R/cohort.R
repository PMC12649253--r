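#' Reference effect table for the CHARLS-like demo scenario
#'
#' Per-transition coefficient estimates, standard errors, transition rate
#' ratios, 95% confidence limits and significance marks from the national
#' ageing-cohort analysis this package's simulator emulates.  The nonzero
#' estimates serve as the simulator's default true coefficients, and the
#' printed TRR/CL columns are the inputs for the arithmetic-reproduction
#' checks in the test suite.
#'
#' @return Data frame with columns `block`, `term`, `est`, `se`, `trr`,
#'   `cl_low`, `cl_high`, `sig` (zero-coefficient rows have `NA` inference
#'   columns).
#' @export
reference_effects <- function() {
  path <- system.file("extdata", "reference_effects.csv", package = "depstate",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(sig = "character"))
}

#' Default covariate marginals for the synthetic cohort
#'
#' Thirteen baseline covariates with the marginal distributions of the
#' middle-aged-and-older Chinese survey population the simulator emulates:
#' twelve binaries at the cohort prevalences, age as Normal(57.88, 8.50)
#' years, household per-capita income as a moment-matched lognormal (mean
#' 10,783.51, sd 11,056.88 yuan), and the number of diagnosed chronic
#' conditions as Poisson(1.1) truncated to 0..8.
#'
#' @return List of covariate specifications (fields `name`, `kind` and
#'   distribution parameters) accepted by [cohort_spec()].
#' @export
default_covariate_specs <- function() {
  bin <- function(name, prop) list(name = name, kind = "binary", prop = prop)
  list(
    bin("residence", 0.2187),
    bin("sex", 0.4662),
    list(name = "age", kind = "continuous", dist = "normal",
         mean = 57.88, sd = 8.50),
    bin("education", 0.6417),
    bin("marital", 0.8116),
    bin("retired", 0.1341),
    list(name = "income", kind = "continuous", dist = "lognormal",
         mean = 10783.51, sd = 11056.88),
    list(name = "n_conditions", kind = "count", mean = 1.1, upper = 8),
    bin("pain", 0.2356),
    bin("badl", 0.0205),
    bin("social", 0.5131),
    bin("child_contact", 0.6513),
    bin("child_support", 0.3124))
}

#' Default interaction candidates
#'
#' The five product terms retained by the screening stage of the reference
#' analysis; built from min-max-normalized factors so products of
#' non-negative covariates stay in \[0, 1\].
#' @return List of character pairs.
#' @export
default_interactions <- function() {
  list(c("education", "income"), c("n_conditions", "income"),
       c("n_conditions", "sex"), c("sex", "age"), c("age", "education"))
}

#' Default true coefficients per transition group
#'
#' The nonzero entries of [reference_effects()], arranged as one named
#' vector per coefficient group so demo cohorts reproduce the reference
#' scenario's effect structure.
#' @return Named list of numeric vectors (length 18 each).
#' @export
default_true_betas <- function() {
  ref <- reference_effects()
  lapply(split(ref, factor(ref$block, levels = unique(ref$block))),
         function(b) stats::setNames(b$est, b$term))
}

#' Default baseline transition intensities
#'
#' Constant per-year intensities for the latent continuous-time process,
#' calibrated so that a default cohort of about 3,900 subjects observed at
#' waves 0/2/4/7 years produces an event mix resembling the reference
#' cohort (roughly 1400 onsets, 400 persistence, 640 remission and 120
#' relapse events).
#' @return Named numeric vector over [transition_paths()].
#' @export
default_baseline_rates <- function() {
  c(`12` = 0.11, `23` = 0.19, `24` = 0.62, `34` = 0.72, `45` = 0.20)
}

#' Cohort specification for the selection-validation study
#'
#' The scenario used to validate variable selection and post-selection
#' estimation: 3,000 subjects, the default 18-column design, and six true
#' nonzero onset coefficients placed on binary covariates that do not enter
#' any interaction product (residence -0.48, marital -0.46, pain 0.48,
#' social -0.48, child_contact 0.46, child_support 0.46).  Magnitudes
#' follow an explicit power rule: each term's expected Wald statistic at
#' the scenario's event count is at least ~5, so BIC-tuned adaptive-Lasso
#' retention has high per-term probability, while staying small enough
#' that the attenuation from wave-grouped event times (~8-9% of the
#' coefficient) remains well below the scale of the effects.  Only the
#' onset transition is active (baseline rate 0.045/yr, all other paths 0),
#' so every episode is observed at the next wave and outcome
#' misclassification cannot bias the estimates; what remains is the
#' estimator itself plus the wave-grouping of event times.
#'
#' @param seed Integer seed.
#' @param n_subjects Cohort size (default 3000).
#' @return A [cohort_spec()] whose `true_betas$onset` carries the scenario
#'   truth (inspect `attr(, "truth")` for the nonzero support).
#' @export
recovery_spec <- function(seed, n_subjects = 3000) {
  terms <- c(vapply(default_covariate_specs(), `[[`, "", "name"),
             vapply(default_interactions(), paste, "", collapse = "_x_"))
  truth <- stats::setNames(numeric(length(terms)), terms)
  truth[c("residence", "marital", "pain", "social",
          "child_contact", "child_support")] <-
    c(-0.48, -0.46, 0.48, -0.48, 0.46, 0.46)
  zero <- stats::setNames(numeric(length(terms)), terms)
  spec <- cohort_spec(n_subjects,
                      true_betas = list(onset = truth, persistence = zero,
                                        remission = zero, relapse = zero),
                      baseline_rates = c(`12` = 0.045),
                      seed = seed)
  attr(spec, "truth") <- truth
  spec
}

#' Specification of a synthetic multi-state cohort
#'
#' Bundles everything needed to generate a reproducible synthetic panel:
#' sample size, wave times, covariate marginals, the true transition-model
#' coefficients, constant baseline intensities and the CES-D emission
#' settings.  Defaults emulate a four-wave national ageing survey (waves at
#' 0, 2, 4 and 7 years, i.e. 2011/2013/2015/2018).
#'
#' @param n_subjects Positive subject count.
#' @param wave_times Strictly increasing non-negative times in years (>= 2).
#' @param covariates Covariate specification list; see
#'   [default_covariate_specs()].
#' @param normalize Names of covariates min-max normalized before entering
#'   the linear predictor (the quantitative covariates).
#' @param interactions List of covariate-name pairs; products of the
#'   (normalized) factors are appended to the design.
#' @param true_betas Named list, one coefficient vector per coefficient
#'   group of `structure`; each vector has one entry per design column
#'   (mains then interactions).
#' @param baseline_rates Named non-negative vector over a subset of
#'   [transition_paths()]; paths not named get rate 0.
#' @param missing_item_rate Probability that an emitted CES-D item is
#'   missing (capped at 2 missing items per wave so no wave is invalidated).
#' @param cutoff Symptom threshold for score emission/classification.
#' @param structure [transition_structure()] defining coefficient sharing.
#' @param seed Integer seed; identical specs generate identical cohorts.
#' @return Object of class `cohort_spec`.
#' @export
#' @examples
#' spec <- cohort_spec(n_subjects = 500, seed = 7)
#' cov <- generate_covariates(spec)
#' sim <- simulate_state_paths(cov, spec)
#' table(sim$states$state[sim$states$wave_index == 4])
cohort_spec <- function(n_subjects,
                        wave_times = c(0, 2, 4, 7),
                        covariates = default_covariate_specs(),
                        normalize = c("age", "income", "n_conditions"),
                        interactions = default_interactions(),
                        true_betas = default_true_betas(),
                        baseline_rates = default_baseline_rates(),
                        missing_item_rate = 0,
                        cutoff = 12,
                        structure = transition_structure(),
                        seed = 1L) {
  stopifnot(length(n_subjects) == 1L, n_subjects >= 1, n_subjects == floor(n_subjects))
  if (length(wave_times) < 2L || any(wave_times < 0) ||
      is.unsorted(wave_times, strictly = TRUE))
    stop("wave_times must be >= 2 non-negative strictly increasing times",
         call. = FALSE)
  for (cv in covariates) {
    if (cv$kind == "binary" && (cv$prop < 0 || cv$prop > 1))
      stop("binary proportion for '", cv$name, "' outside [0,1]", call. = FALSE)
    if (cv$kind == "continuous" && cv$sd < 0)
      stop("negative sd for '", cv$name, "'", call. = FALSE)
  }
  if (!all(names(baseline_rates) %in% transition_paths()))
    stop("baseline_rates keys must be transition paths", call. = FALSE)
  if (any(baseline_rates < 0)) stop("baseline rates must be >= 0", call. = FALSE)
  if (missing_item_rate < 0 || missing_item_rate > 1)
    stop("missing_item_rate must be in [0,1]", call. = FALSE)
  cov_names <- vapply(covariates, `[[`, "", "name")
  p <- length(cov_names) + length(interactions)
  groups <- names(structure$coefficient_groups)
  if (!setequal(names(true_betas), groups))
    stop("true_betas must have one vector per coefficient group", call. = FALSE)
  for (g in groups)
    if (length(true_betas[[g]]) != p)
      stop("true_betas[['", g, "']] must have length ", p,
           " (covariates + interactions)", call. = FALSE)
  rates <- stats::setNames(numeric(5), transition_paths())
  rates[names(baseline_rates)] <- baseline_rates
  structure(list(n_subjects = as.integer(n_subjects), wave_times = wave_times,
                 covariates = covariates, normalize = normalize,
                 interactions = interactions, true_betas = true_betas,
                 baseline_rates = rates, missing_item_rate = missing_item_rate,
                 cutoff = cutoff, structure = structure,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort spec:", x$n_subjects, "subjects,",
      length(x$wave_times), "waves at", paste(x$wave_times, collapse = "/"),
      "years, seed", x$seed, "\n")
  invisible(x)
}

#' Draw baseline covariates for a synthetic cohort
#'
#' Binary covariates are Bernoulli at the specified prevalence; continuous
#' covariates are Normal or moment-matched lognormal, optionally clipped to
#' `lower`/`upper`; count covariates are Poisson truncated to their bounds.
#'
#' @param spec A [cohort_spec()].
#' @return Data frame `subject_id` plus one column per covariate; the same
#'   spec (including seed) always returns the identical table.
#' @export
generate_covariates <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  with_seed(spec$seed, {
    cols <- lapply(spec$covariates, function(cv) {
      x <- switch(cv$kind,
        binary = stats::rbinom(n, 1L, cv$prop),
        count = {
          v <- stats::rpois(n, cv$mean)
          pmin(v, cv$upper %||% Inf)
        },
        continuous = {
          v <- if ((cv$dist %||% "normal") == "lognormal") {
            # match the stated mean/sd on the natural scale
            cv2 <- log(1 + (cv$sd / cv$mean)^2)
            stats::rlnorm(n, meanlog = log(cv$mean) - cv2 / 2, sdlog = sqrt(cv2))
          } else stats::rnorm(n, cv$mean, cv$sd)
          pmin(pmax(v, cv$lower %||% -Inf), cv$upper %||% Inf)
        },
        stop("unknown covariate kind: ", cv$kind, call. = FALSE))
      x
    })
    names(cols) <- vapply(spec$covariates, `[[`, "", "name")
    cbind(data.frame(subject_id = seq_len(n)), as.data.frame(cols))
  })
}

#' Build the model matrix used by the transition models
#'
#' Min-max normalizes the quantitative covariates and appends interaction
#' columns as elementwise products of the (normalized) factors, so products
#' of non-negative inputs stay in \[0, 1\].  Interaction columns are named
#' `a_x_b`.
#'
#' @param covariates Data frame from [generate_covariates()] (or real data
#'   in the same dialect).
#' @param normalize Character names of columns to min-max normalize.
#' @param interactions List of name pairs.
#' @return Numeric matrix, one row per subject.
#' @export
build_model_matrix <- function(covariates,
                               normalize = c("age", "income", "n_conditions"),
                               interactions = default_interactions()) {
  X <- as.matrix(covariates[setdiff(names(covariates), "subject_id")])
  for (nm in intersect(normalize, colnames(X)))
    X[, nm] <- minmax_normalize(X[, nm])
  if (length(interactions)) {
    inter <- vapply(interactions, function(pr) X[, pr[1]] * X[, pr[2]],
                    numeric(nrow(X)))
    colnames(inter) <- vapply(interactions, paste, "", collapse = "_x_")
    X <- cbind(X, inter)
  }
  X
}

# per-subject intensity matrix: n x 5 columns over transition paths
.path_intensities <- function(X, spec) {
  pg <- path_group(spec$structure)
  sapply(transition_paths(), function(path) {
    beta <- spec$true_betas[[pg[[path]]]]
    if (is.null(names(beta))) names(beta) <- colnames(X)
    spec$baseline_rates[[path]] * exp(drop(X[, names(beta), drop = FALSE] %*% beta))
  })
}

#' Simulate latent multi-state paths and wave-censored observations
#'
#' Runs a clock-forward continuous-time Markov process over the five-state
#' symptom graph with constant baseline intensities multiplied by
#' `exp(beta' x)` per subject, then observes each subject only at the wave
#' times: the observed state sequence is the symptom-state classifier
#' applied to the wave-level symptomatic indicator (latent state 2, 3 or 5),
#' exactly as score-based classification would see the data.  Latent jumps
#' between waves are invisible, so e.g. an episode that begins and remits
#' within one inter-wave gap is never observed.
#'
#' @param covariates Data frame from [generate_covariates()].
#' @param spec The [cohort_spec()] (supplies betas, rates, wave times, seed).
#' @return List with `states` (long data frame `subject_id`, `wave_index`,
#'   `wave_time`, `state`), `latent` (data frame of latent jumps
#'   `subject_id`, `time`, `from`, `to` within the observation window),
#'   `X` (the model matrix used) and `spec`.
#' @export
simulate_state_paths <- function(covariates, spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  if (nrow(covariates) != n)
    stop("covariate rows must equal n_subjects", call. = FALSE)
  X <- build_model_matrix(covariates, spec$normalize, spec$interactions)
  lam <- .path_intensities(X, spec)
  horizon <- max(spec$wave_times)
  with_seed(spec$seed + 1L, {
    draw <- function(rate) ifelse(rate > 0, stats::rexp(n) / pmax(rate, 1e-300), Inf)
    t_enter2 <- draw(lam[, "12"])
    mu2 <- lam[, "23"] + lam[, "24"]
    w2 <- draw(mu2)
    to3 <- stats::runif(n) < ifelse(mu2 > 0, lam[, "23"] / pmax(mu2, 1e-300), 0)
    t_leave2 <- t_enter2 + w2
    t_enter3 <- ifelse(to3, t_leave2, Inf)
    w3 <- draw(lam[, "34"])
    t_enter4 <- ifelse(to3, t_enter3 + w3, t_leave2)
    t_enter5 <- t_enter4 + draw(lam[, "45"])
  })
  # latent jump list within the window
  jump <- function(time, from, to) {
    keep <- is.finite(time) & time <= horizon
    data.frame(subject_id = covariates$subject_id[keep], time = time[keep],
               from = rep(from, sum(keep)), to = rep(to, sum(keep)))
  }
  latent <- rbind(jump(t_enter2, 1L, 2L),
                  jump(t_enter3, 2L, 3L),
                  jump(ifelse(to3, t_enter4, Inf), 3L, 4L),
                  jump(ifelse(to3, Inf, t_enter4), 2L, 4L),
                  jump(t_enter5, 4L, 5L))
  latent <- latent[order(latent$subject_id, latent$time), ]
  rownames(latent) <- NULL
  # wave-level observation: symptomatic iff latent state in {2,3,5}
  wt <- spec$wave_times
  sympt_mat <- sapply(wt, function(t) (t >= t_enter2 & t < t_enter4) | (t >= t_enter5))
  if (n == 1L) sympt_mat <- matrix(sympt_mat, nrow = 1L)
  states <- t(apply(sympt_mat, 1L, classify_indicator))
  long <- data.frame(
    subject_id = rep(covariates$subject_id, each = length(wt)),
    wave_index = rep(seq_along(wt), times = n),
    wave_time = rep(wt, times = n),
    state = as.integer(t(states)))
  list(states = long, latent = latent, X = X, spec = spec)
}

#' Emit CES-D totals (and optionally items) consistent with observed states
#'
#' Inverse of the threshold classifier: symptomatic waves (states 2, 3, 5)
#' receive a total at or above the cutoff, non-symptomatic waves (1, 4) a
#' total below it, so classifying the emitted scores recovers the observed
#' states exactly.  Item-level emission distributes the total over ten item
#' contributions in 0..3 and stores items 5 and 8 pre-reversal (raw value
#' `3 - contribution`), so [score_cesd()] sums them back to the total.
#'
#' @param states Long state data frame as returned by
#'   [simulate_state_paths()] (`$states`).
#' @param spec The [cohort_spec()].
#' @param items Emit item-level columns `item_1`..`item_10`?  When
#'   `spec$missing_item_rate > 0`, at most two items per wave are blanked
#'   (never enough to invalidate the wave).
#' @return `panel` data frame: `subject_id`, `wave_index`, `wave_time`,
#'   `cesd_total` and, if requested, the ten item columns.
#' @export
emit_cesd_scores <- function(states, spec, items = FALSE) {
  stopifnot(is.data.frame(states), inherits(spec, "cohort_spec"))
  m <- nrow(states)
  cutoff <- spec$cutoff
  with_seed(spec$seed + 2L, {
    sympt <- states$state %in% .symptomatic_states
    total <- integer(m)
    # right-skewed scores on either side of the cutoff
    total[!sympt] <- stats::rbinom(sum(!sympt), as.integer(cutoff) - 1L, 0.25)
    total[sympt] <- as.integer(cutoff) +
      stats::rbinom(sum(sympt), 30L - as.integer(cutoff), 0.20)
    panel <- data.frame(subject_id = states$subject_id,
                        wave_index = states$wave_index,
                        wave_time = states$wave_time,
                        cesd_total = total)
    if (items) {
      contrib <- matrix(0L, m, 10L)
      for (i in seq_len(m)) {
        left <- total[i]
        while (left > 0L) {
          open <- which(contrib[i, ] < 3L)
          pick <- if (length(open) == 1L) open else sample(open, 1L)
          contrib[i, pick] <- contrib[i, pick] + 1L
          left <- left - 1L
        }
      }
      item <- contrib
      item[, c(5L, 8L)] <- 3L - item[, c(5L, 8L)]
      if (spec$missing_item_rate > 0) {
        for (i in seq_len(m)) {
          miss <- which(stats::runif(10L) < spec$missing_item_rate)
          if (length(miss) > 2L) miss <- miss[1:2]
          item[i, miss] <- NA_integer_
        }
      }
      colnames(item) <- paste0("item_", 1:10)
      panel <- cbind(panel, as.data.frame(item))
    }
    panel
  })
}

#' Generate and write a complete synthetic cohort
#'
#' Convenience wrapper running covariate generation, latent-path simulation
#' and score emission, optionally writing the two interchange tables
#' `covariates.csv` and `panel.csv`.
#'
#' @param spec A [cohort_spec()].
#' @param dir Output directory (created if needed); `NULL` skips writing.
#' @param items Emit item-level CES-D columns?
#' @return List with `covariates`, `panel`, `states`, `latent`, `X`, `spec`.
#' @export
generate_cohort <- function(spec, dir = NULL, items = FALSE) {
  covariates <- generate_covariates(spec)
  sim <- simulate_state_paths(covariates, spec)
  panel <- emit_cesd_scores(sim$states, spec, items = items)
  out <- list(covariates = covariates, panel = panel, states = sim$states,
              latent = sim$latent, X = sim$X, spec = spec)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(covariates, file.path(dir, "covariates.csv"),
                     row.names = FALSE)
    utils::write.csv(panel, file.path(dir, "panel.csv"), row.names = FALSE)
  }
  out
}
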