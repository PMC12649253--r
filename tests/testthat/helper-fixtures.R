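# shared fixture builders (everything generated in code; no stored data)

# three subjects, single 1->2 path, distinct event times: small enough for
# exhaustive hand enumeration of the partial likelihood
toy_single_path_design <- function(x = c(0.5, -1.0, 2.0),
                                   exit = c(1, 2, 3),
                                   status = c(1L, 1L, 0L)) {
  records <- data.frame(subject_id = 1:3, path = "12",
                        entry = 0, exit = exit, status = status)
  stacked_design(records, matrix(x, ncol = 1, dimnames = list(NULL, "x")),
                 transition_structure(coefficient_groups = list(`12` = "12",
                                                                `23` = "23",
                                                                `24` = "24",
                                                                `34` = "34",
                                                                `45` = "45")))
}

singleton_structure <- function() {
  transition_structure(coefficient_groups =
    as.list(stats::setNames(transition_paths(), transition_paths())))
}

# small cohort with a reduced, well-conditioned covariate set so every
# transition path has many more events than coefficients
small_covariate_spec <- function(n = 1000, seed = 1) {
  cohort_spec(
    n_subjects = n,
    covariates = list(
      list(name = "sex", kind = "binary", prop = 0.47),
      list(name = "urban", kind = "binary", prop = 0.3),
      list(name = "pain", kind = "binary", prop = 0.25),
      list(name = "age", kind = "continuous", dist = "normal",
           mean = 58, sd = 8.5)),
    normalize = "age",
    interactions = list(),
    true_betas = {
      b <- function(...) stats::setNames(c(...), c("sex", "urban", "pain", "age"))
      list(onset = b(0.4, -0.3, 0.35, 0.3),
           persistence = b(0.2, 0, 0, 0),
           remission = b(0, 0, -0.2, 0),
           relapse = b(0.3, 0, 0, 0))
    },
    baseline_rates = c(`12` = 0.12, `23` = 0.25, `24` = 0.55, `34` = 0.6,
                       `45` = 0.25),
    seed = seed)
}

# cohort -> classified states -> stacked design in one step
build_demo_design <- function(spec, structure = spec$structure) {
  co <- generate_covariates(spec)
  sim <- simulate_state_paths(co, spec)
  build_transition_records(sim$states, sim$X, structure,
                           subject_id = co$subject_id)
}

# independent per-path Cox fit via the survival package (oracle)
coxph_oracle <- function(design, path) {
  rr <- design$records[design$records$path == path, ]
  df <- cbind(rr[c("entry", "exit", "status")],
              as.data.frame(design$X[rr$subject_row, , drop = FALSE]))
  fml <- stats::as.formula(paste("survival::Surv(entry, exit, status) ~",
                                 paste(colnames(design$X), collapse = "+")))
  fit <- survival::coxph(fml, data = df, ties = "breslow",
                         control = survival::coxph.control(eps = 1e-10,
                                                           iter.max = 100))
  stats::coef(fit)
}
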