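test_that("covariate marginals match their specification at Monte-Carlo scale", {
  spec <- cohort_spec(50000, seed = 31)
  co <- generate_covariates(spec)
  # binary prevalence within 3 MC standard errors
  se_sex <- sqrt(0.4662 * (1 - 0.4662) / 50000)
  expect_lt(abs(mean(co$sex) - 0.4662), 3 * se_sex)
  # continuous mean within 3 MC standard errors
  expect_lt(abs(mean(co$age) - 57.88), 3 * 8.50 / sqrt(50000))
  # lognormal income: moment-matched mean
  expect_lt(abs(mean(co$income) - 10783.51), 3 * 11056.88 / sqrt(50000))
  expect_true(all(co$income > 0))
  expect_true(all(co$n_conditions %in% 0:8))
  bin_cols <- c("residence", "sex", "education", "marital", "retired",
                "pain", "badl", "social", "child_contact", "child_support")
  for (nm in bin_cols) expect_true(all(co[[nm]] %in% 0:1))
})

test_that("degenerate binary proportions give constant columns", {
  spec <- cohort_spec(200, covariates = list(
    list(name = "a", kind = "binary", prop = 0),
    list(name = "b", kind = "binary", prop = 1)),
    normalize = character(0), interactions = list(),
    true_betas = {
      z <- stats::setNames(numeric(2), c("a", "b"))
      list(onset = z, persistence = z, remission = z, relapse = z)
    },
    seed = 3)
  co <- generate_covariates(spec)
  expect_true(all(co$a == 0))
  expect_true(all(co$b == 1))
})

test_that("invalid covariate parameters are configuration errors", {
  expect_error(cohort_spec(10, covariates = list(
    list(name = "a", kind = "binary", prop = 1.2))), "outside")
  expect_error(cohort_spec(10, covariates = list(
    list(name = "a", kind = "continuous", dist = "normal",
         mean = 0, sd = -1))), "negative sd")
  expect_error(cohort_spec(10, wave_times = c(2, 1)), "increasing")
  expect_error(cohort_spec(10, baseline_rates = c(`12` = -0.1)), ">= 0")
  expect_error(cohort_spec(10, baseline_rates = c(`15` = 0.1)), "paths")
  tb <- default_true_betas()
  tb$onset <- tb$onset[-1]
  expect_error(cohort_spec(10, true_betas = tb), "length")
})

test_that("identical specs generate identical cohorts", {
  spec <- cohort_spec(300, missing_item_rate = 0.05, seed = 99)
  a <- generate_cohort(spec, items = TRUE)
  b <- generate_cohort(spec, items = TRUE)
  expect_identical(a$covariates, b$covariates)
  expect_identical(a$panel, b$panel)
  expect_identical(a$latent, b$latent)
  spec2 <- cohort_spec(300, missing_item_rate = 0.05, seed = 100)
  expect_false(identical(generate_cohort(spec2)$panel$cesd_total,
                         a$panel$cesd_total))
})

test_that("zero intensities leave every subject symptom-free", {
  spec <- cohort_spec(400, baseline_rates = c(`12` = 0), seed = 8)
  sim <- simulate_state_paths(generate_covariates(spec), spec)
  expect_true(all(sim$states$state == 1L))
  expect_identical(nrow(sim$latent), 0L)
})

test_that("null-covariate onset matches the exponential closed form", {
  zero <- lapply(default_true_betas(), function(b) b * 0)
  rate <- 0.08
  spec <- cohort_spec(50000, true_betas = zero,
                      baseline_rates = c(`12` = rate), seed = 17)
  sim <- simulate_state_paths(generate_covariates(spec), spec)
  st <- matrix(sim$states$state, ncol = 4, byrow = TRUE)
  for (w in 2:4) {
    t <- spec$wave_times[w]
    p_true <- 1 - exp(-rate * t)
    p_hat <- mean(st[, w] >= 2L)
    expect_lt(abs(p_hat - p_true),
              3 * sqrt(p_true * (1 - p_true) / 50000))
  }
})

test_that("an overwhelming onset intensity forces exactly one 1->2 jump each", {
  zero <- lapply(default_true_betas(), function(b) b * 0)
  spec <- cohort_spec(500, true_betas = zero,
                      baseline_rates = c(`12` = 1000), seed = 21)
  sim <- simulate_state_paths(generate_covariates(spec), spec)
  jumps12 <- sim$latent[sim$latent$from == 1L, ]
  expect_identical(nrow(jumps12), 500L)
  expect_identical(anyDuplicated(jumps12$subject_id), 0L)
  # never remits (no 2->4 route), so symptomatic from wave 2 onward
  st <- matrix(sim$states$state, ncol = 4, byrow = TRUE)
  expect_true(all(st[, 2] == 2L))
  expect_true(all(st[, 3] == 3L & st[, 4] == 3L))
})

test_that("observed transitions always lie in the permitted set", {
  spec <- cohort_spec(2000, seed = 12)
  sim <- simulate_state_paths(generate_covariates(spec), spec)
  st <- matrix(sim$states$state, ncol = 4, byrow = TRUE)
  pairs <- paste0(st[, -4], st[, -1])
  moved <- substr(pairs, 1, 1) != substr(pairs, 2, 2)
  expect_true(all(pairs[moved] %in% transition_paths()))
})

test_that("emitted scores invert the classifier exactly", {
  spec <- cohort_spec(800, seed = 44)
  sim <- simulate_state_paths(generate_covariates(spec), spec)
  panel <- emit_cesd_scores(sim$states, spec)
  sympt <- sim$states$state %in% c(2L, 3L, 5L)
  expect_true(all(panel$cesd_total[sympt] >= 12))
  expect_true(all(panel$cesd_total[!sympt] < 12))
  expect_true(all(panel$cesd_total >= 0 & panel$cesd_total <= 30))
  cls <- classify_panel(panel)
  expect_identical(cls$states$state, sim$states$state)
})

test_that("item-level emission sums back to the total and respects missingness", {
  spec <- cohort_spec(150, seed = 45)
  sim <- simulate_state_paths(generate_covariates(spec), spec)
  panel <- emit_cesd_scores(sim$states, spec, items = TRUE)
  items <- as.matrix(panel[paste0("item_", 1:10)])
  expect_false(anyNA(items))           # missing_item_rate 0 emits no gaps
  expect_identical(score_cesd(items), panel$cesd_total)

  spec2 <- cohort_spec(150, missing_item_rate = 0.08, seed = 45)
  panel2 <- emit_cesd_scores(sim$states, spec2, items = TRUE)
  items2 <- as.matrix(panel2[paste0("item_", 1:10)])
  expect_true(anyNA(items2))
  expect_true(all(rowSums(is.na(items2)) <= 2))  # never invalidates a wave
})

test_that("cohort files round-trip through the interchange CSVs", {
  dir <- withr::local_tempdir()
  spec <- cohort_spec(60, seed = 2)
  co <- generate_cohort(spec, dir = dir)
  cov2 <- read.csv(file.path(dir, "covariates.csv"))
  panel2 <- read.csv(file.path(dir, "panel.csv"))
  expect_equal(cov2, co$covariates, tolerance = 1e-12)
  expect_equal(panel2, co$panel, tolerance = 1e-12)
})
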