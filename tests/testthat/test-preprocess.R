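test_that("min-max normalization maps onto [0,1] and is shift-invariant", {
  expect_equal(minmax_normalize(c(0, 5, 10)), c(0, 0.5, 1))
  set.seed(51)
  for (i in 1:20) {
    x <- rnorm(50, sd = 10)
    z <- minmax_normalize(x)
    expect_equal(range(z), c(0, 1))
    expect_equal(minmax_normalize(x + 17.3), z, tolerance = 1e-12)
  }
  expect_error(minmax_normalize(rep(2, 5)), "degenerate")
  expect_error(minmax_normalize(c(1, NA, 3)), "finite")
})

test_that("normalization is idempotent", {
  x <- c(3, 9, 1, 7)
  expect_equal(minmax_normalize(minmax_normalize(x)), minmax_normalize(x),
               tolerance = 1e-14)
})

test_that("MAD rule flags gross outliers and respects symmetry", {
  r <- mad_outliers(c(1, 2, 1, 2, 100), k = 3)
  expect_identical(which(r$flags), 5L)
  # sign flip leaves flags unchanged
  r2 <- mad_outliers(-c(1, 2, 1, 2, 100), k = 3)
  expect_identical(r2$flags, r$flags)
  # constant data: nothing to flag
  expect_false(any(mad_outliers(rep(4, 6))$flags))
  # zero MAD on non-constant data falls back with a warning
  expect_warning(r3 <- mad_outliers(c(1, 1, 1, 1, 9)), "MAD is zero")
  expect_false(any(r3$flags))
})

test_that("winsorizing clips exactly to the MAD boundaries", {
  r <- mad_outliers(c(1, 2, 1, 2, 100), k = 3, action = "winsorize")
  expect_equal(r$values[5], r$bounds[2])
  expect_identical(r$values[1:4], c(1, 2, 1, 2))
  expect_true(all(r$values >= r$bounds[1] & r$values <= r$bounds[2]))
})

test_that("chained imputation is an identity on complete tables", {
  df <- data.frame(a = rnorm(10), b = rbinom(10, 1, 0.5))
  expect_identical(chained_impute(df), df)
})

test_that("columns over the missing-rate cap are an exclusion error", {
  df <- data.frame(a = c(rep(NA, 4), rnorm(6)), b = rnorm(10))
  expect_error(chained_impute(df, max_missing_rate = 0.30), "cap")
})

test_that("chained imputation beats mean imputation on correlated data", {
  set.seed(77)
  n <- 400
  z <- rnorm(n)
  df <- data.frame(a = z + rnorm(n, sd = 0.3),
                   b = 2 * z + rnorm(n, sd = 0.3),
                   c = as.numeric(z + rnorm(n, sd = 0.5) > 0))
  holdout <- sample(n, 40)
  truth <- df$a[holdout]
  df_miss <- df
  df_miss$a[holdout] <- NA
  done <- chained_impute(df_miss)
  rmse_chain <- sqrt(mean((done$a[holdout] - truth)^2))
  rmse_mean <- sqrt(mean((mean(df_miss$a, na.rm = TRUE) - truth)^2))
  expect_lt(rmse_chain, rmse_mean)
  # binary columns stay binary
  df_miss2 <- df
  df_miss2$c[holdout] <- NA
  expect_true(all(chained_impute(df_miss2)$c %in% 0:1))
  # deterministic
  expect_identical(chained_impute(df_miss), done)
})

test_that("interaction screening ranks a real signal above pure noise", {
  # cohort whose onset intensity depends strongly on a product term
  terms <- c("u", "v", "w", "z", "u_x_v", "w_x_z")
  tb <- stats::setNames(numeric(6), terms)
  tb["u_x_v"] <- 1.6
  zero <- stats::setNames(numeric(6), terms)
  spec <- cohort_spec(
    3000,
    covariates = list(
      list(name = "u", kind = "binary", prop = 0.5),
      list(name = "v", kind = "binary", prop = 0.5),
      list(name = "w", kind = "binary", prop = 0.5),
      list(name = "z", kind = "binary", prop = 0.5)),
    normalize = character(0),
    interactions = list(c("u", "v"), c("w", "z")),
    true_betas = list(onset = tb, persistence = zero,
                      remission = zero, relapse = zero),
    baseline_rates = c(`12` = 0.05),
    seed = 61)
  co <- generate_covariates(spec)
  sim <- simulate_state_paths(co, spec)
  ranked <- screen_interactions(list(c("u", "v"), c("w", "z")),
                                sim$states, co, normalize = character(0))
  expect_identical(ranked$term[1], "u_x_v")
  expect_gt(ranked$utility[1], ranked$utility[2])
})

test_that("screening deduplicates, caps at k, and validates names", {
  spec <- small_covariate_spec(300, seed = 6)
  co <- generate_covariates(spec)
  sim <- simulate_state_paths(co, spec)
  cands <- list(c("sex", "urban"), c("sex", "pain"), c("sex", "urban"))
  ranked <- screen_interactions(cands, sim$states, co, normalize = "age")
  expect_identical(nrow(ranked), 2L)
  top1 <- screen_interactions(cands, sim$states, co, k = 1, normalize = "age")
  expect_identical(nrow(top1), 1L)
  expect_error(screen_interactions(list(c("sex", "nope")), sim$states, co),
               "unknown covariate")
})

test_that("interaction columns are products of normalized factors", {
  co <- data.frame(subject_id = 1:5, a = c(10, 20, 30, 40, 50),
                   b = c(1, 0, 1, 0, 1))
  X <- build_model_matrix(co, normalize = "a", interactions = list(c("a", "b")))
  expect_equal(X[, "a_x_b"], minmax_normalize(co$a) * co$b)
  expect_true(all(X[, "a_x_b"] >= 0 & X[, "a_x_b"] <= 1))
})
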