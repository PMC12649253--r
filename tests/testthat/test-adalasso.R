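test_that("an unpenalized adaptive-Lasso fit reproduces the MLE", {
  spec <- small_covariate_spec(800, seed = 33)
  d <- build_demo_design(spec)
  init <- fit_initial(d)
  pen <- penalty_config(stats::setNames(rep(0, 4), names(init$beta)), init)
  fit <- fit_adaptive_lasso(d, pen, init)
  for (g in names(init$beta))
    expect_lt(max(abs(fit$beta[[g]] - init$beta[[g]])), 1e-5)
  expect_lte(fit$kkt_max_violation, 1e-5)
})

test_that("penalties at or above lambda_max zero every group", {
  spec <- small_covariate_spec(800, seed = 34)
  d <- build_demo_design(spec)
  init <- fit_initial(d)
  lmax <- lambda_max(d, init)
  fit <- fit_adaptive_lasso(d, penalty_config(lmax, init), init)
  expect_true(all(unlist(fit$beta) == 0))
  expect_lte(fit$kkt_max_violation, 1e-5)
  fit2 <- fit_adaptive_lasso(d, penalty_config(lmax * 10, init), init)
  expect_true(all(unlist(fit2$beta) == 0))
})

test_that("every fit carries a KKT certificate within tolerance", {
  spec <- small_covariate_spec(800, seed = 35)
  d <- build_demo_design(spec)
  init <- fit_initial(d)
  lmax <- lambda_max(d, init)
  for (frac in c(0.5, 0.1, 0.02)) {
    fit <- fit_adaptive_lasso(d, penalty_config(lmax * frac, init), init)
    expect_lte(fit$kkt_max_violation, 1e-5)
  }
})

test_that("the penalized objective never increases along the fit", {
  spec <- small_covariate_spec(600, seed = 36)
  d <- build_demo_design(spec)
  init <- fit_initial(d)
  lmax <- lambda_max(d, init)
  pen <- penalty_config(lmax * 0.1, init)
  fit <- fit_adaptive_lasso(d, pen, init)
  # the solution's objective cannot exceed the zero start's
  for (g in names(init$beta)) {
    w <- pen$weights[[g]]
    lam <- pen$lambda_by_group[[g]]
    at <- function(b) neg_log_partial_likelihood(
      stats::setNames(list(b), g), d, groups = g)$value + lam * sum(w * abs(b))
    expect_lte(at(fit$beta[[g]]), at(numeric(d$p)) + 1e-12)
    expect_lte(at(fit$beta[[g]]), at(init$beta[[g]]) + 1e-12)
  }
})

test_that("larger initial estimates are shrunk proportionally less", {
  spec <- small_covariate_spec(800, seed = 37)
  d <- build_demo_design(spec)
  init <- fit_initial(d)
  pen <- penalty_config(stats::setNames(rep(0, 4), names(init$beta)), init)
  for (g in names(init$beta)) {
    o <- order(abs(init$beta[[g]]))
    expect_true(all(diff(pen$weights[[g]][o]) <= 0))  # weight ordering inverted
    expect_true(all(is.finite(pen$weights[[g]])))
    expect_true(all(pen$weights[[g]] > 0))
  }
})

test_that("negative penalties are configuration errors", {
  spec <- small_covariate_spec(200, seed = 38)
  d <- build_demo_design(spec)
  init <- fit_initial(d)
  expect_error(penalty_config(c(onset = -1, persistence = 0, remission = 0,
                                relapse = 0), init), "non-negative")
  expect_error(tune_lambda(d, init, n_lambda = 0), "empty")
})

test_that("BIC tuning returns the audited path and selects within the grid", {
  spec <- small_covariate_spec(800, seed = 39)
  d <- build_demo_design(spec)
  init <- fit_initial(d)
  pen <- tune_lambda(d, init, n_lambda = 25)
  expect_s3_class(pen, "penalty_config")
  expect_true(all(c("group", "lambda", "df", "bic") %in% names(pen$path)))
  for (g in names(init$beta)) {
    pg <- pen$path[pen$path$group == g, ]
    expect_identical(nrow(pg), 25L)
    expect_identical(pg$df[1], 0)           # grid top fully zeroed
    expect_true(pen$lambda_by_group[[g]] %in% pg$lambda)
    expect_equal(pen$lambda_by_group[[g]],
                 pg$lambda[which.min(pg$bic)])
  }
  # deterministic given the design
  pen2 <- tune_lambda(d, init, n_lambda = 25)
  expect_identical(pen$lambda_by_group, pen2$lambda_by_group)
})

test_that("null groups select empty or near-empty active sets", {
  hits <- 0L
  for (s in 1:10) {
    spec <- small_covariate_spec(700, seed = 330 + s)
    spec$true_betas <- lapply(spec$true_betas, function(b) b * 0)
    d <- build_demo_design(spec)
    init <- suppressWarnings(fit_initial(d))
    pen <- tune_lambda(d, init)
    fit <- fit_adaptive_lasso(d, pen, init)
    if (length(fit$active$onset) <= 1L) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})

test_that("post-selection refit recovers strong effects with matching stars", {
  spec <- small_covariate_spec(2000, seed = 41)
  d <- build_demo_design(spec)
  init <- fit_initial(d)
  pen <- tune_lambda(d, init)
  fit <- fit_adaptive_lasso(d, pen, init)
  inf <- post_selection_inference(d, fit)
  expect_true(all(inf$sig == significance_stars(inf$p)))
  # the large onset sex effect (true 0.4) is selected and significant
  io <- inf[inf$group == "onset" & inf$term == "sex", ]
  expect_identical(nrow(io), 1L)
  expect_gt(abs(io$z), 1.96)
})
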