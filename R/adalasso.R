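#' Penalty configuration for the adaptive-Lasso fit
#'
#' Carries the per-group penalty levels and the adaptive weights
#' \eqn{w_r = 1 / \max(|\tilde\beta_r|, \epsilon)} built from an initial
#' unpenalized estimate.  The cap \eqn{\epsilon} keeps weights finite when
#' an initial coefficient is essentially zero; such coordinates carry a
#' very large weight and are effectively excluded, which is the adaptive
#' Lasso's intent.
#'
#' @param lambda_by_group Named non-negative vector, one penalty level per
#'   coefficient group.
#' @param initial An `initial_fit` supplying the weights.
#' @param eps Weight cap (default 1e-4).
#' @param grid Optional candidate lambda grid (kept for audit).
#' @param criterion Tuning criterion label.
#' @return Object of class `penalty_config`.
#' @export
penalty_config <- function(lambda_by_group, initial, eps = 1e-4,
                           grid = NULL, criterion = "bic") {
  stopifnot(inherits(initial, "initial_fit"))
  if (any(lambda_by_group < 0))
    stop("penalty levels must be non-negative", call. = FALSE)
  weights <- lapply(initial$beta, function(b) 1 / pmax(abs(b), eps))
  structure(list(lambda_by_group = lambda_by_group, weights = weights,
                 eps = eps, grid = grid, criterion = criterion),
            class = "penalty_config")
}

# exact penalized objective for one group
.pen_obj <- function(design, g, b, lambda, w) {
  v <- neg_log_partial_likelihood(stats::setNames(list(b), g), design,
                                  groups = g)
  list(value = v$value + lambda * sum(w * abs(b)),
       smooth = v$value, gradient = v$gradient[[g]], hessian = v$hessian[[g]])
}

# proximal-Newton adaptive lasso for one coefficient group:
# outer quadratic model + cyclic coordinate descent with soft-thresholding,
# backtracking on the exact penalized objective
.adalasso_group <- function(design, g, lambda, w, start = NULL,
                            tol = 1e-7, max_outer = 100) {
  p <- design$p
  b <- start %||% numeric(p)
  cur <- .pen_obj(design, g, b, lambda, w)
  for (outer in seq_len(max_outer)) {
    gr <- cur$gradient
    H <- cur$hessian
    hd <- diag(H)
    bt <- b
    delta <- numeric(p)          # bt - b
    Hdelta <- numeric(p)         # H %*% delta, maintained incrementally
    for (inner in seq_len(200)) {
      maxch <- 0
      for (r in seq_len(p)) {
        if (hd[r] < 1e-12) next
        z <- hd[r] * b[r] - gr[r] - (Hdelta[r] - hd[r] * delta[r])
        u <- sign(z) * max(abs(z) - lambda * w[r], 0) / hd[r]
        ch <- u - bt[r]
        if (ch != 0) {
          Hdelta <- Hdelta + H[, r] * ch
          delta[r] <- delta[r] + ch
          bt[r] <- u
          maxch <- max(maxch, abs(ch))
        }
      }
      if (maxch < tol * 0.1) break
    }
    dir <- bt - b
    if (max(abs(dir)) == 0) break
    t <- 1
    repeat {
      cand <- b + t * dir
      new <- .pen_obj(design, g, cand, lambda, w)
      if (is.finite(new$value) && new$value <= cur$value + 1e-12) break
      t <- t / 2
      if (t < 1e-10) { cand <- b; new <- cur; break }
    }
    moved <- max(abs(cand - b))
    b <- cand
    cur <- new
    if (moved < tol) break
  }
  # KKT certificate on the exact gradient
  kkt <- .kkt_violation(cur$gradient, b, lambda, w)
  list(beta = b, value = cur$value, smooth = cur$smooth, kkt = kkt)
}

.kkt_violation <- function(grad, b, lambda, w) {
  active <- b != 0
  v <- 0
  if (any(!active))
    v <- max(v, max(pmax(abs(grad[!active]) - lambda * w[!active], 0)))
  if (any(active))
    v <- max(v, max(abs(grad[active] + lambda * w[active] * sign(b[active]))))
  v
}

#' Fit the adaptive-Lasso penalized stacked multi-state Cox model
#'
#' Minimizes, per coefficient group,
#' \deqn{\frac{1}{n}\,\ell_{hg}(\beta) +
#'   \lambda_{hg} \sum_r |\beta_r| / |\tilde\beta_r|}
#' by proximal Newton: a quadratic model of the partial likelihood is
#' minimized by cyclic coordinate descent with soft-thresholding, with
#' backtracking on the exact penalized objective, until the largest
#' coefficient change falls below `tol`.  Every fit carries a subgradient
#' (KKT) certificate: zeroed coordinates must have score within the penalty
#' level, active ones must satisfy it with equality and sign.
#'
#' @param design A `stacked_design`.
#' @param penalty A [penalty_config()].
#' @param initial The `initial_fit` (for warm starts and weights).
#' @param tol Coordinate-change convergence tolerance (default 1e-7).
#' @return Object of class `penalized_fit`: `beta` (list per group),
#'   `active` (named list of active term indices), `objective` (total
#'   penalized value), `kkt_max_violation`, `lambda`.
#' @export
fit_adaptive_lasso <- function(design, penalty, initial, tol = 1e-7) {
  stopifnot(inherits(design, "stacked_design"),
            inherits(penalty, "penalty_config"),
            inherits(initial, "initial_fit"))
  groups <- names(design$structure$coefficient_groups)
  lam <- penalty$lambda_by_group
  if (!all(groups %in% names(lam)))
    stop("penalty must name every coefficient group", call. = FALSE)
  beta <- active <- stats::setNames(vector("list", length(groups)), groups)
  objective <- 0
  kkt <- 0
  for (g in groups) {
    res <- .adalasso_group(design, g, lam[[g]], penalty$weights[[g]],
                           start = if (lam[[g]] == 0) initial$beta[[g]],
                           tol = tol)
    beta[[g]] <- stats::setNames(res$beta, colnames(design$X))
    active[[g]] <- which(res$beta != 0)
    objective <- objective + res$value
    kkt <- max(kkt, res$kkt)
  }
  structure(list(beta = beta, active = active, objective = objective,
                 kkt_max_violation = kkt, lambda = lam),
            class = "penalized_fit")
}

#' @export
print.penalized_fit <- function(x, ...) {
  cat("Adaptive-Lasso stacked fit; penalized objective =",
      format(x$objective), "\n")
  for (g in names(x$beta)) {
    act <- x$active[[g]]
    cat("  ", g, " (lambda = ", format(x$lambda[[g]]), "): ",
        if (length(act)) paste(names(x$beta[[g]])[act], collapse = ", ")
        else "(empty)", "\n", sep = "")
  }
  cat("  max KKT violation:", format(x$kkt_max_violation), "\n")
  invisible(x)
}

#' Tune per-group penalty levels over a log-spaced grid by BIC
#'
#' For each coefficient group, builds a log-spaced grid from
#' \eqn{\lambda_{max}} (the smallest level that zeroes the whole group,
#' computed from the score at zero and the adaptive weights) down to
#' `lambda_min_ratio` times it, fits the regularization path with warm
#' starts, and selects the level minimizing
#' \deqn{\mathrm{BIC}(\lambda) = 2\,n\,\ell_{hg}(\hat\beta_\lambda)
#'   + \log(d_{hg}) \, |\mathrm{active}|,}
#' with \eqn{d_{hg}} the group's event count.  Ties prefer the larger
#' (sparser) level.  The whole path is returned for audit.
#'
#' @param design A `stacked_design`.
#' @param initial The `initial_fit` supplying adaptive weights.
#' @param n_lambda Grid size per group (default 50).
#' @param lambda_min_ratio Smallest grid point relative to
#'   \eqn{\lambda_{max}} (default 1e-3).
#' @param eps Adaptive-weight cap passed to [penalty_config()].
#' @return A `penalty_config` with the selected `lambda_by_group` and a
#'   `path` attribute: data frame (`group`, `lambda`, `df`, `bic`,
#'   `neg2loglik`) for every grid point.
#' @export
tune_lambda <- function(design, initial, n_lambda = 50,
                        lambda_min_ratio = 1e-3, eps = 1e-4) {
  stopifnot(inherits(design, "stacked_design"), inherits(initial, "initial_fit"))
  if (n_lambda < 1) stop("empty lambda grid", call. = FALSE)
  groups <- names(design$structure$coefficient_groups)
  d <- .group_events(design)
  weights <- lapply(initial$beta, function(b) 1 / pmax(abs(b), eps))
  sel <- stats::setNames(numeric(length(groups)), groups)
  path <- list()
  for (g in groups) {
    w <- weights[[g]]
    g0 <- neg_log_partial_likelihood(numeric(design$p), design,
                                     groups = g)$gradient[[g]]
    lmax <- max(abs(g0) / w)
    if (!is.finite(lmax) || lmax <= 0 || is.na(d[g]) || d[g] < 2) {
      sel[g] <- if (is.finite(lmax) && lmax > 0) lmax else 1
      next
    }
    # a hair of slack at the top so float rounding cannot un-zero the group
    grid <- exp(seq(log(lmax * (1 + 1e-6)), log(lmax * lambda_min_ratio),
                    length.out = n_lambda))
    start <- numeric(design$p)
    bics <- n2ll <- dfs <- numeric(n_lambda)
    for (k in seq_len(n_lambda)) {
      res <- .adalasso_group(design, g, grid[k], w, start = start)
      start <- res$beta
      dfs[k] <- sum(res$beta != 0)
      n2ll[k] <- 2 * design$n * res$smooth
      bics[k] <- n2ll[k] + log(d[g]) * dfs[k]
    }
    sel[g] <- grid[which.min(bics)]   # which.min takes the first = largest
    path[[g]] <- data.frame(group = g, lambda = grid, df = dfs,
                            bic = bics, neg2loglik = n2ll)
  }
  cfg <- penalty_config(sel, initial, eps = eps, criterion = "bic")
  cfg$path <- do.call(rbind, path)
  rownames(cfg$path) <- NULL
  cfg
}

#' Largest penalty level that zeroes a coefficient group
#'
#' @param design A `stacked_design`.
#' @param initial The `initial_fit` (for adaptive weights).
#' @param eps Weight cap.
#' @return Named vector of \eqn{\lambda_{max}} per group.
#' @export
lambda_max <- function(design, initial, eps = 1e-4) {
  groups <- names(design$structure$coefficient_groups)
  out <- stats::setNames(numeric(length(groups)), groups)
  for (g in groups) {
    w <- 1 / pmax(abs(initial$beta[[g]]), eps)
    g0 <- neg_log_partial_likelihood(numeric(design$p), design,
                                     groups = g)$gradient[[g]]
    out[g] <- max(abs(g0) / w)
  }
  out
}

#' Significance marks used in the effect tables
#'
#' @param p Numeric p-values.
#' @return `"**"` for p <= 0.001, `"*"` for 0.001 < p <= 0.05, else `""`.
#' @export
significance_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p <= 0.001, "**", ifelse(p <= 0.05, "*", "")))
}

#' Post-selection Wald inference by unpenalized refit on the active set
#'
#' Refits the partial likelihood of each coefficient group restricted to
#' the coordinates selected by the adaptive Lasso, and reports standard
#' errors from the inverse observed information of the refit, two-sided
#' Wald p-values and significance marks.  Coefficients shrunk to zero get
#' no inference (blank columns), matching refit-style reporting.
#'
#' @param design A `stacked_design`.
#' @param fit A `penalized_fit` (or a named list of active index vectors).
#' @return Object of class `post_selection`: data frame with columns
#'   `group`, `term`, `est`, `se`, `z`, `p`, `sig` for active
#'   coefficients.
#' @export
post_selection_inference <- function(design, fit) {
  active <- if (inherits(fit, "penalized_fit")) fit$active else fit
  groups <- names(design$structure$coefficient_groups)
  rows <- list()
  for (g in groups) {
    idx <- active[[g]]
    if (!length(idx)) next
    sub <- design
    sub$X <- design$X[, idx, drop = FALSE]
    sub$p <- length(idx)
    res <- .newton_group(sub, g)
    if (!res$converged) {
      if (res$gnorm < 1e-5)  # flat likelihood: numerically at the optimum
        warning("post-selection refit for group '", g,
                "' stopped with max |grad| = ", format(res$gnorm))
      else
        stop("post-selection refit did not converge for group '", g,
             "' (max |grad| = ", format(res$gnorm), ")", call. = FALSE)
    }
    H <- neg_log_partial_likelihood(stats::setNames(list(res$beta), g),
                                    sub, groups = g)$hessian[[g]]
    se <- sqrt(diag(solve(design$n * H)))
    z <- res$beta / se
    p <- 2 * stats::pnorm(-abs(z))
    rows[[g]] <- data.frame(group = g, term = colnames(sub$X),
                            est = res$beta, se = se, z = z, p = p,
                            sig = significance_stars(p))
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(group = character(), term = character(), est = numeric(),
                  se = numeric(), z = numeric(), p = numeric(),
                  sig = character())
  rownames(out) <- NULL
  structure(out, class = c("post_selection", "data.frame"))
}
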