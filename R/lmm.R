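#' Grouped design for a linear mixed model
#'
#' Assembles the response vector, fixed-effects design matrix `X` and
#' random-effects design matrix `Z` of a two-level model, with rows grouped by
#' a cluster identifier (here: participants). An intercept column is prepended
#' to both `X` and `Z` unless disabled.
#'
#' @param data A data frame containing all referenced columns.
#' @param response Name of the response column.
#' @param fixed Character vector of fixed-effect columns (may be empty).
#' @param random Character vector of random-slope columns (may be empty;
#'   the random intercept comes from `intercept`).
#' @param group Name of the grouping (cluster id) column.
#' @param intercept Logical; include an intercept column in `X`. Default
#'   `TRUE`.
#' @param random_intercept Logical; include an intercept column in `Z`
#'   (set both this `FALSE` and `random = character()` for a purely fixed
#'   design with `q = 0`). Default `TRUE`.
#' @return An object of class `grouped_design`: list with `y`, `X`, `Z`,
#'   `group` (factor) and dimensions `p`, `q`.
#' @export
grouped_design <- function(data, response, fixed = character(),
                           random = character(), group, intercept = TRUE,
                           random_intercept = TRUE) {
  stopifnot(is.data.frame(data))
  cols <- unique(c(response, fixed, random, group))
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols))
    stop("columns not found in data: ", paste(missing_cols, collapse = ", "))
  used <- unique(c(response, fixed, random))
  cc <- stats::complete.cases(data[used])
  if (!all(cc))
    stop("missing values in model columns at row(s) ",
         paste(utils::head(which(!cc), 5L), collapse = ", "))
  y <- as.numeric(data[[response]])
  n <- length(y)
  build_block <- function(cols, with_intercept) {
    parts <- list()
    if (with_intercept) parts[["(Intercept)"]] <- rep(1, n)
    for (cl in cols) parts[[cl]] <- as.numeric(data[[cl]])
    if (!length(parts)) return(matrix(0, n, 0))
    M <- do.call(cbind, parts)
    storage.mode(M) <- "double"
    M
  }
  X <- build_block(fixed, intercept)
  Z <- build_block(random, random_intercept)
  if (ncol(X) == 0L) stop("fixed-effects design is empty")
  grp <- droplevels(factor(data[[group]]))
  structure(
    list(y = y, X = X, Z = Z, group = grp, p = ncol(X), q = ncol(Z),
         response = response),
    class = "grouped_design")
}

#' @export
print.grouped_design <- function(x, ...) {
  cat("Grouped LMM design: ", length(x$y), " rows, ",
      nlevels(x$group), " groups\n", sep = "")
  cat("  fixed  (p = ", x$p, "): ", paste(colnames(x$X), collapse = ", "),
      "\n", sep = "")
  cat("  random (q = ", x$q, "): ", paste(colnames(x$Z), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# Per-group cross-products of [X, Z, y], stored as a (p+q+1)^3 x J array.
.design_cube <- function(design) {
  idx <- split(seq_along(design$y), design$group)
  d <- design$p + design$q + 1L
  J <- length(idx)
  C <- array(0, dim = c(d, d, J))
  for (j in seq_len(J)) {
    rows <- idx[[j]]
    W <- cbind(design$X[rows, , drop = FALSE],
               design$Z[rows, , drop = FALSE], design$y[rows])
    C[, , j] <- crossprod(W)
  }
  list(C = C, n = vapply(idx, length, 1L), groups = names(idx))
}

#' Grouped marginal log-likelihood
#'
#' Evaluates the exact marginal Gaussian log-likelihood
#' \deqn{\sum_j \log \phi(y_j;\; X_j\beta,\; Z_j \Sigma Z_j' + \sigma^2 I)}
#' including all normalizing constants, by dense per-group Cholesky
#' factorization. This is deliberately a direct evaluation, independent of
#' the profiled code path used by [fit_ml()], and serves as its reference.
#'
#' @param design A [grouped_design()].
#' @param Sigma Random-effects covariance matrix (q x q, PSD); may be a
#'   0 x 0 matrix when the design has no random part.
#' @param sigma2 Residual variance, > 0.
#' @param beta Fixed-effects vector, length p.
#' @return The scalar log-likelihood.
#' @export
marginal_loglik <- function(design, Sigma, sigma2, beta) {
  stopifnot(inherits(design, "grouped_design"))
  Sigma <- as.matrix(Sigma)
  p <- design$p; q <- design$q
  if (length(beta) != p) stop("'beta' must have length ", p)
  if (!all(dim(Sigma) == c(q, q)))
    stop("'Sigma' must be ", q, " x ", q)
  if (!is.finite(sigma2) || sigma2 <= 0) stop("'sigma2' must be positive")
  r <- design$y - as.numeric(design$X %*% beta)
  idx <- split(seq_along(design$y), design$group)
  ll <- 0
  for (j in seq_along(idx)) {
    rows <- idx[[j]]
    nj <- length(rows)
    Zj <- design$Z[rows, , drop = FALSE]
    V <- diag(sigma2, nj) + if (q > 0) Zj %*% Sigma %*% t(Zj) else 0
    R <- tryCatch(chol(V), error = function(e)
      stop("singular covariance for group '", names(idx)[j], "'",
           call. = FALSE))
    w <- backsolve(R, r[rows], transpose = TRUE)
    ll <- ll - 0.5 * (nj * log(2 * pi) + 2 * sum(log(diag(R))) + sum(w^2))
  }
  ll
}

# theta bookkeeping: column-major lower triangle, diagonal log-scale.
.theta_diag_idx <- function(q) {
  if (q == 0L) return(integer())
  pos <- integer(q); k <- 1L
  for (j in seq_len(q)) {
    pos[j] <- k
    k <- k + (q - j + 1L)
  }
  pos
}

.theta_to_G <- function(theta, q) {
  L <- matrix(0, q, q)
  L[lower.tri(L, diag = TRUE)] <- theta
  diag(L) <- exp(diag(L))
  tcrossprod(L)
}

#' Fit a linear mixed model by maximum likelihood
#'
#' Maximizes the marginal likelihood of a random-intercept-random-slope model
#' with an unstructured random-effects covariance. The fixed effects are
#' profiled out by generalized least squares and the residual variance in
#' closed form, so optimization runs only over the log-Cholesky factor of the
#' scaled covariance `Sigma / sigma2` -- a low-dimensional, unconstrained
#' parameterization that keeps `Sigma` positive semidefinite by construction.
#' A quasi-Newton search (`nlminb`) is run from three deterministic starting
#' scales (unit, small, large) to guard against boundary optima; the best
#' optimum is kept.
#'
#' Wald inference uses the GLS covariance of the fixed effects at the optimum
#' with a standard-normal reference (appropriate here, where residual degrees
#' of freedom are in the thousands): `ci95 = beta +/- 1.96 se`. The AIC is
#' `2 k - 2 loglik` with `k = p + q(q+1)/2 + 1` counting fixed effects,
#' covariance parameters and the residual variance; the full `-(N/2) log 2pi`
#' constant is included in the log-likelihood.
#'
#' @param design A [grouped_design()] with at least one random term.
#' @param init Optional numeric starting value for the log-Cholesky parameter
#'   vector (length `q(q+1)/2`), tried in addition to the default starts.
#' @param tol Convergence tolerance passed to the optimizer. Default `1e-6`.
#' @return An object of class `lmm_ml` with elements `beta`, `se`, `z_stat`,
#'   `p_value`, `ci95_low`, `ci95_high`, `Sigma`, `sigma2`, `loglik`,
#'   `k_params`, `aic`, `converged`, `boundary`, `blups`, `vcov_beta`,
#'   `theta`, `n_obs`, `n_groups` and the `design`.
#' @seealso [marginal_loglik()], [blup()], [wald_inference()]
#' @export
fit_ml <- function(design, init = NULL, tol = 1e-6) {
  stopifnot(inherits(design, "grouped_design"))
  p <- design$p; q <- design$q
  N <- length(design$y)
  J <- nlevels(design$group)
  if (q < 1L) stop("fit_ml() requires at least a random intercept")
  if (J < 2L) stop("fit_ml() requires at least 2 groups")
  if (N <= p + q) stop("too few rows (", N, ") for p + q = ", p + q)
  qr_x <- qr(design$X)
  if (qr_x$rank < p) {
    bad <- colnames(design$X)[qr_x$pivot[(qr_x$rank + 1L):p]]
    stop("fixed-effects design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  cube <- .design_cube(design)
  m <- as.integer(q * (q + 1L) / 2L)
  di <- .theta_diag_idx(q)
  # objective and analytic gradient share one C++ evaluation per point
  cache <- new.env(parent = emptyenv())
  evaluate <- function(theta) {
    if (!identical(cache$theta, theta)) {
      cache$res <- .profiled_nll_grad_cpp(theta, cube$C, cube$n, p, q)
      cache$theta <- theta
    }
    cache$res
  }
  objective <- function(theta) {
    nll <- evaluate(theta)$nll
    if (!is.finite(nll)) 1e10 else nll
  }
  gradient <- function(theta) evaluate(theta)$grad
  lower <- rep(-30, m); upper <- rep(30, m)
  lower[di] <- -12; upper[di] <- 6
  mk_start <- function(scale) {
    theta <- rep(0, m); theta[di] <- log(scale); theta
  }
  starts <- list(identity = mk_start(1), small = mk_start(0.1),
                 large = mk_start(3))
  if (!is.null(init)) {
    stopifnot(length(init) == m)
    starts <- c(list(init = init), starts)
  }
  runs <- lapply(starts, function(s)
    stats::nlminb(s, objective, gradient = gradient,
                  lower = lower, upper = upper,
                  control = list(iter.max = 500L, eval.max = 2000L,
                                 rel.tol = 1e-10)))
  vals <- vapply(runs, function(r) r$objective, 0)
  best <- runs[[which.min(vals)]]
  converged <- best$convergence == 0L
  if (!converged)
    warning("ML optimization did not converge: ", best$message)
  fit_q <- .profiled_fit_cpp(best$par, cube$C, cube$n, p, q)
  sigma2 <- fit_q$sigma2
  Sigma <- sigma2 * fit_q$G
  re_names <- colnames(design$Z)
  dimnames(Sigma) <- list(re_names, re_names)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  boundary <- max(ev) > 0 && min(ev) < 1e-8 * max(ev)
  if (boundary)
    warning("random-effects covariance estimate is near the boundary ",
            "(a variance component is essentially zero)")
  beta <- stats::setNames(as.numeric(fit_q$beta), colnames(design$X))
  vcov_beta <- sigma2 * solve(fit_q$A)
  dimnames(vcov_beta) <- list(names(beta), names(beta))
  blups <- fit_q$blups
  dimnames(blups) <- list(cube$groups, re_names)
  k <- p + m + 1L
  fit <- structure(
    list(beta = beta, Sigma = Sigma, sigma2 = sigma2,
         loglik = fit_q$loglik, k_params = k,
         aic = 2 * k - 2 * fit_q$loglik,
         converged = converged, boundary = boundary,
         blups = blups, vcov_beta = vcov_beta,
         theta = best$par, n_obs = N, n_groups = J,
         design = design, call = match.call()),
    class = "lmm_ml")
  wald_inference(fit)
}

#' Wald inference for fixed effects
#'
#' Fills (or refreshes) the standard errors, z statistics, two-sided normal
#' p values and 95% confidence bounds (`beta +/- 1.96 se`) of a fitted model
#' from the GLS covariance of the fixed effects.
#'
#' @param fit An `lmm_ml` fit.
#' @return The fit with `se`, `z_stat`, `p_value`, `ci95_low`, `ci95_high`.
#' @export
wald_inference <- function(fit) {
  stopifnot(inherits(fit, "lmm_ml"))
  d <- diag(fit$vcov_beta)
  if (any(!is.finite(d)) || any(d <= 0))
    stop("information matrix is not positive definite")
  fit$se <- sqrt(d)
  fit$z_stat <- fit$beta / fit$se
  fit$p_value <- 2 * stats::pnorm(-abs(fit$z_stat))
  fit$ci95_low <- fit$beta - 1.96 * fit$se
  fit$ci95_high <- fit$beta + 1.96 * fit$se
  fit
}

#' Akaike information criterion of a fit
#'
#' `2 k - 2 loglik`, with `k` the number of estimated parameters (fixed
#' effects + covariance parameters + residual variance).
#'
#' @param fit An `lmm_ml` fit.
#' @return The scalar AIC.
#' @export
aic <- function(fit) {
  stopifnot(inherits(fit, "lmm_ml"))
  2 * fit$k_params - 2 * fit$loglik
}

#' Best linear unbiased predictions of the random effects
#'
#' Per-group predictions \eqn{\hat b_j = \Sigma Z_j' V_j^{-1} (y_j - X_j\beta)}
#' with \eqn{V_j = Z_j \Sigma Z_j' + \sigma^2 I}, evaluated at the ML
#' estimates.
#'
#' @param fit An `lmm_ml` fit.
#' @param design Optional [grouped_design()]; defaults to the design the model
#'   was fitted to.
#' @return A groups x q matrix of predicted random-effect deviations.
#' @export
blup <- function(fit, design = fit$design) {
  stopifnot(inherits(fit, "lmm_ml"))
  if (identical(design, fit$design)) return(fit$blups)
  Sigma <- fit$Sigma; sigma2 <- fit$sigma2; beta <- fit$beta
  idx <- split(seq_along(design$y), design$group)
  B <- matrix(0, length(idx), design$q,
              dimnames = list(names(idx), colnames(design$Z)))
  r <- design$y - as.numeric(design$X %*% beta)
  for (j in seq_along(idx)) {
    rows <- idx[[j]]
    Zj <- design$Z[rows, , drop = FALSE]
    V <- Zj %*% Sigma %*% t(Zj) + diag(sigma2, length(rows))
    B[j, ] <- as.numeric(Sigma %*% t(Zj) %*% solve(V, r[rows]))
  }
  B
}

#' @export
print.lmm_ml <- function(x, digits = 3, ...) {
  cat("Linear mixed model fit by ML (", x$n_obs, " obs, ",
      x$n_groups, " groups)\n", sep = "")
  cat("  logLik ", format(x$loglik, digits = 8), ",  AIC ",
      format(x$aic, digits = 8), ",  k = ", x$k_params,
      if (!x$converged) "  [NOT CONVERGED]", "\n\n", sep = "")
  tab <- coef_table(x)
  tab[-1] <- lapply(tab[-1], round, digits = digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.lmm_ml <- function(object, ...) {
  structure(list(fit = object), class = "summary.lmm_ml")
}

#' @export
print.summary.lmm_ml <- function(x, digits = 3, ...) {
  fit <- x$fit
  print(fit, digits = digits)
  re_sd <- sqrt(diag(fit$Sigma))
  cat("\nRandom effects (SD):\n")
  print(round(re_sd, digits))
  if (length(re_sd) > 1L) {
    cat("Correlations:\n")
    print(round(stats::cov2cor(fit$Sigma), digits))
  }
  cat("Residual SD:", round(sqrt(fit$sigma2), digits), "\n")
  invisible(x)
}

#' Coefficient table of a fitted model
#'
#' @param fit An `lmm_ml` fit.
#' @return A data frame with columns `term`, `b`, `se`, `z`, `p`, `ci_low`,
#'   `ci_high`.
#' @export
coef_table <- function(fit) {
  stopifnot(inherits(fit, "lmm_ml"))
  data.frame(term = names(fit$beta), b = unname(fit$beta),
             se = unname(fit$se), z = unname(fit$z_stat),
             p = unname(fit$p_value), ci_low = unname(fit$ci95_low),
             ci_high = unname(fit$ci95_high))
}

#' @export
coef.lmm_ml <- function(object, ...) object$beta

#' @export
vcov.lmm_ml <- function(object, ...) object$vcov_beta

#' @export
logLik.lmm_ml <- function(object, ...) {
  structure(object$loglik, df = object$k_params, nobs = object$n_obs,
            class = "logLik")
}

#' @export
confint.lmm_ml <- function(object, parm, level = 0.95, ...) {
  ci <- cbind(object$ci95_low, object$ci95_high)
  dimnames(ci) <- list(names(object$beta), c("2.5 %", "97.5 %"))
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
fitted.lmm_ml <- function(object, type = c("conditional", "marginal"), ...) {
  type <- match.arg(type)
  d <- object$design
  mu <- as.numeric(d$X %*% object$beta)
  if (type == "marginal") return(mu)
  bl <- object$blups[as.integer(d$group), , drop = FALSE]
  mu + rowSums(d$Z * bl)
}

#' @export
residuals.lmm_ml <- function(object, type = c("conditional", "marginal"),
                             ...) {
  object$design$y - fitted(object, type = match.arg(type))
}

#' @export
simulate.lmm_ml <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  d <- object$design
  mu <- as.numeric(d$X %*% object$beta)
  Rs <- chol(object$Sigma + diag(1e-12, d$q))
  out <- replicate(nsim, {
    b <- matrix(stats::rnorm(object$n_groups * d$q), object$n_groups) %*% Rs
    mu + rowSums(d$Z * b[as.integer(d$group), , drop = FALSE]) +
      stats::rnorm(length(mu), 0, sqrt(object$sigma2))
  })
  as.data.frame(out)
}

#' Serialize a fit to JSON and CSV
#'
#' Writes `<stem>.json` (full fit: estimates, covariances, likelihood,
#' convergence) and `<stem>_coefficients.csv` (flat table: term, b, se, z, p,
#' ci_low, ci_high).
#'
#' @param fit An `lmm_ml` fit.
#' @param stem Output path without extension.
#' @return Invisibly, the two paths written.
#' @export
write_fit <- function(fit, stem) {
  stopifnot(inherits(fit, "lmm_ml"))
  json_path <- paste0(stem, ".json")
  csv_path <- paste0(stem, "_coefficients.csv")
  payload <- list(
    beta = as.list(fit$beta), se = as.list(fit$se),
    z = as.list(fit$z_stat), p = as.list(fit$p_value),
    ci95_low = as.list(fit$ci95_low), ci95_high = as.list(fit$ci95_high),
    Sigma = fit$Sigma, sigma2 = fit$sigma2, loglik = fit$loglik,
    k_params = fit$k_params, aic = fit$aic, converged = fit$converged,
    boundary = fit$boundary, n_obs = fit$n_obs, n_groups = fit$n_groups)
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  utils::write.csv(coef_table(fit), csv_path, row.names = FALSE)
  invisible(c(json = json_path, csv = csv_path))
}
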