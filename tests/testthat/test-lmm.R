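# Maximum-likelihood estimation core: likelihood evaluation, profiled
# optimization, Wald inference, BLUPs.

test_that("marginal likelihood matches direct MVN evaluation on random draws", {
  set.seed(101)
  for (i in 1:25) {
    design <- random_tiny_design()
    prm <- random_params(design$p, design$q)
    expect_equal(marginal_loglik(design, prm$Sigma, prm$sigma2, prm$beta),
                 oracle_loglik(design, prm$Sigma, prm$sigma2, prm$beta),
                 tolerance = 1e-10)
  }
})

test_that("marginal likelihood limits: perfect fit and independence", {
  d <- data.frame(g = rep(c("a", "b"), each = 3), x = c(1, 2, 3, 4, 5, 6))
  d$y <- 2 + 0.5 * d$x
  des <- grouped_design(d, "y", fixed = "x", random = character(),
                        group = "g", random_intercept = FALSE)
  expect_identical(des$q, 0L)
  # zero residuals, unit variance: only the normalizing constant remains
  expect_equal(marginal_loglik(des, matrix(0, 0, 0), 1, c(2, 0.5)),
               -(6 / 2) * log(2 * pi))
  # Sigma = 0 reduces to independent normal densities
  des2 <- grouped_design(d, "y", fixed = "x", random = character(),
                         group = "g")
  set.seed(1); des2$y <- des2$y + rnorm(6)
  beta <- c(2, 0.5)
  expect_equal(marginal_loglik(des2, matrix(0, 1, 1), 1.3, beta),
               sum(dnorm(des2$y, des2$X %*% beta, sqrt(1.3), log = TRUE)))
})

test_that("fit collapses towards OLS when there is no grouping structure", {
  set.seed(7)
  n <- 2000
  d <- data.frame(g = rep(sprintf("g%03d", 1:200), each = 10),
                  x = rnorm(n))
  d$y <- 1 + 0.5 * d$x + rnorm(n)  # no random effects in truth
  des <- grouped_design(d, "y", fixed = "x", random = "x", group = "g")
  fit <- suppressWarnings(fit_ml(des))
  ols <- lm(y ~ x, data = d)
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 2e-2)
  expect_lt(max(abs(fit$Sigma)), 5e-2)
})

test_that("balanced one-way layout reproduces the closed-form ML estimators", {
  set.seed(42)
  J <- 60; n <- 8
  g <- rep(sprintf("g%02d", 1:J), each = n)
  y <- rep(rnorm(J, sd = 0.9), each = n) + rnorm(J * n, sd = 0.7) + 2
  ora <- balanced_oneway_ml(y, g)
  expect_true(ora$interior)
  des <- grouped_design(data.frame(g = g, y = y), "y", group = "g")
  fit <- fit_ml(des)
  expect_equal(unname(coef(fit)), ora$mu, tolerance = 1e-6)
  expect_equal(fit$sigma2, ora$sigma_e2, tolerance = 1e-6)
  expect_equal(fit$Sigma[1, 1], ora$sigma_b2, tolerance = 1e-6)
  expect_equal(fit$loglik, ora$loglik, tolerance = 1e-8)
})

test_that("fit agrees with an independent ML mixed-model implementation", {
  requireNamespace("lme4", quietly = TRUE)
  sim <- generate(small_config(n_participants = 120), seed = 9)
  prep <- prepare_daily(sim$states, sim$participants)
  fit <- dgcm(prep$daily, model = "1d")
  m <- lme4::lmer(
    wb_z ~ post_event + level + (1 + post_event + level | participant_id),
    data = prep$daily, REML = FALSE,
    control = lme4::lmerControl(check.conv.singular = "ignore"))
  expect_equal(fit$loglik, as.numeric(stats::logLik(m)), tolerance = 1e-6)
  expect_equal(unname(coef(fit)), unname(lme4::fixef(m)), tolerance = 1e-3)
  expect_equal(unname(fit$se),
               unname(sqrt(diag(as.matrix(stats::vcov(m))))),
               tolerance = 1e-2)
})

test_that("the reported optimum is a stationary point of the likelihood", {
  sim <- generate(small_config(), seed = 13)
  prep <- prepare_daily(sim$states, sim$participants)
  fit <- dgcm(prep$daily, model = "1b")
  expect_true(fit$converged)
  # the profiled C++ path and the dense R evaluation agree at the optimum
  expect_equal(marginal_loglik(fit$design, fit$Sigma, fit$sigma2, fit$beta),
               fit$loglik, tolerance = 1e-8)
  # no coordinate perturbation of theta improves the profiled likelihood
  cube <- dgcm:::.design_cube(fit$design)
  ll_hat <- dgcm:::.profiled_ll_cpp(fit$theta, cube$C, cube$n,
                                    fit$design$p, fit$design$q)
  h <- 1e-4
  for (i in seq_along(fit$theta)) {
    for (s in c(-1, 1)) {
      th <- fit$theta; th[i] <- th[i] + s * h
      ll <- dgcm:::.profiled_ll_cpp(th, cube$C, cube$n,
                                    fit$design$p, fit$design$q)
      expect_lte(ll, ll_hat + 1e-6 * (1 + abs(ll_hat)))
    }
  }
})

test_that("analytic gradient of the profiled deviance matches finite differences", {
  sim <- generate(small_config(n_participants = 30), seed = 17)
  prep <- prepare_daily(sim$states, sim$participants)
  des <- build_design(prep$daily, "2c")
  cube <- dgcm:::.design_cube(des)
  set.seed(2)
  theta <- rnorm(6, sd = 0.3)
  res <- dgcm:::.profiled_nll_grad_cpp(theta, cube$C, cube$n, des$p, des$q)
  h <- 1e-6
  fd <- vapply(seq_along(theta), function(i) {
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    (dgcm:::.profiled_ll_cpp(tm, cube$C, cube$n, des$p, des$q) -
       dgcm:::.profiled_ll_cpp(tp, cube$C, cube$n, des$p, des$q)) / (2 * h)
  }, 0)
  expect_lt(max(abs(res$grad - fd)), 1e-4 * (1 + max(abs(fd))))
  expect_equal(res$nll,
               -dgcm:::.profiled_ll_cpp(theta, cube$C, cube$n, des$p,
                                        des$q))
})

test_that("reordering rows or groups leaves the fit unchanged", {
  sim <- generate(small_config(), seed = 23)
  prep <- prepare_daily(sim$states, sim$participants)
  des <- build_design(prep$daily, "1d")
  fit <- dgcm(prep$daily, model = "1d")
  set.seed(3)
  shuffled <- prep$daily[sample.int(nrow(prep$daily)), ]
  des2 <- grouped_design(shuffled[order(rev(shuffled$participant_id)), ],
                         "wb_z", fixed = c("post_event", "level"),
                         random = c("post_event", "level"),
                         group = "participant_id")
  cube1 <- dgcm:::.design_cube(des)
  cube2 <- dgcm:::.design_cube(des2)
  ll1 <- dgcm:::.profiled_ll_cpp(fit$theta, cube1$C, cube1$n, des$p, des$q)
  ll2 <- dgcm:::.profiled_ll_cpp(fit$theta, cube2$C, cube2$n, des2$p,
                                 des2$q)
  expect_equal(ll1, ll2, tolerance = 1e-8)
  fit2 <- fit_ml(des2)
  expect_equal(fit2$loglik, fit$loglik, tolerance = 1e-6)
  expect_equal(fit2$beta, fit$beta, tolerance = 1e-5)
  expect_equal(fit2$Sigma, fit$Sigma, tolerance = 1e-4)
})

test_that("Wald inference: textbook standard error, normal reference, oracle vcov", {
  # single-coefficient orthonormal design with known variance
  set.seed(4)
  n <- 500
  d <- data.frame(g = rep(sprintf("g%d", 1:50), each = 10), y = rnorm(n))
  des <- grouped_design(d, "y", group = "g")
  fit <- suppressWarnings(fit_ml(des))
  expect_equal(fit$se[["(Intercept)"]], sqrt(fit$sigma2 / n),
               tolerance = 0.05 * sqrt(fit$sigma2 / n))
  # z = 1.96 maps to p ~ 0.05 two-sided
  expect_equal(2 * pnorm(-1.96), 0.05, tolerance = 1e-3)
  expect_equal(fit$p_value[[1]],
               2 * pnorm(-abs(fit$beta[[1]] / fit$se[[1]])))
  expect_equal(fit$ci95_low, fit$beta - 1.96 * fit$se)
  expect_equal(fit$ci95_high, fit$beta + 1.96 * fit$se)
  # grouped toy design: se matches the brute-force GLS information
  sim <- generate(small_config(n_participants = 25), seed = 5)
  prep <- prepare_daily(sim$states, sim$participants)
  f2 <- dgcm(prep$daily, model = "1b")
  idx <- split(seq_along(f2$design$y), f2$design$group)
  info <- matrix(0, f2$design$p, f2$design$p)
  for (rows in idx) {
    Zj <- f2$design$Z[rows, , drop = FALSE]
    Xj <- f2$design$X[rows, , drop = FALSE]
    Vj <- Zj %*% f2$Sigma %*% t(Zj) + diag(f2$sigma2, length(rows))
    info <- info + t(Xj) %*% solve(Vj, Xj)
  }
  expect_equal(unname(f2$se), unname(sqrt(diag(solve(info)))),
               tolerance = 1e-6)
})

test_that("AIC bookkeeping: definition and parameter counts", {
  sim <- generate(small_config(), seed = 27)
  prep <- prepare_daily(sim$states, sim$participants)
  fit <- dgcm(prep$daily)                       # 2d: p = 4, q = 4
  expect_identical(fit$k_params, 4L + 10L + 1L)
  expect_equal(aic(fit), 2 * 15 - 2 * fit$loglik)
  expect_equal(aic(fit), fit$aic)
  expect_equal(AIC(fit), fit$aic)               # via the logLik method
})

test_that("BLUPs match the direct shrinkage formula and its limits", {
  sim <- generate(small_config(n_participants = 20), seed = 29)
  prep <- prepare_daily(sim$states, sim$participants)
  fit <- dgcm(prep$daily, model = "1b")
  # direct evaluation of Sigma Z' V^{-1} (y - X beta) per group
  idx <- split(seq_along(fit$design$y), fit$design$group)
  for (j in seq_along(idx)) {
    rows <- idx[[j]]
    Zj <- fit$design$Z[rows, , drop = FALSE]
    Vj <- Zj %*% fit$Sigma %*% t(Zj) + diag(fit$sigma2, length(rows))
    r <- fit$design$y[rows] - fit$design$X[rows, , drop = FALSE] %*% fit$beta
    expect_equal(unname(fit$blups[j, ]),
                 as.numeric(fit$Sigma %*% t(Zj) %*% solve(Vj, r)),
                 tolerance = 1e-8)
  }
  # Sigma = 0: complete shrinkage to zero
  f0 <- fit
  f0$Sigma[] <- 0
  des0 <- fit$design
  attr(des0, "copy") <- TRUE  # defeat the cached-design shortcut
  expect_true(all(blup(f0, des0) == 0))
  # a group lying far above its fixed prediction gets a positive intercept
  hi <- names(which.max(tapply(residuals(fit, "marginal"),
                               fit$design$group, mean)))
  expect_gt(fit$blups[hi, "(Intercept)"], 0)
})

test_that("degenerate designs are rejected with informative errors", {
  d <- data.frame(g = rep(c("a", "b"), each = 4), x = rnorm(8))
  d$x2 <- 2 * d$x
  d$y <- rnorm(8)
  des <- grouped_design(d, "y", fixed = c("x", "x2"), group = "g")
  expect_error(fit_ml(des), "collinear.*x2")
  one <- grouped_design(d[d$g == "a", ], "y", group = "g")
  expect_error(fit_ml(one), "2 groups")
})
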