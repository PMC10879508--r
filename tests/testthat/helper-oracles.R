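# Independent oracles and small fixtures used across the test files.

# Direct multivariate-normal log-density, deliberately avoiding the Cholesky
# route the package uses: determinant() + solve().
mvn_logdens <- function(y, mu, V) {
  r <- y - mu
  ld <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  -0.5 * (length(y) * log(2 * pi) + ld + sum(r * solve(V, r)))
}

# Grouped marginal log-likelihood by brute force from the raw blocks.
oracle_loglik <- function(design, Sigma, sigma2, beta) {
  idx <- split(seq_along(design$y), design$group)
  mu <- as.numeric(design$X %*% beta)
  sum(vapply(idx, function(rows) {
    Zj <- design$Z[rows, , drop = FALSE]
    V <- diag(sigma2, length(rows)) +
      if (ncol(Zj) > 0) Zj %*% Sigma %*% t(Zj) else 0
    mvn_logdens(design$y[rows], mu[rows], V)
  }, 0))
}

# Closed-form ML estimators for the balanced one-way random-intercept
# layout: J groups of size n. Interior solution requires lambda > sigma_e^2.
balanced_oneway_ml <- function(y, group) {
  gbar <- tapply(y, group, mean)
  n <- as.integer(table(group)[1])
  J <- length(gbar)
  N <- n * J
  stopifnot(all(table(group) == n))
  mu <- mean(y)
  ssw <- sum((y - gbar[group])^2)
  ssb <- n * sum((gbar - mu)^2)
  sigma_e2 <- ssw / (N - J)
  lambda <- ssb / J
  loglik <- -0.5 * (N * log(2 * pi) + (N - J) * log(sigma_e2) +
                      J * log(lambda) + ssw / sigma_e2 + ssb / lambda)
  list(mu = mu, sigma_e2 = sigma_e2, sigma_b2 = (lambda - sigma_e2) / n,
       interior = lambda > sigma_e2, loglik = loglik)
}

# Random tiny grouped dataset for likelihood-oracle property tests.
random_tiny_design <- function(q_max = 2L) {
  n <- sample(4:10, 1)
  J <- sample(2:3, 1)
  q_extra <- sample(0:(q_max - 1L), 1)
  p_extra <- sample(0:2, 1)
  d <- data.frame(g = sample(letters[1:J], n, replace = TRUE),
                  y = rnorm(n))
  # ensure every group appears
  d$g[seq_len(J)] <- letters[1:J]
  for (k in seq_len(max(p_extra, q_extra)))
    d[[paste0("x", k)]] <- rnorm(n)
  fixed <- if (p_extra > 0) paste0("x", seq_len(p_extra)) else character()
  random <- if (q_extra > 0) paste0("x", seq_len(q_extra)) else character()
  grouped_design(d, response = "y", fixed = fixed, random = random,
                 group = "g")
}

# Random covariance parameters for a given q.
random_params <- function(p, q) {
  A <- matrix(rnorm(q * q, sd = 0.7), q, q)
  list(Sigma = crossprod(A) + diag(0.1, q),
       sigma2 = runif(1, 0.3, 2),
       beta = rnorm(p))
}

# Small generator configuration for fast unit tests.
small_config <- function(n_participants = 60, ...) {
  generator_config(n_participants = n_participants, ...)
}

# A tiny hand-made state table (two participants, well-formed).
tiny_states <- function() {
  data.frame(
    participant_id = rep(c("p1", "p2"), each = 3),
    timestamp = c("2022-02-20T10:15:00", "2022-02-20T14:30:00",
                  "2022-02-21T09:05:00", "2022-02-23T11:00:00",
                  "2022-02-25T16:45:00", "2022-02-26T12:10:00"),
    pa1 = c(6, 5, 4, 3, 2, 4), pa2 = c(5, 5, 4, 4, 1, 3),
    pa3 = c(4, 6, 5, 5, 2, 3), na1 = c(1, 2, 1, 2, 6, 3),
    na2 = c(2, 1, 2, 1, 5, 2), na3 = c(1, 1, 3, 3, 6, 4),
    survey_kind = "random_beep")
}

tiny_participants <- function() {
  data.frame(
    participant_id = c("p1", "p2"),
    gender = c("female", "male"), age = c(25, 31),
    subjective_social_status = c(6, 5), political_orientation = c(4, 5),
    bfi_e = c(3.2, 4.0), bfi_a = c(3.8, 3.0), bfi_c = c(4.1, 3.3),
    bfi_n = c(2.5, 3.6), bfi_o = c(3.9, 2.8),
    conscientious_flag = TRUE, mean_seconds_per_item = c(3.5, 4.2),
    country = c("DE", "IT"), is_european = TRUE)
}
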