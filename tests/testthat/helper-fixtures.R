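# Small builders used across the suite.

# Oriented effects from basic parameters with independent (star) geometry.
star_effects <- function(mu, se, name = "outcome",
                         direction = "higher_better") {
  I <- length(mu)
  trt <- LETTERS[seq_len(I)]
  sigma <- diag(c(0, se[-1]^2))
  orient(outcome_effects(trt, mu, sigma, reference = trt[1],
                         direction = direction, outcome_name = name))
}

# Canonical 3-treatment system used by several hand-computed oracles.
eff3 <- function() star_effects(c(0, 0.3, 0.6), c(0, 0.2, 0.25))

# A consistent league table generated from a known covariance.
league_from_sigma <- function(mu, sigma, trt = LETTERS[seq_along(mu)]) {
  rows <- NULL
  for (i in seq_along(mu)) for (j in seq_along(mu)) {
    if (i >= j) next
    se <- sqrt(sigma[i, i] + sigma[j, j] - 2 * sigma[i, j])
    rows <- rbind(rows, data.frame(treatment_i = trt[i],
                                   treatment_j = trt[j],
                                   diff = mu[i] - mu[j], se = se))
  }
  league_table(rows)
}

random_rho <- function(K) {
  A <- matrix(stats::rnorm(K * K), K)
  S <- crossprod(A) + diag(K) * 0.1
  stats::cov2cor(S)
}
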