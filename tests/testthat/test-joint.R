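make_joint <- function(mu1, mu2, se1, se2, r) {
  o1 <- star_effects(mu1, se1, name = "benefit")
  o2 <- star_effects(mu2, se2, name = "harm")
  joint_effects(list(o1, o2),
                correlation_spec(c("benefit", "harm"),
                                 matrix(c(1, r, r, 1), 2)))
}

test_that("correlation specs validate shape, range and PSD", {
  expect_s3_class(correlation_spec("a", matrix(1)), "correlation_spec")
  expect_error(correlation_spec(c("a", "b"), matrix(c(1, 0.5, 0.4, 1), 2)),
               "symmetric")
  expect_error(correlation_spec(c("a", "b"), matrix(c(2, 0, 0, 1), 2)),
               "unit diagonal")
  expect_error(correlation_spec(c("a", "b", "c"),
                                matrix(c(1, 0.9, -0.9,
                                         0.9, 1, 0.9,
                                         -0.9, 0.9, 1), 3)),
               "positive semidefinite")
})

test_that("correlation strategies produce the documented specs", {
  z <- correlation_strategy("zero", c("a", "b", "c"))
  expect_equal(unname(z$rho), diag(3))

  # the illustration matrix: eff/acc +0.5, both against weight -0.5, is PSD
  m <- matrix(c(1, 0.5, -0.5, 0.5, 1, -0.5, -0.5, -0.5, 1), 3)
  f <- correlation_strategy("fixed", c("eff", "acc", "wt"), m)
  expect_equal(unname(f$rho), m)

  r <- correlation_strategy("range", c("a", "b"), c(-0.9, 0.9, 0.3))
  expect_length(r, 7)
  expect_equal(r[[1]]$rho[1, 2], -0.9)
  expect_error(correlation_strategy("range", c("a", "b"), c(-1, 0.9, 0.3)),
               "strictly inside")
  expect_error(correlation_strategy("range", c("a", "b", "c"),
                                    c(-0.5, 0.5, 0.5)), "K = 2")
})

test_that("joint effects demand matching treatment sets and orientation", {
  o1 <- star_effects(c(0, 0.2), c(0, 1), name = "x")
  o2 <- star_effects(c(0, 0.1, 0.2), c(0, 1, 1), name = "y")
  expect_error(joint_effects(list(o1, o2)), "treatment set")
  raw <- outcome_effects(c("A", "B"), c(0, 1), diag(c(0, 1)),
                         outcome_name = "y")
  expect_error(joint_effects(list(o1, raw)), "not oriented")
})

test_that("joint probability factorizes, degenerates and bounds correctly", {
  mu1 <- c(0, 0.4, -0.1); mu2 <- c(0, -0.2, 0.3)
  se1 <- c(0, 0.2, 0.3); se2 <- c(0, 0.3, 0.25)

  # independence: product of marginals
  je0 <- make_joint(mu1, mu2, se1, se2, 0)
  p1 <- pairwise_prob(0.4, 0.2); p2 <- pairwise_prob(-0.2, 0.3)
  expect_equal(joint_pairwise_prob(je0, "B", "A"), p1 * p2,
               tolerance = 1e-7)

  # comonotone identical copies collapse to the single marginal
  o <- star_effects(mu1, se1, name = "x")
  o2 <- o; o2$outcome_name <- "x2"
  je1 <- joint_effects(list(o, o2),
                       correlation_spec(c("x", "x2"),
                                        matrix(c(1, 1, 1, 1), 2)))
  expect_equal(joint_pairwise_prob(je1, "B", "A"), p1, tolerance = 1e-7)

  # joint never exceeds any marginal
  for (r in c(-0.8, -0.3, 0.4, 0.9)) {
    je <- make_joint(mu1, mu2, se1, se2, r)
    jp <- joint_pairwise_prob(je, "B", "C")
    m1 <- pairwise_prob(mu1[2] - mu1[3], sqrt(se1[2]^2 + se1[3]^2))
    m2 <- pairwise_prob(mu2[2] - mu2[3], sqrt(se2[2]^2 + se2[3]^2))
    expect_lte(jp, min(m1, m2) + 1e-9)
  }

  expect_error(joint_pairwise_prob(je0, "B", "Z"), "unknown")
})

test_that("joint probability is nondecreasing in the correlation", {
  set.seed(21)
  for (rep in 1:10) {
    d <- runif(2, -0.5, 0.5); s <- runif(2, 0.1, 0.5)
    civ <- runif(2, -0.3, 0.3)
    rs <- seq(-0.9, 0.9, 0.3)
    vals <- vapply(rs, function(r) {
      je <- make_joint(c(0, d[1], 0.1), c(0, d[2], -0.1),
                       c(0, s[1], 0.2), c(0, s[2], 0.2), r)
      joint_pairwise_prob(je, "B", "A", civs = civ)
    }, numeric(1))
    expect_true(all(diff(vals) >= -1e-7))
  }
})

test_that("joint probability matches the Monte-Carlo sampling oracle", {
  je <- make_joint(c(0, 0.4, -0.1), c(0, -0.2, 0.3),
                   c(0, 0.2, 0.3), c(0, 0.3, 0.25), -0.5)
  analytic <- joint_pairwise_prob(je, "B", "A", civs = c(0, -0.5))
  mc <- mc_joint_prob_oracle(d = c(0.4, -0.2), s = c(0.2, 0.3),
                             civs = c(0, -0.5),
                             rho = matrix(c(1, -0.5, -0.5, 1), 2),
                             n = 1e6, seed = 8)
  expect_lt(abs(analytic - mc$estimate), 3 * mc$mc_se)
})

test_that("multi-outcome P-scores reduce, bound and permute correctly", {
  o1 <- star_effects(c(0, 0.4, -0.1), c(0, 0.2, 0.3), name = "x")
  je1 <- joint_effects(list(o1))
  expect_equal(multi_pscores(je1, civs = 0.1)$scores,
               pscores(o1, civ = 0.1)$scores, tolerance = 1e-9)

  # brute-force re-evaluation of a 3-treatment, 2-outcome system
  o2 <- star_effects(c(0, -0.2, 0.3), c(0, 0.3, 0.25), name = "y")
  rho <- matrix(c(1, 0.5, 0.5, 1), 2)
  je <- joint_effects(list(o1, o2), correlation_spec(c("x", "y"), rho))
  mp <- multi_pscores(je)
  trt <- je$treatments
  for (a in seq_along(trt)) {
    terms <- vapply(setdiff(seq_along(trt), a), function(b) {
      up <- c((o1$mu[a] - o1$mu[b]) / o1$pairwise_se[a, b],
              (o2$mu[a] - o2$mu[b]) / o2$pairwise_se[a, b])
      mvtnorm::pmvnorm(upper = up, corr = rho,
                       algorithm = mvtnorm::TVPACK(1e-10))
    }, numeric(1))
    expect_equal(unname(mp$scores[a]), mean(terms), tolerance = 1e-6)
  }

  # joint scores cannot exceed either single-outcome score at rho = 0
  je0 <- joint_effects(list(o1, o2), correlation_spec(c("x", "y"), diag(2)))
  mp0 <- multi_pscores(je0)
  expect_true(all(mp0$scores <= pmin(pscores(o1)$scores,
                                     pscores(o2)$scores) + 1e-9))

  # invariance under outcome permutation (with matching civ/rho order)
  jeP <- joint_effects(list(o2, o1),
                       correlation_spec(c("y", "x"), rho))
  expect_equal(unname(multi_pscores(jeP, civs = c(0.2, 0.1))$scores),
               unname(multi_pscores(je, civs = c(0.1, 0.2))$scores),
               tolerance = 1e-9)
})

test_that("benefit-risk curves hit their limiting regimes", {
  o1 <- star_effects(c(0, 0.5, 0.1), c(0, 0.2, 0.2), name = "benefit")
  o2 <- star_effects(c(0, 0.6, -0.1), c(0, 0.25, 0.2),
                     direction = "lower_better", name = "harm")
  je <- joint_effects(list(o1, o2),
                      correlation_spec(c("benefit", "harm"),
                                       matrix(c(1, -0.5, -0.5, 1), 2)))

  # a tolerance so large the risk constraint never binds
  slack <- -(max(abs(o2$mu)) + 10 * max(o2$pairwise_se))
  bc <- benefit_risk_curves(je, "benefit", "harm", benefit_civ = 0.2,
                            risk_grid = civ_spec("harm", c(slack, 0)))
  single <- pscores(o1, civ = 0.2)$scores
  expect_equal(unname(bc$scores[, 1]), unname(single), tolerance = 1e-5)

  # maximally strict risk demand kills every score
  strict <- max(abs(o2$mu)) + 10 * max(o2$pairwise_se)
  bs <- benefit_risk_curves(je, "benefit", "harm", benefit_civ = 0,
                            risk_grid = civ_spec("harm", c(0, strict)))
  expect_true(all(bs$scores[, 2] < 1e-6))

  expect_error(benefit_risk_curves(je, "benefit", "benefit", 0, c(0, 1)),
               "must differ")
  expect_error(benefit_risk_curves(je, "benefit", "nope", 0, c(0, 1)),
               "not in the joint set")
})

test_that("benefit-risk crossings are insensitive to the assumed correlation", {
  # A: better benefit, worse harm profile than B
  o1 <- star_effects(c(0, 0.55, 0.25), c(0, 0.15, 0.15), name = "benefit")
  o2 <- star_effects(c(0, 0.5, 0.05), c(0, 0.15, 0.15),
                     direction = "lower_better", name = "harm")
  locs <- vapply(c(-0.8, -0.5, 0, 0.5), function(r) {
    je <- joint_effects(list(o1, o2),
                        correlation_spec(c("benefit", "harm"),
                                         matrix(c(1, r, r, 1), 2)))
    bc <- benefit_risk_curves(je, "benefit", "harm", benefit_civ = 0,
                              risk_grid = civ_spec("harm",
                                                   seq(-1, 0, 0.05)))
    x <- find_crossings(bc, c("B", "C"))
    expect_length(x, 1)
    x
  }, numeric(1))
  expect_lt(max(locs) - min(locs), 0.1)
})
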