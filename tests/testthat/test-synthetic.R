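test_that("generated networks are valid, reproducible and PSD", {
  tiny <- generate_network(I = 2, K = 1, seed = 1)
  eff <- tiny$joint$outcomes[[1]]
  expect_length(eff$treatments, 2)
  expect_identical(unname(eff$mu[eff$reference]), 0)

  a <- generate_network(I = 16, K = 3, seed = 99)
  b <- generate_network(I = 16, K = 3, seed = 99)
  expect_identical(a$joint$outcomes[[2]]$mu, b$joint$outcomes[[2]]$mu)
  expect_identical(a$truth$true_mu, b$truth$true_mu)
  c2 <- generate_network(I = 16, K = 3, seed = 100)
  expect_false(identical(a$joint$outcomes[[1]]$mu,
                         c2$joint$outcomes[[1]]$mu))

  for (o in a$joint$outcomes) {
    ev <- eigen(o$sigma, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10)
  }

  # caller's RNG untouched
  set.seed(5); x1 <- runif(1)
  set.seed(5); invisible(generate_network(I = 3, K = 1, seed = 2))
  expect_identical(runif(1), x1)

  expect_error(generate_network(I = 1, seed = 1), "at least two")
  expect_error(generate_network(I = 3, precision_range = c(0, 1), seed = 1),
               "precision_range")
})

test_that("the Monte-Carlo oracle hits its closed-form checkpoints", {
  o <- mc_joint_prob_oracle(0, 1, 0, n = 1e5, seed = 3)
  expect_lt(abs(o$estimate - 0.5), 3 * o$mc_se)

  # independent outcomes factorize
  o2 <- mc_joint_prob_oracle(c(0.3, -0.1), c(0.5, 0.4), c(0, 0),
                             rho = diag(2), n = 2e5, seed = 4)
  expect_lt(abs(o2$estimate - pnorm(0.3 / 0.5) * pnorm(-0.1 / 0.4)),
            3 * o2$mc_se)

  expect_error(mc_joint_prob_oracle(0, 1, 0, n = 10, seed = 1), "1000")
  expect_error(mc_joint_prob_oracle(c(0, 0), c(1, 1), c(0, 0),
                                    rho = matrix(c(1, 2, 2, 1), 2),
                                    n = 1e4, seed = 1),
               "positive semidefinite")
})

test_that("analytic joint probabilities track the oracle across random setups", {
  set.seed(1234)
  n <- 1e5
  fails <- 0L
  for (rep in 1:20) {
    K <- sample(1:3, 1)
    d <- runif(K, -0.6, 0.6)
    s <- runif(K, 0.1, 0.5)
    civ <- runif(K, -0.4, 0.4)
    rho <- if (K == 1) matrix(1) else random_rho(K)
    upper <- (d - civ) / s
    analytic <- civrank:::.joint_phi(upper, rho)
    mc <- mc_joint_prob_oracle(d, s, civ, rho, n = n,
                               seed = sample.int(1e6, 1))
    if (abs(analytic - mc$estimate) >= 3 * max(mc$mc_se, 1e-4))
      fails <- fails + 1L
  }
  expect_lte(fails, 1L)
})

test_that("P-score ranking recovers the true ordering as noise vanishes", {
  net <- generate_network(I = 8, K = 1, seed = 7,
                          precision_range = c(0.05, 0.3) * 1e-4)
  sc <- pscores(net$joint$outcomes[[1]])$scores
  expect_identical(order(-sc), order(-net$truth$true_mu[[1]]))
})

test_that("the report table lays outcomes and combined columns side by side", {
  rho <- correlation_spec(c("eff", "acc"), matrix(c(1, 0.5, 0.5, 1), 2))
  net <- generate_network(I = 5, K = 2, seed = 12, rho = rho,
                          outcome_names = c("eff", "acc"))
  rep2 <- table1_style_report(net$joint)
  expect_true(all(c("eff_pscore_pct", "eff_rank", "acc_pscore_pct",
                    "acc_rank", "combined_2_outcomes_pscore_pct") %in%
                  names(rep2)))
  # ranks are permutations
  expect_setequal(rep2$eff_rank, 1:5)
  expect_setequal(rep2$combined_2_outcomes_rank, 1:5)
  # joint scores cannot beat either marginal (rho >= 0, civ = 0); compare
  # on the exact scores underneath the rounded percentages
  joint_sc <- multi_pscores(net$joint)$scores
  m1 <- pscores(net$joint$outcomes[[1]])$scores
  m2 <- pscores(net$joint$outcomes[[2]])$scores
  expect_true(all(joint_sc <= pmin(m1, m2) + 1e-9))

  single <- table1_style_report(joint_effects(net$joint$outcomes[1]))
  expect_named(single, c("treatment", "eff_pscore_pct", "eff_rank"))
})

test_that("network JSON round-trips and the packaged fixture loads", {
  rho <- correlation_spec(c("a", "b"),
                          matrix(c(1, -0.3, -0.3, 1), 2))
  net <- generate_network(I = 4, K = 2, seed = 31, rho = rho,
                          directions = c("higher_better", "lower_better"),
                          outcome_names = c("a", "b"))
  p <- withr::local_tempfile(fileext = ".json")
  write_network_json(net, p)
  rt <- read_network_json(p)
  expect_equal(rt$joint$outcomes[[2]]$mu, net$joint$outcomes[[2]]$mu,
               tolerance = 1e-12)
  expect_equal(rt$joint$correlation$rho, net$joint$correlation$rho,
               tolerance = 1e-12)
  expect_equal(unlist(rt$truth$true_mu[[1]]),
               unname(net$truth$true_mu[[1]]), tolerance = 1e-12)

  fx <- antipsychotics_like()
  expect_length(fx$joint$treatments, 16)
  expect_length(fx$joint$outcomes, 3)
  expect_identical(fx$joint$outcomes$weight_gain$direction, "lower_better")
  expect_true(all(vapply(fx$joint$outcomes, `[[`, TRUE, "oriented")))
})
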