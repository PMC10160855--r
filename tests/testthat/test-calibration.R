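# The fixed-M solver, the KL loss, and the generalized-Bayes sampler.

test_that("solve_fixed_M inverts the balance equation", {
  # identity matrix: p = q
  q <- c(0.2, 0.3, 0.5)
  expect_equal(unname(solve_fixed_M(q, diag(3))), q, tolerance = 1e-12)

  # worked 2x2 example: q = (0.55, 0.45) under rows (0.8,0.2)/(0.3,0.7)
  m <- rbind(c(0.8, 0.2), c(0.3, 0.7))
  p <- solve_fixed_M(c(0.55, 0.45), m)
  expect_equal(unname(p), c(0.5, 0.5), tolerance = 1e-10)
  expect_equal(0.8 * p[[1]] + 0.3 * p[[2]], 0.55, tolerance = 1e-10)

  # round trip through q = M'p for random nonsingular stochastic M, C <= 5
  set.seed(8)
  for (C in 2:5) {
    for (rep in 1:3) {
      m <- as_misclass_matrix(row_normalize(diag(C) * 2 + random_stochastic(C)))
      p_true <- as.vector(rdirichlet(1, rep(2, C)))
      q <- drop(crossprod(m, p_true))
      expect_lt(max(abs(solve_fixed_M(q, m) - p_true)), 1e-10)
    }
  }

  # singular matrix advises the sampler
  expect_error(solve_fixed_M(c(0.5, 0.5), matrix(0.5, 2, 2)), "singular")
})

test_that("KL loss reduces to the multinomial log-likelihood and is additive", {
  p <- c(0.2, 0.3, 0.5)
  # one survey record, y one-hot at cause 2, M = identity: loss = -log(p_2)
  sv <- survey_from_matrix(rbind(c(0, 1, 0)), cl3, "algo")
  l <- gb_loss(p, list(algo = diag(3)), survey = sv, cause_list = cl3)
  expect_equal(l, -log(0.3), tolerance = 1e-9)

  # two identical algorithms with weight 1 double the loss
  sv2 <- survey_from_matrix(rbind(c(0, 1, 0)), cl3, "algo2")
  sv_both <- dplyr::bind_cols(sv, sv2[-1])
  l2 <- gb_loss(p, list(algo = diag(3), algo2 = diag(3)), survey = sv_both,
                cause_list = cl3)
  expect_equal(l2, 2 * l, tolerance = 1e-12)

  # weighted sum
  l3 <- gb_loss(p, list(algo = diag(3), algo2 = diag(3)), survey = sv_both,
                cause_list = cl3, weights = c(algo = 1, algo2 = 0.5))
  expect_equal(l3, 1.5 * l, tolerance = 1e-12)
})

test_that("the loss is minimized in p at the matching composition", {
  # survey compositions equal to M'p exactly: perturbing p increases the loss
  set.seed(5)
  m <- diag_m(3, 0.6)
  p0 <- c(0.5, 0.3, 0.2)
  q <- drop(crossprod(m, p0))
  sv <- survey_from_matrix(matrix(q, 20, 3, byrow = TRUE), cl3, "algo")
  l0 <- gb_loss(p0, list(algo = m), survey = sv, cause_list = cl3)
  for (k in 1:10) {
    eps <- rnorm(3, sd = 0.02)
    eps <- eps - mean(eps)
    p_pert <- pmax(p0 + eps, 1e-6); p_pert <- p_pert / sum(p_pert)
    expect_gte(gb_loss(p_pert, list(algo = m), survey = sv, cause_list = cl3),
               l0 - 1e-10)
  }
})

test_that("sampler with fixed identity M matches the conjugate closed form", {
  # single-cause survey records, flat prior: generalized posterior for p is
  # Dirichlet(1 + counts); the MCMC path must agree within MC error
  set.seed(6)
  counts <- c(30, 15, 5)
  y <- diag(3)[rep(1:3, counts), ]
  sv <- survey_from_matrix(y, cl3, "algo")
  cal <- calibrate_csmf(paired = NULL, survey = sv, cl3, "algo",
                        config = gb_config(n_chains = 2, n_iter = 3000,
                                           n_burn = 1000, seed = 2),
                        fix_m = list(algo = diag(3)), pointwise = FALSE)
  alpha <- 1 + counts
  conj_mean <- alpha / sum(alpha)
  conj_sd <- sqrt(conj_mean * (1 - conj_mean) / (sum(alpha) + 1))
  mc_se <- conj_sd / sqrt(min(cal$diagnostics$ess))
  expect_true(all(abs(colMeans(cal$p_draws) - conj_mean) <
                    3 * pmax(mc_se, 1e-4)))

  # closed-form uncalibrated posterior agrees too (it IS the conjugate form)
  unc <- uncalibrated_posterior(sv, cl3, "algo", n_draws = 4000, seed = 3)
  expect_equal(unname(unc$alpha), alpha)
  expect_lt(max(abs(colMeans(unc$p_draws) - conj_mean)), 0.02)
})

test_that("draws are reproducible, simplex-valid, and balance M'p against q", {
  cfg <- twoalgo_cfg(17, n_paired = 250, n_survey = 800, p_inconclusive = 0)
  pd <- simulate_paired(cfg)
  sv <- simulate_survey(cfg)
  gb <- gb_config(n_chains = 2, n_iter = 600, n_burn = 300, seed = 5)
  cal1 <- suppressWarnings(calibrate_csmf(pd, sv, cl3, config = gb))
  cal2 <- suppressWarnings(calibrate_csmf(pd, sv, cl3, config = gb))
  expect_identical(cal1$p_draws, cal2$p_draws)
  expect_identical(cal1$m_draws, cal2$m_draws)

  expect_true(all(abs(rowSums(cal1$p_draws) - 1) < 1e-12))
  for (a in cal1$algorithms)
    expect_true(all(abs(apply(cal1$m_draws[[a]], c(1, 2), sum) - 1) < 1e-12))

  # posterior-predictive identity: mean over draws of M'p tracks the raw q
  for (a in cal1$algorithms) {
    qq <- sapply(seq_len(nrow(cal1$p_draws)), function(k)
      crossprod(cal1$m_draws[[a]][k, , ], cal1$p_draws[k, ]))
    q_hat <- rowMeans(qq)
    se <- apply(qq, 1, sd) / sqrt(min(cal1$diagnostics$ess))
    samp_se <- sqrt(cal1$q_raw[[a]] * (1 - cal1$q_raw[[a]]) / nrow(sv))
    expect_true(all(abs(q_hat - cal1$q_raw[[a]]) <
                      3 * sqrt(se^2 + samp_se^2) + 0.01))
  }
})

test_that("ensemble aligns with the informative algorithm when one is uninformative", {
  # one perfect algorithm (M = I), one with uniform rows carrying no signal:
  # the ensemble posterior should sit near the informative algorithm's p
  set.seed(12)
  n_s <- 1500
  p_true <- c(0.6, 0.25, 0.15)
  z <- sample.int(3, n_s, replace = TRUE, prob = p_true)
  y_good <- diag(3)[z, ]
  y_bad <- rdirichlet(n_s, rep(5, 3))   # uninformative noise around uniform
  sv <- survey_from_matrix(y_good, cl3, "good")
  sv_b <- survey_from_matrix(y_bad, cl3, "bad")
  sv <- dplyr::bind_cols(sv, sv_b[-1])
  attr(sv, "algorithms") <- c("good", "bad")

  # paired data so both matrices are estimated from data
  n_p <- 400
  zp <- sample.int(3, n_p, replace = TRUE)
  xp <- diag(3)[zp, ]
  pd <- paired_from_matrices(xp, diag(3)[zp, ], cl3, "good")
  pd_b <- paired_from_matrices(xp, rdirichlet(n_p, rep(5, 3)), cl3, "bad")
  pd <- dplyr::bind_cols(pd, pd_b[-(1:7)])
  attr(pd, "algorithms") <- c("good", "bad")

  cal <- suppressWarnings(
    calibrate_csmf(pd, sv, cl3, c("good", "bad"),
                   config = gb_config(n_chains = 2, n_iter = 1200,
                                      n_burn = 600, seed = 4),
                   pointwise = FALSE))
  p_hat <- colMeans(cal$p_draws)
  expect_lt(max(abs(p_hat - p_true)), 0.06)
  expect_gt(csmfa(p_hat, p_true), 0.9)
})

test_that("posterior summaries give nested equal-tailed intervals", {
  cfg <- recovery_cfg(41, n_paired = 200, n_survey = 500)
  r <- suppressWarnings(
    recovery_harness(cfg, gb = gb_config(n_chains = 1, n_iter = 800,
                                         n_burn = 400, seed = 41)))
  t95 <- tidy(r$fit, level = 0.95)
  t50 <- tidy(r$fit, level = 0.50)
  expect_true(all(t50$conf.low >= t95$conf.low - 1e-12))
  expect_true(all(t50$conf.high <= t95$conf.high + 1e-12))
  expect_true(all(abs(sum(t95$estimate) - 1) < 1e-8))

  # quantiles of known Dirichlet draws match the closed form within MC error
  set.seed(2)
  d <- rdirichlet(20000, c(4, 6))
  expect_lt(abs(quantile(d[, 1], 0.975) - qbeta(0.975, 4, 6)), 0.01)
})
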