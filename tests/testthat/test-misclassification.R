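# The compositional misclassification regression and its single-cause
# special case.

test_that("one-hot MITS data gives the closed-form per-class mean", {
  x <- rbind(c(1, 0), c(0, 1))
  y <- rbind(c(0.6, 0.4), c(0.2, 0.8))
  fit <- fit_multicause_M(x, y)
  expect_equal(unname(fit$m), y, tolerance = 1e-9)
  expect_true(fit$converged)

  # y == x exactly -> identity (up to the epsilon floor)
  set.seed(4)
  C <- 4
  z <- sample.int(C, 50, replace = TRUE)
  xh <- diag(C)[z, ]
  fit2 <- fit_multicause_M(xh, xh)
  expect_lt(max(abs(fit2$m - diag(C))), 1e-8)
})

test_that("multi-cause fit on one-hot data equals the single-cause closed form", {
  # single-cause reduction: averages equal proportions for one-hot outputs
  set.seed(9)
  n <- 60
  true <- sample.int(3, n, replace = TRUE)
  pred <- ifelse(runif(n) < 0.6, true, sample.int(3, n, replace = TRUE))
  m_single <- fit_singlecause_M(true, pred, cl3)
  x <- diag(3)[true, ]
  y <- diag(3)[pred, ]
  m_multi <- fit_multicause_M(x, y, causes = cl3$causes)$m
  expect_equal(unname(m_multi), unname(m_single), tolerance = 1e-8)

  # the KL loss at the optimum equals the multinomial negative log-likelihood
  nll <- -sum(log(m_single[cbind(true, pred)]))
  loss <- -sum(y * log(pmax(x %*% m_single, 1e-10)))
  expect_equal(loss, nll, tolerance = 1e-9)
})

test_that("single-cause estimator matches sample proportions and errors correctly", {
  m <- fit_singlecause_M(c(1, 1, 1, 1, 2), c(1, 1, 1, 2, 2),
                         cause_list("custom", c("a", "b")))
  expect_equal(unname(m[1, ]), c(0.75, 0.25))
  expect_equal(unname(m[2, ]), c(0, 1))
  expect_error(fit_singlecause_M(c(1, 1), c(1, 2),
                                 cause_list("custom", c("a", "b"))),
               "never observed")
})

test_that("iterative fit matches a brute-force grid search of the same loss", {
  # C = 2 mixed-x dataset; oracle scans the 2-parameter loss surface at 1e-3
  x <- rbind(c(1, 0), c(0, 1), c(0.5, 0.5), c(0.5, 0.5), c(1, 0), c(0.5, 0.5))
  y <- rbind(c(0.7, 0.3), c(0.25, 0.75), c(0.5, 0.5), c(0.35, 0.65),
             c(0.6, 0.4), c(0.45, 0.55))
  oracle <- grid_fit_2x2(x, y, step = 1e-3)
  fit <- fit_multicause_M(x, y)
  expect_lt(max(abs(fit$m - oracle$m)), 2e-3)
  expect_lte(fit$final_loss, oracle$loss + 1e-6)
})

test_that("multiplicative updates decrease the loss and stay row-stochastic", {
  set.seed(14)
  cfg <- twoalgo_cfg(14, n_paired = 150, n_survey = 0, p_inconclusive = 0)
  pd <- simulate_paired(cfg)
  fit <- fit_misclassification(pd, "insilicova", cl3)
  expect_true(all(diff(fit$loss_trace) <= 1e-9))
  expect_true(all(abs(rowSums(fit$m) - 1) < 1e-8))
  expect_true(all(fit$m >= 0))
  expect_true(is.finite(fit$final_loss))
  expect_equal(unname(fit$n_effective),
               unname(colSums(mits_matrix(pd, cl3))))
})

test_that("a cause with zero MITS mass is an error naming the cause", {
  x <- rbind(c(1, 0, 0), c(0, 1, 0))   # gamma never observed
  y <- rbind(c(1, 0, 0), c(0, 1, 0))
  expect_error(fit_multicause_M(x, y, causes = cl3$causes), "gamma")
})

test_that("fitted mean for a half/half record is the M-row mixture", {
  # mixture identity: prediction for x = (0.5, 0.5, 0) is the average of the
  # first two rows of M
  cfg <- twoalgo_cfg(23, n_paired = 400, n_survey = 0, p_inconclusive = 0)
  pd <- simulate_paired(cfg)
  fit <- fit_misclassification(pd, "insilicova", cl3)
  x_mix <- c(0.5, 0.5, 0)
  expect_equal(drop(x_mix %*% fit$m), 0.5 * fit$m[1, ] + 0.5 * fit$m[2, ],
               tolerance = 1e-12)
})

test_that("fit is consistent for the generating matrix at n = 10,000", {
  M <- diag_m(3, 0.65)
  cfg <- sim_config(C = 3, n_paired = 10000, n_survey = 0,
                    M_true = list(insilicova = M),
                    algo_type = c(insilicova = "probabilistic"),
                    concentration = 8, p_inconclusive = 0,
                    causes = cl3$causes, seed = 77)
  pd <- simulate_paired(cfg)
  fit <- fit_misclassification(pd, "insilicova", cl3)
  expect_lt(max(abs(fit$m - M)), 0.03)
})

test_that("sensitivity_delta reports diagonals and their difference", {
  m1 <- diag_m(2, 0.5); m2 <- diag_m(2, 0.5)
  expect_equal(sensitivity_delta(m1, m2)$delta, c(0, 0))
  ms <- rbind(c(0.5, 0.5), c(0.3, 0.7))
  mm <- rbind(c(0.6, 0.4), c(0.3, 0.7))
  out <- sensitivity_delta(ms, mm)
  expect_equal(out$single, c(0.5, 0.7))
  expect_equal(out$delta, c(0.1, 0))
  expect_error(sensitivity_delta(diag(2), diag(3)), "dimensions")
})

test_that("tidy/glance/autoplot methods work on a fit", {
  x <- rbind(c(1, 0), c(0, 1))
  y <- rbind(c(0.8, 0.2), c(0.3, 0.7))
  fit <- fit_multicause_M(x, y, causes = c("a", "b"))
  td <- tidy(fit)
  expect_equal(nrow(td), 4)
  expect_equal(td$estimate[td$mits_cause == "a" & td$va_cause == "a"], 0.8,
               tolerance = 1e-8)
  expect_s3_class(glance(fit), "tbl_df")
  expect_s3_class(autoplot(fit), "ggplot")
})
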