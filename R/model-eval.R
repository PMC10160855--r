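# WAIC for generalized-Bayes fits. The per-record log predictive density is
# taken as the negative of the record's loss contribution (the loss is
# already a negative-log-type quantity; for one-hot records it is exactly
# the multinomial negative log-likelihood).

#' Widely Applicable Information Criterion from pointwise losses
#'
#' Given a draws-by-records matrix of per-record loss contributions,
#' computes
#' \deqn{lppd = \sum_r \log \mathrm{mean}_d \exp(-loss_{dr}), \quad
#'       p_{WAIC} = \sum_r \mathrm{var}_d(-loss_{dr}),}
#' and `waic = -2 (lppd - p_waic)`. The log-mean-exp is max-stabilised.
#' Lower WAIC indicates better estimated out-of-sample fit.
#'
#' @param x Draws x records matrix of pointwise losses (positive
#'   cross-entropy scale), or a [calibrate_csmf()] result carrying its
#'   `pointwise_loss`.
#' @param ... Unused.
#' @return Object of class `va_waic`: list with `lppd`, `p_waic`, `waic` and
#'   a `pointwise` tibble (per-record `lppd_i`, `p_waic_i`).
#' @export
waic <- function(x, ...) UseMethod("waic")

#' @rdname waic
#' @export
waic.matrix <- function(x, ...) {
  if (nrow(x) < 2) stop_input("WAIC needs at least 2 draws")
  if (!all(is.finite(x))) stop_input("pointwise losses must be finite")
  ll <- -x
  lppd_i <- col_log_mean_exp(ll)
  p_i <- col_vars(ll)
  structure(list(lppd = sum(lppd_i), p_waic = sum(p_i),
                 waic = -2 * (sum(lppd_i) - sum(p_i)),
                 pointwise = tibble::tibble(lppd_i = lppd_i, p_waic_i = p_i,
                                            type = attr(x, "type") %||%
                                              rep(NA_character_, ncol(x)))),
            class = "va_waic")
}

#' @rdname waic
#' @export
waic.va_calibration <- function(x, ...) {
  if (is.null(x$pointwise_loss))
    stop_input("calibration was run with pointwise = FALSE; re-run to get WAIC")
  waic(x$pointwise_loss)
}

#' @export
print.va_waic <- function(x, digits = 1, ...) {
  cat(sprintf("WAIC %.*f  (lppd %.*f, p_waic %.*f, %d records)\n", digits,
              x$waic, digits, x$lppd, digits, x$p_waic, nrow(x$pointwise)))
  invisible(x)
}

#' WAIC of the uncalibrated (no-misclassification) model
#'
#' Fits the uncalibrated model — the CSMF posterior with the
#' misclassification matrix fixed at the identity, see
#' [uncalibrated_posterior()] — and evaluates its WAIC on the same
#' observations as a calibrated fit: survey records are predicted by the
#' drawn CSMF q directly, and paired records (if supplied) by the identity
#' matrix, i.e. the MITS encoding itself. Comparing the result against
#' `waic(calibrated_fit)` reproduces the calibrated-vs-uncalibrated
#' goodness-of-fit comparison.
#'
#' @param survey Survey record tibble.
#' @param cause_list A [cause_list()].
#' @param algorithms Algorithm name(s).
#' @param paired Optional paired record tibble; include it when the
#'   calibrated fit being compared against also used paired data.
#' @param draws_of_q Optional draws x C matrix of CSMF draws to use instead
#'   of fitting [uncalibrated_posterior()].
#' @param n_draws,prior_p,weights,seed Passed to [uncalibrated_posterior()].
#' @param epsilon Floor inside logs (an identity matrix predicts zero mass
#'   for any cause the MITS encoding does not carry).
#' @return A `va_waic`.
#' @export
waic_uncalibrated <- function(survey, cause_list, algorithms = NULL,
                              paired = NULL, draws_of_q = NULL,
                              n_draws = 2000, prior_p = 1, weights = NULL,
                              seed = 1L, epsilon = 1e-10) {
  algorithms <- algorithms %||% attr(survey, "algorithms") %||%
    detect_algorithms(survey, cause_list)
  w <- resolve_weights(weights, algorithms)
  if (is.null(draws_of_q))
    draws_of_q <- uncalibrated_posterior(survey, cause_list, algorithms,
                                         n_draws = n_draws, prior_p = prior_p,
                                         weights = weights, seed = seed)$p_draws
  n_d <- nrow(draws_of_q)
  n_paired <- 0L
  paired_pw <- NULL
  if (!is.null(paired) && nrow(paired)) {
    # identity misclassification: predicted VA composition equals x
    per_algo <- lapply(algorithms, function(a) {
      y <- va_matrix(paired, a, cause_list)
      keep <- !apply(is.na(y), 1, any)
      x <- mits_matrix(paired, cause_list)[keep, , drop = FALSE]
      w[[a]] * (-rowSums(y[keep, , drop = FALSE] * safe_log(x, epsilon)))
    })
    const <- Reduce(`+`, per_algo)
    n_paired <- length(const)
    paired_pw <- matrix(const, n_d, n_paired, byrow = TRUE)
  }
  survey_pw <- matrix(0, n_d, nrow(survey))
  for (a in algorithms) {
    y <- va_matrix(survey, a, cause_list)
    if (anyNA(y)) stop_input("survey '%s' has unimputed records", a)
    lq <- safe_log(draws_of_q, epsilon)          # draws x C
    survey_pw <- survey_pw - w[[a]] * lq %*% t(y)
  }
  pw <- cbind(paired_pw, survey_pw)
  attr(pw, "type") <- rep(c("paired", "survey"), c(n_paired, nrow(survey)))
  waic(pw)
}

#' Cause-specific mortality fraction accuracy
#'
#' The standard CSMFA metric,
#' \deqn{1 - \frac{\sum_j |\hat p_j - p_j|}{2 (1 - \min_j p_j)},}
#' equal to 1 iff the estimate matches the truth and 0 at the worst possible
#' estimate (all mass on the rarest cause).
#'
#' @param p_hat Estimated CSMF.
#' @param p_true True CSMF (same cause order).
#' @return Scalar in \[0, 1\].
#' @export
csmfa <- function(p_hat, p_true) {
  p_hat <- as_composition(p_hat, what = "p_hat", quiet = TRUE)
  p_true <- as_composition(p_true, what = "p_true", quiet = TRUE)
  if (length(p_hat) != length(p_true))
    stop_input("p_hat and p_true have different lengths")
  denom <- 2 * (1 - min(p_true))
  if (denom == 0) stop_input("CSMFA undefined: p_true is degenerate (C = 1)")
  1 - sum(abs(p_hat - p_true)) / denom
}
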