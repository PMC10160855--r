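# Compositions: nonnegative score vectors on the unit simplex. They hold VA
# output y, the MITS encoding x, and CSMFs p and q. Validation is strict:
# sums within 1e-6 of 1 are renormalized (CSV rounding), anything further off
# is corrupt data and errors.

#' Validate (and lightly repair) a composition
#'
#' Checks that `x` is a nonnegative vector summing to 1. Sums within
#' `renorm_tol` of 1 are renormalized with a warning; larger deviations are an
#' error.
#'
#' @param x Numeric vector of per-cause scores.
#' @param renorm_tol Maximum deviation of `sum(x)` from 1 that is repaired by
#'   renormalization rather than rejected.
#' @param what Label used in error messages.
#' @param quiet Suppress the renormalization warning.
#' @return The validated (possibly renormalized) numeric vector.
#' @export
as_composition <- function(x, renorm_tol = 1e-6, what = "composition",
                           quiet = FALSE) {
  x <- as.numeric(x)
  if (anyNA(x)) stop_input("%s contains missing values", what)
  if (any(x < -1e-12)) stop_input("%s has negative entries", what)
  x <- pmax(x, 0)
  s <- sum(x)
  if (abs(s - 1) > renorm_tol)
    stop_input("%s sums to %.8g, outside [1 - %g, 1 + %g]", what, s,
               renorm_tol, renorm_tol)
  if (s != 1) {
    if (abs(s - 1) > 1e-12 && !quiet)
      rlang::warn(sprintf("%s sum %.10f off 1 by <= %g; renormalized",
                          what, s, renorm_tol))
    x <- x / s
  }
  x
}

is_simplex <- function(x, tol = 1e-8) {
  !anyNA(x) && all(x >= -1e-12) && abs(sum(x) - 1) <= tol
}

# Row-wise validation for a score matrix (n records x C causes); returns the
# renormalized matrix. Used by readers and simulators.
validate_score_matrix <- function(y, renorm_tol = 1e-6, what = "scores") {
  if (anyNA(y)) stop_input("%s contain missing values", what)
  if (any(y < -1e-12))
    stop_input("%s contain negative entries (first at record %d)", what,
               which(apply(y, 1, function(r) any(r < -1e-12)))[1])
  y[y < 0] <- 0
  s <- rowSums(y)
  off <- abs(s - 1)
  if (any(off > renorm_tol))
    stop_input("%s: record %d sums to %.8g, outside [1 - %g, 1 + %g]", what,
               which.max(off), s[which.max(off)], renorm_tol, renorm_tol)
  if (any(off > 1e-12))
    rlang::warn(sprintf("%s: %d record(s) off simplex by <= %g; renormalized",
                        what, sum(off > 1e-12), renorm_tol))
  y / s
}

#' Validate a misclassification matrix
#'
#' A misclassification matrix is square and row-stochastic: entry (i, j) is
#' the average score the CCVA algorithm assigns to cause j among deaths whose
#' reference (MITS) cause is i.
#'
#' @param m Numeric matrix.
#' @param causes Optional character vector of cause labels to attach as
#'   dimnames.
#' @param tol Row-sum tolerance.
#' @return `m` with dimnames set, invisibly validated.
#' @export
as_misclass_matrix <- function(m, causes = NULL, tol = 1e-8) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop_input("misclassification matrix must be square")
  if (anyNA(m) || any(m < -1e-12))
    stop_input("misclassification matrix has missing or negative entries")
  m[m < 0] <- 0
  rs <- rowSums(m)
  if (any(abs(rs - 1) > tol))
    stop_input("row %d of misclassification matrix sums to %.10g (tolerance %g)",
               which.max(abs(rs - 1)), rs[which.max(abs(rs - 1))], tol)
  m <- m / rs
  if (!is.null(causes)) dimnames(m) <- list(mits = causes, va = causes)
  m
}
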