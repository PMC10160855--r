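#' Fit the multi-cause misclassification matrix
#'
#' Estimates the row-stochastic matrix M in the compositional regression
#' y = M'x of multi-cause VA compositions y on multi-cause MITS encodings x,
#' by pseudo-maximum likelihood: M minimises the summed Kullback-Leibler
#' cross-entropy loss
#' \deqn{L(M) = -\sum_k \sum_j y_{kj} \log (M'x_k)_j}
#' over row-stochastic matrices. The fit uses multiplicative EM-style updates
#' (the transformation-free compositional-regression iteration), which keep
#' every row on the simplex without projection and decrease the loss
#' monotonically. When every x is one-hot the minimiser is the closed-form
#' per-class mean of y, and for one-hot y it is the classical contingency
#' proportion matrix — the single-cause definition of M.
#'
#' @param x Numeric matrix (records by causes) of MITS encodings, rows on the
#'   simplex (entries in \{0, 0.5, 1\}); or a composition list.
#' @param y Numeric matrix of VA compositions, same shape.
#' @param tol Convergence tolerance on the loss decrease per iteration.
#' @param max_iter Maximum number of multiplicative updates.
#' @param epsilon Floor applied to fitted entries (then renormalized) so that
#'   structurally zero columns — an algorithm that never identifies a cause —
#'   cannot produce infinite downstream log terms.
#' @param causes Optional cause labels for dimnames.
#' @return Object of class `va_misclass_fit`: list with elements `m`,
#'   `n_effective` (per-cause total x mass), `converged`, `iterations`,
#'   `final_loss`, `loss_trace`, `causes`.
#' @seealso [fit_misclassification()] for the tibble-first interface,
#'   [fit_singlecause_M()] for the single-cause closed form.
#' @export
fit_multicause_M <- function(x, y, tol = 1e-8, max_iter = 10000,
                             epsilon = 1e-10, causes = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(nrow(x) == nrow(y), ncol(x) == ncol(y))
  if (nrow(x) == 0) stop_input("no records to fit")
  C <- ncol(x)
  causes <- causes %||% colnames(x) %||% paste0("cause", seq_len(C))
  mass <- colSums(x)
  if (any(mass <= 0))
    stop_input("cause(s) with zero total MITS mass: %s; the regression row is undefined",
               paste(causes[mass <= 0], collapse = ", "))

  # deterministic start: uniform plus a diagonal bump to break label symmetry
  m <- matrix(1 / C, C, C) + diag(0.1, C)
  m <- m / rowSums(m)

  loss_of <- function(m) -sum(y * safe_log(x %*% m, epsilon))
  trace <- numeric(0)
  loss <- loss_of(m)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    pred <- pmax(x %*% m, epsilon)
    s <- m * crossprod(x, y / pred)    # E-step responsibilities folded in
    m_new <- s / rowSums(s)
    new_loss <- loss_of(m_new)
    trace <- c(trace, new_loss)
    delta <- loss - new_loss
    m <- m_new
    loss <- new_loss
    if (is.finite(delta) && delta >= 0 && delta < tol) { converged <- TRUE; break }
  }
  m <- pmax(m, epsilon)
  m <- m / rowSums(m)
  dimnames(m) <- list(mits = causes, va = causes)
  structure(
    list(m = m, n_effective = setNames(mass, causes), converged = converged,
         iterations = it, final_loss = loss_of(m), loss_trace = trace,
         causes = causes),
    class = "va_misclass_fit"
  )
}

#' Estimate a misclassification matrix from a paired record tibble
#'
#' Tibble-first wrapper around [fit_multicause_M()]: extracts the MITS
#' encoding (`x_*` columns) and one algorithm's score columns, dropping
#' records whose scores are still missing (unimputed inconclusive records).
#'
#' @param data Paired record tibble.
#' @param algorithm Algorithm name (column prefix).
#' @param cause_list A [cause_list()].
#' @param ... Passed to [fit_multicause_M()].
#' @return A `va_misclass_fit`.
#' @export
fit_misclassification <- function(data, algorithm, cause_list, ...) {
  y <- va_matrix(data, algorithm, cause_list)
  x <- mits_matrix(data, cause_list)
  keep <- !apply(is.na(y), 1, any)
  if (!all(keep))
    rlang::inform(sprintf("dropping %d record(s) with missing '%s' scores",
                          sum(!keep), algorithm))
  fit_multicause_M(x[keep, , drop = FALSE], y[keep, , drop = FALSE],
                   causes = cause_list$causes, ...)
}

#' Single-cause misclassification matrix (closed form)
#'
#' For single-cause data, entry (i, j) of M is the sample proportion of
#' deaths with reference cause i that the algorithm labels cause j:
#' `count(i -> j) / count(i)`. No iteration is involved.
#'
#' @param true Vector of reference (MITS underlying) cause labels or indices.
#' @param predicted Vector of predicted (VA plurality) cause labels or
#'   indices.
#' @param cause_list A [cause_list()].
#' @return Row-stochastic matrix with dimnames over the causes.
#' @export
fit_singlecause_M <- function(true, predicted, cause_list) {
  C <- length(cause_list)
  ti <- if (is.numeric(true)) as.integer(true) else
    cause_index(true, cause_list, "true cause")
  pi <- if (is.numeric(predicted)) as.integer(predicted) else
    cause_index(predicted, cause_list, "predicted cause")
  stopifnot(length(ti) == length(pi))
  counts <- matrix(0, C, C)
  for (k in seq_along(ti)) counts[ti[k], pi[k]] <- counts[ti[k], pi[k]] + 1
  n_i <- rowSums(counts)
  if (any(n_i == 0))
    stop_input("true cause(s) never observed: %s",
               paste(cause_list$causes[n_i == 0], collapse = ", "))
  m <- counts / n_i
  dimnames(m) <- list(mits = cause_list$causes, va = cause_list$causes)
  m
}

#' Compare single- and multi-cause sensitivities
#'
#' Returns, per cause, the single-cause sensitivity (diagonal of the
#' single-cause matrix) and the gain from the multi-cause analysis (the
#' difference of diagonals). Deaths whose VA output matches the immediate but
#' not the underlying cause count as complete misclassifications in the
#' single-cause analysis but only as half misclassifications in the
#' multi-cause one, so gains are expected to be mostly positive.
#'
#' @param m_single,m_multi Square matrices in the same cause order (matrices
#'   or `va_misclass_fit` objects).
#' @return Tibble with columns `cause`, `single`, `delta` (multi minus
#'   single).
#' @export
sensitivity_delta <- function(m_single, m_multi) {
  if (inherits(m_single, "va_misclass_fit")) m_single <- m_single$m
  if (inherits(m_multi, "va_misclass_fit")) m_multi <- m_multi$m
  if (!all(dim(m_single) == dim(m_multi)))
    stop_input("matrices have different dimensions")
  causes <- rownames(m_single) %||% paste0("cause", seq_len(nrow(m_single)))
  tibble::tibble(cause = causes, single = diag(m_single),
                 delta = diag(m_multi) - diag(m_single))
}

#' @export
print.va_misclass_fit <- function(x, digits = 3, ...) {
  cat("<va_misclass_fit> ", nrow(x$m), "x", ncol(x$m),
      if (x$converged) " (converged in " else " (NOT converged after ",
      x$iterations, " iterations, loss ", format(x$final_loss, digits = 6),
      ")\n", sep = "")
  print(round(x$m, digits))
  invisible(x)
}

#' @rdname fit_multicause_M
#' @param x A `va_misclass_fit`.
#' @export
tidy.va_misclass_fit <- function(x, ...) {
  tibble::tibble(
    mits_cause = rep(x$causes, times = length(x$causes)),
    va_cause = rep(x$causes, each = length(x$causes)),
    estimate = as.vector(x$m)
  )
}

#' @rdname fit_multicause_M
#' @export
glance.va_misclass_fit <- function(x, ...) {
  tibble::tibble(n_causes = length(x$causes), converged = x$converged,
                 iterations = x$iterations, final_loss = x$final_loss,
                 mean_sensitivity = mean(diag(x$m)))
}

#' Heatmap of a fitted misclassification matrix
#'
#' @param object A `va_misclass_fit`.
#' @param ... Unused.
#' @return A ggplot object (MITS cause on rows, VA cause on columns).
#' @export
autoplot.va_misclass_fit <- function(object, ...) {
  df <- tidy(object)
  df$mits_cause <- factor(df$mits_cause, levels = rev(object$causes))
  df$va_cause <- factor(df$va_cause, levels = object$causes)
  ggplot2::ggplot(df, ggplot2::aes(.data$va_cause, .data$mits_cause,
                                   fill = .data$estimate)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.0f%%",
                                                    100 * .data$estimate)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "VA cause", y = "MITS cause", fill = "rate") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 40, hjust = 1))
}
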