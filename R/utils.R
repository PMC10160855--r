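# Internal helpers shared across the package. Cause labels appear in two forms:
# the display label ("severe malnutrition") and the column token
# ("severe_malnutrition") used in tibble/CSV headers.

cause_token <- function(x) gsub("_+", "_", gsub("[^a-z0-9]+", "_", tolower(trimws(x))))

cause_cols <- function(prefix, causes) paste0(prefix, "_", cause_token(causes))

# columns holding one algorithm's per-cause scores
algo_cols <- function(algorithm, causes) cause_cols(algorithm, causes)

stop_input <- function(msg, ...) rlang::abort(sprintf(msg, ...), class = "vacalibrate_error")

#' @noRd
row_normalize <- function(m) sweep(m, 1, rowSums(m), "/")

# numerically safe log of a (floored) probability vector/matrix
safe_log <- function(x, epsilon = 1e-10) log(pmax(x, epsilon))

# Dirichlet sampler via gamma representation; alpha may be a vector (one draw
# distribution) or a matrix (one row of alpha per draw).
rdirichlet <- function(n, alpha) {
  if (is.matrix(alpha)) {
    stopifnot(nrow(alpha) == n)
    g <- matrix(stats::rgamma(length(alpha), shape = as.vector(alpha)),
                nrow = n, ncol = ncol(alpha))
  } else {
    g <- matrix(stats::rgamma(n * length(alpha), shape = rep(alpha, each = n)),
                nrow = n)
  }
  rs <- rowSums(g)
  # all-zero rows only arise when every shape is ~0; keep them at the mean
  bad <- rs <= 0
  if (any(bad)) {
    a <- if (is.matrix(alpha)) alpha[bad, , drop = FALSE] else
      matrix(alpha, sum(bad), length(alpha), byrow = TRUE)
    g[bad, ] <- a
    rs[bad] <- rowSums(g[bad, , drop = FALSE])
  }
  g / rs
}

# additive-log-ratio transform (last cause is the reference) and its inverse.
alr <- function(p) {
  C <- length(p)
  log(pmax(p[-C], 1e-300)) - log(pmax(p[C], 1e-300))
}

alr_inv <- function(z) {
  e <- exp(c(z, 0) - max(z, 0))
  e / sum(e)
}

# column-wise log(mean(exp(x))) with the usual max shift
col_log_mean_exp <- function(x) {
  m <- apply(x, 2, max)
  m + log(colMeans(exp(sweep(x, 2, m, "-"))))
}

col_vars <- function(x) {
  n <- nrow(x)
  mu <- colMeans(x)
  (colSums(x^2) - n * mu^2) / (n - 1)
}

# draw one category per row of a row-stochastic weight matrix
sample_rows <- function(w) {
  u <- stats::runif(nrow(w))
  cw <- t(apply(w, 1, cumsum))
  max.col(cw >= u, ties.method = "first")
}
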