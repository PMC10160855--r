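# Generalized-Bayes calibration of the CSMF. The model couples the paired
# (calibration) data, which inform the misclassification matrices M_a, with
# the survey data, which inform the apparent CSMF q_a = M_a' p, through the
# Kullback-Leibler loss
#
#   L(p, {M_a}) = sum_a w_a [ - sum_paired  y_i . log(M_a' x_i)
#                             - sum_survey  y_k . log(M_a' p) ]
#
# (y-entropy constants dropped). The generalized posterior is
# exp(-L) * prior, with independent Dirichlet priors on p and on each M row.
# For one-hot data the loss is the multinomial negative log-likelihood, so
# the multi-cause calibration generalizes the single-cause one.

#' Configuration for the generalized-Bayes sampler
#'
#' @param prior_p Dirichlet concentration for p: scalar or length-C vector
#'   (default 1, flat).
#' @param prior_m Dirichlet concentration for each misclassification-matrix
#'   row: scalar or C x C matrix (default 1).
#' @param n_chains Number of MCMC chains.
#' @param n_iter Iterations per chain (including burn-in).
#' @param n_burn Burn-in iterations discarded per chain; proposal scales are
#'   adapted only during burn-in.
#' @param proposal_scale Initial random-walk scale on the additive-log-ratio
#'   scale; adapted toward ~25% acceptance.
#' @param loss_weights Named numeric vector of per-algorithm loss weights
#'   (default all 1; the unweighted sum is the ensemble loss).
#' @param learning_rate Scale on the loss inside the exponent. The
#'   generalized posterior uses 1; other values are exposed for research use
#'   only.
#' @param epsilon Floor under predicted compositions inside logs.
#' @param seed Integer seed; chain c uses `seed + c`.
#' @return List of class `gb_config`.
#' @export
gb_config <- function(prior_p = 1, prior_m = 1, n_chains = 4, n_iter = 5000,
                      n_burn = 2500, proposal_scale = 0.15, loss_weights = NULL,
                      learning_rate = 1, epsilon = 1e-10, seed = 1L) {
  stopifnot(all(prior_p > 0), all(prior_m > 0), n_chains >= 1,
            n_burn >= 0, n_burn < n_iter, proposal_scale > 0,
            learning_rate > 0)
  structure(list(prior_p = prior_p, prior_m = prior_m, n_chains = n_chains,
                 n_iter = n_iter, n_burn = n_burn,
                 proposal_scale = proposal_scale, loss_weights = loss_weights,
                 learning_rate = learning_rate, epsilon = epsilon,
                 seed = as.integer(seed)),
            class = "gb_config")
}

#' Deterministic calibration with a fixed misclassification matrix
#'
#' Solves the balance equation q = M'p for p on the simplex. When M' is
#' nonsingular and the exact solution is feasible (nonnegative), the linear
#' solve is returned; otherwise the simplex-constrained least-squares
#' solution of `||M'p - q||` is found by optimisation on the softmax scale.
#'
#' @param q Apparent (raw) CSMF composition.
#' @param m Row-stochastic misclassification matrix.
#' @return Calibrated CSMF composition.
#' @examples
#' m <- rbind(c(0.8, 0.2), c(0.3, 0.7))
#' solve_fixed_M(c(0.55, 0.45), m)  # (0.5, 0.5)
#' @export
solve_fixed_M <- function(q, m) {
  q <- as_composition(q, what = "q", quiet = TRUE)
  m <- as_misclass_matrix(m)
  C <- length(q)
  stopifnot(nrow(m) == C)
  if (rcond(t(m)) < 1e-12)
    stop_input(paste("misclassification matrix is numerically singular;",
                     "use the generalized-Bayes sampler instead"))
  p <- drop(solve(t(m), q))
  if (all(p >= -1e-10)) {
    p <- pmax(p, 0)
    return(setNames(p / sum(p), rownames(m)))
  }
  # constrained least squares on the simplex via softmax parameterisation
  obj <- function(z) { p <- alr_inv(z); sum((crossprod(m, p) - q)^2) }
  fit <- stats::optim(rep(0, C - 1), obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  setNames(alr_inv(fit$par), rownames(m))
}

#' Kullback-Leibler calibration loss
#'
#' Evaluates the generalized-Bayes loss for given parameters and data. The
#' paired term measures how well each algorithm's matrix explains its VA
#' compositions given the MITS encodings; the survey term measures how well
#' the implied apparent CSMF M'p explains the survey compositions. Additive
#' over algorithms (weighted).
#'
#' @param p CSMF composition.
#' @param m_by_algo Named list of misclassification matrices.
#' @param paired Paired record tibble (or `NULL`).
#' @param survey Survey record tibble (or `NULL`).
#' @param cause_list A [cause_list()].
#' @param weights Named per-algorithm weights (default 1).
#' @param epsilon Floor under predicted compositions inside logs.
#' @return Scalar loss.
#' @export
gb_loss <- function(p, m_by_algo, paired = NULL, survey = NULL, cause_list,
                    weights = NULL, epsilon = 1e-10) {
  p <- as_composition(p, what = "p", quiet = TRUE)
  algos <- names(m_by_algo)
  weights <- resolve_weights(weights, algos)
  total <- 0
  for (a in algos) {
    m <- as_misclass_matrix(m_by_algo[[a]])
    la <- 0
    if (!is.null(paired) && nrow(paired)) {
      y <- va_matrix(paired, a, cause_list)
      keep <- !apply(is.na(y), 1, any)
      x <- mits_matrix(paired, cause_list)[keep, , drop = FALSE]
      la <- la - sum(y[keep, , drop = FALSE] * safe_log(x %*% m, epsilon))
    }
    if (!is.null(survey) && nrow(survey)) {
      y <- va_matrix(survey, a, cause_list)
      if (anyNA(y))
        stop_input("survey '%s' has unimputed inconclusive records", a)
      qa <- drop(crossprod(m, p))
      la <- la - sum(colSums(y) * safe_log(qa, epsilon))
    }
    total <- total + weights[[a]] * la
  }
  total
}

resolve_weights <- function(weights, algos) {
  if (is.null(weights)) return(setNames(rep(1, length(algos)), algos))
  if (is.null(names(weights))) {
    stopifnot(length(weights) == length(algos))
    return(setNames(as.numeric(weights), algos))
  }
  miss <- setdiff(algos, names(weights))
  if (length(miss)) stop_input("no loss weight for algorithm(s): %s",
                               paste(miss, collapse = ", "))
  setNames(as.numeric(weights[algos]), algos)
}

# ---- the sampler ----------------------------------------------------------

#' Calibrate CSMFs by generalized-Bayes MCMC
#'
#' Samples the generalized posterior over the population CSMF p and the
#' per-algorithm misclassification matrices M_a jointly, propagating the
#' uncertainty of the paired calibration data into the calibrated CSMF.
#' Sampling is random-walk Metropolis within Gibbs blocks (one block for p,
#' one per M row) on additive-log-ratio coordinates, so every retained draw
#' lies exactly on the simplex. Proposal scales adapt toward ~25% acceptance
#' during burn-in. M blocks are initialized at the pseudo-ML fit from
#' [fit_misclassification()]; p starts at the raw survey CSMF.
#'
#' Passing more than one algorithm performs the ensemble calibration: the
#' losses are summed (equal weights by default, see
#' `gb_config(loss_weights=)`), so the calibrated CSMF is consistent with all
#' algorithms at once.
#'
#' @param paired Paired record tibble (imputed/grouped/site-filtered).
#' @param survey Survey record tibble (imputed/grouped).
#' @param cause_list A [cause_list()].
#' @param algorithms Algorithm names to calibrate with (default: all
#'   detected).
#' @param config A [gb_config()].
#' @param fix_m Optional named list of matrices to hold fixed (no M
#'   sampling), e.g. `list(insilicova = diag(7))`; used for reductions and
#'   checks.
#' @param pointwise Compute per-record loss contributions for WAIC (capped at
#'   `max_pointwise_draws` evenly spaced draws).
#' @param max_pointwise_draws Cap on draws used for the pointwise matrix.
#' @return Object of class `va_calibration` with elements `p_draws` (draws x
#'   C), `m_draws` (per algorithm, draws x C x C), `chain`, `pointwise_loss`
#'   (draws x records, attribute `type` marking paired/survey columns),
#'   `diagnostics` (split-Rhat, ESS per cause), `acceptance`, `q_raw`,
#'   `m_init`, `cause_list`, `algorithms`, `config`.
#' @export
calibrate_csmf <- function(paired, survey, cause_list, algorithms = NULL,
                           config = gb_config(), fix_m = NULL,
                           pointwise = TRUE, max_pointwise_draws = 1000) {
  C <- length(cause_list)
  algorithms <- algorithms %||% attr(survey, "algorithms") %||%
    detect_algorithms(survey, cause_list)
  if (!length(algorithms)) stop_input("no algorithms to calibrate")
  w <- resolve_weights(config$loss_weights, algorithms)
  eps <- config$epsilon
  lr <- config$learning_rate

  # data blocks per algorithm
  dat <- list()
  for (a in algorithms) {
    ya_s <- va_matrix(survey, a, cause_list)
    if (anyNA(ya_s))
      stop_input("survey '%s' has unimputed inconclusive records", a)
    blk <- list(ys_agg = colSums(ya_s), ys = ya_s)
    if (!is.null(paired) && nrow(paired)) {
      yp <- va_matrix(paired, a, cause_list)
      keep <- !apply(is.na(yp), 1, any)
      blk$yp <- yp[keep, , drop = FALSE]
      blk$x <- mits_matrix(paired, cause_list)[keep, , drop = FALSE]
    }
    dat[[a]] <- blk
  }
  n_survey <- nrow(survey)
  q_raw <- lapply(dat, function(b) b$ys_agg / n_survey)

  # initial values
  m_init <- lapply(algorithms, function(a) {
    if (!is.null(fix_m[[a]])) return(as_misclass_matrix(fix_m[[a]],
                                                        cause_list$causes))
    if (is.null(dat[[a]]$x))
      return(as_misclass_matrix(matrix(1 / C, C, C), cause_list$causes))
    fit_multicause_M(dat[[a]]$x, dat[[a]]$yp, epsilon = eps,
                     causes = cause_list$causes)$m
  })
  names(m_init) <- algorithms
  sample_m <- setNames(!algorithms %in% names(fix_m %||% list()), algorithms)

  p0 <- Reduce(`+`, q_raw) / length(q_raw)
  p0 <- pmax(p0, 1e-4); p0 <- p0 / sum(p0)

  alpha_p <- rep(config$prior_p, length.out = C)
  alpha_m <- if (is.matrix(config$prior_m)) config$prior_m else
    matrix(config$prior_m, C, C)

  paired_loss <- function(a, m) {
    b <- dat[[a]]
    if (is.null(b$x)) 0 else -sum(b$yp * safe_log(b$x %*% m, eps))
  }
  survey_loss <- function(a, m, p)
    -sum(dat[[a]]$ys_agg * safe_log(drop(crossprod(m, p)), eps))

  if (!is.finite(sum(vapply(algorithms, function(a)
    paired_loss(a, m_init[[a]]) + survey_loss(a, m_init[[a]], p0),
    numeric(1)))))
    stop_input("non-finite loss at initialization")

  n_keep <- config$n_iter - config$n_burn
  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + ch)
    chains[[ch]] <- run_gb_chain(dat, algorithms, w, p0, m_init, sample_m,
                                 alpha_p, alpha_m, config, paired_loss,
                                 survey_loss, lr, C)
  }

  p_draws <- do.call(rbind, lapply(chains, `[[`, "p"))
  colnames(p_draws) <- cause_list$causes
  m_draws <- setNames(lapply(algorithms, function(a) {
    arr <- array(NA_real_, c(n_keep * config$n_chains, C, C),
                 dimnames = list(NULL, cause_list$causes, cause_list$causes))
    for (ch in seq_along(chains))
      arr[(ch - 1) * n_keep + seq_len(n_keep), , ] <- chains[[ch]]$m[[a]]
    arr
  }), algorithms)
  chain_id <- rep(seq_len(config$n_chains), each = n_keep)

  diagnostics <- mcmc_diagnostics(p_draws, chain_id, cause_list$causes)
  acceptance <- list(
    p = mean(vapply(chains, function(c) c$accept_p, numeric(1))),
    m = mean(vapply(chains, function(c) c$accept_m, numeric(1)))
  )
  if (any(diagnostics$rhat > 1.05, na.rm = TRUE))
    rlang::warn(sprintf("split-Rhat > 1.05 for: %s; consider longer chains",
                        paste(diagnostics$cause[diagnostics$rhat > 1.05],
                              collapse = ", ")))

  pw <- NULL
  if (pointwise)
    pw <- pointwise_loss_matrix(p_draws, m_draws, dat, algorithms, w, eps,
                                max_pointwise_draws)

  structure(list(p_draws = p_draws, m_draws = m_draws, chain = chain_id,
                 pointwise_loss = pw, diagnostics = diagnostics,
                 acceptance = acceptance, q_raw = q_raw, m_init = m_init,
                 cause_list = cause_list, algorithms = algorithms,
                 weights = w, config = config),
            class = "va_calibration")
}

# one chain of Metropolis-within-Gibbs; returns kept draws
run_gb_chain <- function(dat, algorithms, w, p0, m_init, sample_m, alpha_p,
                         alpha_m, config, paired_loss, survey_loss, lr, C) {
  n_iter <- config$n_iter; n_burn <- config$n_burn
  n_keep <- n_iter - n_burn
  zp <- alr(p0); p <- alr_inv(zp)
  M <- m_init
  zM <- lapply(M, function(m) t(apply(m, 1, alr)))
  pl <- vapply(algorithms, function(a) paired_loss(a, M[[a]]), numeric(1))
  sl <- vapply(algorithms, function(a) survey_loss(a, M[[a]], p), numeric(1))

  s_p <- config$proposal_scale
  s_m <- lapply(M, function(m) rep(config$proposal_scale, C))
  acc_p <- 0L; try_p <- 0L; acc_m <- 0L; try_m <- 0L
  # batch counters for burn-in adaptation
  bacc_p <- 0L; btry_p <- 0L
  bacc_m <- lapply(M, function(m) integer(C))
  btry_m <- lapply(M, function(m) integer(C))

  p_out <- matrix(NA_real_, n_keep, C)
  m_out <- lapply(M, function(m) array(NA_real_, c(n_keep, C, C)))
  keep_i <- 0L

  log_prior_p <- function(p) sum(alpha_p * log(pmax(p, 1e-300)))
  log_prior_mrow <- function(row, i) sum(alpha_m[i, ] * log(pmax(row, 1e-300)))

  for (it in seq_len(n_iter)) {
    # p block: only the survey terms depend on p
    zp_new <- zp + s_p * stats::rnorm(C - 1)
    p_new <- alr_inv(zp_new)
    sl_new <- vapply(algorithms, function(a) survey_loss(a, M[[a]], p_new),
                     numeric(1))
    log_r <- -lr * sum(w * sl_new) + log_prior_p(p_new) -
      (-lr * sum(w * sl) + log_prior_p(p))
    try_p <- try_p + 1L; btry_p <- btry_p + 1L
    if (log(stats::runif(1)) < log_r) {
      zp <- zp_new; p <- p_new; sl <- sl_new
      acc_p <- acc_p + 1L; bacc_p <- bacc_p + 1L
    }

    # M row blocks
    for (a in algorithms) {
      if (!sample_m[[a]]) next
      for (i in seq_len(C)) {
        z_new <- zM[[a]][i, ] + s_m[[a]][i] * stats::rnorm(C - 1)
        row_new <- alr_inv(z_new)
        m_new <- M[[a]]; m_new[i, ] <- row_new
        pl_new <- paired_loss(a, m_new)
        sl_a_new <- survey_loss(a, m_new, p)
        log_r <- -lr * w[[a]] * (pl_new + sl_a_new) +
          log_prior_mrow(row_new, i) -
          (-lr * w[[a]] * (pl[[a]] + sl[[a]]) +
             log_prior_mrow(M[[a]][i, ], i))
        try_m <- try_m + 1L; btry_m[[a]][i] <- btry_m[[a]][i] + 1L
        if (log(stats::runif(1)) < log_r) {
          zM[[a]][i, ] <- z_new; M[[a]] <- m_new
          pl[[a]] <- pl_new; sl[[a]] <- sl_a_new
          acc_m <- acc_m + 1L; bacc_m[[a]][i] <- bacc_m[[a]][i] + 1L
        }
      }
    }

    # scale adaptation in batches of 50, burn-in only
    if (it <= n_burn && it %% 50 == 0) {
      rate <- bacc_p / max(btry_p, 1L)
      s_p <- min(max(s_p * exp(rate - 0.25), 1e-3), 10)
      bacc_p <- 0L; btry_p <- 0L
      for (a in algorithms) {
        if (!sample_m[[a]]) next
        rate <- bacc_m[[a]] / pmax(btry_m[[a]], 1L)
        s_m[[a]] <- pmin(pmax(s_m[[a]] * exp(rate - 0.25), 1e-3), 10)
        bacc_m[[a]][] <- 0L; btry_m[[a]][] <- 0L
      }
    }

    if (it > n_burn) {
      keep_i <- keep_i + 1L
      p_out[keep_i, ] <- p / sum(p)        # exact simplex renormalization
      for (a in algorithms)
        m_out[[a]][keep_i, , ] <- M[[a]] / rowSums(M[[a]])
    }
  }
  list(p = p_out, m = m_out, accept_p = acc_p / max(try_p, 1L),
       accept_m = if (try_m > 0) acc_m / try_m else NA_real_)
}

# per-record loss contributions for WAIC, on a thinned set of draws
pointwise_loss_matrix <- function(p_draws, m_draws, dat, algorithms, w, eps,
                                  max_draws) {
  n_d <- nrow(p_draws)
  use <- if (n_d > max_draws) round(seq(1, n_d, length.out = max_draws)) else
    seq_len(n_d)
  first <- dat[[algorithms[1]]]
  n_paired <- if (is.null(first$x)) 0L else nrow(first$x)
  n_survey <- nrow(first$ys)
  out <- matrix(0, length(use), n_paired + n_survey)
  for (a in algorithms) {
    b <- dat[[a]]
    for (d in seq_along(use)) {
      k <- use[d]
      m <- m_draws[[a]][k, , ]
      if (n_paired)
        out[d, seq_len(n_paired)] <- out[d, seq_len(n_paired)] -
          w[[a]] * rowSums(b$yp * safe_log(b$x %*% m, eps))
      qa <- drop(crossprod(m, p_draws[k, ]))
      out[d, n_paired + seq_len(n_survey)] <-
        out[d, n_paired + seq_len(n_survey)] -
        w[[a]] * drop(b$ys %*% safe_log(qa, eps))
    }
  }
  attr(out, "type") <- rep(c("paired", "survey"), c(n_paired, n_survey))
  attr(out, "draws") <- use
  out
}

# split-Rhat and a simple autocorrelation-based ESS per component
mcmc_diagnostics <- function(draws, chain_id, causes) {
  split_chains <- function(v, id) {
    out <- list()
    for (c in unique(id)) {
      x <- v[id == c]
      h <- floor(length(x) / 2)
      out <- c(out, list(x[seq_len(h)], x[h + seq_len(h)]))
    }
    out
  }
  rhat1 <- function(chains) {
    m <- length(chains); n <- length(chains[[1]])
    if (n < 4) return(NA_real_)
    mu <- vapply(chains, mean, numeric(1))
    s2 <- vapply(chains, var, numeric(1))
    W <- mean(s2); B <- n * var(mu)
    if (W <= 0) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  }
  ess1 <- function(v) {
    n <- length(v)
    v <- v - mean(v)
    if (sd(v) == 0) return(n)
    nf <- stats::nextn(2 * n)
    ac <- Re(stats::fft(Mod(stats::fft(c(v, rep(0, nf - n))))^2,
                        inverse = TRUE))[seq_len(n)]
    ac <- ac / ac[1]
    # initial positive sequence
    s <- 0; k <- 1
    while (k + 1 < n) {
      pair <- ac[k + 1] + ac[k + 2]
      if (is.na(pair) || pair < 0) break
      s <- s + pair; k <- k + 2
    }
    max(1, n / (1 + 2 * s))
  }
  tibble::tibble(
    cause = causes,
    rhat = vapply(seq_along(causes), function(j)
      rhat1(split_chains(draws[, j], chain_id)), numeric(1)),
    ess = vapply(seq_along(causes), function(j) ess1(draws[, j]), numeric(1))
  )
}

# ---- posterior summaries --------------------------------------------------

#' Summarise a calibration posterior
#'
#' @param x A `va_calibration`.
#' @param level Credible level for equal-tailed intervals.
#' @param pars `"p"` (the CSMF) or `"m"` (misclassification matrices).
#' @param ... Unused.
#' @return Tibble: for `pars = "p"`, columns `cause`, `estimate` (posterior
#'   mean), `conf.low`, `conf.high`; for `pars = "m"` additionally
#'   `algorithm`, `mits_cause`, `va_cause`.
#' @export
tidy.va_calibration <- function(x, level = 0.95, pars = c("p", "m"), ...) {
  pars <- match.arg(pars)
  a2 <- (1 - level) / 2
  if (pars == "p") {
    return(tibble::tibble(
      cause = colnames(x$p_draws),
      estimate = colMeans(x$p_draws),
      conf.low = apply(x$p_draws, 2, quantile, a2),
      conf.high = apply(x$p_draws, 2, quantile, 1 - a2)
    ))
  }
  purrr::map_dfr(x$algorithms, function(a) {
    arr <- x$m_draws[[a]]
    C <- dim(arr)[2]
    grid <- expand.grid(i = seq_len(C), j = seq_len(C))
    tibble::tibble(
      algorithm = a,
      mits_cause = x$cause_list$causes[grid$i],
      va_cause = x$cause_list$causes[grid$j],
      estimate = mapply(function(i, j) mean(arr[, i, j]), grid$i, grid$j),
      conf.low = mapply(function(i, j) quantile(arr[, i, j], a2),
                        grid$i, grid$j),
      conf.high = mapply(function(i, j) quantile(arr[, i, j], 1 - a2),
                         grid$i, grid$j)
    )
  })
}

#' @rdname tidy.va_calibration
#' @export
glance.va_calibration <- function(x, ...) {
  tibble::tibble(
    n_draws = nrow(x$p_draws),
    n_chains = x$config$n_chains,
    algorithms = paste(x$algorithms, collapse = "+"),
    accept_p = x$acceptance$p,
    accept_m = x$acceptance$m,
    max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
    min_ess = min(x$diagnostics$ess, na.rm = TRUE)
  )
}

#' @export
print.va_calibration <- function(x, ...) {
  cat("<va_calibration> ", paste(x$algorithms, collapse = " + "), ", ",
      nrow(x$p_draws), " draws (", x$config$n_chains, " chains)\n", sep = "")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Calibrated vs raw CSMF plot
#'
#' Diamonds mark the raw (uncalibrated) CSMF; points and vertical bars the
#' calibrated posterior means and credible intervals.
#'
#' @param object A `va_calibration`.
#' @param level Credible level.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.va_calibration <- function(object, level = 0.95, ...) {
  cal <- tidy(object, level = level)
  raw <- tibble::tibble(
    cause = rep(object$cause_list$causes, length(object$q_raw)),
    algorithm = rep(names(object$q_raw),
                    each = length(object$cause_list$causes)),
    csmf = unlist(object$q_raw, use.names = FALSE)
  )
  cal$cause <- factor(cal$cause, levels = object$cause_list$causes)
  raw$cause <- factor(raw$cause, levels = object$cause_list$causes)
  ggplot2::ggplot(cal, ggplot2::aes(.data$cause, .data$estimate)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$conf.low,
                                        ymax = .data$conf.high),
                           width = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_point(data = raw,
                        ggplot2::aes(y = .data$csmf, shape = .data$algorithm),
                        size = 2.5, colour = "firebrick") +
    ggplot2::scale_shape_manual(values = c(5, 6, 9, 10)[
      seq_along(object$q_raw)]) +
    ggplot2::labs(y = "CSMF", x = NULL, shape = "raw",
                  title = "Calibrated (point + interval) vs raw (diamond) CSMF") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 40, hjust = 1))
}

#' Uncalibrated generalized posterior over the CSMF
#'
#' Under the no-misclassification model (M fixed at the identity) the
#' generalized posterior for p given survey compositions is conjugate:
#' exp(sum_k y_k . log p) times a Dirichlet(alpha) prior is
#' Dirichlet(alpha + colSums(Y)) (aggregate scores act as pseudo-counts, per
#' algorithm loss weight). Draws are taken directly from that closed form.
#'
#' @param survey Survey record tibble.
#' @param cause_list A [cause_list()].
#' @param algorithms Algorithm(s) whose (weighted) losses to combine.
#' @param n_draws Number of posterior draws.
#' @param prior_p Dirichlet prior concentration.
#' @param weights Per-algorithm loss weights.
#' @param seed Integer seed.
#' @return List of class `va_uncalibrated`: `p_draws` (draws x C), `alpha`
#'   (posterior concentration), `algorithms`, `cause_list`.
#' @export
uncalibrated_posterior <- function(survey, cause_list, algorithms = NULL,
                                   n_draws = 2000, prior_p = 1, weights = NULL,
                                   seed = 1L) {
  algorithms <- algorithms %||% attr(survey, "algorithms") %||%
    detect_algorithms(survey, cause_list)
  w <- resolve_weights(weights, algorithms)
  C <- length(cause_list)
  alpha <- rep(prior_p, length.out = C)
  for (a in algorithms) {
    y <- va_matrix(survey, a, cause_list)
    if (anyNA(y)) stop_input("survey '%s' has unimputed records", a)
    alpha <- alpha + w[[a]] * colSums(y)
  }
  set.seed(seed)
  draws <- rdirichlet(n_draws, alpha)
  colnames(draws) <- cause_list$causes
  structure(list(p_draws = draws, alpha = setNames(alpha, cause_list$causes),
                 algorithms = algorithms, weights = w,
                 cause_list = cause_list),
            class = "va_uncalibrated")
}
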