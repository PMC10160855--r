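# Synthetic data with the statistical structure the calibration assumes:
# a calibration population with paired MITS + VA records (distinct CSMF from
# the survey population), an underlying -> immediate transition kernel, a
# probabilistic (Dirichlet) VA algorithm and a rank-based 0.75/0.25
# algorithm, a stated fraction of inconclusive records, and a site flag.

#' Configuration for the synthetic-data generator
#'
#' Defaults mirror the child-stratum study conditions: 7 causes, 426 paired
#' calibration deaths, 1,841 survey deaths, distinct calibration and survey
#' CSMFs, an immediate-cause kernel with substantial off-diagonal mass, one
#' probabilistic algorithm (`"insilicova"`-like, Dirichlet output) and one
#' rank-based algorithm (`"eava"`-like, 0.75/0.25 two-spike output) with an
#' 18% inconclusive rate.
#'
#' @param C Number of causes (>= 2).
#' @param n_paired,n_survey Record counts for the two populations.
#' @param p_survey True CSMF of the survey population.
#' @param p_calib_underlying CSMF of underlying causes in the calibration
#'   population (deliberately different from `p_survey`; the method assumes
#'   shared misclassification rates, not shared CSMFs).
#' @param immediate_kernel C x C row-stochastic matrix: row i is the
#'   distribution of the immediate cause given underlying cause i. Diagonal
#'   mass yields single-cause deaths.
#' @param M_true Named list of true row-stochastic misclassification matrices,
#'   one per algorithm.
#' @param algo_type Named character vector, `"probabilistic"` or `"rank"` per
#'   algorithm.
#' @param concentration Dirichlet concentration of the probabilistic
#'   algorithm's output around the relevant M row (mean-preserving; larger is
#'   less noisy).
#' @param eava_weight Weight on the first-ranked cause of the rank algorithm,
#'   in (0.5, 1].
#' @param p_inconclusive Probability that a rank-algorithm output is
#'   inconclusive (scores withheld).
#' @param p_site_excluded Probability a paired record is flagged with site
#'   `"excluded"`.
#' @param causes Optional cause labels (default `cause1..causeC`).
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(C = 7, n_paired = 426, n_survey = 1841,
                       p_survey = NULL, p_calib_underlying = NULL,
                       immediate_kernel = NULL, M_true = NULL,
                       algo_type = NULL, concentration = 8,
                       eava_weight = 0.75, p_inconclusive = 0.18,
                       p_site_excluded = 0, causes = NULL, seed = 1L) {
  stopifnot(C >= 2, n_paired >= 0, n_survey >= 0, concentration > 0,
            eava_weight > 0.5, eava_weight <= 1,
            p_inconclusive >= 0, p_inconclusive < 1,
            p_site_excluded >= 0, p_site_excluded < 1)
  causes <- causes %||% paste0("cause", seq_len(C))
  # default CSMFs: smoothly decaying, and shifted between the two populations
  p_survey <- as_composition(p_survey %||% {
    w <- 0.75^(seq_len(C) - 1); w / sum(w)
  }, what = "p_survey", quiet = TRUE)
  p_calib_underlying <- as_composition(p_calib_underlying %||% {
    w <- 0.75^(rev(seq_len(C)) - 1); w / sum(w)
  }, what = "p_calib_underlying", quiet = TRUE)
  immediate_kernel <- immediate_kernel %||% {
    k <- matrix(0.3 / (C - 1), C, C); diag(k) <- 0.7; k
  }
  immediate_kernel <- as_misclass_matrix(immediate_kernel, causes)
  M_true <- M_true %||% {
    m <- matrix(0.35 / (C - 1), C, C); diag(m) <- 0.65
    list(insilicova = m, eava = as_misclass_matrix(0.6 * m + 0.4 / C, causes))
  }
  M_true <- lapply(M_true, as_misclass_matrix, causes = causes)
  if (is.null(names(M_true)) || any(names(M_true) == ""))
    stop_input("M_true must be a named list (one matrix per algorithm)")
  if (any(vapply(M_true, function(m) any(rowSums(m) <= 0), logical(1))))
    stop_input("degenerate all-zero row in M_true")
  algo_type <- algo_type %||%
    setNames(ifelse(grepl("eava", names(M_true)), "rank", "probabilistic"),
             names(M_true))
  stopifnot(all(names(M_true) %in% names(algo_type)),
            all(algo_type %in% c("probabilistic", "rank")))
  structure(list(C = C, n_paired = n_paired, n_survey = n_survey,
                 p_survey = p_survey, p_calib_underlying = p_calib_underlying,
                 immediate_kernel = immediate_kernel, M_true = M_true,
                 algo_type = algo_type[names(M_true)],
                 concentration = concentration, eava_weight = eava_weight,
                 p_inconclusive = p_inconclusive,
                 p_site_excluded = p_site_excluded, causes = causes,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> C =", x$C, "| paired", x$n_paired, "| survey", x$n_survey,
      "| algorithms:", paste(names(x$M_true), collapse = ", "), "\n")
  invisible(x)
}

# VA outputs for latent single cause z (vector), one algorithm
sim_va_scores <- function(cfg, a, z) {
  n <- length(z)
  M <- cfg$M_true[[a]]
  C <- cfg$C
  if (cfg$algo_type[[a]] == "probabilistic") {
    alpha <- cfg$concentration * M[z, , drop = FALSE]
    return(rdirichlet(n, alpha))
  }
  # rank algorithm: first cause ~ M row, second from the renormalized
  # remainder; two-spike eava_weight / (1 - eava_weight) output
  first <- sample_rows(M[z, , drop = FALSE])
  w2 <- M[z, , drop = FALSE]
  w2[cbind(seq_len(n), first)] <- 0
  rs <- rowSums(w2)
  flat <- rs <= 0        # only one positive entry in the row: uniform fallback
  if (any(flat)) {
    w2[flat, ] <- 1
    w2[cbind(which(flat), first[flat])] <- 0
    rs[flat] <- rowSums(w2[flat, , drop = FALSE])
  }
  second <- sample_rows(w2 / rs)
  y <- matrix(0, n, C)
  y[cbind(seq_len(n), first)] <- cfg$eava_weight
  y[cbind(seq_len(n), second)] <- y[cbind(seq_len(n), second)] +
    (1 - cfg$eava_weight)
  y
}

assemble_records <- function(cfg, z, ids, paired, ui = NULL, ii = NULL,
                             x = NULL, site = NULL) {
  n <- length(z)
  out <- tibble::tibble(id = ids)
  if (paired) {
    out$underlying <- cfg$causes[ui]
    out$immediate <- cfg$causes[ii]
    out$site <- site
    colnames(x) <- cause_cols("x", cfg$causes)
    out <- dplyr::bind_cols(out, tibble::as_tibble(as.data.frame(x)))
  }
  for (a in names(cfg$M_true)) {
    y <- sim_va_scores(cfg, a, z)
    inc <- if (cfg$algo_type[[a]] == "rank" && cfg$p_inconclusive > 0)
      stats::runif(n) < cfg$p_inconclusive else rep(FALSE, n)
    y[inc, ] <- NA_real_
    colnames(y) <- algo_cols(a, cfg$causes)
    out <- dplyr::bind_cols(out, tibble::as_tibble(as.data.frame(y)))
    out[[paste0(a, "_inconclusive")]] <- inc
    out[[paste0(a, "_imputed")]] <- FALSE
  }
  attr(out, "algorithms") <- names(cfg$M_true)
  out
}

#' Generate the paired (calibration) population
#'
#' Per death: an underlying cause is drawn from `p_calib_underlying`, an
#' immediate cause from the corresponding `immediate_kernel` row, and the
#' MITS encoding is formed by [encode_mits()]. A latent single cause z is
#' drawn from the encoding x (the mixture interpretation of the two-cause
#' record), and each algorithm's VA output is generated around row z of its
#' true misclassification matrix. Rank-algorithm outputs are marked
#' inconclusive with probability `p_inconclusive`; a fraction
#' `p_site_excluded` of records is flagged with site `"excluded"`.
#'
#' @param cfg A [sim_config()].
#' @return Paired record tibble (possibly empty).
#' @export
simulate_paired <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_paired
  if (n == 0) return(empty_records(
    cause_list("custom", cfg$causes), "paired", names(cfg$M_true)))
  ui <- sample.int(cfg$C, n, replace = TRUE, prob = cfg$p_calib_underlying)
  ii <- sample_rows(cfg$immediate_kernel[ui, , drop = FALSE])
  x <- mits_encode_rows(ui, ii, cfg$C)
  # latent class: underlying or immediate with the weights in x
  z <- ifelse(stats::runif(n) < 0.5, ui, ii)   # x is 0.5/0.5 or one-hot
  z[ui == ii] <- ui[ui == ii]
  site <- ifelse(stats::runif(n) < cfg$p_site_excluded, "excluded", "included")
  assemble_records(cfg, z, sprintf("cal%05d", seq_len(n)), paired = TRUE,
                   ui = ui, ii = ii, x = x, site = site)
}

#' Generate the survey population
#'
#' As [simulate_paired()] but the (single) cause of each death is drawn from
#' `p_survey` and no MITS encoding or site is attached.
#'
#' @param cfg A [sim_config()].
#' @return Survey record tibble.
#' @export
simulate_survey <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  n <- cfg$n_survey
  if (n == 0) return(empty_records(
    cause_list("custom", cfg$causes), "survey", names(cfg$M_true)))
  z <- sample.int(cfg$C, n, replace = TRUE, prob = cfg$p_survey)
  assemble_records(cfg, z, sprintf("svy%05d", seq_len(n)), paired = FALSE)
}

#' Average-score matrix induced by the rank-algorithm generator
#'
#' The two-spike rank output draws the first cause from a row of `m` and the
#' second from the renormalized remainder, so its expected score vector is
#' not the row of `m` itself but
#' \deqn{E[y_j | z] = w\, m_{zj} + (1 - w) \sum_{i \ne j} m_{zi}
#'       \frac{m_{zj}}{1 - m_{zi}}.}
#' This function returns that induced row-stochastic matrix; it is the
#' population average-score misclassification matrix of the simulated rank
#' algorithm, and what [fit_multicause_M()] is consistent for on such data.
#' (For the probabilistic algorithm the Dirichlet output is mean-preserving
#' and the induced matrix is `m` itself.)
#'
#' @param m True row-stochastic matrix used by the generator.
#' @param w First-cause weight (the generator's `eava_weight`).
#' @return Row-stochastic matrix of expected scores.
#' @export
rank_effective_M <- function(m, w = 0.75) {
  m <- as_misclass_matrix(m)
  C <- ncol(m)
  out <- matrix(0, C, C, dimnames = dimnames(m))
  for (z in seq_len(C)) {
    row <- m[z, ]
    p2 <- numeric(C)
    for (i in which(row > 0)) {
      rem <- row; rem[i] <- 0
      q <- if (sum(rem) > 0) rem / sum(rem) else {
        u <- rep(1 / (C - 1), C); u[i] <- 0; u
      }
      p2 <- p2 + row[i] * q
    }
    out[z, ] <- w * row + (1 - w) * p2
  }
  out
}

#' Write a simulated dataset to disk
#'
#' Writes `paired.csv`, `survey.csv` and a JSON sidecar `truth.json` holding
#' the generating parameters (including the seed).
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the list of file paths.
#' @export
simulate_to_csv <- function(cfg, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paired <- simulate_paired(cfg)
  survey <- simulate_survey(cfg)
  paths <- list(paired = file.path(dir, "paired.csv"),
                survey = file.path(dir, "survey.csv"),
                truth = file.path(dir, "truth.json"))
  readr::write_csv(paired, paths$paired)
  readr::write_csv(survey, paths$survey)
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop_input("writing the truth sidecar requires the 'jsonlite' package")
  truth <- cfg
  class(truth) <- NULL
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(paths)
}
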