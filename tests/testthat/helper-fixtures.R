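# Shared builders for the test suite. Everything is generated in code; no
# binary fixtures.

cl3 <- cause_list("custom", c("alpha", "beta", "gamma"))

# diagonally dominant 3x3 misclassification matrix
diag_m <- function(C = 3, diag = 0.7) {
  m <- matrix((1 - diag) / (C - 1), C, C)
  diag(m) <- diag
  m
}

# small recovery-study configuration (single probabilistic algorithm)
recovery_cfg <- function(seed, n_paired = 500, n_survey = 2000) {
  sim_config(C = 3, n_paired = n_paired, n_survey = n_survey,
             p_survey = c(0.5, 0.3, 0.2),
             p_calib_underlying = c(0.2, 0.3, 0.5),
             M_true = list(insilicova = diag_m()),
             algo_type = c(insilicova = "probabilistic"),
             p_inconclusive = 0, causes = cl3$causes, seed = seed)
}

# two-algorithm configuration exercising imputation and both output types
twoalgo_cfg <- function(seed, n_paired = 300, n_survey = 1000,
                        p_inconclusive = 0.15, ...) {
  sim_config(C = 3, n_paired = n_paired, n_survey = n_survey,
             M_true = list(insilicova = diag_m(), eava = diag_m(diag = 0.6)),
             p_inconclusive = p_inconclusive, causes = cl3$causes,
             seed = seed, ...)
}

# build a paired tibble directly from matrices (x rows must be valid
# encodings; underlying/immediate derived from x for convenience)
paired_from_matrices <- function(x, y, cl, algorithm = "algo") {
  und <- apply(x, 1, function(r) cl$causes[which(r > 0)[1]])
  imm <- apply(x, 1, function(r) {
    nz <- which(r > 0)
    cl$causes[nz[length(nz)]]
  })
  out <- tibble::tibble(id = sprintf("r%03d", seq_len(nrow(x))),
                        underlying = und, immediate = imm,
                        site = "included")
  colnames(x) <- paste0("x_", cl$tokens)
  colnames(y) <- paste0(algorithm, "_", cl$tokens)
  out <- dplyr::bind_cols(out, tibble::as_tibble(as.data.frame(x)),
                          tibble::as_tibble(as.data.frame(y)))
  out[[paste0(algorithm, "_inconclusive")]] <- FALSE
  out[[paste0(algorithm, "_imputed")]] <- FALSE
  attr(out, "algorithms") <- algorithm
  out
}

survey_from_matrix <- function(y, cl, algorithm = "algo") {
  out <- tibble::tibble(id = sprintf("s%03d", seq_len(nrow(y))))
  colnames(y) <- paste0(algorithm, "_", cl$tokens)
  out <- dplyr::bind_cols(out, tibble::as_tibble(as.data.frame(y)))
  out[[paste0(algorithm, "_inconclusive")]] <- FALSE
  out[[paste0(algorithm, "_imputed")]] <- FALSE
  attr(out, "algorithms") <- algorithm
  out
}

# random row-stochastic matrix
random_stochastic <- function(C, conc = 2) {
  m <- matrix(rgamma(C * C, conc), C)
  m / rowSums(m)
}

# brute-force KL-loss oracle for a 2x2 misclassification fit: grid over the
# two free parameters (row-wise first entries) at the given step
grid_fit_2x2 <- function(x, y, step = 1e-3, epsilon = 1e-10) {
  a <- seq(0, 1, by = step)
  b <- seq(0, 1, by = step)
  best <- c(NA, NA); best_loss <- Inf
  for (bi in b) {
    # predicted first-column mass for every record, vectorised over a
    p1 <- outer(x[, 1], a) + x[, 2] * bi          # n x length(a)
    l <- -colSums(y[, 1] * log(pmax(p1, epsilon)) +
                    y[, 2] * log(pmax(1 - p1, epsilon)))
    j <- which.min(l)
    if (l[j] < best_loss) { best_loss <- l[j]; best <- c(a[j], bi) }
  }
  list(m = rbind(c(best[1], 1 - best[1]), c(best[2], 1 - best[2])),
       loss = best_loss)
}
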