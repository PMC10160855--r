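# Data adjustments applied before misclassification estimation and
# calibration: the {1, 0.5, 0} MITS encoding, the plurality rule, the
# two-pass EAVA multi-cause construction, imputation of inconclusive
# records, site exclusion, cause grouping and raw CSMF aggregation.

#' Encode MITS underlying and immediate causes as a composition
#'
#' Up to two reference causes (underlying and immediate) are captured per
#' death. The encoding `x` assigns 1 to a cause identified as both underlying
#' and immediate, 0.5 to a cause identified as exactly one of the two, and 0
#' otherwise. A missing immediate cause is treated as single-cause.
#'
#' @param underlying Underlying cause label.
#' @param immediate Immediate cause label, or `NA`.
#' @param cause_list A [cause_list()].
#' @return Named numeric vector over `cause_list$causes` with entries in
#'   \{0, 0.5, 1\}.
#' @examples
#' encode_mits("infection", "prematurity", cause_list("neonates"))
#' @export
encode_mits <- function(underlying, immediate = NA, cause_list) {
  u <- cause_index(underlying, cause_list, "underlying cause")
  i <- if (is.na(immediate) || !nzchar(immediate)) NA_integer_ else
    cause_index(immediate, cause_list, "immediate cause")
  x <- drop(mits_encode_rows(u, i, length(cause_list)))
  names(x) <- cause_list$causes
  x
}

# vectorised worker: ui, ii integer indices (ii may be NA)
mits_encode_rows <- function(ui, ii, C) {
  n <- length(ui)
  x <- matrix(0, n, C)
  ii <- ifelse(is.na(ii), ui, ii)
  single <- ii == ui
  x[cbind(which(single), ui[single])] <- 1
  x[cbind(which(!single), ui[!single])] <- 0.5
  x[cbind(which(!single), ii[!single])] <- 0.5
  x
}

#' Collapse a probabilistic cause composition to a single cause
#'
#' The plurality rule picks the cause with the highest score. Ties are broken
#' deterministically to the lowest cause index.
#'
#' @param y Composition (numeric vector).
#' @param tie_break Only `"lowest-index"` is implemented.
#' @return Integer cause index.
#' @export
plurality_rule <- function(y, tie_break = "lowest-index") {
  tie_break <- match.arg(tie_break)
  y <- as_composition(y, what = "plurality input", quiet = TRUE)
  which.max(y)
}

#' Build a two-cause EAVA-style composition
#'
#' The deterministic EAVA algorithm is run twice: once normally to find the
#' most likely cause, and once with that cause removed from its hierarchy to
#' find a runner-up. The multi-cause output assigns weight `w` (default 0.75)
#' to the first cause and `1 - w` to the second.
#'
#' @param first,second Cause labels; must differ.
#' @param w Weight on the first cause, in (0.5, 1].
#' @param cause_list A [cause_list()].
#' @return Named composition.
#' @export
eava_multicause <- function(first, second, w = 0.75, cause_list) {
  if (!(w > 0.5 && w <= 1)) stop_input("w must lie in (0.5, 1]")
  fi <- cause_index(first, cause_list, "first cause")
  si <- cause_index(second, cause_list, "second cause")
  if (fi == si) stop_input("first and second cause must differ")
  y <- numeric(length(cause_list))
  y[fi] <- w; y[si] <- 1 - w
  names(y) <- cause_list$causes
  y
}

#' Impute inconclusive survey records
#'
#' Survey deaths for which an algorithm is inconclusive (no cause identified)
#' are assigned the element-wise mean composition of all conclusive records
#' of that algorithm; the `<algorithm>_imputed` flag is set. Conclusive
#' records are untouched.
#'
#' @param data Survey record tibble.
#' @param algorithm Algorithm name.
#' @param cause_list A [cause_list()].
#' @return `data` with inconclusive scores filled in.
#' @export
impute_survey_inconclusive <- function(data, algorithm, cause_list) {
  inc <- inconclusive_flags(data, algorithm)
  if (!any(inc)) return(data)
  if (all(inc))
    stop_input("no conclusive '%s' records to impute from", algorithm)
  cols <- algo_cols(algorithm, cause_list$causes)
  y <- as.matrix(data[cols])
  mean_y <- colMeans(y[!inc, , drop = FALSE])
  mean_y <- mean_y / sum(mean_y)
  y[inc, ] <- matrix(mean_y, sum(inc), length(cols), byrow = TRUE)
  data[cols] <- as.data.frame(y)
  data[[paste0(algorithm, "_imputed")]] <- inc
  data
}

#' Impute inconclusive paired (calibration) records
#'
#' A paired death with an inconclusive algorithm result is assigned, as its
#' VA composition, the row of the algorithm's *single-cause* misclassification
#' matrix indexed by the death's MITS underlying cause. That matrix is
#' computed from the conclusive records only, against the single-cause MITS
#' assignment (underlying cause, one-hot encoding) — i.e. row i is the mean
#' conclusive VA composition among deaths with underlying cause i.
#'
#' @inheritParams impute_survey_inconclusive
#' @return `data` with inconclusive scores filled in.
#' @export
impute_paired_inconclusive <- function(data, algorithm, cause_list) {
  inc <- inconclusive_flags(data, algorithm)
  if (!any(inc)) return(data)
  if (all(inc))
    stop_input("no conclusive '%s' records to impute from", algorithm)
  cols <- algo_cols(algorithm, cause_list$causes)
  y <- as.matrix(data[cols])
  ui <- cause_index(data$underlying, cause_list, "underlying cause")
  conc <- !inc
  need <- unique(ui[inc])
  absent <- setdiff(need, unique(ui[conc]))
  if (length(absent))
    stop_input("cannot impute '%s': no conclusive record with underlying cause %s",
               algorithm, paste(cause_list$causes[absent], collapse = ", "))
  m_single <- rowsum(y[conc, , drop = FALSE], group = ui[conc])
  m_single <- m_single / rowSums(m_single)
  y[inc, ] <- m_single[match(ui[inc], as.integer(rownames(m_single))), ,
                       drop = FALSE]
  data[cols] <- as.data.frame(y)
  data[[paste0(algorithm, "_imputed")]] <- inc
  data
}

inconclusive_flags <- function(data, algorithm) {
  col <- paste0(algorithm, "_inconclusive")
  imp <- paste0(algorithm, "_imputed")
  inc <- if (col %in% names(data)) as.logical(data[[col]]) else
    rep(FALSE, nrow(data))
  inc[is.na(inc)] <- FALSE
  if (imp %in% names(data)) inc <- inc & !as.logical(data[[imp]])
  inc
}

#' Drop records from excluded sites
#'
#' @param data Paired record tibble with a `site` column.
#' @param sites Character vector of site labels to exclude.
#' @return Filtered tibble; the number of removed records is reported.
#' @export
exclude_sites <- function(data, sites) {
  if (!length(sites) || !"site" %in% names(data)) return(data)
  drop <- data$site %in% sites
  rlang::inform(sprintf("excluding %d record(s) from site(s): %s", sum(drop),
                        paste(sites, collapse = ", ")))
  data[!drop, , drop = FALSE]
}

#' Aggregate scores and raw (uncalibrated) CSMF
#'
#' Sums an algorithm's per-death compositions over all records and divides by
#' the number of deaths, giving the apparent CSMF `q` — the uncalibrated
#' population estimate that the calibration corrects.
#'
#' @inheritParams impute_survey_inconclusive
#' @return Tibble with columns `cause`, `aggregate`, `csmf`.
#' @export
raw_csmf <- function(data, algorithm, cause_list) {
  if (nrow(data) == 0) stop_input("no records")
  y <- va_matrix(data, algorithm, cause_list)
  if (anyNA(y))
    stop_input("'%s' has unimputed inconclusive records; impute first", algorithm)
  agg <- colSums(y)
  tibble::tibble(cause = cause_list$causes, aggregate = unname(agg),
                 csmf = unname(agg) / nrow(data))
}

#' Expand a MITS contingency table into per-death paired records
#'
#' Each count in an underlying-by-immediate contingency table becomes one
#' record whose MITS encoding comes from [encode_mits()]. No VA scores are
#' attached (the published tables carry none).
#'
#' @param table Integer matrix as returned by `load_fixture("table3")` /
#'   `"table4"`, rows underlying and columns immediate causes.
#' @param cause_list A [cause_list()].
#' @return Paired-record tibble with `underlying`, `immediate` and `x_*`
#'   columns.
#' @export
contingency_to_paired <- function(table, cause_list) {
  C <- length(cause_list)
  stopifnot(nrow(table) == C, ncol(table) == C)
  ri <- cause_index(rownames(table), cause_list, "underlying cause")
  ci <- cause_index(colnames(table), cause_list, "immediate cause")
  cells <- which(table > 0, arr.ind = TRUE)
  ui <- rep(ri[cells[, 1]], table[cells])
  ii <- rep(ci[cells[, 2]], table[cells])
  x <- mits_encode_rows(ui, ii, C)
  colnames(x) <- cause_cols("x", cause_list$causes)
  out <- tibble::tibble(id = sprintf("mits%04d", seq_along(ui)),
                        underlying = cause_list$causes[ui],
                        immediate = cause_list$causes[ii],
                        site = NA_character_)
  dplyr::bind_cols(out, tibble::as_tibble(as.data.frame(x)))
}

#' Collapse fine causes onto a grouped cause vocabulary
#'
#' Applies the `grouping` map of `cause_list` to a record tibble whose score
#' columns are indexed by fine causes: score columns are summed within each
#' group (mass-preserving) and `underlying`/`immediate` labels are relabelled.
#' Grouping is applied before every other preprocessing step.
#'
#' @param data Record tibble with fine-cause score columns.
#' @param cause_list A [cause_list()] whose `grouping` maps each fine cause to
#'   one of its `causes`.
#' @param algorithms Algorithm prefixes present in `data`; detected when
#'   `NULL`.
#' @return Tibble with score columns over the grouped causes.
#' @export
group_causes <- function(data, cause_list, algorithms = NULL) {
  g <- cause_list$grouping
  if (is.null(g)) stop_input("cause_list has no grouping map")
  fine <- names(g)
  fine_tok <- cause_token(fine)
  grp_idx <- cause_index(unname(g), cause_list, "group label")
  prefixes <- c(algorithms %||% detect_algorithms_fine(data, fine_tok),
                if (any(startsWith(names(data), "x_"))) "x")
  out <- data
  for (pf in unique(prefixes)) {
    cols <- paste0(pf, "_", fine_tok)
    have <- cols %in% names(out)
    if (!any(have)) next
    if (!all(have))
      stop_input("prefix '%s': missing fine-cause column(s) %s", pf,
                 paste(cols[!have], collapse = ", "))
    y <- as.matrix(out[cols])
    gsum <- sapply(seq_along(cause_list$causes), function(k)
      rowSums(y[, grp_idx == k, drop = FALSE]))
    if (nrow(out) == 1) gsum <- matrix(gsum, nrow = 1)
    colnames(gsum) <- paste0(pf, "_", cause_list$tokens)
    out <- out[setdiff(names(out), cols)]
    out <- dplyr::bind_cols(out, tibble::as_tibble(as.data.frame(gsum)))
  }
  relabel <- function(v) {
    hit <- match(cause_token(v), fine_tok)
    ifelse(is.na(hit), v, unname(g)[hit])
  }
  for (col in intersect(c("underlying", "immediate"), names(out)))
    out[[col]] <- relabel(out[[col]])
  out
}

detect_algorithms_fine <- function(data, fine_tokens) {
  pat <- paste0("_", fine_tokens[1], "$")
  cand <- sub(pat, "", grep(pat, names(data), value = TRUE))
  setdiff(cand, "x")
}
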