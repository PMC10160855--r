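#' Read per-death VA records from CSV
#'
#' Reads a paired (calibration) or survey record table. Expected columns:
#'
#' * `id` — record identifier (created if absent);
#' * paired schema only: `underlying` (cause label), `immediate` (cause label
#'   or blank), `site`;
#' * per algorithm `a`: one score column per cause, named `<a>_<cause token>`
#'   (e.g. `insilicova_malaria`), and optionally `<a>_inconclusive`
#'   (logical/0-1).
#'
#' Score rows of a conclusive record must be nonnegative and sum to 1; sums
#' off by at most 1e-6 are renormalized with a warning, larger deviations are
#' an error. Scores of inconclusive records are ignored and stored as `NA`
#' until imputed (see [impute_survey_inconclusive()],
#' [impute_paired_inconclusive()]). For the paired schema the MITS encoding
#' columns `x_<cause token>` are rebuilt from `underlying`/`immediate` via
#' [encode_mits()].
#'
#' @param path CSV file path.
#' @param cause_list A [cause_list()].
#' @param schema `"paired"` or `"survey"`.
#' @param algorithms Character vector of algorithm names; by default detected
#'   from the header (any prefix with a full set of cause columns).
#' @return A tibble, one row per death.
#' @export
read_va_records <- function(path, cause_list, schema = c("paired", "survey"),
                            algorithms = NULL) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop_input("file not found: %s", path)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  algorithms <- algorithms %||% detect_algorithms(raw, cause_list)
  if (!length(algorithms))
    stop_input("no algorithm score columns found (expected e.g. '%s')",
               cause_cols("algo", cause_list$causes)[1])
  for (a in algorithms) {
    miss <- setdiff(algo_cols(a, cause_list$causes), names(raw))
    if (length(miss))
      stop_input("missing required column(s) for algorithm '%s': %s", a,
                 paste(miss, collapse = ", "))
  }
  if (schema == "paired") {
    if (!"underlying" %in% names(raw))
      stop_input("paired schema requires an 'underlying' column")
    if (!"immediate" %in% names(raw)) raw$immediate <- NA_character_
    if (!"site" %in% names(raw)) raw$site <- NA_character_
  }
  if (!"id" %in% names(raw)) raw$id <- sprintf("rec%05d", seq_len(nrow(raw)))
  raw$id <- as.character(raw$id)

  out <- tibble::as_tibble(raw)
  if (nrow(out) == 0) return(empty_records(cause_list, schema, algorithms))

  for (a in algorithms) {
    inc_col <- paste0(a, "_inconclusive")
    inc <- if (inc_col %in% names(out)) as.logical(out[[inc_col]]) else
      rep(FALSE, nrow(out))
    inc[is.na(inc)] <- FALSE
    out[[inc_col]] <- inc
    cols <- algo_cols(a, cause_list$causes)
    y <- as.matrix(out[cols])
    if (any(!inc))
      y[!inc, ] <- validate_score_matrix(y[!inc, , drop = FALSE],
                                         what = paste0(a, " scores"))
    y[inc, ] <- NA_real_
    out[cols] <- as.data.frame(y)
    imp_col <- paste0(a, "_imputed")
    if (!imp_col %in% names(out)) out[[imp_col]] <- FALSE
  }

  if (schema == "paired") {
    ui <- cause_index(out$underlying, cause_list, "underlying cause")
    imm <- ifelse(is.na(out$immediate) | out$immediate == "", NA, out$immediate)
    ii <- rep(NA_integer_, nrow(out))
    ii[!is.na(imm)] <- cause_index(imm[!is.na(imm)], cause_list,
                                   "immediate cause")
    x <- mits_encode_rows(ui, ii, length(cause_list))
    colnames(x) <- cause_cols("x", cause_list$causes)
    out <- dplyr::bind_cols(
      out[setdiff(names(out), colnames(x))],
      tibble::as_tibble(as.data.frame(x))
    )
  }
  attr(out, "algorithms") <- algorithms
  out
}

detect_algorithms <- function(data, cause_list) {
  first <- paste0("_", cause_token(cause_list$causes)[1], "$")
  cand <- sub(first, "", grep(first, names(data), value = TRUE))
  cand <- setdiff(cand, "x")
  cand[vapply(cand, function(a)
    all(algo_cols(a, cause_list$causes) %in% names(data)), logical(1))]
}

empty_records <- function(cause_list, schema, algorithms) {
  cols <- c("id",
            if (schema == "paired") c("underlying", "immediate", "site"),
            if (schema == "paired") cause_cols("x", cause_list$causes),
            unlist(lapply(algorithms, function(a)
              c(algo_cols(a, cause_list$causes),
                paste0(a, c("_inconclusive", "_imputed"))))))
  out <- tibble::as_tibble(setNames(rep(list(logical(0)), length(cols)), cols))
  attr(out, "algorithms") <- algorithms
  out
}

#' Extract an algorithm's score matrix from a record tibble
#'
#' @param data Record tibble (paired or survey).
#' @param algorithm Algorithm name (column prefix).
#' @param cause_list A [cause_list()].
#' @return Numeric matrix, records by causes.
#' @export
va_matrix <- function(data, algorithm, cause_list) {
  cols <- algo_cols(algorithm, cause_list$causes)
  miss <- setdiff(cols, names(data))
  if (length(miss))
    stop_input("no score columns for algorithm '%s' (missing %s)", algorithm,
               paste(miss, collapse = ", "))
  m <- as.matrix(data[cols])
  colnames(m) <- cause_list$causes
  m
}

#' Extract the MITS encoding matrix from a paired record tibble
#' @inheritParams va_matrix
#' @return Numeric matrix with entries in \{0, 0.5, 1\}.
#' @export
mits_matrix <- function(data, cause_list) {
  cols <- cause_cols("x", cause_list$causes)
  if (!all(cols %in% names(data)))
    stop_input("no MITS encoding columns (x_*) found; is this a paired table?")
  m <- as.matrix(data[cols])
  colnames(m) <- cause_list$causes
  m
}

#' Write / read a misclassification matrix as CSV
#'
#' Round-trips losslessly (shortest round-trip decimal representation): a
#' matrix written with `write_misclass()` and re-read with `read_misclass()`
#' is equal to the original to better than 1e-12. Writing validates
#' row-stochasticity first.
#'
#' @param m Square row-stochastic matrix.
#' @param path Output CSV path.
#' @param cause_list A [cause_list()] providing labels.
#' @return `write_misclass()` returns `path` invisibly; `read_misclass()`
#'   returns the validated matrix.
#' @export
write_misclass <- function(m, path, cause_list = NULL) {
  causes <- cause_list$causes %||% rownames(m) %||%
    paste0("cause", seq_len(nrow(m)))
  m <- as_misclass_matrix(m, causes)
  df <- tibble::tibble(mits_cause = causes)
  df <- dplyr::bind_cols(df, tibble::as_tibble(as.data.frame(m)))
  names(df) <- c("mits_cause", cause_token(causes))
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_misclass
#' @export
read_misclass <- function(path, cause_list = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[-1])
  if (is.null(cause_list)) return(as_misclass_matrix(m, df[[1]]))
  C <- length(cause_list)
  ri <- cause_index(df[[1]], cause_list, "MITS cause")
  ci <- cause_index(names(df)[-1], cause_list, "VA cause")
  out <- matrix(NA_real_, C, C)
  out[ri, ci] <- m
  if (anyNA(out)) stop_input("matrix file does not cover all causes of the cause_list")
  as_misclass_matrix(out, cause_list$causes)
}

#' Write / read a CSMF summary table as CSV
#'
#' @param summary A tibble (typically from [tidy.va_calibration()] or
#'   [raw_csmf()]).
#' @param path CSV path.
#' @return `write_csmf()` returns `path` invisibly; `read_csmf()` the tibble.
#' @export
write_csmf <- function(summary, path) {
  stopifnot(is.data.frame(summary))
  readr::write_csv(summary, path)
  invisible(path)
}

#' @rdname write_csmf
#' @export
read_csmf <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Packaged summary tables from the published child/neonate analyses
#'
#' Four small fixtures ship with the package, holding printed aggregate
#' results exactly as published (they are evidence, never re-derived):
#'
#' * `"table1"` — raw multi-cause aggregate scores and percentages for 1,841
#'   child (1-59 months) VA records, InSilicoVA and EAVA;
#' * `"table2"` — the same for 818 neonate VA records;
#' * `"table3"` — 7x7 contingency table of MITS underlying (rows) vs
#'   immediate (columns) causes for 426 children;
#' * `"table4"` — 5x5 contingency table for 340 neonates (after excluding the
#'   274 South Africa neonates).
#'
#' @param name One of `"table1"`, `"table2"`, `"table3"`, `"table4"`.
#' @return For tables 1-2 a tibble with columns `algorithm`, `cause`, `score`,
#'   `pct`, `n_total` (attribute `n`). For tables 3-4 an integer matrix
#'   (underlying x immediate) with class `contingency_table`.
#' @examples
#' load_fixture("table4")
#' @export
load_fixture <- function(name = c("table1", "table2", "table3", "table4")) {
  name <- match.arg(name)
  files <- c(table1 = "table1_child_raw_scores.csv",
             table2 = "table2_neonate_raw_scores.csv",
             table3 = "table3_child_mits_contingency.csv",
             table4 = "table4_neonate_mits_contingency.csv")
  path <- system.file("extdata", files[[name]], package = "vacalibrate",
                      mustWork = TRUE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (name %in% c("table1", "table2")) {
    out <- tibble::as_tibble(df)
    attr(out, "n") <- df$n_total[1]
    # aggregate scores must sum to n up to fixture rounding (one decimal)
    chk <- tapply(out$score, out$algorithm, sum)
    if (any(abs(chk - attr(out, "n")) > 0.5))
      stop_input("fixture %s inconsistent: aggregate scores do not sum to n", name)
    return(out)
  }
  m <- as.matrix(df[-1])
  storage.mode(m) <- "integer"
  rownames(m) <- df$underlying
  colnames(m) <- colnames(df)[-1]
  expected <- c(table3 = 426L, table4 = 340L)[[name]]
  if (sum(m) != expected)
    stop_input("fixture %s inconsistent: grand total %d != %d", name, sum(m),
               expected)
  structure(m, class = c("contingency_table", class(m)))
}
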