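#' Cause vocabularies for an age stratum
#'
#' A `cause_list` fixes the ordered cause vocabulary used by every matrix and
#' composition in an analysis, so that columns can never be silently permuted.
#' Two strata are built in, matching the cause groupings used in the
#' COMSA-Mozambique child and neonate analyses:
#'
#' * `"children"` (1-59 months), 7 causes: malaria, pneumonia, diarrhea,
#'   severe malnutrition, HIV, other, other infections;
#' * `"neonates"` (1-28 days), 5 causes: congenital malformation, infection,
#'   IPRE (intrapartum-related events), other, prematurity.
#'
#' A `grouping` map (named character vector, fine cause -> group label) may be
#' supplied to collapse a finer cause vocabulary onto `causes`; it is applied
#' by [group_causes()]. Every value of `grouping` must be one of `causes`.
#'
#' @param stratum `"children"`, `"neonates"`, or `"custom"`.
#' @param causes Ordered character vector of cause labels. Required for
#'   `"custom"`; for the built-in strata it must be omitted or match the
#'   built-in order.
#' @param grouping Optional named character vector mapping fine cause labels to
#'   members of `causes`.
#'
#' @return An object of class `cause_list`: a list with elements `stratum`,
#'   `causes`, `tokens` (column-name-safe versions of the labels) and
#'   `grouping`.
#' @examples
#' cl <- cause_list("neonates")
#' cl$causes
#' @export
cause_list <- function(stratum = c("children", "neonates", "custom"),
                       causes = NULL, grouping = NULL) {
  stratum <- match.arg(stratum)
  builtin <- list(
    children = c("malaria", "pneumonia", "diarrhea", "severe malnutrition",
                 "HIV", "other", "other infections"),
    neonates = c("congenital malformation", "infection", "IPRE", "other",
                 "prematurity")
  )
  if (stratum != "custom") {
    if (!is.null(causes) && !identical(cause_token(causes),
                                       cause_token(builtin[[stratum]])))
      stop_input("causes for the '%s' stratum are fixed; use stratum = 'custom' to override", stratum)
    causes <- builtin[[stratum]]
  } else {
    if (is.null(causes) || length(causes) < 2)
      stop_input("a custom cause_list needs at least 2 cause labels")
    if (anyDuplicated(cause_token(causes)))
      stop_input("duplicate cause labels (after tokenisation)")
  }
  if (!is.null(grouping)) {
    if (is.null(names(grouping)) || any(names(grouping) == ""))
      stop_input("grouping must be a named character vector (fine cause -> group)")
    bad <- setdiff(cause_token(grouping), cause_token(causes))
    if (length(bad))
      stop_input("grouping targets not in causes: %s", paste(bad, collapse = ", "))
  }
  structure(
    list(stratum = stratum, causes = causes, tokens = cause_token(causes),
         grouping = grouping),
    class = "cause_list"
  )
}

#' @export
print.cause_list <- function(x, ...) {
  cat("<cause_list: ", x$stratum, ", ", length(x$causes), " causes>\n", sep = "")
  cat(paste(seq_along(x$causes), x$causes, sep = ". "), sep = "\n")
  if (!is.null(x$grouping))
    cat("grouping:", length(x$grouping), "fine causes ->",
        length(unique(x$grouping)), "groups\n")
  invisible(x)
}

#' @export
length.cause_list <- function(x) length(x$causes)

# resolve user-supplied labels to canonical indices, with a clear error
cause_index <- function(labels, cl, what = "cause") {
  idx <- match(cause_token(labels), cl$tokens)
  if (anyNA(idx)) {
    bad <- unique(labels[is.na(idx)])
    stop_input("unknown %s label(s): %s (known: %s)", what,
               paste(bad, collapse = ", "), paste(cl$causes, collapse = ", "))
  }
  idx
}
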