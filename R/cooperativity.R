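# Affinity bookkeeping: per-domain binding free energies with/without the
# partner protein assembled into cooperativity and domain-comparison
# statistics with propagated errors.

AFFINITY_COLS <- c("pou_s_without", "pou_hd_without", "pou_s_with",
                   "pou_hd_with")

#' Per-domain DNA-binding affinity table
#'
#' Validates and normalizes a table of per-domain binding free energies
#' (kcal/mol) at a set of bound/unbound thresholds: columns
#' `threshold` (A, strictly increasing), `pou_s_without`, `pou_hd_without`,
#' `pou_s_with`, `pou_hd_with` and the matching `*_err` columns
#' (non-negative). "with"/"without" refer to the presence of the partner
#' protein (SOX2).
#'
#' @param x A data frame with the columns above.
#' @return A tibble of class `affinity_table`.
#' @export
affinity_table <- function(x) {
  x <- tibble::as_tibble(x)
  need <- c("threshold", AFFINITY_COLS, paste0(AFFINITY_COLS, "_err"))
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("affinity table is missing: ", paste(miss, collapse = ", "))
  if (is.unsorted(x$threshold, strictly = TRUE))
    stop("thresholds must be strictly increasing")
  errs <- as.matrix(x[paste0(AFFINITY_COLS, "_err")])
  if (any(errs < 0)) stop("errors must be >= 0")
  structure(x, class = c("affinity_table",
                         setdiff(class(x), "affinity_table")))
}

#' Packaged per-domain affinity table for the OCT4/SOX2-UTF1 system
#'
#' The published per-domain DNA-binding free energies of the two OCT4
#' domains on the UTF1 enhancer element, with and without SOX2, at
#' bound/unbound thresholds 3.1-4.3 A, including the printed cooperativity
#' column used by [table_audit()].
#'
#' @return An `affinity_table` with `printed_cooperativity` columns.
#' @export
utf1_affinity_table <- function() {
  path <- system.file("extdata", "utf1_affinity_table.tsv",
                      package = "dnacoop", mustWork = TRUE)
  affinity_table(utils::read.table(path, header = TRUE, sep = "\t"))
}

check_cells <- function(table, cols) {
  for (cc in cols) {
    bad <- which(!is.finite(table[[cc]]))
    if (length(bad))
      stop("missing value in column '", cc, "' at threshold ",
           table$threshold[bad[1]], " A")
  }
}

#' Partner-induced cooperativity per threshold
#'
#' The cooperativity is the sum of the partner-induced changes in the
#' affinity of both domains:
#' `ddG = (dG_S(+) - dG_S(-)) + (dG_HD(+) - dG_HD(-))`,
#' reported to 2 decimals (half away from zero) alongside the exact value.
#'
#' @param table An [affinity_table()].
#' @return A tibble with `threshold`, `cooperativity` (2 decimals),
#'   `cooperativity_exact`, `error` (quadrature of the four cell errors, 2
#'   decimals).
#' @export
cooperativity <- function(table) {
  table <- affinity_table(table)
  check_cells(table, AFFINITY_COLS)
  co <- (table$pou_s_with - table$pou_s_without) +
    (table$pou_hd_with - table$pou_hd_without)
  tibble::tibble(threshold = table$threshold,
                 cooperativity = round_half_away(co, 2),
                 cooperativity_exact = co,
                 error = cooperativity_error(table))
}

#' Quadrature error of the cooperativity
#'
#' Independent linear error propagation through the four-term sum: the
#' square root of the sum of the four squared cell errors, to 2 decimals.
#'
#' @param table An [affinity_table()].
#' @return Numeric vector, one value per threshold row.
#' @export
cooperativity_error <- function(table) {
  table <- affinity_table(table)
  check_cells(table, paste0(AFFINITY_COLS, "_err"))
  e <- as.matrix(table[paste0(AFFINITY_COLS, "_err")])
  round_half_away(sqrt(rowSums(e^2)), 2)
}

#' Per-domain and inter-domain affinity differences
#'
#' Signed differences per threshold row, each with quadrature errors and
#' rounded to 2 decimals: the partner-induced change of each domain
#' (`delta_s`, `delta_hd`), the domain comparison without partner
#' (`hd_minus_s_without`; negative when the homeodomain binds stronger) and
#' with partner (`s_minus_hd_with`).
#'
#' @param table An [affinity_table()].
#' @return A tibble with the four deltas and their `*_err` columns.
#' @export
domain_deltas <- function(table) {
  table <- affinity_table(table)
  check_cells(table, c(AFFINITY_COLS, paste0(AFFINITY_COLS, "_err")))
  q <- function(a, b) sqrt(a^2 + b^2)
  tibble::tibble(
    threshold = table$threshold,
    delta_s  = round_half_away(table$pou_s_with - table$pou_s_without, 2),
    delta_s_err = round_half_away(
      q(table$pou_s_with_err, table$pou_s_without_err), 2),
    delta_hd = round_half_away(table$pou_hd_with - table$pou_hd_without, 2),
    delta_hd_err = round_half_away(
      q(table$pou_hd_with_err, table$pou_hd_without_err), 2),
    hd_minus_s_without = round_half_away(
      table$pou_hd_without - table$pou_s_without, 2),
    hd_minus_s_without_err = round_half_away(
      q(table$pou_hd_without_err, table$pou_s_without_err), 2),
    s_minus_hd_with = round_half_away(
      table$pou_s_with - table$pou_hd_with, 2),
    s_minus_hd_with_err = round_half_away(
      q(table$pou_s_with_err, table$pou_hd_with_err), 2)
  )
}

#' Audit an affinity table for internal consistency
#'
#' Recomputes the cooperativity column from the four per-domain columns and
#' flags rows where the recomputation differs from a provided printed column
#' by more than `tol`; also flags thresholds at which any per-domain column
#' breaks the monotone trend of increasing binding strength with threshold.
#'
#' @param table An [affinity_table()]; a `printed_cooperativity` column (or
#'   the `printed` argument) enables the recomputation check.
#' @param printed Optional printed cooperativity values to audit against.
#' @param tol Allowed recomputation discrepancy, kcal/mol (default 0.01).
#' @return A tibble with `threshold`, `recomputed`, `printed`, `consistent`,
#'   `nonmonotone_columns`.
#' @export
table_audit <- function(table, printed = NULL, tol = 0.01) {
  table <- affinity_table(table)
  printed <- printed %||% table$printed_cooperativity
  co <- cooperativity(table)
  mono <- vapply(seq_len(nrow(table)), function(i) {
    bad <- character()
    for (cc in AFFINITY_COLS) {
      v <- table[[cc]]
      if (i > 1 && v[i] > v[i - 1]) bad <- c(bad, cc)
    }
    paste(bad, collapse = ",")
  }, character(1))
  tibble::tibble(
    threshold = table$threshold,
    recomputed = co$cooperativity,
    printed = if (is.null(printed)) NA_real_ else printed,
    consistent = if (is.null(printed)) NA else
      abs(co$cooperativity - printed) <= tol + 1e-9,
    nonmonotone_columns = mono
  )
}
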