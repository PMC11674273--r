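# Cross-platform (qPCR vs RNA-Seq) concordance rule.
#
# For each chemical x gene, the RNA-Seq fold change (TPM ratio of treated
# to control) is compared with each of the three qPCR replicate fold
# changes. A replicate is flagged discrepant when the two values differ by
# two-fold or more (symmetric ratio max/min >= 2, inclusive). A cell is a
# mismatch when at least 2 of 3 replicates are flagged; a gene is retained
# as a marker only if every reference chemical's cell is a match.

#' Flag a two-fold-or-greater discrepancy between platforms
#'
#' The comparison is symmetric and scale-invariant:
#' `max(pcr, ngs) / min(pcr, ngs) >= threshold`. Values are compared as
#' supplied. Zeros (fold changes below the precision of a printed table)
#' are handled by convention: two zeros are concordant, a zero against a
#' non-zero value is flagged, since their ratio exceeds any threshold.
#' Negative inputs are rejected.
#'
#' @param pcr_fc qPCR linear fold change(s).
#' @param ngs_fc RNA-Seq linear fold change(s).
#' @param threshold Ratio cutoff (default 2).
#' @param inclusive Logical; flag at exactly the threshold (default `TRUE`,
#'   which the published boundary verdicts require).
#' @return Logical vector.
#' @export
discrepancy_flag <- function(pcr_fc, ngs_fc, threshold = 2,
                             inclusive = TRUE) {
  if (any(!is.finite(pcr_fc)) || any(!is.finite(ngs_fc)) ||
      any(pcr_fc < 0) || any(ngs_fc < 0)) {
    stop("fold changes must be finite and non-negative", call. = FALSE)
  }
  hi <- pmax(pcr_fc, ngs_fc)
  lo <- pmin(pcr_fc, ngs_fc)
  both_zero <- hi == 0
  ratio <- ifelse(both_zero, 1, hi / lo)  # lo = 0, hi > 0 gives Inf
  if (inclusive) ratio >= threshold else ratio > threshold
}

#' Concordance verdict for one chemical x gene cell
#'
#' @param pcr Numeric vector of qPCR replicate fold changes (usually 3).
#' @param ngs_fc Single RNA-Seq fold change for the same chemical x gene.
#' @param threshold,inclusive Passed to [discrepancy_flag()].
#' @param quorum Number of flagged replicates that makes the cell a
#'   mismatch (default 2).
#' @return List with `replicate_flags` (logical vector) and `verdict`
#'   (`"match"` or `"mismatch"`).
#' @export
concordance_cell <- function(pcr, ngs_fc, threshold = 2, inclusive = TRUE,
                             quorum = 2) {
  flags <- discrepancy_flag(pcr, ngs_fc, threshold = threshold,
                            inclusive = inclusive)
  list(replicate_flags = flags,
       verdict = if (sum(flags) >= quorum) "mismatch" else "match")
}

#' Recompute concordance verdicts for a chemical x gene table
#'
#' @param cells Data frame with columns `chemical`, `gene`, `ngs_fc` and
#'   `pcr_fc1`..`pcr_fc3` (as returned by [candidate_marker_concordance()]).
#' @param threshold,inclusive,quorum Passed to [concordance_cell()].
#' @return The input with added columns `n_flagged` and `verdict`.
#' @export
concordance_table <- function(cells, threshold = 2, inclusive = TRUE,
                              quorum = 2) {
  pcr_cols <- grep("^pcr_fc", names(cells), value = TRUE)
  if (length(pcr_cols) == 0 || !"ngs_fc" %in% names(cells)) {
    stop("cells must have 'ngs_fc' and 'pcr_fc*' columns", call. = FALSE)
  }
  res <- lapply(seq_len(nrow(cells)), function(i) {
    concordance_cell(as.numeric(cells[i, pcr_cols]), cells$ngs_fc[i],
                     threshold = threshold, inclusive = inclusive,
                     quorum = quorum)
  })
  cells$n_flagged <- vapply(res, function(r) sum(r$replicate_flags), 0L)
  cells$verdict <- vapply(res, function(r) r$verdict, "")
  cells
}

#' Decide marker retention from a gene's concordance cells
#'
#' A candidate marker survives the platform-concordance screen only if its
#' verdict is `match` for every reference chemical.
#'
#' @param verdicts Character vector of per-chemical verdicts for one gene.
#' @param chemicals Optional chemical ids matching `verdicts`.
#' @param expected_chemicals Optional full set of reference chemical ids;
#'   if given, missing chemicals raise an error naming them.
#' @return `TRUE` iff every verdict is `match`.
#' @export
retain_marker <- function(verdicts, chemicals = NULL,
                          expected_chemicals = NULL) {
  if (!is.null(expected_chemicals)) {
    if (is.null(chemicals)) {
      stop("chemicals must be supplied with expected_chemicals",
           call. = FALSE)
    }
    missing <- setdiff(expected_chemicals, chemicals)
    if (length(missing) > 0) {
      stop("missing concordance cells for chemical(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  all(verdicts == "match")
}

#' Retained markers from a full concordance table
#'
#' @param cells Output of [concordance_table()].
#' @param expected_chemicals Optional chemical ids each gene must cover.
#' @return Character vector of retained gene ids.
#' @export
retained_markers <- function(cells, expected_chemicals = NULL) {
  genes <- unique(cells$gene)
  keep <- vapply(genes, function(g) {
    sub <- cells[cells$gene == g, , drop = FALSE]
    retain_marker(sub$verdict, sub$chemical, expected_chemicals)
  }, logical(1))
  genes[keep]
}
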