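# Accuracy accounting against reference labels, and threshold sweeps.

#' Score a binary call against a murine LLNA category
#'
#' @param call Character vector of calls (`sensitizer` /
#'   `non_sensitizer`).
#' @param llna Character vector of LLNA categories (potency class,
#'   `non_sensitizer`, or `ND`).
#' @return Character vector: `match`, `mismatch`, or `not_evaluable` when
#'   no LLNA data exist.
#' @export
judge_against_llna <- function(call, llna) {
  ref <- llna_binary(llna)
  ifelse(is.na(ref), "not_evaluable",
         ifelse(call == ref, "match", "mismatch"))
}

#' Accuracy report for a set of judgments
#'
#' Counts matches and mismatches against the reference label, excluding
#' chemicals without reference data (`not_evaluable`) from the denominator.
#' Every report states its own denominator (`n_evaluable`) explicitly.
#'
#' @param judgments Data frame with columns `chemical`, `match` and,
#'   optionally, per-gene positivity columns named `<gene>_positive`.
#' @return An object of class `accuracy_report`: `n_total`, `n_evaluable`,
#'   `n_match`, `n_mismatch`, `mismatched_chemicals`,
#'   `per_gene_consistency`.
#' @export
accuracy <- function(judgments) {
  if (nrow(judgments) == 0) stop("judgments must be non-empty", call. = FALSE)
  ev <- judgments$match %in% c("match", "mismatch")
  n_match <- sum(judgments$match == "match")
  n_mismatch <- sum(judgments$match == "mismatch")
  gene_cols <- grep("_positive$", names(judgments), value = TRUE)
  per_gene <- NULL
  if (length(gene_cols) > 0 && "reference" %in% names(judgments)) {
    per_gene <- lapply(gene_cols, function(col) {
      pos <- judgments[[col]]
      call_g <- ifelse(pos, "sensitizer", "non_sensitizer")
      ok <- ev & call_g == judgments$reference
      c(n_match = sum(ok), n_evaluable = sum(ev))
    })
    names(per_gene) <- sub("_positive$", "", gene_cols)
  }
  structure(
    list(
      n_total = nrow(judgments),
      n_evaluable = sum(ev),
      n_match = n_match,
      n_mismatch = n_mismatch,
      mismatched_chemicals = judgments$chemical[judgments$match == "mismatch"],
      per_gene_consistency = per_gene
    ),
    class = "accuracy_report"
  )
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("accuracy: %d/%d evaluable chemicals match (%d mismatch, %d not evaluable)\n",
              x$n_match, x$n_evaluable, x$n_mismatch,
              x$n_total - x$n_evaluable))
  if (length(x$mismatched_chemicals) > 0) {
    cat("mismatches:", paste(x$mismatched_chemicals, collapse = ", "), "\n")
  }
  if (!is.null(x$per_gene_consistency)) {
    for (g in names(x$per_gene_consistency)) {
      v <- x$per_gene_consistency[[g]]
      cat(sprintf("  %s alone: %d/%d\n", g, v["n_match"], v["n_evaluable"]))
    }
  }
  invisible(x)
}

#' Accuracy of the flow-cytometry h-CLAT judgments against LLNA
#'
#' Uses the `p`/`n` h-CLAT judgments carried in the chemical metadata
#' verbatim (`p` maps to `sensitizer`, `n` to `non_sensitizer`; `ND`
#' chemicals contribute to the total but not the denominator).
#'
#' @param records Chemical metadata data frame (see
#'   [read_chemical_table()]).
#' @return An [accuracy()] report.
#' @export
hclat_accuracy <- function(records) {
  call <- ifelse(records$hclat_judgment == "p", "sensitizer",
                 ifelse(records$hclat_judgment == "n", "non_sensitizer",
                        NA_character_))
  match <- ifelse(is.na(call), "not_evaluable",
                  judge_against_llna(call, records$llna_category))
  judgments <- data.frame(chemical = records$name, call = call,
                          reference = llna_binary(records$llna_category),
                          match = match, stringsAsFactors = FALSE)
  accuracy(judgments)
}

#' Accuracy sweep over marker panels and fold-change thresholds
#'
#' Re-runs the classification for each threshold, once per single-gene
#' panel and once for the combined panel, and reports the accuracy against
#' the LLNA categories. Used to explore alternative cutoffs (e.g. 1.5-fold)
#' and the added value of the two-gene OR rule.
#'
#' @param foldchanges Long-format fold-change data frame.
#' @param chemicals Chemical metadata data frame.
#' @param genes Marker genes to sweep (default: genes present in
#'   `foldchanges`).
#' @param thresholds Numeric vector of linear fold-change cutoffs, all > 1.
#' @param rule Template [decision_rule()] supplying quorum, replicate count
#'   and inclusivity.
#' @return Data frame with one row per (panel, threshold): `panel`,
#'   `threshold`, `n_evaluable`, `n_match`, `n_mismatch`, `n_sensitizer`.
#' @export
marker_sweep <- function(foldchanges, chemicals, genes = NULL,
                         thresholds = c(1.5, 2), rule = decision_rule()) {
  if (any(thresholds <= 1)) stop("thresholds must exceed 1", call. = FALSE)
  if (is.null(genes)) genes <- sort(unique(foldchanges$gene))
  panels <- c(as.list(genes),
              if (length(genes) > 1) list(genes))
  rows <- list()
  for (th in thresholds) {
    for (panel in panels) {
      r <- decision_rule(threshold = th, quorum = rule$quorum,
                         n_replicates = rule$n_replicates, panel = panel,
                         inclusive = rule$inclusive)
      fit <- rt_hclat(foldchanges, chemicals = chemicals, rule = r)
      rows[[length(rows) + 1L]] <- data.frame(
        panel = paste(panel, collapse = "+"),
        threshold = th,
        n_evaluable = fit$accuracy$n_evaluable,
        n_match = fit$accuracy$n_match,
        n_mismatch = fit$accuracy$n_mismatch,
        n_sensitizer = sum(fit$judgments$call == "sensitizer"),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
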