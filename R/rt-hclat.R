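# The central classifier object: apply the decision rule to a table of
# fold-change triplicates and (optionally) score the calls against murine
# LLNA categories carried in a chemical metadata table.

#' Classify chemicals with the RT h-CLAT decision rule
#'
#' Applies a [decision_rule()] to a long-format table of fold-change
#' triplicates (one row per chemical, gene, replicate) and returns a classed
#' object holding the per-chemical judgments. A chemical is called a
#' `sensitizer` if any panel gene is positive under the replicate-majority
#' rule, otherwise `non_sensitizer`. If a chemical metadata table is
#' supplied, each call is additionally scored against the binarized murine
#' LLNA category (`match` / `mismatch`; `not_evaluable` when the LLNA
#' category is `ND`).
#'
#' @param foldchanges Long-format fold-change data frame (`chemical`,
#'   `gene`, `replicate`, `fc`) or a path to such a file.
#' @param chemicals Optional chemical metadata (data frame from
#'   [read_chemical_table()] or a path). Matched to fold-change rows by
#'   chemical name.
#' @param rule A [decision_rule()]; the default is the published rule
#'   (>= 2-fold in >= 2 of 3 replicates, *HMOX1* or *JUN*).
#' @return An object of class `rt_hclat` with components `judgments` (data
#'   frame: chemical, one logical column per panel gene, `call`,
#'   `reference`, `match`), `rule`, `accuracy` (an [accuracy()] report, or
#'   `NULL` without metadata) and `foldchanges`.
#' @examples
#' fc <- read_foldchange_table(
#'   system.file("extdata", "hmox1_jun_panel.tsv", package = "rthclat"))
#' chem <- read_chemical_table(
#'   system.file("extdata", "chemicals.tsv", package = "rthclat"))
#' fit <- rt_hclat(fc, chemicals = chem)
#' fit
#' summary(fit)
#' @export
rt_hclat <- function(foldchanges, chemicals = NULL, rule = decision_rule()) {
  if (is.character(foldchanges) && length(foldchanges) == 1) {
    foldchanges <- read_foldchange_table(foldchanges,
                                         n_replicates = rule$n_replicates)
  }
  foldchanges <- validate_foldchanges(foldchanges,
                                      n_replicates = rule$n_replicates)
  if (is.character(chemicals) && length(chemicals) == 1) {
    chemicals <- read_chemical_table(chemicals)
  }
  stopifnot(inherits(rule, "decision_rule"))
  chems <- unique(foldchanges$chemical)
  missing_panel <- vapply(chems, function(ch) {
    genes <- unique(foldchanges$gene[foldchanges$chemical == ch])
    paste(setdiff(rule$panel, genes), collapse = ", ")
  }, character(1))
  if (any(nzchar(missing_panel))) {
    i <- which(nzchar(missing_panel))[1]
    stop(sprintf("panel gene(s) %s missing for chemical '%s'",
                 missing_panel[i], chems[i]), call. = FALSE)
  }
  pos <- matrix(NA, nrow = length(chems), ncol = length(rule$panel),
                dimnames = list(chems, rule$panel))
  for (ch in chems) {
    for (g in rule$panel) {
      pos[ch, g] <- gene_positive(fc_triplicate(foldchanges, ch, g), rule)
    }
  }
  call <- ifelse(rowSums(pos) > 0, "sensitizer", "non_sensitizer")
  judgments <- data.frame(chemical = chems, pos,
                          call = unname(call),
                          stringsAsFactors = FALSE, check.names = FALSE)
  names(judgments)[seq_along(rule$panel) + 1L] <-
    paste0(rule$panel, "_positive")
  rownames(judgments) <- NULL

  acc <- NULL
  if (!is.null(chemicals)) {
    idx <- match(judgments$chemical, chemicals$name)
    if (anyNA(idx)) {
      stop("chemical(s) missing from metadata: ",
           paste(judgments$chemical[is.na(idx)], collapse = ", "),
           call. = FALSE)
    }
    judgments$reference <- llna_binary(chemicals$llna_category[idx])
    judgments$match <- judge_against_llna(judgments$call,
                                          chemicals$llna_category[idx])
    acc <- accuracy(judgments)
  } else {
    judgments$reference <- NA_character_
    judgments$match <- NA_character_
  }

  structure(
    list(judgments = judgments, rule = rule, accuracy = acc,
         foldchanges = foldchanges),
    class = "rt_hclat"
  )
}

#' @export
print.rt_hclat <- function(x, ...) {
  n <- nrow(x$judgments)
  ns <- sum(x$judgments$call == "sensitizer")
  cat(sprintf("RT h-CLAT classification of %d chemical(s)\n", n))
  print(x$rule)
  cat(sprintf("calls: %d sensitizer, %d non-sensitizer\n", ns, n - ns))
  if (!is.null(x$accuracy)) {
    cat(sprintf("agreement with LLNA: %d/%d evaluable chemicals\n",
                x$accuracy$n_match, x$accuracy$n_evaluable))
  }
  invisible(x)
}

#' @export
summary.rt_hclat <- function(object, ...) {
  structure(list(fit = object), class = "summary.rt_hclat")
}

#' @export
print.summary.rt_hclat <- function(x, ...) {
  fit <- x$fit
  print(fit)
  cat("\nJudgments:\n")
  print(fit$judgments, row.names = FALSE)
  if (!is.null(fit$accuracy) && fit$accuracy$n_mismatch > 0) {
    cat("\nMismatched chemicals:",
        paste(fit$accuracy$mismatched_chemicals, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Apply a fitted RT h-CLAT rule to new fold-change data
#'
#' @param object An `rt_hclat` object.
#' @param newdata Long-format fold-change data frame (or path) for new
#'   chemicals.
#' @param chemicals Optional metadata for the new chemicals.
#' @param ... Unused.
#' @return A new `rt_hclat` object for `newdata` under the same rule.
#' @export
predict.rt_hclat <- function(object, newdata, chemicals = NULL, ...) {
  rt_hclat(newdata, chemicals = chemicals, rule = object$rule)
}

#' Plot per-chemical marker fold changes against the decision threshold
#'
#' Draws, for each chemical, the replicate fold changes of every panel gene
#' on a log2 axis, with the decision threshold as a horizontal line.
#' Chemicals called sensitizers are drawn with filled points.
#'
#' @param x An `rt_hclat` object.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.rt_hclat <- function(x, ...) {
  fc <- x$foldchanges
  fc <- fc[fc$gene %in% x$rule$panel, , drop = FALSE]
  chems <- unique(fc$chemical)
  xi <- match(fc$chemical, chems)
  called <- x$judgments$call[match(fc$chemical, x$judgments$chemical)]
  pch <- ifelse(called == "sensitizer", 16, 1)
  col <- match(fc$gene, x$rule$panel)
  graphics::plot(xi, log2(fc$fc), pch = pch, col = col,
                 xaxt = "n", xlab = "", ylab = "log2 fold change", ...)
  graphics::abline(h = log2(x$rule$threshold), lty = 2)
  graphics::axis(1, at = seq_along(chems), labels = chems, las = 2,
                 cex.axis = 0.6)
  graphics::legend("topright", legend = x$rule$panel,
                   col = seq_along(x$rule$panel), pch = 16, bty = "n")
  invisible(x)
}
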