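# Fold-change triplicate tables: long-format IO and validation.
#
# The unit of the decision rule is a triplicate of linear expression ratios
# (treated / solvent control) for one chemical x gene. On disk a table is
# long format with one row per replicate: chemical, gene, replicate, fc.

#' Validate a long-format fold-change table
#'
#' Checks that every (chemical, gene) block has exactly `n_replicates`
#' finite, strictly positive values with unique replicate indices.
#'
#' @param fc Data frame with columns `chemical`, `gene`, `replicate`, `fc`.
#' @param n_replicates Required replicates per chemical x gene block.
#' @return The validated data frame, invisibly, ordered by chemical, gene,
#'   replicate.
#' @export
validate_foldchanges <- function(fc, n_replicates = 3L) {
  required <- c("chemical", "gene", "replicate", "fc")
  missing <- setdiff(required, names(fc))
  if (length(missing) > 0) {
    stop("fold-change table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(fc$fc)) stop("fc column must be numeric", call. = FALSE)
  bad <- which(!is.finite(fc$fc) | fc$fc <= 0)
  if (length(bad) > 0) {
    stop(sprintf(
      "non-positive or non-finite fold change for chemical '%s', gene '%s', replicate %s",
      fc$chemical[bad[1]], fc$gene[bad[1]], fc$replicate[bad[1]]
    ), call. = FALSE)
  }
  key <- interaction(fc$chemical, fc$gene, drop = TRUE)
  sizes <- table(key)
  off <- names(sizes)[sizes != n_replicates]
  if (length(off) > 0) {
    stop(sprintf("expected %d replicates but found %d for block '%s'",
                 n_replicates, sizes[[off[1]]], off[1]), call. = FALSE)
  }
  dup <- tapply(fc$replicate, key, function(r) anyDuplicated(r) > 0)
  if (any(dup)) {
    stop("duplicated replicate index in block '", names(dup)[dup][1], "'",
         call. = FALSE)
  }
  fc <- fc[order(fc$chemical, fc$gene, fc$replicate), , drop = FALSE]
  rownames(fc) <- NULL
  invisible(fc)
}

#' Read a fold-change triplicate table
#'
#' @param path Delimited text file (tab or comma) with header columns
#'   `chemical`, `gene`, `replicate`, `fc`.
#' @param n_replicates Required replicates per chemical x gene block
#'   (default 3).
#' @return Long-format data frame, validated and ordered.
#' @seealso [write_foldchange_table()], [validate_foldchanges()]
#' @export
read_foldchange_table <- function(path, n_replicates = 3L) {
  tab <- .read_delim(path)
  fc <- validate_foldchanges(tab, n_replicates = n_replicates)
  fc
}

#' Write a fold-change triplicate table
#'
#' Inverse of [read_foldchange_table()]: writes the long format back to
#' tab-separated text so that a write-then-read round trip reproduces the
#' input exactly.
#'
#' @param fc Long-format fold-change data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_foldchange_table <- function(fc, path) {
  fc <- validate_foldchanges(fc)
  utils::write.table(fc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Split a long table into a named list of per-(chemical, gene) numeric
# triplicates, ordered by replicate index.
.fc_blocks <- function(fc) {
  fc <- validate_foldchanges(fc)
  split(fc$fc, list(chemical = fc$chemical, gene = fc$gene), drop = TRUE,
        sep = "\r")
}

#' Extract one fold-change triplicate
#'
#' @param fc Long-format fold-change data frame.
#' @param chemical,gene Block to extract.
#' @return Numeric vector of the replicate fold changes, in replicate order.
#' @export
fc_triplicate <- function(fc, chemical, gene) {
  sel <- fc$chemical == chemical & fc$gene == gene
  if (!any(sel)) {
    stop(sprintf("no fold changes for chemical '%s', gene '%s'",
                 chemical, gene), call. = FALSE)
  }
  block <- fc[sel, , drop = FALSE]
  block$fc[order(block$replicate)]
}
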