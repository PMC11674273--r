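# Gene x sample count container for the RNA-Seq marker-discovery stage.
#
# Deliberately light-weight: a classed list holding an integer count matrix,
# per-gene effective lengths (bases, for TPM) and a sample sheet assigning
# each sample to a treatment (one chemical or control, the "test segment")
# and a group (sensitizer / non_sensitizer / control).

.group_levels <- c("sensitizer", "non_sensitizer", "control")

#' Construct a count matrix object
#'
#' @param counts Integer matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). Counts must be
#'   non-negative integers.
#' @param lengths Numeric vector of effective gene lengths in bases, one
#'   per row of `counts` (named or in row order); all > 0.
#' @param samples Data frame with columns `sample`, `treatment`, `group`
#'   (one row per column of `counts`). `group` must be one of
#'   `sensitizer`, `non_sensitizer`, `control`.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, lengths, samples) {
  counts <- as.matrix(counts)
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      is.null(colnames(counts))) {
    stop("counts must have gene rownames and sample colnames", call. = FALSE)
  }
  if (nrow(counts) == 0) rownames(counts) <- character(0)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  if (!is.null(names(lengths))) {
    missing <- setdiff(rownames(counts), names(lengths))
    if (length(missing) > 0) {
      stop("gene length missing for: ", paste(utils::head(missing, 3),
           collapse = ", "), call. = FALSE)
    }
    lengths <- lengths[rownames(counts)]
  }
  if (length(lengths) != nrow(counts)) {
    stop("lengths must have one entry per gene", call. = FALSE)
  }
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    stop("gene lengths must be positive", call. = FALSE)
  }
  names(lengths) <- rownames(counts)
  required <- c("sample", "treatment", "group")
  missing <- setdiff(required, names(samples))
  if (length(missing) > 0) {
    stop("sample sheet is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  unmatched <- setdiff(colnames(counts), samples$sample)
  if (length(unmatched) > 0) {
    stop("sample(s) in counts missing from metadata: ",
         paste(unmatched, collapse = ", "), call. = FALSE)
  }
  # preserve the column order of the count matrix
  samples <- samples[match(colnames(counts), samples$sample), , drop = FALSE]
  rownames(samples) <- NULL
  bad <- setdiff(unique(samples$group), .group_levels)
  if (length(bad) > 0) {
    stop("invalid group label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(counts = counts, lengths = lengths, samples = samples),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  tab <- table(x$samples$group)
  cat("groups: ", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
      "\n", sep = "")
  cat("treatments:", length(unique(x$samples$treatment)), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read a count matrix and its sample metadata
#'
#' The counts file is delimited text with a `gene_id` column, a `length`
#' column (effective gene length in bases) and one column per sample. The
#' metadata file assigns each sample a `treatment` id and a `group` label.
#'
#' @param path Path to the counts file.
#' @param metadata_path Path to the sample sheet (`sample`, `treatment`,
#'   `group`).
#' @return A [count_matrix()] object; sample order follows the counts file.
#' @export
read_count_matrix <- function(path, metadata_path) {
  tab <- .read_delim(path)
  if (!all(c("gene_id", "length") %in% names(tab))) {
    stop("counts file must have 'gene_id' and 'length' columns",
         call. = FALSE)
  }
  meta <- .read_delim(metadata_path)
  sample_cols <- setdiff(names(tab), c("gene_id", "length"))
  counts <- as.matrix(tab[, sample_cols, drop = FALSE])
  rownames(counts) <- tab$gene_id
  count_matrix(counts, stats::setNames(tab$length, tab$gene_id), meta)
}

#' Write a count matrix to delimited text
#'
#' @param cm A [count_matrix()] object.
#' @param path Output path for the counts file.
#' @param metadata_path Output path for the sample sheet.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(cm, path, metadata_path) {
  stopifnot(inherits(cm, "count_matrix"))
  tab <- data.frame(gene_id = rownames(cm$counts),
                    length = unname(cm$lengths),
                    cm$counts, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cm$samples, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
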