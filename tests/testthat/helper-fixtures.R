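# Shared builders for small in-code fixtures.

# Long-format fold-change table from a named list of triplicates, e.g.
# make_fc(chemA = list(HMOX1 = c(2, 2, 1))).
make_fc <- function(...) {
  chems <- list(...)
  rows <- list()
  for (chem in names(chems)) {
    for (gene in names(chems[[chem]])) {
      v <- chems[[chem]][[gene]]
      rows[[length(rows) + 1L]] <- data.frame(
        chemical = chem, gene = gene, replicate = seq_along(v), fc = v,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

# Tiny count matrix with two treatments (control / treat), n replicates
# each; counts supplied as a gene x sample matrix or built constant.
make_cm <- function(counts, lengths = NULL,
                    groups = c("control", "sensitizer")) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("g%02d", seq_len(nrow(counts)))
  }
  n <- ncol(counts)
  half <- n / 2
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("s%02d", seq_len(n))
  }
  if (is.null(lengths)) {
    lengths <- stats::setNames(rep(1000, nrow(counts)), rownames(counts))
  }
  samples <- data.frame(
    sample = colnames(counts),
    treatment = rep(c("t_ctrl", "t_trt"), each = half),
    group = rep(groups, each = half),
    stringsAsFactors = FALSE
  )
  count_matrix(counts, lengths, samples)
}

# Minimal chemical metadata table for evaluation tests.
make_chem <- function(names, llna, hclat = NULL) {
  data.frame(
    name = names, abbreviation = NA_character_, cas = NA_character_,
    solvent = NA_character_, cv75 = NA_real_, cv75_raw = NA_character_,
    llna_category = llna,
    hclat_judgment = if (is.null(hclat)) rep("ND", length(names)) else hclat,
    stringsAsFactors = FALSE
  )
}
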