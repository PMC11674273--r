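# RNA-Seq marker discovery: low-count filter, TPM, a simplified
# negative-binomial Wald test, sensitizer-specific gene selection and
# candidate ranking.

#' Remove genes with uniformly low counts
#'
#' A "test segment" is one treatment condition (one chemical, or a
#' control); its per-gene statistic is the mean (default) or sum of the
#' replicate counts. A gene is retained when its statistic reaches
#' `min_count` in at least one segment, and dropped when it stays below the
#' cutoff in all segments.
#'
#' @param cm A [count_matrix()].
#' @param min_count Count cutoff (default 10, non-negative).
#' @param segment_statistic `"mean"` (default) or `"sum"` of the replicate
#'   counts per segment.
#' @param boundary `"inclusive"` (default; retain at exactly `min_count`)
#'   or `"exclusive"` (require strictly more).
#' @return A [count_matrix()] restricted to the retained genes.
#' @export
filter_low_counts <- function(cm, min_count = 10,
                              segment_statistic = c("mean", "sum"),
                              boundary = c("inclusive", "exclusive")) {
  stopifnot(inherits(cm, "count_matrix"))
  segment_statistic <- match.arg(segment_statistic)
  boundary <- match.arg(boundary)
  if (min_count < 0) stop("min_count must be non-negative", call. = FALSE)
  seg <- factor(cm$samples$treatment)
  stat <- t(apply(cm$counts, 1, function(x) {
    tapply(x, seg, if (segment_statistic == "mean") mean else sum)
  }))
  best <- apply(stat, 1, max)
  keep <- if (boundary == "inclusive") best >= min_count else best > min_count
  count_matrix(cm$counts[keep, , drop = FALSE], cm$lengths[keep],
               cm$samples)
}

#' Transcripts per million
#'
#' Per sample: `TPM_g = (count_g / length_g) / sum_h(count_h / length_h)
#' * 1e6`, so every column sums to one million.
#'
#' @param cm A [count_matrix()] with gene lengths.
#' @return Numeric gene x sample matrix of TPM values.
#' @export
compute_tpm <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  rate <- cm$counts / cm$lengths
  totals <- colSums(rate)
  if (any(totals == 0)) {
    stop("sample(s) with zero total read rate: ",
         paste(colnames(cm$counts)[totals == 0], collapse = ", "),
         call. = FALSE)
  }
  sweep(rate, 2, totals, "/") * 1e6
}

# Median-of-ratios size factors. The reference is the per-gene geometric
# mean over all samples; genes with any zero count are excluded from the
# reference. Falls back to total-count ratios when no gene is usable
# (tiny fixtures).
.size_factors <- function(counts) {
  logs <- log(counts)
  usable <- rowSums(!is.finite(logs)) == 0
  if (sum(usable) >= 1) {
    ref <- rowMeans(logs[usable, , drop = FALSE])
    sf <- apply(logs[usable, , drop = FALSE], 2,
                function(lc) exp(stats::median(lc - ref)))
  } else {
    tot <- colSums(counts)
    sf <- tot / exp(mean(log(tot)))
  }
  sf / exp(mean(log(sf)))
}

#' Simplified negative-binomial differential-expression test
#'
#' A self-contained approximation of the standard count-based
#' differential-expression analysis: library composition is normalized with
#' median-of-ratios size factors; a per-gene negative-binomial dispersion is
#' estimated by method of moments from the pooled within-group variability,
#' with a small-sample floor of `1e-4` and no shrinkage toward a trend; and
#' a Wald-type statistic tests the log2 ratio of the two group means of
#' normalized counts, with the delta-method standard error
#' `var(log mu_g) = (1/n_g^2) sum_j 1/(mu_g s_j) + alpha / n_g` per group.
#' P-values use a t reference distribution with `n_a + n_b - 2` degrees of
#' freedom (which keeps the test calibrated at triplicate sample sizes) and
#' are Benjamini-Hochberg adjusted across all tested genes.
#'
#' The log2 fold change is reported as `group_b` relative to `group_a`
#' (positive = higher in `group_b`).
#'
#' @param cm A [count_matrix()].
#' @param group_a,group_b Group labels (values of `cm$samples$group`) or
#'   treatment ids; each must select at least two samples.
#' @param pseudocount Added to each group's mean normalized count before
#'   taking logs (default 0.5), so genes absent from one group remain
#'   testable.
#' @param dispersion_floor Lower bound for the method-of-moments dispersion
#'   estimate (default 1e-4).
#' @return Data frame with one row per gene: `gene_id`, `base_mean`,
#'   `log2_fold_change`, `p_value`, `adjusted_p`.
#' @export
differential_test <- function(cm, group_a, group_b, pseudocount = 0.5,
                              dispersion_floor = 1e-4) {
  stopifnot(inherits(cm, "count_matrix"))
  pick <- function(label) {
    sel <- cm$samples$group == label | cm$samples$treatment == label
    which(sel)
  }
  ia <- pick(group_a)
  ib <- pick(group_b)
  if (length(ia) < 2 || length(ib) < 2) {
    stop("each group must contain at least two samples", call. = FALSE)
  }
  if (length(intersect(ia, ib)) > 0) {
    stop("groups overlap", call. = FALSE)
  }
  idx <- c(ia, ib)
  counts <- cm$counts[, idx, drop = FALSE]
  sf <- .size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  na <- length(ia)
  nb <- length(ib)
  ga <- seq_len(na)
  gb <- na + seq_len(nb)
  ma <- rowMeans(norm[, ga, drop = FALSE])
  mb <- rowMeans(norm[, gb, drop = FALSE])
  base_mean <- rowMeans(norm)

  # pooled within-group variance of normalized counts
  ss <- rowSums((norm[, ga, drop = FALSE] - ma)^2) +
    rowSums((norm[, gb, drop = FALSE] - mb)^2)
  df <- na + nb - 2
  v <- ss / df
  # method-of-moments: Var(y_j) ~ m / s_j + alpha m^2 on the normalized
  # scale, averaged over samples
  cbar <- mean(1 / sf)
  m_pool <- (na * ma + nb * mb) / (na + nb)
  alpha <- (v - m_pool * cbar) / m_pool^2
  alpha[!is.finite(alpha)] <- dispersion_floor
  alpha <- pmax(alpha, dispersion_floor)

  ma_ <- ma + pseudocount
  mb_ <- mb + pseudocount
  lfc <- log2(mb_ / ma_)
  var_log <- function(m, js, n) {
    (1 / n^2) * rowSums(outer(1 / m, 1 / sf[js])) + alpha / n
  }
  se_ln <- sqrt(var_log(ma_, ga, na) + var_log(mb_, gb, nb))
  z <- log(mb_ / ma_) / se_ln
  p <- 2 * stats::pt(-abs(z), df = df)
  p[ma == 0 & mb == 0] <- 1
  lfc[ma == 0 & mb == 0] <- 0
  data.frame(
    gene_id = rownames(cm$counts),
    base_mean = base_mean,
    log2_fold_change = lfc,
    p_value = p,
    adjusted_p = stats::p.adjust(p, method = "BH"),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Select sensitizer-specific genes from two contrasts
#'
#' A gene is sensitizer-specific when it passes the effect-size and
#' significance cutoffs in the sensitizer-vs-control contrast
#' (`|log2FC| > lfc_cut` and `adjusted_p < alpha`) but does not pass them
#' in the non-sensitizer-vs-control contrast: its expression is altered
#' only by sensitizing chemicals. Direction is taken from the sensitizer
#' contrast's sign.
#'
#' @param de_sens_ctrl [differential_test()] result for sensitizer vs
#'   control.
#' @param de_nonsens_ctrl Result for non-sensitizer vs control; must cover
#'   the same gene universe.
#' @param lfc_cut Absolute log2 fold-change cutoff (default 1, strict).
#' @param alpha Adjusted p-value cutoff (default 0.05, strict).
#' @return Data frame of candidates: `gene_id`, `direction` (`up`/`down`),
#'   `log2_fold_change`, `adjusted_p`, `base_mean`.
#' @export
select_sensitizer_specific <- function(de_sens_ctrl, de_nonsens_ctrl,
                                       lfc_cut = 1, alpha = 0.05) {
  if (!setequal(de_sens_ctrl$gene_id, de_nonsens_ctrl$gene_id) ||
      nrow(de_sens_ctrl) != nrow(de_nonsens_ctrl)) {
    stop("the two contrasts must cover the same gene universe",
         call. = FALSE)
  }
  dn <- de_nonsens_ctrl[match(de_sens_ctrl$gene_id,
                              de_nonsens_ctrl$gene_id), ]
  hit <- function(d) abs(d$log2_fold_change) > lfc_cut & d$adjusted_p < alpha
  sel <- hit(de_sens_ctrl) & !hit(dn)
  out <- de_sens_ctrl[sel, c("gene_id", "log2_fold_change", "adjusted_p",
                             "base_mean")]
  out$direction <- ifelse(out$log2_fold_change > 0, "up", "down")
  rownames(out) <- NULL
  out[, c("gene_id", "direction", "log2_fold_change", "adjusted_p",
          "base_mean")]
}

#' Rank marker candidates by effect size and expression
#'
#' Among candidates whose mean TPM over the sensitizer-treated samples
#' reaches `min_tpm`, picks the `n_up` up-regulated genes with the largest
#' log2 fold change and the `n_down` down-regulated genes with the most
#' negative log2 fold change. Ties are broken by higher mean TPM, then by
#' gene id.
#'
#' @param candidates Output of [select_sensitizer_specific()].
#' @param tpm TPM matrix from [compute_tpm()].
#' @param sensitizer_samples Column names of `tpm` over which mean TPM is
#'   computed (the sensitizer-treated samples); defaults to all columns.
#' @param n_up,n_down Number of up-/down-regulated genes to keep
#'   (defaults 10 and 2).
#' @param min_tpm Mean-TPM floor for eligibility (default 10).
#' @return The selected candidates with a `mean_tpm` column, up-regulated
#'   first, each block in rank order. If fewer candidates are eligible than
#'   requested, all are returned with a warning.
#' @export
rank_candidates <- function(candidates, tpm, sensitizer_samples = NULL,
                            n_up = 10, n_down = 2, min_tpm = 10) {
  if (nrow(candidates) == 0) stop("no candidates to rank", call. = FALSE)
  cols <- if (is.null(sensitizer_samples)) colnames(tpm)
          else sensitizer_samples
  missing <- setdiff(candidates$gene_id, rownames(tpm))
  if (length(missing) > 0) {
    stop("TPM values missing for: ", paste(utils::head(missing, 3),
         collapse = ", "), call. = FALSE)
  }
  mean_tpm <- rowMeans(tpm[candidates$gene_id, cols, drop = FALSE])
  candidates$mean_tpm <- unname(mean_tpm)
  eligible <- candidates[candidates$mean_tpm >= min_tpm, , drop = FALSE]
  pick <- function(dir, n) {
    sub <- eligible[eligible$direction == dir, , drop = FALSE]
    score <- if (dir == "up") sub$log2_fold_change else -sub$log2_fold_change
    ord <- order(-score, -sub$mean_tpm, sub$gene_id)
    sub[utils::head(ord, n), , drop = FALSE]
  }
  n_elig_up <- sum(eligible$direction == "up")
  n_elig_down <- sum(eligible$direction == "down")
  if (n_elig_up < n_up || n_elig_down < n_down) {
    warning(sprintf(
      "only %d up and %d down eligible candidates (requested %d + %d); returning all",
      n_elig_up, n_elig_down, n_up, n_down), call. = FALSE)
  }
  out <- rbind(pick("up", n_up), pick("down", n_down))
  rownames(out) <- NULL
  out
}

#' One-call marker-discovery cascade
#'
#' Convenience wrapper running the full published filter cascade on a
#' count matrix: low-count filtering, the sensitizer-vs-control and
#' non-sensitizer-vs-control differential tests, sensitizer-specific
#' selection, and TPM-based ranking.
#'
#' @param cm A [count_matrix()] with `sensitizer`, `non_sensitizer` and
#'   `control` groups.
#' @param min_count,lfc_cut,alpha,n_up,n_down,min_tpm Stage parameters; see
#'   the individual functions.
#' @return List with elements `filtered` (count matrix), `de_sens`,
#'   `de_nonsens` (differential tables), `candidates` and `ranked`.
#' @export
select_markers <- function(cm, min_count = 10, lfc_cut = 1, alpha = 0.05,
                           n_up = 10, n_down = 2, min_tpm = 10) {
  filtered <- filter_low_counts(cm, min_count = min_count)
  de_sens <- differential_test(filtered, "control", "sensitizer")
  de_nonsens <- differential_test(filtered, "control", "non_sensitizer")
  candidates <- select_sensitizer_specific(de_sens, de_nonsens,
                                           lfc_cut = lfc_cut, alpha = alpha)
  tpm <- compute_tpm(filtered)
  sens_cols <- filtered$samples$sample[filtered$samples$group == "sensitizer"]
  ranked <- if (nrow(candidates) > 0) {
    rank_candidates(candidates, tpm, sensitizer_samples = sens_cols,
                    n_up = n_up, n_down = n_down, min_tpm = min_tpm)
  } else {
    candidates
  }
  list(filtered = filtered, de_sens = de_sens, de_nonsens = de_nonsens,
       candidates = candidates, ranked = ranked)
}
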