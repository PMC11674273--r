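test_that("low-count filter keeps genes expressed in at least one segment", {
  # gene 1: all zero -> dropped; gene 2: one segment mean 50 -> kept;
  # gene 3: both segments below 10 -> dropped
  counts <- rbind(
    g1 = rep(0L, 6),
    g2 = c(0L, 0L, 0L, 50L, 50L, 50L),
    g3 = c(5L, 5L, 5L, 9L, 9L, 9L)
  )
  colnames(counts) <- paste0("s", 1:6)
  cm <- make_cm(counts)
  kept <- filter_low_counts(cm)
  expect_equal(rownames(kept$counts), "g2")
  # idempotent, subset of input
  expect_equal(filter_low_counts(kept)$counts, kept$counts)
  # boundary: segment mean exactly 10 retained inclusively, dropped strictly
  counts2 <- rbind(g1 = c(10L, 10L, 10L, 0L, 0L, 0L))
  colnames(counts2) <- paste0("s", 1:6)
  cm2 <- make_cm(counts2)
  expect_equal(nrow(filter_low_counts(cm2)$counts), 1)
  expect_equal(nrow(filter_low_counts(cm2, boundary = "exclusive")$counts), 0)
  expect_error(filter_low_counts(cm, min_count = -1), "non-negative")
})

test_that("low-count filter drops exactly the planted low-count genes", {
  set.seed(10)
  n <- 1000
  counts <- matrix(rpois(n * 6, 100), n, 6,
                   dimnames = list(sprintf("g%04d", 1:n), paste0("s", 1:6)))
  low <- sample(n, 100)
  counts[low, ] <- matrix(sample(0:5, 100 * 6, replace = TRUE), 100, 6)
  cm <- make_cm(counts)
  kept <- filter_low_counts(cm, min_count = 10)
  expect_equal(nrow(kept$counts), 900)
  expect_false(any(rownames(counts)[low] %in% rownames(kept$counts)))
})

test_that("TPM normalizes by length and sums to one million per sample", {
  # single gene: whole library
  cm1 <- make_cm(matrix(c(5L, 7L, 9L, 11L, 2L, 3L), 1, 6))
  expect_equal(unname(compute_tpm(cm1)[1, ]), rep(1e6, 6))
  # two genes, equal counts, lengths 1kb vs 2kb: rate ratio 2:1
  counts <- matrix(100L, 2, 6, dimnames = list(c("a", "b"), paste0("s", 1:6)))
  cm2 <- make_cm(counts, lengths = c(a = 1000, b = 2000))
  tpm <- compute_tpm(cm2)
  expect_equal(unname(tpm[, 1]), c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)
  # column sums invariant
  set.seed(4)
  cm3 <- make_cm(matrix(rpois(60, 30), 10, 6),
                 lengths = setNames(runif(10, 500, 5000),
                                    sprintf("g%02d", 1:10)))
  expect_equal(unname(colSums(compute_tpm(cm3))), rep(1e6, 6),
               tolerance = 1e-6)
  # a sample with zero counts is an error
  z <- matrix(0L, 2, 6, dimnames = list(c("a", "b"), paste0("s", 1:6)))
  expect_error(compute_tpm(make_cm(z)), "zero total")
})

test_that("differential test is null on identical groups and sign-symmetric", {
  set.seed(5)
  half <- matrix(rpois(30, 50), 10, 3)
  counts <- cbind(half, half)
  dimnames(counts) <- list(sprintf("g%02d", 1:10), paste0("s", 1:6))
  cm <- make_cm(counts)
  de <- differential_test(cm, "control", "sensitizer")
  expect_equal(de$log2_fold_change, rep(0, 10))
  expect_true(all(de$p_value > 0.99))

  set.seed(6)
  counts2 <- matrix(rpois(60, 50), 10, 6,
                    dimnames = list(sprintf("g%02d", 1:10), paste0("s", 1:6)))
  cm2 <- make_cm(counts2)
  ab <- differential_test(cm2, "control", "sensitizer")
  ba <- differential_test(cm2, "sensitizer", "control")
  expect_equal(ab$log2_fold_change, -ba$log2_fold_change)
  expect_equal(ab$p_value, ba$p_value)
  # reordering samples within groups changes nothing
  perm <- c(3, 1, 2, 6, 4, 5)
  cm3 <- count_matrix(counts2[, perm], cm2$lengths, cm2$samples[perm, ])
  expect_equal(differential_test(cm3, "control", "sensitizer")$p_value,
               ab$p_value)
  small <- count_matrix(
    counts2[, 1:3], cm2$lengths,
    data.frame(sample = paste0("s", 1:3), treatment = c("a", "a", "b"),
               group = c("control", "control", "sensitizer"))
  )
  expect_error(differential_test(small, "control", "sensitizer"),
               "two samples")
})

test_that("differential test flags planted effects and controls the null", {
  # planted: 200 genes at true log2FC = 3, mean 500, dispersion 0.05
  set.seed(7)
  n <- 2000
  counts <- matrix(rnbinom(n * 6, mu = 500, size = 1 / 0.05), n, 6,
                   dimnames = list(sprintf("g%04d", 1:n), paste0("s", 1:6)))
  planted <- 1:200
  counts[planted, 4:6] <- rnbinom(200 * 3, mu = 500 * 8, size = 1 / 0.05)
  cm <- make_cm(counts)
  de <- differential_test(cm, "control", "sensitizer")
  expect_gte(mean(de$adjusted_p[planted] < 0.05), 0.9)
  # estimated effect close to truth on average
  expect_equal(mean(de$log2_fold_change[planted]), 3, tolerance = 0.1)

  # null: 5000 genes, no effect, BH keeps flags at or below 1%
  cm0 <- generate_counts(rnaseq_scenario(
    n_genes = 5000, n_sensitizer = 1, n_nonsensitizer = 0, n_control = 1,
    planted_up = 0, planted_down = 0, seed = 42))
  de0 <- differential_test(cm0, "control", "sensitizer")
  expect_lte(mean(de0$adjusted_p < 0.05), 0.01)
})

test_that("simplified NB test tracks an established reference implementation", {
  set.seed(8)
  n <- 600
  mu <- rlnorm(n, log(100), 1)
  counts <- matrix(rnbinom(n * 6, mu = rep(mu, 6), size = 20), n, 6,
                   dimnames = list(sprintf("g%04d", 1:n), paste0("s", 1:6)))
  idx <- 1:60
  counts[idx, 4:6] <- rnbinom(60 * 3, mu = rep(mu[idx] * 8, 3), size = 20)
  cm <- make_cm(counts)
  de <- differential_test(cm, "control", "sensitizer")

  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      counts, S4Vectors::DataFrame(condition = factor(rep(c("a", "b"),
                                                          each = 3))),
      ~condition)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    ref <- as.data.frame(DESeq2::results(dds))
  })
  # effect sizes agree closely
  expect_gt(cor(de$log2_fold_change, ref$log2FoldChange), 0.95)
  # the simplified test is the more conservative of the two at n = 3, so
  # its discoveries should sit almost entirely inside the reference set,
  # and both should find nearly all strongly planted genes
  mine <- de$gene_id[de$adjusted_p < 0.05 & abs(de$log2_fold_change) > 1]
  theirs <- rownames(ref)[!is.na(ref$padj) & ref$padj < 0.05 &
                            abs(ref$log2FoldChange) > 1]
  expect_gte(length(intersect(mine, theirs)) / length(mine), 0.9)
  strong <- rownames(counts)[idx][mu[idx] > 50]
  expect_gte(mean(strong %in% mine), 0.8)
  expect_gte(mean(strong %in% theirs), 0.8)
})

test_that("sensitizer-specific selection excludes shared and non-specific hits", {
  de <- function(genes, lfc, padj) {
    data.frame(gene_id = genes, base_mean = 100, log2_fold_change = lfc,
               p_value = padj, adjusted_p = padj, stringsAsFactors = FALSE)
  }
  genes <- c("shared", "specific_up", "specific_down", "null")
  sens <- de(genes, c(5.2, 5.2, -2, 0.1), c(1e-8, 1e-8, 1e-4, 0.9))
  nons <- de(genes, c(4.0, 0.2, 0.1, 0.2), c(1e-6, 0.8, 0.7, 0.8))
  sel <- select_sensitizer_specific(sens, nons)
  expect_setequal(sel$gene_id, c("specific_up", "specific_down"))
  expect_equal(sel$direction[sel$gene_id == "specific_up"], "up")
  expect_equal(sel$direction[sel$gene_id == "specific_down"], "down")
  # identical significant sets give the empty selection
  expect_equal(nrow(select_sensitizer_specific(sens, sens)), 0)
  # mismatched gene universes error
  expect_error(select_sensitizer_specific(sens, nons[-1, ]), "universe")
})

test_that("candidate ranking matches a brute-force sort oracle", {
  set.seed(9)
  n <- 40
  cand <- data.frame(
    gene_id = sprintf("g%02d", 1:n),
    direction = rep(c("up", "down"), c(30, 10)),
    log2_fold_change = c(runif(30, 1, 6), runif(10, -6, -1)),
    adjusted_p = 1e-4, base_mean = 100, stringsAsFactors = FALSE
  )
  # force ties in log2FC to exercise the TPM tie-break
  cand$log2_fold_change[1:2] <- 3
  tpm <- matrix(runif(n * 3, 0, 200), n, 3,
                dimnames = list(cand$gene_id, paste0("s", 1:3)))
  tpm[1, ] <- 100; tpm[2, ] <- 10
  ranked <- rank_candidates(cand, tpm, n_up = 5, n_down = 2, min_tpm = 10)

  # oracle: filter, order by (score, mean TPM, id), take heads
  m <- rowMeans(tpm)
  elig <- cand[m[cand$gene_id] >= 10, ]
  sc <- ifelse(elig$direction == "up", 1, -1) * elig$log2_fold_change
  ord <- elig[order(-sc, -m[elig$gene_id], elig$gene_id), ]
  want <- rbind(head(ord[ord$direction == "up", ], 5),
                head(ord[ord$direction == "down", ], 2))
  expect_equal(ranked$gene_id, want$gene_id)

  # equal-lfc tie broken toward the higher-TPM gene
  two <- cand[1:2, ]
  r2 <- rank_candidates(two, tpm, n_up = 1, n_down = 0, min_tpm = 0)
  expect_equal(r2$gene_id, "g01")
  # single candidate comes back as-is
  r1 <- rank_candidates(cand[1, ], tpm, n_up = 1, n_down = 0, min_tpm = 0)
  expect_equal(r1$gene_id, "g01")
  # asking for more than available warns and returns all eligible
  expect_warning(
    rank_candidates(cand[1:3, ], tpm, n_up = 10, n_down = 2, min_tpm = 0),
    "returning all"
  )
})
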