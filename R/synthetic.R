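# Synthetic-data generators: qPCR Cq tables with known true fold changes,
# group-structured negative-binomial RNA-Seq counts with planted
# sensitizer-specific genes, and chemical metadata panels. All generators
# are deterministic for a fixed seed.

#' Describe a synthetic qPCR experiment
#'
#' True fold changes are planted per chemical x gene; the reference gene is
#' fixed at fold change 1. Measurement error is additive Gaussian on the
#' cycle (Cq) scale, i.e. log2-normal on the ratio scale - the standard
#' qPCR error model.
#'
#' @param true_fc Matrix or data frame of true linear fold changes,
#'   chemicals in rows (rownames = chemical ids), target genes in columns;
#'   all > 0.
#' @param reference_gene Reference gene symbol (default `"GAPDH"`).
#' @param baseline_cq Named numeric vector of baseline cycles per gene
#'   (targets and reference). Defaults to 25 cycles for targets, 20 for
#'   the reference.
#' @param replicate_noise_sd Per-well Cq noise, in cycles (default 0.1;
#'   0 gives a noiseless table).
#' @param n_replicates Replicates per condition (default 3).
#' @param seed Integer seed.
#' @return An object of class `qpcr_scenario`.
#' @export
qpcr_scenario <- function(true_fc, reference_gene = "GAPDH",
                          baseline_cq = NULL, replicate_noise_sd = 0.1,
                          n_replicates = 3, seed = 1L) {
  true_fc <- as.matrix(true_fc)
  if (is.null(rownames(true_fc)) || is.null(colnames(true_fc))) {
    stop("true_fc needs chemical rownames and gene colnames", call. = FALSE)
  }
  if (any(true_fc <= 0)) stop("true fold changes must be > 0", call. = FALSE)
  if (replicate_noise_sd < 0) stop("noise sd must be >= 0", call. = FALSE)
  genes <- c(colnames(true_fc), reference_gene)
  if (is.null(baseline_cq)) {
    baseline_cq <- stats::setNames(
      c(rep(25, ncol(true_fc)), 20), genes)
  }
  missing <- setdiff(genes, names(baseline_cq))
  if (length(missing) > 0) {
    stop("baseline_cq missing for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(true_fc = true_fc, reference_gene = reference_gene,
         baseline_cq = baseline_cq, replicate_noise_sd = replicate_noise_sd,
         n_replicates = as.integer(n_replicates), seed = as.integer(seed)),
    class = "qpcr_scenario"
  )
}

#' Generate a raw Cq table from a scenario
#'
#' For a target gene with true fold change F, the treated Cq is
#' `baseline - log2(F) + noise` (higher expression -> earlier
#' amplification), while solvent-control and reference wells sit at their
#' baselines plus noise. A noiseless scenario therefore inverts exactly
#' through [foldchange_from_cq()].
#'
#' @param scenario A [qpcr_scenario()].
#' @return Long-format Cq data frame (`chemical`, `gene`, `condition`,
#'   `replicate`, `cq`).
#' @export
generate_cq <- function(scenario) {
  stopifnot(inherits(scenario, "qpcr_scenario"))
  set.seed(scenario$seed)
  chems <- rownames(scenario$true_fc)
  genes <- c(colnames(scenario$true_fc), scenario$reference_gene)
  n <- scenario$n_replicates
  grid <- expand.grid(
    replicate = seq_len(n),
    condition = c("treated", "solvent_control"),
    gene = genes, chemical = chems,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )[, c("chemical", "gene", "condition", "replicate")]
  base <- scenario$baseline_cq[grid$gene]
  shift <- numeric(nrow(grid))
  is_target <- grid$condition == "treated" &
    grid$gene != scenario$reference_gene
  shift[is_target] <- log2(
    scenario$true_fc[cbind(grid$chemical[is_target], grid$gene[is_target])]
  )
  grid$cq <- base - shift +
    stats::rnorm(nrow(grid), sd = scenario$replicate_noise_sd)
  grid
}

#' Describe a synthetic RNA-Seq experiment
#'
#' Emulates the marker-discovery design: six sensitizer treatments, three
#' non-sensitizer treatments and two controls, each with triplicate
#' samples. Baseline expression is log-normal across genes, gene lengths
#' are log-uniform in [500, 1e5] bases, per-gene dispersions are log-normal
#' around 0.05, and counts are negative-binomial. A set of planted genes is
#' shifted in all sensitizer-treated samples only: `planted_up` genes with
#' log2 fold change drawn uniform in [1.5, 6] and `planted_down` genes with
#' the negated range.
#'
#' @param n_genes Number of genes (default 8000).
#' @param n_sensitizer,n_nonsensitizer,n_control Numbers of treatments per
#'   group (defaults 6, 3, 2).
#' @param n_replicates Samples per treatment (default 3).
#' @param planted_up,planted_down Planted gene counts (defaults 60, 2).
#' @param lfc_range Range of the planted |log2 fold change|
#'   (default `c(1.5, 6)`).
#' @param mean_log_mu,sd_log_mu Parameters of the log-normal baseline mean
#'   (defaults `log(100)` and 1.5).
#' @param dispersion_meanlog,dispersion_sdlog Log-normal dispersion
#'   parameters (defaults `log(0.05)` and 0.5).
#' @param library_size Mean library-size factor; per-sample factors are
#'   drawn uniform in [0.7, 1.3] times this value (default 1).
#' @param seed Integer seed.
#' @return An object of class `rnaseq_scenario`.
#' @export
rnaseq_scenario <- function(n_genes = 8000, n_sensitizer = 6,
                            n_nonsensitizer = 3, n_control = 2,
                            n_replicates = 3, planted_up = 60,
                            planted_down = 2, lfc_range = c(1.5, 6),
                            mean_log_mu = log(100), sd_log_mu = 1.5,
                            dispersion_meanlog = log(0.05),
                            dispersion_sdlog = 0.5,
                            library_size = 1, seed = 1L) {
  if (planted_up + planted_down > n_genes) {
    stop("more planted genes than genes", call. = FALSE)
  }
  if (any(lfc_range < 1)) {
    stop("planted |log2 fold changes| must exceed 1", call. = FALSE)
  }
  structure(
    list(n_genes = n_genes, n_sensitizer = n_sensitizer,
         n_nonsensitizer = n_nonsensitizer, n_control = n_control,
         n_replicates = n_replicates, planted_up = planted_up,
         planted_down = planted_down, lfc_range = lfc_range,
         mean_log_mu = mean_log_mu, sd_log_mu = sd_log_mu,
         dispersion_meanlog = dispersion_meanlog,
         dispersion_sdlog = dispersion_sdlog,
         library_size = library_size, seed = as.integer(seed)),
    class = "rnaseq_scenario"
  )
}

#' Generate a count matrix with planted sensitizer-specific genes
#'
#' @param scenario An [rnaseq_scenario()].
#' @return A [count_matrix()] with attributes `planted_up`, `planted_down`
#'   (gene ids) and `planted_lfc` (named log2 fold changes).
#' @export
generate_counts <- function(scenario) {
  stopifnot(inherits(scenario, "rnaseq_scenario"))
  set.seed(scenario$seed)
  s <- scenario
  genes <- sprintf("gene%05d", seq_len(s$n_genes))
  treatments <- c(
    sprintf("sens%d", seq_len(s$n_sensitizer)),
    sprintf("nonsens%d", seq_len(s$n_nonsensitizer)),
    sprintf("ctrl%d", seq_len(s$n_control))
  )
  groups <- rep(c("sensitizer", "non_sensitizer", "control"),
                c(s$n_sensitizer, s$n_nonsensitizer, s$n_control))
  samples <- data.frame(
    sample = paste0(rep(treatments, each = s$n_replicates), "_r",
                    rep(seq_len(s$n_replicates), length(treatments))),
    treatment = rep(treatments, each = s$n_replicates),
    group = rep(groups, each = s$n_replicates),
    stringsAsFactors = FALSE
  )
  mu0 <- stats::rlnorm(s$n_genes, s$mean_log_mu, s$sd_log_mu)
  lengths <- stats::setNames(
    round(exp(stats::runif(s$n_genes, log(500), log(1e5)))), genes)
  disp <- stats::rlnorm(s$n_genes, s$dispersion_meanlog, s$dispersion_sdlog)
  planted <- sample.int(s$n_genes, s$planted_up + s$planted_down)
  up <- planted[seq_len(s$planted_up)]
  down <- setdiff(planted, up)
  lfc <- numeric(s$n_genes)
  lfc[up] <- stats::runif(s$planted_up, s$lfc_range[1], s$lfc_range[2])
  lfc[down] <- -stats::runif(s$planted_down, s$lfc_range[1], s$lfc_range[2])
  sf <- stats::runif(nrow(samples), 0.7, 1.3) * s$library_size
  is_sens <- samples$group == "sensitizer"
  mu <- outer(mu0, sf)
  mu[, is_sens] <- mu[, is_sens] * 2^lfc
  counts <- matrix(
    stats::rnbinom(length(mu), mu = mu, size = rep(1 / disp, ncol(mu))),
    nrow = s$n_genes, dimnames = list(genes, samples$sample)
  )
  cm <- count_matrix(counts, lengths, samples)
  attr(cm, "planted_up") <- genes[up]
  attr(cm, "planted_down") <- genes[down]
  attr(cm, "planted_lfc") <- stats::setNames(lfc[planted], genes[planted])
  cm
}

#' Generate a chemical metadata panel
#'
#' Produces plausible chemical records for evaluation tests: sensitizers
#' get a random LLNA potency class and non-sensitizers the
#' `non_sensitizer` label; h-CLAT judgments are set consistently with the
#' LLNA label.
#'
#' @param n_sensitizers,n_nonsensitizers Record counts (non-negative).
#' @param seed Integer seed.
#' @return A chemical metadata data frame in the [read_chemical_table()]
#'   layout.
#' @export
generate_chemical_panel <- function(n_sensitizers, n_nonsensitizers,
                                    seed = 1L) {
  if (n_sensitizers < 0 || n_nonsensitizers < 0) {
    stop("counts must be non-negative", call. = FALSE)
  }
  set.seed(seed)
  n <- n_sensitizers + n_nonsensitizers
  potency <- c("extreme", "strong", "moderate", "weak")
  cat <- c(sample(potency, n_sensitizers, replace = TRUE),
           rep("non_sensitizer", n_nonsensitizers))
  data.frame(
    name = sprintf("CHEM-%03d", seq_len(n)),
    abbreviation = NA_character_,
    cas = NA_character_,
    solvent = sample(c("DMSO", "medium"), n, replace = TRUE),
    cv75 = NA_real_,
    cv75_raw = NA_character_,
    llna_category = cat,
    hclat_judgment = ifelse(cat == "non_sensitizer", "n", "p"),
    stringsAsFactors = FALSE
  )
}
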