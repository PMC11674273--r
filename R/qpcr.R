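# Comparative Cq quantification and the RT h-CLAT decision rule.
#
# Fold changes are computed by the comparative Cq method: the target gene's
# quantification cycle is normalized to the GAPDH reference (delta Cq), the
# treated delta Cq is contrasted with the solvent control's (delta delta
# Cq), and the linear ratio is 2^-(ddCq). One PCR cycle equals one doubling
# of template.

#' Normalize a target Cq to the reference gene
#'
#' @param cq_target Quantification cycle(s) of the target gene.
#' @param cq_reference Quantification cycle(s) of the reference gene
#'   (e.g. *GAPDH*) from the same sample.
#' @return `cq_target - cq_reference`, in cycles.
#' @export
delta_cq <- function(cq_target, cq_reference) {
  if (any(!is.finite(cq_target)) || any(!is.finite(cq_reference))) {
    stop("Cq values must be finite", call. = FALSE)
  }
  cq_target - cq_reference
}

#' Linear fold change from two delta Cq values
#'
#' Implements the comparative Cq method: the expression ratio of treated to
#' control is `2^-(dcq_treated - dcq_control)`.
#'
#' @param dcq_treated Delta Cq of the treated sample (cycles).
#' @param dcq_control Delta Cq of the matched solvent control (cycles).
#' @return Strictly positive linear expression ratio.
#' @export
fold_change <- function(dcq_treated, dcq_control) {
  if (any(!is.finite(dcq_treated)) || any(!is.finite(dcq_control))) {
    stop("delta Cq values must be finite", call. = FALSE)
  }
  2^-(dcq_treated - dcq_control)
}

#' Validate a raw Cq table
#'
#' A Cq table is long-format: one row per (chemical, gene, condition,
#' replicate) with columns `chemical`, `gene`, `condition` (`treated` or
#' `solvent_control`), `replicate` and `cq` (cycles, finite and positive).
#'
#' @param cq Data frame as described above.
#' @return The validated data frame, invisibly.
#' @export
validate_cq_table <- function(cq) {
  required <- c("chemical", "gene", "condition", "replicate", "cq")
  missing <- setdiff(required, names(cq))
  if (length(missing) > 0) {
    stop("Cq table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad_cond <- setdiff(unique(cq$condition), c("treated", "solvent_control"))
  if (length(bad_cond) > 0) {
    stop("invalid condition label(s): ", paste(bad_cond, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(cq$cq)) || any(cq$cq <= 0)) {
    stop("Cq values must be finite and positive", call. = FALSE)
  }
  key <- interaction(cq$chemical, cq$gene, cq$condition, drop = TRUE)
  dup <- tapply(cq$replicate, key, function(r) anyDuplicated(r) > 0)
  if (any(dup)) {
    stop("duplicated replicate index in Cq block '", names(dup)[dup][1], "'",
         call. = FALSE)
  }
  invisible(cq)
}

#' Fold-change triplicates from a raw Cq table
#'
#' Converts raw quantification cycles to per-replicate linear fold changes
#' by the comparative Cq method: each target gene is normalized to the
#' reference gene within the same sample, and the treated delta Cq is
#' contrasted with the solvent control delta Cq of the same chemical.
#'
#' Two control conventions are supported. With `control = "paired"` (the
#' default) treated replicate i is contrasted with control replicate i;
#' with `control = "mean"` every treated replicate is contrasted with the
#' mean control delta Cq. Both are common comparative-Cq conventions; the
#' default is stated so results are reproducible.
#'
#' @param cq Long-format Cq table (see [validate_cq_table()]).
#' @param reference_gene Symbol of the reference gene (default `"GAPDH"`).
#' @param control One of `"paired"` or `"mean"`.
#' @return Long-format fold-change data frame (`chemical`, `gene`,
#'   `replicate`, `fc`) with one triplicate per chemical x target gene.
#' @export
foldchange_from_cq <- function(cq, reference_gene = "GAPDH",
                               control = c("paired", "mean")) {
  control <- match.arg(control)
  validate_cq_table(cq)
  targets <- setdiff(unique(cq$gene), reference_gene)
  if (length(targets) == 0) {
    stop("no target genes besides the reference '", reference_gene, "'",
         call. = FALSE)
  }
  out <- list()
  for (chem in unique(cq$chemical)) {
    sub <- cq[cq$chemical == chem, , drop = FALSE]
    ref_t <- sub[sub$gene == reference_gene & sub$condition == "treated", ]
    ref_c <- sub[sub$gene == reference_gene &
                   sub$condition == "solvent_control", ]
    if (nrow(ref_t) == 0 || nrow(ref_c) == 0) {
      stop(sprintf("missing reference-gene rows for chemical '%s'", chem),
           call. = FALSE)
    }
    for (g in intersect(targets, unique(sub$gene))) {
      tg_t <- sub[sub$gene == g & sub$condition == "treated", ]
      tg_c <- sub[sub$gene == g & sub$condition == "solvent_control", ]
      if (nrow(tg_t) == 0 || nrow(tg_c) == 0) {
        stop(sprintf("missing %s rows for chemical '%s', gene '%s'",
                     if (nrow(tg_t) == 0) "treated" else "solvent-control",
                     chem, g), call. = FALSE)
      }
      reps <- sort(tg_t$replicate)
      dcq_t <- delta_cq(tg_t$cq[match(reps, tg_t$replicate)],
                        ref_t$cq[match(reps, ref_t$replicate)])
      if (any(is.na(dcq_t))) {
        stop(sprintf("reference replicate missing for chemical '%s'", chem),
             call. = FALSE)
      }
      dcq_c_all <- delta_cq(
        tg_c$cq[order(tg_c$replicate)],
        ref_c$cq[match(sort(tg_c$replicate), ref_c$replicate)]
      )
      dcq_c <- if (control == "paired") {
        creps <- sort(tg_c$replicate)
        idx <- match(reps, creps)
        if (any(is.na(idx))) {
          stop(sprintf(
            "control replicate missing for chemical '%s', gene '%s'",
            chem, g), call. = FALSE)
        }
        dcq_c_all[idx]
      } else {
        rep(mean(dcq_c_all), length(reps))
      }
      out[[length(out) + 1L]] <- data.frame(
        chemical = chem, gene = g, replicate = reps,
        fc = fold_change(dcq_t, dcq_c), stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' The RT h-CLAT decision rule
#'
#' A chemical is called a sensitizer if, for at least one gene of the marker
#' panel, at least `quorum` of the `n_replicates` fold changes reach the
#' `threshold`. The default rule is the published one: a two-fold or greater
#' increase in two or more of three replicates, on the *HMOX1*/*JUN* panel.
#' The threshold comparison is inclusive by default (a replicate exactly at
#' 2.0 counts as positive); set `inclusive = FALSE` for a strict comparison
#' in sensitivity analyses. Only increases ever count: fold changes below 1
#' never contribute to positivity.
#'
#' @param threshold Linear fold-change cutoff, must exceed 1 (default 2).
#' @param quorum Minimum number of positive replicates (default 2).
#' @param n_replicates Total replicates per triplicate (default 3).
#' @param panel Ordered character vector of marker genes
#'   (default `c("HMOX1", "JUN")`).
#' @param inclusive Logical; count a replicate exactly at the threshold as
#'   positive (default `TRUE`).
#' @return An object of class `decision_rule`.
#' @export
decision_rule <- function(threshold = 2, quorum = 2, n_replicates = 3,
                          panel = c("HMOX1", "JUN"), inclusive = TRUE) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 1) {
    stop("threshold must be a single number > 1", call. = FALSE)
  }
  if (quorum < 1 || quorum > n_replicates) {
    stop("quorum must be between 1 and n_replicates", call. = FALSE)
  }
  if (length(panel) < 1) stop("panel must name at least one gene",
                              call. = FALSE)
  structure(
    list(threshold = threshold, quorum = as.integer(quorum),
         n_replicates = as.integer(n_replicates),
         panel = as.character(panel), inclusive = isTRUE(inclusive)),
    class = "decision_rule"
  )
}

#' @export
print.decision_rule <- function(x, ...) {
  cat(sprintf(
    "decision_rule: fc %s %.3g in >= %d of %d replicates; panel: %s\n",
    if (x$inclusive) ">=" else ">", x$threshold, x$quorum, x$n_replicates,
    paste(x$panel, collapse = " or ")
  ))
  invisible(x)
}

#' Replicate-majority positivity for one gene
#'
#' @param fc Numeric vector of replicate fold changes for one
#'   chemical x gene.
#' @param rule A [decision_rule()].
#' @return `TRUE` iff the number of replicates at or above the threshold
#'   (strictly above when `inclusive = FALSE`) reaches the quorum.
#' @export
gene_positive <- function(fc, rule = decision_rule()) {
  stopifnot(inherits(rule, "decision_rule"))
  if (any(!is.finite(fc)) || any(fc <= 0)) {
    stop("fold changes must be finite and positive", call. = FALSE)
  }
  if (length(fc) != rule$n_replicates) {
    stop(sprintf("expected %d replicates, got %d", rule$n_replicates,
                 length(fc)), call. = FALSE)
  }
  hits <- if (rule$inclusive) sum(fc >= rule$threshold)
          else sum(fc > rule$threshold)
  hits >= rule$quorum
}
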