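# Accessors for the bundled validation datasets: the chemical metadata
# panel, the 12-candidate-gene qPCR/RNA-Seq concordance table for the nine
# reference chemicals, and the HMOX1/JUN fold-change triplicates for the
# 28-chemical evaluation panel, together with the originally reported
# judgments.

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "rthclat")
  if (path == "") stop("bundled dataset not found: ", file, call. = FALSE)
  path
}

#' Bundled chemical metadata
#'
#' Metadata for the 37 test chemicals of the validation study: the nine
#' OECD reference chemicals used for RNA-Seq marker discovery and the 28
#' chemicals of the evaluation panel, with murine LLNA potency categories
#' and h-CLAT judgments. Fields not reported (CAS, solvent, CV75 for most
#' chemicals) are left blank.
#'
#' @return Data frame from [read_chemical_table()].
#' @export
study_chemicals <- function() {
  read_chemical_table(.extdata("chemicals.tsv"))
}

#' Bundled qPCR/RNA-Seq concordance data for the 12 candidate markers
#'
#' One row per reference chemical x candidate gene (9 x 12 = 108 cells):
#' the RNA-Seq fold change (TPM ratio), the three qPCR replicate fold
#' changes, and the originally reported Match/Mismatch verdict.
#'
#' @return Data frame with columns `chemical`, `gene`, `ngs_fc`,
#'   `pcr_fc1`..`pcr_fc3`, `printed_verdict`.
#' @seealso [concordance_table()], [retained_markers()]
#' @export
candidate_marker_concordance <- function() {
  .read_delim(.extdata("candidate_marker_concordance.tsv"))
}

#' Bundled HMOX1/JUN fold changes for the 28-chemical evaluation panel
#'
#' Long-format triplicate fold changes (28 chemicals x 2 genes x 3
#' replicates).
#'
#' @return Long-format fold-change data frame.
#' @seealso [rt_hclat()], [hmox1_jun_reported_judgments()]
#' @export
hmox1_jun_panel <- function() {
  read_foldchange_table(.extdata("hmox1_jun_panel.tsv"))
}

#' Originally reported judgments for the 28-chemical panel
#'
#' The published per-chemical sensitizer calls and LLNA match status, used
#' to validate that the decision rule reproduces them.
#'
#' @return Data frame with columns `chemical`, `printed_call`,
#'   `printed_match`.
#' @export
hmox1_jun_reported_judgments <- function() {
  .read_delim(.extdata("hmox1_jun_judgments.tsv"))
}
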