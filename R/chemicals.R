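# Chemical metadata: reading, validation, LLNA binarization.

.llna_levels <- c("extreme", "strong", "moderate", "weak", "non_sensitizer", "ND")
.hclat_levels <- c("p", "n", "ND")

# Normalize the spellings found in published tables to the internal enums.
.normalize_llna <- function(x) {
  x <- trimws(as.character(x))
  x[x == "" | is.na(x)] <- "ND"
  key <- tolower(gsub("[ -]", "_", x))
  map <- c(
    extreme = "extreme", strong = "strong", moderate = "moderate",
    weak = "weak", non_sensitizer = "non_sensitizer",
    nonsensitizer = "non_sensitizer", nd = "ND"
  )
  out <- unname(map[key])
  bad <- which(is.na(out))
  if (length(bad) > 0) {
    stop(sprintf("invalid LLNA category '%s' in row %d", x[bad[1]], bad[1]),
         call. = FALSE)
  }
  out
}

.normalize_hclat <- function(x) {
  x <- trimws(as.character(x))
  x[x == "" | is.na(x)] <- "ND"
  bad <- which(!x %in% .hclat_levels)
  if (length(bad) > 0) {
    stop(sprintf("invalid h-CLAT judgment '%s' in row %d", x[bad[1]], bad[1]),
         call. = FALSE)
  }
  x
}

.cas_pattern <- "^[0-9]{2,7}-[0-9]{2}-[0-9]$"

#' Read a chemical metadata table
#'
#' Reads a delimited text file describing the test chemicals: name,
#' abbreviation, CAS registry number, solvent, CV75 (the concentration
#' giving 75% cell viability, carried as supplied), murine LLNA potency
#' category and h-CLAT judgment. LLNA categories are normalized to
#' `extreme`/`strong`/`moderate`/`weak`/`non_sensitizer`/`ND`; h-CLAT
#' judgments to `p`/`n`/`ND`. Empty cells for CAS, solvent and CV75 are
#' allowed (`NA`); a CAS number, when present, must match the usual
#' `NN...N-NN-N` pattern.
#'
#' @param path Path to a tab- or comma-delimited file with a header row
#'   naming at least `name`, `llna_category` and `hclat_judgment`.
#' @return A data frame with columns `name`, `abbreviation`, `cas`,
#'   `solvent`, `cv75` (numeric where parseable), `cv75_raw`,
#'   `llna_category`, `hclat_judgment`.
#' @seealso [llna_binary()], [study_chemicals()]
#' @export
read_chemical_table <- function(path) {
  tab <- .read_delim(path)
  required <- c("name", "llna_category", "hclat_judgment")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("chemical table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  n <- nrow(tab)
  get <- function(col) {
    if (col %in% names(tab)) as.character(tab[[col]]) else rep(NA_character_, n)
  }
  cas <- get("cas")
  cas[!is.na(cas) & trimws(cas) == ""] <- NA_character_
  bad_cas <- which(!is.na(cas) & !grepl(.cas_pattern, cas))
  if (length(bad_cas) > 0) {
    stop(sprintf("malformed CAS number '%s' in row %d", cas[bad_cas[1]],
                 bad_cas[1]), call. = FALSE)
  }
  solvent <- get("solvent")
  solvent[!is.na(solvent) & trimws(solvent) == ""] <- NA_character_
  bad_sol <- which(!is.na(solvent) & !solvent %in% c("DMSO", "medium"))
  if (length(bad_sol) > 0) {
    stop(sprintf("invalid solvent '%s' in row %d (expected DMSO or medium)",
                 solvent[bad_sol[1]], bad_sol[1]), call. = FALSE)
  }
  cv75_raw <- get("cv75")
  cv75 <- suppressWarnings(as.numeric(cv75_raw))
  abbreviation <- get("abbreviation")
  abbreviation[!is.na(abbreviation) & trimws(abbreviation) == ""] <- NA_character_
  out <- data.frame(
    name = as.character(tab$name),
    abbreviation = abbreviation,
    cas = cas,
    solvent = solvent,
    cv75 = cv75,
    cv75_raw = cv75_raw,
    llna_category = .normalize_llna(tab$llna_category),
    hclat_judgment = .normalize_hclat(tab$hclat_judgment),
    stringsAsFactors = FALSE
  )
  out
}

#' Binarize a murine LLNA potency category
#'
#' Any potency class (`extreme`, `strong`, `moderate`, `weak`) counts as
#' `sensitizer`; `non_sensitizer` maps to `non_sensitizer`; `ND` (no data)
#' maps to `NA`, meaning the chemical cannot be scored against LLNA.
#'
#' @param category Character vector of LLNA categories.
#' @return Character vector with values `sensitizer`, `non_sensitizer` or
#'   `NA`.
#' @export
llna_binary <- function(category) {
  bad <- setdiff(unique(category), .llna_levels)
  if (length(bad) > 0) {
    stop("invalid LLNA category: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- ifelse(category == "ND", NA_character_,
                ifelse(category == "non_sensitizer", "non_sensitizer",
                       "sensitizer"))
  out
}

# Shared delimited reader: sniffs tab vs comma from the header line.
.read_delim <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, check.names = TRUE,
                    comment.char = "", na.strings = c("NA"),
                    colClasses = NA, fill = TRUE)
}
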