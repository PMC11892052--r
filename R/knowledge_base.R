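#' @import data.table
#' @importFrom stats rbinom rpois rnorm runif rbeta qpois dpois median qnorm qt pnorm
#'   dnorm pt lm glm binomial coef vcov predict model.matrix as.formula
#'   complete.cases t.test sd quantile plogis qlogis setNames optim
#' @importFrom utils head
NULL

# ICD-10-CM full code: letter + 2 digits, optional "." + 1-4 alphanumerics.
ICD10_FULL_RE <- "^[A-Za-z][0-9]{2}(\\.[A-Za-z0-9]{1,4})?$"
# 3-character category code.
ICD10_CAT_RE <- "^[A-Z][0-9]{2}$"

RELATIONS <- c("indication", "contraindication")

#' Truncate an ICD-10-CM code to its 3-character category
#'
#' Disease matching in the knowledge base is done at the 3-digit ICD-10
#' category level: full-precision codes such as \code{"E11.9"} collapse to
#' their category \code{"E11"}. Letters are upper-cased.
#'
#' @param code Character vector of ICD-10-CM codes (e.g. \code{"E11.9"},
#'   \code{"J45"}).
#' @return Character vector of 3-character upper-case category codes.
#' @examples
#' truncate_icd10(c("E11.9", "J45", "k52.9"))
#' @export
truncate_icd10 <- function(code) {
  if (!is.character(code)) stop("`code` must be a character vector")
  bad <- !grepl(ICD10_FULL_RE, code)
  if (any(bad)) {
    stop("malformed ICD-10-CM code(s): ",
         paste(unique(code[bad]), collapse = ", "))
  }
  toupper(substr(code, 1L, 3L))
}

#' Build a drug indication/contraindication knowledge base
#'
#' Expands drug-to-SNOMED concept pairs through a SNOMED CT to ICD-10-CM map,
#' truncates the mapped codes to 3-character categories, and deduplicates to a
#' canonical set of (drug, ICD-10 category, relation) pairs. SNOMED concepts
#' mapping to several ICD-10-CM codes expand to all targets (the NLM map is
#' one-to-many); concepts absent from the map are dropped and counted in the
#' QC report rather than guessed.
#'
#' @param drug_records data.frame with columns \code{drug_id},
#'   \code{ingredient_name}, \code{approval_year}. Drug identity is at
#'   active-ingredient level; names are normalised to trimmed lower case.
#' @param concept_pairs data.frame with columns \code{drug_id},
#'   \code{snomed_id}, \code{relation} (\code{"indication"} or
#'   \code{"contraindication"}). May have zero rows.
#' @param concept_map data.frame with columns \code{snomed_id},
#'   \code{icd10_code} (one row per SNOMED-to-ICD target; full-precision
#'   ICD-10-CM codes).
#' @return An object of class \code{rx_kb}: a list with \code{drugs}
#'   (data.table), \code{pairs} (data.table of drug_id, icd10_3, relation) and
#'   \code{qc} (counts of drugs, pairs by relation, and dropped concepts).
#' @export
build_knowledge_base <- function(drug_records, concept_pairs, concept_map) {
  drugs <- as.data.table(drug_records)
  need <- c("drug_id", "ingredient_name", "approval_year")
  if (!all(need %in% names(drugs))) {
    stop("drug_records must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(drugs) == 0L) stop("drug_records must be non-empty")
  drugs <- drugs[, .(drug_id = as.character(drug_id),
                     ingredient_name = tolower(trimws(ingredient_name)),
                     approval_year = as.integer(approval_year))]
  if (anyDuplicated(drugs$drug_id)) {
    stop("duplicate drug_id in drug_records: ",
         paste(unique(drugs$drug_id[duplicated(drugs$drug_id)]), collapse = ", "))
  }
  bad_year <- drugs$approval_year < 1900L | drugs$approval_year > 2025L |
    is.na(drugs$approval_year)
  if (any(bad_year)) {
    stop("approval_year outside [1900, 2025] for drug(s): ",
         paste(drugs$drug_id[bad_year], collapse = ", "))
  }

  cp <- as.data.table(concept_pairs)
  if (nrow(cp) == 0L) {
    cp <- data.table(drug_id = character(), snomed_id = character(),
                     relation = character())
  }
  if (!all(c("drug_id", "snomed_id", "relation") %in% names(cp))) {
    stop("concept_pairs must have columns drug_id, snomed_id, relation")
  }
  cp <- cp[, .(drug_id = as.character(drug_id),
               snomed_id = as.character(snomed_id),
               relation = as.character(relation))]
  if (nrow(cp) && !all(cp$relation %in% RELATIONS)) {
    stop("invalid relation value(s): ",
         paste(setdiff(unique(cp$relation), RELATIONS), collapse = ", "))
  }
  unknown <- setdiff(cp$drug_id, drugs$drug_id)
  if (length(unknown)) {
    stop("concept_pairs reference unknown drug_id(s): ",
         paste(unknown, collapse = ", "))
  }

  cm <- as.data.table(concept_map)
  if (!all(c("snomed_id", "icd10_code") %in% names(cm))) {
    stop("concept_map must have columns snomed_id, icd10_code")
  }
  cm <- cm[, .(snomed_id = as.character(snomed_id),
               icd10_code = as.character(icd10_code))]
  cm[, icd10_3 := if (nrow(cm)) truncate_icd10(icd10_code) else character(0)]

  # expand each (drug, snomed, relation) to one pair per mapped target
  mapped <- merge(cp, cm[, .(snomed_id, icd10_3)],
                  by = "snomed_id", allow.cartesian = TRUE)
  dropped <- unique(cp[!snomed_id %in% cm$snomed_id, snomed_id])
  pairs <- unique(mapped[, .(drug_id, icd10_3, relation)])
  setkey(pairs, drug_id, relation, icd10_3)

  qc <- list(
    n_drugs = nrow(drugs),
    n_indication_pairs = nrow(pairs[relation == "indication"]),
    n_contraindication_pairs = nrow(pairs[relation == "contraindication"]),
    n_concepts_dropped = length(dropped),
    dropped_snomed_ids = dropped
  )
  structure(list(drugs = drugs, pairs = pairs, qc = qc), class = "rx_kb")
}

#' @export
print.rx_kb <- function(x, ...) {
  cat("Drug knowledge base (rx_kb)\n")
  cat(sprintf("  drugs: %d\n", nrow(x$drugs)))
  cat(sprintf("  indication pairs: %d\n", x$qc$n_indication_pairs))
  cat(sprintf("  contraindication pairs: %d\n", x$qc$n_contraindication_pairs))
  cat(sprintf("  unmapped concepts dropped: %d\n", x$qc$n_concepts_dropped))
  invisible(x)
}

#' Look up the ICD-10 categories paired with a drug
#'
#' @param kb An \code{rx_kb} knowledge base.
#' @param drug_id Drug identifier present in \code{kb}.
#' @param relation \code{"indication"} or \code{"contraindication"}.
#' @return Sorted character vector of 3-character ICD-10 category codes
#'   (possibly empty).
#' @export
kb_lookup <- function(kb, drug_id, relation = c("indication", "contraindication")) {
  stopifnot(inherits(kb, "rx_kb"))
  relation <- match.arg(relation)
  if (!drug_id %in% kb$drugs$drug_id) {
    stop("unknown drug_id: ", drug_id)
  }
  rel <- relation
  id <- drug_id
  sort(kb$pairs[drug_id == id & relation == rel, icd10_3])
}

# delimiter from extension: .csv -> comma, anything else -> tab
.read_delim <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  fread(path, sep = sep, colClasses = "character", encoding = "UTF-8")
}

#' Read knowledge-base input tables and build the knowledge base
#'
#' Reads the three delimited input files (dialect chosen by extension: .csv
#' comma, otherwise tab; UTF-8, header rows required) and calls
#' \code{\link{build_knowledge_base}}.
#'
#' @param drugs_file File with columns drug_id, ingredient_name, approval_year.
#' @param pairs_file File with columns drug_id, snomed_id, relation.
#' @param map_file File with columns snomed_id, icd10_code.
#' @return An \code{rx_kb} object.
#' @export
read_knowledge_base_inputs <- function(drugs_file, pairs_file, map_file) {
  for (f in c(drugs_file, pairs_file, map_file)) {
    if (!file.exists(f)) stop("input file not found: ", f)
  }
  build_knowledge_base(.read_delim(drugs_file), .read_delim(pairs_file),
                       .read_delim(map_file))
}

#' Write a knowledge base to its canonical on-disk form
#'
#' Writes \code{drugs.csv}, \code{pairs.csv} (one pair per row: drug_id,
#' icd10_3, relation) and \code{qc.json} under \code{dir}.
#'
#' @param kb An \code{rx_kb}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of paths written.
#' @export
write_knowledge_base <- function(kb, dir) {
  stopifnot(inherits(kb, "rx_kb"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("drugs.csv", "pairs.csv", "qc.json"))
  fwrite(kb$drugs, paths[1])
  fwrite(kb$pairs, paths[2])
  jsonlite::write_json(kb$qc, paths[3], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a knowledge base from its canonical on-disk form
#'
#' @param dir Directory produced by \code{\link{write_knowledge_base}}.
#' @return An \code{rx_kb}.
#' @export
read_knowledge_base <- function(dir) {
  drugs <- fread(file.path(dir, "drugs.csv"),
                 colClasses = list(character = c("drug_id", "ingredient_name"),
                                   integer = "approval_year"))
  pairs <- fread(file.path(dir, "pairs.csv"), colClasses = "character")
  bad <- !grepl(ICD10_CAT_RE, pairs$icd10_3)
  if (any(bad)) stop("invalid icd10_3 code(s) in pairs file: ",
                     paste(unique(pairs$icd10_3[bad]), collapse = ", "))
  setkey(pairs, drug_id, relation, icd10_3)
  qc_path <- file.path(dir, "qc.json")
  qc <- if (file.exists(qc_path)) jsonlite::read_json(qc_path, simplifyVector = TRUE) else
    list(n_drugs = nrow(drugs),
         n_indication_pairs = sum(pairs$relation == "indication"),
         n_contraindication_pairs = sum(pairs$relation == "contraindication"),
         n_concepts_dropped = NA_integer_, dropped_snomed_ids = character())
  structure(list(drugs = drugs, pairs = pairs, qc = qc), class = "rx_kb")
}
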