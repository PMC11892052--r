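# Canonical column schemas for the four survey tables. Binary limitation
# outcomes follow MEPS consolidated-file naming; utilisation outcomes are
# counts except total_expenditure (USD).
BINARY_OUTCOMES <- c("ANYLMT", "ACTLIM31", "UNABLE31", "WLKLIM31", "WRKLIM31",
                     "SCHLIM31", "HSELIM31", "SOCLIM31", "COGLIM31")
COUNT_OUTCOMES <- c("ipdis", "ertot", "obtotv")
OUTCOME_VARS <- c(BINARY_OUTCOMES, "total_expenditure", COUNT_OUTCOMES)

PERSON_COLS <- c("person_id", "year", "sex", "age", "education", "race",
                 "medicare", "medicaid", "weight", OUTCOME_VARS)
CONDITION_COLS <- c("condition_id", "person_id", "year", "icd10_3", "is_current")
RX_COLS <- c("rx_id", "person_id", "year", "drug_id", "therapeutic_class", "ndc")
LINK_COLS <- c("rx_id", "condition_id")

SEX_LEVELS <- c("male", "female")
EDUCATION_LEVELS <- c("missing", "0-11 years", "12 years", "13+ years", "18+ years")
RACE_LEVELS <- c("White", "Black", "American Indian-Alaska", "Asian", "Multiple")

.apply_schema <- function(dt, schema) {
  if (is.null(schema) || !length(schema)) return(dt)
  src <- unlist(schema)
  have <- names(schema)[src %in% names(dt)]
  if (length(have)) setnames(dt, unname(src[have]), have)
  dt
}

.require_cols <- function(dt, cols, what) {
  miss <- setdiff(cols, names(dt))
  if (length(miss)) {
    stop("schema error in ", what, " table: missing column(s) ",
         paste(miss, collapse = ", "))
  }
  invisible(dt)
}

#' Assemble and validate a survey dataset
#'
#' Bundles person, condition, prescription and event-condition link tables
#' into a validated \code{rx_survey} object with referential integrity across
#' all four: every condition and prescription references an existing
#' person-year, every link connects an existing prescription to an existing
#' condition of the same person and year.
#'
#' @param persons data.frame with the person-year demographics and outcomes
#'   (columns \code{person_id, year, sex, age, education, race, medicare,
#'   medicaid, weight} plus the binary limitation outcomes, \code{
#'   total_expenditure} and visit counts).
#' @param conditions data.frame: \code{condition_id, person_id, year, icd10_3,
#'   is_current}.
#' @param prescriptions data.frame: \code{rx_id, person_id, year, drug_id,
#'   therapeutic_class, ndc}.
#' @param links data.frame: \code{rx_id, condition_id}.
#' @return An \code{rx_survey} object (list of the four data.tables).
#' @export
as_survey <- function(persons, conditions, prescriptions, links) {
  p <- as.data.table(persons); cnd <- as.data.table(conditions)
  rx <- as.data.table(prescriptions); lnk <- as.data.table(links)
  .require_cols(p, PERSON_COLS, "persons")
  .require_cols(cnd, CONDITION_COLS, "conditions")
  .require_cols(rx, RX_COLS, "prescriptions")
  .require_cols(lnk, LINK_COLS, "links")

  p[, `:=`(person_id = as.character(person_id), year = as.integer(year),
           age = as.integer(age), medicare = as.integer(medicare),
           medicaid = as.integer(medicaid), weight = as.numeric(weight))]
  for (v in BINARY_OUTCOMES) set(p, j = v, value = as.integer(p[[v]]))
  for (v in COUNT_OUTCOMES) set(p, j = v, value = as.integer(p[[v]]))
  p[, total_expenditure := as.numeric(total_expenditure)]
  cnd[, `:=`(condition_id = as.character(condition_id),
             person_id = as.character(person_id), year = as.integer(year),
             icd10_3 = toupper(as.character(icd10_3)),
             is_current = as.integer(is_current))]
  rx[, `:=`(rx_id = as.character(rx_id), person_id = as.character(person_id),
            year = as.integer(year), drug_id = as.character(drug_id),
            therapeutic_class = as.character(therapeutic_class),
            ndc = as.character(ndc))]
  lnk[, `:=`(rx_id = as.character(rx_id),
             condition_id = as.character(condition_id))]

  ds <- structure(list(persons = p, conditions = cnd, prescriptions = rx,
                       links = lnk), class = "rx_survey")
  validate_survey(ds)
  ds
}

#' Validate an rx_survey dataset
#'
#' Checks key uniqueness, value domains and referential integrity; stops with
#' diagnostics naming the offending identifiers on the first failure.
#'
#' @param ds An \code{rx_survey}.
#' @return Invisibly, \code{ds}.
#' @export
validate_survey <- function(ds) {
  stopifnot(inherits(ds, "rx_survey"))
  p <- ds$persons; cnd <- ds$conditions; rx <- ds$prescriptions; lnk <- ds$links

  dup <- duplicated(p[, .(person_id, year)])
  if (any(dup)) stop("duplicate (person_id, year): ",
                     paste(head(p$person_id[dup], 5), collapse = ", "))
  if (any(p$age < 0, na.rm = TRUE)) stop("negative age for person(s): ",
    paste(head(p$person_id[p$age < 0], 5), collapse = ", "))
  if (any(p$weight < 0, na.rm = TRUE)) stop("negative survey weight")
  for (v in BINARY_OUTCOMES) {
    bad <- !p[[v]] %in% c(0L, 1L)
    if (any(bad)) stop("binary outcome ", v, " outside {0,1} for person(s): ",
                       paste(head(p$person_id[bad], 5), collapse = ", "))
  }
  if (any(p$total_expenditure < 0, na.rm = TRUE)) stop("negative total_expenditure")
  if (!all(p$sex %in% SEX_LEVELS)) stop("invalid sex value(s): ",
    paste(setdiff(unique(p$sex), SEX_LEVELS), collapse = ", "))

  if (anyDuplicated(cnd$condition_id)) stop("duplicate condition_id: ",
    paste(head(unique(cnd$condition_id[duplicated(cnd$condition_id)]), 5), collapse = ", "))
  bad_code <- !grepl(ICD10_CAT_RE, cnd$icd10_3)
  if (any(bad_code)) stop("invalid icd10_3 category code(s): ",
    paste(head(unique(cnd$icd10_3[bad_code]), 5), collapse = ", "))

  if (anyDuplicated(rx$rx_id)) stop("duplicate rx_id: ",
    paste(head(unique(rx$rx_id[duplicated(rx$rx_id)]), 5), collapse = ", "))

  pkeys <- p[, paste(person_id, year)]
  orphan_c <- !cnd[, paste(person_id, year)] %in% pkeys
  if (any(orphan_c)) stop("integrity error: condition(s) reference unknown ",
    "person-year: ", paste(head(cnd$condition_id[orphan_c], 5), collapse = ", "))
  orphan_r <- !rx[, paste(person_id, year)] %in% pkeys
  if (any(orphan_r)) stop("integrity error: prescription(s) reference unknown ",
    "person-year: ", paste(head(rx$rx_id[orphan_r], 5), collapse = ", "))

  bad_rx <- !lnk$rx_id %in% rx$rx_id
  if (any(bad_rx)) stop("integrity error: link(s) reference unknown rx_id: ",
    paste(head(unique(lnk$rx_id[bad_rx]), 5), collapse = ", "))
  bad_cnd <- !lnk$condition_id %in% cnd$condition_id
  if (any(bad_cnd)) stop("integrity error: link(s) reference unknown ",
    "condition_id: ", paste(head(unique(lnk$condition_id[bad_cnd]), 5), collapse = ", "))

  # link endpoints must share person and year
  lj <- merge(merge(lnk, rx[, .(rx_id, person_id, year)], by = "rx_id"),
              cnd[, .(condition_id, c_person = person_id, c_year = year)],
              by = "condition_id")
  mism <- lj[person_id != c_person | year != c_year]
  if (nrow(mism)) stop("integrity error: link endpoints differ in person/year ",
    "for rx_id(s): ", paste(head(unique(mism$rx_id), 5), collapse = ", "))
  invisible(ds)
}

#' @export
print.rx_survey <- function(x, ...) {
  cat("Survey dataset (rx_survey)\n")
  cat(sprintf("  persons:       %d person-years\n", nrow(x$persons)))
  cat(sprintf("  conditions:    %d records\n", nrow(x$conditions)))
  cat(sprintf("  prescriptions: %d events\n", nrow(x$prescriptions)))
  cat(sprintf("  links:         %d rx-condition links\n", nrow(x$links)))
  invisible(x)
}

#' Read a survey dataset from delimited files
#'
#' Reads the four tables from delimited text files with header rows (dialect
#' by extension: .csv comma, otherwise tab). Source column names can be mapped
#' to the canonical schema through \code{schema_config}, so real survey
#' exports (e.g. RXRECIDX, ICD10CDX, CONDIDX) are readable without code
#' changes.
#'
#' @param paths Named list/vector with elements \code{persons},
#'   \code{conditions}, \code{prescriptions}, \code{links}.
#' @param schema_config Optional named list with elements per table, each a
#'   named list mapping canonical field name -> source column name.
#' @return A validated \code{rx_survey}.
#' @export
read_survey <- function(paths, schema_config = NULL) {
  need <- c("persons", "conditions", "prescriptions", "links")
  miss <- setdiff(need, names(paths))
  if (length(miss)) stop("paths must name files for: ", paste(miss, collapse = ", "))
  for (f in unlist(paths[need])) if (!file.exists(f)) stop("file not found: ", f)
  tabs <- lapply(need, function(nm) {
    .apply_schema(.read_delim(paths[[nm]]), schema_config[[nm]])
  })
  names(tabs) <- need
  as_survey(tabs$persons, tabs$conditions, tabs$prescriptions, tabs$links)
}

#' Write a survey dataset as delimited files
#'
#' @param ds An \code{rx_survey}.
#' @param dir Output directory; writes \code{persons.csv},
#'   \code{conditions.csv}, \code{prescriptions.csv}, \code{links.csv}.
#' @return Invisibly, a named list of the paths written (usable as the
#'   \code{paths} argument of \code{\link{read_survey}}).
#' @export
write_survey <- function(ds, dir) {
  stopifnot(inherits(ds, "rx_survey"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(persons = file.path(dir, "persons.csv"),
                conditions = file.path(dir, "conditions.csv"),
                prescriptions = file.path(dir, "prescriptions.csv"),
                links = file.path(dir, "links.csv"))
  fwrite(ds$persons, paths$persons)
  fwrite(ds$conditions, paths$conditions)
  fwrite(ds$prescriptions, paths$prescriptions)
  fwrite(ds$links, paths$links)
  invisible(paths)
}

#' Condition categories linked to one prescription
#'
#' @param ds An \code{rx_survey}.
#' @param rx_id Prescription identifier.
#' @return Character vector of distinct 3-character ICD-10 codes of the
#'   conditions linked to the prescription (possibly empty).
#' @export
linked_condition_codes <- function(ds, rx_id) {
  stopifnot(inherits(ds, "rx_survey"))
  id <- as.character(rx_id)
  if (!id %in% ds$prescriptions$rx_id) stop("unknown rx_id: ", id)
  cids <- ds$links[rx_id == id, condition_id]
  sort(unique(ds$conditions[condition_id %in% cids, icd10_3]))
}

#' Condition categories recorded for a person-year
#'
#' @param ds An \code{rx_survey}.
#' @param person_id Person identifier.
#' @param year Survey year.
#' @param current_only If \code{TRUE} (default, mirroring the survey's
#'   "current condition" definition) only conditions with \code{is_current ==
#'   1} are included.
#' @return Character vector of distinct 3-character ICD-10 codes.
#' @export
person_condition_codes <- function(ds, person_id, year, current_only = TRUE) {
  stopifnot(inherits(ds, "rx_survey"))
  pid <- as.character(person_id); yr <- as.integer(year)
  if (!nrow(ds$persons[person_id == pid & year == yr])) {
    stop("unknown person-year: ", pid, "/", yr)
  }
  sub <- ds$conditions[person_id == pid & year == yr]
  if (current_only) sub <- sub[is_current == 1L]
  sort(unique(sub$icd10_3))
}
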