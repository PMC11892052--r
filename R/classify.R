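#' Classify a single prescription against the knowledge base
#'
#' Computes the four per-prescription use indicators by set intersection at
#' the 3-character ICD-10 category level:
#' \itemize{
#'   \item \code{indic_narrow}: a condition explicitly linked to the
#'     prescription event matches an approved indication of the drug;
#'   \item \code{indic_broad}: any condition recorded for the patient in the
#'     survey year matches an approved indication;
#'   \item \code{contraindicated}: any recorded condition is a
#'     contraindication of the drug;
#'   \item \code{indic_not_contra}: broad-indicated and not contraindicated.
#' }
#' A drug absent from the knowledge base yields \code{in_scope = 0} with all
#' indicators zero and the record flagged excluded.
#'
#' @param kb An \code{rx_kb}.
#' @param linked_codes Character vector of ICD-10 categories linked to the
#'   prescription (subset of \code{person_codes}).
#' @param person_codes Character vector of all ICD-10 categories recorded for
#'   the person-year.
#' @param drug_id Drug identifier.
#' @return One-row data.frame: \code{in_scope, indic_narrow, indic_broad,
#'   contraindicated, indic_not_contra}.
#' @export
classify_prescription <- function(kb, linked_codes, person_codes, drug_id) {
  stopifnot(inherits(kb, "rx_kb"))
  if (!drug_id %in% kb$drugs$drug_id) {
    return(data.frame(in_scope = 0L, indic_narrow = 0L, indic_broad = 0L,
                      contraindicated = 0L, indic_not_contra = 0L))
  }
  ind <- kb_lookup(kb, drug_id, "indication")
  con <- kb_lookup(kb, drug_id, "contraindication")
  narrow <- as.integer(length(intersect(linked_codes, ind)) > 0L)
  broad <- as.integer(length(intersect(person_codes, ind)) > 0L)
  contra <- as.integer(length(intersect(person_codes, con)) > 0L)
  data.frame(in_scope = 1L, indic_narrow = narrow, indic_broad = broad,
             contraindicated = contra,
             indic_not_contra = broad * (1L - contra))
}

#' Classify every prescription in a survey dataset
#'
#' Vectorised batch version of \code{\link{classify_prescription}}: joins
#' prescriptions to their linked conditions and to the person-year condition
#' sets, intersects with the knowledge base's indication and contraindication
#' pairs, and returns one classification row per prescription event. A QC
#' report (exclusion counts and indicator prevalences among in-scope
#' prescriptions) is attached as attribute \code{"qc"}.
#'
#' @param kb An \code{rx_kb}.
#' @param ds An \code{rx_survey}.
#' @param current_only Restrict person condition sets to current conditions
#'   (default \code{TRUE}).
#' @param out_of_scope Policy for drugs absent from the knowledge base:
#'   \code{"exclude"} (default; \code{in_scope = 0}, excluded from downstream
#'   denominators) or \code{"offlabel"} (kept in scope with all indicators 0,
#'   i.e. counted as off-label, for sensitivity analysis).
#' @return data.table with columns \code{rx_id, person_id, year, drug_id,
#'   in_scope, indic_narrow, indic_broad, contraindicated, indic_not_contra}.
#' @export
classify_all <- function(kb, ds, current_only = TRUE,
                         out_of_scope = c("exclude", "offlabel")) {
  stopifnot(inherits(kb, "rx_kb"), inherits(ds, "rx_survey"))
  out_of_scope <- match.arg(out_of_scope)
  rx <- ds$prescriptions[, .(rx_id, person_id, year, drug_id)]
  if (nrow(rx) == 0L) {
    out <- data.table(rx_id = character(), person_id = character(),
                      year = integer(), drug_id = character(),
                      in_scope = integer(), indic_narrow = integer(),
                      indic_broad = integer(), contraindicated = integer(),
                      indic_not_contra = integer())
    setattr(out, "qc", list(n_rx = 0L, n_excluded = 0L, prevalence = NULL))
    return(out[])
  }

  ind <- kb$pairs[relation == "indication", .(drug_id, icd10_3)]
  con <- kb$pairs[relation == "contraindication", .(drug_id, icd10_3)]

  cnd <- ds$conditions
  pc <- if (current_only) cnd[is_current == 1L] else cnd
  person_codes <- unique(pc[, .(person_id, year, icd10_3)])

  # narrow: linked condition code matches an indication of the drug
  linked <- merge(ds$links, cnd[, .(condition_id, icd10_3)], by = "condition_id")
  linked <- merge(linked, rx[, .(rx_id, drug_id)], by = "rx_id")
  narrow_hit <- unique(merge(linked, ind, by = c("drug_id", "icd10_3"))$rx_id)

  # broad / contraindicated: any person-year condition matches
  rx_ind <- merge(rx, ind, by = "drug_id", allow.cartesian = TRUE)
  broad_hit <- unique(merge(rx_ind, person_codes,
                            by = c("person_id", "year", "icd10_3"))$rx_id)
  rx_con <- merge(rx, con, by = "drug_id", allow.cartesian = TRUE)
  contra_hit <- unique(merge(rx_con, person_codes,
                             by = c("person_id", "year", "icd10_3"))$rx_id)

  out <- copy(rx)
  out[, in_scope := as.integer(drug_id %in% kb$drugs$drug_id)]
  out[, indic_narrow := as.integer(rx_id %in% narrow_hit & in_scope == 1L)]
  out[, indic_broad := as.integer(rx_id %in% broad_hit & in_scope == 1L)]
  out[, contraindicated := as.integer(rx_id %in% contra_hit & in_scope == 1L)]
  out[, indic_not_contra := indic_broad * (1L - contraindicated)]
  n_excluded <- sum(out$in_scope == 0L)
  if (out_of_scope == "offlabel") out[, in_scope := 1L]

  insc <- out[in_scope == 1L]
  qc <- list(
    n_rx = nrow(out), n_excluded = n_excluded,
    out_of_scope_policy = out_of_scope,
    prevalence = if (nrow(insc)) as.list(insc[, .(
      indic_narrow = mean(indic_narrow), indic_broad = mean(indic_broad),
      contraindicated = mean(contraindicated),
      indic_not_contra = mean(indic_not_contra))]) else NULL
  )
  setattr(out, "qc", qc)
  out[]
}

#' Person-level exposure fractions
#'
#' Aggregates prescription classifications to one row per person-year:
#' the fraction of the person's in-scope prescriptions that were
#' broad-indicated (\code{frac_indicated}, with \code{frac_offlabel = 1 -
#' frac_indicated}) or contraindicated (\code{frac_contraindicated}), the
#' in-scope prescription count, and the mean FDA approval year of the
#' prescribed drugs (one term per prescription event, so repeated fills
#' count repeatedly). Person-years without in-scope prescriptions are
#' omitted.
#'
#' @param classifications Output of \code{\link{classify_all}}.
#' @param ds The \code{rx_survey} the classifications came from.
#' @param kb The \code{rx_kb} supplying FDA approval years.
#' @return data.table with columns \code{person_id, year, n_rx,
#'   frac_indicated, frac_offlabel, frac_contraindicated,
#'   mean_approval_year}.
#' @export
person_exposures <- function(classifications, ds, kb) {
  stopifnot(inherits(ds, "rx_survey"), inherits(kb, "rx_kb"))
  cls <- as.data.table(classifications)[in_scope == 1L]
  cls <- merge(cls, kb$drugs[, .(drug_id, approval_year)],
               by = "drug_id", all.x = TRUE)
  out <- cls[, .(
    n_rx = .N,
    frac_indicated = mean(indic_broad),
    frac_contraindicated = mean(contraindicated),
    mean_approval_year = mean(approval_year, na.rm = TRUE)
  ), by = .(person_id, year)]
  out[, frac_offlabel := 1 - frac_indicated]
  setcolorder(out, c("person_id", "year", "n_rx", "frac_indicated",
                     "frac_offlabel", "frac_contraindicated",
                     "mean_approval_year"))
  setkey(out, person_id, year)
  out[]
}
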