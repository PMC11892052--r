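INDICATOR_COLS <- c("indic_narrow", "indic_broad", "contraindicated",
                    "indic_not_contra")
PCT_COLS <- paste0("pct_", INDICATOR_COLS)

# default stratification bins mirroring common survey reporting
AGE_BREAKS <- c(-Inf, 17, 44, 64, 84, Inf)
AGE_LABELS <- c("0-17", "18-44", "45-64", "65-84", "85 or older")
APPROVAL_BREAKS <- c(-Inf, 1978, 1991, 1997, Inf)
APPROVAL_LABELS <- c("1941-1978", "1979-1991", "1992-1997", "1998-2018")

.rx_attributes <- function(classifications, ds, kb = NULL) {
  cls <- as.data.table(classifications)[in_scope == 1L]
  cls <- merge(cls, ds$prescriptions[, .(rx_id, therapeutic_class)],
               by = "rx_id", all.x = TRUE)
  cls <- merge(cls,
               ds$persons[, .(person_id, year, sex, age, education, race,
                              medicare, medicaid)],
               by = c("person_id", "year"), all.x = TRUE)
  cls[, age_group := as.character(cut(age, AGE_BREAKS, AGE_LABELS))]
  cls[, year := as.character(year)]
  cls[, medicare := ifelse(medicare == 1L, "Medicare", "No Medicare")]
  cls[, medicaid := ifelse(medicaid == 1L, "Medicaid", "No Medicaid")]
  if (!is.null(kb)) {
    cls <- merge(cls, kb$drugs[, .(drug_id, approval_year)],
                 by = "drug_id", all.x = TRUE)
    cls[, approval_year_group := as.character(
      cut(approval_year, APPROVAL_BREAKS, APPROVAL_LABELS))]
  }
  cls
}

.prevalence_rows <- function(dt, variable, by_col) {
  rows <- dt[, c(list(n_rx = .N),
                 setNames(lapply(.SD, function(x) 100 * mean(x)), PCT_COLS)),
             by = by_col, .SDcols = INDICATOR_COLS]
  setnames(rows, by_col, "category")
  rows[, grouping_variable := variable]
  setcolorder(rows, c("grouping_variable", "category", "n_rx", PCT_COLS))
  rows
}

#' Prescription-level prevalence table by demographic strata
#'
#' For each grouping variable, computes the percentage of in-scope
#' prescriptions that were narrow-indicated, broad-indicated, contraindicated
#' and indicated-but-not-contraindicated, plus an overall row. Percentages are
#' 100 times the indicator mean among the group's in-scope prescriptions;
#' internal computation is at full precision.
#'
#' @param classifications Output of \code{\link{classify_all}}.
#' @param ds The \code{rx_survey}.
#' @param groupers Character vector of grouping variables among \code{sex,
#'   education, age_group, race, year, medicare, medicaid,
#'   approval_year_group, therapeutic_class}.
#' @param kb Required (an \code{rx_kb}) when \code{"approval_year_group"} is
#'   among \code{groupers}.
#' @return data.table of prevalence rows: \code{grouping_variable, category,
#'   n_rx, pct_indic_narrow, pct_indic_broad, pct_contraindicated,
#'   pct_indic_not_contra}; first row is the overall ("all") row.
#' @export
prevalence_table <- function(classifications, ds,
                             groupers = c("sex", "education", "age_group",
                                          "race", "year"),
                             kb = NULL) {
  stopifnot(inherits(ds, "rx_survey"))
  known <- c("sex", "education", "age_group", "race", "year", "medicare",
             "medicaid", "approval_year_group", "therapeutic_class")
  bad <- setdiff(groupers, known)
  if (length(bad)) stop("unknown grouper(s): ", paste(bad, collapse = ", "),
                        "; available: ", paste(known, collapse = ", "))
  if ("approval_year_group" %in% groupers && is.null(kb)) {
    stop("grouper 'approval_year_group' requires the knowledge base `kb`")
  }
  dt <- .rx_attributes(classifications, ds, kb)
  overall <- .prevalence_rows(copy(dt)[, all_ := "all"], "all", "all_")
  rows <- lapply(groupers, function(g) .prevalence_rows(dt, g, g))
  rbindlist(c(list(overall), rows))
}

#' Prevalence rates by therapeutic class
#'
#' One prevalence row per therapeutic class, ordered by descending
#' prescription count. Empty or missing class labels are grouped under
#' \code{"unclassified"}.
#'
#' @inheritParams prevalence_table
#' @return data.table of prevalence rows keyed by class.
#' @export
therapeutic_class_rates <- function(classifications, ds) {
  dt <- .rx_attributes(classifications, ds)
  dt[is.na(therapeutic_class) | therapeutic_class == "",
     therapeutic_class := "unclassified"]
  rows <- .prevalence_rows(dt, "therapeutic_class", "therapeutic_class")
  setorder(rows, -n_rx)
  rows[]
}

#' Pool prevalence rows into one combined row
#'
#' Recombines category rows of a partitioning variable into the pooled row by
#' prescription-count weighting: pooled percentage = sum(n_i * pct_i) /
#' sum(n_i). With the rows of a complete partition this reproduces the
#' overall row exactly (before rounding).
#'
#' @param rows data.table/data.frame of prevalence rows (needs \code{n_rx}
#'   and the four percentage columns).
#' @return One-row data.table with the pooled counts and percentages.
#' @export
combine_prevalence_rows <- function(rows) {
  rows <- as.data.table(rows)
  n <- sum(rows$n_rx)
  out <- data.table(grouping_variable = "combined", category = "combined",
                    n_rx = n)
  for (p in intersect(PCT_COLS, names(rows))) {
    set(out, j = p, value = sum(rows$n_rx * rows[[p]]) / n)
  }
  out[]
}

#' Overall contraindication rate from conditional rates
#'
#' Law-of-total-probability mixture: combines the contraindication rates among
#' indicated and off-label prescriptions with the indicated share to give the
#' overall contraindicated percentage.
#'
#' @param pct_indicated Percentage of prescriptions that were broad-indicated.
#' @param pct_contra_given_indicated Contraindication percentage among
#'   indicated prescriptions.
#' @param pct_contra_given_offlabel Contraindication percentage among
#'   off-label prescriptions.
#' @return Overall contraindicated percentage.
#' @export
contra_mixture <- function(pct_indicated, pct_contra_given_indicated,
                           pct_contra_given_offlabel) {
  w <- pct_indicated / 100
  w * pct_contra_given_indicated + (1 - w) * pct_contra_given_offlabel
}

#' Compare outcomes between below- and above-median exposure groups
#'
#' Splits analysis persons at the median of an exposure fraction (ties go to
#' the low group: low = value <= median, high = value > median) and compares
#' each outcome between groups with a Welch unequal-variance two-sample
#' t-test. Total expenditure is compared on the log scale
#' (\code{log(total_expenditure + 1)}), reported as
#' \code{log_total_expenditure}.
#'
#' @param exposures Output of \code{\link{person_exposures}}.
#' @param persons Person table (e.g. \code{ds$persons}) carrying the outcome
#'   columns.
#' @param split_var \code{"frac_indicated"} or \code{"frac_contraindicated"}.
#' @param outcome_vars Outcomes to compare; defaults to the utilisation and
#'   limitation set.
#' @return data.table: \code{variable, mean_low, mean_high, difference
#'   (mean_low - mean_high), p_value}.
#' @export
median_split_compare <- function(exposures, persons,
                                 split_var = c("frac_indicated",
                                               "frac_contraindicated"),
                                 outcome_vars = c("total_expenditure",
                                                  COUNT_OUTCOMES,
                                                  BINARY_OUTCOMES)) {
  split_var <- match.arg(split_var)
  ex <- as.data.table(exposures)
  p <- as.data.table(persons)
  dt <- merge(ex, p, by = c("person_id", "year"))
  med <- median(dt[[split_var]])
  if (med >= max(dt[[split_var]])) {
    warning("degenerate median split: median equals the maximum of ",
            split_var)
  }
  grp_high <- dt[[split_var]] > med
  if (sum(grp_high) < 2L || sum(!grp_high) < 2L) {
    stop("need at least 2 persons per median-split group")
  }
  rows <- lapply(outcome_vars, function(v) {
    x <- if (v == "total_expenditure") log1p(dt[[v]]) else as.numeric(dt[[v]])
    lo <- x[!grp_high]; hi <- x[grp_high]
    pval <- if (sd(lo) == 0 && sd(hi) == 0 && mean(lo) == mean(hi)) 1
            else t.test(lo, hi)$p.value
    data.table(variable = if (v == "total_expenditure")
                 "log_total_expenditure" else v,
               mean_low = mean(lo), mean_high = mean(hi),
               difference = mean(lo) - mean(hi), p_value = pval)
  })
  rbindlist(rows)
}
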