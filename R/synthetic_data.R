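SURVEY_YEARS <- 2016:2021

default_outcome_model <- function() {
  binary <- list(
    ANYLMT   = list(intercept = 0.30),
    ACTLIM31 = list(intercept = 0.15),
    UNABLE31 = list(intercept = 0.10),
    WLKLIM31 = list(intercept = 0.20),
    WRKLIM31 = list(intercept = 0.14),
    SCHLIM31 = list(intercept = 0.06),
    HSELIM31 = list(intercept = 0.10),
    SOCLIM31 = list(intercept = 0.09),
    COGLIM31 = list(intercept = 0.08)
  )
  binary <- lapply(binary, function(b) {
    b$beta_contra <- 0.04; b$beta_indic <- -0.03; b
  })
  list(
    binary = binary,
    condition_effect_scale = 0.02,
    link = "linear",
    expenditure = list(intercept = 7.6, beta_contra = 0.6, beta_indic = -0.3,
                       condition_multiplier = 5, sigma = 1.2),
    counts = list(
      ipdis  = list(base = 0.12, gamma_contra = 0.5, gamma_indic = -0.3),
      ertot  = list(base = 0.30, gamma_contra = 0.5, gamma_indic = -0.3),
      obtotv = list(base = 8.00, gamma_contra = 0.4, gamma_indic = -0.2)
    ),
    count_condition_multiplier = 2
  )
}

#' Configure the synthetic microdata generator
#'
#' Describes a synthetic study population: a drug universe with per-drug
#' indication and contraindication ICD-10 category sets and FDA approval
#' years; persons with demographics and Poisson-distributed condition sets;
#' prescriptions drawn indicated for one of the person's conditions with
#' probability \code{p_indicated_prescribing} and otherwise uniformly from
#' drugs not indicated for any of the person's conditions (so broad
#' indication status is known by construction and contraindication status
#' emerges organically from the person's conditions); and outcomes generated
#' from the person's true exposure fractions with stated coefficients.
#'
#' @param seed Integer seed; all generation is reproducible from it.
#' @param n_persons Number of person-years.
#' @param n_drugs Drug universe size.
#' @param n_condition_codes Size of the ICD-10 category universe.
#' @param mean_conditions_per_person Poisson rate of distinct conditions.
#' @param mean_rx_per_person Zero-truncated Poisson rate of prescriptions.
#' @param indication_density,contraindication_density Per-drug Poisson rates
#'   of paired indication / contraindication categories.
#' @param p_indicated_prescribing Probability a prescription is drawn
#'   indicated for one of the person's conditions.
#' @param p_indicated_sd Between-person standard deviation of the indicated
#'   prescribing probability (0 = identical for everyone; positive values
#'   draw each person's probability from a Beta distribution with mean
#'   \code{p_indicated_prescribing}, modelling patient/provider prescribing
#'   styles that vary independently of the condition profile).
#' @param p_narrow_link For indicated prescriptions, probability the recorded
#'   event-condition link points at the matching indication (otherwise a
#'   uniformly chosen condition of the person).
#' @param p_zero_rx Fraction of persons with no prescriptions (retained in
#'   the person table, excluded from analysis downstream).
#' @param approval_year_range Integer range FDA approval years are drawn from.
#' @param outcome_model Coefficient list (see \code{default_outcome_model}):
#'   per-binary-outcome intercept, beta_contra and beta_indic on the
#'   linear-probability scale (clipped to [0.01, 0.99]; set
#'   \code{outcome_model$link = "logit"} for a logistic link), a zero-mean
#'   normal per-condition effect scale creating confounding, log-normal
#'   expenditure and Poisson visit-count models.
#' @return An \code{rx_generator_config}.
#' @export
generator_config <- function(seed = 1L, n_persons = 2000L, n_drugs = 60L,
                             n_condition_codes = 120L,
                             mean_conditions_per_person = 6,
                             mean_rx_per_person = 5,
                             indication_density = 3.5,
                             contraindication_density = 16,
                             p_indicated_prescribing = 0.75,
                             p_indicated_sd = 0,
                             p_narrow_link = 0.67,
                             p_zero_rx = 0.15,
                             approval_year_range = c(1950L, 2018L),
                             outcome_model = default_outcome_model()) {
  probs <- c(p_indicated_prescribing, p_narrow_link, p_zero_rx)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (p_indicated_sd < 0) stop("p_indicated_sd must be non-negative")
  if (p_indicated_sd > 0) {
    maxsd <- sqrt(p_indicated_prescribing * (1 - p_indicated_prescribing))
    if (p_indicated_sd >= maxsd) {
      stop("infeasible config: p_indicated_sd must be below ",
           "sqrt(p(1-p)) = ", round(maxsd, 4))
    }
  }
  rates <- c(mean_conditions_per_person, mean_rx_per_person,
             indication_density, contraindication_density)
  if (any(rates <= 0)) stop("rates must be positive")
  if (n_persons < 1L || n_drugs < 1L || n_condition_codes < 3L) {
    stop("population sizes too small")
  }
  structure(list(seed = as.integer(seed), n_persons = as.integer(n_persons),
                 n_drugs = as.integer(n_drugs),
                 n_condition_codes = as.integer(n_condition_codes),
                 mean_conditions_per_person = mean_conditions_per_person,
                 mean_rx_per_person = mean_rx_per_person,
                 indication_density = indication_density,
                 contraindication_density = contraindication_density,
                 p_indicated_prescribing = p_indicated_prescribing,
                 p_indicated_sd = p_indicated_sd,
                 p_narrow_link = p_narrow_link, p_zero_rx = p_zero_rx,
                 approval_year_range = as.integer(approval_year_range),
                 outcome_model = outcome_model),
            class = "rx_generator_config")
}

#' Generator preset calibrated to published headline prevalence rates
#'
#' A shipped configuration whose emitted data yield, at the prescription
#' level, roughly 75\% broad-indicated (25\% off-label), 54\% contraindicated
#' and 33\% indicated-but-not-contraindicated use, the headline rates
#' reported for US outpatient prescriptions 2016-2021. The densities were
#' derived from the hit-probability identity 1 - (1 - k/C)^m for a person
#' with m conditions facing a drug with k paired categories out of C.
#'
#' @param n_persons Population size (default 5000; the calibration statement
#'   holds to within about 3 percentage points at this size and above).
#' @param seed Seed.
#' @return An \code{rx_generator_config}.
#' @export
preset_paperlike <- function(n_persons = 5000L, seed = 1L) {
  generator_config(seed = seed, n_persons = n_persons, n_drugs = 60L,
                   n_condition_codes = 120L,
                   mean_conditions_per_person = 6,
                   mean_rx_per_person = 5,
                   indication_density = 3.5,
                   contraindication_density = 16,
                   p_indicated_prescribing = 0.75,
                   p_narrow_link = 0.67)
}

#' Generator preset for parameter-recovery simulation studies
#'
#' A configuration designed for validating the estimators rather than for
#' emulating published prevalence rates: few prescriptions per person (so
#' the person-level exposure fractions retain enough variance for precise
#' coefficient estimates), no zero-prescription persons, and a smaller
#' condition universe (so the condition-dummy control block stays modest).
#' Power analysis for the harness: with about 1.6 prescriptions per person
#' the per-person sampling variance of an exposure fraction is roughly
#' p(1-p) * E[1/n_rx], giving coefficient standard errors near 0.015 at
#' n = 5000, so effects of magnitude 0.03-0.04 are detected with the
#' correct sign in well over 95 percent of replicates.
#'
#' @param n_persons Population size (default 5000).
#' @param seed Seed.
#' @param beta_contra,beta_indic True coefficients placed on every binary
#'   outcome (defaults +0.04 / -0.03).
#' @return An \code{rx_generator_config}.
#' @export
preset_recovery <- function(n_persons = 5000L, seed = 1L,
                            beta_contra = 0.04, beta_indic = -0.03) {
  om <- default_outcome_model()
  om$binary <- lapply(om$binary, function(b) {
    b$beta_contra <- beta_contra; b$beta_indic <- beta_indic; b
  })
  generator_config(seed = seed, n_persons = n_persons, n_drugs = 40L,
                   n_condition_codes = 60L,
                   mean_conditions_per_person = 4,
                   mean_rx_per_person = 1.5,
                   indication_density = 3,
                   contraindication_density = 8,
                   p_indicated_prescribing = 0.6,
                   p_indicated_sd = 0.25,
                   p_narrow_link = 0.67, p_zero_rx = 0,
                   outcome_model = om)
}

# deterministic ICD-10 category universe: letters x 2-digit numbers
.code_universe <- function(n) {
  grid <- as.vector(outer(LETTERS[1:20], sprintf("%02d", 0:99),
                          function(a, b) paste0(a, b)))
  if (n > length(grid)) stop("condition universe larger than code grid")
  grid[seq(1L, length(grid), length.out = n)]
}

#' Generate a synthetic knowledge base and survey dataset with ground truth
#'
#' Draws the full study population described by the configuration and routes
#' the drug-condition layer through \code{\link{build_knowledge_base}} (via a
#' generated SNOMED-style concept layer and one-to-many concept map, so the
#' emitted files exercise the same ingestion path as real inputs). Returns
#' the knowledge base, the validated survey dataset, and a ground-truth
#' record of every prescription's true indicators, every person's true
#' exposure fractions, and the outcome coefficients used.
#'
#' @param config An \code{rx_generator_config}.
#' @param out_dir Optional directory; when given, writes the knowledge-base
#'   input files (drugs/concept pairs/concept map), the canonical knowledge
#'   base, the four survey tables, and ground-truth sidecar files
#'   (\code{truth_prescriptions.csv}, \code{truth_exposures.csv},
#'   \code{truth_meta.json}).
#' @return List with elements \code{kb}, \code{survey}, \code{truth}
#'   (prescriptions, exposures, coefficients, qc), \code{config} and, when
#'   \code{out_dir} is given, \code{paths}.
#' @export
generate_data <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "rx_generator_config"))
  set.seed(config$seed)
  om <- config$outcome_model

  ## drug universe and paired condition categories
  codes <- .code_universe(config$n_condition_codes)
  n_codes <- length(codes)
  drug_id <- sprintf("D%04d", seq_len(config$n_drugs))
  drugs <- data.table(
    drug_id = drug_id,
    ingredient_name = paste0("ingredient_", seq_len(config$n_drugs)),
    approval_year = sample(seq(config$approval_year_range[1],
                               config$approval_year_range[2]),
                           config$n_drugs, replace = TRUE)
  )
  draw_sets <- function(rate) {
    k <- pmin(rpois(config$n_drugs, rate), n_codes)
    lapply(k, function(ki) if (ki == 0L) character(0) else sample(codes, ki))
  }
  ind_sets <- draw_sets(config$indication_density)
  con_sets <- draw_sets(config$contraindication_density)
  if (config$p_indicated_prescribing > 0 && all(lengths(ind_sets) == 0L)) {
    stop("infeasible config: indicated prescribing requested but no drug ",
         "has any indication")
  }

  ## SNOMED-style concept layer: one concept per category; each maps to one
  ## or two full-precision codes in the category (one-to-many map)
  concept_map <- rbindlist(lapply(codes, function(cd) {
    targets <- if (runif(1) < 0.5) paste0(cd, ".9") else c(paste0(cd, ".9"),
                                                           paste0(cd, ".0"))
    data.table(snomed_id = paste0("SCT", cd), icd10_code = targets)
  }))
  concept_pairs <- rbindlist(list(
    data.table(drug_id = rep(drug_id, lengths(ind_sets)),
               snomed_id = paste0("SCT", unlist(ind_sets)),
               relation = "indication"),
    data.table(drug_id = rep(drug_id, lengths(con_sets)),
               snomed_id = paste0("SCT", unlist(con_sets)),
               relation = "contraindication")
  ))
  kb <- build_knowledge_base(drugs, concept_pairs, concept_map)

  ## persons
  np <- config$n_persons
  person_id <- sprintf("P%06d", seq_len(np))
  age <- sample(18:85, np, replace = TRUE)
  persons <- data.table(
    person_id = person_id,
    year = sample(SURVEY_YEARS, np, replace = TRUE),
    sex = sample(SEX_LEVELS, np, replace = TRUE, prob = c(0.45, 0.55)),
    age = age,
    education = sample(EDUCATION_LEVELS, np, replace = TRUE,
                       prob = c(0.01, 0.20, 0.31, 0.07, 0.41)),
    race = sample(RACE_LEVELS, np, replace = TRUE,
                  prob = c(0.76, 0.16, 0.01, 0.03, 0.04)),
    medicare = rbinom(np, 1L, ifelse(age >= 65, 0.95, 0.02)),
    medicaid = rbinom(np, 1L, 0.17),
    weight = round(exp(rnorm(np, 8.5, 0.7)), 2)
  )

  ## conditions: distinct categories per person
  n_cond <- pmin(rpois(np, config$mean_conditions_per_person), n_codes)
  cond_person <- rep(seq_len(np), n_cond)
  cond_code <- unlist(lapply(n_cond, function(k)
    if (k == 0L) character(0) else sample(codes, k)), use.names = FALSE)
  conditions <- data.table(
    condition_id = sprintf("C%07d", seq_along(cond_person)),
    person_id = person_id[cond_person],
    year = persons$year[cond_person],
    icd10_3 = cond_code,
    is_current = 1L
  )
  .by_person <- function(x, idx) {
    s <- split(x, idx)
    out <- vector("list", np)
    out[as.integer(names(s))] <- s
    out
  }
  person_codes <- .by_person(cond_code, cond_person)
  cond_ids <- .by_person(conditions$condition_id, cond_person)

  ## candidate indicated drugs per person, with the matching categories
  ind_dt <- data.table(drug_id = rep(drug_id, lengths(ind_sets)),
                       icd10_3 = unlist(ind_sets))
  con_dt <- data.table(drug_id = rep(drug_id, lengths(con_sets)),
                       icd10_3 = unlist(con_sets))
  cond_dt <- data.table(pidx = cond_person, icd10_3 = cond_code)
  cand <- merge(cond_dt, ind_dt, by = "icd10_3", allow.cartesian = TRUE)
  cand_drugs <- .by_person(cand$drug_id, cand$pidx)   # with repeats per code
  cand_codes <- .by_person(cand$icd10_3, cand$pidx)
  contra_hits <- unique(merge(cond_dt, con_dt, by = "icd10_3",
                              allow.cartesian = TRUE)[, .(pidx, drug_id)])
  contra_keys <- paste(contra_hits$pidx, contra_hits$drug_id)

  ## prescriptions
  lam <- config$mean_rx_per_person
  n_rx <- qpois(runif(np, dpois(0, lam), 1), lam)
  n_rx[runif(np) < config$p_zero_rx] <- 0L
  total <- sum(n_rx)
  rx_person <- rep(seq_len(np), n_rx)
  p_ind <- rep(config$p_indicated_prescribing, np)
  if (config$p_indicated_sd > 0) {
    mu <- config$p_indicated_prescribing
    nu <- mu * (1 - mu) / config$p_indicated_sd^2 - 1
    p_ind <- rbeta(np, mu * nu, (1 - mu) * nu)
  }
  rx_drug <- character(total); rx_link <- rep(NA_character_, total)
  rx_linked_code <- rep(NA_character_, total)
  true_broad <- integer(total)
  n_fallback <- 0L
  pos <- 0L
  for (p in which(n_rx > 0L)) {
    k <- n_rx[p]
    pcodes <- person_codes[[p]]
    pcids <- cond_ids[[p]]
    cdr <- cand_drugs[[p]]
    ccode <- cand_codes[[p]]
    ucdr <- unique(cdr)
    offpool <- setdiff(drug_id, ucdr)
    want_ind <- runif(k) < p_ind[p]
    for (j in seq_len(k)) {
      i <- pos + j
      if (want_ind[j] && length(ucdr)) {
        d <- ucdr[sample.int(length(ucdr), 1L)]
        true_broad[i] <- 1L
        # matching categories of this drug among the person's conditions
        match_codes <- unique(ccode[cdr == d])
        lc <- if (runif(1) < config$p_narrow_link) {
          match_codes[sample.int(length(match_codes), 1L)]
        } else pcodes[sample.int(length(pcodes), 1L)]
        rx_drug[i] <- d
        rx_linked_code[i] <- lc
        rx_link[i] <- pcids[match(lc, pcodes)]
      } else {
        if (want_ind[j]) n_fallback <- n_fallback + 1L
        d <- if (length(offpool)) offpool[sample.int(length(offpool), 1L)] else
          drug_id[sample.int(length(drug_id), 1L)]
        rx_drug[i] <- d
        if (length(pcodes)) {
          lidx <- sample.int(length(pcodes), 1L)
          rx_linked_code[i] <- pcodes[lidx]
          rx_link[i] <- pcids[lidx]
        }
      }
    }
    pos <- pos + k
  }

  rx_id <- sprintf("RX%07d", seq_len(total))
  tc_labels <- c("cardiovascular agents", "central nervous system agents",
                 "metabolic agents", "gastrointestinal agents",
                 "anti-infectives", "respiratory agents", "topical agents",
                 "psychotherapeutic agents", "hormones",
                 "genitourinary tract agents")
  drug_class <- setNames(sample(tc_labels, config$n_drugs, replace = TRUE),
                         drug_id)
  prescriptions <- data.table(
    rx_id = rx_id,
    person_id = person_id[rx_person],
    year = persons$year[rx_person],
    drug_id = rx_drug,
    therapeutic_class = drug_class[rx_drug],
    ndc = sprintf("%011d", match(rx_drug, drug_id))
  )
  links <- data.table(rx_id = rx_id, condition_id = rx_link)[!is.na(condition_id)]

  ## construction-side truth (set membership on the drawn sets)
  ind_keys <- paste(ind_dt$drug_id, ind_dt$icd10_3)
  true_narrow <- as.integer(!is.na(rx_linked_code) &
                              paste(rx_drug, rx_linked_code) %in% ind_keys)
  true_contra <- as.integer(paste(rx_person, rx_drug) %in% contra_keys)
  truth_rx <- data.table(
    rx_id = rx_id, person_id = person_id[rx_person],
    year = persons$year[rx_person], drug_id = rx_drug, in_scope = 1L,
    indic_narrow = true_narrow, indic_broad = true_broad,
    contraindicated = true_contra,
    indic_not_contra = true_broad * (1L - true_contra)
  )
  truth_exp <- truth_rx[, .(
    n_rx = .N, frac_indicated = mean(indic_broad),
    frac_contraindicated = mean(contraindicated),
    mean_approval_year = mean(drugs$approval_year[match(drug_id,
                                                        drugs$drug_id)])
  ), by = .(person_id, year)]
  truth_exp[, frac_offlabel := 1 - frac_indicated]

  ## outcomes from true exposure fractions + condition-level confounding
  cond_eff <- setNames(rnorm(n_codes, 0, om$condition_effect_scale), codes)
  condsum <- numeric(np)
  if (length(cond_person)) {
    cs <- rowsum(cond_eff[cond_code], cond_person)
    condsum[as.integer(rownames(cs))] <- cs[, 1]
  }
  fc <- fi <- numeric(np)
  idx <- match(person_id, truth_exp$person_id)
  has <- !is.na(idx)
  fc[has] <- truth_exp$frac_contraindicated[idx[has]]
  fi[has] <- truth_exp$frac_indicated[idx[has]]

  link <- if (is.null(om$link)) "linear" else om$link
  for (nm in names(om$binary)) {
    b <- om$binary[[nm]]
    lin <- b$intercept + b$beta_contra * fc + b$beta_indic * fi + condsum
    pr <- if (link == "logit") {
      plogis(qlogis(b$intercept) +
               (b$beta_contra * fc + b$beta_indic * fi + condsum) /
               (b$intercept * (1 - b$intercept)))
    } else pmin(pmax(lin, 0.01), 0.99)
    set(persons, j = nm, value = rbinom(np, 1L, pr))
  }
  ex <- om$expenditure
  ltot <- ex$intercept + ex$beta_contra * fc + ex$beta_indic * fi +
    ex$condition_multiplier * condsum + rnorm(np, 0, ex$sigma)
  persons[, total_expenditure := round(expm1(pmax(ltot, 0)), 2)]
  for (nm in names(om$counts)) {
    cm <- om$counts[[nm]]
    mu <- exp(log(cm$base) + cm$gamma_contra * fc + cm$gamma_indic * fi +
                om$count_condition_multiplier * condsum)
    set(persons, j = nm, value = rpois(np, mu))
  }

  survey <- as_survey(persons, conditions, prescriptions, links)
  truth <- list(prescriptions = truth_rx, exposures = truth_exp,
                coefficients = om,
                qc = list(n_rx = total, n_fallback_offlabel = n_fallback,
                          prevalence = as.list(truth_rx[, .(
                            indic_narrow = mean(indic_narrow),
                            indic_broad = mean(indic_broad),
                            contraindicated = mean(contraindicated),
                            indic_not_contra = mean(indic_not_contra))])))

  out <- list(kb = kb, survey = survey, truth = truth, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    kb_in <- file.path(out_dir, c("drugs.csv", "concept_pairs.csv",
                                  "concept_map.csv"))
    fwrite(drugs, kb_in[1]); fwrite(concept_pairs, kb_in[2])
    fwrite(concept_map, kb_in[3])
    write_knowledge_base(kb, file.path(out_dir, "kb"))
    survey_paths <- write_survey(survey, out_dir)
    fwrite(truth_rx, file.path(out_dir, "truth_prescriptions.csv"))
    fwrite(truth_exp, file.path(out_dir, "truth_exposures.csv"))
    jsonlite::write_json(list(coefficients = om, qc = truth$qc,
                              config = unclass(config)),
                         file.path(out_dir, "truth_meta.json"),
                         auto_unbox = TRUE, digits = NA)
    out$paths <- c(list(kb_inputs = kb_in, kb = file.path(out_dir, "kb")),
                   survey_paths)
  }
  out
}
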