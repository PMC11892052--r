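# Shared fixtures and brute-force oracles. Oracles are written as plain
# nested loops / set comprehensions, independent of the package's join-based
# implementations.

tiny_drugs <- function(n = 3) {
  data.frame(drug_id = paste0("D", seq_len(n)),
             ingredient_name = paste0(" Ingredient_", seq_len(n), " "),
             approval_year = 1990 + seq_len(n))
}

# random knowledge-base raw input for oracle-equivalence tests
random_kb_input <- function(n_drugs = 50, n_pairs = 200, n_concepts = 40,
                            seed = 1) {
  set.seed(seed)
  drugs <- data.frame(drug_id = sprintf("D%03d", seq_len(n_drugs)),
                      ingredient_name = paste0("ing", seq_len(n_drugs)),
                      approval_year = sample(1950:2020, n_drugs, TRUE))
  concepts <- sprintf("SCT%04d", seq_len(n_concepts))
  # most concepts map to 1-3 full codes; a few are unmappable
  mapped <- concepts[seq_len(round(0.85 * n_concepts))]
  map <- do.call(rbind, lapply(mapped, function(sc) {
    k <- sample(1:3, 1)
    cat3 <- paste0(sample(LETTERS[1:8], k, TRUE),
                   sprintf("%02d", sample(0:99, k, TRUE)))
    data.frame(snomed_id = sc,
               icd10_code = ifelse(runif(k) < 0.5, cat3, paste0(cat3, ".9")))
  }))
  pairs <- data.frame(
    drug_id = sample(drugs$drug_id, n_pairs, TRUE),
    snomed_id = sample(concepts, n_pairs, TRUE),
    relation = sample(c("indication", "contraindication"), n_pairs, TRUE))
  list(drugs = drugs, pairs = pairs, map = map)
}

# brute-force set-comprehension oracle for build_knowledge_base
oracle_kb_pairs <- function(pairs, map) {
  seen <- character(0)
  for (i in seq_len(nrow(pairs))) {
    targets <- map$icd10_code[map$snomed_id == pairs$snomed_id[i]]
    for (tg in targets) {
      key <- paste(pairs$drug_id[i], toupper(substr(tg, 1, 3)),
                   pairs$relation[i], sep = "|")
      if (!key %in% seen) seen <- c(seen, key)
    }
  }
  sort(seen)
}

kb_pair_keys <- function(kb) {
  sort(paste(kb$pairs$drug_id, kb$pairs$icd10_3, kb$pairs$relation, sep = "|"))
}

# brute-force per-record classification oracle (plain set intersections)
oracle_classify <- function(ind_set, con_set, linked, person) {
  narrow <- as.integer(any(linked %in% ind_set))
  broad <- as.integer(any(person %in% ind_set))
  contra <- as.integer(any(person %in% con_set))
  c(indic_narrow = narrow, indic_broad = broad, contraindicated = contra,
    indic_not_contra = broad * (1L - contra))
}

# textbook Welch two-sample t-test
oracle_welch <- function(x, y) {
  v1 <- var(x) / length(x); v2 <- var(y) / length(y)
  tstat <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  list(t = tstat, df = df, p = 2 * pt(-abs(tstat), df))
}

# minimal consistent survey fixture: 2 persons, 3 conditions, 3 rx, 2 links
tiny_survey <- function() {
  persons <- data.frame(
    person_id = c("P1", "P2"), year = 2018L,
    sex = c("male", "female"), age = c(40L, 70L),
    education = c("12 years", "18+ years"), race = c("White", "Black"),
    medicare = c(0L, 1L), medicaid = c(0L, 0L), weight = c(1000, 2000),
    ANYLMT = c(0L, 1L), ACTLIM31 = c(0L, 1L), UNABLE31 = c(0L, 0L),
    WLKLIM31 = c(0L, 1L), WRKLIM31 = c(0L, 0L), SCHLIM31 = c(0L, 0L),
    HSELIM31 = c(0L, 0L), SOCLIM31 = c(0L, 1L), COGLIM31 = c(0L, 0L),
    total_expenditure = c(1500.5, 9200), ipdis = c(0L, 1L),
    ertot = c(0L, 2L), obtotv = c(3L, 11L))
  conditions <- data.frame(
    condition_id = c("C1", "C2", "C3"),
    person_id = c("P1", "P1", "P2"), year = 2018L,
    icd10_3 = c("E11", "N18", "I10"), is_current = c(1L, 1L, 1L))
  prescriptions <- data.frame(
    rx_id = c("R1", "R2", "R3"), person_id = c("P1", "P1", "P2"),
    year = 2018L, drug_id = c("D1", "D2", "D9"),
    therapeutic_class = c("metabolic agents", "cardiovascular agents", ""),
    ndc = c("001", "002", "009"))
  links <- data.frame(rx_id = c("R1", "R3"), condition_id = c("C1", "C3"))
  as_survey(persons, conditions, prescriptions, links)
}

tiny_kb <- function() {
  drugs <- data.frame(drug_id = c("D1", "D2"),
                      ingredient_name = c("metformin", "lisinopril"),
                      approval_year = c(1995L, 1988L))
  pairs <- data.frame(
    drug_id = c("D1", "D1", "D2"),
    snomed_id = c("S_E11", "S_N18", "S_I10"),
    relation = c("indication", "contraindication", "indication"))
  map <- data.frame(snomed_id = c("S_E11", "S_N18", "S_I10"),
                    icd10_code = c("E11.9", "N18.4", "I10"))
  build_knowledge_base(drugs, pairs, map)
}

paper_prevalence_reference <- function() {
  read.csv(system.file("extdata", "us_rx_prevalence_2016_2021.csv",
                       package = "rxscreen"), check.names = FALSE)
}

paper_contra_by_indication <- function() {
  read.csv(system.file("extdata", "us_rx_contra_by_indication_2016_2021.csv",
                       package = "rxscreen"))
}
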