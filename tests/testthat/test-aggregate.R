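test_that("percentages are 100 x indicator means", {
  ds <- tiny_survey()
  kb <- tiny_kb()
  cls <- classify_all(kb, ds)  # two in-scope rx (R1, R2 for P1)
  tab <- prevalence_table(cls, ds, groupers = "sex")
  overall <- tab[tab$grouping_variable == "all", ]
  expect_equal(overall$n_rx, 2L)
  expect_equal(overall$pct_indic_narrow, 100 * mean(c(1, 0)))
  # 4 prescriptions with broad pattern (1,1,1,0) -> 75%
  sim <- generate_data(generator_config(seed = 2, n_persons = 30))
  cls2 <- classify_all(sim$kb, sim$survey)
  tab2 <- prevalence_table(cls2, sim$survey, groupers = character(0))
  insc <- cls2[cls2$in_scope == 1L, ]
  expect_equal(tab2$pct_indic_broad[1], 100 * mean(insc$indic_broad))
})

test_that("unknown groupers give a config error", {
  ds <- tiny_survey()
  cls <- classify_all(tiny_kb(), ds)
  expect_error(prevalence_table(cls, ds, groupers = "starsign"),
               "unknown grouper")
  expect_error(prevalence_table(cls, ds, groupers = "approval_year_group"),
               "requires the knowledge base")
})

test_that("category rows recombine exactly to the overall row", {
  sim <- generate_data(generator_config(seed = 12, n_persons = 400))
  cls <- classify_all(sim$kb, sim$survey)
  tab <- prevalence_table(cls, sim$survey,
                          groupers = c("sex", "race", "year",
                                       "approval_year_group"),
                          kb = sim$kb)
  overall <- tab[tab$grouping_variable == "all", ]
  for (g in c("sex", "race", "year", "approval_year_group")) {
    rows <- tab[tab$grouping_variable == g, ]
    pooled <- combine_prevalence_rows(rows)
    expect_equal(pooled$n_rx, overall$n_rx, info = g)
    for (p in grep("^pct_", names(tab), value = TRUE)) {
      expect_equal(pooled[[p]], overall[[p]], tolerance = 1e-9, info = g)
    }
  }
})

test_that("overall contraindication rate is the mixture over indication status", {
  sim <- generate_data(preset_paperlike(n_persons = 1500, seed = 4))
  cls <- classify_all(sim$kb, sim$survey)
  insc <- as.data.frame(cls[cls$in_scope == 1L, ])
  p_ind <- 100 * mean(insc$indic_broad)
  c_ind <- 100 * mean(insc$contraindicated[insc$indic_broad == 1])
  c_off <- 100 * mean(insc$contraindicated[insc$indic_broad == 0])
  expect_equal(contra_mixture(p_ind, c_ind, c_off),
               100 * mean(insc$contraindicated), tolerance = 1e-9)
})

test_that("therapeutic class rates equal per-class recomputation, descending n", {
  sim <- generate_data(generator_config(seed = 8, n_persons = 200))
  cls <- classify_all(sim$kb, sim$survey)
  rows <- therapeutic_class_rates(cls, sim$survey)
  expect_false(is.unsorted(rev(rows$n_rx)))
  merged <- merge(as.data.frame(cls[cls$in_scope == 1L, ]),
                  as.data.frame(sim$survey$prescriptions)[, c("rx_id",
                                                              "therapeutic_class")],
                  by = "rx_id")
  for (k in seq_len(nrow(rows))) {
    sub <- merged[merged$therapeutic_class == rows$category[k], ]
    expect_equal(rows$n_rx[k], nrow(sub))
    expect_equal(rows$pct_contraindicated[k], 100 * mean(sub$contraindicated))
  }
})

test_that("empty therapeutic class labels fall into 'unclassified'", {
  ds <- tiny_survey()
  kb <- build_knowledge_base(
    data.frame(drug_id = c("D1", "D2", "D9"),
               ingredient_name = c("a", "b", "c"),
               approval_year = c(1990L, 1991L, 1992L)),
    data.frame(drug_id = "D1", snomed_id = "S1", relation = "indication"),
    data.frame(snomed_id = "S1", icd10_code = "E11"))
  cls <- classify_all(kb, ds)
  rows <- therapeutic_class_rates(cls, ds)
  expect_true("unclassified" %in% rows$category)
})

test_that("median-split comparisons match the textbook Welch oracle", {
  # constructed 6-person example with a known split
  ex <- data.frame(person_id = paste0("P", 1:6), year = 2019L,
                   n_rx = 2L,
                   frac_indicated = c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9),
                   frac_offlabel = 1 - c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9),
                   frac_contraindicated = 0.5,
                   mean_approval_year = 2000)
  out <- c(4, 6, 5, 9, 11, 10)
  persons <- data.frame(person_id = paste0("P", 1:6), year = 2019L,
                        obtotv = out)
  cmp <- median_split_compare(ex, persons, "frac_indicated",
                              outcome_vars = "obtotv")
  orc <- oracle_welch(out[1:3], out[4:6])
  expect_equal(cmp$mean_low, mean(out[1:3]))
  expect_equal(cmp$mean_high, mean(out[4:6]))
  expect_equal(cmp$difference, mean(out[1:3]) - mean(out[4:6]))
  expect_equal(cmp$p_value, orc$p, tolerance = 1e-12)
})

test_that("identical groups give zero difference and p = 1", {
  ex <- data.frame(person_id = paste0("P", 1:4), year = 2019L, n_rx = 1L,
                   frac_indicated = c(0, 0, 1, 1), frac_offlabel = NA,
                   frac_contraindicated = 0.5, mean_approval_year = 2000)
  persons <- data.frame(person_id = paste0("P", 1:4), year = 2019L,
                        ANYLMT = c(1L, 0L, 1L, 0L))
  cmp <- median_split_compare(ex, persons, "frac_indicated",
                              outcome_vars = "ANYLMT")
  expect_equal(cmp$difference, 0)
  expect_equal(cmp$p_value, 1)
})

test_that("swapping groups flips the difference and preserves p", {
  set.seed(40)
  n <- 101  # odd, continuous values: no ties at the median
  vals <- runif(n)
  ex <- data.frame(person_id = sprintf("P%03d", 1:n), year = 2020L, n_rx = 1L,
                   frac_contraindicated = vals, frac_indicated = 0.5,
                   frac_offlabel = 0.5, mean_approval_year = 2000)
  persons <- data.frame(person_id = sprintf("P%03d", 1:n), year = 2020L,
                        obtotv = rpois(n, 4 + 3 * vals))
  cmp <- median_split_compare(ex, persons, "frac_contraindicated",
                              outcome_vars = "obtotv")
  ex2 <- ex; ex2$frac_contraindicated <- 1 - ex2$frac_contraindicated
  cmp2 <- median_split_compare(ex2, persons, "frac_contraindicated",
                               outcome_vars = "obtotv")
  # the person at the median changes sides in the mirrored split; exclude it
  med <- median(vals)
  keep <- vals != med
  orc <- oracle_welch(persons$obtotv[keep & vals < med],
                      persons$obtotv[keep & vals > med])
  expect_equal(sign(cmp2$difference), -sign(cmp$difference))
  expect_equal(cmp$p_value, oracle_welch(persons$obtotv[vals <= med],
                                         persons$obtotv[vals > med])$p,
               tolerance = 1e-12)
  expect_true(is.finite(orc$p))
})

test_that("harmful contraindicated use raises limitation prevalence above the median split", {
  sim <- generate_data(preset_recovery(n_persons = 2000, seed = 6))
  cls <- classify_all(sim$kb, sim$survey)
  ex <- person_exposures(cls, sim$survey, sim$kb)
  cmp <- median_split_compare(ex, sim$survey$persons, "frac_contraindicated",
                              outcome_vars = "ANYLMT")
  expect_lt(cmp$difference, 0)  # low-exposure group has fewer limitations
})

test_that("expenditure is compared on the log scale", {
  sim <- generate_data(generator_config(seed = 14, n_persons = 200))
  cls <- classify_all(sim$kb, sim$survey)
  ex <- person_exposures(cls, sim$survey, sim$kb)
  cmp <- median_split_compare(ex, sim$survey$persons, "frac_indicated",
                              outcome_vars = "total_expenditure")
  expect_equal(cmp$variable, "log_total_expenditure")
  expect_lt(cmp$mean_low, 20)  # log-scale magnitude, not dollars
})
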