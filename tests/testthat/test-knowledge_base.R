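test_that("truncate_icd10 truncates, upper-cases and rejects malformed codes", {
  expect_equal(truncate_icd10("E11.9"), "E11")
  expect_equal(truncate_icd10("J45"), "J45")
  expect_equal(truncate_icd10("k52.9"), "K52")
  expect_equal(truncate_icd10(c("A00", "b99.12")), c("A00", "B99"))
  expect_error(truncate_icd10("11E"), "11E")
  expect_error(truncate_icd10("E1"), "malformed")
  expect_error(truncate_icd10("E11.12345"), "malformed")
})

test_that("one-to-many concept maps collapse to unique 3-digit pairs", {
  drugs <- tiny_drugs(1)
  pairs <- data.frame(drug_id = "D1", snomed_id = "S1", relation = "indication")
  map <- data.frame(snomed_id = c("S1", "S1"),
                    icd10_code = c("E11.9", "E11.65"))
  kb <- build_knowledge_base(drugs, pairs, map)
  expect_equal(nrow(kb$pairs), 1L)
  expect_equal(kb$pairs$icd10_3, "E11")
  expect_equal(kb$qc$n_indication_pairs, 1L)
})

test_that("empty concept pairs give an empty knowledge base", {
  kb <- build_knowledge_base(tiny_drugs(2),
                             data.frame(drug_id = character(),
                                        snomed_id = character(),
                                        relation = character()),
                             data.frame(snomed_id = "S1", icd10_code = "E11"))
  expect_equal(nrow(kb$pairs), 0L)
  expect_equal(kb$qc$n_indication_pairs, 0L)
  expect_equal(kb$qc$n_contraindication_pairs, 0L)
})

test_that("unmappable concepts are dropped and counted, not guessed", {
  drugs <- tiny_drugs(1)
  pairs <- data.frame(drug_id = c("D1", "D1"),
                      snomed_id = c("S1", "S_unknown"),
                      relation = "indication")
  map <- data.frame(snomed_id = "S1", icd10_code = "E11.9")
  kb <- build_knowledge_base(drugs, pairs, map)
  expect_equal(nrow(kb$pairs), 1L)
  expect_equal(kb$qc$n_concepts_dropped, 1L)
  expect_equal(kb$qc$dropped_snomed_ids, "S_unknown")
})

test_that("builder validates drugs, years and referential integrity", {
  expect_error(build_knowledge_base(data.frame(), NULL, NULL), "non-empty|columns")
  d <- tiny_drugs(2); d$approval_year[1] <- 1850
  expect_error(build_knowledge_base(d, data.frame(drug_id = character(),
                                                  snomed_id = character(),
                                                  relation = character()),
                                    data.frame(snomed_id = "S", icd10_code = "E11")),
               "approval_year")
  expect_error(
    build_knowledge_base(tiny_drugs(1),
                         data.frame(drug_id = "D9", snomed_id = "S1",
                                    relation = "indication"),
                         data.frame(snomed_id = "S1", icd10_code = "E11")),
    "unknown drug_id")
  expect_error(
    build_knowledge_base(tiny_drugs(1),
                         data.frame(drug_id = "D1", snomed_id = "S1",
                                    relation = "bogus"),
                         data.frame(snomed_id = "S1", icd10_code = "E11")),
    "relation")
})

test_that("ingredient names are normalised to trimmed lower case", {
  kb <- build_knowledge_base(tiny_drugs(2),
                             data.frame(drug_id = character(),
                                        snomed_id = character(),
                                        relation = character()),
                             data.frame(snomed_id = character(),
                                        icd10_code = character()))
  expect_equal(kb$drugs$ingredient_name, c("ingredient_1", "ingredient_2"))
})

test_that("kb_lookup returns exactly the paired categories", {
  kb <- tiny_kb()
  expect_equal(kb_lookup(kb, "D1", "indication"), "E11")
  expect_equal(kb_lookup(kb, "D1", "contraindication"), "N18")
  expect_equal(kb_lookup(kb, "D2", "contraindication"), character(0))
  expect_error(kb_lookup(kb, "D99", "indication"), "unknown drug_id")
})

test_that("a drug with 9 indication and 17 contraindication concepts yields sets of 9 and 17", {
  # replicates the most-prescribed-drug pattern: nine indications, seventeen
  # contraindications, each concept mapping to a distinct category
  codes <- paste0("K", sprintf("%02d", 1:26))
  drugs <- data.frame(drug_id = "OME", ingredient_name = "omeprazole",
                      approval_year = 1989)
  pairs <- data.frame(drug_id = "OME", snomed_id = paste0("S", 1:26),
                      relation = rep(c("indication", "contraindication"),
                                     c(9, 17)))
  map <- data.frame(snomed_id = paste0("S", 1:26),
                    icd10_code = paste0(codes, ".9"))
  kb <- build_knowledge_base(drugs, pairs, map)
  expect_length(kb_lookup(kb, "OME", "indication"), 9L)
  expect_length(kb_lookup(kb, "OME", "contraindication"), 17L)
})

test_that("random inputs match the brute-force set-comprehension oracle", {
  for (seed in 1:3) {
    inp <- random_kb_input(n_drugs = 50, n_pairs = 200, seed = seed)
    kb <- build_knowledge_base(inp$drugs, inp$pairs, inp$map)
    expect_equal(kb_pair_keys(kb), oracle_kb_pairs(inp$pairs, inp$map))
    # lookups agree with the oracle keys
    for (dd in sample(inp$drugs$drug_id, 5)) {
      keys <- oracle_kb_pairs(inp$pairs[inp$pairs$drug_id == dd, ], inp$map)
      parts <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
      for (rel in c("indication", "contraindication")) {
        want <- if (is.null(parts)) character(0) else
          sort(parts[parts[, 3] == rel, 2])
        expect_equal(kb_lookup(kb, dd, rel), want)
      }
    }
  }
})

test_that("rebuilding from a knowledge base's own pairs is idempotent", {
  inp <- random_kb_input(seed = 7)
  kb <- build_knowledge_base(inp$drugs, inp$pairs, inp$map)
  # re-ingest: each canonical pair as its own already-3-digit concept
  pairs2 <- data.frame(drug_id = kb$pairs$drug_id,
                       snomed_id = paste0("X", kb$pairs$icd10_3),
                       relation = kb$pairs$relation)
  map2 <- unique(data.frame(snomed_id = paste0("X", kb$pairs$icd10_3),
                            icd10_code = kb$pairs$icd10_3))
  kb2 <- build_knowledge_base(inp$drugs, pairs2, map2)
  expect_equal(kb_pair_keys(kb2), kb_pair_keys(kb))
})

test_that("adding a concept pair never shrinks a lookup set", {
  inp <- random_kb_input(n_pairs = 60, seed = 11)
  kb <- build_knowledge_base(inp$drugs, inp$pairs, inp$map)
  extra <- data.frame(drug_id = inp$drugs$drug_id[1],
                      snomed_id = inp$map$snomed_id[1],
                      relation = "indication")
  kb2 <- build_knowledge_base(inp$drugs, rbind(inp$pairs, extra), inp$map)
  for (dd in unique(inp$pairs$drug_id)) {
    for (rel in c("indication", "contraindication")) {
      expect_true(all(kb_lookup(kb, dd, rel) %in% kb_lookup(kb2, dd, rel)))
    }
  }
})

test_that("knowledge base round-trips through its canonical files", {
  inp <- random_kb_input(seed = 3)
  kb <- build_knowledge_base(inp$drugs, inp$pairs, inp$map)
  dir <- withr::local_tempdir()
  write_knowledge_base(kb, dir)
  kb2 <- read_knowledge_base(dir)
  expect_equal(kb_pair_keys(kb2), kb_pair_keys(kb))
  expect_equal(as.data.frame(kb2$drugs), as.data.frame(kb$drugs))
  expect_equal(kb2$qc$n_concepts_dropped, kb$qc$n_concepts_dropped)
})

test_that("delimited inputs are read by extension dialect", {
  inp <- random_kb_input(seed = 5)
  dir <- withr::local_tempdir()
  df <- file.path(dir, "drugs.csv"); pf <- file.path(dir, "pairs.tsv")
  mf <- file.path(dir, "map.csv")
  write.csv(inp$drugs, df, row.names = FALSE)
  write.table(inp$pairs, pf, sep = "\t", row.names = FALSE, quote = FALSE)
  write.csv(inp$map, mf, row.names = FALSE)
  kb <- read_knowledge_base_inputs(df, pf, mf)
  expect_equal(kb_pair_keys(kb), oracle_kb_pairs(inp$pairs, inp$map))
  expect_error(read_knowledge_base_inputs("nope.csv", pf, mf), "not found")
})
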