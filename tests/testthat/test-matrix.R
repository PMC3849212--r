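# Build a store object directly from flat tables (the matrix builder
# only reads the age and phenotype tables).
mk_store <- function(ages, phen) {
  ids <- unique(c(ages$evidence_id, phen$evidence_id))
  structure(list(
    evidence = data.frame(evidence_id = ids, pmid = as.character(ids),
                          snippet = "s", strain = "", gender = "none",
                          year = 2010L, pub_type = ""),
    evidence_age = ages, evidence_phenotype = phen),
    class = "evidence_store")
}

test_that("counts accumulate per disease per age bin", {
  ages <- data.frame(evidence_id = 1:3, start_days = c(42, 42, 100),
                     end_days = c(42, 42, 100), inferred = FALSE)
  phen <- data.frame(evidence_id = 1:3, concept_id = "X",
                     source = "disease_ontology")
  m <- build_matrix(mk_store(ages, phen), "mouse")
  expect_equal(unname(m$counts["X", "42"]), 2)
  expect_equal(unname(m$counts["X", "100"]), 1)
  expect_equal(sum(m$counts), 3)
})

test_that("inferred age ranges contribute nothing", {
  ages <- data.frame(evidence_id = 1:2, start_days = c(0, 42),
                     end_days = c(30, 42), inferred = c(TRUE, FALSE))
  phen <- data.frame(evidence_id = 1:2, concept_id = "X",
                     source = "disease_ontology")
  m <- build_matrix(mk_store(ages, phen), "mouse")
  expect_equal(sum(m$counts), 1)
  expect_equal(unname(m$counts["X", "42"]), 1)
})

test_that("explicit ranges land on the midpoint bin (or start on request)", {
  ages <- data.frame(evidence_id = 1L, start_days = 360, end_days = 450,
                     inferred = FALSE)
  phen <- data.frame(evidence_id = 1L, concept_id = "X",
                     source = "disease_ontology")
  m_mid <- build_matrix(mk_store(ages, phen), "mouse")
  expect_equal(unname(m_mid$counts["X", "405"]), 1)
  m_start <- build_matrix(mk_store(ages, phen), "mouse",
                          range_policy = "start")
  expect_equal(unname(m_start$counts["X", "360"]), 1)
})

test_that("ages beyond the axis are dropped and recorded", {
  ages <- data.frame(evidence_id = 1:2, start_days = c(42, 5000),
                     end_days = c(42, 5000), inferred = FALSE)
  phen <- data.frame(evidence_id = 1:2, concept_id = "X",
                     source = "disease_ontology")
  expect_message(m <- build_matrix(mk_store(ages, phen), "mouse"),
                 "dropped")
  expect_equal(sum(m$counts), 1)
  expect_equal(m$dropped$over_max, 1L)
})

test_that("conservation: total counts equal contributions after exclusions", {
  sim <- generate_corpus(example_disease_specs(), seed = 21, n_inferred = 8)
  inst <- mine_corpus(sim$corpus,
                      build_lexicon(generate_ontology(sim$specs)))
  d <- withr::local_tempdir()
  write_store(inst, d)
  store <- read_store(d)
  m <- build_matrix(store, "mouse")
  contributions <- sum(!store$evidence_age$inferred)
  expect_equal(sum(m$counts), contributions)
})

test_that("normalization makes rows sum to 1 and cannot be repeated", {
  ages <- data.frame(evidence_id = 1:5, start_days = c(2, 2, 3, 9, 0),
                     end_days = c(2, 2, 3, 9, 0), inferred = FALSE)
  phen <- data.frame(evidence_id = 1:5,
                     concept_id = c("X", "X", "X", "X", "Y"),
                     source = "disease_ontology")
  m <- build_matrix(mk_store(ages, phen), "mouse")
  n <- normalize_matrix(m)
  expect_equal(unname(rowSums(n$counts)), c(1, 1), tolerance = 1e-12)
  # count row (2, 1, 1) becomes frequencies (0.5, 0.25, 0.25)
  expect_equal(unname(n$counts["X", c("2", "3", "9")]), c(0.5, 0.25, 0.25))
  expect_error(normalize_matrix(n), "already normalized")
})

test_that("all-zero rows are dropped during normalization", {
  counts <- rbind(X = c(2, 1, 1), Z = c(0, 0, 0))
  colnames(counts) <- as.character(0:2)
  m <- agemapr:::new_age_disease_matrix(counts, "mouse", 1)
  expect_message(n <- normalize_matrix(m), "Z")
  expect_equal(rownames(n$counts), "X")
})

test_that("the minimum-instance filter removes sparse diseases", {
  counts <- rbind(A = c(4, 0, 0), B = c(3, 2, 0), C = c(0, 0, 0))
  colnames(counts) <- as.character(0:2)
  m <- agemapr:::new_age_disease_matrix(counts, "mouse", 1)
  f <- filter_min_instances(m, k = 5)
  expect_equal(rownames(f$counts), "B")
  expect_equal(rownames(filter_min_instances(m, k = 0)$counts),
               c("A", "B", "C"))
  expect_warning(filter_min_instances(m, k = 100), "no disease")
  expect_error(filter_min_instances(normalize_matrix(f), k = 5), "raw")
})

test_that("day-to-week rebinning commutes with normalization", {
  set.seed(8)
  counts <- matrix(rpois(3 * 70, 2), nrow = 3,
                   dimnames = list(c("A", "B", "C"), as.character(0:69)))
  m <- agemapr:::new_age_disease_matrix(counts, "mouse", 1)
  a <- rebin_matrix(normalize_matrix(m), 7)
  b <- normalize_matrix(rebin_matrix(m, 7))
  expect_equal(a$counts, b$counts, tolerance = 1e-9)
  expect_equal(a$resolution_days, 7)
})

test_that("matrices survive a TSV round-trip with metadata", {
  counts <- rbind(X = c(1, 2, 0), Y = c(0, 1, 4))
  colnames(counts) <- as.character(0:2)
  m <- agemapr:::new_age_disease_matrix(counts, "mouse", 1)
  path <- file.path(withr::local_tempdir(), "m.tsv")
  write_matrix(m, path)
  back <- read_matrix(path)
  expect_equal(back$counts, m$counts)
  expect_equal(back$species, "mouse")
  expect_false(back$normalized)
})
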