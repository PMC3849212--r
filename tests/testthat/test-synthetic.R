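test_that("generated ontologies round-trip through the lexicon builder", {
  specs <- example_disease_specs()
  obo <- generate_ontology(specs)
  lex <- build_lexicon(obo)
  all_surfaces <- tolower(unlist(lapply(specs, function(sp)
    c(sp$name, sp$synonyms))))
  expect_setequal(lex$entries$surface, all_surfaces)
  dup <- c(specs, specs[1])
  expect_error(generate_ontology(dup), "duplicate")
})

test_that("disease specs validate their mixture model", {
  expect_error(disease_spec("D:1", "x", weight = c(0.5, 0.6),
                            mean_years = c(10, 50), sd_years = c(5, 5)))
  expect_error(disease_spec("D:1", "x", sd_years = 0))
  expect_error(disease_spec("D:1", "x", shift_days = -1))
})

test_that("specs survive a YAML round-trip", {
  specs <- example_disease_specs()
  path <- file.path(withr::local_tempdir(), "specs.yaml")
  write_disease_specs(specs, path)
  back <- read_disease_specs(path)
  expect_equal(length(back), length(specs))
  expect_equal(back[[1]]$concept_id, specs[[1]]$concept_id)
  expect_equal(back[[2]]$weight, specs[[2]]$weight)
})

test_that("corpus generation is a pure function of its seed", {
  specs <- example_disease_specs()
  a <- generate_corpus(specs, n_distractors = 12, seed = 33,
                       n_organism = 4, n_inferred = 4)
  b <- generate_corpus(specs, n_distractors = 12, seed = 33,
                       n_organism = 4, n_inferred = 4)
  c <- generate_corpus(specs, n_distractors = 12, seed = 34,
                       n_organism = 4, n_inferred = 4)
  expect_identical(a$corpus, b$corpus)
  expect_identical(a$gold, b$gold)
  expect_false(identical(a$corpus$body, c$corpus$body))
  expect_identical(write_medline(a$corpus), write_medline(b$corpus))
})

test_that("MEDLINE output parses back to the same records", {
  sim <- generate_corpus(example_disease_specs(), n_distractors = 5,
                         seed = 12)
  path <- file.path(withr::local_tempdir(), "corpus.medline")
  write_medline(sim$corpus, path)
  back <- read_medline(path)
  expect_equal(back$pmid, sim$corpus$pmid)
  expect_equal(back$body, sim$corpus$body)
  expect_equal(back$year, sim$corpus$year)
})

test_that("mining a clean template corpus reproduces the gold exactly", {
  specs <- example_disease_specs()
  sim <- generate_corpus(specs, n_distractors = 0, seed = 51)
  lex <- build_lexicon(generate_ontology(specs))
  inst <- mine_corpus(sim$corpus, lex)
  expect_length(inst, sum(sim$gold$stored))
  ev <- evaluate_mining(inst, sim$corpus, sim$gold, lex)
  expect_equal(ev$age_flagging$sensitivity, 1)
  expect_equal(ev$phenotype_mapping$precision, 1)
  # planted mouse ages are recovered to the day
  got <- vapply(inst, function(x) x$ages$start_days[1], numeric(1))
  want <- sim$gold$age_days[match(vapply(inst, `[[`, character(1), "pmid"),
                                  sim$gold$pmid)]
  expect_equal(got, want)
})

test_that("matrix pairs are deterministic and place the planted shift", {
  specs <- planted_specs(c(0, 75))
  a <- generate_matrix_pair(specs, noise_cv = 0.2, seed = 9)
  b <- generate_matrix_pair(specs, noise_cv = 0.2, seed = 9)
  expect_identical(a$human$counts, b$human$counts)
  expect_identical(a$mouse$counts, b$mouse$counts)
  noiseless <- generate_matrix_pair(specs, noise_cv = 0, seed = 1)
  expect_true(noiseless$human$normalized && noiseless$mouse$normalized)
  # the mouse row is the human row moved by the planted shift
  h <- noiseless$human$counts["TEST:75", ]
  m <- noiseless$mouse$counts["TEST:75", ]
  expect_equal(unname(m[75 + seq_along(h)]), unname(h), tolerance = 1e-12)
  expect_equal(sum(m[seq_len(75)]), 0)
})
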