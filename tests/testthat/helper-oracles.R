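# Independent oracles and shared fixtures for the test suite.

# Pearson r from the raw sum formula (independent of stats::cor).
naive_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Exhaustive-scan best shift using the naive correlation; the reference
# the package's best_shift is checked against.
naive_best_shift <- function(h, m, max_shift, min_overlap = 10) {
  best_s <- NA_integer_
  best_r <- -Inf
  for (s in 0:max_shift) {
    n <- min(length(h), length(m) - s)
    if (n < min_overlap) next
    hw <- h[1:n]
    mw <- m[(1 + s):(n + s)]
    if (length(unique(hw)) == 1L || length(unique(mw)) == 1L) next
    r <- naive_pearson(hw, mw)
    if (r > best_r) {
      best_r <- r
      best_s <- s
    }
  }
  if (is.na(best_s)) NULL else list(shift = best_s, r = best_r)
}

# Disease specs with given planted shifts, one unimodal pattern each.
planted_specs <- function(shifts, mean_years = 50, sd_years = 15) {
  lapply(shifts, function(s)
    disease_spec(paste0("TEST:", s), paste0("testdisease", s),
                 mean_years = mean_years, sd_years = sd_years,
                 shift_days = s))
}

# Two planted age-pattern groups for clustering: young narrow unimodal
# vs old wide (the two extreme cluster shapes).
young_old_specs <- function(n_per_group = 5) {
  young <- lapply(seq_len(n_per_group), function(i)
    disease_spec(paste0("YNG:", i), paste0("youngdisease", i),
                 mean_years = 4 + i, sd_years = 4, shift_days = 25))
  old <- lapply(seq_len(n_per_group), function(i)
    disease_spec(paste0("OLD:", i), paste0("olddisease", i),
                 mean_years = 55 + 2 * i, sd_years = 22, shift_days = 400))
  c(young, old)
}

young_old_truth <- function(n_per_group = 5) {
  stats::setNames(rep(1:2, each = n_per_group),
                  c(paste0("YNG:", seq_len(n_per_group)),
                    paste0("OLD:", seq_len(n_per_group))))
}

# A tiny OBO document used across lexicon tests.
tiny_obo <- function() {
  c("format-version: 1.2", "",
    "[Term]", "id: DOID:9351", "name: diabetes mellitus",
    "synonym: \"DM\" EXACT []", "",
    "[Term]", "id: DOID:1240", "name: leukemia", "",
    "[Term]", "id: DOID:0001", "name: old disease", "is_obsolete: true", "")
}

# Hand-built evidence set (two instances) for store tests.
tiny_instances <- function() {
  structure(list(
    list(pmid = "1", snippet = "Mice aged 6 weeks developed diabetes mellitus.",
         ages = data.frame(surface = c("aged 6 weeks", "aged 2 weeks"),
                           start_days = c(42, 14), end_days = c(42, 14),
                           unit = "week", inferred = FALSE,
                           char_start = c(6L, 20L), char_end = c(17L, 31L)),
         phenotypes = data.frame(concept_id = "DOID:9351",
                                 surface = "diabetes mellitus",
                                 source = "disease_ontology",
                                 char_start = 30L, char_end = 46L),
         strain = NA_character_, gender = "none", year = 2010L,
         pub_type = "Journal Article"),
    list(pmid = "2", snippet = "Leukemia in mice at 100 days of age.",
         ages = data.frame(surface = "100 days of age",
                           start_days = 100, end_days = 100, unit = "day",
                           inferred = FALSE, char_start = 18L,
                           char_end = 33L),
         phenotypes = data.frame(concept_id = "DOID:1240",
                                 surface = "Leukemia",
                                 source = "disease_ontology",
                                 char_start = 1L, char_end = 8L),
         strain = "C57BL/6", gender = "female", year = 2011L,
         pub_type = "Journal Article")),
    stats = c(abstracts_in = 2L, age_related = 2L, snippets = 2L,
              excluded_organism = 0L, excluded_no_phenotype = 0L,
              instances = 2L),
    class = "evidence_set")
}
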