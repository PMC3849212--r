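# Synthetic-data generators: toy ontologies, template MEDLINE corpora
# with exact gold annotations, and human/mouse matrix pairs with planted
# disease-specific shifts. Every generator is a pure function of
# (specs, parameters, seed).

#' Specify a synthetic disease
#'
#' A disease is described by its human age model (a mixture of Gaussian
#' components over age in years, supporting unimodal and bimodal
#' patterns), the number of evidence instances to plant, and the planted
#' mouse-vs-human age shift in days: a human case at year `y` corresponds
#' to a mouse case at day `y + shift_days`.
#'
#' @param concept_id Concept identifier (e.g. `"DOID:9351"`).
#' @param name Preferred disease name.
#' @param synonyms Character vector of synonyms (may be empty).
#' @param mean_years,sd_years,weight Numeric vectors describing the
#'   mixture components (weights must sum to 1, sds positive).
#' @param n_instances Number of evidence instances to plant in corpora.
#' @param shift_days Planted mouse-minus-human age offset, in days.
#' @param related If `FALSE`, matrix pairs give this disease an
#'   independent random mouse pattern (no cross-species age equivalence).
#' @return A `disease_spec` list.
#' @export
disease_spec <- function(concept_id, name, synonyms = character(),
                         mean_years = 50, sd_years = 15, weight = 1,
                         n_instances = 30, shift_days = 0,
                         related = TRUE) {
  stopifnot(length(mean_years) == length(sd_years),
            length(mean_years) == length(weight),
            all(sd_years > 0), abs(sum(weight) - 1) < 1e-9,
            n_instances >= 0, shift_days >= 0)
  structure(list(concept_id = concept_id, name = name, synonyms = synonyms,
                 mean_years = mean_years, sd_years = sd_years,
                 weight = weight, n_instances = n_instances,
                 shift_days = shift_days, related = related),
            class = "disease_spec")
}

#' A reference set of synthetic diseases
#'
#' The default study conditions for end-to-end runs: five mapped diseases
#' spanning small to large planted shifts (including the shifts behind
#' the worked conversion examples: 99, 90 and 265 days) and one disease
#' with no cross-species age equivalence.
#'
#' @return List of [disease_spec()] objects.
#' @export
example_disease_specs <- function() {
  list(
    disease_spec("DOID:9351", "diabetes mellitus", synonyms = "DM",
                 mean_years = 55, sd_years = 18, shift_days = 99),
    disease_spec("DOID:1240", "leukemia",
                 mean_years = c(10, 65), sd_years = c(6, 12),
                 weight = c(0.4, 0.6), shift_days = 90),
    disease_spec("DOID:2355", "anemia", mean_years = 45, sd_years = 20,
                 shift_days = 265),
    disease_spec("DOID:10652", "Alzheimer's disease", synonyms = "AD",
                 mean_years = 75, sd_years = 9, shift_days = 500),
    disease_spec("DOID:0050117", "hypothyroidism", mean_years = 8,
                 sd_years = 5, shift_days = 20),
    disease_spec("DOID:8398", "osteoarthritis", mean_years = 60,
                 sd_years = 14, related = FALSE)
  )
}

#' Generate a toy OBO ontology from disease specs
#'
#' @param specs List of [disease_spec()] objects (unique concept ids).
#' @return Character vector of OBO 1.2 lines; feed to [build_lexicon()].
#' @export
generate_ontology <- function(specs) {
  stopifnot(length(specs) > 0L)
  ids <- vapply(specs, `[[`, character(1L), "concept_id")
  if (anyDuplicated(ids)) {
    stop("duplicate concept ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  lines <- c("format-version: 1.2", "ontology: synthetic-disease", "")
  for (sp in specs) {
    lines <- c(lines, "[Term]", paste0("id: ", sp$concept_id),
               paste0("name: ", sp$name))
    for (syn in sp$synonyms) {
      lines <- c(lines, paste0("synonym: \"", syn, "\" EXACT []"))
    }
    lines <- c(lines, "")
  }
  lines
}

# Sentence frames for planted evidence. {age} is replaced by an age
# phrase the mining grammar covers; {disease} by a surface form.
EVIDENCE_FRAMES <- c(
  "In this study, {age} mice developed {disease}.",
  "{disease} was observed in mice aged {n} {units}.",
  "Mice examined at {n} {units} of age showed signs of {disease}.",
  "C57BL/6 mice at {n} {units} of age exhibited {disease}.",
  "Male mice aged {n} {units} were used as a model of {disease}.",
  "Female mice developed {disease} when examined at {n} {units} of age.",
  "We studied {disease} in {age} mice.",
  "Severity of {disease} increased in mice aged {n} {units}.",
  "By {n} {units} of age, the mice displayed overt {disease}.",
  "Onset of {disease} occurred in {age} BALB/c mice.")

FILLER_SENTENCES <- c(
  "This report extends earlier observations on murine physiology.",
  "Samples were processed following standard laboratory protocols.",
  "Statistical analyses were performed on all collected measurements.",
  "These findings may inform the design of future experiments.",
  "Histological sections were prepared for microscopic review.",
  "The results were consistent across independent cohorts.")

# Pick a unit that represents the day value exactly, preferring coarser
# units when they divide evenly; keeps the gold age arithmetic exact.
format_age_days <- function(days) {
  choices <- "day"
  if (days > 0 && days %% 7 == 0) choices <- c(choices, "week")
  if (days > 0 && days %% 30 == 0) choices <- c(choices, "month")
  unit <- sample(choices, 1L)
  n <- days / AGE_UNIT_DAYS[[unit]]
  list(n = n, unit = unit,
       units = if (n == 1) unit else paste0(unit, "s"),
       hyphenated = paste0(n, "-", unit, "-old"))
}

fill_frame <- function(frame, age, disease_surface) {
  s <- frame
  if (!is.null(age)) {
    s <- gsub("{age}", age$hyphenated, s, fixed = TRUE)
    s <- gsub("{n}", format(age$n), s, fixed = TRUE)
    s <- gsub("{units}", age$units, s, fixed = TRUE)
  }
  s <- gsub("{disease}", disease_surface, s, fixed = TRUE)
  sub("^(.)", "\\U\\1", s, perl = TRUE)
}

sample_year <- function(sp) {
  comp <- sample.int(length(sp$weight), 1L, prob = sp$weight)
  y <- round(stats::rnorm(1L, sp$mean_years[comp], sp$sd_years[comp]))
  max(0L, min(HUMAN_MAX_AGE_YEARS, as.integer(y)))
}

#' Generate a synthetic MEDLINE corpus with gold annotations
#'
#' For every spec, `n_instances` abstracts are built from sentence
#' templates that embed one age phrase (sampled from the disease's age
#' model, expressed as a mouse age of `year + shift_days` days in a
#' randomly chosen exact unit) and one disease surface form in the same
#' sentence, padded with neutral filler sentences. Distractor abstracts
#' carry an age but no disease, a disease but no age, or neither;
#' organism distractors pair age and disease with a blocked organism
#' term, and inferred distractors use an open-ended age expression.
#' Gold annotations are exact by construction.
#'
#' @param specs List of [disease_spec()] objects.
#' @param n_distractors Number of age-only/disease-only/neither abstracts
#'   (cycled in that order).
#' @param seed Integer seed; the corpus is a pure function of
#'   (specs, parameters, seed).
#' @param n_organism Abstracts about a blocked organism (age + disease
#'   present but never stored).
#' @param n_inferred Abstracts whose only age expression is open-ended
#'   (stored with `inferred = TRUE`, excluded from matrices).
#' @return List with `corpus` (data frame as from [read_medline()]),
#'   `gold` (columns `pmid`, `is_age_related`, `concept_ids`
#'   (pipe-separated expected stored concepts), `age_days`, `year_bin`,
#'   `inferred`, `stored`) and `specs`.
#' @export
generate_corpus <- function(specs, n_distractors = 0, seed = 1,
                            n_organism = 0, n_inferred = 0) {
  set.seed(seed)
  records <- list()
  gold <- list()
  pmid_next <- 1000001L
  add <- function(body, is_age_related, concept_ids, age_days, year_bin,
                  inferred, stored) {
    pmid <- as.character(pmid_next)
    pmid_next <<- pmid_next + 1L
    records[[length(records) + 1L]] <<- data.frame(
      pmid = pmid, title = paste("Synthetic abstract", pmid),
      body = body, year = sample(2000:2012, 1L),
      pub_type = "Journal Article", stringsAsFactors = FALSE)
    gold[[length(gold) + 1L]] <<- data.frame(
      pmid = pmid, is_age_related = is_age_related,
      concept_ids = paste(concept_ids, collapse = "|"),
      age_days = if (is.na(age_days)) NA_real_ else age_days,
      year_bin = if (is.na(year_bin)) NA_integer_ else year_bin,
      inferred = inferred, stored = stored, stringsAsFactors = FALSE)
  }
  wrap_fillers <- function(sentence) {
    paste(sample(FILLER_SENTENCES, 1L), sentence,
          sample(FILLER_SENTENCES, 1L))
  }

  for (sp in specs) {
    surfaces <- c(sp$name, sp$synonyms)
    for (i in seq_len(sp$n_instances)) {
      y <- sample_year(sp)
      # unrelated diseases get mouse ages independent of the human age
      # model, so no cross-species shift exists to recover
      d <- if (sp$related) y + sp$shift_days
           else sample(0:MOUSE_MAX_AGE_DAYS, 1L)
      age <- format_age_days(d)
      frame <- sample(EVIDENCE_FRAMES, 1L)
      sentence <- fill_frame(frame, age, sample(surfaces, 1L))
      add(wrap_fillers(sentence), TRUE, sp$concept_id, d, y, FALSE, TRUE)
    }
  }

  kinds <- rep_len(c("age_only", "disease_only", "neither"),
                   max(0L, n_distractors))
  for (kind in kinds) {
    body <- switch(kind,
      age_only = wrap_fillers(fill_frame(
        "Tissue remodeling was assessed in mice aged {n} {units}.",
        format_age_days(sample(7:700, 1L)), "")),
      disease_only = wrap_fillers(fill_frame(
        "The genetic basis of {disease} remains incompletely understood.",
        NULL, sample(specs, 1L)[[1L]]$name)),
      neither = paste(sample(FILLER_SENTENCES, 3L), collapse = " "))
    add(body, kind == "age_only", character(), NA, NA, FALSE, FALSE)
  }

  for (i in seq_len(n_organism)) {
    sp <- sample(specs, 1L)[[1L]]
    age <- format_age_days(sample(7:700, 1L))
    sentence <- fill_frame(
      "Rats aged {n} {units} developed {disease} in this model.",
      age, sp$name)
    add(wrap_fillers(sentence), TRUE, character(), NA, NA, FALSE, FALSE)
  }

  for (i in seq_len(n_inferred)) {
    sp <- sample(specs, 1L)[[1L]]
    n <- sample(5:90, 1L)
    sentence <- paste0("Mice under the age of ", n,
                       " days frequently developed ", sp$name, ".")
    add(wrap_fillers(sentence), TRUE, sp$concept_id, NA, NA, TRUE, TRUE)
  }

  empty_corpus <- data.frame(pmid = character(), title = character(),
                             body = character(), year = integer(),
                             pub_type = character(), stringsAsFactors = FALSE)
  empty_gold <- data.frame(pmid = character(), is_age_related = logical(),
                           concept_ids = character(), age_days = numeric(),
                           year_bin = integer(), inferred = logical(),
                           stored = logical(), stringsAsFactors = FALSE)
  list(corpus = if (length(records)) do.call(rbind, records) else empty_corpus,
       gold = if (length(gold)) do.call(rbind, gold) else empty_gold,
       specs = specs)
}

# Mixture density of a spec evaluated on integer year bins 0..n_bins-1.
mixture_pattern <- function(sp, n_bins = HUMAN_MAX_AGE_YEARS + 1L) {
  years <- 0:(n_bins - 1L)
  v <- numeric(n_bins)
  for (j in seq_along(sp$weight)) {
    v <- v + sp$weight[j] * stats::dnorm(years, sp$mean_years[j],
                                         sp$sd_years[j])
  }
  v
}

# Mean-1 multiplicative lognormal noise with coefficient of variation cv.
multiplicative_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a human/mouse matrix pair with planted shifts
#'
#' The human row of each disease is its age-model density on integer year
#' bins 0--120. For `related` diseases the mouse row places the same
#' values at day bin `year + shift_days`; for unrelated diseases the
#' mouse row is independent uniform noise. Independent mean-1
#' multiplicative noise with coefficient of variation `noise_cv` is then
#' applied cell-wise to both matrices, and both are row-normalized.
#'
#' @param specs List of [disease_spec()] objects; every planted shift
#'   must fit the mouse axis.
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (0 = noiseless).
#' @param seed Integer seed.
#' @param mouse_bins,human_bins Axis lengths (days / years + 1).
#' @return List with `human` and `mouse` (normalized
#'   `age_disease_matrix`) and `truth` (data frame `disease`,
#'   `shift_days`, `related`).
#' @export
generate_matrix_pair <- function(specs, noise_cv = 0, seed = 1,
                                 mouse_bins = MOUSE_MAX_AGE_DAYS + 1L,
                                 human_bins = HUMAN_MAX_AGE_YEARS + 1L) {
  set.seed(seed)
  shifts <- vapply(specs, `[[`, numeric(1L), "shift_days")
  stopifnot(all(shifts + human_bins - 1L <= mouse_bins - 1L |
                !vapply(specs, `[[`, logical(1L), "related")))
  ids <- vapply(specs, `[[`, character(1L), "concept_id")
  human <- matrix(0, length(specs), human_bins,
                  dimnames = list(ids, as.character(0:(human_bins - 1L))))
  mouse <- matrix(0, length(specs), mouse_bins,
                  dimnames = list(ids, as.character(0:(mouse_bins - 1L))))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    h <- mixture_pattern(sp, human_bins)
    human[i, ] <- h
    if (sp$related) {
      mouse[i, sp$shift_days + seq_len(human_bins)] <- h
    } else {
      mouse[i, ] <- stats::runif(mouse_bins)
    }
  }
  human <- human * matrix(multiplicative_noise(length(human), noise_cv),
                          nrow(human))
  mouse <- mouse * matrix(multiplicative_noise(length(mouse), noise_cv),
                          nrow(mouse))
  truth <- data.frame(disease = ids, shift_days = shifts,
                      related = vapply(specs, `[[`, logical(1L), "related"))
  list(
    human = normalize_matrix(new_age_disease_matrix(human, "human", 365)),
    mouse = normalize_matrix(new_age_disease_matrix(mouse, "mouse", 1)),
    truth = truth)
}

#' Read disease specs from a YAML file
#'
#' The file holds a list of records with the fields of [disease_spec()].
#'
#' @param path YAML path.
#' @return List of `disease_spec` objects.
#' @export
read_disease_specs <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(r) do.call(disease_spec, r))
}

#' Write disease specs to a YAML file
#'
#' @param specs List of `disease_spec` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_disease_specs <- function(specs, path) {
  yaml::write_yaml(lapply(specs, unclass), path)
  invisible(path)
}
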