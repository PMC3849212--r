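# End-to-end orchestration: simulate/mine -> store -> matrices ->
# map/cluster, with a JSON run manifest of per-stage counts.

#' Default pipeline configuration
#'
#' @param out_dir Run directory (created if needed).
#' @param seed Integer seed driving every random choice.
#' @return A `run_config` list; fields can be overridden before passing
#'   to [run_pipeline()].
#' @export
default_config <- function(out_dir = tempfile("agemap_run_"), seed = 1) {
  structure(list(
    out_dir = out_dir, seed = seed,
    specs_file = NULL,            # YAML of disease specs; NULL = built-in set
    corpus_file = NULL,           # pre-existing MEDLINE file; NULL = simulate
    n_distractors = 60, n_organism = 10, n_inferred = 10,
    min_instances = 5,
    max_shift = 1028, r2_threshold = 0.5, min_overlap = 10,
    objective = "r", linkage = "average"), class = "run_config")
}

validate_config <- function(config) {
  bad <- character()
  for (f in c("specs_file", "corpus_file")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]])) {
      bad <- c(bad, paste0(f, " (missing file: ", config[[f]], ")"))
    }
  }
  num <- c("seed", "n_distractors", "n_organism", "n_inferred",
           "min_instances", "max_shift", "r2_threshold", "min_overlap")
  for (f in num) {
    if (!is.numeric(config[[f]]) || length(config[[f]]) != 1L ||
        is.na(config[[f]])) {
      bad <- c(bad, f)
    }
  }
  if (length(bad)) {
    stop("invalid run configuration; offending fields: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(config)
}

# Human-side count matrix from gold annotations (the simulated analogue
# of the human knowledgebase): stored, non-inferred instances counted at
# their year bin.
gold_human_matrix <- function(gold) {
  g <- gold[gold$stored & !gold$inferred & !is.na(gold$year_bin), ,
            drop = FALSE]
  diseases <- sort(unique(g$concept_ids))
  counts <- matrix(0, length(diseases), HUMAN_MAX_AGE_YEARS + 1L,
                   dimnames = list(diseases,
                                   as.character(0:HUMAN_MAX_AGE_YEARS)))
  if (nrow(g)) {
    tab <- table(factor(g$concept_ids, levels = diseases),
                 factor(g$year_bin, levels = 0:HUMAN_MAX_AGE_YEARS))
    counts <- counts + unclass(tab)
    dimnames(counts) <- list(diseases, as.character(0:HUMAN_MAX_AGE_YEARS))
  }
  new_age_disease_matrix(counts, "human", 365)
}

#' Run the full pipeline
#'
#' Executes, in order: corpus simulation (or loading), lexicon building,
#' mining, evidence storage, matrix construction and normalization for
#' both species, disease mapping, and hierarchical clustering. All
#' artifacts (corpus, gold annotations, ontology, store, matrices, age
#' map, dendrogram) and a `manifest.json` of per-stage counts are written
#' to the run directory. Any stage failure aborts with the stage name.
#'
#' @param config A [default_config()] list (or a YAML path with the same
#'   fields).
#' @return Invisibly, a list with the main in-memory objects (`store`,
#'   `mouse_matrix`, `human_matrix`, `map`, `dendrogram`, `manifest`).
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) {
    overrides <- yaml::read_yaml(config)
    config <- utils::modifyList(default_config(), overrides)
  }
  validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "setup"
  result <- tryCatch({
    stage <- "specs"
    specs <- if (is.null(config$specs_file)) example_disease_specs()
             else read_disease_specs(config$specs_file)

    stage <- "corpus"
    if (is.null(config$corpus_file)) {
      sim <- generate_corpus(specs, n_distractors = config$n_distractors,
                             seed = config$seed,
                             n_organism = config$n_organism,
                             n_inferred = config$n_inferred)
      corpus <- sim$corpus
      gold <- sim$gold
      write_medline(corpus, file.path(config$out_dir, "corpus.medline"))
      utils::write.table(gold, file.path(config$out_dir, "gold.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      corpus <- read_medline(config$corpus_file)
      gold <- NULL
    }

    stage <- "lexicon"
    obo <- generate_ontology(specs)
    writeLines(obo, file.path(config$out_dir, "ontology.obo"))
    lexicon <- build_lexicon(obo)

    stage <- "mining"
    instances <- mine_corpus(corpus, lexicon,
                             strain_list = c("C57BL/6", "BALB/c"))
    stats <- attr(instances, "stats")

    stage <- "store"
    store_dir <- file.path(config$out_dir, "store")
    write_store(instances, store_dir)
    store <- read_store(store_dir)

    stage <- "matrices"
    mouse_counts <- build_matrix(store, "mouse")
    mouse_matrix <- normalize_matrix(mouse_counts)
    human_counts <- if (is.null(gold)) NULL else gold_human_matrix(gold)
    write_matrix(mouse_counts, file.path(config$out_dir, "mouse_counts.tsv"))

    stage <- "mapping"
    map <- NULL
    if (!is.null(human_counts) && nrow(human_counts$counts) > 0L) {
      human_matrix <- normalize_matrix(human_counts)
      map <- map_diseases(human_matrix, mouse_matrix,
                          max_shift = config$max_shift,
                          r2_threshold = config$r2_threshold,
                          min_overlap = config$min_overlap,
                          objective = config$objective)
      write_age_map(map, file.path(config$out_dir, "agemap.json"),
                    tsv_path = file.path(config$out_dir, "agemap.tsv"),
                    concept_names = lexicon$concept_names)
    } else {
      human_matrix <- NULL
    }

    stage <- "clustering"
    dendro <- NULL
    clusterable <- filter_min_instances(mouse_counts,
                                        k = config$min_instances)
    if (nrow(clusterable$counts) >= 2L) {
      dendro <- cluster_diseases(normalize_matrix(clusterable),
                                 linkage = config$linkage)
      write_dendrogram(dendro, file.path(config$out_dir, "diseases.nwk"))
    }

    stage <- "manifest"
    manifest <- list(
      seed = config$seed,
      counts = c(as.list(stats), list(
        instances_stored = nrow(store$evidence),
        diseases_mouse = nrow(mouse_matrix$counts),
        diseases_human = if (is.null(human_matrix)) 0L
                         else nrow(human_matrix$counts),
        diseases_compared = if (is.null(map)) 0L else map$n_compared,
        diseases_accepted = if (is.null(map)) 0L else map$n_accepted)),
      options = config[c("min_instances", "max_shift", "r2_threshold",
                         "min_overlap", "objective", "linkage")],
      unit_conversions = as.list(AGE_UNIT_DAYS))
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)

    list(store = store, mouse_matrix = mouse_matrix,
         human_matrix = human_matrix, map = map, dendrogram = dendro,
         manifest = manifest, gold = gold, lexicon = lexicon)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
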