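# The three-table evidence store: evidence, evidence-age and
# evidence-phenotype tables persisted as TSV with referential integrity.

sanitize_tsv <- function(x) gsub("[\t\r\n]+", " ", x)

#' Write an evidence set to a three-table TSV store
#'
#' Persists mined evidence as `evidence.tsv` (one row per instance),
#' `evidence_age.tsv` (one row per age mention) and
#' `evidence_phenotype.tsv` (one row per concept link), with
#' `evidence_id` as the foreign key. The layout round-trips losslessly
#' through [read_store()].
#'
#' @param instances An `evidence_set` from [mine_corpus()].
#' @param path Directory to create/write into.
#' @return The path, invisibly.
#' @export
write_store <- function(instances, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create store at ", path, call. = FALSE)
  store <- store_tables(instances)
  write_tsv <- function(d, f)
    utils::write.table(d, file.path(path, f), sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  write_tsv(store$evidence, "evidence.tsv")
  write_tsv(store$evidence_age, "evidence_age.tsv")
  write_tsv(store$evidence_phenotype, "evidence_phenotype.tsv")
  invisible(path)
}

# Flatten an evidence set into the three relational tables.
store_tables <- function(instances) {
  n <- length(instances)
  evidence <- data.frame(
    evidence_id = integer(), pmid = character(), snippet = character(),
    strain = character(), gender = character(), year = integer(),
    pub_type = character(), stringsAsFactors = FALSE)
  ages <- data.frame(evidence_id = integer(), start_days = numeric(),
                     end_days = numeric(), inferred = logical())
  phen <- data.frame(evidence_id = integer(), concept_id = character(),
                     source = character(), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    inst <- instances[[i]]
    stopifnot(nrow(inst$ages) >= 1L, nrow(inst$phenotypes) >= 1L)
    evidence <- rbind(evidence, data.frame(
      evidence_id = i, pmid = inst$pmid,
      snippet = sanitize_tsv(inst$snippet),
      strain = ifelse(is.na(inst$strain), "", inst$strain),
      gender = inst$gender,
      year = ifelse(is.na(inst$year), NA_integer_, inst$year),
      pub_type = inst$pub_type, stringsAsFactors = FALSE))
    ages <- rbind(ages, data.frame(
      evidence_id = i, start_days = inst$ages$start_days,
      end_days = inst$ages$end_days, inferred = inst$ages$inferred))
    phen <- rbind(phen, data.frame(
      evidence_id = i, concept_id = inst$phenotypes$concept_id,
      source = inst$phenotypes$source, stringsAsFactors = FALSE))
  }
  structure(list(evidence = evidence, evidence_age = ages,
                 evidence_phenotype = phen), class = "evidence_store")
}

#' Read a three-table evidence store
#'
#' Referential integrity (every age/phenotype row pointing at an existing
#' evidence row) is checked on read.
#'
#' @param path Store directory written by [write_store()].
#' @return An object of class `evidence_store`: list of the three data
#'   frames `evidence`, `evidence_age`, `evidence_phenotype`.
#' @export
read_store <- function(path) {
  read_tsv <- function(f, colClasses)
    utils::read.delim(file.path(path, f), sep = "\t", quote = "",
                      colClasses = colClasses, stringsAsFactors = FALSE,
                      na.strings = "NA")
  evidence <- read_tsv("evidence.tsv", c(
    evidence_id = "integer", pmid = "character", snippet = "character",
    strain = "character", gender = "character", year = "integer",
    pub_type = "character"))
  evidence$strain[is.na(evidence$strain)] <- ""
  ages <- read_tsv("evidence_age.tsv", c(
    evidence_id = "integer", start_days = "numeric", end_days = "numeric",
    inferred = "logical"))
  phen <- read_tsv("evidence_phenotype.tsv", c(
    evidence_id = "integer", concept_id = "character",
    source = "character"))
  store <- structure(list(evidence = evidence, evidence_age = ages,
                          evidence_phenotype = phen),
                     class = "evidence_store")
  validate_store(store)
  store
}

validate_store <- function(store) {
  ids <- store$evidence$evidence_id
  if (anyDuplicated(ids)) stop("duplicate evidence_id", call. = FALSE)
  orphan_a <- setdiff(store$evidence_age$evidence_id, ids)
  orphan_p <- setdiff(store$evidence_phenotype$evidence_id, ids)
  if (length(orphan_a) || length(orphan_p)) {
    stop("referential integrity violated; orphan evidence_ids: ",
         paste(unique(c(orphan_a, orphan_p)), collapse = ", "),
         call. = FALSE)
  }
  no_age <- setdiff(ids, store$evidence_age$evidence_id)
  no_phen <- setdiff(ids, store$evidence_phenotype$evidence_id)
  if (length(no_age) || length(no_phen)) {
    stop("evidence rows lacking an age or phenotype link: ",
         paste(unique(c(no_age, no_phen)), collapse = ", "), call. = FALSE)
  }
  invisible(store)
}

#' @export
print.evidence_store <- function(x, ...) {
  cat("<evidence_store>", nrow(x$evidence), "instances,",
      nrow(x$evidence_age), "age rows,", nrow(x$evidence_phenotype),
      "phenotype rows\n")
  invisible(x)
}

#' Query an evidence store by age and/or phenotype
#'
#' Implements the three query types of the data browser: by age, by
#' phenotype, or by both, with conjunctive refinement by publication year
#' and publication type. Age matching uses closed day intervals: an
#' instance matches when its `[start_days, end_days]` interval overlaps
#' the query interval (a point age is a 1-day interval).
#'
#' @param store An `evidence_store`.
#' @param age_range Numeric length-2 vector (days) or `NULL`.
#' @param phenotype A concept id, or a concept name when a `lexicon` is
#'   supplied, or `NULL`.
#' @param year_range Integer length-2 vector or `NULL`.
#' @param pub_type Exact publication-type label or `NULL`.
#' @param lexicon Optional lexicon for resolving phenotype names.
#' @return The matching subset of the evidence table, with ages and
#'   phenotype links attached as the data frames `ages` and `phenotypes`
#'   in `attr(, "detail")`.
#' @export
query_store <- function(store, age_range = NULL, phenotype = NULL,
                        year_range = NULL, pub_type = NULL,
                        lexicon = NULL) {
  if (is.null(age_range) && is.null(phenotype)) {
    stop("query_store: give at least one of age_range or phenotype",
         call. = FALSE)
  }
  keep <- store$evidence$evidence_id
  if (!is.null(age_range)) {
    stopifnot(length(age_range) == 2L, age_range[1L] <= age_range[2L])
    a <- store$evidence_age
    hit <- a$evidence_id[a$start_days <= age_range[2L] &
                         a$end_days >= age_range[1L]]
    keep <- intersect(keep, hit)
  }
  if (!is.null(phenotype)) {
    concept <- resolve_concept(phenotype, store, lexicon)
    p <- store$evidence_phenotype
    keep <- intersect(keep, p$evidence_id[p$concept_id == concept])
  }
  out <- store$evidence[store$evidence$evidence_id %in% keep, , drop = FALSE]
  if (!is.null(year_range)) {
    out <- out[!is.na(out$year) & out$year >= year_range[1L] &
               out$year <= year_range[2L], , drop = FALSE]
  }
  if (!is.null(pub_type)) {
    out <- out[vapply(strsplit(out$pub_type, "|", fixed = TRUE),
                      function(x) pub_type %in% x, logical(1L)), ,
               drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "detail") <- list(
    ages = store$evidence_age[
      store$evidence_age$evidence_id %in% out$evidence_id, , drop = FALSE],
    phenotypes = store$evidence_phenotype[
      store$evidence_phenotype$evidence_id %in% out$evidence_id, ,
      drop = FALSE])
  out
}

resolve_concept <- function(phenotype, store, lexicon) {
  known <- unique(store$evidence_phenotype$concept_id)
  if (phenotype %in% known) return(phenotype)
  if (!is.null(lexicon)) {
    hit <- lexicon$entries$concept_id[
      lexicon$entries$surface == tolower(phenotype)]
    if (length(hit)) return(hit[1L])
    near <- utils::head(unique(lexicon$entries$surface[
      order(utils::adist(tolower(phenotype), lexicon$entries$surface))]), 5L)
    stop("unknown phenotype '", phenotype, "'; nearest lexicon names: ",
         paste(near, collapse = ", "), call. = FALSE)
  }
  stop("unknown phenotype concept '", phenotype, "'", call. = FALSE)
}
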