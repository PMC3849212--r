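# Age-disease matrices: per-species counts of evidence instances per
# disease per age bin, and their row normalization.

# Default axes: mouse in whole days 0..1028, human in whole years 0..120.
MOUSE_MAX_AGE_DAYS <- 1028
HUMAN_MAX_AGE_YEARS <- 120

new_age_disease_matrix <- function(counts, species, resolution_days,
                                   normalized = FALSE, dropped = list()) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  structure(list(counts = counts, species = species,
                 resolution_days = resolution_days,
                 normalized = normalized, dropped = dropped),
            class = "age_disease_matrix")
}

#' @export
print.age_disease_matrix <- function(x, ...) {
  cat("<age_disease_matrix>", x$species, ":", nrow(x$counts), "diseases x",
      ncol(x$counts), "bins of", x$resolution_days, "day(s);",
      if (x$normalized) "normalized" else "counts", "\n")
  invisible(x)
}

#' Build an age-disease count matrix from an evidence store
#'
#' Each evidence instance contributes +1 to the (disease, age bin) cell
#' for every distinct phenotype it carries. Evidence with inferred
#' (open-ended) age ranges is excluded. Explicit ranges are placed at
#' their midpoint bin (rounded down) or at their start, per
#' `range_policy`. Ages beyond the axis maximum are dropped and recorded
#' in the `dropped` field.
#'
#' @param store An `evidence_store`.
#' @param species `"mouse"` (1-day bins, ages 0--1028 days) or `"human"`
#'   (1-year bins, ages 0--120 years).
#' @param resolution_days Bin width in days; default 1 for mouse, 365 for
#'   human.
#' @param max_bins Number of bins; default covers the species axis.
#' @param range_policy `"midpoint"` (default) or `"start"`.
#' @return An `age_disease_matrix` of raw counts; rows are concept ids,
#'   columns are bin indices starting at 0 (days/`resolution_days`).
#' @export
build_matrix <- function(store, species = c("mouse", "human"),
                         resolution_days = NULL, max_bins = NULL,
                         range_policy = c("midpoint", "start")) {
  species <- match.arg(species)
  range_policy <- match.arg(range_policy)
  if (is.null(resolution_days))
    resolution_days <- if (species == "mouse") 1 else 365
  if (is.null(max_bins)) {
    max_bins <- if (species == "mouse")
      MOUSE_MAX_AGE_DAYS %/% resolution_days + 1L
    else HUMAN_MAX_AGE_YEARS %/% (resolution_days %/% 365) + 1L
  }
  stopifnot(resolution_days > 0)

  ages <- store$evidence_age
  phen <- store$evidence_phenotype
  keep <- !ages$inferred & is.finite(ages$end_days)
  ages <- ages[keep, , drop = FALSE]
  age_days <- switch(range_policy,
    midpoint = floor((ages$start_days + ages$end_days) / 2),
    start = ages$start_days)
  bin <- floor(age_days / resolution_days)

  joined <- merge(data.frame(evidence_id = ages$evidence_id, bin = bin),
                  phen[, c("evidence_id", "concept_id")],
                  by = "evidence_id")
  # one count per (evidence, phenotype, bin); duplicate age rows mapping
  # to the same bin for the same instance count once
  joined <- unique(joined)
  over <- joined$bin >= max_bins
  dropped <- list(over_max = sum(over))
  if (any(over)) {
    message("build_matrix: dropped ", sum(over),
            " contribution(s) beyond the age axis")
    joined <- joined[!over, , drop = FALSE]
  }

  diseases <- sort(unique(phen$concept_id))
  counts <- matrix(0, nrow = length(diseases), ncol = max_bins,
                   dimnames = list(diseases, as.character(0:(max_bins - 1L))))
  if (nrow(joined)) {
    tab <- table(factor(joined$concept_id, levels = diseases),
                 factor(joined$bin, levels = 0:(max_bins - 1L)))
    counts <- counts + unclass(tab)
    dimnames(counts) <- list(diseases, as.character(0:(max_bins - 1L)))
  }
  if (nrow(counts) == 0L) warning("build_matrix: empty store, empty matrix")
  new_age_disease_matrix(counts, species, resolution_days,
                         dropped = dropped)
}

#' Row-normalize an age-disease matrix
#'
#' Divides each disease row by its total instance count, controlling for
#' disease over- or under-representation in the literature. Rows whose
#' total is zero are dropped (their frequency pattern is undefined).
#'
#' @param matrix An unnormalized `age_disease_matrix`.
#' @return The normalized matrix; every remaining row sums to 1.
#' @export
normalize_matrix <- function(matrix) {
  stopifnot(inherits(matrix, "age_disease_matrix"))
  if (matrix$normalized) {
    stop("matrix is already normalized", call. = FALSE)
  }
  totals <- rowSums(matrix$counts)
  zero <- totals == 0
  if (any(zero)) {
    message("normalize_matrix: dropping ", sum(zero), " all-zero row(s): ",
            paste(rownames(matrix$counts)[zero], collapse = ", "))
  }
  counts <- matrix$counts[!zero, , drop = FALSE] / totals[!zero]
  new_age_disease_matrix(counts, matrix$species, matrix$resolution_days,
                         normalized = TRUE, dropped = matrix$dropped)
}

#' Drop diseases with too few instances
#'
#' @param matrix An unnormalized `age_disease_matrix`.
#' @param k Minimum total instance count (default 5, the threshold used
#'   for the clustering analysis).
#' @return The filtered matrix.
#' @export
filter_min_instances <- function(matrix, k = 5) {
  stopifnot(inherits(matrix, "age_disease_matrix"), k >= 0)
  if (matrix$normalized) {
    stop("filter_min_instances needs raw counts, not a normalized matrix",
         call. = FALSE)
  }
  keep <- rowSums(matrix$counts) >= k
  if (!any(keep)) warning("filter_min_instances: no disease passes k = ", k)
  new_age_disease_matrix(matrix$counts[keep, , drop = FALSE],
                         matrix$species, matrix$resolution_days,
                         dropped = matrix$dropped)
}

#' Aggregate adjacent age bins
#'
#' Rebins a matrix to a coarser resolution by summing `factor` adjacent
#' bins (e.g. `factor = 7` turns mouse day bins into week bins). Works on
#' counts or normalized frequencies; normalized rows still sum to 1.
#'
#' @param matrix An `age_disease_matrix`.
#' @param factor Integer number of adjacent bins to merge.
#' @return The rebinned matrix.
#' @export
rebin_matrix <- function(matrix, factor) {
  stopifnot(inherits(matrix, "age_disease_matrix"),
            factor == as.integer(factor), factor >= 1)
  nb <- ncol(matrix$counts)
  group <- (seq_len(nb) - 1L) %/% factor
  counts <- t(rowsum(t(matrix$counts), group = group))
  colnames(counts) <- as.character(unique(group))
  new_age_disease_matrix(counts, matrix$species,
                         matrix$resolution_days * factor,
                         normalized = matrix$normalized,
                         dropped = matrix$dropped)
}

#' Write an age-disease matrix as TSV plus a JSON metadata sidecar
#'
#' @param matrix An `age_disease_matrix`.
#' @param path Output TSV path; metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path) {
  d <- data.frame(concept_id = rownames(matrix$counts), matrix$counts,
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(species = matrix$species,
               resolution_days = matrix$resolution_days,
               n_bins = ncol(matrix$counts),
               normalized = matrix$normalized,
               unit_conversions = as.list(AGE_UNIT_DAYS),
               dropped = matrix$dropped)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Read an age-disease matrix written by [write_matrix()]
#'
#' @param path TSV path with `<path>.json` sidecar.
#' @return An `age_disease_matrix`.
#' @export
read_matrix <- function(path) {
  d <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                         stringsAsFactors = FALSE)
  counts <- as.matrix(d[, -1L, drop = FALSE])
  rownames(counts) <- d[[1L]]
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new_age_disease_matrix(counts, meta$species, meta$resolution_days,
                         normalized = meta$normalized,
                         dropped = as.list(meta$dropped))
}
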