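# Disease-specific human<->mouse age mapping: the human age pattern
# (1-year bins) is slid along the mouse age pattern (1-day bins) and the
# shift maximizing the Pearson correlation is the disease's age offset.

#' Pearson correlation between the human and mouse pattern at one shift
#'
#' Aligns human bin `y` with mouse bin `y + s` for
#' `y = 0 ... min(len(human) - 1, len(mouse) - 1 - s)` and returns the
#' Pearson correlation over the aligned window. One human bin (a year)
#' aligns with one mouse bin (a day) inside the window; only the offset
#' `s` differs between diseases.
#'
#' @param human_vec Numeric vector indexed by year bin (0-based).
#' @param mouse_vec Numeric vector indexed by day bin (0-based).
#' @param s Non-negative integer shift (days).
#' @param min_overlap Minimum aligned window length; shorter windows give
#'   `NA`.
#' @return Pearson r, or `NA` when the window is too short or either
#'   window has zero variance.
#' @export
pearson_at_shift <- function(human_vec, mouse_vec, s, min_overlap = 10) {
  stopifnot(s >= 0, s == as.integer(s))
  n <- min(length(human_vec), length(mouse_vec) - s)
  if (n < min_overlap) return(NA_real_)
  h <- human_vec[seq_len(n)]
  m <- mouse_vec[seq_len(n) + s]
  if (stats::sd(h) == 0 || stats::sd(m) == 0) return(NA_real_)
  stats::cor(h, m)
}

#' Find the shift best aligning a human and a mouse age pattern
#'
#' Evaluates every shift `s = 0 ... max_shift` and returns the one
#' maximizing the Pearson correlation `r` (ties broken by the smallest
#' shift). With `objective = "r2"` the squared correlation is maximized
#' instead, which would also accept strongly anti-correlated patterns.
#'
#' @param human_vec,mouse_vec Normalized frequency vectors (year bins /
#'   day bins). Pearson correlation is affine-invariant, so raw counts
#'   give the same answer.
#' @param max_shift Largest shift tried (default 1028 days, the full
#'   mouse axis).
#' @param min_overlap Passed to [pearson_at_shift()].
#' @param objective `"r"` (default) or `"r2"`.
#' @return List with `shift`, `r`, `r2`, `n_overlap`, or `NULL` when no
#'   shift yields a defined correlation.
#' @export
best_shift <- function(human_vec, mouse_vec, max_shift = 1028,
                       min_overlap = 10, objective = c("r", "r2")) {
  objective <- match.arg(objective)
  stopifnot(max_shift >= 0)
  shifts <- 0:max_shift
  r <- vapply(shifts, function(s)
    pearson_at_shift(human_vec, mouse_vec, s, min_overlap), numeric(1L))
  score <- if (objective == "r") r else r^2
  if (all(is.na(score))) return(NULL)
  best <- which.max(score)  # first maximum = smallest shift on ties
  s <- shifts[best]
  list(shift = s, r = r[best], r2 = r[best]^2,
       n_overlap = min(length(human_vec), length(mouse_vec) - s))
}

#' Map diseases between species by their age patterns
#'
#' For every disease present in both normalized matrices, finds the best
#' shift of the human pattern against the mouse pattern and accepts the
#' disease into the age map when the correlation at the best shift
#' satisfies `r^2 > r2_threshold`. By default acceptance additionally
#' requires `r > 0` (an anti-correlated pattern carries no usable age
#' equivalence); set `objective = "r2"` for the permissive squared-r
#' criterion alone.
#'
#' @param human_matrix,mouse_matrix Normalized `age_disease_matrix`
#'   objects (human 1-year bins, mouse 1-day bins).
#' @param max_shift,min_overlap,objective Passed to [best_shift()].
#' @param r2_threshold Acceptance threshold on r squared (default 0.5).
#' @return An object of class `age_map`: list with `table` (one row per
#'   compared disease: `disease`, `shift_days`, `r`, `r2`, `n_overlap`,
#'   `accepted`), `n_compared`, `n_accepted`, and `options`.
#' @export
map_diseases <- function(human_matrix, mouse_matrix, max_shift = 1028,
                         r2_threshold = 0.5, min_overlap = 10,
                         objective = c("r", "r2")) {
  objective <- match.arg(objective)
  stopifnot(inherits(human_matrix, "age_disease_matrix"),
            inherits(mouse_matrix, "age_disease_matrix"))
  if (!human_matrix$normalized || !mouse_matrix$normalized) {
    stop("map_diseases expects normalized matrices", call. = FALSE)
  }
  shared <- intersect(rownames(human_matrix$counts),
                      rownames(mouse_matrix$counts))
  if (!length(shared)) {
    warning("map_diseases: no disease present in both matrices")
  }
  rows <- lapply(shared, function(d) {
    fit <- best_shift(human_matrix$counts[d, ], mouse_matrix$counts[d, ],
                      max_shift = max_shift, min_overlap = min_overlap,
                      objective = objective)
    if (is.null(fit)) {
      return(data.frame(disease = d, shift_days = NA_integer_,
                        r = NA_real_, r2 = NA_real_,
                        n_overlap = NA_integer_, accepted = FALSE))
    }
    accepted <- fit$r2 > r2_threshold &&
      (objective == "r2" || fit$r > 0)
    data.frame(disease = d, shift_days = fit$shift, r = fit$r,
               r2 = fit$r2, n_overlap = fit$n_overlap, accepted = accepted)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(disease = character(), shift_days = integer(), r = numeric(),
               r2 = numeric(), n_overlap = integer(), accepted = logical())
  rownames(tab) <- NULL
  structure(list(table = tab, n_compared = nrow(tab),
                 n_accepted = sum(tab$accepted),
                 options = list(max_shift = max_shift,
                                r2_threshold = r2_threshold,
                                min_overlap = min_overlap,
                                objective = objective)),
            class = "age_map")
}

#' Construct an age map directly from per-disease shifts
#'
#' Convenience constructor for a map whose shifts are already known
#' (e.g. published best shifts), bypassing the correlation step.
#'
#' @param entries Data frame with columns `disease` and `shift_days`;
#'   optional `r`, `r2`, `n_overlap`.
#' @return An `age_map` whose entries are all accepted.
#' @export
age_map <- function(entries) {
  stopifnot(all(c("disease", "shift_days") %in% names(entries)))
  for (col in c("r", "r2", "n_overlap"))
    if (is.null(entries[[col]])) entries[[col]] <- NA_real_
  entries$accepted <- TRUE
  tab <- entries[, c("disease", "shift_days", "r", "r2", "n_overlap",
                     "accepted")]
  structure(list(table = tab, n_compared = nrow(tab),
                 n_accepted = nrow(tab), options = list()),
            class = "age_map")
}

#' @export
print.age_map <- function(x, ...) {
  cat("<age_map>", x$n_accepted, "of", x$n_compared,
      "diseases accepted\n")
  if (x$n_accepted) {
    print(utils::head(x$table[x$table$accepted, ], 10L), row.names = FALSE)
  }
  invisible(x)
}

map_entry <- function(map, disease) {
  tab <- map$table[map$table$accepted, , drop = FALSE]
  hit <- tab[tab$disease == disease, , drop = FALSE]
  if (nrow(hit) == 0L) {
    stop("disease '", disease, "' is not in the age map", call. = FALSE)
  }
  hit[1L, ]
}

#' Convert a mouse age to the equivalent human age for a disease
#'
#' Under the additive-shift model a mouse age of `d` days corresponds to
#' human age `d - shift` read on the human year axis (one human year bin
#' per mouse day within the aligned window).
#'
#' @param map An `age_map`.
#' @param disease Concept id of an accepted disease.
#' @param mouse_age_days Mouse age in days; must be at least the
#'   disease's shift.
#' @return Human age in years.
#' @examples
#' m <- age_map(data.frame(disease = "DOID:9351", shift_days = 99))
#' mouse_to_human_age(m, "DOID:9351", 120)  # 21 years
#' @export
mouse_to_human_age <- function(map, disease, mouse_age_days) {
  entry <- map_entry(map, disease)
  if (any(mouse_age_days < entry$shift_days)) {
    stop("mouse age ", min(mouse_age_days), " d is below the shift (",
         entry$shift_days, " d); it maps to a negative human age",
         call. = FALSE)
  }
  mouse_age_days - entry$shift_days
}

#' Convert a human age to the equivalent mouse age for a disease
#'
#' Exact inverse of [mouse_to_human_age()] on its domain.
#'
#' @param map An `age_map`.
#' @param disease Concept id of an accepted disease.
#' @param human_age_years Human age in years (non-negative).
#' @return Mouse age in days.
#' @export
human_to_mouse_age <- function(map, disease, human_age_years) {
  stopifnot(all(human_age_years >= 0))
  entry <- map_entry(map, disease)
  human_age_years + entry$shift_days
}

#' Write an age map as JSON (and optionally a flat TSV)
#'
#' @param map An `age_map`.
#' @param path Output JSON path.
#' @param tsv_path Optional TSV path for the full comparison table.
#' @param concept_names Optional named vector concept_id -> name.
#' @return `path`, invisibly.
#' @export
write_age_map <- function(map, path, tsv_path = NULL,
                          concept_names = NULL) {
  accepted <- map$table[map$table$accepted, , drop = FALSE]
  entries <- lapply(seq_len(nrow(accepted)), function(i) {
    e <- as.list(accepted[i, ])
    e$name <- if (!is.null(concept_names) &&
                  e$disease %in% names(concept_names))
      unname(concept_names[[e$disease]]) else e$disease
    e
  })
  jsonlite::write_json(
    list(entries = entries,
         n_compared = map$n_compared, n_accepted = map$n_accepted,
         options = map$options),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(tsv_path)) {
    utils::write.table(map$table, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read an age map written by [write_age_map()]
#'
#' @param path JSON path.
#' @return An `age_map`.
#' @export
read_age_map <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  tab <- as.data.frame(j$entries)
  if (nrow(tab) == 0L) {
    tab <- data.frame(disease = character(), shift_days = integer(),
                      r = numeric(), r2 = numeric(), n_overlap = integer(),
                      accepted = logical())
  }
  tab$accepted <- TRUE
  structure(list(table = tab[, c("disease", "shift_days", "r", "r2",
                                 "n_overlap", "accepted")],
                 n_compared = j$n_compared, n_accepted = j$n_accepted,
                 options = as.list(j$options)),
            class = "age_map")
}
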