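# Dictionary matching of snippets against the disease lexicon, plus the
# strain and gender assignment rules.

# Token-boundary literal matching; boundaries are alphanumeric transitions
# so that terms containing '/' or '-' (e.g. strain names) match whole.
literal_matches <- function(text, term) {
  re <- paste0("(?<![A-Za-z0-9])",
               gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", term),
               "(?![A-Za-z0-9])")
  m <- gregexpr(re, text, perl = TRUE, ignore.case = TRUE)[[1L]]
  if (m[1L] == -1L) return(NULL)
  data.frame(start = as.integer(m),
             end = as.integer(m) + attr(m, "match.length") - 1L)
}

#' Match disease/phenotype concepts in a snippet
#'
#' Case-insensitive, token-boundary dictionary matching against the
#' lexicon. Longer surface forms win over shorter ones at overlapping
#' positions ("diabetes mellitus" suppresses "diabetes"), and repeated
#' hits of the same concept are collapsed to one match per concept.
#'
#' @param snippet Text to scan.
#' @param lexicon A [build_lexicon()] result.
#' @return Data frame with columns `concept_id`, `surface`, `source`,
#'   `char_start`, `char_end`; zero rows when nothing matches.
#' @export
match_phenotypes <- function(snippet, lexicon) {
  stopifnot(inherits(lexicon, "disease_lexicon"))
  if (nrow(lexicon$entries) == 0L) {
    stop("empty lexicon: nothing to match against", call. = FALSE)
  }
  entries <- lexicon$entries[order(-nchar(lexicon$entries$surface)), ,
                             drop = FALSE]
  out <- data.frame(concept_id = character(), surface = character(),
                    source = character(), char_start = integer(),
                    char_end = integer(), stringsAsFactors = FALSE)
  taken <- matrix(numeric(0), ncol = 2)
  for (k in seq_len(nrow(entries))) {
    hits <- literal_matches(snippet, entries$surface[k])
    if (is.null(hits)) next
    for (i in seq_len(nrow(hits))) {
      if (nrow(taken) &&
          any(hits$start[i] <= taken[, 2] & hits$end[i] >= taken[, 1])) next
      taken <- rbind(taken, c(hits$start[i], hits$end[i]))
      out <- rbind(out, data.frame(
        concept_id = entries$concept_id[k],
        surface = substr(snippet, hits$start[i], hits$end[i]),
        source = entries$source[k],
        char_start = hits$start[i], char_end = hits$end[i],
        stringsAsFactors = FALSE))
    }
  }
  out <- out[!duplicated(out$concept_id), , drop = FALSE]
  out <- out[order(out$char_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign gender to a snippet
#'
#' A gender is assigned only when exactly one gender term class
#' (male/males vs female/females) occurs in the snippet.
#'
#' @param snippet Text to scan.
#' @return `"male"`, `"female"` or `"none"`.
#' @export
assign_gender <- function(snippet) {
  has_male <- grepl("\\bmales?\\b", snippet, ignore.case = TRUE, perl = TRUE)
  has_female <- grepl("\\bfemales?\\b", snippet, ignore.case = TRUE,
                      perl = TRUE)
  if (has_male && !has_female) "male"
  else if (has_female && !has_male) "female"
  else "none"
}

#' Assign a mouse strain to a snippet
#'
#' Returns the first strain-name occurrence in the snippet (ties at the
#' same position broken by the longer name), or `NA` when no strain from
#' the list is mentioned.
#'
#' @param snippet Text to scan.
#' @param strain_list Character vector of strain names.
#' @return A strain label or `NA_character_`.
#' @export
assign_strain <- function(snippet, strain_list) {
  stopifnot(length(strain_list) > 0L)
  best <- NULL
  for (s in strain_list) {
    hits <- literal_matches(snippet, s)
    if (is.null(hits)) next
    cand <- data.frame(strain = s, start = hits$start[1L],
                       len = hits$end[1L] - hits$start[1L] + 1L)
    best <- rbind(best, cand)
  }
  if (is.null(best)) return(NA_character_)
  best <- best[order(best$start, -best$len), , drop = FALSE]
  best$strain[1L]
}

# Default organism exclusion list: snippets mentioning these are assumed
# to describe non-mouse work and are never stored.
DEFAULT_ORGANISM_BLOCKLIST <- c("rat", "rats", "human", "humans",
                                "patient", "patients", "zebrafish",
                                "drosophila")

mentions_blocked_organism <- function(snippet, blocklist) {
  for (term in blocklist) {
    if (!is.null(literal_matches(snippet, term))) return(TRUE)
  }
  FALSE
}
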