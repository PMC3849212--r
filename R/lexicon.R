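# Disease lexicon: surface-form dictionary compiled from an OBO ontology
# plus an optional plain-text term list.

#' Build a disease lexicon from an OBO document and an extra term list
#'
#' Parses `[Term]` stanzas of an OBO 1.2 flat file and collects, for every
#' non-obsolete term, its primary name and all quoted synonyms as
#' lower-cased surface forms mapping to the term's concept id. An optional
#' two-column table of extra concept/synonym pairs (standing in for a
#' licensed vocabulary subset such as UMLS) is appended with source
#' `"term_list"`.
#'
#' Surface-form collisions across concepts are resolved in favour of the
#' concept that appears first in the ontology file (extra terms come after
#' the ontology); each dropped duplicate is reported via [message()].
#'
#' @param obo Path to an OBO file, or a character vector of OBO lines, or
#'   `NULL` for an ontology-free lexicon.
#' @param extra_terms A data frame with columns `concept_id` and `surface`
#'   (optionally `name`), or the path of a two-column TSV
#'   (concept_id, surface form), or `NULL`.
#' @return An object of class `disease_lexicon`: a list with `entries`
#'   (data frame `surface`, `concept_id`, `source`) and `concept_names`
#'   (named character vector concept_id -> preferred name).
#' @examples
#' obo <- c("[Term]", "id: DOID:9351", "name: diabetes mellitus",
#'          "synonym: \"DM\" EXACT []")
#' lex <- build_lexicon(obo)
#' lexicon_size(lex)
#' @export
build_lexicon <- function(obo = NULL, extra_terms = NULL) {
  entries <- list()
  concept_names <- character()

  if (!is.null(obo)) {
    lines <- if (length(obo) == 1L && file.exists(obo)) readLines(obo, warn = FALSE) else obo
    stanzas <- split_obo_stanzas(lines)
    for (i in seq_along(stanzas)) {
      term <- parse_obo_term(stanzas[[i]], stanza_index = i)
      if (is.null(term) || isTRUE(term$obsolete)) next
      concept_names[term$id] <- term$name
      surfaces <- unique(tolower(c(term$name, term$synonyms)))
      entries[[length(entries) + 1L]] <- data.frame(
        surface = surfaces,
        concept_id = term$id,
        source = "disease_ontology",
        stringsAsFactors = FALSE
      )
    }
  }

  if (!is.null(extra_terms)) {
    if (is.character(extra_terms) && length(extra_terms) == 1L) {
      extra_terms <- utils::read.delim(extra_terms, header = TRUE,
                                       stringsAsFactors = FALSE)
    }
    stopifnot(all(c("concept_id", "surface") %in% names(extra_terms)))
    if (nrow(extra_terms) > 0L) {
      entries[[length(entries) + 1L]] <- data.frame(
        surface = tolower(extra_terms$surface),
        concept_id = extra_terms$concept_id,
        source = "term_list",
        stringsAsFactors = FALSE
      )
      extra_names <- if ("name" %in% names(extra_terms)) extra_terms$name else extra_terms$surface
      new_ids <- setdiff(extra_terms$concept_id, names(concept_names))
      concept_names[new_ids] <- extra_names[match(new_ids, extra_terms$concept_id)]
    }
  }

  tab <- if (length(entries)) do.call(rbind, entries) else
    data.frame(surface = character(), concept_id = character(),
               source = character(), stringsAsFactors = FALSE)

  dup <- duplicated(tab$surface)
  if (any(dup)) {
    clash <- tab[tab$surface %in% tab$surface[dup], ]
    real <- tapply(clash$concept_id, clash$surface,
                   function(x) length(unique(x)) > 1L)
    for (s in names(real)[real]) {
      ids <- unique(tab$concept_id[tab$surface == s])
      message("lexicon: surface form '", s, "' claimed by ",
              paste(ids, collapse = ", "), "; keeping first (", ids[1L], ")")
    }
    tab <- tab[!dup, , drop = FALSE]
  }
  rownames(tab) <- NULL

  structure(list(entries = tab, concept_names = concept_names),
            class = "disease_lexicon")
}

#' Number of surface forms in a lexicon
#' @param lexicon A `disease_lexicon`.
#' @return Integer count of surface forms.
#' @export
lexicon_size <- function(lexicon) nrow(lexicon$entries)

#' @export
print.disease_lexicon <- function(x, ...) {
  cat("<disease_lexicon>", nrow(x$entries), "surface forms,",
      length(unique(x$entries$concept_id)), "concepts\n")
  invisible(x)
}

split_obo_stanzas <- function(lines) {
  lines <- sub("\\s+$", "", lines)
  starts <- grep("^\\[Term\\]$", lines)
  if (!length(starts)) return(list())
  any_stanza <- grep("^\\[.+\\]$", lines)
  lapply(seq_along(starts), function(i) {
    from <- starts[i] + 1L
    nxt <- any_stanza[any_stanza > starts[i]]
    to <- if (length(nxt)) nxt[1L] - 1L else length(lines)
    if (from > to) character() else lines[from:to]
  })
}

parse_obo_term <- function(stanza_lines, stanza_index) {
  stanza_lines <- stanza_lines[nzchar(stanza_lines)]
  if (!length(stanza_lines)) return(NULL)
  get_field <- function(key) {
    hits <- grep(paste0("^", key, ":"), stanza_lines, value = TRUE)
    trimws(sub(paste0("^", key, ":\\s*"), "", hits))
  }
  id <- get_field("id")
  name <- get_field("name")
  if (length(id) != 1L || !nzchar(id) || length(name) != 1L || !nzchar(name)) {
    stop("malformed OBO [Term] stanza #", stanza_index,
         ": exactly one non-empty 'id' and 'name' required", call. = FALSE)
  }
  obsolete <- any(grepl("^is_obsolete:\\s*true", stanza_lines))
  syn_lines <- get_field("synonym")
  synonyms <- character()
  for (s in syn_lines) {
    m <- regmatches(s, regexpr('"[^"]*"', s))
    if (!length(m)) {
      stop("malformed OBO [Term] stanza #", stanza_index,
           " (", id, "): synonym without quoted text", call. = FALSE)
    }
    synonyms <- c(synonyms, substr(m, 2L, nchar(m) - 1L))
  }
  list(id = id, name = name, synonyms = synonyms[nzchar(synonyms)],
       obsolete = obsolete)
}

#' Restrict a lexicon to a subset of concepts
#'
#' Used for sensitivity checks: mining output can only shrink when the
#' lexicon shrinks.
#'
#' @param lexicon A `disease_lexicon`.
#' @param concept_ids Concept ids to keep.
#' @return A smaller `disease_lexicon`.
#' @export
subset_lexicon <- function(lexicon, concept_ids) {
  keep <- lexicon$entries$concept_id %in% concept_ids
  structure(list(entries = lexicon$entries[keep, , drop = FALSE],
                 concept_names = lexicon$concept_names[
                   names(lexicon$concept_names) %in% concept_ids]),
            class = "disease_lexicon")
}
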