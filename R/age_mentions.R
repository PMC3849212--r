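# Age-mention detection: a small regular-expression grammar over ages
# expressed in days/weeks/months/years, normalized to days.

# Fixed unit conversions (days per unit). Round values keep all worked
# arithmetic exact; they are recorded in output metadata.
AGE_UNIT_DAYS <- c(day = 1, week = 7, month = 30, year = 365)

.num <- "\\d+(?:\\.\\d+)?"
.unit <- "(day|week|month|year)"
.dash <- "[-–—]"
.rel <- "(under|below|over|above|less than|more than|younger than|older than)"

# Patterns are tried in priority order; lower-priority matches overlapping
# an accepted span are suppressed. Named groups: rel, n1, n2, unit.
age_patterns <- function() {
  list(
    # relational (open-ended) expressions -> inferred = TRUE
    list(kind = "relational", re = paste0(
      "\\b(?<rel>", .rel, ")\\s+(?:the\\s+)?age\\s+(?:of\\s+)?(?<n1>", .num,
      ")(?:\\s+(?<unit>", .unit, ")s?)?\\b")),
    list(kind = "relational", re = paste0(
      "\\b(?<rel>", .rel, ")\\s+(?<n1>", .num, ")\\s+(?<unit>", .unit,
      ")s?(?:\\s+(?:of\\s+age|old))?\\b")),
    # explicit ranges
    list(kind = "range", re = paste0(
      "\\b(?:age\\s+of|aged)\\s+(?<n1>", .num, ")\\s*", .dash,
      "\\s*(?<n2>", .num, ")\\s+(?<unit>", .unit, ")s?\\b")),
    list(kind = "range", re = paste0(
      "\\b(?<n1>", .num, ")\\s*", .dash, "\\s*(?<n2>", .num,
      ")\\s+(?<unit>", .unit, ")s?\\s+(?:of\\s+age|old)\\b")),
    list(kind = "range", re = paste0(
      "\\b(?<n1>", .num, ")\\s*", .dash, "\\s*(?<n2>", .num,
      ")[- ](?<unit>", .unit, ")[- ]old\\b")),
    # point ages
    list(kind = "point", re = paste0(
      "\\b(?<n1>", .num, ")[- ](?<unit>", .unit, ")s?[- ]old\\b")),
    list(kind = "point", re = paste0(
      "\\baged\\s+(?<n1>", .num, ")\\s+(?<unit>", .unit, ")s?\\b")),
    list(kind = "point", re = paste0(
      "\\b(?:at\\s+)?(?<n1>", .num, ")\\s+(?<unit>", .unit,
      ")s?\\s+of\\s+age\\b")),
    list(kind = "point", re = paste0(
      "\\b(?:at\\s+the\\s+|the\\s+)?age\\s+of\\s+(?<n1>", .num,
      ")\\s+(?<unit>", .unit, ")s?\\b"))
  )
}

empty_mentions <- function() {
  data.frame(surface = character(), start_days = numeric(),
             end_days = numeric(), unit = character(), inferred = logical(),
             char_start = integer(), char_end = integer(),
             stringsAsFactors = FALSE)
}

#' Detect age mentions in free text
#'
#' Scans text with a fixed grammar of age expressions: point ages
#' ("6-week-old", "aged 42 days", "at 6 weeks of age"), explicit ranges
#' ("12--15 months of age") and open-ended relational expressions
#' ("under age 30", "older than 8 weeks"). Every match is normalized to
#' days using the conversions day = 1, week = 7, month = 30, year = 365.
#' Relational expressions are flagged `inferred = TRUE`; "under N" yields
#' the interval `[0, N]` and "over N" the interval `[N, Inf)`.
#'
#' @param body Plain text (a single string).
#' @param default_unit Unit assumed when a relational expression carries no
#'   explicit unit ("under age 30"); `"day"` for mouse text, `"year"` for
#'   human text.
#' @return A data frame with one row per mention: `surface`, `start_days`,
#'   `end_days`, `unit`, `inferred`, `char_start`, `char_end`. Point ages
#'   have `start_days == end_days`.
#' @examples
#' detect_age_mentions("C57BL/6 mice aged 6 weeks were examined")
#' @export
detect_age_mentions <- function(body, default_unit = "day") {
  stopifnot(is.character(body), length(body) == 1L)
  stopifnot(default_unit %in% names(AGE_UNIT_DAYS))
  out <- empty_mentions()
  taken <- matrix(numeric(0), ncol = 2)  # accepted [start, end] spans

  for (pat in age_patterns()) {
    m <- gregexpr(pat$re, body, perl = TRUE, ignore.case = TRUE)[[1L]]
    if (m[1L] == -1L) next
    cs <- attr(m, "capture.start")
    cl <- attr(m, "capture.length")
    for (i in seq_along(m)) {
      from <- m[i]
      to <- m[i] + attr(m, "match.length")[i] - 1L
      if (nrow(taken) && any(from <= taken[, 2] & to >= taken[, 1])) next
      grab <- function(name) {
        j <- match(name, colnames(cs))
        if (is.na(j) || cs[i, j] <= 0L) return(NA_character_)
        substr(body, cs[i, j], cs[i, j] + cl[i, j] - 1L)
      }
      unit <- tolower(grab("unit"))
      if (is.na(unit)) unit <- default_unit
      f <- AGE_UNIT_DAYS[[unit]]
      n1 <- as.numeric(grab("n1"))
      row <- switch(pat$kind,
        point = list(start = n1 * f, end = n1 * f, inferred = FALSE),
        range = {
          n2 <- as.numeric(grab("n2"))
          lo <- min(n1, n2) * f
          hi <- max(n1, n2) * f
          list(start = lo, end = hi, inferred = FALSE)
        },
        relational = {
          rel <- tolower(grab("rel"))
          if (rel %in% c("under", "below", "less than", "younger than")) {
            list(start = 0, end = n1 * f, inferred = TRUE)
          } else {
            list(start = n1 * f, end = Inf, inferred = TRUE)
          }
        })
      out <- rbind(out, data.frame(
        surface = substr(body, from, to),
        start_days = row$start, end_days = row$end, unit = unit,
        inferred = row$inferred, char_start = from, char_end = to,
        stringsAsFactors = FALSE))
      taken <- rbind(taken, c(from, to))
    }
  }
  out <- out[order(out$char_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Sentence segmentation: break at [.?!] followed by whitespace and an
# uppercase letter or digit, unless the candidate terminates a known
# abbreviation. Deterministic by construction.
SENTENCE_ABBREVIATIONS <- c("e.g.", "i.e.", "vs.", "et al.", "Fig.",
                            "cf.", "ca.", "approx.", "no.", "St.")

#' Split text into sentence spans
#'
#' @param text A single string.
#' @param abbreviations Trailing strings that block a sentence break.
#' @return Data frame of 1-based character spans `start`, `end`, one row
#'   per sentence.
#' @export
sentence_spans <- function(text, abbreviations = SENTENCE_ABBREVIATIONS) {
  stopifnot(is.character(text), length(text) == 1L)
  m <- gregexpr("[.?!](?=\\s+[A-Z0-9])", text, perl = TRUE)[[1L]]
  breaks <- integer()
  if (m[1L] != -1L) {
    for (p in as.integer(m)) {
      head_txt <- substr(text, max(1L, p - 12L), p)
      is_abbrev <- any(vapply(abbreviations, function(a)
        endsWith(head_txt, a), logical(1L)))
      if (!is_abbrev) breaks <- c(breaks, p)
    }
  }
  starts <- 1L
  for (p in breaks) {
    rest <- substr(text, p + 1L, nchar(text))
    ws <- attr(regexpr("^\\s+", rest), "match.length")
    starts <- c(starts, p + ws + 1L)
  }
  ends <- c(breaks, nchar(text))
  data.frame(start = starts, end = ends)
}

#' Extract the snippet around an age mention
#'
#' Returns the sentence containing the mention plus its immediate
#' predecessor and successor sentences when they exist (at most three
#' sentences, in original order).
#'
#' @param body Abstract text.
#' @param char_start,char_end Character span of the mention within `body`.
#' @return A single string.
#' @export
extract_snippet <- function(body, char_start, char_end = char_start) {
  if (char_start < 1L || char_end > nchar(body) || char_start > char_end) {
    stop("mention span [", char_start, ", ", char_end,
         "] lies outside the abstract body", call. = FALSE)
  }
  sp <- sentence_spans(body)
  idx <- which(sp$start <= char_start & sp$end >= char_start)[1L]
  if (is.na(idx)) idx <- nrow(sp)  # span inside trailing whitespace
  lo <- max(1L, idx - 1L)
  hi <- min(nrow(sp), idx + 1L)
  trimws(substr(body, sp$start[lo], sp$end[hi]))
}

# Index of the sentence containing a character position (used to group
# mentions into one evidence instance per age sentence).
sentence_index <- function(spans, pos) {
  idx <- which(spans$start <= pos & spans$end >= pos)[1L]
  if (is.na(idx)) nrow(spans) else idx
}
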