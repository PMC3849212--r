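# Reading and writing the MEDLINE tagged flat-file format (the PubMed
# export format: 4-character tags, ' - ' separator, 6-space continuation
# lines, blank line between records).

#' Read abstracts from a MEDLINE flat file
#'
#' Parses the tagged PubMed export format, keeping the fields the mining
#' pipeline uses: PMID, TI (title), AB (abstract body), DP (publication
#' date; the leading 4-digit year is extracted) and PT (publication type,
#' repeatable; multiple values joined with "|").
#'
#' @param con Path to a MEDLINE file, or a character vector of its lines.
#' @return Data frame with columns `pmid`, `title`, `body`, `year`
#'   (integer, `NA` if absent) and `pub_type`.
#' @export
read_medline <- function(con) {
  lines <- if (length(con) == 1L && file.exists(con))
    readLines(con, warn = FALSE) else con
  # unfold continuation lines (6 leading spaces)
  folded <- character()
  for (ln in lines) {
    if (grepl("^      ", ln) && length(folded)) {
      folded[length(folded)] <- paste(folded[length(folded)], trimws(ln))
    } else {
      folded <- c(folded, ln)
    }
  }
  rec_breaks <- cumsum(!nzchar(trimws(folded)))
  groups <- split(folded, rec_breaks)
  records <- list()
  for (g in groups) {
    g <- g[nzchar(trimws(g))]
    if (!length(g)) next
    tags <- toupper(trimws(substr(g, 1L, 4L)))
    vals <- trimws(sub("^.{4}-\\s*", "", g))
    field <- function(tag) vals[tags == tag]
    pmid <- field("PMID")
    if (!length(pmid)) next
    if (!nzchar(pmid[1L])) {
      stop("MEDLINE record with empty PMID field", call. = FALSE)
    }
    dp <- field("DP")
    year <- if (length(dp)) {
      y <- regmatches(dp[1L], regexpr("\\d{4}", dp[1L]))
      if (length(y)) as.integer(y) else NA_integer_
    } else NA_integer_
    body <- paste(field("AB"), collapse = " ")
    records[[length(records) + 1L]] <- data.frame(
      pmid = pmid[1L],
      title = paste(field("TI"), collapse = " "),
      body = body,
      year = year,
      pub_type = paste(field("PT"), collapse = "|"),
      stringsAsFactors = FALSE)
  }
  out <- if (length(records)) do.call(rbind, records) else
    data.frame(pmid = character(), title = character(), body = character(),
               year = integer(), pub_type = character(),
               stringsAsFactors = FALSE)
  if (anyDuplicated(out$pmid)) {
    stop("duplicate PMIDs in corpus: ",
         paste(unique(out$pmid[duplicated(out$pmid)]), collapse = ", "),
         call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

medline_fold <- function(tag, value, width = 80L) {
  words <- strsplit(value, " ", fixed = TRUE)[[1L]]
  lines <- character()
  cur <- sprintf("%-4s- ", tag)
  first <- TRUE
  for (w in words) {
    cand <- if (first) paste0(cur, w) else paste(cur, w)
    if (nchar(cand) > width && !first) {
      lines <- c(lines, cur)
      cur <- paste0("      ", w)
    } else {
      cur <- cand
    }
    first <- FALSE
  }
  c(lines, cur)
}

#' Write abstracts as a MEDLINE flat file
#'
#' @param records Data frame as returned by [read_medline()].
#' @param path Output path; when `NULL` the lines are returned invisibly
#'   instead of written.
#' @return The lines, invisibly.
#' @export
write_medline <- function(records, path = NULL) {
  out <- character()
  for (i in seq_len(nrow(records))) {
    out <- c(out, medline_fold("PMID", records$pmid[i]))
    if (nzchar(records$title[i]))
      out <- c(out, medline_fold("TI", records$title[i]))
    out <- c(out, medline_fold("AB", records$body[i]))
    if (!is.na(records$year[i]))
      out <- c(out, medline_fold("DP", as.character(records$year[i])))
    if (nzchar(records$pub_type[i])) {
      for (pt in strsplit(records$pub_type[i], "|", fixed = TRUE)[[1L]])
        out <- c(out, medline_fold("PT", pt))
    }
    out <- c(out, "")
  }
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}
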