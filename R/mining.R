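# Corpus mining: age detection -> snippet -> phenotype/strain/gender
# assignment -> organism filter, with per-stage counts, plus the
# evaluation harness against gold annotations.

#' Mine an abstract corpus for age-disease evidence
#'
#' Runs the three-stage pipeline over every abstract: (1) detect age
#' mentions, (2) build one snippet per sentence containing at least one
#' mention (the sentence plus its neighbours), (3) map the snippet to
#' lexicon concepts, a strain and a gender. One evidence instance is
#' produced per (abstract, age sentence) pair. Instances whose snippet
#' contains no phenotype match, or mentions an organism from the
#' blocklist, are discarded and counted, never stored.
#'
#' @param corpus Data frame from [read_medline()].
#' @param lexicon A [build_lexicon()] result (must be non-empty).
#' @param strain_list Character vector of strain names (may be empty).
#' @param blocklist Organism terms that disqualify a snippet; defaults to
#'   a small non-mouse organism list.
#' @param default_unit Unit assumed for unitless relational ages.
#' @return An object of class `evidence_set`: a list of evidence
#'   instances, each a list with fields `pmid`, `snippet`, `ages` (data
#'   frame of mentions), `phenotypes` (data frame of concept matches),
#'   `strain`, `gender`, `year`, `pub_type`. Per-stage counts are attached
#'   as `attr(, "stats")`.
#' @export
mine_corpus <- function(corpus, lexicon, strain_list = character(),
                        blocklist = DEFAULT_ORGANISM_BLOCKLIST,
                        default_unit = "day") {
  stopifnot(inherits(lexicon, "disease_lexicon"))
  if (nrow(lexicon$entries) == 0L) {
    stop("mine_corpus: the lexicon is empty", call. = FALSE)
  }
  stats <- c(abstracts_in = nrow(corpus), age_related = 0L, snippets = 0L,
             excluded_organism = 0L, excluded_no_phenotype = 0L,
             instances = 0L)
  instances <- list()
  for (i in seq_len(nrow(corpus))) {
    body <- corpus$body[i]
    if (!nzchar(body)) next
    mentions <- detect_age_mentions(body, default_unit = default_unit)
    if (nrow(mentions) == 0L) next
    stats["age_related"] <- stats["age_related"] + 1L
    spans <- sentence_spans(body)
    sent <- vapply(mentions$char_start, function(p)
      sentence_index(spans, p), integer(1L))
    for (s in sort(unique(sent))) {
      stats["snippets"] <- stats["snippets"] + 1L
      in_sent <- mentions[sent == s, , drop = FALSE]
      snippet <- extract_snippet(body, in_sent$char_start[1L],
                                 in_sent$char_end[1L])
      if (mentions_blocked_organism(snippet, blocklist)) {
        stats["excluded_organism"] <- stats["excluded_organism"] + 1L
        next
      }
      phen <- match_phenotypes(snippet, lexicon)
      if (nrow(phen) == 0L) {
        stats["excluded_no_phenotype"] <- stats["excluded_no_phenotype"] + 1L
        next
      }
      strain <- if (length(strain_list))
        assign_strain(snippet, strain_list) else NA_character_
      instances[[length(instances) + 1L]] <- list(
        pmid = corpus$pmid[i], snippet = snippet, ages = in_sent,
        phenotypes = phen, strain = strain,
        gender = assign_gender(snippet),
        year = corpus$year[i], pub_type = corpus$pub_type[i])
      stats["instances"] <- stats["instances"] + 1L
    }
  }
  structure(instances, stats = stats, class = "evidence_set")
}

#' @export
print.evidence_set <- function(x, ...) {
  s <- attr(x, "stats")
  cat("<evidence_set>", length(x), "instances from", s[["abstracts_in"]],
      "abstracts (", s[["age_related"]], "age-related )\n")
  invisible(x)
}

evaluation_result <- function(tp, fp, tn, fn) {
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(
    true_pos = tp, false_pos = fp, true_neg = tn, false_neg = fn,
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    precision = ratio(tp, tp + fp)), class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf(
    "TP=%d FP=%d TN=%d FN=%d | sensitivity=%.3f specificity=%.3f precision=%.3f\n",
    x$true_pos, x$false_pos, x$true_neg, x$false_neg,
    x$sensitivity, x$specificity, x$precision))
  invisible(x)
}

check_same_pmids <- function(predicted_pmids, gold_pmids) {
  only_p <- setdiff(predicted_pmids, gold_pmids)
  only_g <- setdiff(gold_pmids, predicted_pmids)
  if (length(only_p) || length(only_g)) {
    stop("predicted and gold annotations cover different abstracts; ",
         "only in predicted: [", paste(only_p, collapse = ", "),
         "]; only in gold: [", paste(only_g, collapse = ", "), "]",
         call. = FALSE)
  }
}

#' Evaluate a binary flagging task against gold annotations
#'
#' @param predicted,gold Data frames with columns `pmid` and logical
#'   `flag`, covering the same abstract set.
#' @return An `evaluation_result` with confusion counts and sensitivity
#'   (recall), specificity and precision; a metric whose denominator is
#'   zero is reported as `NA` (not applicable).
#' @export
evaluate_flagging <- function(predicted, gold) {
  check_same_pmids(predicted$pmid, gold$pmid)
  p <- predicted$flag[match(gold$pmid, predicted$pmid)]
  g <- gold$flag
  evaluation_result(tp = sum(p & g), fp = sum(p & !g),
                    tn = sum(!p & !g), fn = sum(!p & g))
}

#' Evaluate phenotype mapping against gold concept annotations
#'
#' Treats every (abstract, concept) pair over the supplied concept
#' universe as one classification decision.
#'
#' @param predicted_pairs,gold_pairs Data frames with columns `pmid` and
#'   `concept_id`.
#' @param pmids The full abstract set evaluated.
#' @param concept_ids The concept universe (typically the lexicon's
#'   concept ids).
#' @return An `evaluation_result`.
#' @export
evaluate_phenotype_mapping <- function(predicted_pairs, gold_pairs, pmids,
                                       concept_ids) {
  key <- function(d) unique(paste(d$pmid, d$concept_id, sep = "\r"))
  p <- key(predicted_pairs)
  g <- key(gold_pairs)
  total <- length(pmids) * length(concept_ids)
  tp <- length(intersect(p, g))
  fp <- length(setdiff(p, g))
  fn <- length(setdiff(g, p))
  evaluation_result(tp = tp, fp = fp, tn = total - tp - fp - fn, fn = fn)
}

#' Evaluate a mined evidence set against gold annotations
#'
#' Scores the two mining tasks separately: flagging abstracts as
#' age-related, and mapping abstracts to phenotype concepts.
#'
#' @param instances An `evidence_set` from [mine_corpus()].
#' @param corpus The corpus the instances were mined from.
#' @param gold Gold annotations as produced by [generate_corpus()]: a data
#'   frame with columns `pmid`, `is_age_related` and `concept_ids`
#'   (pipe-separated, empty when none).
#' @param lexicon The lexicon used for mining (defines the concept
#'   universe).
#' @return List with elements `age_flagging` and `phenotype_mapping`,
#'   each an `evaluation_result`.
#' @export
evaluate_mining <- function(instances, corpus, gold, lexicon) {
  check_same_pmids(corpus$pmid, gold$pmid)
  # an abstract is flagged age-related if any age mention was found,
  # stored or not; recompute the flag so distractors count correctly
  flagged <- vapply(corpus$body, function(b)
    nrow(detect_age_mentions(b)) > 0L, logical(1L), USE.NAMES = FALSE)
  predicted_flags <- data.frame(pmid = corpus$pmid, flag = flagged)
  gold_flags <- data.frame(pmid = gold$pmid, flag = gold$is_age_related)

  pred_pairs <- do.call(rbind, c(list(
    data.frame(pmid = character(), concept_id = character())),
    lapply(instances, function(inst)
      data.frame(pmid = inst$pmid, concept_id = inst$phenotypes$concept_id))))
  gold_pairs <- do.call(rbind, lapply(seq_len(nrow(gold)), function(i) {
    ids <- strsplit(gold$concept_ids[i], "|", fixed = TRUE)[[1L]]
    ids <- ids[nzchar(ids)]
    if (!length(ids)) return(NULL)
    data.frame(pmid = gold$pmid[i], concept_id = ids)
  }))
  if (is.null(gold_pairs))
    gold_pairs <- data.frame(pmid = character(), concept_id = character())

  list(
    age_flagging = evaluate_flagging(predicted_flags, gold_flags),
    phenotype_mapping = evaluate_phenotype_mapping(
      pred_pairs, gold_pairs, pmids = corpus$pmid,
      concept_ids = unique(lexicon$entries$concept_id)))
}
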