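---
title: "Mapping disease-specific ages between mice and humans: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping disease-specific ages between mice and humans: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agemapr)
```

## The problem

Mice are the workhorse model of human disease, but a mouse experiment run
at the wrong age can say little about the human condition it models: the
age at which a disease is studied or manifests differs between the
species, and differs *per disease*. `agemapr` estimates, for each
disease, the age offset that best aligns the distribution of ages at
which the disease is discussed in the mouse literature with the
distribution of ages attached to the same disease in humans. The result
is a disease-specific conversion between mouse age (in days) and human
age (in years).

The package covers the whole chain: mining age and disease mentions from
abstracts, storing the evidence in a relational knowledgebase, turning it
into per-species age-disease matrices, correlating the patterns across
species at every possible lag, and clustering diseases by their age
pattern. A seeded synthetic-data generator provides every input with
known ground truth, so each stage is validated end to end.

## Text mining

Abstracts are read from the MEDLINE tagged flat format (`read_medline()`).
Mining proceeds in three stages per abstract:

1. **Age detection.** A fixed regular-expression grammar
   (`detect_age_mentions()`) recognizes point ages ("6-week-old",
   "aged 42 days", "at 3 months of age"), explicit ranges
   ("12–15 months of age") and open-ended relational expressions
   ("under age 30", "older than 8 weeks"). Every mention is normalized
   to days with the conversions day = 1, week = 7, month = 30,
   year = 365. These round constants are a package choice: they keep all
   downstream arithmetic exact and are recorded in every output's
   metadata. Relational expressions are flagged *inferred*; they are kept
   in the evidence store (they are real evidence) but excluded from the
   quantitative matrices, where an open-ended interval has no usable bin.
   Gestational/embryonic ages ("E14.5") are deliberately not captured.

2. **Snippet extraction.** For each sentence containing an age mention,
   the snippet is that sentence plus its immediate neighbours (at most
   three sentences). The symmetric one-sentence window is a deterministic
   choice; sentence boundaries are `[.?!]` followed by whitespace and an
   uppercase letter or digit, with a small abbreviation stoplist
   ("e.g.", "i.e.", "vs.", ...). One evidence instance is produced per
   (abstract, age sentence) pair.

3. **Concept mapping.** Snippets are matched against a disease lexicon
   built from an OBO ontology plus an optional plain-text term list
   (`build_lexicon()`), case-insensitively, on token boundaries, with
   longest-match-wins ("diabetes mellitus" suppresses the contained
   "diabetes") and one match per concept per snippet. Synonym collisions
   across concepts are resolved in file order (first concept wins) and
   logged. A strain is assigned from a user list (first occurrence wins),
   and a gender only when exactly one gender term class occurs in the
   snippet. Snippets mentioning a blocked organism (default list: rat,
   human, patient, zebrafish, drosophila and plurals) are discarded:
   the knowledgebase is about mice. Instances lacking either an age or a
   phenotype are never stored.

Mining quality is scored against gold annotations with
`evaluate_mining()`: sensitivity (recall), specificity and precision for
two tasks — flagging abstracts as age-related, and mapping abstracts to
concepts (every (abstract, concept) pair over the lexicon's concepts is
one decision). Metrics with a zero denominator are reported as `NA`.

## The evidence store

Evidence lives in three TSV tables — `evidence` (snippet, strain, gender,
year, publication type), `evidence_age` (day intervals, inferred flag)
and `evidence_phenotype` (concept links) — joined by `evidence_id`.
Referential integrity is checked on both write and read. Plain TSV was
chosen over a database engine because the contribution is the schema and
the analysis, not the storage; the files round-trip byte-identically.
`query_store()` answers the three browser-style query types (by age, by
phenotype, by both) with conjunctive refinement by year and publication
type; age matching uses closed day intervals, a point age being a one-day
interval.

## Age-disease matrices

`build_matrix()` counts instances per disease per age bin: mouse in
1-day bins over days 0–1028, human in 1-year bins over years 0–120. The
mouse maximum of 1028 days is tied to the mapper's full-length shift
scan (below). Explicit ranges land on their midpoint bin rounded down —
unbiased and deterministic — with a `range_policy = "start"` option for
sensitivity analysis. An instance with several diseases counts once per
disease. `normalize_matrix()` divides each row by its total, controlling
for disease over- or under-representation in the literature; all-zero
rows are dropped, and normalizing twice is an error rather than a silent
no-op. `filter_min_instances()` (default k = 5) removes diseases with
too little evidence before clustering, and `rebin_matrix()` provides the
day-to-week aggregation used to compare resolutions.

## The shift-correlation age map

For a disease present in both matrices, the human pattern
$h_0, \dots, h_{120}$ (year bins) is slid along the mouse pattern
$m_0, \dots, m_{1028}$ (day bins). At shift $s$ the aligned window pairs
$h_y$ with $m_{y+s}$ for $y = 0 \dots \min(120,\, 1028 - s)$, and the
Pearson correlation $r(s)$ is computed over that window. The best shift

$$s^{*} = \arg\max_{s \in \{0,\dots,1028\}} r(s)$$

defines the disease's age map entry; a disease is accepted when
$r(s^{*})^2 > 0.5$ and $r(s^{*}) > 0$. Within the window one human year
bin aligns with one mouse day bin, so the accepted mapping is the
additive rule

$$\text{human years} = \text{mouse days} - s^{*}, \qquad
  \text{mouse days} = \text{human years} + s^{*},$$

queryable in both directions with `mouse_to_human_age()` and
`human_to_mouse_age()`. For example, a disease whose best shift is
99 days maps a 120-day-old mouse to a 21-year-old human.

Design choices that were genuinely open, and how they were settled:

* **Maximize r, not r².** Thresholding r² alone would accept a strongly
  *anti*-correlated pattern pair, which carries no usable age
  equivalence; the default therefore maximizes r and additionally
  requires r > 0. A compatibility mode (`objective = "r2"`) restores the
  permissive squared-correlation criterion.
* **Non-negative shifts only.** The mouse pattern is never assumed to
  precede human year 0.
* **Ties break toward the smaller shift** — the more conservative claim.
* **`min_overlap = 10`**: at extreme shifts the aligned window shrinks;
  windows shorter than 10 bins, or with zero variance on either side,
  are skipped rather than allowed to produce unstable correlations.
* Pearson correlation is invariant under affine rescaling, so raw counts
  and normalized frequencies give identical shifts; the package computes
  on normalized matrices and asserts this invariance in its tests.

## Clustering diseases by age pattern

`cluster_diseases()` computes the correlation distance
$d = 1 - r$ between disease rows (anti-correlated patterns are maximally
distant — deliberately not $1 - |r|$) and applies agglomerative
clustering, average linkage by default with complete and single as
options. Zero-variance rows are removed first. `cut_diseases()` cuts the
tree into k groups and `write_dendrogram()` exports Newick via ape.

## The synthetic-data generator

The generator is first-class, tested code; it defines the study
conditions under which the package validates itself.

* A disease is specified by a Gaussian-mixture age model over human
  years (unimodal or bimodal), an instance count, and a planted shift in
  days; a disease can also be flagged *unrelated*, meaning its mouse
  ages carry no cross-species correspondence.
* `generate_corpus()` builds template abstracts: one evidence sentence
  drawn from ~10 frames covering the grammar's age-phrase variants (the
  frames are data, so coverage is extendable), embedding a sampled age
  — a human year $y$ rendered as the mouse age $y + s$ days in a
  randomly chosen exact unit — and a disease surface form, padded with
  neutral filler sentences. Distractors carry an age but no disease, a
  disease but no age, or neither; organism distractors add a blocked
  term, and inferred distractors use an open-ended age phrase. Gold
  annotations are exact by construction, and all generators are pure
  functions of (specs, parameters, seed).
* `generate_matrix_pair()` skips the text layer: the human row is the
  mixture density on year bins, the mouse row the same values placed at
  day $y + s$ (or independent noise for unrelated diseases), with
  optional mean-1 multiplicative lognormal noise of a given coefficient
  of variation applied cell-wise before normalization.

The default spec set (`example_disease_specs()`) holds five mapped
diseases with planted shifts from 20 to 500 days — including 99, 90 and
265, the shifts behind the package's worked conversion examples — plus
one unrelated disease, 30 instances each. What the templates do **not**
emulate is real PubMed language: paraphrase, negation, hedging,
cross-sentence coreference. Perfect scores on template corpora therefore
validate the pipeline's mechanics (normalization, windowing, filtering,
bookkeeping), not its recall on free text; real-corpus precision would
be lower.

## Numerical choices and problem sizes

* Unit conversions (7/30/365 days) are fixed constants written into
  output metadata.
* Correlation windows with zero variance are undefined (`NA`), never
  coerced to 0.
* The validation suite runs at deliberately desk-sized conditions chosen
  to keep every check exact: ~260-abstract corpora, six diseases, full
  1029-shift scans; 200 replicates for shift recovery under 20%
  multiplicative noise (recovered within ±5 days in ≥95% of replicates)
  and 100 replicates for two-group cluster recovery under 30% noise
  (adjusted Rand index ≥ 0.8 in ≥90%).

## Limitations

* The mining grammar is a reconstruction of the approach, not a port of
  any particular tool's term lists; figures obtained on real corpora
  depend on the corpus snapshot and lexicon versions used.
* The additive shift is a one-parameter alignment; diseases whose
  cross-species age relation is nonlinear (piecewise, proportional) will
  be rejected or mis-shifted by design, and nonlinear warping is out of
  scope.
* Human ages enter at year resolution; sub-year human structure is
  invisible to the mapper.
* Literature-derived age distributions reflect how diseases are
  *studied*, with all attendant reporting biases, not their clinical
  incidence.
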