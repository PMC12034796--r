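---
title: "Precision-oriented retrieval of guideline update signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Precision-oriented retrieval of guideline update signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guidesignal)
```

## The problem

Clinical guidelines are updated through systematic literature reviews whose
Boolean searches aim for near-perfect recall and consequently suffer very low
precision: thousands of references are screened by hand for a handful of
practice-changing trials. Between scheduled reviews, a complementary
*high-precision* surveillance strategy can monitor the literature for
**signal publications** — reports of randomized controlled trials (RCTs)
likely to affect current recommendations — and surface only those, at the
cost of recall that a later full review will recover anyway.

`guidesignal` implements such a surveillance pipeline at desk scale:

1. **Harmonization.** Evidence from publication metadata (Medline-style
   XML), registered trials (registry CSV tables) and a curated
   precision-oncology knowledge base (assertion TSV) is normalized to one
   record schema keyed by concept identifiers (CUIs) from a common
   vocabulary graph. Registry conditions and knowledge-base
   diseases/phenotypes map to *population* concepts, registry interventions
   and knowledge-base therapies to *intervention* concepts.
2. **Population scoping.** Guideline topics are defined by seed concepts;
   the reflexive–transitive descendant closure over the concept hierarchy
   (child → parent edges, multiple parents allowed) expands a topic into the
   full set of population concepts it subsumes, so a trial coded with a
   subtype is retrieved for the parent topic.
3. **The filter cascade.** A conjunctive ladder of per-record predicates —
   source, date window, population match, RCT flag, minimum trial phase,
   pediatric exclusion, statistical significance, and the guideline-context
   filters — trades recall for precision one notch at a time.
4. **Guideline contextualization.** Each trial intervention stands in one
   of three relations to the current guideline: `IN_RECOMMENDATION`
   (mentioned inside a recommendation section — dominates), `MENTIONED`
   (anywhere else), or `ABSENT`. A *known* intervention is any non-`ABSENT`
   one; an *unknown* intervention is an `ABSENT` concept not on the
   generic-concept stoplist.
5. **Evaluation.** Screening logs from real update projects provide
   ground-truth relevance labels; retrieval is scored with a three-way
   confusion accounting that acknowledges references the screeners never
   saw.
6. **Time lags.** Across guideline versions, newly recommended
   interventions are identified and the elapsed time from first-in-human
   trial to recommendation is decomposed into trial-to-publication and
   publication-to-recommendation legs.

## Scoring with unknown relevance

Screening logs label only the references the reviewers screened (plus a few
system results they reviewed on request). A retrieved reference can
therefore be a true positive (labelled relevant), a false positive
(labelled irrelevant), or simply *unlabelled*. `score_retrieval()` keeps the
three categories separate, and `retrieval_metrics()` computes

$$\mathrm{precision} = \frac{TP}{TP + FP}, \qquad
  \mathrm{recall} = \frac{TP}{TP + FN}, \qquad
  F_1 = \frac{2PR}{P + R},$$

with unlabelled retrieved items **excluded from the precision
denominator**. This is not a stylistic choice: an unlabelled reference is no
evidence of a retrieval error, and the confusion identities of the bundled
benchmarks ($TP + ? + FP = \text{retrieved}$ and $TP + FN = |\text{relevant}|$
on every cascade row) only hold under this accounting. Undefined metrics
(zero denominators) are reported as `NA`, never zeroed. Display values are
rounded to two decimals, half away from zero, applied to the
double-precision ratio; raw values are carried alongside in every report.

## Constructing ground truth from screening logs

`construct_dataset()` replays the manual screening pipeline: duplicate rows
are dropped; title–abstract and full-text exclusions are applied; excluded
references that are already cited in a previous guideline version are
reinstated as included (if the system retrieved them, treating them as
errors would be wrong); references added through manual review of system
output, and system results already cited in the current version, enter with
their manual labels; finally both sides are restricted to RCTs, which is the
ground truth used for retrieval evaluation. References that never received a
decision have unknown relevance and belong to neither set. The per-stage
counts are reported so the bookkeeping of an external screening export can
be verified line by line.

Deduplication keys references by PMID when present, else by lower-cased
DOI, else by case-folded, punctuation-stripped title plus year (exact match
on the normalized form). Logs that begin at the full-text stage (no
title–abstract decisions recorded) are handled by leaving that column
empty.

## The bundled benchmarks

`benchmark_fixtures()` reconstructs, deterministically and entirely in
code, the two guideline-update evaluation settings the package is
calibrated against: the completed oesophageal-cancer update (3147 screened
references, 139 duplicates, 35 relevant / 296 irrelevant RCTs after all
steps) and the ongoing Hodgkin-lymphoma update (168 full-text-screened
references, 40 relevant / 35 irrelevant RCTs). Each fixture contains a
synthetic screening log reproducing those stage counts and a corpus whose
planted phase, significance, pediatric and intervention-context attributes
reproduce the published cascade confusion counts cell by cell (e.g.
precision rising from 0.18 to 0.45 for oesophageal cancer and from 0.73 to
1.00 for Hodgkin lymphoma as filters accumulate). The construction is
assignment, not sampling: identifiers are opaque and synthetic, but every
count is exact. These fixtures are the package's acceptance surface — the
test suite asserts every cell.

## Design choices where the design was open

* **Phase thresholds.** Phases are ordered
  `EARLY_1 < P1 < P1_2 < P2 < P2_3 < P3 < P4`; records with unknown phase
  fail *any* threshold (precision-first). For threshold tests, mixed
  designations are promoted to their higher component — a phase I/II trial
  passes "phase ≥ II" — because the most advanced claim in the design is
  what a reviewer would examine.
* **Filter nesting.** The known-intervention and unknown-intervention
  filters can be combined; the bundled ladders apply the unknown filter on
  top of the known one (a record must carry both a guideline-known and a
  guideline-absent intervention), matching the nested layout of the
  benchmark tables. Both filters are also usable standalone.
* **Date window.** The search window is a closed interval
  `[date_min, date_max]` on the record date (publication date, else results
  posting, else trial start). Screening-log header dates are read day-first
  (`09/01/2019` = 9 January 2019), consistent with the benchmark search
  windows.
* **Significance.** A trial is significant iff any structured outcome
  analysis has p < 0.05 (strict); the structured flag takes precedence over
  the rule-based abstract classifier, which parses p-value expressions and
  affirmative/negated significance phrases. Records with unknown
  significance are dropped by the significance filter.
* **Pediatric exclusion** consults a configurable concept set (typically
  the descendant closure of child/adolescent seeds) against a record's
  population concepts; the mechanism is deliberately data-driven rather
  than hard-coded.
* **Annotation baselines.** The NLP components a production system would
  use (neural NER/normalization, PICO tagging, significance classification)
  are replaced by deterministic baselines behind plug-in contracts:
  dictionary annotation is case-insensitive, longest-leftmost at token
  boundaries, ties broken by smallest concept id; PICO spans come from
  structured-abstract headers, with the whole abstract used when
  unlabelled. Any function with the same signature can be plugged in.
* **Cycles are hard errors.** The concept hierarchies this package consumes
  are curated; silently breaking a cycle would hide a data bug.
* **Time lags** are measured in 365.25-day years. The recommendation date
  is the release date of the guideline version that first recommends the
  concept (no finer dating is available in guideline metadata). "First
  trial in humans" is the earliest start date over all phases including
  early phase 1. The first result publication is by default the earliest
  over all trials of the intervention; a flag restricts it to
  phase-III-or-later trials (the "pivotal trial" reading). Negative
  publication-to-recommendation lags are legitimate and preserved. New
  interventions must pass four quality filters: mention confidence ≥ 0.1,
  not on the generic-intervention stoplist, semantic type T121
  (pharmacologic substance) or T061 (therapeutic/preventive procedure), and
  at least one trial in the corpus.

## What the synthetic generator does and does not emulate

`generate_graph()` / `generate_corpus()` produce seeded, reproducible
corpora with *planted* attributes: every property a pipeline stage should
recover (population match, RCT flag, phase, pediatric population,
significance, known/unknown intervention context, relevance label) is
assigned per record and then made true by construction. This supports exact
plant-and-recover testing: cascade survivor counts, dataset sizes and lag
summaries must equal the planted values with no tolerance.

The generator emulates the *structure* of real sources — file formats,
concept coding, multi-parent hierarchies, screening-log bookkeeping — but
not their content: abstracts are templated sentences, term lexicons are
one-to-one, annotation is noise-free, and attribute assignments are
independent across records. Passing tests therefore demonstrate that the
pipeline machinery is correct, not that the shipped annotation baselines
reach any particular accuracy on real clinical text; on real data the
quality of upstream annotation bounds retrieval performance, as the
pluggable contracts make explicit.

Default problem sizes (60-concept graphs, 40–200-record corpora, 100
random corpora for the anti-monotonicity property, 200 random DAGs up to
200 nodes for the closure oracle) keep the full suite comfortably fast
while exercising every code path; all sizes are configurable.

## Known limitations

* Real-world absolute statistics (corpus-wide concept counts, the
  multi-year lag distributions of actual guideline programmes) require the
  licensed/remote sources themselves; the package reproduces the published
  evaluation *methodology* and its benchmark arithmetic, not those
  absolute numbers.
* Fuzzy title deduplication is exact-normalized rather than
  similarity-thresholded; references lacking both PMID and DOI with
  typographically divergent titles will not be merged.
* The abstract significance classifier is a regular-expression baseline;
  non-inferiority phrasing and multi-endpoint abstracts are out of its
  scope (the contract accepts a trained replacement).
* Retrieval is article-level; indirect retrieval of publications via links
  from registered trials is supported for timelines but not scored.
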