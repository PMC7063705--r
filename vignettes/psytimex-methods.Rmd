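---
title: "Temporal information extraction for mental-health records: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal information extraction for mental-health records: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psytimex)
```

## The problem

Duration of untreated psychosis (DUP) — the time between first psychosis
symptom onset and the start of adequate treatment — is a clinically
important construct that is rarely available as structured data. In
mental-health EHRs the relevant evidence sits in long narrative letters
and assessments: a first-referral document may run to thousands of tokens
and mix structured header dates, past-history paragraphs and
current-state observations. Recovering onset anchors from such text
requires (i) finding documents likely to describe onset, (ii) detecting
time expressions, and (iii) normalizing them to values that can be placed
on a timeline. `psytimex` implements these three stages plus the
evaluation machinery and a synthetic corpus so that everything is
testable without access to restricted clinical data.

Two domain features drive the design. First, onset is often anchored to
the patient's *age* rather than to a date ("at age 8", "in his teens"),
so age-related references are a first-class expression type
(`AGE_RELATED`) alongside the TimeML-style `DATE`, `TIME`, `DURATION`
and `FREQUENCY`. Second, mental-health narratives are rich in relative
and imprecise expressions whose resolution depends on a document
creation time (DCT) that, in EHR exports, does not always match the
letter date written in the text.

## The value grammar

Every expression normalizes to one variant of a tagged union, each with
a canonical string (`serialize_value()` / `parse_value()`):

| variant | examples | notes |
|---|---|---|
| calendar | `2011`, `2011-05`, `2011-05-03`, `2011-05-03T18:00`, `XXXX-XX-XXT18:00` | granularity follows the surface; placeholders when the date part is unknowable |
| day part | `TMO`, `TAF`, `TEV`, `TNI` | times of day without a clock value |
| period | `P4Y`, `PT15M`, `PXH` | `P (T)? count unit`; `X` is the vague-count placeholder |
| bounded interval | `SIN2007`, `UNT2018` | open-ended durations ("since", "until") |
| range | `(2009, 2012)` | explicit start–end durations, keeping both endpoints |
| age | `P45Y` (current age), `A15Y` (past age) | `A3M` supports infant ages in months |
| categorical | `PAST_REF`, `PRESENT_REF`, `CHILD_REF`, `SCHOOL_REF`, `TEENS_REF`, `ADULT_REF`, `UNI_REF`, `OTHER_REF` | vague deictic and life-stage references |
| `UNRESOLVED` | — | sentinel for surfaces the rules cannot value; never dropped |

Three string-level subtleties are resolved as follows:

* **`P45Y` ambiguity.** A current-age value and a 45-year duration share
  a string. Disambiguation uses only the carrying expression's type
  (`parse_value(s, type = "AGE_RELATED")`), never string inspection.
* **Month/minute collision.** `P3M` is three months; `PT3M` is three
  minutes. The `T` clock marker is positional, so minutes and seconds
  require it and month/week units forbid it. The vague-hours value is
  `PXH` (no `T`), matching its printed form; clock `T` on hour counts is
  permitted but not produced by the normalizer.
* **Bounded anchors.** Bounds accept calendar anchors of any granularity
  (`SIN2007-05` is grammatical although only year-granular anchors occur
  in practice). As a documented extension, anchors may also be life-stage
  references ("since his teens" → `SINTEENS_REF`) and past ages
  ("since age 3 months" → `SINA3M`): no canonical form exists for these
  in the value scheme this grammar follows, and dropping the bound would
  lose onset information that DUP reasoning needs.

Round-trip (`parse(serialize(v)) == v`) and within-variant injectivity
are enforced by property tests.

## Extraction

Extraction is a rule engine (`extract_timexes()`): an ordered table of
case-insensitive PCRE patterns, each carrying a type, a priority and
optional normalization hints, shipped as `extdata/default_rules.tsv` and
replaceable via `load_ruleset()`. Patterns are wrapped in alphanumeric
boundary lookarounds, so rules match whole words only. Overlapping
candidates are resolved longest-match first, then by rule priority, then
leftmost (`resolve_overlaps()`); the result is deterministic and
pairwise disjoint.

Design choices:

* **Prepositions are decisive.** Date/Duration confusion is the largest
  source of annotation disagreement in this domain, and keeping temporal
  prepositions inside the span makes the decision mechanical:
  "since 2007", "until 2018" and "for 4 years" are `DURATION`; a bare
  "2007" is a `DATE`.
* **U.K. date dialect by default.** Ambiguous numeric dates parse
  day-first (`03/05/1966` → `1966-05-03`), with `date_order = "MDY"`
  available; cross-dialect full-date errors are a known failure mode
  when moving between U.K. and U.S. corpora.
* **Full textual dates** with weekday prefixes ("Friday 5 October 2012")
  are covered by a dedicated rule — these were a documented miss in the
  system this package's ruleset is modeled on.
* **Structured header dates are extracted like any date.** Excluding
  them from clinical-history reasoning is a consumer concern, not an
  extractor concern.
* **Non-standard date idioms** ("week 3", "over the weekend") are
  deliberately not covered by the default ruleset; they have no agreed
  gold treatment. The ruleset file format makes such extensions a
  one-line addition.

## Normalization and anchoring

`normalize_timex()` assigns values per type; `tag_document()` combines
extraction and normalization under a DCT policy:

* `STRUCTURED` (default) uses the structured document date;
* `FIRST_IN_TEXT_DATE` re-anchors to the first full date written in the
  text — useful because incorrect structured DCT fields are a measurable
  error source (about an eighth of value errors in the error analysis
  this design follows);
* `OVERRIDE` takes an explicit date.

Numerical and degenerate-input choices:

* **Granularity preservation.** Relative expressions resolve at the
  coarsest unit mentioned: "2 yrs back" under a 2011 anchor is `2009`
  (never a fabricated full date), "3 months ago" is `2010-12`, "2 weeks
  ago" a full date. With no anchor available the result is a placeholder
  calendar value at the same granularity (`XXXX`, `XXXX-XX`,
  `XXXX-XX-XX`) rather than an error or a silent drop.
* **`PRESENT_REF` vs the DCT.** Deictic "now / currently / at this
  time" normalize to `PRESENT_REF`; only the explicit "today" resolves
  to the DCT date. Collapsing the two is a known annotation confusion,
  and keeping them distinct preserves the uncertainty.
* **"last week"-type expressions** normalize as the Monday of the
  preceding ISO week at day granularity when used bare (a `DATE`
  reading); preposition-led forms ("for the last week") take the
  duration reading (`P1W`). This is the main systematic ambiguity in the
  domain and has no agreed resolution; the package picks one reading per
  syntactic frame and documents it.
* **Frequencies** reuse the period template: "twice a week" gives value
  `P1W` with the multiplier stored as `meta$freq_count = 2`, keeping the
  value grammar closed while preserving the rate.
* **Running anchor off by default.** Re-anchoring relative expressions
  to previously mentioned dates is a known error source and
  per-paragraph anchoring is future work; `anchor_context()` carries a
  `last_resolved_date` slot for consumers who opt in.
* Unknown surfaces always receive `UNRESOLVED` and stay in the output.

Age-related post-processing (`postprocess_age()`) distinguishes
current-age attributes ("a 45 year old", "aged 45" → `P45Y`) from past
references ("when he was 15", "at age 8" → `A15Y`) by surface frame,
then falls back to a keyword lexicon for life-stage references
(`default_age_lexicon()`, user-replaceable), and finally to `OTHER_REF`.
For downstream DUP arithmetic, `age_ref_to_range()` maps life stages to
past-age intervals; only the teens range `(A13Y, A19Y)` has a
conventional definition — the other defaults (`CHILD_REF` = 0–12,
`SCHOOL_REF` = 5–18, `UNI_REF` = 18–22, `ADULT_REF` = 18–65) are
explicitly non-authoritative package choices and must be overridden to
match a study's definitions.

## Document triage

`filter_corpus()` implements the four-measure triage that selects
DUP-relevant notes: character length and average line length strictly
above thresholds (defaults 2000 and 30, or corpus percentiles — nearest
rank, 50th/25th — via `percentile_mode`), at least one psychosis symptom
keyword, and strictly more than five extracted time expressions. The
inequality directions are taken literally from their prose statement:
a 2000-character document and a five-expression document are excluded.
Each measure depends only on the document, so the final retained set is
order-invariant; the implementation still applies stages sequentially so
that the expensive time-expression count only runs on survivors, and the
per-stage report reflects the configured order. Keyword matching is
whole-word and case-insensitive without stemming (a conservative
default; a substring mode exists), and the report exposes both
occurrence counts and distinct-term counts since only presence matters
for the filter itself. The shipped 26-term keyword list is a stand-in
assembled from standard psychosis symptom vocabulary — the original
clinician-curated list is external — and is config-replaceable.

## Evaluation

Span agreement uses lenient matching: any character overlap can pair two
expressions, and conflicts are resolved by exact maximum-cardinality
one-to-one matching (Kuhn's augmenting paths; sets are small, and the
test suite checks cardinality against brute-force enumeration). One-to-one
matching is the strictest reading consistent with "a span identified by
both annotators" and prevents double counting. Precision is matches over
the system side, recall over the reference side; the degenerate
empty-set conventions (both empty → 1; one empty → precision 1 by
convention, recall 0) are documented because real corpora never hit
them.

Value accuracy (`acc`) is computed only on matched spans as the share of
identical canonical strings. The relaxed accuracy (`acc*`) re-compares
Time-typed pairs whose values are full date-times on the `Thh:mm`
portion only, so `2011-03-14T18:00` vs `2011-03-13T18:00` counts as a
match — isolating clock errors from the much harder date-part anchoring
problem. Since relaxation only merges equivalence classes, `acc* >= acc`
always. For per-type tables the type of a matched pair is read from the
reference side, with disagreements tallied. Aggregation across documents
is micro (pooled) by default, macro by flag; the choice is unstated in
the evaluation scheme this follows, and pooling matches how the
single-corpus tables are computed.

## The synthetic corpus

`generate_corpus()` produces gold-annotated notes that emulate the
*statistical shell* of mental-health narratives: structured header dates
(visit date, date of birth), long filler paragraphs, and embedded
expressions drawn from surface templates. Distributional defaults with
an external basis: mean 3974 tokens per document, Age_related share
0.089 of expressions, 37% of Date+Time expressions relative, and a 0.6
probability that a document mentions symptom keywords (mirroring the
share of long documents that survive the keyword triage stage). Package
choices without an external anchor, fixed once: expression density of
roughly one per 50 tokens (long assessment letters are timex-rich; this
yields realistic per-document annotation counts in the tens), Date
dominant in the residual type mix (0.55/0.09/0.171/0.10/0.089), a 0.3
vague/categorical share within durations and age references, and a 0.9
header probability. A single integer seed governs everything through
per-document substreams, so generation is reproducible and
order-independent; the generator restores the caller's RNG state.

What the generator does **not** emulate: real clinical language,
misspellings beyond a small variant list, section structure beyond
paragraph breaks, event-anchored expressions ("at the time of
discharge"), de-identification artifacts, or patient trajectories. Gold
values are computed by direct arithmetic on the sampled slots, not by
running the normalizer — so recovery tests are meaningful — but surfaces
are drawn from the template families the ruleset is co-designed to
cover. A green end-to-end recovery test (lenient F1 ≥ 0.95, value
accuracy ≥ 0.90 on 500 documents) therefore establishes that the
pipeline is sound *on the supported surface inventory*; it says nothing
about recall on unrestricted clinical text, where the reference systems
this design follows plateau far below that.

`simulate_second_annotator()` perturbs gold sets (deletions, boundary
jitter that preserves overlap, value corruption guaranteed to change the
string) to exercise the evaluation module at known ground truth: zero
noise must give F1 = acc = 1, a 15% value-error rate must land `acc`
inside the binomial interval around 0.85.

## Known limitations

* The ruleset covers the quoted phrase inventory of its domain plus
  conservative generalizations; it is not a general-purpose tagger, and
  bare month names, weekday-only references and "week 3"-style idioms
  are out of scope by default.
* Interval expressions over times ("from 10 pm to 4 am") and imprecise
  quantities ("for many years") normalize to vague or unresolved values
  rather than rich intervals.
* The i2b2-style XML adapter maps types and preserves foreign value
  strings verbatim; it never converts them into this value scheme, so
  cross-scheme value accuracy is not a meaningful number.
* Patient-level selection windows (e.g. documents within three months of
  service acceptance) need service metadata that no shareable input
  carries; the triage starts from the documents given to it.
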