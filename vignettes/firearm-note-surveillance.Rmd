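---
title: "Rule-based surveillance of firearm-violence exposure in clinical notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based surveillance of firearm-violence exposure in clinical notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(firearmtext)
```

## The problem and the procedure

Structured EHR data understate exposure to firearm violence: ICD-10-CM
external-cause codes capture treated injuries, while witnessing violence,
threats at gunpoint, or bereavement appear — when they appear at all — in
free-text notes. The workflow this package implements is the standard
feasibility study that precedes an NLP classifier: identify patients with
*any* structured indication of exposure, search all of their notes for
firearm keywords, sample hits for manual-style review, categorize what the
keywords actually mean in context, and report the distribution with
small-cell suppression. Every step is a function; every step is tested
against synthetic data with known ground truth.

## Cohort rules

A patient has indication of exposure if either criterion holds:

* **ICD**: at least one diagnosis/problem-list code starting with a
  firearm external-cause prefix, dated inside the ICD window
  (default 2012-01-01 – 2022-12-31, the span of available data).
* **SmartForm**: at least one "exposure to gun violence" response of
  `recent` or `historical`, dated inside the SmartForm window (default
  2022-02-01 – 2022-12-31; the form went live in February 2022).

`source` is `both` exactly when both criteria hold. Diagnosis and
problem-list entries are treated identically, and `recent` vs
`historical` carry no downstream distinction. The firearm code set is a
**parameter**, defaulting to the conventional surveillance families
(W32–W34 accidental, X72–X74 self-harm, X93–X95 assault, Y22–Y24
undetermined, Y35.0 legal intervention); published studies rarely print
their exact list, so any cohort count should be read as code-set
dependent. Prefix matching is case- and dot-insensitive so 7th-character
encounter extensions ("W34.00XA") qualify.

## Matching: substring by default

`find_matches()` matches lexicon terms case-insensitively as literal
substrings, reporting 0-based character offsets into the original text
and all overlapping occurrences (including self-overlaps of a single
term). Substring mode is the default deliberately: surveillance keyword
search favors sensitivity, and the interesting false positives —
"Gunther", "nailgun", "snap shot", "gunpoint" inside a longer token —
only arise under substring matching. They are handled downstream by the
categorizer and refinement filters rather than being invisibly excluded.
`word_boundary` mode is available where precision matters more. Matching
operates on case-folded text; offsets always index the original. Each
match carries a context window of 60 characters per side by default — a
value wide enough to span a clinical clause, narrow enough that cues from
a neighboring sentence rarely intrude; it is configurable everywhere.

## Categorization rules

Each match is assigned one of seven mutually exclusive categories. For a
single match, categories are tried in a fixed order that puts
exclusion-like, highly specific rules first: keyword inside a name,
template phrase, explicit "other" confounders (nailgun, snap shot), then
treatment/care, guidance and education, assessment, and exposure; a match
firing nothing is `other`. Two structural rules need no cue list:

* **proper name** — the match sits inside a token whose original casing
  begins uppercase and whose length exceeds the term's ("Gunther" vs
  "gun"). A capitalized token of exactly the term's length ("GSW",
  sentence-initial "Shot") is *not* a name. One known edge: a
  sentence-initial capitalized plural ("Guns in the home…") trips the
  length test for the singular term; the shipped cue lists and synthetic
  templates phrase such sentences with lowercase "guns", and rule files
  can add cues where local note style differs.
* **template phrase** — the context contains a configured SmartPhrase
  such as `[Shot for Birth Control: Care Instructions.]`.

Cue evaluation is two-pass. In the first pass a cue only fires if one of
its occurrences **overlaps the matched term itself** — "no guns" elsewhere
in the window cannot relabel a "hears gunshots" match; in the second pass
plain containment anywhere in the window suffices (this is what lets
"Shot of Hepatitis A." reach `treatment_care` although the cue
"hepatitis" does not touch "shot"). Within each pass the category order
above is respected.

A multi-match note takes the highest-precedence match label, with
precedence exposure > assessment > guidance/education > treatment/care >
template > name > other. Putting exposure first is a sensitivity choice:
a note with any exposure evidence is an exposure note. Published chart
reviews report one category per note without stating their tie-break, so
both orders are configurable in the YAML rules file and the defaults are
documented here as this package's decisions.

## Refinement filters

`apply_refinement_filters()` partitions matches into kept and removed,
each removal tagged with the first applicable reason: `template_phrase`,
`proper_name`, `injection_shot` ("shot" with an injectable cue —
immunization, vaccine, hepatitis, DMPA, cortisone, birth control, flu —
in context), `pain_shooting` ("shooting" with "pain" in context and no
other firearm term nearby). "No other firearm term" is operationalized
as: no other match within this match's context window whose surface is
something besides *shot*/*shooting* — so "shooting pain after gunshot
wound" is kept, "shooting pain all the way down" is removed. Removal
never alters stored matches; the result retains both partitions so a
labeled training set can include the negatives, which is precisely what
refinement is for.

## Synthetic data: what it does and does not emulate

`generate_population()` draws patients with indication sources from the
mixture (66.4% ICD, 33.3% SmartForm, 0.3% both), qualifying events dated
uniformly inside the study windows (plus non-qualifying filler
diagnoses and SmartForm "none" answers), 1–5 notes per patient, and 30%
decoy notes with no firearm term (a twentieth of decoys are empty, like
refill requests). Non-decoy notes instantiate phrase templates per
category, with slot fillers (body sites, injectables, relatives,
"Gun-" surnames); the category mixture defaults to the 90-note review
distribution 13/36/20/16/2/2/1 over 90. Ground-truth spans are recorded
exactly as the matcher finds them, and the shipped rules recover the
truth category for 100% of template notes — that consistency is a design
property, verified by test, that makes generated corpora usable as
labeled ground truth.

What passing tests on this corpus shows: the plumbing is correct — exact
offsets, partition properties, determinism, funnel monotonicity, mixture
recovery within binomial error, suppression behavior. What it does not
show: performance on real clinical language. Real notes paraphrase,
misspell, negate at a distance, and copy text forward; template-built
notes do none of that, so the 100% recovery rate is a consistency check,
not an accuracy estimate. Estimating real-world precision/recall is the
job of the chart review and the future classifier, not of this generator.

`make_table3_fixture()` builds the fixed 90-note review set: counts
13/36/20/16 for the four reported categories and 2/2/1 for the three
suppressed cells — those three are only known to be below 10 and to sum
to 5, so the 2/2/1 split is a documented choice among the consistent
allocations. Seeds vary fillers and row order, never counts.

## Sampling and reporting choices

`stratified_sample()` processes strata sequentially (broad, gun_only,
shooting), excluding previously chosen patients, drawing patients then
one qualifying note each, uniformly; eligibility lists are sorted before
drawing so plans depend only on the seed and the hit set. Sequential
exclusion is the simplest scheme achieving cross-category patient
distinctness; a patient eligible for several categories may be consumed
early, and a resulting shortfall is an error, never a silent relaxation.

Percents use half-up rounding (13/90 → 14, 16/90 → 18; banker's rounding
would differ at .5 boundaries) — one decimal in the indication table,
integers in the category table. Suppression displays counts below 10 as
`"<10"` and their percents as `"<5"` (the conventional percent mask for a
suppressed cell, applied only to suppressed rows); exact values are
retained internally and written only under an explicit `unsafe` flag.
There is no complementary suppression — with a known total and a single
small cell, a reader of several tables could in principle difference it
out; the simple threshold rule is the scope here.

## Problem sizes and numerical notes

The test suite and acceptance script run the generator at 150–5,000
patients (up to roughly 15,000 notes), sizes at which mixture-recovery
checks have comfortable power under a 3-standard-error criterion while
the whole suite completes in well under a minute; matcher–oracle
equivalence uses 1,000 random text/lexicon instances against a
brute-force all-positions scan. All randomness flows through explicit
seeds (`withr::with_seed`), so every reported number is reproducible
from the calls shown. Degenerate inputs are defined behavior: empty text
yields an empty match set, empty notes are skipped and counted,
mixtures must sum to 1 within 1e-9, windows must be ordered, and a note
with no matches cannot be categorized (error, not a silent `other`).

## Known limitations

* Cue matching is literal containment: no stemming, no spelling
  correction, no negation-scope parsing beyond the cue phrases
  themselves ("no guns" is an assessment cue, not a parsed negation).
* Copy-forwarded (duplicated) note text is not deduplicated.
* The shipped lexicon is an exemplar set; site keyword lists should be
  supplied as files. Per-category hit rates in real data are unknown —
  the published counts pool all categories — so the generator's
  per-category hit profile is a free parameter.
* The categorizer is a rule engine intended to construct labeled
  training data and triage review, not a validated classifier.
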