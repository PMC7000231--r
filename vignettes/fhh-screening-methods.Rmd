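---
title: "Methods: family-history screening for hereditary cancer risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: family-history screening for hereditary cancer risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fhhscreen)
```

## The problem

Most health systems already hold structured family health history (FHH) —
captured by medical assistants during visit intake — that is sufficient to
decide whether a patient meets guideline criteria for genetic evaluation of
hereditary breast/ovarian (HBOC) or colorectal (Lynch-syndrome) cancer
risk. What is usually missing is a systematic process that evaluates that
FHH at population scale, refers the patients it finds, and tracks the
outreach. `fhhscreen` implements that process as a self-contained pipeline:
FHIR-style ingest → terminology normalization → comment extraction →
pedigree fact base → rule engine → registry → outreach state machine →
disposition reporting, plus a synthetic-cohort generator so the whole
pipeline is testable without any EHR connection.

The design bias throughout is toward **positive predictive value over
sensitivity**: documentation in primary care is incomplete and messy, and a
population-outreach program is better served by flagging patients whose
documented FHH *certainly* meets a criterion than by chasing every possible
match. That bias shows up in three places: exact-match terminology (no
fuzzy matching), the conservative onset-interval semantics, and the rule
that unknown-lineage relatives never combine to satisfy a same-side
requirement in conservative mode.

## Data model

Each relative's raw record carries the local relationship term, a list of
diagnoses (each with an optional structured onset age and an optional short
free-text comment), a capture date, and an optional record-level comment.
Normalization fuses three sources into one fact per relative:

* **Terminology** maps the relationship term to degree (1st/2nd/3rd,
  not-blood, unknown), lineage side, sex, and blood-relative status, and
  maps each condition term to a cancer category (`breast`, `ovarian`,
  `colorectal`, `endometrial`, `pancreatic`, `other_lynch_associated`,
  `other_cancer`, `non_cancer`). Lookup is exact after case folding and
  whitespace collapse; site tables override the built-in defaults;
  unmapped terms are reported, never guessed. Male breast cancer is not a
  separate category — it is derived at rule time as `breast` ∧ relative
  sex male, which keeps the terminology orthogonal to pedigree facts.
* **Comment extraction** recovers what intake staff write in free text:
  ages of onset ("dx at 42", "early 30s", "premenopausal") and lineage
  sides ("maternal side"). A lineage side found in comments fills in an
  unknown lineage but never overrides the structured term; a contradiction
  resets the lineage to unknown and is logged.
* **Onset resolution** prefers the structured age when present; otherwise
  the comment is parsed into an interval.

Within one record, events deduplicate by category (keeping the
lower-bound-minimal onset), so a relative documented twice with the same
cancer cannot double-count toward a "≥ 2 relatives" criterion. Records are
deliberately *not* merged across relatives: nothing in intake
documentation reliably identifies two records as the same person, so each
record counts once. If a site's documentation duplicates relatives across
capture dates, multi-relative criteria will over-count; this is a known
limitation.

## Onset intervals and their conventions

Free-text onsets become closed intervals `[low, high]` in whole years. The
phrase inventory and the interval bounds are a declared convention of this
package (the phrases are what intake staff actually write; published
sources give no bound table):

| phrase family | convention |
|---|---|
| "dx/diagnosed/at/age N" | `[N, N]` (exact) |
| "X0s" | `[X0, X0+9]` |
| "early X0s" | `[X0, X0+3]` |
| "mid X0s" | `[X0+4, X0+6]` |
| "late X0s" | `[X0+7, X0+9]` |
| "premenopausal" | `[0, 50]` |
| "early onset", "young" | `[0, 45]` |

The qualitative bounds are aligned with the criterion thresholds those
phrases clinically signal (≤ 50, ≤ 45), so that a phrase meant to flag
early onset can actually satisfy the criterion it gestures at. The
qualitative table ships as a plain-text file
(`inst/extdata/onset-qualitative.tsv`) so sites can extend it. Extraction
is rule-based (regular-expression grade) and a bare number is never taken
as an age — a cue word must introduce it. The scan is left-to-right; the
earliest-starting match wins, with explicit ages beating decades beating
qualitative phrases on ties.

An age threshold T ("diagnosed at or before T", inclusive) is evaluated
against the interval in one of two modes:

* **conservative** (default): satisfied iff `high ≤ T` — the whole
  uncertainty interval is under the threshold, so a fuzzy onset can only
  fire a criterion it cannot fail. This is the high-PPV choice.
* **optimistic**: satisfied iff `low ≤ T` — overlap suffices.

Unknown onsets never satisfy an age threshold in either mode, and
conservative-met always implies optimistic-met (tested as a property).

## The rule engine

Criteria are declarative data, not code. Each criterion names: the disease
track, the qualifying cancer categories, the minimum number of relatives,
the allowed degrees, an optional onset threshold with how many counted
relatives must individually satisfy it, an optional same-lineage
requirement, an optional relative-sex restriction, and an optional
proband-ancestry gate. A relative counts iff it is a blood relative of an
allowed degree with at least one event in the categories (sex matching if
required). Same-lineage criteria must be satisfiable on a *single* side;
first-degree relatives sit on the proband's own line and count toward
either side, while unknown-lineage relatives count toward a side only in
optimistic mode. The proband's own cancer history is never evaluated —
this is FHH-only screening of unaffected primary-care patients.

The engine is verified against an independent brute-force oracle that
enumerates all relative subsets and lineage assignments (10,000 randomized
cases in the acceptance suite), plus property tests: monotonicity (adding
facts never un-meets a criterion), mode dominance, and trace soundness
(removing the audit-trace relatives un-meets the fired criterion).

The shipped ruleset (version `nccn-2018-derived`,
`inst/extdata/ruleset-nccn-2018-derived.yaml`) encodes criteria derived
from the 2018 NCCN guidelines for HBOC and Lynch-syndrome genetic
evaluation: single early-onset breast relatives (≤ 45), ovarian at any
age, male breast cancer, same-side breast clusters (2 with one ≤ 50; 3 at
any age) on the HBOC track; first-degree colorectal or endometrial ≤ 50
and same-side Lynch-category clusters (2 with one ≤ 50; 3 at any age) on
the colorectal track. An Ashkenazi-ancestry criterion ships disabled
because ancestry flags require a site-specific source (for example an
opt-in mapping from religion codes, which the terminology layer supports
but ships empty). These thresholds are a best-effort transcription of
guideline-derived screening criteria, not a certified clinical artifact;
the engine/config split exists precisely so a site can correct them
without touching code.

## Target population and screening accounting

The target population is patients whose floor age at the screening date is
in [25, 60] (inclusive) with at least one completed primary-care encounter
in the preceding 3 years (window inclusive at both ends). These values are
configurable (`target_population_config()`).

Screening produces one registry entry per patient with any met track.
Patients with documented prior genetic counseling still *count* as meeting
criteria — the exclusion happens after eligibility counting, entering them
with status `prior_counseling_excluded` — so summary accounting follows
the order a screening program reports: total met (by inclusion–exclusion
over the two tracks), then exclusions, then the outreach remainder.
Percentages are rounded half away from zero — 1 decimal for prevalences, 0
decimals for disposition rates — which reproduces standard published
accounting figures from their count pairs (verified over eleven
count/percent pairs in the tests).

## Outreach state machine

Registry lifecycle is an explicit transition table: `identified →
provider_notified → outreach_sent → {scheduled | declined |
consider_future | no_need | unreachable}`; `scheduled →
{appointment_pending | completed_visit}`; `completed_visit →
{tested_negative | tested_positive | completed_no_test}`. Provider
notification precedes patient outreach by 7 days. The initial outreach
message counts as contact attempt 1 and at most three phone attempts
follow, so `unreachable` is only reachable at exactly 4 attempts.
`appointment_pending` is modeled as terminal (it stays in the scheduled
disposition bucket but out of the completed-visit denominator). Histories
are append-only `(timestamp, event, from, to)` rows; replaying a history
onto a fresh entry reproduces the final state, which is the integrity
check after CSV/JSON persistence. Illegal transitions are rejected with
the allowed events named.

The disposition report partitions concluded-outreach entries into five
buckets (scheduled — including everything downstream —, declined, consider
future, unreachable, no need) over that denominator, and computes nested
rates over their own denominators (completed among scheduled; test
outcomes among completed). Zero-denominator rates are reported as
undefined, never 0. Overlapping facts that are not dispositions (e.g.
self-reported prior counseling discovered during outreach) are supported
as annotation flags tallied outside the partition.

## The synthetic cohort generator

`generate_cohort()` emulates the documentation realities the pipeline must
survive, with planted ground truth:

* a configurable fraction of patients is placed in the target population
  (default 0.8); eligibility is planted only inside it;
* planted-eligible patients (defaults: 5% HBOC track, 2% colorectal
  track — deliberately richer than real-world prevalence so small test
  cohorts contain enough positives; real-EHR prevalence is not a
  reproduction target) receive relatives constructed to satisfy one
  randomly chosen enabled criterion;
* planted negatives miss every criterion *by construction*: benign or
  non-criterion cancer categories, at most one criterion-category cancer
  per patient (so multi-relative criteria cannot fire) diagnosed at ≥ 56
  — strictly above every threshold plus the widest decade interval — and
  optional cancer-affected non-blood relatives (spouses) as decoys;
* noise knobs rewrite structured facts into comments: onset ages become
  phrases whose convention interval still satisfies (or still misses) the
  planted criterion; lineage-carrying terms ("maternal aunt") are stripped
  to the plain term with the side moved to the comment; terms are replaced
  by site-local aliases ("mom", "CA breast") covered by the bundled
  mapping table (`site_mapping_table()`), which the generator writes
  alongside the cohort so the output is screenable;
* prior genetic counseling is a demographics boolean (default 1%).

Labels come from the planting construction, never from the engine, so
recovery tests are not circular. All randomness flows through one private
RNG stream seeded from the spec; the same spec and seed give byte-identical
files. Every random draw in the renderer is made unconditionally, so two
runs differing only in a noise fraction see identical streams — the noise
knobs are then monotone by construction, and the tests assert it.

What the generator does **not** emulate: realistic familial aggregation of
cancer, correlated documentation quality, duplicate relatives, non-English
text, and real-world criterion prevalence. Passing recovery tests
therefore demonstrates the pipeline's correctness on well-posed
documentation patterns, not its sensitivity on real EHR data — on real
data, sensitivity is bounded by what intake actually documents.

## Numerical and scale choices

Problem sizes in the test and acceptance suites were chosen to keep the
full run within a few minutes on one CPU while exercising every property
at meaningful scale: 10,000 randomized engine-vs-oracle cases (relatives
capped at 6 so exhaustive enumeration stays exact), planted-cohort
recovery at n = 1,000, and a rendered-comment corpus of ≥ 1,000 phrases.
Partial dates resolve deterministically (year → July 1; year-month → the
15th). Rounding is half-away-from-zero with a representation-error guard.
Registry ordering is lexicographic by patient id, making every pipeline
output reproducible byte-for-byte.

## Worked example

```{r example}
spec <- cohort_spec(n_patients = 200, seed = 7)
gen <- generate_cohort(spec)
cfg <- target_population_config(as_of_date = spec$as_of_date)
out <- screen_population(gen$cohort, gen$table, cfg = cfg)
out$summary
```

```{r example2}
# outreach for one flagged patient
reg <- out$registry
pid <- reg$patient_id[1]
reg <- notify_providers(reg, spec$as_of_date)$registry
reg <- advance(reg, pid, "send_outreach")
reg <- advance(reg, pid, "schedule")
reg <- advance(reg, pid, "visit_completed")
reg <- advance(reg, pid, "test_negative")
disposition_report(reg)
```

## Known limitations

* The shipped criteria are guideline-derived screening stand-ins; a
  clinical deployment must review them against the current NCCN text.
* Exact-match terminology means misspellings land in the unmapped report
  rather than being rescued; that is intentional but means the unmapped
  report must actually be read.
* No relative deduplication (see above).
* The comment extractor covers short English intake phrases only; full
  clinical notes, negation, and non-English text are out of scope.
* Live EHR/FHIR-server integration, portal messaging, and scheduling are
  out of scope; files stand in for those interfaces.
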