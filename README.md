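# fhhscreen

Population screening of family health history (FHH) for hereditary cancer
risk, as an R package. `fhhscreen` is for informatics teams and
genetic-counseling programs who want to evaluate the structured FHH a
health system already collects — at scale, against guideline-derived
criteria — and then manage the resulting referral registry. It implements
the full population-health-management loop:

1. **Ingest** FHIR-R4-style JSON (Patient, Encounter,
   FamilyMemberHistory; Bundle or NDJSON) into an internal cohort.
2. **Normalize** local relationship and diagnosis terms to pedigree
   concepts (degree, lineage side, sex, blood-relative status; cancer
   category) through an exact-match term-mapping table.
3. **Extract** fuzzy ages of onset ("early 30s", "premenopausal") and
   lineage sides ("maternal side") from the short free-text comments that
   supplement structured intake FHH.
4. **Evaluate** each target-population patient (age 25–60 with a
   completed primary-care visit in the last 3 years, configurable)
   against a declarative ruleset of NCCN-2018-derived criteria for
   hereditary breast/ovarian and colorectal cancer, with a full audit
   trace per fired criterion.
5. **Manage** the registry through an explicit outreach state machine
   (provider notification → outreach → up to 3 phone attempts →
   scheduling → visit → testing) with disposition reporting.

A synthetic-cohort generator with planted ground truth makes the entire
pipeline testable without any EHR connection.

## The screening rule in brief

Each criterion is data, not code: a patient meets criterion *c* iff at
least `min_relatives` blood relatives of allowed degree (and sex, if
restricted) have a cancer event in `c`'s categories, of whom at least
`min_onset_qualifying` were diagnosed at or before `max_onset_age`
(inclusive), on a single lineage side if required (first-degree relatives
count toward either side). A fuzzy onset interval `[low, high]` satisfies
a threshold T conservatively iff `high ≤ T` — the default, which favours
positive predictive value — or optimistically iff `low ≤ T`. The engine is
verified against an exhaustive subset/lineage-assignment oracle.

## Worked example

```r
library(fhhscreen)

spec <- cohort_spec(n_patients = 200, seed = 7)   # synthetic cohort
gen  <- generate_cohort(spec)
cfg  <- target_population_config(as_of_date = spec$as_of_date)
out  <- screen_population(gen$cohort, gen$table, cfg = cfg)
out$summary
#> Screening summary
#>   screened:                 160
#>   met criteria:             14 (8.8%)
#>     breast/ovarian track:   10
#>     colorectal track:       4
#>     both tracks:            0
#>   prior counseling (excl.): 0
#>   remaining for outreach:   14
```

160 of the 200 generated patients are in the target population; the rule
engine flags 14 (exactly the planted-eligible patients: 10 on the
breast/ovarian track, 4 colorectal — the generator's labels confirm no
false positives). Each registry row carries the fired criteria as an audit
trace:

```r
head(as.data.frame(out$registry)[c("patient_id", "fired_criteria", "status")], 3)
#>   patient_id fired_criteria     status
#> 1     P00015          B1,B4 identified
#> 2     P00022             B4 identified
#> 3     P00042             B2 identified
```

Outreach tracking and reporting:

```r
reg <- notify_providers(out$registry, spec$as_of_date)$registry
pid <- reg$patient_id[1]
reg <- advance(reg, pid, "send_outreach")
reg <- advance(reg, pid, "schedule")
reg <- advance(reg, pid, "visit_completed")
reg <- advance(reg, pid, "test_negative")
disposition_report(reg)
#> Disposition report (n = 1 contacted patients)
#>   scheduled           1 (100%)
#>   ...
#>   completed visit: 1 of 1 scheduled (100%)
#>   of completed: 1 tested negative (100%), 0 positive (0%), 0 not tested (0%)
```

## Command line

A thin CLI over the same functions is installed with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "fhh-screen", package = "fhhscreen"))')
Rscript $CLI simulate --out sim/
Rscript $CLI screen --cohort sim/cohort.ndjson --mappings sim/mappings.tsv \
        --as-of 2019-07-05 --out registry.csv --summary summary.json
Rscript $CLI map-terms --check sim/mappings.tsv --cohort sim/cohort.ndjson
Rscript $CLI track --registry registry.csv --event P00007:notify_provider
Rscript $CLI report --registry registry.csv
```

## Layout

* `R/` — implementation (ingest, terminology, onset extraction, pedigree
  normalization, rule engine, screening, outreach, synthetic cohorts)
* `inst/extdata/ruleset-nccn-2018-derived.yaml` — the shipped criteria
  (edit or replace to localize)
* `inst/extdata/onset-qualitative.tsv` — extensible qualitative onset
  phrase table
* `inst/cli/fhh-screen` — command-line front end
* `vignettes/fhh-screening-methods.Rmd` — the model, its conventions and
  assumptions, design choices, and known limitations
* `tests/testthat/` — unit, property, and acceptance suites

Not in scope: live EHR/FHIR-server queries, patient-portal messaging,
quantitative risk models (Tyrer-Cuzick, BRCAPRO), pedigree drawing, and
genetic-test interpretation. The shipped criteria are guideline-derived
screening stand-ins and not a certified clinical artifact.
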