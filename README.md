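# firearmtext

Surveillance of firearm-violence exposure from electronic health records
(EHRs) usually relies on ICD-10-CM external-cause codes, which capture
acute bodily trauma and little else. Experiences such as witnessing a
shooting, being threatened at gunpoint, or losing a family member to gun
violence surface instead in free-text clinical notes — if they surface at
all. `firearmtext` implements the keyword-search-and-chart-review workflow
that health-informatics teams use to assess this signal before training an
NLP classifier, as reusable, tested R code:

1. **Cohort rules** over structured data: a patient has *indication of
   exposure* if they carry a firearm external-cause ICD code
   (W32–W34, X72–X74, X93–X95, Y22–Y24, Y35.0 by default; configurable)
   in a 2012–2022 window, and/or a "recent"/"historical" value in a
   behavioral-health SmartForm "exposure to gun violence" field from the
   form's February 2022 go-live onward.
2. **Lexicon search** of all clinical notes with a three-category term
   lexicon — broad terms (*firearm*, *GSW*), gun-only terms (*gun*,
   *gunpoint*), shooting verbs (*shot*, *shooting*, *gunshot*) — matched
   case-insensitively as substrings with exact character offsets, so
   hits like "Gunther", "nailgun" and "snap shot" are found (and later
   filtered) rather than silently missed.
3. **Stratified sampling** of notes for review: *n* notes per term
   category, one note per patient, patients distinct across categories,
   reproducible from a seed.
4. **Rule-based categorization** of each sampled note into one of seven
   mutually exclusive context categories — exposure to firearms,
   assessment, guidance and education, treatment planning/care delivery,
   "shot" in a template phrase, keyword inside a name, other — via
   ordered cue rules, plus **refinement filters** that remove matches
   that are proper names (`Gunther`), injection "shots" (immunization,
   DMPA, cortisone, birth control, flu), "shooting" pain, or EHR
   template phrases.
5. **Suppressed reporting**: aggregate tables with half-up-rounded
   percents and small-cell suppression (counts `< 10` display as `"<10"`,
   their percents as `"<5"`).

Because patient-level EHR data cannot be shared, the package ships a
synthetic-data module (`generate_population()`, `make_table3_fixture()`)
that emulates the statistical structure of the study population —
indication-source mixture 66.4% ICD / 33.3% SmartForm / 0.3% both, note
categories mixed as in the 90-note chart review, plus decoy notes and
name/template confounders — so every stage runs and is verified end to
end without any real data.

## Worked example

```r
library(firearmtext)

fx   <- make_table3_fixture(seed = 7)   # 90 labeled review notes, 90 patients
hits <- search_corpus(fx, default_lexicon())
hits
#> <corpus search (substring mode): 90/90 notes with >=1 match; 90/90 distinct patients; 107 matches; 0 empty notes skipped>
#> # A tibble: 3 × 2
#>   category n_patients
#>   <chr>         <int>
#> 1 broad            10
#> 2 gun_only         62
#> 3 shooting         26

labels <- categorize_notes(hits, default_rules())
category_table(labels)
#> Category                                   %    N
#> Exposure to firearms                      14   13
#> Assessment                                40   36
#> Guidance and education                    22   20
#> Treatment planning and/or care delivery   18   16
#> Word "shot" in a template phrase          <5  <10
#> "Gun" in a name                           <5  <10
#> Other                                     <5  <10
#> Total                                    100   90

apply_refinement_filters(hits)
#> <refinement: 83 matches kept, 24 removed (injection_shot 12, pain_shooting 4, proper_name 6, template_phrase 2)>
```

Reading the output: of 90 review notes containing a firearm keyword, only
14% actually document exposure to firearm violence or injury; 40% are
risk-assessment questions ("Do you have any guns in the home?"), 22%
anticipatory guidance ("Remove guns from the home."), and 18% clinical
care where "shot"/"shooting" mean injections or pain. The three remaining
categories each hold fewer than 10 notes and are suppressed in display;
the refinement filters remove exactly those non-violence matches, with a
reason per match.

The whole pipeline — cohort → notes → search → sample → categorize →
report — runs in one call and returns a manifest with the funnel of
counts at each stage:

```r
man <- run_pipeline(run_config(
  generator   = generator_config(n_patients = 500, seed = 2),
  seed_sample = 3))
glance(man)
#> # A tibble: 1 × 7
#>   n_patients_input n_patients_indicated n_patients_with_notes n_notes_searched ...
#> 1              500                  500                   500             1580 ...
```

`tidy()`, `glance()` and `autoplot()` methods are provided for search
results, cohorts, refinement results, tables and manifests.

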