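# caremap

Decision support for community elderly-care planning: identify and
prioritize age-friendly service needs from **dual digital capability
portraits** of older adults.

Community care teams must decide, for each older adult, which services to
offer and how urgently — but self-reported demand is unreliable and
single-dimension functional scores ignore the household context that
determines whether a need can be met at home. caremap encodes each subject
as two ordinal score vectors on a shared 0–4 scale (4 = full capability,
0 = complete loss):

- an individual functional capability portrait
  *A<sub>i</sub>* = (*a*<sub>i,1</sub>, …, *a*<sub>i,28</sub>) over 28
  indicators (basic ADL, continence, mobility, orientation, cognition,
  communication, behavioral/emotional status, sensory function,
  instrumental & social function, chronic-disease status), and
- a family caregiving capability portrait
  *B<sub>i</sub>* = (*b*<sub>i,1</sub>, …, *b*<sub>i,8</sub>) over 8
  indicators in three domains (economic, caregiving, emotional support
  capacity).

Needs are identified in two stages:

1. **Rule-based mapping.** Total rule tables — one rule per (indicator,
   score level), 140 individual + 40 family — translate every capability
   state into candidate service items with an intervention intensity grade
   (1 preventive … 5 full care, grade = 5 − score). Individual and family
   candidates are merged, deduplicating on normalized service identity and
   keeping the higher grade.
2. **Collaborative-filtering re-ranking.** Candidates are scored
   `total = 0.5·severity + 0.3·familyDeficit + 0.2·support`, where severity
   is the trigger's impairment (4 − score)/4, familyDeficit is the
   household's mean impairment for individually triggered items (a weak
   family raises the priority of external services), and support is the
   similarity-weighted prevalence of the same service among the subject's
   k = 5 nearest neighbors by portrait similarity. The ranking is stratified
   into high / medium / low priority (cuts at 2/3 and 1/3). Stage 2 only
   reorders — it never adds or removes candidates.

The package also provides community-level aggregation (`community_profile()`,
`flag_high_risk()`), a correlated latent-Gaussian generator for synthetic
communities (`generate_population()`), CSV/JSON I/O, and a CLI.

## Worked example

"Mr. Zhang" — a frail subject (many ADL scores of 1) in a household with
almost no financial resources (first family score 0) — against a synthetic
community of 20:

```r
library(caremap)
fx <- example_portraits()
zhang <- dual_portrait(fx$zhang_individual, fx$zhang_family)
ind <- load_mapping_matrix("individual_demo", load_registry("individual_v1"))
fam <- load_mapping_matrix("family_v1", load_registry("family_v1"))
pop <- generate_population(generator_profile(n = 20, seed = 2026))
rec <- recommend(zhang, pop, ind, fam)
print(rec, n = 5)
```

```
Service recommendations for zhang (47 candidates, 5 neighbors considered)
                    item_label                  category intensity_grade
       Emergency financial aid financial_welfare_linkage               5
 Government safety-net support financial_welfare_linkage               5
            Medical assistance financial_welfare_linkage               5
      Minimum living guarantee financial_welfare_linkage               5
             Emotional support     psychological_support               4
 priority_level severity family_deficit support total
           high     1.00           1.00   0.000  0.80
           high     1.00           1.00   0.000  0.80
           high     1.00           1.00   0.000  0.80
           high     1.00           1.00   0.000  0.80
           high     0.75           0.75   0.398  0.68
```

Reading the output: the four grade-5 welfare-linkage items come from the
family's `financial_resources = 0` (severity 1) in a household whose overall
weakness also maximizes the family-deficit moderator, so they total
0.5 + 0.3 = 0.8 — top priority. "Emotional support" is lifted into the high
band partly by its neighbor support (0.398): similar subjects in this
community also carry it. Every individually triggered item shares the
family-deficit component (4 − 1.125)/4 = 0.71875, the household's mean
impairment.

The same pipeline runs from the shell:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","caremap.R",package="caremap"))')" \
  simulate --n 20 --seed 7 --out pop.csv
Rscript .../caremap.R recommend --assessments pop.csv --subject S0003 \
  --rules-individual individual_demo --rules-family family_v1 --out rec.json
```

## Fixture provenance

`inst/extdata/mapping_family_v1.csv` is fully transcribed content. In
`inst/extdata/mapping_individual_demo.csv` only the eating, personal
grooming and bathing indicators are transcribed; the remaining 25
indicators carry synthetic placeholder items (marked
`provenance = "synthetic"`) so the 28-indicator engine is exercisable end to
end. See `vignettes/methods.Rmd` for the model, conventions and
limitations.
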