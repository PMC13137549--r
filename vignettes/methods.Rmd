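---
title: "Dual capability portraits and two-stage service-need identification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual capability portraits and two-stage service-need identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caremap)
```

## The problem and the model

Community elderly-care planning needs to know, for each older adult, which
services they are likely to need and how urgently. caremap operationalizes a
dual-capability view of that question. Each subject is described by two
ordinal score vectors on a shared 0–4 scale (4 = full capability, 0 =
complete loss):

* an **individual functional capability portrait**
  $A_i = (a_{i,1}, \dots, a_{i,28})$ over 28 indicators spanning basic ADL,
  continence, mobility, orientation, cognition, communication,
  behavioral/emotional status, sensory function, instrumental and social
  function, and chronic-disease status; and
* a **family caregiving capability portrait**
  $B_i = (b_{i,1}, \dots, b_{i,8})$ over 8 indicators in three domains:
  economic capacity, caregiving capacity, and emotional support capacity.

The individual portrait is the *source* of potential needs; the family
portrait is a *moderator* — the weaker the household's caregiving capacity,
the more of those needs must be met by external community services. Stacking
the vectors of all $N$ subjects gives community matrices
$\mathbf{A} \in \{0..4\}^{N \times 28}$ and
$\mathbf{B} \in \{0..4\}^{N \times 8}$ used for distribution summaries
(`community_profile()`) and high-risk screening (`flag_high_risk()`).

## Stage 1: total rule-based mapping

A mapping matrix is a *total* rule table: exactly one rule for every
(indicator, score level) pair — $28 \times 5 = 140$ rules for the individual
portrait, $8 \times 5 = 40$ for the family portrait — each rule listing one
or more service items with an intervention intensity grade. Totality is the
load-bearing property: it makes stage 1 a deterministic, exhaustive function
of the portrait. `map_portrait()` applies one lookup per indicator;
`merge_candidates()` unions the individual and family candidate lists,
deduplicating on a normalized (casefolded, whitespace-collapsed) label +
category identity and keeping the higher intensity grade while recording all
triggers.

Conventions fixed by this package:

* **Score polarity.** Higher score = greater capability. The shipped rule
  tables map score 4 to preventive, environmental items and score 0 to full
  care, consistent with that polarity.
* **Intensity grade** is $5 - \text{score level}$ in every shipped fixture
  (grade 1 lightest/preventive at score 4, grade 5 heaviest/full care at
  score 0). The rule tables print no numeric grade; the linear inverse is
  the simplest encoding of "lighter needs at higher capability" and makes
  grade monotone in severity within each indicator.
* **Levels are replacements, not accumulations**: the rule at a subject's
  score replaces, rather than adds to, the rules at other levels of the same
  indicator.
* **Category vocabulary.** Service items carry one of ten controlled
  categories (`service_categories()`), from daily-living assistance to
  monitoring; the vocabulary is a package convention used for tagging,
  tie-breaking and community demand summaries.
* **Fixture provenance.** `family_v1` is fully transcribed. The individual
  table `individual_demo` has three fully transcribed indicators (eating,
  personal grooming, bathing); the other 25 × 5 cells carry clearly marked
  synthetic placeholder items (`provenance = "synthetic"`) so that the
  engine is exercisable end-to-end. Content-fidelity tests use only
  transcribed cells.

## Stage 2: collaborative-filtering re-prioritization

Stage 2 never adds or removes candidates; it only reorders them. Each
candidate $c$ of subject $i$ receives

$$\text{total}(c) = w_s \cdot \text{severity}(c)
  + w_f \cdot \text{familyDeficit}(c)
  + w_u \cdot \text{support}(c)$$

with defaults $w = (0.5, 0.3, 0.2)$, all components in $[0,1]$:

* $\text{severity} = (4 - \text{trigger score})/4$ — how impaired the
  triggering capability is (max over triggers for merged duplicates);
* $\text{familyDeficit} = (4 - \bar{B_i})/4$ for individually triggered
  candidates (mean household impairment moderates every individual need) and
  $(4 - \text{trigger score})/4$ for family-triggered ones;
* $\text{support}$ is the user-based collaborative-filtering term: with
  neighbor set $K$ (the $k = 5$ most similar subjects by portrait
  similarity, ties broken by subject id), it is the similarity-weighted
  fraction of neighbors whose own stage-1 candidate set contains the same
  service identity, $\sum_{j \in K} s_j \mathbb{1}[c \in S_j] / \sum_{j \in K} s_j$.

Similarity operates on the normalized concatenation of the two portraits
(length 36, each score divided by 4). Two metrics are available: cosine
(default; the similarity of a zero vector to anything is defined as 0) and
inverse Euclidean $1/(1 + \lVert u - v \rVert)$. They answer different
questions: cosine compares the *profile shape* of impairment and is
insensitive to a uniform shift in overall capability level, while inverse
Euclidean compares *levels*. That is why the cluster-recovery check below
uses the inverse-Euclidean metric: the generator's clusters differ by a
uniform latent shift, which changes magnitude, not direction, of the score
vector, and cosine is structurally blind to it (measured neighbor purity
~0.6 versus ~0.9).

The CF layer operates on neighbors' *rule-derived* candidate sets, not on
observed service utilization: no utilization data exists at assessment time,
so prevalence-among-similar-profiles is the prototype semantics. When
$w_u = 0$ the layer is skipped entirely and the output is literally
invariant to the population argument.

Ranking sorts by descending total with a fully deterministic tie-break
(higher intensity grade, then category order, then label in C-locale order);
no randomness is consumed anywhere in the pipeline. Stratification maps the
total to priority levels with closed lower bounds: high at total
$\ge 2/3$, medium at $\ge 1/3$, else low. The closed-bound convention puts
a total of exactly $2/3$ in the high band.

Weights, $k$, the similarity floor, the metric and the thresholds live in
`similarity_config()`. The fusion weights are a design choice, not an
estimate: severity leads (it is the need's source), family deficit second
(the moderator), CF support last (a refinement layer, matching its role of
adjusting rather than determining the ranking).

## Worked example

```{r example}
fx <- example_portraits()
zhang <- dual_portrait(fx$zhang_individual, fx$zhang_family)
pop <- generate_population(generator_profile(n = 20, seed = 2026))
rec <- recommend(zhang, pop,
                 load_mapping_matrix("individual_demo",
                                     load_registry("individual_v1")),
                 load_mapping_matrix("family_v1",
                                     load_registry("family_v1")))
print(rec, n = 5)
```

With a household mean score of $1.125$, every individually triggered
candidate carries a family-deficit component of $(4 - 1.125)/4 = 0.71875$ —
a weak household uniformly raises the priority of external services.

## The synthetic-community generator

No subject-level dataset is published, so the package generates correlated
ordinal populations from a latent-Gaussian threshold model: each subject
draws a 36-dimensional standard normal vector with exchangeable
within-portrait correlation (default 0.6), a cross-portrait block (default
0.3), and optional per-cluster mean shifts; each coordinate is then cut at
four thresholds into 0–4. The thresholds are equally spaced base quantiles
shifted by a location found by monotone root search (`uniroot`) so the
marginal mean equals the target (default 2.5 — a moderately capable
community). Defaults are placeholders in the sense that no empirical
correlation magnitudes exist to calibrate against; they encode the
qualitative structure (capabilities decline together; individual and family
capability are positively but more weakly coupled).

What the generator emulates: integer 0–4 marginals with a controllable mean,
positive cross-indicator dependence, subpopulation structure, and seeded
reproducibility (ids `S0001`…, no global random state disturbed). What it
does not emulate: indicator-specific marginal shapes, floor/ceiling effects
of real assessment instruments, assessor bias, and missingness. Tests that
pass on generated data therefore certify the engine's algebraic behavior,
not the realism of any particular community.

For the cluster-recovery property the two subpopulations are given latent
shifts of $\pm 1.5$ SD — 3 SD between centers, the package's operational
definition of "well separated".

## Numerical and degenerate-input choices

* Validation is strict: wrong length, non-integers, values outside 0–4 and
  missing values are errors, never coerced or imputed.
* Zero-vector cosine similarity is 0 by convention (avoids 0/0); cosine is
  clamped at 1 against floating-point overshoot.
* Weights must sum to 1 within $10^{-9}$; stratification thresholds must be
  strictly ordered inside (0, 1).
* An empty population is a valid input (CF no-op), not an error; an empty
  candidate merge is an error (a total matrix cannot produce one).
* High-risk policy defaults ($m = 3$ indicators at score $\le 1$) are
  configurable plumbing, not a clinical standard.

Problem sizes used by the test-suite and the reproduction script — 1000
random portraits for the stage-1 oracle check, 1000 random vector pairs for
the similarity oracle, populations of 20/100/1000/2000 for the pipeline,
cluster-recovery, calibration and coupling checks — were chosen as the
smallest sizes at which the binomial/simulation tolerances quoted above are
comfortably discriminating.

## Known limitations

* 25 of the 28 individual indicators carry synthetic rule content; engine
  behavior on them is structurally correct but not content-faithful.
* The CF layer is a prototype over rule-derived candidate sets; it cannot
  learn from actual service uptake, and its weights are conventions.
* Moderation monotonicity (lowering family scores never lowers an
  individually triggered candidate's total) is formula-exact for the
  rule-based components, i.e. whenever $w_u = 0$ or the population is empty.
  With the CF term active, changing the family vector also changes who the
  neighbors are, so the guarantee is not global; the invariant is tested in
  the regime where it is forced.
* Demographics are contextual only: they are carried through I/O but never
  enter validation, mapping or similarity.
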