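---
title: "Phenotype-first triage of inherited bone marrow failure syndromes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotype-first triage of inherited bone marrow failure syndromes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibmfs)
library(dplyr)
```

## The clinical problem

Inherited bone marrow failure syndromes (IBMFS) — dyskeratosis congenita
(DC), Diamond–Blackfan anemia (DBA), Shwachman–Diamond syndrome (SDS),
thrombocytopenia with absent radii (TAR), severe congenital neutropenia
(SCN) and Fanconi anemia (FA) — are rare germline disorders that present
with cytopenias, characteristic physical anomalies and a raised cancer
risk. Where next-generation sequencing is not readily available, the
combination of longitudinal blood counts and careful dysmorphological
examination remains the main route to a working diagnosis. This package
encodes that reasoning as an auditable rule engine: a structured patient
record goes in (HPO-coded features, a CBC time series, screening labs,
family and prenatal history), and a ranked syndrome suspicion comes out,
with every gate and rule evaluation logged.

The engine is a triage aid, not a diagnostic oracle: its output is a
*suspicion* meant to direct confirmatory testing (DEB chromosomal breakage,
telomere length, pancreatic enzymes, targeted sequencing), never to replace
it.

## The decision pipeline

`classify()` runs a fixed pipeline:

1. **Eligibility.** The record must show (a) any cytopenia or bone-marrow
   failure evidence, *or* at least two non-hematological manifestations in
   distinct organ-system groups of the catalog; and (b) at least one of a
   positive family history (consanguinity, endogamy, familial hematologic
   disorder), a physical abnormality, or hematologic onset before 18 years.
   Counting manifestations across *distinct* organ systems prevents two
   synonymous terms in one system from satisfying the gate.
2. **Exclusion.** A positive diepoxybutane (DEB) breakage test is a
   confirmed FA diagnosis and terminates triage. An explicit positive
   acquired-cause screen (nutritional deficiency, viral serology,
   drug/radiation exposure, PNH clone) excludes the record as acquired.
   Unknown results never exclude — they are reported as incomplete work-up.
   This true/false/unknown distinction is load-bearing throughout: absent
   JSON keys parse to unknown, never to negative.
3. **Beacons.** Hereditary-suspicion flags are collected from the history:
   consanguinity of any recorded degree, endogamy (settlement below 5,000
   inhabitants), isonymy, familial hematologic disease, personal early
   malignancy, fetal growth restriction or small-for-gestational-age birth,
   and physical alterations.
4. **Six syndrome rules** (summarised below), each returning a finding with
   matched and missing criteria, a score (the count of matched
   syndrome-specific features) and the pathway through which it fired.
5. **Primary label.** When several rules fire, a fixed precedence picks the
   primary: TAR > SCN > DC > SDS > DBA. The order runs from the most
   structurally specific hallmark (radial-ray aplasia with preserved
   thumbs) to the least (macrocytic anemia), so a rarer, more specific
   pattern is never shadowed by a commoner one; all fired findings remain
   in the result. An eligible, non-excluded record that fires nothing is
   labelled `undefined_IBMFS` — a deliberate catch-all mirroring clinical
   practice, where a substantial fraction of strongly suspected IBMFS
   patients cannot be assigned a specific syndrome on phenotype alone.

### The syndrome rules

| Rule | Hematologic trigger | Phenotype requirement | Phenotype-only arm |
|------|--------------------|-----------------------|--------------------|
| DC   | any cytopenia | ≥ 1 mucocutaneous-triad element | complete triad |
| SDS  | any cytopenia | ≥ 3 of 8 associated features, or positive fecal-fat test | positive fecal-fat test |
| DBA  | macrocytic anemia **with** reticulocytopenia in one measurement | minors add score only | — |
| TAR  | thrombocytopenia (ever) | radial-ray alteration, thumbs *not* absent | — |
| SCN  | persistent or cyclic neutropenia | ≥ 2 of {short stature, CHD, urogenital} | — |
| FA   | any cytopenia | ≥ 1 VACTERL-H/PHENOS feature (≥ 3 without cytopenia) | ≥ 3 features |

Phenotype-only firing is restricted to the three patterns with a true
hallmark (the complete DC triad, exocrine pancreatic insufficiency for SDS,
and a heavy VACTERL-H/PHENOS load for FA); the other syndromes require a
hematologic trigger.

FA is handled as a **referral**, not a primary suspicion: a positive DEB
test is confirmatory and excludes the record upstream, and a documented
negative DEB test stands the pattern down (the evidence is retained as
`pattern_present`, but the finding does not fire — a negative breakage test
rules FA out). Only while the DEB result is outstanding does an
exclusively-FA pattern yield the primary label `FA_referral`, carrying the
action "order DEB test". This keeps the invariant that `undefined_IBMFS`
means *no* rule fired, which would otherwise be unattainable for worked-up
patients whose features overlap the broad PHENOS set (short stature,
neurological findings, pigmentation anomalies are all PHENOS members).

The TAR thumb rule is the one deliberate non-monotonicity in the engine:
asserting thumb *absence* un-fires TAR (absent thumbs point to FA, so an FA
cross-flag is raised instead). A hypoplastic but present thumb does not
veto. Every other rule is monotone in its own criteria set, and the test
suite checks this property on randomized records.

## CBC interpretation and its thresholds

All thresholds live in one config block (`default_config()`), overridable
from YAML; units are hemoglobin g/dL, ANC and platelets cells/µL, absolute
reticulocytes ×10⁹/L, MCV fL.

* **Anemia**: Hb < 10.5 g/dL, a flat pediatric screening reference. An
  age/sex reference table can be substituted via config.
* **Neutropenia**: half-open bands — severe < 500, moderate [500, 1000),
  mild [1000, 1500), normal ≥ 1500 cells/µL. Clinical prose usually quotes
  overlapping bands ("1,000–1,500", "500–1,000"); the half-open convention
  makes the partition exhaustive and deterministic at the shared endpoints
  (1,000 grades mild, 500 grades moderate), and the test suite verifies the
  partition by brute-force sweep.
* **Thrombocytopenia**: platelets < 150,000/µL.
* **Macrocytosis**: age-banded MCV upper limits (108 fL to 6 months, 86 to
  2 y, 87 to 6 y, 95 to 12 y, 98 to 18 y, 100 thereafter; flat 100 fL
  fallback). No single published cutoff governs pediatric macrocytosis, so
  the bands are shipped as config and overridable. With the MCV unknown an
  anemia is reported normocytic by default, with a provenance flag.
* **Reticulocytopenia**: absolute reticulocytes < 20 ×10⁹/L. The DBA
  trigger requires macrocytic anemia and reticulocytopenia *within the same
  measurement*; if reticulocytes were never measured during macrocytic
  anemia the trigger is unknown, not false.
* **Transfusion dependency**: ≥ 2 RBC units within any window of inclusive
  span ≤ 28 days ("per 28 days" read literally); non-RBC products are
  ignored. The implementation (a sorted sliding scan) is checked against an
  O(n²) pairwise oracle on 1,000 random transfusion logs.
* **Persistent neutropenia**: ANC < 1,500 in ≥ 90% of measurements *and*
  never ≥ 2,500. The 90% fraction (rather than "all measurements")
  tolerates isolated post-G-CSF or post-transfusion values, while the 2,500
  ceiling ensures a genuinely normal count still vetoes lifelong
  neutropenia; both are configurable.
* **Cyclic neutropenia**: ≥ 2 downward crossings of 1,500 with at least one
  nadir < 500, over ≥ 4 measurements (shorter series report `FALSE` with an
  `insufficient` flag).
* **Onset** is the age of the *first* CBC meeting any cytopenia criterion —
  records often open with a normal baseline count — with the earliest
  hematologic HPO feature onset as fallback for phenotype-only records.
  Whether clinical onset should instead be the first abnormal clinical
  note is unknowable from counts alone; first-abnormal-CBC is the
  documented choice. Buckets: ≤ 2, > 2–≤ 5, > 5–< 18 years, adult.
* **HbF** is carried as data but no cutoff is enforced (elevated HbF is
  suggestive, not specific, in DBA). Erythrocyte adenosine deaminase is
  likewise not gated on: it is screening support, not a rule input.

## The feature catalog

The package embeds a ~60-term curated slice of the HPO: every term the
rules and summaries reference, plus the parent links needed for descendant
matching (developmental delay counts toward nervous-system abnormality; a
nephrolithiasis assertion counts toward the urogenital group). It is
deliberately not a full ontology — matching outside the embedded graph
never succeeds — which keeps reasoning auditable and the artifact
self-contained. A YAML config can add terms and extend groups, but removing
a rule-required member is rejected.

One curation point deserves mention: clinical sources cite both nail
dysplasia (HP:0002164) and the broader nail abnormality (HP:0001597) for
the DC triad's nail element. The catalog makes HP:0001597 the parent of
HP:0002164 and the DC rule tests the parent's subtree, so either assertion
satisfies the element.

Identifiers are normalized to the zero-padded 7-digit form on read;
truncated codes occasionally seen in print (`HP:001972`, `HP:001,972`) are
repaired with a warning rather than rejected, since the canonical form is
unambiguous.

## The reference cohort and the simulator

`build_reference_fixture()` constructs — deterministically, with no random
number generation — a 48-patient cohort realizing one feasible
patient-level assignment consistent with the cohort-level characteristics
the package is designed to reproduce: group sizes 15 DBA / 9 SDS / 7 DC /
2 TAR / 2 SCN / 13 undefined (35 specific of 48); 46 families with a
sibling pair each in DC and SDS; 23 patients reaching pancytopenia; onset
buckets 22 / 9 / 14 over the 45 patients with any hematologic onset (three
patients — one complete-triad DC and two fecal-fat-positive SDS — have no
hematologic history at all); 10 transfusion-dependent patients; 40
craniofacial, 25 neurological, 23 integument and 21 growth-restricted
patients (8/9 SDS, 8/15 DBA); the complete triad in 4 of 7 DC patients;
29 males / 19 females; evaluation ages with mean 9.02 and SD 6.01 years.
Marginals not pinned by those targets are filled minimally (one patient per
unconstrained cell, normal values elsewhere). Every record is built to
satisfy exactly its intended rule pathway, and the classifier recovers all
48 intended labels — which is the package's central consistency check, not
a statement about real-world accuracy.

`simulate_cohort()` complements the fixture for property testing: features
are sampled independently per patient from per-archetype prevalences
(`default_params()` encodes the reference cohort's observed fractions), CBC
trajectories follow the archetype course with 4% multiplicative log-normal
measurement noise, and each patient draws from its own substream (derived
from the base seed and patient index) so cohorts are reproducible and
patient draws do not interact. The generator marks each record with the
label its sampled features still support: an SDS draw that lands below the
three-feature threshold without a positive fecal-fat test is *expected* to
fall back to `undefined_IBMFS`, and the label-recovery test asserts exactly
that. Noise is clamped where it would blur an archetype's defining trigger
(the DBA macrocytic-reticulocytopenic measurement, the SCN cyclic nadirs);
the point of the simulator is controlled variation around the rules, not
realism.

What the synthetic data does **not** emulate: measurement timing
irregularity, treatment effects (G-CSF, transfusion rebound) inside the
series, feature correlation beyond the archetype structure, missingness
patterns of real charts, or diagnostic ambiguity between overlapping
syndromes. Passing tests on synthetic cohorts therefore demonstrate
internal consistency of the rules and their implementation — they say
nothing about sensitivity or specificity on real patients, which only a
genotyped cohort can establish.

## Statistics

Cohort summaries report counts with both raw and integer-truncated
percentages (clinical tables mix conventions; both are exposed, and the
denominator is always stated — onset categories use the 45 patients with
onset, not 48). Group comparisons use chi-square for categorical variables
(no continuity correction by default, with a low-expected-cell warning
below 5) and one-way ANOVA for continuous ones; both are verified in the
test suite against explicit hand-computed oracles. Descriptives follow the
usual conventions: sample SD (n−1), midpoint median for even n, SD
undefined for a single value.

## Problem sizes and numerical choices

The test suite and acceptance script run entirely at desk scale: the
48-record reference cohort, a 480-record simulated cohort for
label-recovery and prevalence properties, 1,000 random transfusion logs
against the quadratic oracle, and a 3,001-point ANC sweep. Record
constructors round numeric fields to 10⁻⁶ (finer precision is clinically
meaningless) so that JSON serialization is exactly invertible — round-trip
equality is `identical()`, not tolerance-based. Tie-breaks are all
deterministic: precedence is a fixed order, band edges are half-open, and
the audit log is part of the reproducibility contract (identical record and
config give identical audit).

## Known limitations

* The rules operate on *ever*-observed lineage status; a cytopenia that
  resolved years ago still counts, which matches retrospective chart review
  but may over-call on long stable records.
* The SCN associated-feature set is read as the closed 3-member list
  {short stature, CHD, urogenital}; a wider reading ("including") would
  admit more features and fire more often.
* No probabilistic reasoning: rules are crisp thresholds, and near-misses
  (2 of 3 SDS features) score but never fire.
* Telomere length, genotype and treatment response are out of scope; the
  engine stops where confirmatory testing begins.
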