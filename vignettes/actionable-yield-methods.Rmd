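---
title: "Models and methods behind alsyield"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind alsyield}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alsyield)
library(dplyr)
```

# The question the package answers

Amyotrophic lateral sclerosis (ALS) is usually sporadic, yet a substantial
minority of apparently sporadic patients carry a reportable Mendelian variant
or repeat expansion. Several health systems restrict diagnostic genetic
testing to patients with a family history or an onset age below some cutoff
(in the UK, 40 years). `alsyield` implements the full decision chain needed
to quantify what such a policy costs:

1. decide, per person, whether a genetic test result is *clinically
   actionable* (QC → rarity/impact prioritisation → ACMG classification →
   panel and inheritance logic → repeat-expansion thresholds);
2. estimate the probability of an actionable result by onset-age group, with
   binomial confidence intervals;
3. combine those probabilities with age- and sex-specific incidence to
   estimate how many actionable results per year an age-restricted testing
   policy misses.

Because real sequencing cohorts of this kind are access-controlled, the
package includes a synthetic-cohort generator with *planted, analytically
known* ground truth, so that every stage is testable end to end.

# Variant and sample quality control

Site-level rules mirror routine short-read WGS reporting practice, with
removal conditions taken strictly: genotype quality < 10, site quality < 20
(SNVs) or < 30 (indels), missingness > 2%. Boundary values are therefore
retained. Rarity requires allele frequency strictly below 0.001 in **both**
an external non-Finnish-European reference and an internal control set.
Impact is the most severe sequence-ontology consequence term: high (stop
gained/lost, start lost, transcript amplification/ablation, frameshift,
splice acceptor/donor) or moderate (missense, in-frame indel,
protein-altering); everything else is dropped. When a variant carries
several terms the most severe wins — the closest deterministic analogue of
annotating one selected allele per variant.

Sample-level QC removes samples whose Ti/Tv ratio or SNV/indel/singleton
counts fall outside mean ± 6 SD of the *full* input distribution (one pass,
not iterated), samples whose genetically inferred sex contradicts the
reported sex (an `unknown` on either side is not a contradiction — a
mismatch requires positive disagreement), and samples with missing onset
age. Removal reasons are attributed in a fixed order (metric outlier → sex
mismatch → missing age) so audit counts always sum to the input; the same
fixed attribution (site QC → frequency → impact) holds for variants.

# The ACMG engine

The classifier works on the standard 28 evidence criteria (16 pathogenicity:
PVS1, PS1–PS4, PM1–PM6, PP1–PP5; 12 benignity: BA1, BS1–BS4, BP1–BP7).
Seven criteria have automatic evaluators, chosen because they depend only on
fields present in the input schema:

| criterion | evaluator | default threshold |
|---|---|---|
| PVS1 | high impact in a loss-of-function-mechanism gene | gene list (ALS2, FIG4, OPTN, SPG11, TBK1) |
| PM2 | absent/ultra-rare in both reference sets | AF < 1e-4 |
| PM4 | in-frame length change or stop lost | term match |
| BA1 | stand-alone benign frequency | AF > 0.05 |
| BS1 | frequency above disease-based expectation | AF > 0.001 |
| PP3 / BP4 | in-silico score beyond the deleterious / benign cut | ≥ 0.7 / ≤ 0.15 (scaled score in [0, 1]) |

The remaining 21 criteria would require per-variant literature review; at
cohort scale they are *fixed* per impact class through a
`fixed_profile()`. Two documented profiles ship: `conservative` (all manual
criteria forced false) and `permissive` (the manual supporting criteria
PP1/PP2/PP4/PP5 forced true for high-impact variants). The choice is a
sensitivity parameter, not a hidden constant; results should state the
profile used. Custom profiles can force any criterion per impact class; the
numeric cuts above are configuration defaults, not published constants.

Flags are combined by the published combining table (pathogenic, likely
pathogenic, benign, likely benign; VUS when no rule is met **or** when a
pathogenic-side and a benign-side rule are met simultaneously —
contradictory evidence). A subtlety worth making explicit: a lone strong
criterion (say PS1) completes *no* pathogenic rule, so PS1 + 2×BS classifies
benign, not contradictory-VUS; contradiction requires full rules on both
sides. The implementation is vectorised over count sums; the test suite
checks it against an independently hand-coded, rule-by-rule transcription of
the table over *every* profile with ≤ 4 active criteria (~24,000 profiles)
plus 100,000 random profiles, and verifies monotonicity (adding a
pathogenic criterion never moves a variant toward benign).

VUS are sub-stratified: *high probability of pathogenicity* when at least
one pathogenicity criterion is met and no benignity criterion; *low to
medium* otherwise.

# Repeat expansions, panels and actionability

C9orf72 GGGGCC expansions are pathogenic above 30 repeats (larger allele —
the dominant-acting reading when two alleles are reported). ATXN2 CAG
intermediate expansions of 29–33 inclusive are treated as pathogenic ALS
risk alleles; counts above 33 (the SCA2 full-expansion range) are flagged
but not counted as ALS-actionable.

Three panels ship: the four commonest ALS genes (C9orf72, FUS, SOD1,
TARDBP), a 24-gene panel of rare large-effect Mendelian ALS genes, and a
26-gene panel reflecting UK testing practice in which ALS2 — ALS-associated
only in homozygosity — is reported for bi-allelic variants only. The
bi-allelic rule is implemented as *homozygous genotype required*; two
heterozygous variants in the same gene are never combined, because phase is
unknown. A variant is actionable when it survives prioritisation and is
pathogenic, likely pathogenic, or a high-probability VUS; low/medium VUS are
excluded by default (`include_low_vus = TRUE` gives the broader reading in
which only benign/likely-benign calls are excluded — the narrow reading is
the default because it matches the headline composition of actionable
results). A pathogenic repeat is actionable in any panel containing its
locus, so the four-gene panel admits C9orf72 expansions but not ATXN2.
Persons with no reportable finding stay in the denominator.

A corroboration route re-derives the four-gene decision from databases
instead of the ACMG engine: any C9orf72 expansion > 30; any retained rare
SOD1 variant; TARDBP/FUS variants that are ClinVar pathogenic/likely
pathogenic or recorded in the ALS online database with ≥ 1 publication and
≥ 2 patients. On noise-free synthetic cohorts whose database flags are
generated consistently with the planted classes, the two routes agree
exactly (this is a test).

# Yield and its intervals

Onset ages are grouped `<40, 40–49, 50–59, 60–69, ≥70` (left-closed, so 40
belongs to 40–49). Per panel and group the package reports `p = k/n` with a
Wald interval `p ± z·sqrt(p(1−p)/n)`, deliberately *not* clipped to [0, 1].
Wald was chosen because it exactly reproduces the published printed
intervals for 115/117 (0.98, 0.96–1.01) and 56/58 (0.97, 0.92–1.01),
including upper bounds above 1; a Clopper–Pearson exact interval is
available via `method = "exact"` for small strata. Stored values keep full
precision; rounding (half-up, 2 dp for proportions, whole percent for
percentages) happens only at presentation.

# Incidence, standardization and the policy model

Crude rates are cases per 100,000 person-years. Direct standardization
multiplies each stratum's crude rate by the standard population of the same
age-sex cell; with the study population as its own standard this reproduces
the crude overall rate exactly (a 10-significant-digit test). Intervals for
weighted sums of Poisson counts use the gamma exact method: with
`X = Σ w_i d_i`, `V = Σ w_i² d_i`, `w_M = max w_i`,

* lower = gamma quantile(α/2; shape X²/V, scale V/X), 0 when X = 0,
* upper = gamma quantile(1−α/2; shape (X+w_M)²/(V+w_M²), scale (V+w_M²)/(X+w_M)).

With a single stratum of weight 1 this collapses to the Garwood
Poisson-exact interval (tested against the chi-square closed form, and by
Monte-Carlo coverage at nominal 95% over 2000 simulated registers).

All-ALS incidence is converted to sporadic incidence by the factor 0.875,
the midpoint of the 80–95% sporadic share implied by a 5–20% familial
fraction; the adjustment is linear and applied after standardization (the
two operations commute — the order is fixed only for reproducibility).

The missed-results estimator multiplies expected sporadic diagnoses per
year `E_i` (age × sex) by the age-group actionable probabilities `p_i`, and
sums over strata at or above the testing age cutoff (missed) and over all
strata (total). Probabilities default to age-only, shared across sexes —
the granularity at which such yields are published; sex-specific
probabilities are supported through a `sex` column. The missed-proportion
interval is Wald on the rounded counts (`k = round(missed)`,
`n = round(total)`), the scale on which annual counts are reported; this
choice reproduces both published printed intervals.

## Calibration of the UK probability table

`uk_actionable_probabilities()` carries published endpoints (0.23 youngest /
0.17 oldest for the 26-gene panel; 0.11 / 0.06 for the four-gene panel). The
three middle-group probabilities are not published at this granularity, so
they are set to one flat value per panel, calibrated so that the policy sum
over the published expected-diagnosis table reproduces the published annual
actionable totals: 0.222 (26-gene) and 0.122 (four-gene). With those inputs
the estimator returns 115 missed of 117 expected actionable results per
year (26-gene) and 56 of 57 (four-gene; published total 58 — within the ±1
slack that stratum-level rounding of the source table allows). Per-sex
splits under age-only probabilities land within 2 of the published 63/52
male/female break-down, the residual being exactly what sex-specific
probabilities would absorb.

The per-cell standard populations behind the expected counts are likewise
not published; `uk_standard_population()` back-calculates them as
`expected × 1e5 / (rate × 0.875)` and the default synthetic register scales
them to a 12.5-million catchment.

# The synthetic cohort generator

The generator defines the study conditions for all simulation-based tests:
1551 persons, 60% male, onset ages from a normal(65, 12) truncated to
18–95 years (population studies put mean ALS onset near 65), and the
UK-like actionable probabilities above. Per person it draws an actionable
indicator from the age-group probability, then a mechanism: C9orf72
expansion (35%), ATXN2 intermediate expansion (5%), or a sequence variant
(60%) in a gene drawn from configurable weights (C9orf72/ATXN2 weight zero
— their mechanism here is the repeat; the per-gene split of actionable
results is not published, so the weights are documented as arbitrary but
plausible). Planted variants follow explicit recipes whose classification
is analytically known under the conservative profile:

* *pathogenic*: stop-lost SNV in a LoF-mechanism gene, absent from both
  references → PVS1 + PM2 + PM4;
* *likely pathogenic*: frameshift indel in a LoF-mechanism gene, absent →
  PVS1 + PM2;
* *high-probability VUS*: missense in a panel gene, absent, mid-range
  in-silico score → PM2 only.

Class mix defaults to 15/25/60. ALS2 plants are homozygous (so they are
reportable under the bi-allelic rule); UBQLN2 plants in males are
hemizygous. Database flags are generated consistently with the planted
class, which is what makes the corroboration-route identity testable.
Ground truth is emitted in a sidecar table, never in the variant table, so
the pipeline cannot read its own answers.

Noise features are what the QC stage exists to remove: background variants
(default mean 2 per person — common missense, rare synonymous, low-score
VUS, QC-failing sites, heterozygous ALS2 calls), sex-mismatched samples
(0.5%), missing onset ages (1%). At noise zero, pipeline output equals
planted truth *exactly* (an identity test). The generator plants no genome
positions, linkage, haplotypes or reads — nothing downstream depends on
them — so passing tests say nothing about, for example, alignment artefacts
or annotation errors in real data; they do establish that the decision
logic downstream of annotation is correct.

The register generator draws stratum case counts from Poisson(rate ×
person-years / 1e5) with person-years = population × years. A configured
duration of 0 years is accepted and yields zero cases (the degenerate case
is well-defined even though a real register would never use it).

# Numerical and design choices

* All random generation runs under `withr::with_seed`; same config ⇒
  byte-identical outputs, and the user's RNG state is left untouched.
* Filters treat quoted inequalities literally (strict removal conditions,
  strict rarity), so boundary values behave predictably.
* `sd = 0` sample-metric distributions (all values identical) retain
  everyone: the outlier interval degenerates to the mean.
* Wald intervals are unclipped by design; the exact alternative is clipped
  by construction.
* Problem sizes in the shipped tests — 500 seeds × n = 1551 for interval
  calibration, ~124,000 profiles for the engine-oracle comparison, 2000
  registers for gamma coverage — were chosen to keep Monte-Carlo error
  comfortably below the bands being asserted.
* The youngest onset group holds only ~2% of the cohort (~29 of 1551
  persons); at that size the exact coverage of a 95% Wald interval at
  p = 0.23 is 90.6% — a well-known small-sample property of the Wald
  interval, not a defect of the estimator. The calibration test therefore
  checks pooled coverage against the nominal window, each group against its
  *exact* binomial coverage oracle, and the nominal window itself only for
  groups of 100+ persons. For small strata, `method = "exact"` is the
  better reporting choice.

# Known limitations

* The fixed-value approximation cannot reproduce criteria that genuinely
  need segregation, de-novo or functional evidence (PS2, PP1, ...); they
  enter only through the profile.
* Database flags are inputs; there is no live ClinVar/ALSoD lookup.
* Two heterozygous variants in a bi-allelic-only gene are never phased into
  a compound heterozygote, a deliberately conservative choice.
* The policy model is static: no trends, no geography, no repeat testing.
* Synthetic cohorts share none of the linkage structure of real genomes;
  estimates of anything other than decision-logic correctness and interval
  calibration should not be read off them.
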