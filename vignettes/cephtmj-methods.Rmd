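---
title: "Methods: cephalometric measurement, condylar classification and group comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cephalometric measurement, condylar classification and group comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cephtmj)
```

`cephtmj` implements the computational chain of a cephalometric study of
temporomandibular joint (TMJ) osteoarthrosis: landmark-based measurement
in a rotated cranial-base coordinate system, a rule-based three-tier
osseous diagnosis of each condyle with worst-side aggregation to a
patient diagnosis, method-error analysis for repeated digitizations, and
a three-group statistical comparison of the cephalometric variables.  A
synthetic cohort generator reproduces the statistical structure the
analysis assumes, so every stage runs and is testable without any
external data.  This vignette records the model, the parameters that
matter, and the design decisions taken where the underlying procedure
left choices open.

## The coordinate system and the measurement vector

All measurements are made in a cranial-base frame anchored on the
sella-nasion (SN) line: the X-axis passes through sella at 7 degrees to
SN, rotated towards the inferior field, and the Y-axis is the
perpendicular through sella.  The 7-degree offset is the conventional
correction that brings the anterior cranial base close to a true
horizontal; the magnitude is configurable (`rotation_deg`).

The direction of the rotation (inferior, i.e. the X-axis passes below
nasion) is a convention rather than a stated rule; it matches the usual
cranial-base horizontals.  Rather than hard-coding an orientation of the
digitizing plane, `build_coordinate_system()` identifies the inferior
side from menton, which makes every measurement invariant under rigid
motions *and* reflections of the tracing — digitizations in mirrored or
rotated scanner frames measure identically.  For image-convention files
(y increasing downwards) the readers accept `invert_y = TRUE`.

Nine variables are computed per subject by `ceph_measure()`:

| variable | definition | units |
|----------|------------|-------|
| SNA, SNB | angles S-N-A and S-N-B at nasion | degrees |
| ANB      | SNA − SNB (identity, never measured independently) | degrees |
| MP-SN    | angle between the mandibular plane (Go-Gn) and SN | degrees |
| A-to-Y, Pg-to-Y | unsigned distance of A and Pg to the Y-axis | mm |
| S-Go     | posterior facial height: unsigned distance of Go to the X-axis | mm |
| N-Me     | anterior facial height: N-to-Me distance along the Y direction | mm |
| ratio    | facial height ratio, 100 × S-Go / N-Me | % |

Decisions worth recording: distances are reported unsigned (signed local
coordinates remain available through `to_local()` for diagnostics);
A-to-Y is the distance *perpendicular to the Y-axis* (|local x|),
consistent with the frame geometry even though such distances are
sometimes loosely called "vertical"; MP-SN is the unsigned angle between
undirected lines, in [0, 90] — anatomical values (roughly 25-70 degrees)
live well inside that range; gnathion is the exact Me-Pg midpoint when
not digitized directly.  `construct_gonion()` implements the
tangent-bisector construction of gonion against a mandibular contour,
but the pipeline treats Go as a digitized input landmark; the
construction is auxiliary.  Values are kept at full precision and
rounded only at report time (2 decimals for means/SDs, 1 for
percentages).

## Condylar osseous classification

Each condyle carries eight adjudicated boolean flags.  The diagnosis is
a strict tier dominance rule:

* **osteoarthrosis** — any of: subcortical cyst, surface erosion,
  osteophyte, generalized sclerosis, or a short condyle (decreased head
  height with continuous cortex);
* **indeterminate for osteoarthrosis** — otherwise, any of: subcortical
  sclerosis, articular surface flattening, or condylar hypoplasia
  (normal morphology, decreased size);
* **normal** — no flags.

The tiers are written as mutually exclusive descriptions in the source
criteria; for mixed records (e.g. flattening plus erosion) dominance by
severity is the only consistent completion, so an osteoarthrosis-tier
flag always wins, and hypoplasia co-flagged with a short condyle is
osteoarthrosis.  All 256 flag combinations classify deterministically
(the test suite checks them exhaustively against an independent
restatement).  Slice-level confirmation of findings is an
annotation-time rule and out of computational scope: flags arrive
adjudicated.

A patient's diagnosis is the more severe of the two condylar diagnoses
(worst-side rule, `aggregate_patients()`); laterality is *bilateral*
when both condyles carry the patient category, *unilateral* otherwise
(bilaterally normal patients are tabulated as bilateral, matching the
reference patient table).  `summarize_cohort()` produces the two cohort
tables: patients by category × laterality, and per-feature record
prevalences in which each true flag on each condyle contributes one
record and each flagless condyle contributes one "normal" record.

## Reliability

For repeated digitizations, `dahlberg_error()` returns the Dahlberg
method error `sqrt(sum(d^2) / (2n))` over paired differences — the
standard estimate of random digitizing error, in the units of the
variable — and `reliability_report()` adds a two-sided paired t test for
systematic error, per variable.  Zero-variance edge cases follow
explicit conventions: identical repeats give p = 1 (no detectable
systematic error), a constant nonzero shift gives p = 0 as the limit of
the t statistic as the difference SD vanishes.

## Group comparison

`compare_groups()` treats each variable independently:

1. one-way ANOVA (classical between/within F on k − 1 and N − k df;
   the degenerate all-equal input is defined as F = 0, p = 1);
2. a mean-centered Levene test of variance homogeneity — an ANOVA on
   absolute deviations from group means.  The homogeneity test used in
   the original analysis is not named; the mean-centered Levene test is
   the default of the statistical software it reports, and is
   cross-checked against `car::leveneTest(center = mean)` in the tests;
3. routing: Fisher LSD pairwise tests (pooled MSE, N − k df,
   unadjusted) when the Levene p exceeds `alpha`, otherwise Dunnett T3
   (Welch-type pairwise statistics with unpooled variances and
   Welch-Satterthwaite df, referred to the studentized maximum modulus
   (SMM) distribution with m = k(k−1)/2 contrasts).  Which variables
   were routed where in the original analysis is unreported, so the
   routing actually taken is itself reported (`glance()`, run log)
   rather than guessed;
4. a compact letter display: groups sharing a letter are not
   significantly different pairwise at `alpha`.

The SMM cumulative distribution is computed by numerical integration of
`[2Φ(qu) − 1]^m` against the chi-square mixing density
(`integrate()`, relative tolerance 1e-9).  Using each pair's own Welch
df with the common m is the standard independent-contrast approximation
for T3; the suite validates the CDF against a Monte-Carlo oracle and
checks the family-wise error of the full procedure under a
heteroscedastic complete null (10,000 replicates at group sizes
17/19/39): the realized error stays at or below 0.06 at alpha = 0.05.
For k = 2 the LSD p-value equals the pooled two-sample t p-value
exactly, and T3 with m = 1 reduces to the Welch t test.

The letter display uses the insert-and-absorb algorithm: start with one
column containing all groups; for every significant pair split each
column containing both members into two copies, delete one member from
each, and absorb columns that became subsets.  Pairs are processed in
label order and letters assigned by first-group membership, which makes
the display deterministic; a property test re-derives the
shared-letter relation from the pairwise matrix on hundreds of random
instances.  `alpha` is 0.05 by default and configurable everywhere.

## The synthetic generator

The generator emulates two aspects of the reference cohort:

**Measurement space.**  Seven free variables (SNA, SNB, MP-SN, A-to-Y,
Pg-to-Y, N-Me, S-Go) are drawn from group-conditional normal
distributions whose means/SDs and group sizes (17/19/39) are the
published ones (`tmjoa_group_params()`).  ANB is always derived as
SNA − SNB and the facial height ratio as 100 × S-Go / N-Me — the two
identities are never sampled independently.  Correlations among the
measurements are unreported, so the default is independent sampling
with an optional user-supplied correlation matrix.  Two consequences
are worth stating plainly: with independent SNA and SNB the derived ANB
has a larger SD (about 5 degrees) than the published ANB column, and
the derived ratio's distribution is a ratio of normals whose mean
emerges (about 0.05% above the published mean at the osteoarthrosis
parameters) rather than being matched exactly.  A `ratio_mode =
"direct"` option instead samples the ratio from its own published
distribution and derives S-Go = ratio × N-Me / 100, for checks that
target the ratio itself.  Draws beyond 5 SD from their mean, or
violating positivity/angle-range constraints, are rejected and
resampled with the count recorded.

**Inverse geometry.**  `construct_landmarks()` turns a measurement
vector into a landmark configuration that `ceph_measure()` maps back to
the same seven values within 1e-9 (the suite sweeps 1,000 random
vectors plus the published normal-group means).  Sella sits at the
origin with nasion on +x; B lies on the SNB ray at a nuisance distance;
Me at a nuisance abscissa and depth N-Me below nasion's level; Pg on
the A-to-Y-style vertical at `Pg_to_Y` with a nuisance rise above Me;
Gn is the Me-Pg midpoint; Go is the intersection of the line through Gn
at angle MP-SN to SN with the horizontal at depth S-Go (singular only
when MP-SN equals the axis rotation, which is flagged as infeasible).

The A point needs care.  Constrained to the Y-parallel line at A-to-Y,
the angle S-N-A can only approach `90 − rotation` degrees (83 degrees
at the default rotation) asymptotically as A recedes downwards, and
which side of that ceiling is reachable depends on whether the line
passes anterior or posterior of nasion.  With a *fixed* sella-nasion
distance this makes realistic draw combinations (SNA near or above 83
with the published A-to-Y values) unreachable or absurdly deep.  The
default therefore solves the sella-nasion distance in closed form so
that A sits at a fixed 45 mm depth below nasion's level — a
mid-anatomical position — which makes every admissible draw feasible
with sella-nasion distances near 60-66 mm, while leaving all seven
measurements exact.  This extends the same principle used for Go (a
nuisance degree of freedom is spent to make the targets simultaneously
exact).  A user-fixed `sn_mm` is honored through a one-dimensional root
solve and raises an informative infeasibility error when the requested
angle is unreachable.  Nuisance defaults (`nb_mm = 100`, `me_x_mm =
46`, `pg_rise_mm = 8`) are mid-anatomical values; the tests verify that
perturbing any nuisance leaves all nine measurements unchanged.

**Condylar rosters.**  `generate_condylar_roster()` emits per-condyle
flags such that classification plus worst-side aggregation reproduces a
prescribed patient table exactly; per-feature record tallies are
matched exactly where given (the default specification reconstructs the
reference cohort: 83 patients, 183 records, 39 flagless condyles) and
sampled uniformly within the required tier otherwise.  Feature
multisets are dealt one flag per condyle first, then leftovers to
random condyles not yet carrying the flag, and the result is
self-checked by classifying it back.

All sampling is routed through R's default Mersenne-Twister stream;
every generating function takes a `seed` argument applied locally (via
`withr::with_seed`), so identical seeds give identical cohorts without
disturbing the caller's RNG state.

## What the synthetic checks do and do not show

Because group-conditional distributions are normal, independent across
variables and subjects, the generator reproduces the *marginal*
statistical structure of the reference cohort but not: inter-variable
correlations (notably SNA-SNB, hence ANB's spread), left/right condylar
dependence beyond the roster's patterns, age or clinical covariates,
or digitizing error (landmarks are exact by construction — reliability
analysis is exercised by adding explicit noise in the tests).  Passing
tests therefore demonstrate correctness of the measurement geometry,
the classification logic and the statistical machinery under the stated
distributional conditions; they are not evidence about real cephalogram
populations.

A consequence of taking the published means/SDs at face value: exact
noncentral-F power at n = 17/19/39 is essentially 1 for MP-SN, S-Go,
Pg-to-Y and the ratio, about 0.63 for SNB and ANB, 0.51 for N-Me, 0.32
for A-to-Y and 0.14 for SNA.  A single cohort's significance verdict
for the middle variables (SNB, ANB, N-Me) is close to a coin flip, so
the property tests assert the reproducible split — the four
high-powered variables reject in nearly all seeds, SNA and A-to-Y in a
minority — plus the ordering between the middle and bottom tiers,
rather than pretending every published significance replicates.

## Problem sizes and numerical tolerances

The shipped checks use: 1,000 random measurement vectors for the
round-trip sweep (tolerance 1e-9); 1,000 seeds for the MP-SN ANOVA
rejection rate; 10,000 draws for parameter recovery through the full
landmark round trip (agreement within 3 standard errors); 10,000
Monte-Carlo replicates for the T3 family-wise error; 5,000 draws per
variable for Kolmogorov-Smirnov checks of the sampled marginals
(p > 0.01 at fixed seed).  These sizes put Monte-Carlo error well below
every tolerance asserted while keeping a full run in the order of a
minute or two on a single core.

## Limitations

No automatic landmark detection, image handling or slice-level
adjudication; no ICC or Bland-Altman variants of the reliability
analysis; no covariate adjustment or nonparametric fallbacks in the
group comparison; the TPS reader covers the minimal LM=/ID=/SCALE=
dialect with positional landmark naming.  The published random-error
ranges for repeated digitizations depend on supplementary repeat data
that are not machine-readable here; the reliability module is validated
on synthetic repeats instead.
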