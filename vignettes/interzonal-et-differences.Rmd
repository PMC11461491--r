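---
title: "Inter-zonal epithelial thickness differences: model, design and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inter-zonal epithelial thickness differences: model, design and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(etdiff)
```

## The statistic and its rationale

Anterior-segment OCT devices summarize the corneal epithelium over a 7-mm
zone as 41 zonal mean thicknesses (µm): a central disc and five annuli of
eight octants (superior S, superior-nasal SN, nasal N, nasal-inferior NI,
inferior I, inferior-temporal IT, temporal T, temporal-superior TS). In
keratoconus the epithelium thins over the stromal cone and thickens around
it, creating *local* irregularity, whereas absolute zonal ET varies widely
between healthy individuals. The inter-zonal ET difference of a zone $a$
with neighbours $x_1,\dots,x_n$,

$$D(a) = \frac{1}{n}\sum_{i=1}^{n} \lvert ET(a) - ET(x_i)\rvert,$$

discards the absolute level (it is invariant to adding a constant to the
whole map and scales linearly with the map) and responds only to local
relief. Two summary parameters are used for screening: the localized
parameter $\tfrac12\{D(\mathrm{cI}) + D(\mathrm{cTI})\}$ over the
paracentral inferior and inferior-temporal zones, and the global parameter
$\tfrac{1}{41}\sum_a D(a)$. Five conventional comparators (mean, SD,
minimum, maximum of the zonal values, and the inferior-minus-superior
asymmetry) are computed alongside.

## Grid topology and laterality

The device's zone layout is modelled as the unique regular ring/octant
decomposition summing to 41 zones. Two zones are adjacent when they share
a boundary arc or radial segment: same ring and neighbouring octant,
neighbouring ring and same octant, and the central disc with all eight
paracentral sectors. Zones touching only at a corner are *not* neighbours
by default; an `edge+corner` switch exposes the alternative reading, since
devices do not document which convention their "neighbouring zones"
follow. Neighbour counts are then 8 (centre), 4 (rings 1–4) and 3
(outermost ring). Ring radii default to six equal radial bins across the
7-mm map; they affect rendering and the synthetic generator's geometry
only — no statistic depends on them, because the statistic sees only the
adjacency relation.

Sector labels name anatomical directions, which mirror between eyes, so
all maps are canonicalized to the right-eye (OD) convention before
analysis: left-eye maps are mirrored across the vertical meridian
(N↔T, SN↔TS, NI↔IT; S and I fixed). Mirroring is an involution, and every
downstream parameter is invariant to whether the same anatomical eye was
recorded as OD or OS — both properties are tested.

## Statistical machinery

**ROC and AUC.** The empirical ROC uses the rule "score ≥ threshold ⇒
positive" (scores are negated for lower-is-disease parameters). The AUC is
the trapezoid area, identical to the Mann–Whitney concordance probability
with ties counted ½; its 95% CI uses the DeLong variance (clipped to
[0, 1]). DeLong was chosen over a bootstrap because it is deterministic
and standard; the test suite cross-checks both AUC and CI against pROC.

**Zone selection.** Per-zone ROC of the 41 difference values, higher =
disease, keeping the $k = 2$ largest AUCs. Exact AUC ties are routine on
well-separated cohorts (every cone-affected zone can discriminate
perfectly), so ties break by the larger between-group median difference —
the zone carrying the larger effect — and only then by canonical zone
order; a tie at the selection boundary is flagged in the result.

**Cut-offs.** Candidate thresholds are midpoints between adjacent distinct
observed scores, extended half a median score-gap beyond the extremes.
The lower (screening) cut-off is the largest candidate whose sensitivity
still reaches the 95% floor; the upper (confirmation) cut-off is the
smallest candidate whose specificity reaches 95%. On heavily overlapping
scores this yields lower ≤ upper; when a cohort separates almost
perfectly, both floors are simultaneously over-satisfiable and the literal
definitions can invert — the achieved sensitivity/specificity printed next
to each cut-off make the operating points unambiguous. With the extended
candidate grid every target in [0, 1] is attainable (possibly at a
degenerate operating point such as sensitivity 0); the `attained` flags
are kept for robustness.

**Group comparisons.** Two-sided Mann–Whitney U per prespecified pair,
exact enumeration when both groups have ≤ 8 tie-free observations and the
tie-corrected continuity-corrected normal approximation otherwise (the
`stats::wilcox.test` rules). The validation stage tests exactly four
prespecified comparisons (each keratoconus group vs healthy, for both
parameters) at the Bonferroni-adjusted per-comparison level
0.05/4 = 0.0125; the development-stage per-zone screening is deliberately
uncorrected, since it is a ranking step, not an inference.

**Repeatability.** Per eye, the sample SD of a quantity across its
repeated measurements; summarized by the cohort median and IQR. Quartiles
use linear interpolation (type 7) by default with a type-6 (SPSS-like)
switch. Note that the median sample SD of three repeats is a *biased*
estimate of the underlying noise SD (median of $\sigma\,\chi_2/\sqrt2$,
about $0.83\sigma$); calibration checks therefore use the pooled RMS SD
$\sqrt{\overline{SD^2}}$, which is unbiased for $\sigma^2$, while reports
keep the median/IQR convention used in practice.

**Aggregation over repeats.** Validation averages the per-measurement
parameters over each eye's repeats (mean of parameters), not the
parameter of the mean map; since $D$ is a folded (absolute-value)
statistic the two differ, and the maximum per-eye gap between the two
conventions is computed and stored in the report
(`settings$aggregation_gap`) so the choice stays visible.

## The synthetic cohort generator

The generator produces zonal maps with the structure the analysis assumes:

* **Healthy surface** — baseline 53 µm; superior and temporal thinning
  gradients of 5.9 µm and 1.3 µm (sector difference at the 3-mm reference
  radius). The gradient rises quadratically from a 1.2-mm onset: healthy
  central and paracentral ET is flat, and the eyelid-related
  superior/temporal thinning is a peripheral phenomenon. This also gives
  the statistic a strictly increasing severity response from zero — with
  a gradient reaching into the paracentral ring, a microscopic cone first
  *flattens* the local relief and the localized parameter would dip by a
  few hundredths of a µm before rising.
* **Cone** — a raised-cosine depression in (ring, angle) coordinates,
  centred by default on the cI/cTI boundary (247.5°, ring 1; half-widths
  55° and 1.3 rings), with a raised-cosine annular elevation (35% of the
  cone depth) peaking two rings outward. Severity is the cone depth in µm;
  severity 0 reproduces the healthy model exactly under the same seed.
* **Noise** — a per-eye biological offset (SD 1.5 µm) plus independent
  zonal measurement noise (SD 0.6 µm, the repeatability magnitude of
  zonal ET in clinical practice). Spatially correlated noise is *not*
  modelled; this is the main acknowledged gap between the generator and
  real maps.
* **Groups** — cone-depth severities are uniform per group: healthy fixed
  at 0, tomographically normal fellow eyes 0.5–3 µm, significant
  keratoconus 4–16 µm (development-stage keratoconus spans 3–16 µm to
  include milder bilateral ectasia). BAD-D and Belin ABCD indices are
  affine in severity with noise, truncated so group definitions hold by
  construction (BAD-D ≥ 2.69 for significant, < 1.65 and ABCD stage 0
  otherwise); they are consumed only by the correlation analysis.
* **Reproducibility** — one root seed; each eye draws its own
  deterministic substream, so cohorts are reproducible eye-by-eye
  regardless of group sizes.

With these defaults the healthy global inter-zonal difference comes out
near 1 µm — from the noise level and gradient alone
($E\lvert N(0, 2\sigma^2)\rvert \approx 0.68$ µm at $\sigma = 0.6$ plus
peripheral gradient steps — no group median is hard-coded, which keeps the
end-to-end checks non-circular.

What passing tests on synthetic cohorts do show: the statistic recovers
seeded cones at any paracentral position, orders the three groups
correctly in essentially every replicate cohort, and separates significant
keratoconus from healthy eyes with AUC near 1. What they cannot show:
performance on real corneas, where cone morphology, spatially correlated
segmentation error, dry eye and contact-lens artefacts all perturb the map
in ways the generator does not emulate. Cut-off values derived from
synthetic cohorts are therefore illustrative, not clinical.

## Numerical and design choices

* SD of the zonal values uses the sample (n−1) convention, switchable to
  population.
* The inferior–superior comparator is the mean of all I-octant zones minus
  all S-octant zones (ring subset configurable), since devices differ in
  which radius their I–S value samples.
* Comparator ROC directions: higher-is-disease for the difference
  parameters, map SD and maximum; lower-is-disease for mean, minimum and
  the I–S asymmetry (keratoconic thinning is inferior, reversing the
  physiological inferior-thicker asymmetry).
* Degenerate inputs: identical scores in both classes give AUC 0.5 with a
  warning; single-class ROC input is an error; eyes with fewer than two
  repeats are excluded from repeatability with a warning; a cohort with a
  single measurement per eye skips the repeatability section only.
* Zonal values are validated to be finite, positive, and plausibly within
  20–120 µm (warning outside).
* Problem sizes in the test suite (e.g. 100 replicate cohorts of 21 eyes
  per group for the ordering check, 200 random instances per oracle
  comparison) were chosen to keep the full suite under a minute of
  statistics per property while leaving Monte-Carlo margins wide.

## Known limitations

* The real device's zone boundaries, ring radii and corner-adjacency
  semantics are not published; the reconstructed layout is declared, and
  the `edge+corner` switch exists precisely because the alternative cannot
  be ruled out.
* Independent zonal noise understates the spatial correlation of real
  segmentation error, which would inflate inter-zonal differences less
  than independent noise of equal variance.
* The generator couples tomographic indices to severity affinely, which is
  sufficient for rank-correlation checks but not a tomography model.
* ET pattern-deviation and Gaussian-fit coincident-thinning indices are
  out of scope; only the five conventional whole-map comparators are
  implemented.
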