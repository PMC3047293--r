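---
title: "The Structure Function Index: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Structure Function Index: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfindex)
```

## The model

The clinical diagnosis of glaucoma rests on finding *matching* damage in
optic-nerve structure and visual function. The Structure Function Index
(SFI) turns that clinical rule into a probability. For each of the 52
scored locations of the Humphrey 24-2 field it computes

$$\mathrm{SFI} = \sum_{s \in \text{sectors}} P_{\text{field}} \cdot
  P_{\text{sector}}(s) \cdot P_{\text{anatomy}}(s),$$

the probability that the field point is abnormal, that a disc sector is
abnormal, and that the two are connected by retinal nerve fiber layer
(RNFL) anatomy. Three consequences follow directly from the formula and
are what the index is designed to achieve:

* if either the field or the whole disc is quiet, the SFI stays near zero;
* because $\sum_s P_{\text{anatomy}}(s) = 1$, the SFI can never exceed
  $P_{\text{field}} \cdot \max_s P_{\text{sector}}(s)$ — structural damage in
  a sector unrelated to the field point is discounted;
* two *modest*, anatomically linked deficits reinforce each other, which a
  pair of independent single-modality cut-offs would miss.

### Probabilities of abnormality: empirical CPFs

Device printouts only flag points beyond extreme percentiles (5%, 2%, 1%,
0.5%), which throws away the whole interior of the distribution. We
instead fit, from a reference cohort, an empirical cumulative probability
function (CPF) per field point (on total deviation, dB) and per disc
sector (on measured minus Moorfields-predicted rim area, mm²). Total
deviation and the Moorfields prediction are used precisely because both
already include age (and disc-size) normalisation, so the reference model
needs no demographic regression of its own.

A CPF is evaluated with Hazen plotting positions $(i - 0.5)/n$ on the
order statistics, linear interpolation between them, and clamping to
$[1/(2n),\, 1 - 1/(2n)]$. The three numerical choices are deliberate:

* *Hazen positions* avoid probabilities of exactly 0 or 1 at the sample
  extremes and treat the sample symmetrically;
* *interpolation* (rather than a step ECDF) matches the continuous-curve
  reading of the index; evaluation between observed reference values is
  not specified by a step function, and an interpolated CPF keeps the
  index continuous in its inputs;
* *clamping* guarantees that $1 - \mathrm{CPF}$ never reaches 0 or 1,
  which the hemifield score (below) requires because its per-point term
  diverges as SFI approaches 1. Tied sample values take the highest
  plotting position, i.e. $(\#\{x_j \le x\} - 0.5)/n$; a degenerate
  all-equal sample evaluates as a clamped step.

Fitting requires at least 20 reference values per CPF (configurable);
right and left eyes get separate models and data are never mirrored
between lateralities.

### The anatomical map

Each field point's insertion angle on the disc circumference is modelled
as a normal distribution; the linkage probability of a sector is the mass
of that distribution, wrapped on the circle, inside the sector's arc.
Wrapping is evaluated by summing the plain normal CDF over ±2 extra
periods (error far below 1e-12 for SDs up to 60°). The six HRT arcs
default to temporal [315°, 45°), superotemporal [45°, 90°), superonasal
[90°, 135°), nasal [135°, 225°), inferonasal [225°, 270°),
inferotemporal [270°, 315°), in a per-eye convention with 0° at the
temporal pole and 90° superior; both the arcs and the per-point map are
configurable.

Published maps assign each point to a single sector, and the per-point
spread of insertion angles is not published. The packaged defaults are
therefore generated from a smooth geometric model of fiber courses: the
disc sits 15.5° nasal and 1.5° superior on the retina; points nasal of
the disc insert along the straight line to the disc; points temporal of
the disc follow arcuate courses whose entry angle is pushed toward the
vertical poles, with an amplitude (67°) saturating over a distance scale
of 15° and capped 2° short of the vertical, so fibers never cross the
horizontal raphe. The single calibration anchor is the known example
point 3° right / 15° up in a right eye, which the default map links
roughly 74%/26% to the inferotemporal/inferonasal sectors. The uniform
default SD is 15°: wide enough that neighbouring sectors share linkage
near arc boundaries (the behaviour the probabilistic map exists to
capture), narrow enough that linkage never crosses the horizontal. The
defaults are explicitly approximate; any table of per-point means and SDs
can be supplied from CSV.

### The SFI Hemifield Test

Because glaucoma respects the horizontal raphe, pointwise SFI values are
summarised GHT-style. Each hemifield is partitioned into five clusters
(3–6 points, region 1 the 3-point nasal-step cluster, region 4 the
6-point arcuate), mirrored across the horizontal meridian; cluster
coordinates are packaged data and overridable. The published figure
depicting the clusters does not list coordinates, so the packaged table
is a faithful re-encoding of the GHT layout on the 24-2 grid, chosen to
cover all 52 points (the score arithmetic — an all-zero eye totals
52 × 0.1 = 5.2 — presumes full coverage).

Each cluster is scored $\sum_{\text{points}} 1/(10(1 - \mathrm{SFI}))$,
with the per-point term capped at 100 (the cap binds at SFI = 99.9%), so
region scores range from 0.1 per point to 100 per point — 300 maximum for
region 1 and 600 for region 4. Five signed superior-minus-inferior
differences localise asymmetric damage; the sum of all ten region scores
catches diffuse loss that produces no asymmetry. All six statistics are
referred to empirical reference distributions (fitted on the scored
reference cohort with the same machinery as the CPFs), and the eye is
summarised by the largest of the six abnormality probabilities, together
with *which* statistic was most abnormal.

Two decisions here were genuinely open. The paired differences are
treated **two-sided** (extremity $2\max(F(d), 1-F(d)) - 1$): either
hemifield may be the damaged one, and a one-sided rule would halve
sensitivity to inferior-field disease. The total is treated **one-sided**
(abnormality $= F(t)$): only high totals indicate damage. Both choices
are configurable in spirit — the statistics and reference samples are
exposed — and because the reference CPFs are clamped, no abnormality
probability ever reaches 1, which keeps ROC thresholds well defined.

## Evaluation

ROC analysis uses all distinct thresholds, trapezoidal area, and
half-credit ties, making the AUC exactly the Mann–Whitney concordance
statistic (the test suite asserts this against an exhaustive pairwise
oracle, and against an independent ROC implementation). AUC standard
errors use the Hanley–McNeil exponential-approximation formula with
$Q_1 = A/(2-A)$, $Q_2 = 2A^2/(1+A)$. For paired AUC comparison the
between-area correlation is approximated by the average of the two
class-conditional Spearman correlations between the score vectors — the
quantity the published lookup table is indexed by, used directly in place
of the table; the unpaired variant ($r = 0$) is the plain two-SE z-test.
Sensitivity/specificity intervals are exact Clopper–Pearson (implemented
via the beta quantile and cross-checked against `binom.test`), a
deliberate substitution for the originally cited interval method, and are
labelled as such in the output. The optimal operating point minimises
Euclidean distance to (sensitivity, specificity) = (1, 1), ties resolved
to the lower threshold.

## The synthetic cohort generator

No patient data ship with the package; the generator exists so that every
stage is testable end to end. It emulates:

* **reference/suspect eyes** — per-point TD $= \mu + g + \varepsilon_j$
  with group mean $\mu = -0.46$ dB, a shared global shift
  $g \sim N(0, 1.7^2)$ (test-to-test and media effects) and local noise
  $\varepsilon_j \sim N(0, 2.0^2)$; sector rim differences
  $\sim N(0, 0.12^2)$ mm² around plausible predicted sector areas. These
  defaults reproduce the suspect-cohort MD moments of the study
  population (−0.46, SD ≈ 1.7 dB);
* **glaucoma eyes** — additionally, with probability 0.9, a focal arc
  defect on the disc: arc width 60°, center drawn from a wrapped-normal
  mixture favouring the inferotemporal (60%) and superotemporal (40%)
  poles, matching where glaucomatous damage concentrates. Each field
  point is depressed by the defect depth times the overlap of its
  insertion-angle distribution with the arc, and each sector loses rim
  area (0.015 mm²/dB) in proportion to the arc fraction it contains — so
  structure and function are damaged *jointly through the same anatomy*,
  which is the premise the SFI tests. Depths are exponential, giving the
  long left MD tail of real glaucoma populations, and the mean depth is
  derived analytically at run time so the cohort mean MD equals −6.3 dB:
  $\bar D = (\mu - \mathrm{MD}_{\text{target}})/(p_{\text{defect}} \cdot
  \bar\omega)$, where $\bar\omega$ is the expected mean anatomical
  overlap, computed by numerical integration over the arc-center
  distribution (`expected_mean_overlap()`). This is calibration by
  construction, not tuning.

MD and PSD are computed as the unweighted mean and SD of the simulated
TDs — a documented simplification of the proprietary device formulas that
affects only simulation labels, never the SFI itself. A *discordant* mode
places the rim loss 180° away from the field defect while preserving both
marginal severities; comparing concordant to discordant cohorts isolates
exactly the anatomical-linkage term of the index. One defect per eye;
simulated TD is unbounded below (no perimetric floor); the glaucoma MD
*SD* comes out near 7 dB rather than the reported 8.3 — the calibration
targets are the group means.

What passing tests on these cohorts do show: the pipeline's arithmetic,
its invariances, and that anatomically concordant damage raises the SFI
above discordant damage of equal marginal severity. What they do not
show: performance on real eyes — real fields have floor effects,
test–retest variability, media opacities and multi-focal damage that the
generator does not model, and the synthetic separability (AUC ≈ 0.84 at
300 eyes per group) is accordingly more optimistic than clinical reports
(≈ 0.78).

## Degenerate inputs, tie-breaks and problem sizes

* Worse-eye selection keeps the lower MD; an exact tie keeps the right
  eye (deterministic and documented).
* Sectors carrying anatomy mass below 1e-6 are skipped in the fusion sum
  (they contribute only zero terms); this perturbs the SFI by at most
  ~1e-6, which the affected test tolerances absorb.
* Rows failing validation on cohort read are rejected with row numbers
  and reasons, never imputed; eyes with missing or non-finite TD points
  are invalid by construction.
* Model serialization writes reference samples in hexadecimal float
  notation, so save/load round trips are bitwise exact; files carry a
  format version and refuse to load on mismatch.
* Default analysis sizes used throughout the tests — 500 reference eyes
  per laterality, 300 suspects and 300 glaucoma eyes for discrimination,
  499/895 for cohort-moment checks, 1e6 draws for the Monte-Carlo
  linkage oracle — were chosen to keep every check well-powered while
  the full suite runs in about a minute.

## Known limitations

* The packaged anatomical map is a calibrated geometric heuristic, not a
  re-derivation from fundus photographs; per-point means and SDs should
  be overridden where better estimates exist.
* The Moorfields-predicted rim area is a required *input*; the package
  does not reimplement the regression.
* The hemifield cluster table is a re-encoding of the GHT layout, not an
  exact copy of unpublished coordinates.
* Single-time-point analysis only; progression is out of scope.
* The correlated AUC comparison approximates the published correlation
  table as described above; for borderline comparisons a resampling
  method is advisable.
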