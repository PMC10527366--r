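---
title: "Measuring DEJ protrusions and grading the PRO score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring DEJ protrusions and grading the PRO score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dejpro)
library(dplyr)
```

## The measurement model

`dejpro` works on a columnar representation of a vertical skin slice: two
single-valued depth profiles per image, the skin surface and the
dermo-epidermal junction (DEJ), one value per lateral column in
micrometres, with depth increasing downward from the image top. This
representation is deliberate. Real filiform downgrowths can fold over,
but label masks produced by skin-layer segmentation are columnar, and
the crossing-based ledge-width definition below presumes the DEJ is a
function of lateral position. "The DEJ lies below the reference"
therefore means *numerically greater* throughout the package, since the
anatomical "below" points toward larger depth values.

Protrusions are defined against a **flat-DEJ reference estimator**: the
surface contour offset downward by the image's mean epidermal thickness,

$$\mathrm{ref}(x) = s(x) + \overline{t}, \qquad
  \overline{t} = \frac{1}{W}\sum_x \big(d(x) - s(x)\big),$$

so the baseline follows the skin surface and the comparison is local to
each image. The offset is estimated per image, not per acquisition:
epidermal thickness varies across a lesion, and a per-image offset keeps
the estimator meaningful for every frame independently.

A **protrusion** is a maximal lateral interval where $d(x) >
\mathrm{ref}(x)$. Its bounds are the two points where the DEJ crosses
the estimator, located with sub-column precision by linear interpolation
between the adjacent columns; at a 1.1 µm lateral pitch, whole-column
bounds would quantise ledge widths too coarsely for the depth/width
ratio used in grading. The **ledge width** is the lateral distance
between the crossings. The **depth** is the difference between the
deepest and shallowest DEJ points within the interval expanded by a
10 µm margin on each side (clipped at the image edges); the margin is
applied symmetrically. Intervals that touch an image edge are kept and
flagged `truncated` — discarding them would bias protrusion counts
downward on narrow fields — but this is configurable. The **undulation
index** is the polyline arc length of the DEJ divided by the
straight-line width $(W-1)\cdot\text{pitch}$; it is 1 exactly for a
flat junction.

Depth is measured on the *raw* contour in all cases. The optional
moving-average smoothing (`smooth_window_um`, default 0 = off) affects
only crossing detection; it exists for staircase contours extracted from
label masks, where pixel quantisation adds spurious micro-crossings.

## Detection and grading parameters

| parameter | default | units | role |
|---|---|---|---|
| `min_depth_um` | 5 | µm | noise floor: intervals shallower than this are discarded (≈ 4 axial pixels at 1.3 µm pitch) |
| `margin_um` | 10 | µm | symmetric expansion of the interval for the depth measurement |
| `spike_depth_um` | 60 | µm | absolute depth at which a protrusion counts as spiky (PRO III) |
| `spike_aspect` | 0.5 | – | depth / ledge width at which a protrusion counts as spiky |
| `max_rule_fraction` | 0.10 | – | share of images a grade needs to qualify for the lesion maximum |
| `smooth_window_um` | 0 | µm | optional pre-crossing moving average |

The per-image rule is: PRO I when no protrusion is detected; PRO III
when any protrusion satisfies `depth >= spike_depth_um` **or**
`depth / ledge_width >= spike_aspect`; PRO II otherwise. The two spike
thresholds are this package's own operationalisation of the morphology
of the grades — published descriptions distinguish hemispherical buds
(PRO II) from spiky or filiform elongations (PRO III) without printing
numeric cutoffs. A hemisphere's depth is half its width, so a
depth-to-width ratio of 0.5 marks "deeper than hemispherical", and 60 µm
marks a downgrowth that is deep in absolute terms regardless of shape.
Both are configurable, and all phantom-based validation generates
phantoms against the same rule it tests.

Lesion aggregation offers both published conventions: the **average
rule** (arithmetic mean of ordinal grade values, rounded half-up — a
deterministic rounding rule is required to report a categorical grade,
and half-up is the convention chosen here) and the **max-10% rule** (the
highest grade present in at least 10% of a lesion's images, a share
exactly at the threshold qualifying, per "at least"). The experimental
`continuous_protrusion_score()` combines normalised depth, undulation
and count into a single non-negative number; it has no validated
thresholds and its output column is named `cps_experimental` to say so.

## What the phantom generator emulates

`generate_phantom()` builds contour pairs from four ingredients:

1. a surface wave (amplitude `surface_waviness_um`, default 2 µm, one
   period per field) standing in for gentle skin curvature;
2. a flat epidermal thickness (default 120 µm, a typical thickened AK
   epidermis);
3. disjoint raised-cosine downgrowths. Raised cosines have compact
   support, so the nominal width is well defined and estimator crossings
   are exact — a property Gaussian bumps lack. Grade defaults: PRO I
   none; PRO II 1–3 buds, widths 80–180 µm, depths 20–40 µm capped at a
   depth/width aspect of 0.3; PRO III 2–5 spikes, widths 40–100 µm,
   depths 80–150 µm;
4. a smooth DEJ micro-undulation ("noise"): a random-phase sinusoid with
   RMS amplitude `noise_sd_um` and wavelength drawn from 100–200 µm,
   emulating rete-ridge-like texture and residual segmentation
   variability.

Two of these choices deserve justification. The PRO II aspect cap is 0.3
rather than "just under the 0.5 rule threshold" because the measured
aspect is systematically inflated relative to the nominal one: protrusion
mass raises the mean epidermal thickness, which pushes the reference
below the flat base, which narrows the measured ledge width (by up to
~30% for narrow bumps). Buds capped at 0.3 are measured well below 0.5
and are still realistic sub-hemispherical PRO II morphology.

The noise is a bounded periodic texture rather than a Gaussian process
because the 5 µm detection floor is *defined* as a noise floor. Any
Gaussian model with sd 2 µm exceeds 5 µm peak excursions somewhere in a
1.2 mm field with non-trivial probability, which would make flat images
sprout spurious protrusions at a rate governed by extreme-value
statistics rather than by the floor. The sinusoid's excursion is bounded
at $\sqrt{2}\,\mathrm{sd} \approx 2.8$ µm at the default noise level, so
sub-floor noise stays sub-floor by construction. What the generator does
**not** emulate: folded/overhanging rete pegs, hyperkeratosis and
acquisition artifacts, physically realistic OCT speckle or PSF effects
(the rasterised B-scan uses stylised per-layer means with multiplicative
gamma speckle), or correlations between neighbouring images of a lesion.
Passing phantom tests therefore demonstrates that the geometry,
thresholds and statistics behave as specified on clean columnar
contours; it does not certify segmentation quality or robustness to
clinical artifacts, which the manifest's manual exclusion flags exist to
handle.

`generate_cohort()` simulates lesion-level grade triples (truth, expert,
automated) with marginals 21/48/11 per 80 lesions and a row-stochastic
confusion matrix defaulting to the adjacent-grade error structure
observed for automated average-rule AK grading; it exists to exercise the
agreement statistics at arbitrary cohort sizes.

## Agreement statistics

`weighted_kappa()` implements linearly weighted Cohen's kappa,
$w_{ij} = 1 - |i-j|/(k-1)$,
$\kappa = (P_o^w - P_e^w)/(1 - P_e^w)$, with the chance term from the
outer product of the margins. The confidence interval uses the
large-sample Fleiss–Cohen–Everitt variance; the p-value tests
$\kappa = 0$ with the corresponding null variance. A seeded percentile
bootstrap is available (`ci_method = "bootstrap"`) and is checked to
overlap the asymptotic interval on large simulated cohorts. Degenerate
tables (a margin concentrated on one grade) raise an explicit error
rather than propagating `NaN`. Spearman correlations use average ranks
for ties — with a 3-level grade, ties dominate — and a Fisher-z interval
with variance $1.06/(n-3)$. Group contrasts between adjacent grades use
two-sided Welch tests (the unequal-variance variant, since grade groups
differ in spread); no multiple-testing correction is applied by default,
with Holm adjustment available.

## Numerical choices and degenerate inputs

- Crossings with an exactly-zero excursion at a column resolve to that
  column (the interpolation fraction is 0); strict inequality defines
  "above", so a DEJ exactly on the reference is not a protrusion.
- Single-column excursions still get positive ledge widths because both
  crossings are interpolated into the neighbouring columns.
- `aggregate_max10()`'s share comparison uses a 1e-12 tolerance so an
  exact 10% share qualifies despite floating-point division.
- Rasterisation assigns a pixel row to a layer if the contour lies at or
  above the row's depth, so extracted contours are biased upward by at
  most one axial pixel and round-trip within it; an epidermis thinner
  than one pixel, a surface above the first row, or a DEJ beyond the
  field depth raise errors.
- Zero-variance groups in Welch tests return p = 1 (identical means) or
  p = 0 (different means) with a `flagged` marker instead of erroring.

## Problem sizes used in validation

The shipped test-suite works at sizes chosen to make sampling error
negligible while keeping a laptop run comfortable: 1,000 random rough
contour pairs (plus 200 with the full uniroot-based crossing oracle) for
the geometry equivalence checks; 300 phantoms per grade, noiseless and
at 2 µm noise, for grade recovery; 25 phantoms per grade for the
metric-separation contrasts; 8,000 simulated lesions for kappa
convergence; 1,000 null replicates for Welch-test calibration.
`scripts/acceptance.R` re-runs the same computations from scratch under
a caller-supplied seed.

## Known limitations

Columnar contours cannot represent overhanging downgrowths, so extreme
filiform morphology is measured by its vertical extent only. The
reference estimator assumes the epidermis away from protrusions has
roughly constant thickness; a strongly wedge-shaped epidermis shifts the
baseline. The PRO II/III thresholds are geometric conventions, not
clinically validated cutoffs, and should be calibrated against expert
grading before clinical use. The undulation index conflates protrusion
depth and count with any other source of DEJ roughness.
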