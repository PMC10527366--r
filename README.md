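# dejpro

Quantification of dermo-epidermal junction (DEJ) protrusions and PRO
grading for vertical-slice (B-scan) skin images, such as those produced by
line-field confocal optical coherence tomography (LC-OCT).

## The problem

Actinic keratosis (AK) is a keratinocyte carcinoma in situ that can
progress to invasive squamous cell carcinoma. Its severity is graded by
the basal growth pattern of atypical keratinocytes at the DEJ on the
ordinal **PRO score**: PRO I (no downward protrusion), PRO II (small
hemispherical buds protruding into the papillary dermis), PRO III
(spiky/filiform elongations). LC-OCT images the DEJ in vivo at micrometre
resolution, and automated skin-layer segmentation makes the grade
computable from contour geometry instead of visual inspection.

`dejpro` implements the geometric core of that automation, for image
analysts and dermatology researchers working with segmented skin B-scans:

- **Flat-DEJ reference estimator.** With depth increasing downward, the
  expected position of an undisturbed DEJ is the skin surface contour
  offset by the image's mean epidermal thickness:
  `ref(x) = surface(x) + mean(dej - surface)`.
- **Protrusion detection.** Protrusions are maximal lateral intervals
  where the DEJ lies deeper than the reference; the *ledge width* is the
  distance between the two estimator crossings (located by linear
  interpolation), and the *depth* is `max(dej) - min(dej)` over the
  interval expanded by a 10 µm margin. Intervals shallower than a 5 µm
  noise floor are discarded.
- **Per-image morphometrics.** Undulation index (DEJ arc length over the
  straight-line width; 1 for a flat junction), protrusion count and
  maximum protrusion depth.
- **Grading.** PRO I if no protrusion; PRO III if any protrusion is deep
  (≥ 60 µm) or steeper than hemispherical (depth/width ≥ 0.5); PRO II
  otherwise. Lesion level: the rounded ordinal mean ("average" rule) and
  the highest grade present in ≥ 10% of a lesion's images ("max-10%"
  rule).
- **Agreement statistics.** Contingency tables, percent agreement,
  per-class recall, over/under-call rates, linearly weighted Cohen's
  kappa (`w_ij = 1 - |i-j|/(k-1)`) with asymptotic or bootstrap
  confidence intervals, Spearman correlations with Fisher-z intervals,
  and Welch tests between adjacent grades.
- **Phantoms.** A seeded generator of ground-truthed contour pairs,
  B-scan-like label masks with speckle, and simulated expert/AI grade
  cohorts, so the whole pipeline is testable without clinical data.

Everything is tidyverse-native: data frames in, tibbles out, pipeable,
with `tidy()`/`glance()` methods and ggplot2 helpers
(`plot_contours()`, `plot_metrics_by_grade()`, `autoplot()`).

## Worked example

Generate a ground-truthed PRO III phantom, measure it, and grade it:

```r
library(dejpro)

ph <- generate_phantom(phantom_spec("PRO III", noise_sd_um = 2, seed = 42))
metrics <- compute_image_metrics(ph$contours) |> classify_images()
metrics
#> # A tibble: 1 × 6
#>   image_id undulation_index n_protrusions max_depth_um pro_grade
#> 1 phantom              1.31             2         126. PRO III

metrics$protrusions[[1]]
#> # A tibble: 2 × 6
#>   protrusion start_x end_x ledge_width_um depth_um truncated
#> 1          1    157.  226.           75.6     119. FALSE
#> 2          2    761.  804.           47.8     126. FALSE
```

The DEJ of this phantom is 31% longer than a flat junction
(undulation index 1.31), with two detected downgrowths 119 and 126 µm
deep — both far beyond the 60 µm spike threshold, hence PRO III.

Agreement between visual and automated lesion grades is summarised from
a 3×3 contingency table; for example, for a cohort of 80 lesions with
the counts below:

```r
tab <- as_grade_table(rbind(c(14, 7, 0), c(10, 38, 0), c(0, 6, 5)))
glance(tab)
#> # A tibble: 1 × 7
#>       n agreement over_rate under_rate recall_pro1 recall_pro2 recall_pro3
#> 1    80     0.712    0.0875        0.2       0.667       0.792       0.455

weighted_kappa(tab)
#> Weighted Cohen's kappa (linear weights)
#>   kappa = 0.511, 95% CI [0.337, 0.685] (asymptotic), p = 1.28e-09, n = 80
```

That is: 71.2% of lesions graded identically, 8.75% over-called, 20%
under-called, and chance-corrected ordinal agreement κ = 0.51.

A full simulate → score → evaluate pipeline run is available from the
shell:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/dejpro.R", package = "dejpro"))')" \
    all --out-dir demo --seed 3
```

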