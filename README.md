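# morphoscreen

Morphometric screening of immunostained tumor histopathology for
metastasis prognosis.

In early node-negative breast cancer, classical staging says little about
who will develop distant metastasis. Pan-cytokeratin staining renders
epithelial structures as dark particles on a light background — from large
irregular malignant clusters down to single epithelial cells scattered in
the stroma. `morphoscreen` implements the discovery pipeline that finds,
among all size/shape-defined particle subsets, the one whose features best
prognosticate metastasis:

1. **Binarize** each 8-bit image, automatically (isodata) or at fixed
   thresholds (220/240/250); stain is dark, so foreground is `[0, T]`.
2. **Outline and measure** every connected particle: area `A`, outer
   boundary perimeter `P` (corner-aware crack-polygon estimator, ≤2%
   error on convex shapes ≥10 px), circularity `4πA/P²` (capped at 1),
   convex-hull area and solidity `A/A_hull`, maximum Feret diameter (px
   and µm at 1.4 µm/px).
3. **Filter** particles by inclusive circularity and size (area) ranges;
   the default grid is 4 binarizations × 5 circularity minima × 4 size
   minima = 80 subsets.
4. **Aggregate** to per-image features (count, total area, average size,
   mean circularity, mean solidity) and per-patient averages over ~5
   images.
5. **Evaluate** every subset × feature record: Mann–Whitney AUC on the
   continuous values with optimism-bootstrap correction (B = 1000,
   stratified), and a Cox proportional-hazards fit (Breslow ties) on the
   optimal log-rank cutpoint dichotomization. Records are ranked by
   `|corrected AUC − 0.5|`.

Supporting tools include a maximally selected log-rank cutpoint search,
backward-elimination multivariate Cox modelling, reverse Kaplan–Meier
median follow-up, the Hanley–McNeil ROC sample-size calculation, and a
fully seeded synthetic-data module (tumor-like images plus survival
cohorts with a known generating AUC `Φ(d/√2)`) so the entire pipeline is
testable without patient data.

## Worked example

Simulate a cohort at the default study conditions (102 patients, 20
metastasis events, 5 images each, generating AUC 0.82 for the latent
single-cell density) and screen all 80 subsets:

```r
library(morphoscreen)

cohort <- simulate_cohort(cohort_spec(), seed = 42)
scr <- particle_screen(cohort, B = 1000, seed = 42)
scr
#> Particle subset screen: 80 filter specs x 5 features = 400 records
#>   cohort: 102 patients, 20 events, 510 images
#>   bootstrap B = 1000, connectivity 8, perimeter: corner-aware crack polygon
#>   top subset: binarization auto, circularity >= 0.8, size >= 20 px, feature 'count'
#>     AUC 0.818 (corrected 0.816), HR 8.85 at cutpoint 14.70
```

The screen recovers the planted signal: the top-ranked record is the
particle **count** in the high-circularity (≥ 0.8), cell-sized (≥ 20 px)
subset — the scattered single epithelial cells. The corrected AUC ≈ 0.82
sits at the generating value 0.82, and dichotomizing patients at the
optimal cutpoint (≈ 15 cells per image on average) gives a hazard ratio
of ≈ 9 for metastasis. Median follow-up of the censored patients:

```r
reverse_km_median(cohort$patients$time_months, cohort$patients$event)
#> [1] 129.4421
```

Profile where along the size axis the signal lives (it peaks in the
20–60 px single-cell band):

```r
size_profile(cohort, breaks = c(1, 10, 20, 60, 120, Inf),
             binarization = "250", circularity_min = 0.8)
#> Prognostic AUC of the particle count by size window:
#>  size_lo size_hi   auc    auc_p n_particles
#>        1      10 0.531 6.67e-01        8928
#>       10      20 0.490 8.59e-01          45
#>       20      60 0.822 8.52e-06        4722
#>       60     120 0.524 7.22e-01          94
#>      120     Inf 0.494 9.28e-01         215
```

And the classical design calculation behind a 0.72-AUC biomarker study
with four negatives per positive:

```r
roc_sample_size(alpha = 0.05, power = 0.80, auc_alt = 0.72,
                neg_per_pos_ratio = 4)
#> $n_positive
#> [1] 17
#> $n_total
#> [1] 85
```

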