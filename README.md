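# spinethrust

Semi-automatic measurement of *Drosophila* ventral-branch form from
hand-digitized contours.

The ventral branches — paired cuticular structures of the male genitalia in
the *D. yakuba* / *D. santomea* species pair — are spiny in one species and
rounded in the other, and their form matters for reproductive isolation.
Full image-based automation is out of reach (the structures sit in cluttered
micrographs), but tracing the outline with a digital pen is fast and robust.
This package computes everything downstream of that trace:

* **Curvature profile** — the open contour is smoothed with a rectangular
  filter (fraction α of the points), signed curvature is estimated at each
  point as the inverse circumradius of a three-point circumscribed circle,
  refined over an adaptive window (a = round(1/|k|) points where
  |k| < 0.1 µm⁻¹, else 10), and smoothed with triangular weights
  (fraction β).
* **Landmark detection** — five Bookstein type-2 landmarks are assigned
  from the curvature extrema inside the central 60% of the profile:
  maxima for the two spine tips and the central ridge (landmarks 1, 3, 5),
  minima for the two cavities (2, 4). Specimens missing any landmark are
  excluded with a reason, never imputed.
* **Spine thrust (ST)** — in the frame whose X axis runs from landmark 2 to
  landmark 4 (Y completing a right-handed basis),

  ST = (Y<sub>L1</sub> + Y<sub>L5</sub>)/2 − Y<sub>L3</sub>  (µm),

  the mean height of the spines above the central ridge: positive for
  spiny, null-to-negative for rounded branches.
* **Calibration** — `tune_smoothing()` grid-searches (α, β) maximizing the
  squared Pearson correlation between automatic ST and reference ST from
  manual landmarks; ties go to the lowest degree of smoothing. The shipped
  defaults are α = 0.025, β = 0.055.
* **Synthetic benchmark** — `generate_branch_contour()` and
  `generate_population()` build branch-like contours and whole simulated
  temperature studies with exact ground-truth landmarks and ST, so the
  entire pipeline is testable without any micrograph data.

## Worked example

```r
library(spinethrust)

# a synthetic branch: spines 4 um above the cavities, ridge 1 um,
# freehand digitization jitter of 0.5 um
shp <- generate_branch_contour(spine_height = 4, ridge_height = 1,
                               jitter_sd = 0.5, seed = 2)
shp
#> <synthetic_branch> 700 points, span 50 um, true ST = 2.998 um, jitter sd 0.5 um

prof <- curvature_profile(shp$contour)       # smoothing + 3-stage curvature
det  <- detect_landmarks(prof)               # the five landmarks, by rule
det
#> <branch_detection> status: valid
#> # A tibble: 5 x 7
#>   landmark index s_norm  value kind        x     y
#>      <int> <int>  <dbl>  <dbl> <chr>   <dbl> <dbl>
#> 1        1   190  0.268  0.355 maximum  14.7  9.21
#> 2        2   265  0.399 -0.305 minimum  20.2  6.12
#> 3        3   318  0.474  0.189 maximum  23.7  6.96
#> 4        4   391  0.589 -0.231 minimum  29.1  5.37
#> 5        5   481  0.749  0.298 maximum  35.8  9.29

spine_thrust(det)
#> # A tibble: 1 x 4
#>   st_um  y_l1  y_l3  y_l5
#> 1  2.41  2.61  1.13  4.47
```

The five landmarks alternate spine / cavity / ridge / cavity / spine along
the contour (`kind`, and positive/negative curvature `value`); `st_um` is
the spine thrust of this jittered trace, 2.41 µm against a construction
truth of 3.0 µm — within the sub-micrometer error expected at this noise
level. `plot_curvature_profile(prof, det)` draws the profile with the
landmarks colored by kind.

Batch work goes through a manifest (one CSV row per specimen with its
species, strain, temperature, pixel scale and contour file):

```r
pop  <- generate_population(seed = 1, dir = "simdata")  # or your own data
meas <- measure_branches("simdata/manifest.csv", verbose = TRUE)
#> measured 120/120 specimens (0 excluded or errored, 0.0%)
summarize_st(meas, species, temperature_C)
#> # A tibble: 4 x 10
#>   species       temperature_C     n   mean    se median ...  notch
#> 1 santomea_like            18    30  3.72  0.259   3.80      0.523
#> 2 santomea_like            25    30  0.524 0.244   0.428     0.583
#> 3 yakuba_like              18    30  8.64  0.244   8.78      0.382
#> 4 yakuba_like              25    30  8.70  0.238   8.36      0.529
```

The simulated plastic species shows its designed ~3.4 µm shift between
rearing temperatures; the spiny species does not. A thin command-line
wrapper with `measure` / `tune` / `simulate` / `summarize` subcommands is
installed at `inst/cli/spinethrust.R`.

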