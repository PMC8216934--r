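---
title: "Measuring ventral-branch form from digitized contours: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring ventral-branch form from digitized contours: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 4)
library(spinethrust)
```

## The measurement problem

Male genitalia of the *Drosophila yakuba* species complex carry paired
cuticular structures, the ventral branches, whose form separates the sibling
species: spiny in *D. yakuba*, rounded in *D. santomea*. Quantifying that
form from micrographs is hard to automate fully — the structures sit in
cluttered images where edge detection is unreliable — but easy to
semi-automate: a person traces the outline of the branch with a digital pen
(a single stroke, fast, and insensitive to exact pen placement), and
everything downstream is computed. This package implements that downstream
computation:

1. smooth the digitized open contour,
2. estimate a signed curvature profile along it,
3. detect five curvature-extremum landmarks by rule,
4. compute **spine thrust (ST)**, a scalar form statistic in micrometers,
5. calibrate the two smoothing parameters against reference measurements,
   and summarize groups.

Because the package is meant to be verifiable without any particular
micrograph collection, it also contains a synthetic contour generator with
exact ground-truth landmarks, used throughout the test suite.

## The pipeline

### Units and orientation

A raw contour is an ordered open polyline of pixel coordinates, typically
500–1000 points. `normalize_contour()` converts it to the frame every later
stage assumes: coordinates in micrometers (the pixel scale must be supplied;
a silent default would corrupt the scale-dependent refinement step below),
image y axis flipped so the spines point toward +Y, and traversal forced
left-to-right. Under this contract the signed curvature defined next is
*positive where the contour bulges toward +Y*, so spine tips are curvature
maxima, cavities are minima, and spiny forms get positive ST. The transform
is recorded in attributes and `denormalize_contour()` inverts it.

### Contour smoothing (parameter $\alpha$)

The first smoothing layer is a rectangular (moving-average) filter: each
smoothed point is the mean of the $2\lfloor\alpha n\rfloor + 1$ raw points
centered on it, where $n$ is the raw point count and $\alpha$ is a
*fraction* of it. The smoothed contour is $\lfloor\alpha n\rfloor$ points
shorter at each end. We divide by the true window count so the filter is
mean-preserving (a filter that divided by $2\alpha n$ would inflate every
coordinate slightly).

### Curvature: circumscribed circles with adaptive refinement

For three pairwise-distinct points $M, N, P$ the curvature at $N$ is the
inverse circumradius of the triangle,

$$k = \frac{2\,\vec{MN}\times\vec{NP}}{\lVert MN\rVert\,\lVert NP\rVert\,\lVert PM\rVert},$$

signed by turn direction (collinear points give exactly 0). The **raw
profile** applies this to each interior point with its immediate neighbors,
alongside the curvilinear abscissa $s$ (cumulative arc length). The
**refined profile** recomputes $k$ over a symmetric window of $a$ points,
where

$$a = \begin{cases}\mathrm{round}(1/|k_{\text{raw}}|) & |k_{\text{raw}}| < 0.1\ \mu m^{-1}\\ 10 & \text{otherwise,}\end{cases}$$

so flat regions are measured over a longer baseline (suppressing
digitization noise) while sharp spine peaks keep their short window and
their height. Near the profile ends the window is clamped to the available
points rather than dropped, so the refined profile keeps the raw profile's
support. The threshold ($0.1\ \mu m^{-1}$) and cap (10 points) are
configurable in `smoothing_params()`; the window uses $|k_{\text{raw}}|$,
since a signed $k$ would send every concave point into the $1/k$ branch
with a negative width. The **smoothed profile** (parameter $\beta$, again a
fraction of $n$) is a weighted moving average of the *refined* curvature
with triangular weights $w_i = b - |i - j|$, $b = \lfloor\beta n\rfloor$,
trimming $b$ further points per side.

Three numerical consequences are pinned by tests: stage lengths are exact
($|p'| = n - 2\lfloor\alpha n\rfloor$ and
$|k''| = |p'| - 2 - 2\lfloor\beta n\rfloor$); reversing the traversal
negates every signed curvature; and on sampled circular arcs the smoothed
curvature recovers $1/R$ to well under 2% median relative error. Uniform
scaling is an exact $1/c$ equivariance for the raw stage only: the
refinement window keys on absolute curvature in $\mu m^{-1}$, which is
precisely why the pixel scale is mandatory.

### Landmark detection

Curvature near the stroke's start and end is noisy (the digitizer starts at
a deliberate point and ends in a long stroke), so extremum detection is
restricted to the central window, excluding the first and last 20% of the
smoothed-curvature profile by normalized arc length. Candidate extrema are
strict sign changes of the first difference (plateaus contribute their
first index). The five landmarks are then assigned by rule:

* **L3** — the maximum closest to the midline position (0.475 by default;
  the empirical axis of symmetry sits slightly left of 0.5 because of the
  digitization asymmetry noted above),
* **L2** — the lowest minimum left of L3; **L1** — the maximum left of L2
  closest to L2,
* **L4** — the lowest minimum right of L3; **L5** — the maximum right of
  L4 closest to L4,
* if more than one maximum lies strictly between L2 and L4, L3 is
  reassigned to the highest of them (the other four are not re-derived).

"Closest" is measured in normalized abscissa with ties broken toward the
smaller index, making the assignment total and deterministic. L1 is
restricted to maxima strictly left of L2 (and L5 strictly right of L4);
without that restriction L3 itself could be "closest". A profile missing
any role is *excluded with a reason* (`missing-L2`, ...), never imputed —
on real datasets a few percent of specimens fail this way and are reported,
not guessed. The test suite checks the assignment against an independent
brute-force implementation of the same rules, case by case.

The midline is exposed as a constant because it was estimated empirically
on the original training data; for a new dataset `estimate_midline()`
(mean abscissa of the global curvature maximum across profiles) can
re-estimate it. That helper is an extension, not part of the original
procedure.

### Spine thrust

With the five landmarks in hand, the branch frame is the X axis through
L2 and L4 (oriented L2→L4) with Y completing a right-handed basis. Spine
thrust is

$$ST = \tfrac{1}{2}(Y_{L1} + Y_{L5}) - Y_{L3},$$

the mean height of the spine tips above the central ridge, in micrometers.
ST is rigid-invariant, scales linearly with the specimen (it measures
*form*, deliberately not separating size from shape), is positive for spiny
branches and null-to-negative for rounded ones.

### Calibration and repeatability

$\alpha$ and $\beta$ modulate how many extrema survive smoothing, so they
are calibrated, not guessed: `tune_smoothing()` runs the full pipeline at
every cell of an ($\alpha$, $\beta$) grid and scores the squared Pearson
correlation between automatic ST and reference ST from manually placed
landmarks on the same specimens. Correlation rather than landmark-position
agreement is the target on purpose: human landmark placement may itself be
biased, so the human output is treated as a reference signal, not as ground
truth to mimic point-by-point. Specimens excluded at a cell are dropped
from that cell's correlation (with `n_used` reported); cells with fewer
than three survivors are undefined and never selected. Ties in $r^2$ go to
the *lowest degree of smoothing*, formalized here as smallest
$\alpha+\beta$, then smallest $\beta$. The default grid
($\alpha \in \{0.005,\dots,0.05\}$, $\beta \in \{0.005,\dots,0.1\}$)
brackets the calibrated defaults $\alpha = 0.025$, $\beta = 0.055$ used by
`smoothing_params()`.

`repeatability()` quantifies measurement stability across two digitization
passes of the same specimens as an OLS fit of the second pass on the first.
Note the interpretation caveat: with noise in *both* passes the slope is
attenuated below 1 (errors-in-variables), so slope, intercept and $r^2$
together describe correspondence, not calibration.

### Group summaries

`summarize_st()` reports per group: n, mean, SE, median, quartiles (linear
interpolation between order statistics — the convention must be fixed
somewhere, and this is the plotting default in R), IQR, and the
notched-boxplot 95% CI half-width of the median, $1.58\,\mathrm{IQR}/\sqrt{n}$.
SE and notch are reported missing for $n<2$. Inferential model fits (linear
models, trees, forests) are deliberately out of scope: they are
off-the-shelf analyses users can run on the measurements CSV with any
statistics package.

## The synthetic generator

`generate_branch_contour()` builds an analytic stand-in for a digitized
ventral-branch outline: three Gaussian bumps (two spines of amplitude
`spine_height` at normalized positions 0.30/0.70, one central ridge of
amplitude `ridge_height`, all with `bump_width` = 2.5 um) on a raised
plateau whose C² smootherstep shoulders fall outside the landmark window.
The plateau is exactly flat across all five extrema, so the construction's
ground-truth ST is `spine_height - ridge_height` up to Gaussian tail
overlap (about 1%), and ground truth is computed *exactly*: the five true
landmarks are located by numeric optimization of the generating function
and `true_st` is `spine_thrust()` of them, identically. Parameter
combinations that merge extrema are a generator error, not silently wrong
truth.

Digitization noise is modeled as low-pass-filtered Gaussian displacement
along the local normal (window ~3% of the contour), mimicking the smooth
wobble of a freehand pen stroke rather than white pixel noise; the sd
defaults to 0.5 um in population simulations. What the generator does *not*
emulate: background clutter, partial occlusion of the branch outline,
digitizer-specific systematic bias, and real biological shape variation
beyond the spine/ridge amplitudes. Passing recovery tests on these shapes
therefore demonstrates the correctness of the computation, not the field
accuracy of the whole imaging protocol.

`generate_population()` simulates a rearing-temperature study. The default
design is 2 species × 2 temperatures × 30 individuals: a plastic rounded
species with mean ST 0.5 um at 25 °C rising by 3.4 um at 18 °C (the
magnitude of the temperature effect reported for *D. santomea*), and a
spiny species at mean ST 9.0 um at both temperatures (the magnitude of the
interspecific difference, with no plastic response, as in *D. yakuba*).
Within-group sd defaults to 1.5 um — a free simulation parameter chosen to
give a few micrometers of within-group spread, not an empirical value.
Individual target ST values are realized geometrically
(`spine_height = ridge_height + target`), so group effects are carried by
contour geometry, and contours are emitted in pixel image coordinates so a
simulated study exercises the full normalization path. Guard rails clamp
targets to the range where all five extrema exist (spine amplitude at least
0.5 um); at the default means this truncates under 3% of draws and shifts
group means by well under 0.1 um. All randomness flows from the explicit
seed.

```{r example, eval = FALSE}
shp <- generate_branch_contour(spine_height = 4, ridge_height = 1,
                               jitter_sd = 0.5, seed = 1)
prof <- curvature_profile(shp$contour)
det <- detect_landmarks(prof)
plot_curvature_profile(prof, det)
spine_thrust(det)
```

## Problem sizes and determinism

The shipped tests and the acceptance script use synthetic datasets sized
for quick, exact verification: 800-point arcs for the curvature oracle, 100
shapes per recovery sweep, 20 specimens × 3×3 grid for the tuner oracle,
and the 120-specimen default population. These sizes give stable statistics
(group-mean standard errors near 0.3 um) while keeping a full verification
run in minutes on one core. The pipeline itself is deterministic: identical
inputs and parameters give bit-identical measurement tables, which the
tests assert by hashing rerun outputs.

## Known limitations

* The method starts at digitized contours; it does not do image processing,
  and poor mounting or tracing quality surfaces only as exclusions.
* ST conflates size and shape by design; centroid size and full Procrustes
  analyses are out of scope.
* The refinement stage is unit-calibrated (threshold in inverse
  micrometers, window in points), so results depend on supplying the
  correct pixel scale and on point densities in the typical 500–1000 range.
* The midline constant and the 20% exclusion window were estimated on the
  original training material; strongly asymmetric digitization styles may
  need re-estimation.
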