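---
title: "From repeated field imagery to genotype-level phenology: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From repeated field imagery to genotype-level phenology: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`phenofield` turns a season of repeated RGB images of a field trial into
genotype-level phenology. This vignette explains the statistical model and
the procedure behind each stage, the tunable parameters and their defaults,
what the synthetic campaign generator emulates (and what it does not), and
the numerical and design choices a maintainer would want spelled out.

## The greenness signal

The pixel-level quantity is the green chromatic coordinate,

$$\mathrm{gcc} = \frac{G}{R + G + B},$$

where $R, G, B$ are the digital numbers of a pixel. Because gcc is a ratio,
multiplying all three channels by a common factor leaves it unchanged, which
is what makes it usable with uncalibrated cameras under changing scene
illumination. Its two companions, the red and blue chromatic coordinates,
complete a partition of unity; `compute_gcc()` treats an all-zero pixel as
invalid (excluded from statistics) rather than an error.

A plot observation is the *interquartile mean* of the per-pixel gcc values
inside the plot's polygon mask: pixels whose gcc lies within the 25th-75th
percentile band (linear-interpolation percentiles, bounds included) are
averaged. The trim exists because fixed obstacles -- platform cables, patches
of visible soil -- contaminate a minority of pixels with extreme values; any
contamination confined to less than a quarter of the mask on one side of the
distribution is excluded wholesale. Masks are static over the season and
deliberately conservative (drawn inside the plot), and an observation needs
at least `min_mask_pixels = 40` valid pixels, otherwise it is recorded as
missing. Frames are screened by a local-time daylight window (default
08:00-18:00) and a mean-luminance floor (default 20 on the 8-bit scale)
before extraction.

## Daily signal

Within a day, the plot's observations are collapsed to their median
(`daily_aggregator = "median"`). The median was preferred over the 90th
percentile used elsewhere in the PhenoCam literature because it is markedly
less sensitive to illumination regimes that brighten a minority of frames;
the 90th-percentile aggregator remains available behind the config switch
for comparison. Days with no valid observation stay missing in the raw
series -- they are flagged, never silently interpolated.

The daily series is then smoothed with a Savitzky-Golay filter, third-order
polynomial, seven-day window (`sg_poly_order = 3`, `sg_window = 7`). Two
numerical choices matter here:

* **Gaps.** The filter needs a regular grid. Interior gaps of at most
  `max_gap_interp_days = 3` days are bridged by linear interpolation (and
  flagged in the output); longer gaps split the series into segments that
  are smoothed independently. Segments shorter than the window pass through
  unsmoothed with a warning.
* **Edges.** Boundaries use polynomial extension -- the boundary-window
  least-squares polynomial evaluated at the edge days -- rather than mirror
  padding, which would manufacture artificial extrema exactly where the
  season's start and end points are detected. The smoothing engine is
  `signal::sgolayfilt()`, which implements both the interior projection and
  this edge rule; the test suite checks it against a brute-force windowed
  least-squares oracle at every interior point.

## Phenological time points

Detection operates on the per-plot signal rescaled to $[0,1]$
(min-max over the season), which makes every rule invariant to affine
transformations of the raw signal; the slope thresholds below are in scaled
units per day. Four points are extracted, in this order:

1. **Green peak (GP)** -- the first local maximum after green-up onset
   (the first day the scaled signal exceeds `greenup_level = 0.2`).
2. **Senescence peak (SP)** -- the last local maximum. A unimodal signal
   yields SP = GP, flagged `"unimodal"`.
3. **Start of green-up (SOG)** -- the first day before GP whose backward
   difference exceeds `sog_slope = 0.015`.
4. **End of senescence (EOS)** -- the first day after SP, beyond the initial
   steep decline, whose backward difference exceeds `eos_slope = -0.01`
   (strict inequality). A variant that takes the first local minimum after
   SP instead is available via `eos_method = "minimum"`; the slope rule is
   the operative default because it is the quantitative definition.

Start of senescence is deliberately not extracted: slope-change rules for it
are unreliable across genotypes whose yellowing begins gradually.

Robustness refinements, each motivated by an identified noise mechanism and
exposed as a config key:

* **Local maxima** require $s(d)$ at least its neighbours with one strict
  inequality; plateaus resolve to their earliest day. Candidate peaks must
  reach a scaled height of `min_peak_height = 0.35` and a topographic
  prominence of `min_prominence = 0.02`. The height floor is set well above
  the dormant-baseline level of a scaled greenness series (typically
  0.15-0.2): without it, noise bumps on the pre-green-up baseline or the
  post-season tail can qualify as "first" or "last" maxima.
* **The SOG scan skips the first half-window of days** (`sg_window`-driven):
  at the series edge the smoother extrapolates its boundary polynomial,
  which inflates the variance of the first few slopes enough to trip a
  strict threshold spuriously.
* **SOG crossings must lie on the rising envelope into the peak**: after the
  crossing the signal may never fall back to within `sog_slope` of the
  pre-crossing level before GP. Weather episodes shared across plots can
  produce multi-day rises of the dormant baseline that clear the slope
  threshold; requiring the rise to be sustained all the way into the peak
  separates these from the true green-up.
* **The EOS scan starts only after the signal has dropped
  `eos_drop_guard = 0.05` below SP**, so the flat top of the peak itself
  cannot satisfy the slow-decline rule.

Phase durations (`GP_SOG`, `SP_SOG`, `SP_GP`, `EOS_SP`, `EOS_GP`) are plain
DAS differences. Time points are detected on the spatially *uncorrected*
per-plot signal; correction happens afterwards, and phase durations at the
genotype level are computed from the *corrected* time-point estimates --
that ordering is part of the workflow definition.

## Spatial correction and heritability

Plot values of any response -- gcc at a date, a time point's DAS, a trait --
are decomposed as

$$Y = f(r, c) + Z_g c_g + Z_r c_r + \varepsilon,$$

with $f(r,c)$ a smooth bivariate surface over row and range (column)
positions, $c_g$ genotype effects, $c_r$ random row effects and
$\varepsilon$ i.i.d. noise. The surface absorbs classical field
heterogeneity *and* the viewing-geometry pattern of an obliquely mounted
camera: the zenith angle varies continuously across the field, so its effect
on the signal is treated as one more continuous component of spatial
heterogeneity rather than modelled through the zenith covariate (which is
carried in the layout only as diagnostic metadata).

The surface is parameterized PS-ANOVA style: cubic B-spline bases per
dimension (default `min(ceiling(d/2), 10)` segments for `d` distinct
positions) with second-order difference penalties, eigendecomposed into an
unpenalized polynomial part (intercept, linear row, linear column, their
product) plus five penalized smooth blocks (row-smooth, column-smooth, two
linear-by-smooth interactions, smooth-by-smooth), each entering the mixed
model with its own variance. Second differences annihilate linear trends,
so the polynomial part alone reproduces plane surfaces exactly.

Variance components are estimated by deterministic Schall-type REML
iteration on the mixed-model equations: solve the penalized normal
equations, compute each random block's *effective dimension*
$\mathrm{ED}_k = q_k - \lambda_k\,\mathrm{tr}(C^{-1}_{kk})$ (its share of
the hat-matrix trace), update
$\hat\sigma^2_k = \lVert u_k\rVert^2/\mathrm{ED}_k$, and iterate. The
relative tolerance is $10^{-6}$ on effective dimensions and variances.
Because these fixed-point updates converge only linearly -- and slow down
markedly when a variance approaches zero -- the iteration cap defaults to
5000 (iterations cost well under a millisecond at trial sizes), and a
component whose variance ratio falls below $10^{-8}$ is pinned at a fixed
large penalty and frozen: it is numerically out of the model, and letting
its penalty crawl upward would stall convergence without changing any
estimate. The trace identity (fixed-effect count plus all effective
dimensions equals the trace of the influence matrix) holds to numerical
precision and is asserted in the tests.

Two fits per response:

* **Genotype fixed** gives the genotype BLUEs ("genotypic values"). Each
  BLUE is reported on the response scale as the model prediction for that
  genotype averaged over all observed field positions, so BLUEs are
  directly comparable to phenotypic means and shift one-to-one under
  location shifts of the data. BLUEs rather than BLUPs are the primary
  output: with ten genotypes and no pedigree information, the genetic
  variance needed for meaningful shrinkage cannot be estimated reliably.
* **Genotype random** gives the generalized heritability
  $H^2 = \mathrm{ED}_g / (m_g - 1)$, where $m_g - 1$ is the upper bound the
  genotype effective dimension attains when genotypic variance dominates.

## Trait analysis

`correlate()` reports the coefficient of determination of a simple linear
regression with the slope sign carried separately, mirroring how such
results are presented graphically (bars below a dashed zero line for
negative relationships). The analysis level -- phenotypic (plot values) or
genotypic (BLUEs, $n$ = number of genotypes) -- is an explicit field of the
result, and inputs must be keyed, so the two levels cannot be mixed
silently. All pairs are reported with their p-values (flag at $p < 0.01$
downstream if desired); no multiple-testing correction is applied, which is
a caveat to keep in mind when scanning many pairs.

Two structured relationships get dedicated fits. The senescence-rating
regression is split at a configurable rating (default 65%): greenness rises
with the rating while leaves yellow in place, and falls once leaf drop sets
in, so a single regression would be meaningless. The gcc-LAI curve is
fitted linearly on LAI between `lai_min = 1` (the optical reference is
unreliable below) and 2.5, and the saturation LAI is estimated as the
midpoint of the first 0.5-wide LAI bin from which the local slope stays
below `lai_sat_frac = 0.1` of the linear-regime slope; the persistence
requirement keeps single noisy bins from declaring saturation. The
saturation rule itself is a package invention -- the underlying phenomenon
is usually eyeballed -- so its two parameters are exposed in the config.

## The synthetic campaign generator

No suitable public campaign dataset exists at this scale, so the generator
is a first-class module with exact ground truth; every claim the test suite
makes about recovery is a claim against this truth, recorded in the
campaign manifest.

**Trajectories.** A plot's noise-free season is built from an explicit
per-day slope schedule through anchor days -- start of green-up, green peak,
shoulder dip, senescence peak, end of senescence -- with linear slope ramps
per segment, rescaled to hit each anchor value exactly. Compared with
fitting a closed-form double logistic, this makes the true transition days
exact by construction: anchors are exact local extrema on the daily grid,
the first post-onset slope exceeds the green-up threshold while the
approach slopes stay below it, and the senescence decline eases through the
end-of-senescence threshold at its anchor. Defaults place the anchors at
DAS 48 / 76 / 125 / 144 with a baseline gcc of 0.345 and a green-peak gcc
of 0.44 -- the canonical soybean season. The default season length is 156
days (sowing to harvest plus the senescence tail of the latest genotypes).

**Design and effects.** Ten genotypes in eight complete blocks (one block
per grid column) on a 10 x 8 grid, genotype order randomized within block.
Genotype timing shifts are evenly spaced: 2 days of spread for green-up
onset, 6 for the green peak and 14 for the senescence peak -- the maturity
range of a realistic cultivar set -- plus per-plot jitter (SD 0.8 days). On
top of the trajectories sit a smooth field trend (amplitude 0.006 gcc), and
a zenith-angle gradient (mid-season amplitude 0.006 gcc) whose sign is
positive early and negative mid-season, with cosine-eased transitions over
20 days -- an abrupt sign flip would inject a slope step into every signal
and masquerade as a phenological event.

**Observation noise.** Timestamps are shared across plots (one camera):
4-60 images per hour within the daylight window. Noise has four parts: a
per-timestamp illumination term shared across plots (SD 0.01, largely
removed by the daily median over hundreds of images), a shared AR(1)
day effect (innovation SD 8e-4, autocorrelation 0.6 -- weather carries
over), independent per-observation noise (SD 0.004), and a configurable
fraction (1%) of obstacle outliers at cable-dark gcc. The day-effect
magnitude reproduces the tight scatter of daily medians around the smoothed
curve that a fixed camera produces; configurations with rougher weather are
available but then slope-threshold detection degrades for the start of
green-up first -- that is a property of threshold rules on shared noise, and
the reason the SOG envelope condition exists.

**Rendering.** Optionally, each plot is drawn on a canvas as a rectangle
whose colour encodes its true gcc (green channel solved from the gcc at
fixed red and blue), with per-pixel Gaussian channel noise, soil background
and dark cable stripes. The default canvas (600 x 400, 80 plots) yields
masks of roughly 2,500 pixels, inside the 1,000-9,400 range typical of real
plot masks. Rendering density (default 2 frames/day) is an artifact control
separate from the observation-level capture frequency: rendering a full
campaign at tens of frames per hour would produce hundreds of thousands of
images without testing anything the extractor does not already see. Note
that 8-bit PNG quantization bounds the attainable round-trip accuracy of
the colour encoding at about 2.5e-3 gcc.

**Traits.** Early vigor (1-8) is generated anticorrelated with the
genotype's green-peak timing; LAI follows a logistic rise saturating near 6;
senescence ratings at six dates per plot pass 65% at the plot's senescence
peak and 100% at its end of senescence; harvest traits (yield, thousand
kernel weight, oil content) carry configurable linear dependencies on phase
durations. Setting `dependency_scale = 0` yields null traits for
calibration checks.

**What passing tests do and do not show.** The generator emulates the
*structure* of a real campaign -- design, trajectories, spatial and
viewing-geometry confounding, shared weather noise, obstacles -- but not
soil-background reflectance changes with crop cover, canopy-structure
interactions with direct versus diffuse light, mask drift with crop height,
or within-canopy senescence gradients that oblique cameras cannot see.
Recovery results on synthetic campaigns therefore validate the pipeline's
logic and statistics, not its performance on any particular real camera
installation.

## Problem sizes used in the checks

The automated checks run at deliberately moderate sizes chosen to exercise
the methods fully: one 80-plot campaign at full capture frequency for the
end-to-end statistics, 100-200 simulated plots for detector recovery
rates, 100 simulations per arm for the heritability calibration, 20
campaigns for the viewing-geometry absorption property, and a rendered
150-day campaign at 2 frames/day for the deterministic end-to-end run.

## Known limitations

* Geometric registration, camera calibration and plant/soil segmentation
  are out of scope; masks are assumed static and conservative.
* The SOG slope rule remains the least robust of the four detectors under
  strongly autocorrelated day-to-day noise, even with the envelope
  condition; the senescence-side points are insensitive to the same noise.
* Heritability from effective dimensions is bounded in $[0,1]$ by
  construction but is a generalized, design-dependent quantity; it is not
  comparable across trial designs.
* BLUE standard errors condition on the estimated variance components, as
  is conventional for mixed-model downstream reporting.
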