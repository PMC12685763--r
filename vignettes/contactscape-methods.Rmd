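---
title: "Inferring resource-driven contacts from GPS telemetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring resource-driven contacts from GPS telemetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(contactscape)
```

## The problem

When solitary mesocarnivores such as raccoons share an urban greenspace,
their opportunities to interact — and to transmit pathogens like canine
distemper virus — are shaped by where clumped resources sit on the
landscape. `contactscape` implements a complete pipeline for asking whether
conspecific *contacts* (close spatiotemporal co-occurrences on GPS collar
tracks) happen disproportionately near particular resources, over and above
each animal's own use of those resources, and for characterising the types
of contact that occur.

The pipeline has six analysis stages plus a synthetic-data generator that
makes every stage testable with known ground truth:

1.  fix quality control (`filter_fixes`, `apply_capture_mask`,
    `check_min_support`);
2.  continuous-time movement models and range residency
    (`empirical_variogram`, `assess_range_residency`,
    `fit_movement_models`, `estimate_home_range`, `crossing_time`);
3.  1-minute conditional-mean track interpolation (`predict_track`);
4.  dyadic contact detection and event grouping
    (`detect_contact_points`, `group_events`, `classify_event`);
5.  availability sampling and the weighted mixed logistic contact RSF
    (`sample_non_contacts`, `build_rsf_data`, `fit_rsf`, `rss_report`,
    `validate_calibration`);
6.  multiple correspondence analysis of contact-event typologies
    (`build_indicator`, `run_mca`, `assign_typologies`).

## Quality control

Fixes are dropped when they are 2D with pDOP above 5 or have fewer than
three satellites in view; 3D fixes are kept regardless of pDOP, because the
precision rule binds only the weaker 2D solutions. Relocations from
recaptured animals are masked from 20:00 local on the capture night until
14:00 the next afternoon; we treat the window as half-open (the 14:00 fix
survives) since boundary semantics are otherwise arbitrary, and a capture
logged before 14:00 local is attributed to the night that began the
previous evening. Animals enter the analysis with at least 150 relocations
(inclusive) and a range-resident variogram. All local-time logic uses a
fixed UTC offset (default -4 h, matching the US East Coast in late summer);
there is no daylight-saving handling.

An optional maximum-speed screen is deliberately not enabled by default:
speed/distance outlier rules need study-specific thresholds, and none is
built into the package.

## Movement models

Three stationary Gaussian forms are fitted per animal by exact maximum
likelihood: IID (uncorrelated positions), OU (range-resident positions with
autocorrelation timescale `tau_pos`), and OUF (OU positions with correlated
velocities, `tau_vel < tau_pos`). The likelihood is evaluated with a
sequential Kalman filter over the irregular fix schedule — one state per
axis for OU, a position-velocity pair for OUF — with the GPS error variance
as a fitted or fixed nugget. A dense multivariate-Gaussian evaluation from
the model autocovariance is kept as an independent route; the test suite
checks the two agree to 1e-8. Plain ML is used rather than a
restricted/perturbative-hybrid variant, which biases variance estimates
slightly low at small effective sample sizes; parameter-recovery tests run
at the sample sizes we actually use.

Model selection uses AICc, `-2 lnL + 2k + 2k(k+1)/(n-k-1)`, with the
penalty set to infinity when `n - k - 1 <= 0`. For the IID form the error
nugget is not separable from the positional variance, so a single total
variance is fitted there.

Range residency is assessed from the empirical variogram (half the mean
squared displacement per lag bin, both axes summed; for an isotropic OU
process it converges to `2 sigma2 (1 - exp(-lag/tau))`). The default bins
stop at one fifth of the track span: longer lags are carried by few, highly
dependent pairs whose empirical semivariance is unstable. An animal is
resident when the mean semivariance over the last half of the bins has not
grown more than 15% over the preceding window and shows no significant
monotone increase (one-sided Spearman test at p = 0.01) — a significant
trend only disqualifies when the window in fact grew, since pure wiggle
without growth is noise. This operationalises what is usually a visual
"reached an asymptote" judgement; on simulated data it separates OU tracks
from random-walk drifters cleanly across seeds.

## Home ranges

Home ranges are Gaussian kernel density estimates whose reference
bandwidth uses the autocorrelation-adjusted effective sample size
`N_eff = tracking duration / tau_pos` instead of the raw fix count
(`H = S * N_eff^(-1/3)` with `S` the fix covariance). The 95% isopleth is
the smallest set of grid cells holding 95% of the kernel mass; area is
reported in hectares. This is a simplification of the weighted,
area-corrected autocorrelated KDE used in the source workflow: it keeps the
autocorrelation adjustment that matters downstream (the home-range union
constraint on availability sampling) while avoiding that estimator's
optimal-weighting machinery. Ranges are represented as grid masks, and
point-in-range queries are nearest-cell lookups; landscape polygons, by
contrast, stay vector rings with an even-odd containment rule. KDE
smoothing inflates the area of a Gaussian truth by roughly
`(1 + N_eff^(-1/3))`; tests allow 15%.

## Interpolation and contact detection

Tracks are interpolated to a shared 1-minute grid with the conditional
mean of the fitted process given the two flanking fixes (an OU bridge),
clipped to the observed span — no extrapolation. For a Markov (OU) process
without measurement error this two-point bridge *is* the exact full-track
smoother; with a GPS error nugget it deviates from the dense smoother by
under 5% of the typical prediction SD while costing O(1) per grid point, so
the bridge is the default and the smoother sits behind
`predict_track(..., method = "smoother")`. Conditional simulation, which
would widen detection by sampling around the mean path, is intentionally
not used; the conditional mean makes detection conservative.

A contact point is a grid minute at which a dyad's predicted positions are
within 15 m (inclusive; the comparator is exposed because "within 15 m"
and "15 m or less" coexist in common usage), retained only in runs of at
least two consecutive minutes. Contact points live at the dyad midpoint.
Maximal 1-minute-lag runs form contact events, located at the
minimum-distance minute (ties to the earliest). Durations class as short
(1-3 min), medium (4-6) and long (7+; seven minutes is assigned long so
the classes partition the integers). The clock window of the *first*
minute classes an event as foraging (21:30-04:30 local) or denning
(otherwise — including daytime, when the animals den). Detection offers a
spatial-hash path that only computes distances for minutes whose 15 m grid
cells are adjacent; it is bit-identical to the brute-force path and both
are kept so each can audit the other.

## Availability sampling and the contact RSF

For every contact point, five minutes per dyad member are drawn uniformly
without replacement from that member's eligible predicted minutes:
inside the union of the dyad's 95% home ranges, within the overlapping
tracking period, at least 25 m (1.5x the contact threshold) from every
tracked individual at that minute, and not during any contact involving
the member. Without-replacement is enforced within each contact point's
draw; across contact points minutes may recur. When fewer than five
eligible minutes exist the sampler takes what there is and logs the
shortfall — it never resamples with replacement. The eligible pool is not
restricted to night minutes; a night-only restriction is a caller-side
filter if wanted.

Distance covariates come from the five-class resource landscape
(anthropogenic, fruiting plant, denning tree, meadow, water). Point
features carry a 2 m buffer; building footprints become 2 m exterior rings
with the interior excluded; den trees qualify by DBH > 76.2 cm on-site or
volume > 1000 (an opaque attribute threshold, units as supplied) off-site.
Distances can be rasterized (0.25 m cells by default, evaluated at cell
centres from the min corner) or computed exactly from the vector geometry;
at fine resolutions over large extents the exact path is the default
choice since a full raster would be enormous. Covariates are screened for
collinearity (|Pearson r| >= 0.6, inclusive; within an offending pair the
member with the larger mean absolute correlation to the others is dropped
— a resolution rule of ours, since any screen needs one) and z-scored with
moments pooled over used and available rows, the spec persisted so new
points transform identically.

The population-level contact RSF is a weighted logistic mixed model:
used (1) versus available (0) with weights 1/1000 to approximate the
inhomogeneous point-process likelihood, a random intercept per dyad whose
variance is *fixed* at 1e6 (imposed through the optimizer's parameter map,
so it is never estimated — the standard large-variance trick that frees
the dyad-specific availability constant), and independent random slopes
per covariate. Dyads enter with at least 10 contact points over at least
2 events (both inclusive). Fitting uses glmmTMB's Laplace approximation;
a singular slope variance is fixed at zero and the model refitted, with a
warning. A hand-written IRLS fitter for the no-random-effect model
(`rsf_irls`) is the independent cross-check: with random effects removed
the two routes agree to 1e-4 or better. Candidate covariate sets are
compared by AIC with exact ties going to the smaller set.

`rss_table` exponentiates coefficients into relative selection strengths
with Wald 95% intervals, plus the one-SD-closer multiplier `exp(-beta)`
natural for distance covariates. Calibration (`validate_calibration`)
ranks rows into equal-count bins of the fitted selection score and
regresses each bin's observed share of used points on the share expected
from availability-weighted selection weights; a well-specified model gives
slope near 1 and high R-squared.

## Contact typologies (MCA)

Events are described by six categorical variables — duration class (3
levels), sex pairing (3), clock window (2), and binary presence of
anthropogenic, natural (fruiting plant) and denning-tree resources within
15 m of the event location (2 each) — giving J = 14 categories when all
levels occur. The natural-resource layer is the fruiting-plant class;
meadows and water are covariates for the RSF only. The indicator matrix is
decomposed by plain correspondence analysis (no Burt matrix, no
Benzecri/Greenacre correction): total inertia is `(J - Q)/Q = 4/3`, and an
eigenvalue of 0.27 therefore carries 20.25% of the variance — the
uncorrected convention is the one under which that arithmetic goes
through. cos2 (quality of representation) and per-dimension contributions
are returned for every category. Because SVD axis signs are arbitrary, the
axes are oriented so anthropogenic presence loads negative on dimension 1
and long duration positive on dimension 2; events are then typed by
quadrant — (+,+) Type I, (-,+) Type II, (+,-) Type III, remainder
unassigned — keeping quadrant semantics stable across platforms.

## The synthetic generator

`sim_config` defaults encode the study conditions the package emulates:
19 collared adults (9 males, 10 females); positions every 15 min through
the 19:00-07:00 night window and every 4 h by day; isotropic OU movement
with `tau_pos = 2.81` h (the reported mean home-range crossing time) and
`sigma2 = 17465` m^2, whose Gaussian-equivalent 95% range of ~33 ha
matches the reported mean home range; 5 m GPS error (the 15 m contact
threshold is described as covering typical GPS error); pDOP lognormal
around 2.5 with mostly-3D fixes, enough to exercise the QC rules; and 5%
fix dropout, the kind of loss a LoRaWAN downlink produces. OU tracks are
sampled with the exact transition law, so simulated marginals are correct
at any gap; OUF is fitted but not simulated (OU suffices as a generative
counterpart). `implant_co_occurrences` deforms both members' fixes toward
an anchor feature over a visit window with a raised-cosine blend over
±10 min so the track stays continuous (no teleportation artifacts in the
variogram); fixes outside the blend are bit-identical.
`generate_used_available` inverts the RSF directly: available points
uniform in each dyad polygon, used points by true rejection sampling
against `exp(sum beta_k z_k)` with covariates standardized by reference
moments from a pooled uniform sample, so recovery tests have an exact
known truth.

What the generator does **not** emulate: behavioural feedback (foraging
decisions, social attraction), habitat-dependent movement, anisotropy,
temporally varying GPS quality, or fix-rate changes. Passing tests
therefore show the *estimators* are correct under the stated model, not
that the model captures every feature of real telemetry.

## Problem sizes and numerical choices

The test-suite and acceptance-script scenarios use sizes chosen to make
Monte-Carlo tolerances meaningful while keeping runs comfortably
reproducible on a laptop: movement recovery uses 20 replicate tracks of
1000 fixes; RSF recovery uses the study's scale (38 dyads, ~85 used
points each, 10:1 availability) over 10 replicates; the end-to-end
scenario uses 8 animals over 12 days with 28 implanted 30-minute trash
visits (30 minutes spans at least three scheduled fixes, so a single
dropout cannot erase a visit), each dyad splitting its visits across two
different cans so the used points do not collapse onto a handful of
locations (quasi-separation makes weighted-logistic coefficients
explode). The end-to-end landscape is the fixed layout of
`validation_landscape()`, not a random draw: fruiting plants and denning
trees sit on a dense lattice excluding the neighbourhoods of the cans,
so the implanted anthropogenic effect cannot be confounded by a chance
adjacency between a can and another class — a random landscape would
test the draw, not the pipeline, and single draws do occasionally place
a meadow beside a visited can. The run seed still drives all movement,
GPS and sampling randomness. In this small-dyad scenario the RSF is
fitted with the fixed-variance random intercept but without random
slopes: with only four dyads the slope variances are unidentifiable,
and the full random-slope model is exercised at the study scale instead.
Optimization uses Nelder-Mead on log/logit-transformed parameters with two
timescale starts; `tau_vel` is parameterised as a fraction of `tau_pos` so
the OUF constraint can never be violated. Zero-length runs, empty feature
classes, all-zero acceptance regions, sub-3 effective sample sizes and
constant covariates all raise early, descriptive errors.

## Known limitations

* ML (not REML-like) variance estimates are biased low for short tracks.
* The KDE isopleth area inflates with bandwidth; at `N_eff` below ~30 the
  15% agreement with a Gaussian truth degrades.
* The anthropogenic-RSS lower interval printed in the source study does
  not follow the Wald transformation of its own coefficient table; we
  implement the Wald rule and make no attempt to reproduce that single
  endpoint.
* The published coefficient table's water-body row duplicates the meadow
  row; the packaged estimate file carries the four internally consistent
  rows only.
* Dyad random-slope variances near zero leave the Laplace Hessian
  non-positive-definite; the refit-at-zero path handles it but the
  reported slope variance is then a boundary value, not an estimate.
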