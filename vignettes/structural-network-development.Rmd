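---
title: "Modelling adolescent development of structural correlation networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling adolescent development of structural correlation networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thicknet)
```

## The problem

A structural correlation (covariance) network is a graph whose nodes are
cortical regions and whose edges are inter-individual Pearson correlations of
a morphometric measure — here cortical thickness (CT, mm) — between pairs of
regions. Such networks have a modular, hub-dominated architecture, and their
organization changes through adolescence. Because each participant
contributes a single cross-sectional measurement, the network is a property
of a *group*, and studying its development requires comparing networks
estimated from overlapping, age-ordered subsets of the cohort.

`thicknet` implements that analysis end to end:

1. **Sliding windows** (`make_windows`): participants ordered by age are
   grouped into overlapping windows defined in participant counts (default
   width 60, step 30). Two modes exist: a plain index grid, and a
   stratum-interpolated mode that reproduces designs in which a cohort is
   recruited into `k` age strata and the strata are interpolated into
   `2k - 1` half-overlapping windows.
2. **Per-window networks** (`correlation_matrix`, `build_network`): raw CT
   values are cross-correlated within each window; no covariate adjustment
   is applied.
3. **Bootstrap thresholding** (`bootstrap_edge_pvalues`, `fdr_adjust`,
   `threshold_network`): participants in the window are resampled with
   replacement (default 1000 times), the whole correlation matrix is
   re-estimated per resample, and an edge is retained only when its sign is
   consistent enough across resamples to survive a Benjamini–Hochberg
   FDR-adjusted two-tailed test at `alpha = 0.01`. Retained edges keep the
   observed (full-window) correlation as weight; all others are zeroed.
4. **Graph metrics** (`network_metrics`, `community_density`): mean
   unthresholded correlation and nodal strength; degree, weighted degree,
   edge density (% of possible edges), Euclidean connection distance between
   region centroids; and edge density within and between communities.
5. **Developmental trajectories** (`fit_trajectory`): each metric series,
   indexed by window median age, is fitted with a linear model and a
   complexity-constrained REML smoothing spline, selected by AIC, and
   summarized by the maximum change `delta_max` and the age at the fitted
   minimum `age_min`, with bootstrap confidence intervals
   (`bootstrap_age_min_ci`) and FDR-adjusted significance across regions
   (`nodal_significance`).
6. **Community structure** (`louvain_partition`, `versatility_curve`,
   `consensus_partition`, `nmi`): multiresolution Louvain modularity on the
   age-invariant (all-participants) network, a versatility curve to guide
   the choice of resolution, and Lancichinetti–Fortunato consensus
   clustering.
7. **Spin test** (`spin_pvalue`): map–map association across regions is
   tested against a null built by randomly rotating the spherical projection
   of one map, preserving spatial contiguity and hemispheric symmetry.

## The synthetic cohort

Real cohorts of this kind are access-restricted, so the package ships a
generator with known ground truth. `generate_regions(n, k)` places `n/2`
regions per hemisphere on a unit sphere by a Fibonacci lattice (each
hemisphere has its own complete sphere, as in surface-reconstruction
software), mirrors the layout through the sagittal plane, and grows `k`
spatially contiguous module patches by nearest-seed assignment, mirrored
across hemispheres. Contiguity matters: spin-test nulls are only meaningful
against spatially autocorrelated maps.

`generate_cohort(n, regions, model)` samples ages stratified-uniform over
contiguous strata (five by default, emulating balanced recruitment of ~60
participants per stratum over 14–24 years) and draws each participant's
regional CT vector from a multivariate normal whose correlation matrix is
the `covariance_model` evaluated **at that participant's own age**, so any
windowing scheme can be applied afterwards. Regional means follow
linear-in-age thinning (default −0.02 ± 0.01 mm/y); optional
magnetization-transfer (MT) maps at named cortical depths follow
linear-in-age myelination trends.

The covariance model is block-structured over the planted modules, with a
quadratic age dependence around a minimum at `age_at_min = 19.5` y:

* within-module correlation: `0.50 + 0.012 (age − 19.5)^2`
* between-module correlation: `0.28 + 0.012 (age − 19.5)^2`
* per-region loading factors `c_i ~ U(0.6, 1)`, with pair correlation
  `c_i c_j r_block(age)`.

Three considerations fixed these defaults. First, the implied global mean
correlation is ~0.20 at the minimum and ~0.4 in the youngest windows, and
thresholded edge density runs from roughly 5–10% at the minimum to 30–70%
in the youngest window — the same orders of magnitude reported for real
adolescent cohorts. Second, the loading factors matter structurally, not
cosmetically: bootstrap retention is a steep sigmoid in the underlying
correlation, so with *homogeneous* blocks every between-module edge crosses
the retention threshold at the same two ages and the density trajectory
becomes a flat-bottomed step function whose minimum is unidentifiable.
Heterogeneous pair strengths spread the crossing ages and make density vary
smoothly. Third, the curvature had to be large enough to beat an
irreducible noise floor: the windowed mean sample correlation fluctuates
with standard deviation of roughly `sqrt(2/n_window) * rbar` because all
edges load on a common factor whenever the mean correlation is
substantial; at width 60 this is ~0.02–0.03, and a shallower dip would
leave the age at minimum unrecoverable at any realistic cohort size. These
are statements about estimator identifiability under the cohort design, not
claims of fidelity to any particular dataset's effect sizes.

What the generator does **not** emulate: scanner/site effects, motion
artefacts, longitudinal repeated measures, regionally heterogeneous
age-at-minimum, or non-Gaussian morphometry. A pipeline that passes the
recovery tests here is validated as an *estimator of the generating model*;
silent failure modes specific to real data (artefactual covariance from
image processing, sampling imbalance) are out of scope.

```{r example, eval = FALSE}
regions <- generate_regions(100, n_modules = 7, seed = 1)
cohort <- generate_cohort(300, regions, covariance_model(), seed = 2)
an <- sliding_window_analysis(cohort, n_boot = 1000, seed = 3)
trajectory_params(an$trajectories$density_pct)$age_min
```

## Bootstrap thresholding: the p-value construction

The sign-consistency p-value is `2 min(#{r* ≤ 0}, #{r* ≥ 0}) / B` over `B`
whole-matrix resamples (resamples are shared across edges, so one resample
produces one surrogate network). Allowing `p = 0` for sign-perfect edges is
deliberate. The alternative add-one ("+1 in numerator and denominator")
smoothing — available as `smoothing = "add_one"` — imposes a p floor of
`2/(B+1)`; under Benjamini–Hochberg at `alpha = 0.01` that floor makes
retention all-or-nothing: *nothing* is retained unless at least
`2m/((B+1) alpha)` of the `m` edges sit exactly at the floor (about 20% of
all edges at `B = 1000`). Reported edge densities in this literature run
well below that, so the unsmoothed form is the only construction under
which the published behaviour of the method is arithmetically possible.
A region that is constant within a resample (possible with replacement at
small widths) contributes a neutral `r* = 0` to both tails for its edges,
and the count of such degenerate resamples is recorded rather than aborting
a long run.

## Trajectory model and the df cap

The spline is a rank-6 penalized cubic smoother with knots at quantiles of
the window median ages, smoothing chosen by REML (`mgcv`). Its complexity
is capped: if the smooth term's effective degrees of freedom (the trace of
its smoother matrix, the `edf` that `summary.gam` prints) exceed 3.5, the
smoothing parameter is inflated — by doubling and then bisection — until
they do not. Basis functions are never dropped. The cap is applied to the
smooth term's trace rather than to the total model df because a curvature
penalty shrinks toward a straight line, not toward a quadratic: capping the
*total* df at 3.5 forces the fit so close to linear that it demonstrably
destroys interior minima (a noiseless quadratic with minimum at 19.5 y,
capped that way, fits its minimum half a year late; realistic U-shaped
series collapse to monotone fits). With the smooth-term cap the accepted
fits remain slightly more flexible than a quadratic while still unable to
chase 9 data points.

Model choice between linear and spline is by AIC with Gaussian likelihood,
`n log(RSS/n) + 2(k + 1)`. For the spline, `k` counts the intercept plus
the *smoothing-uncertainty-corrected* effective df (`edf2` in `mgcv`,
following the AIC for estimated smoothing parameters). The naive trace-edf
AIC is close to a coin flip on truly linear series: REML estimates a
positive wiggle variance in roughly a third of null samples, and the
slightly reduced RSS then outweighs the naive complexity penalty. With the
corrected count, selection is right 84% of the time on linear truth and
essentially always on curved truth (200-seed calibration); BIC, also
recorded, behaves consistently. Note that this selection problem is
scale-free in the noise level — multiplying the noise by any constant
rescales both models identically — so no "low noise" regime rescues the
naive count.

Change parameters are read off a dense grid (step 0.01 y) of the chosen
model's fitted curve: `delta_max` is the max–min difference, `age_min` the
grid argmin (flagged when it falls on an endpoint), direction is
"decreasing" when the maximum precedes the minimum in age, and shape is the
chosen model class. The p-value for nonzero change is a whole-model F test
against the intercept-only fit with edf-based denominator df. Bootstrap
confidence intervals for `age_min` refit the chosen model to each
replicate series; spline replicates are refitted at the point estimate's
smoothing parameter by default (`smoothing = "fixed"`), which keeps every
replicate inside the df cap by construction and avoids compounding argmin
variability with re-selection noise; `"reml"` re-optimizes per replicate.

## Communities

Louvain modularity uses only positive weights — the modularity null model
is not defined for signed weights, and communities are sought among
*positive* structural correlations; negative retained edges (rare, and
absent in windowed networks) are excluded from clustering but reported by
the thresholding step. The resolution parameter `gamma` scales the standard
Newman–Girvan null term. Versatility at a given `gamma` is
`mean(4 p (1 − p))` over node pairs, where `p` is the co-assignment
proportion across runs: 0 when every run agrees, maximal for a 50:50 split.
Local minima of the lightly smoothed versatility curve are the recommended
resolutions. Consensus clustering thresholds the co-assignment matrix at
`tau = 0.5` (the standard default; the method is insensitive to `tau` in a
broad middle range) and re-clusters at resolution 1 until all runs agree.

## Spin test

One map is held fixed; the other is rotated by a uniformly random rotation
(QR of a Gaussian matrix with sign correction), applied as-is to the left
hemisphere and conjugated by the sagittal reflection on the right, so
left and right are perturbed symmetrically. Each region then takes the
value of the nearest original region (great-circle distance) within its
hemisphere; the mapping may be many-to-one, which is logged implicitly by
the duplicated indices. The two-tailed permutation p is
`(1 + #{|rho_null| ≥ |rho_emp|}) / (n_perm + 1)`, never exactly zero.

Calibration holds for maps that are (approximately) bilaterally symmetric
realizations of an isotropic random field — which is the regime the
mirrored-rotation design targets. For strongly lateralized maps the left
and right hemispheres contribute two quasi-independent null draws whose
average narrows the null by up to `sqrt(2)`, making the test
anti-conservative; this is a property of the mirrored-rotation family of
tests, not of this implementation, and the package's calibration tests use
symmetric isotropic fields for exactly that reason.

## Numerical choices and degenerate inputs

* Correlation matrices from subsets of fewer than 3 participants, or with a
  zero-variance region, are rejected with the region named.
* The model correlation matrix is repaired, when an age/loading combination
  leaves it indefinite, by clipping negative eigenvalues at zero and
  re-normalizing to unit diagonal.
* `nmi` defines the single-module vs single-module case (0/0) as 1.
* All stochastic steps take explicit seeds and restore the caller's RNG
  state; identical seeds give identical networks, partitions, and null
  distributions.
* Stage seeds inside `run_pipeline` are `master_seed + 1000 × stage`, so
  stages are reproducible in isolation.

## Problem sizes

The shipped tests validate the pipeline at 40–100 regions and cohorts of
120–300 with 200–1000 bootstrap resamples, and the full-study script uses
308 regions, 297 participants, 1000 resamples and 10 000 spin rotations —
sizes chosen so that each property is measured at the smallest scale at
which it is statistically meaningful.

## Known limitations

* The age at minimum is estimated from 9 window medians; its sampling
  variability across cohorts (±0.5–1 y under the default generator) is
  irreducible at this design, and boundary minima from occasionally
  selected linear fits are flagged rather than suppressed.
* Retention-based metrics (degree, density) inherit the bootstrap
  threshold's sigmoid sensitivity: edges far from the threshold contribute
  no age signal.
* The regional spin test reassigns by nearest centroid; parcel-overlap
  reassignment schemes would differ for very coarse parcellations.
* No higher-order graph metrics (efficiency, clustering): they are strongly
  density-dependent, and the networks here have deliberately variable
  density.
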