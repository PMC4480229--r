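---
title: "The windrift drift model: methods, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The windrift drift model: methods, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`windrift` simulates the drift of pleustonic colonies — organisms such as
the Portuguese Man-of-War that float at the air–sea interface and feel both
the surface current and the wind on their sail.  This vignette is the
package's own account of the model: what is computed, under which
assumptions, which parameters matter, what the synthetic environments do and
do not emulate, and where the genuinely open design choices were made.

## 1. The drift rule

Every colony is an inert Lagrangian particle at the sea surface.  Its
velocity is

$$\mathbf{u} \;=\; \mathbf{u}_c(\mathbf{x}, t)
  \;+\; \alpha\, R\!\left(\pm\theta_{\mathrm{eff}}(|\mathbf{w}|)\right)
  \mathbf{w}(\mathbf{x}, t),$$

with $\mathbf{u}_c$ the gridded surface current, $\mathbf{w}$ the 10-m wind,
and $\alpha$ the windage (leeway) coefficient.

* **Windage $\alpha$** — dimensionless, default **0.10**: colonies are
  dragged downwind at 10 % of the wind speed, the standard leeway figure for
  a colony with an inflated pneumatophore.  At moderately strong winds
  (about 5 m/s) this already yields drift speeds (0.5 m/s) above typical
  open-ocean currents, which is why wind drag dominates offshore while
  shelf/slope currents take over near the coast.
* **Handedness rotation** — *off by default*.  Colonies come in two mirror
  morphologies whose sail is set at an angle, making them sail 10–15° to the
  left or to the right of the wind.  When `handedness_enabled = TRUE`,
  right-handed colonies deviate clockwise (to the right looking downwind)
  and left-handed counterclockwise by
  $$\theta_{\mathrm{eff}} = \theta_{\max}\,
    \mathrm{clip}\!\left(1 - \frac{|\mathbf{w}| - s}{s},\, 0,\, 1\right),$$
  i.e. the full $\theta_{\max}$ (default 12.5°, admissible 10–15°) up to the
  taper wind speed $s$ (default 10 m/s), decaying linearly to zero at $2s$.
  Only the *direction* of the taper is established knowledge (the sail
  flattens and the angle decreases under intense winds); the linear form and
  the $[s, 2s]$ ramp are this package's parameterization.  The sign
  convention (right = clockwise) is a documented convention, audited by the
  mirror-symmetry test rather than asserted from first principles.
* The reference configuration runs without handedness because beaching
  events of interest happen under strong onshore winds, precisely where the
  angle collapses; the left/right machinery exists for sensitivity
  experiments, which show per-beach stranding fractions shifting by well
  under 5 percentage points between an all-right and a 50/50 population.

Colonies do not grow, die, swim, or re-float once stranded: over a two-month
event window they are pure drifters, and tidal washout of stranded colonies
is deliberately out of scope.

## 2. Numerics

* **Integrator.** Fixed-step RK4, default $\Delta t = 1800$ s; a
  forward-Euler option exists for oracle comparisons.  No source states the
  original tool chain's scheme or step; RK4 at 30 min is accurate far beyond
  the physical uncertainty (a gyre-trapped particle holds its orbital radius
  to ≪ 1 % over 30 days) at negligible cost.
* **Interpolation.** Bilinear in space, linear in time.  Corner weights on
  land cells are zeroed and the remaining weights renormalized, which keeps
  near-coast speeds continuous without spurious onshore pull; if all four
  corners are land the sampled velocity is zero.
* **Metric.** Coordinates are geographic degrees; metres are converted with
  a local equirectangular approximation, $dx = \cos\varphi\,M\,d\lambda$,
  $dy = M\,d\varphi$ with $M = 111{,}195$ m/deg.  For domains a few degrees
  across the error is far below the grid resolution.  `grid_spec()` also
  accepts `metric_ref_lat`, which freezes $\cos\varphi$ at a reference
  latitude (an f-plane).  This matters for one audit: reflecting the
  geometry and winds about a zonal midline and swapping left/right
  handedness must produce the mirrored stranding pattern, but on the
  spherical metric $\cos\varphi$ itself breaks the symmetry (reflected
  trajectories see a different longitude metric, enough to move a crossing
  point by a kilometre).  On the f-plane the mirror symmetry is exact — the
  symmetry suite runs there, and the default everywhere else remains the
  spherical-local metric.
* **Beaching.** A step whose end point falls in a land cell strands the
  colony.  The crossing point is located by bisection along the straight
  chord of that step (30 iterations, i.e. to ~$10^{-9}$ of a step), the
  stranding time by the corresponding fraction of $\Delta t$, and the event
  is assigned to the nearest beach segment (ties to the lower id; records
  farther than two grid cells from any segment are kept but flagged
  unassigned).  Stranding is terminal.
* **Exit.** Forward-integrated colonies crossing the open boundary are
  marked `exited` at the clamped boundary position and take no further part.
* **Step-length guard.** If $\Delta t \times$ (peak current + windage × peak
  wind) exceeds one grid cell, the run warns (beaching detection could skip
  a cell) but proceeds.
* **Conservation.** After every step, seeded = active + stranded + exited
  exactly; the per-step ledger is part of every run object and is asserted
  in the test suite.

## 3. The synthetic environments

All experiments run on generated domains so that no stage needs external
data.  The generators emulate the *structure* of the Gulf-of-Cadiz /
Alboran drift problem, not any year's hindcast:

* `two_basin_strait` — two basins separated by a central landmass pierced by
  one narrow strait whose northern shore is continuous with the northern
  coast (as at Gibraltar, where the strait's north side *is* the Iberian
  coast; this continuity is what lets a coastal eastward sweep feed the
  strait).  The eastern basin is closed at its far end.
* `open_coast` — land along the northern edge only.
* `single_gyre_basin` — a fully enclosed basin for retention experiments.

Bathymetry is an exponential offshore profile reaching 20 m one cell off the
coast and 200 m at a configurable shelf width, so the 20–200 m seeding band
exists along every coast by construction.  Beach segments are derived as
maximal straight runs of land–ocean boundary faces, subdivided into chunks
of at most `beach_max_cells` cells (administrative "beaches"), and labelled
west to east — which is what makes "arrivals progressed west to east" a
well-defined statement.

Current kinds: `uniform`; `gyre` (solid-body rotation to the rim radius,
exponential decay outside with a short e-folding, default R/8, so the flow
does not leak through the basin boundary); `slope_current` (zonal,
exponential offshore decay); `strait_jet`; and `composite` (exact cell-wise
sum).  The strait jet is an aperture-flow streamfunction
$\psi = \tfrac{Q}{2}\tanh\!\big(2(y - y_0)/W(x)\big)$ whose width $W(x)$
narrows linearly from the basin scale to the gap width at the strait: the
zonal jet peaks at the requested speed in the gap, and the associated
meridional component converges into the strait from the west and fans out
east of it — the "suction" that lets an upstream coastal population be
drawn through.  A plain zonal jet (no convergence) cannot move coastal
particles through the gap at all.

Winds are lists of non-overlapping episodes of spatially uniform (optionally
linearly sheared) wind, capped at 40 m/s — idealized westerly/easterly
events of order 5–15 m/s.

What these environments deliberately do **not** contain: mesoscale
turbulence, tides, Stokes drift, realistic coastline curvature, or any
reconstruction of an actual year's circulation.  Tests passing on them show
that the *model machinery* behaves correctly (rules, conservation,
integrator accuracy, recovery properties); they do not validate any real
hindcast.

## 4. Seeding

`seed_depth_band()` places $n$ colonies uniformly over the area between two
isobaths (reference configuration: 25,000 colonies between 20 m and 200 m,
the coast-to-continental-slope band).  Sampling is rejection sampling on the
band's bounding box with a $\cos\varphi$ latitude density (uniform over
*area*, not over degrees), using bilinear depth interpolation for the
accept test — consistent with the velocity interpolation.  Whether the real
source population was uniform over the band is unknown; uniform is the
assumption, and the test suite verifies it against stratum probabilities
computed by independent numerical integration (chi-square over 20 equal-area
strata, $\alpha = 0.01$, $n = 25{,}000$).  Handedness labels are allocated
in exact largest-remainder proportions and permuted; populations are
bit-reproducible from (scenario, parameters, seed), and seeding does not
disturb the caller's RNG stream.  An optional `bbox` restricts seeding to a
sub-region of the band — the natural way to express "the population off one
particular stretch of coast".

## 5. Backward source localization

`localize_origin()` answers: given arrivals at one beach segment over a
window, where did that population come from?  It releases `n_virtual`
particles one grid cell off the segment along its outward normal, jittered
uniformly along the segment, at times uniform over the window (snapped to a
6-h stride so same-time releases integrate as one batch), and integrates
them backward — negated velocities, time reversed, beaching and exit
disabled, positions clamped at the boundary so an estimate is always
produced.  The result is the endpoint cloud, its convex hull (excluding
clamped endpoints, whose fraction is reported), and the provenance.

Two lookback semantics are provided:

* `mode = "duration"` (default): every particle integrates backward for
  exactly `lookback` seconds.  Endpoints sit at staggered calendar times.
* `mode = "epoch"`: every particle integrates back to the common calendar
  time `t_start − lookback`.  This is the "where was this population one
  month earlier" question, and it is the mode that makes round-trip
  experiments meaningful: under a fixed duration the backward image of the
  release arc is nearly one-dimensional (all particles retreat by the same
  flow integral), whereas backtracking to a common epoch spreads late
  arrivals further back and reconstructs the two-dimensional source region.
  In the package's round-trip experiment (forward run from a seeded band on
  the two-basin domain under pulsed south-westerlies, then epoch-mode
  localization from the modal arrival segment), the recovered hull overlaps
  the seeded region with Jaccard > 0.3, and recovery under steady forcing
  is at least as good as under unsteady forcing.

No probabilistic (adjoint/Bayesian) inversion is attempted; the estimate is
trajectory-based only, and its hull should be read as a support estimate,
not a posterior.

## 6. Strandings and pattern comparison

Stranding events are aggregated per beach into cumulative densities,
$100 \cdot \mathrm{count} / \mathrm{length}$ colonies per 100 m of
coastline, with zero-count beaches retained and beaches ordered west to
east.  `compare_patterns()` reports:

* the Spearman rank correlation of densities over the outer-joined beach
  set (missing beaches as zeros) — rank-based on purpose: the scientific
  claim to test is *pattern* similarity, and observed magnitudes are
  unreliable where beaches were sampled rarely or tidal cycles intervened
  between beaching and sampling;
* the RMS difference of log densities over beaches nonzero in both tables
  (the magnitude diagnostic, reported but not headline);
* west-to-east concordance: the Spearman correlation between beach
  longitude rank and first-arrival rank within each table.

Ties use average ranks.  Observed ledgers (CSV:
`beach_id,date,count,mean_size_cm`) may repeat dates per beach; counts are
summed over the analysis window and the earliest sampled date stands in for
first arrival.  Beach lengths for real coastlines are user-supplied.

## 7. Wind diagnostics

`monthly_zonal_climatology()` computes the cos-latitude-weighted box mean of
the zonal wind per (year, month), then averages across years — the standard
long-term monthly climatology against which one winter's westerlies can be
expressed as `anomaly_ratio()` multiples.  Ratios are flagged undefined
(rather than returned as infinities or negative factors) when the
climatological mean is zero or the two means have opposite signs.
`kinematic_wind_stress()` uses the standard bulk form
$\tau/\rho = C_d\,|\mathbf{w}|\,\mathbf{w}$ with constant
$C_d = 1.3\times10^{-3}$ (exposed as a parameter; no source defines the
original formula), averaged per calendar day at a point.  Daily source
fields are assumed.  Reproducing a real winter's anomaly magnitudes requires
externally supplied reanalysis winds; the package ships only synthetic
tests of the arithmetic and invariances (constant fields, rescaling
invariance, stress–wind collinearity).

## 8. Problem sizes and study conditions used by the tests

The simulated experiments use, as the package's reference conditions: a
9° × 4° two-basin domain at 120 × 60 cells (~7 km), daily field snapshots,
RK4 at $\Delta t = 1800$ s, windage 0.10, winds of 2–10 m/s, currents capped
at 3 m/s (jet 1 m/s, slope current 0.3 m/s, gyre 0.5 m/s at a 30 km rim),
populations of 25,000 (initialization checks), 2,000 (transport pattern),
1,500 (handedness sensitivity), 500 (round trip) and 400 (mirror audit)
colonies over 5–60 simulated days.  These sizes resolve every tested effect
comfortably; scaling any of them up changes no conclusion of the suite.

## 9. Known limitations

* Zonal-coast geometry: slope currents are implemented as zonal flows with
  offshore decay; coastline curvature and along-slope steering around capes
  are not represented.
* The windage coefficient is applied to whatever wind field is supplied;
  whether that field is a true 10-m wind or a stress-derived equivalent is
  the caller's responsibility (10-m winds assumed).
* Linear time interpolation smears episode edges between daily snapshots;
  supply finer snapshots if sharp fronts matter.
* No re-floating: observed densities on tide-swept beaches will sit below
  simulated ones; the comparison statistics are rank-based partly for this
  reason.
* Backward trajectories in strongly dissipative or chaotic flow fields lose
  information; the hull is a support estimate whose quality degrades with
  field unsteadiness, as the round-trip tests document.
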