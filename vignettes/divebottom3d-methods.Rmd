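---
title: "From raw bio-logging streams to prey-field density: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From raw bio-logging streams to prey-field density: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divebottom3d)
```

## The problem

Deep-diving predators such as southern elephant seals forage on mesopelagic
prey layers hundreds of metres below the surface, where direct observation is
impossible. Modern tags record depth at 1 Hz, tri-axial body acceleration and
tri-axial magnetics at 5 Hz, sound, and surface GPS positions. From these
streams one can reconstruct, dive by dive, *where* the animal went in three
dimensions, *when* it attempted to capture prey, and — by combining the two —
a proxy of the local prey density it experienced: prey-encounter events per
cubic metre of water prospected during the bottom phase of each dive.

`divebottom3d` implements that full chain as a pipeline of small, testable
stages, together with a forward sensor simulator that generates synthetic
deployments with known truth so that every stage has a parameter-recovery
test.

## Conventions

All angles are radians internally (degrees only at documented surfaces).
Depth is positive down; the local frame is East-North-Up with `z = -depth`.
Pitch is positive nose-up, roll positive right-side-down, heading clockwise
from magnetic north in `[0, 2*pi)`. GPS fixes are projected onto a local
equirectangular tangent plane anchored at the deployment's first fix; at
dive scales (under ~2 km) the projection error is negligible.

## Dive segmentation

A zero-offset correction removes the slow drift of the pressure sensor: the
median reading of every surface interval is interpolated linearly across the
record and subtracted, leaving within-dive depth differences untouched.
Dives are maximal runs deeper than 15 m — a conservative threshold that keeps
brief sub-surface excursions from counting as dives.

The bottom phase is delimited from the vertical speed (first difference of
depth). A degree-4 polynomial in time is least-squares fitted to the vertical
speed of the dive; the bottom phase is the contiguous interval containing the
deepest sample on which the absolute fitted vertical speed stays below
0.75 m s^-1. The polynomial responds to the overall dive shape (V-shaped
versus U-shaped) but not to small steps in the profile. Degree 4 is the
lowest degree that can represent a descend–wander–ascend speed profile with
two internal extrema. The interval is anchored at the deepest sample because
"bottom" is a statement about the deepest part of the dive; without the
anchor, a flat segment in mid-descent could masquerade as the bottom.

Drift dives (passive resting/digesting dives) are removed before analysis.
The criterion used here is a documented, configurable stand-in: a dive is a
drift dive when its bottom phase lasts at least 200 s and contains a 200-s
window whose swimming-speed SD is below 0.15 m s^-1 and whose vertical-rate
SD is below 0.1 m s^-1 — passive sinking with no propulsion. The windowed
form matters because the polynomial delimitation overruns a drift dive's
slow sink into the active transitions, which would mask the passive core in
whole-bottom statistics. Thresholds are exposed in `pipeline_control()`.

## Prey-encounter detection

Prey capture attempts leave short, sharp transients on all three acceleration
axes. The detector:

1. high-passes each 5 Hz axis with a zero-phase order-3 Butterworth filter
   (two passes via `signal::filtfilt`), normalized cut-off 2.4;
2. computes the SD of the filtered signal in fixed one-second windows
   (a 1 Hz activity series), then a centred five-second moving SD;
3. splits the resulting series into a "high" and a "low" state by a
   two-means clustering (the cluster with the larger mean is high);
4. declares a prey-encounter event (PEE) wherever all three axes are high
   simultaneously, merging every contiguous run of high seconds into a
   single event.

Two numerical choices deserve comment.

**Cut-off normalization.** The nominal cut-off of 2.4 is interpreted as
normalized by the *sampling rate* (2.4/5 = 0.48 of Nyquist, an effective
1.2 Hz), not by the Nyquist frequency. Read against Nyquist, the passband
would be the 0.1-Hz-wide sliver from 2.4 to 2.5 Hz; a filter that narrow
rings for roughly ten seconds, so every impulsive strike is smeared into a
smooth multi-second activity bell. The five-second moving SD of a smooth
bell is *low at the top and high on the flanks*, and the clustering then
splits every single strike into two events — contradicting the premise that
a continuous high-state run is one event. Under the rate-normalized reading
the passband is broad, impulses stay impulsive, and the detector returns one
event per strike. The same convention is applied to the 0.20 low-pass used
for attitude estimation (an effective 0.1 Hz), which comfortably separates
gravity and posture (below ~0.05 Hz) from stroking (~0.5–1.5 Hz).

**Deterministic two-means.** One-dimensional 2-means is solved by Lloyd
iterations initialized at the 10th and 90th percentiles, with no random
restarts; the scalar clustering is effectively exact and, importantly,
deterministic and scale-equivariant (event detection is invariant under a
uniform rescaling of the axes). Two degenerate clauses guard it: a series
whose activity range is below `1e-6` is declared all low state, and the
high state is only accepted when the cluster means separate by more than 8
low-cluster SDs. Without the second clause a burst-free axis would be split
through the bulk of its noise (any two-means of unimodal data puts ~30–50%
of points in the upper cluster) and spurious conjunctions would follow; a
genuine strike stands tens of low-cluster SDs above background (measured:
~3 for pure noise against ~20 even at a burst-to-noise ratio of 5), so the
threshold costs no sensitivity in the operating regime.

## Attitude and speed

The gravity-dominated ("static") component of acceleration is obtained with
the low-pass filter above; pitch and roll follow from the direction of
gravity in body coordinates (`pitch = atan2(gx, sqrt(gy^2+gz^2))`,
`roll = atan2(-gy, gz)`, with roll set to 0 in the nose-vertical gimbal
case). The same low-pass applied to the magnetics gives a static magnetic
vector that, de-rotated by roll and pitch, yields the tilt-compensated
heading. On noise-free forward-modelled inputs the recovery is exact to
numerical precision; this round trip is a test.

Swimming speed in the steep descent and ascent phases comes from the
pressure-derived vertical speed and the pitch: `v_seal = |v_z / sin(pitch)|`.
The estimate degenerates as pitch approaches horizontal, so samples with
|pitch| below 20 degrees are left missing — the bottom phase is mostly
near-horizontal swimming, which is exactly where this estimator fails. There
the flow-noise level takes over: descent/ascent pairs of (noise level,
pitch-derived speed) calibrate a linear model of level against log speed
(flow noise grows roughly log-linearly with speed), which is inverted to
predict speed over the rest of the dive, clipped to [0, 3] m s^-1. The
calibration requires at least 100 pairs spanning at least 0.5 m s^-1 and
fails loudly otherwise — a deployment whose acoustic duty cycle never
overlaps its dives yields no bottom speed and its dives are excluded, which
mirrors the fact that 3D dives exist only where sound was recorded.

## Dead-reckoning and GPS closure

Positions are integrated at 1 Hz from the pre-dive fix: the horizontal step
at second *t* is `v_seal * cos(pitch) * (sin(heading), cos(heading))`,
assuming the animal travels along its longitudinal axis. The vertical
coordinate is never integrated: pressure depth is a direct measurement and
simply overwrites `z`. Speed gaps up to 5 s are bridged linearly; longer
gaps reject the dive rather than silently inventing motion.

The raw dead-reckoned endpoint misses the post-dive fix because of ocean
currents and accumulated sensor error. The closure correction divides the
horizontal offset by the track's time span and shifts every sample by that
constant velocity times elapsed time — the signature of a constant current.
The corrected endpoint matches the fix to numerical precision and the anchor
is untouched. With fixes taken immediately before and after the dive, the
recovered correction velocity estimates the true current; the simulator
recovery test checks this to 10%.

## Bottom-phase shape

The covariance matrix of the bottom-phase positions is eigen-decomposed.
The eigenvalues (sorted descending, sample covariance with the n−1
denominator) measure dispersion along the three main components; their sum
is the total dispersion (equal to the covariance trace — a conservation
test); the share of the first eigenvalue (MC1 dispersion) is 1 for a
straight line and 1/3 for isotropic wandering. The first eigenvector's sign
is fixed so its horizontal projection points along the net displacement;
`horizontality` is the norm of that horizontal projection (1 = horizontal
course, 0 = vertical).

Extents and widths use 10%/90% quantiles (type-7, the ecosystem default)
for robustness rather than minima and maxima:

- **MC1 extents**: the 10–90% quantile range of the centred scores on the
  first eigenvector, decomposed into horizontal and vertical parts by the
  eigenvector's components.
- **Widths**: plane A passes through the centroid and contains the first
  eigenvector and the vertical; plane B contains the first eigenvector and
  the normal of A. The horizontal (resp. vertical) width is the 10–90%
  quantile range of *signed* distances to plane A (resp. B). Signed
  distances (rather than absolute) make the width collapse to zero for
  perfectly planar tracks and equal a one-dimensional quantile oracle on
  constructed waveforms — both are tests. If the first eigenvector is within
  1 degree of vertical the planes are built with a fixed arbitrary azimuth
  and the row is flagged.

## Prospected volume and the density proxy

The water volume prospected during a bottom phase is the volume of the union
of spheres of detection radius *r* centred on every 1 Hz position — an
object with no closed form for self-intersecting paths, hence Monte-Carlo
integration: uniform samples in the track's bounding box expanded by *r*;
the volume is the box volume times the fraction of samples within *r* of any
track position, with the binomial relative SE reported. Radii of 1.5, 9 and
18 m represent opportunistic, intermediate and far-field detection
scenarios. The hit test culls samples through a spatial hash (cell size *r*,
27-neighbour active set) before exact distance evaluation; exact agreement
with brute force is a test. When several radii are evaluated for one dive,
a single sample stream in the largest box makes the hit sets nested, so the
estimated volume is monotone in *r* realisation by realisation.

The default is 2e5 samples per dive (relative SE around 1% for typical
bottom phases), with the seed recorded per row. The density proxy is
`1e6 * pee_count / volume`, in μPEE m^-3; its reciprocal (divided by 1e6) is
the average volume a predator must prospect per encounter.

Track positions are used at 1 Hz without segment interpolation: at ~1–2 m
s^-1 and r ≥ 1.5 m consecutive spheres overlap or nearly touch, and —
importantly — the simulator's encounter definition uses the same per-second
discretisation, so volume and count stay mutually consistent.

## Count models of density

PEE counts per bottom phase are modelled with a log link and
`offset(log(volume))`, so the linear predictor describes density while the
likelihood remains a proper count distribution. The ladder is: Poisson GLM;
negative binomial (`MASS::glm.nb`) when the Pearson-residual overdispersion
`sum(r_p^2)/df` exceeds 1 materially; zero-inflated Poisson/NB (`glmmTMB`
with a logistic zero part) when excess zeros remain. Covariates are
standardized before fitting, so coefficients are per-SD effects; quadratic
terms are centred before squaring to limit collinearity; covariate pairs
with |r| > 0.9 are rejected up front. Exhaustive subset enumeration ranks
candidates by AIC and returns the best model whose every explanatory
variable is significant at 5% (or the overall AIC winner, flagged
non-conforming). Vuong's closeness test (`z = sqrt(n) mean(m)/sd(m)` on
pointwise log-likelihood differences) compares non-nested families.

The zero part is parameterised as the probability of an *excess zero* — it
predicts the absence of encounters, not their presence; `tidy()` labels the
part explicitly so the sign convention cannot be misread.

## The simulator: what it emulates and what it does not

`simulate_deployment()` forward-models a deployment under a `sim_config()`:

- **Dive geometry.** Smooth pitch plans (10-s ramps, 9-s blending) at ±50
  degrees in descent/ascent; bottom phases of mean 500 s oscillating
  vertically inside a prey layer (default 50 m thick, centred at 450 m) with
  a weak depth-restoring term — the animal tracks its layer; heading mostly
  along one azimuth per dive with a random-walk wiggle scaled by
  `1 - bottom_linearity` (default 0.9, matching strongly directional bottom
  courses). Speeds are AR(1) around 2 m s^-1.
- **Prey.** A Poisson point field of intensity 7e-4 m^-3 inside the layer
  slab, realised lazily per dive in the track's expanded bounding box; an
  encounter is the first second the true path comes within the detection
  radius (1.5 m) of a prey point. No escape or avoidance behaviour is
  modelled, matching the detection-sphere assumption downstream.
- **Sensors.** Depth with a linear pressure-offset drift and noise;
  acceleration as gravity rotated by the true attitude (noise applied in
  angle space, so the gravity norm stays exact) plus rhythmic 0.7 Hz
  propulsive stroking while actively swimming, broadband sensor noise, and
  strike transients at encounters: a sign-alternating near-Nyquist carrier
  under a random magnitude envelope shared across axes (a strike jerks the
  whole body), floored so each strike keeps the nominal burst-to-noise
  ratio of 6; magnetics consistent with the attitude and a 65-degree
  southern-hemisphere inclination; a flow-noise level `60 + 20 log(speed)`
  gated by the acoustic duty cycle (3 h per 12 h by default); GPS fixes at
  the first and last second of each surface interval, displaced by the
  constant current (default (0.1, 0.05) m s^-1).
- **Drift dives** (optional) sink passively at 0.3 m s^-1 with no stroking
  and no prey reaction.

It does *not* emulate: hydrodynamics or biomechanics beyond kinematics,
prey avoidance, GPS position error, magnetic declination or anomalies,
diel vertical migration of the layer, or raw audio. Tests passing on these
synthetics therefore demonstrate the correctness and internal consistency of
the pipeline under its own assumptions — not detector performance on real
tags, where backgrounds are richer and strike signatures vary.

## Problem sizes and determinism

Simulation-based checks use deployments of 2–50 dives (a 50-dive deployment
is ~16 h of 1 Hz data and ~300k samples at 5 Hz) and Monte-Carlo volumes at
1e5–1e6 samples; generative model-recovery checks use n = 300–1000 dives and
up to 50 replicates. These sizes keep each check's sampling error well below
the tolerance it asserts. Every stochastic stage takes an explicit seed
(`sim_config(seed=)`, `mc_volume(seed=)`, `pipeline_control(seed=)`), reruns
are bit-identical, and the per-dive Monte-Carlo seed is derived from the
pipeline seed plus the dive id.

## Known limitations

- Dead-reckoned positions carry no uncertainty estimate; closure removes the
  endpoint error but not path-local error (~1–2% of path length through the
  full sensor chain in simulations).
- The end-to-end density proxy is mildly conservative: detector misses
  (recall ~0.95–0.98) and events whose midpoints fall just outside the
  delimited bottom window shave the count, while the prospected volume is
  unbiased, leaving a net recovery around 0.8–0.9 of the true intensity in
  simulations — inside the sampling error of a 50-dive deployment, but a
  systematic tendency worth remembering when comparing absolute densities.
- The drift-dive criterion is a stand-in; real classifications use richer
  dive-shape features.
- The flow-noise calibration assumes a monotone log-linear level–speed
  relation per deployment and a single calibration across the record.
- The detector's two-means step assumes strikes are rare relative to the
  record; a record that is mostly strikes would shift the threshold.
- Bottom phases shorter than 4 s, or geometrically degenerate (a point), have
  no shape metrics and are dropped with a logged warning.
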