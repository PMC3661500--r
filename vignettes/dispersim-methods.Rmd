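---
title: "Simulating animal dispersal on vector landscapes: models and methods"
author: "dispersim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating animal dispersal on vector landscapes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dispersim)
```

## The model

`dispersim` is a spatially explicit, individual-based simulator of natal
dispersal: juvenile animals leave their birth site, move across a
heterogeneous landscape, forage, run mortality risks, remember what they
have seen, and try to establish an exclusive home range before the
dispersal season ends.  Residents survive, breed, and supply the next
season's dispersers, so multi-year population dynamics emerge from
individual behaviour.

The landscape is a set of four polygon (vector-GIS) layers sharing one
planar coordinate frame in metres, plus a point layer of release sites:

* a **movement** map (per polygon: wrapped-Cauchy turning concentration,
  step-length mean and SD, per-step energy cost, a boundary-permeability
  rank, and a perception-radius multiplier),
* a **food** map (per-step prey-capture probability; prey-size mean and SD
  in energy units),
* a **risk** map (per-step predation probability),
* a **suitability** map (binary suitability for home-range establishment
  and binary male/female occupancy flags).

Polygon rather than raster layers avoid grid-imposed directional bias and
let habitat attributes follow real patch boundaries.  Each map must
tessellate its rectangular extent — a hole is a validation error, because
every animal position must yield attributes on all four layers.  Any layer
can be replaced at scheduled times (*map swapping*), which is how seasonal
food pulses or day/night predation regimes are represented: the active map
is piecewise constant in time and right-continuous, i.e. a swap applies at
exactly its timestamp.

## Movement

Animals move by a correlated random walk.  Each active time-step draws a
turning angle from a wrapped Cauchy distribution with concentration
$\rho \in [0,1]$ ($\rho = 0$: uniform turning, a pure random walk;
$\rho = 1$: no turning, straight-line movement), via the exact inverse-CDF
transform $\theta = 2\arctan\!\big(\tfrac{1-\rho}{1+\rho}
\tan(\pi(u - \tfrac12))\big)$, and a step length from a normal
distribution truncated below at zero by clamping.  The mean resultant
length of the turning kernel equals $\rho$, which the test-suite verifies
by Monte Carlo.

$\rho$, the step-length moments, the energy cost and the permeability rank
for a step are those of the polygon containing the step's **origin**; this
anchoring is deterministic and matches per-time-step map querying.

As the step ray crosses a polygon boundary the animal decides whether to
cross by comparing the permeability ranks of the two polygons: it crosses
with probability

$$P(\text{cross}) = \frac{q_{to}}{q_{from} + q_{to}},$$

one independent uniform draw per boundary encountered, in traversal order.
This odds form is symmetric, invariant to rescaling all ranks, gives equal
ranks a 50 % crossing rate, makes a rank-0 polygon absolutely impassable,
and lets an animal always leave a rank-0 location.  A refused crossing
truncates the step at the boundary — the remaining distance is forfeited
rather than reflected, the simplest behaviour consistent with animals
preferentially remaining in higher-quality habitat.  At the map extent the
heading reflects specularly, keeping animals in-domain without absorbing
or wrapping walls.

Numerically, the traversal anchors the current polygon by a strict
(tolerance-free) containment test probed marginally ahead of the ray, so a
position resting exactly on a shared edge resolves to the side the ray
actually travels; the intersection tolerance scales with polygon size, not
step length, so a position nudged just inside an edge by an earlier
refusal still triggers the next boundary decision.  Each step records
every boundary decision (from, to, crossed) on the returned path object,
which is what the permeability tests tabulate — avoiding biased
reconstruction from endpoints.

## Energetics, foraging and mortality

Energy is a unitless reserve (a surrogate for body mass) with three
species constants: initial value, a starvation floor (death strictly below
it) and a ceiling (gains clamp to it).  Per active step the animal pays
the movement map's energy cost and, with the effective capture
probability, gains a prey item drawn from the food polygon's truncated
normal size distribution.  Cost and gain are netted before a single
starvation check, so no ordering artefact can kill an animal twice.
Predation is a per-step Bernoulli draw at the effective mortality
probability; under a constant hazard $p$ survival over $n$ steps is
$(1-p)^n$, which the suite checks against the closed form.  Resting
animals remain static: they neither move, forage, pay map costs, nor face
predation — the model scopes hazards to dispersal activity.  Every dead
animal carries exactly one cause: starvation, predation, or failure to
settle by season end.

Residents face an aspatial per-step mortality during the dispersal season
and a single inter-dispersal mortality between seasons; their deaths free
home ranges (occupancy is cleared the same step, so a vacated range is
available immediately).

## Behavioural states and modifiers

Animals carry two independent binary states.  The **activity mode**
(searching/foraging) is energy-driven: strictly below a configurable
threshold the animal forages, at or above it searches, and the transition
is symmetric, so reserves oscillate around the threshold when foraging is
profitable.  The **vigilance mode** (risky/safe) is purely stochastic: one
uniform draw per step switches the mode with a mode-specific probability;
every season starts risky.  Run lengths under a constant switch
probability $p$ are geometric with mean $1/p$ (verified by Monte Carlo).

Behavioural variation enters through multiplicative **modifiers**: tables
keyed by sex, by the four vigilance-activity states, by hour-of-day
window, and by date window multiply the baseline capture probability,
mortality, energy cost, speed, tortuosity, or perception radius.  Absent
keys multiply by 1; windows are half-open $[start, end)$ (hour windows may
wrap midnight) so boundary hours are never double-counted; the four key
types commute because the combined multiplier is a product.  Setting every
multiplier to 1 is bit-identical to disabling the machinery — the null
convention used when behavioural variation should be switched off — and
the suite asserts that equivalence on whole-run traces.

Activity/rest bouts alternate with normally distributed durations
(truncated below at one time-step rather than redrawn; the bias is
negligible at realistic SDs).  The mean active plus rest durations must
divide 24 h so the average cycle is day-synchronised, while stochastic
durations let individual schedules drift.  Animals begin each year active
at the configured start hour.

## Perception and memory

Each step the animal senses a perceptual window: the realised path
buffered by the effective perception radius (round caps and joins — a
stadium per straight sub-segment, discretised at 24 arc points per cap,
keeping buffer areas within a few tenths of a percent of the closed
form).  The suitability and occupancy inside the window enter an
append-only, time-stamped **memory map** whose effective status at any
point is that of the latest covering record — revisits overwrite.

Perception is *patch-granular*: when the window touches a suitability
polygon the whole polygon is remembered with its current status, and it is
re-remembered only when that status changes (a per-feature cache
deduplicates).  Suitability and occupancy are polygon-level attributes, so
patch granularity loses no information about them, and it bounds memory
size by the number of patches rather than the number of steps — an early
sliver-granular implementation made memory queries the dominant cost of
whole simulations.  The memory structures themselves accept arbitrary
overlapping regions, which the unit tests exercise against a brute-force
reverse-chronological oracle.

Candidate home-range centres are drawn uniformly from the union of
remembered regions whose effective status is suitable and not occupied by
the animal's own sex.  The sampler proposes an eligible-status record with
probability proportional to its area, draws a uniform point inside it, and
accepts iff that record is the latest one covering the point; this yields
exactly the uniform distribution over the eligible latest-wins union while
staying fast when eligible area is scarce.  Proposals are capped (10 000
per point, 10 × n per call): a hopeless draw returns fewer points instead
of stalling the simulation, and the animal simply retries next step.

## Home-range establishment

Settlement attempts begin once a trigger is reached: either a fixed count
of active steps since dispersal began, or a fixed count of *distinct*
suitability polygons entered that were suitable and unoccupied by the
animal's sex at entry.  Each attempt draws up to 30 candidate points from
memory and scores them as

$$W = Q \cdot e^{-d/w},$$

where $d$ is the distance from the animal, $w$ a per-sex distance
weighting factor, and $Q$ is 1 (*closest* criterion), the candidate-set
maximum-normalised expected food gain (*food*), the normalised safety
$1 - p_{mort}$ (*risk*), or their product (*integrated*).  The centre is
**sampled** with probability proportional to $W$: selection favours good,
nearby sites but stays stochastic, and a very large $w$ removes distance
from the decision entirely.  The exponential kernel was chosen because it
satisfies those qualitative requirements with a single interpretable
length scale; the normalisation by the candidate-set maximum makes food
and risk magnitudes comparable without user tuning.

The animal relocates to the chosen centre (instantaneously — pathing to
the site is not re-simulated, and the step's hazards have already been
applied).  A candidate range polygon is generated around the centre: 12
vertices at equally spaced angles with one random rotation, radii
$\mathcal{N}(r_0, 0.15\,r_0)$ truncated positive, where $r_0$ makes the
regular 12-gon attain exactly the sex's minimum area $A_{min}$; sorting
vertices by angle guarantees a simple (star-shaped) ring, and generation
retries until the area reaches $A_{min}$.  Settlement succeeds iff the
polygon's overlap with every existing same-sex range is zero (within
$10^{-6}\,\mathrm{m}^2$; the live range registry is authoritative) and its
suitable, same-sex-unoccupied area reaches $A_{min}$.  On success the
animal becomes a resident, and every suitability polygon its range touches
gains the sex's occupancy flag — feature-level flags mirror the coarse map
semantics while the registry preserves exactness.  On failure a small disc
(a quarter of $r_0$) around the rejected centre is remembered as
ineligible — the site, not the whole candidate polygon, is marked, so the
surrounding patch stays available and repeated failures do not blanket the
landscape.  Dispersers still unsettled at season close die (cause
`season_end`).

## Demography and the annual cycle

The inter-dispersal period is a single discrete event: residents survive
it with probability $1 - p_{inter}$; each surviving female is pregnant
with probability $p_{preg}$ and bears
$\max(\mathrm{round}(\mathcal{N}(\mu, \sigma)), 0)$ young (rounding half
away from zero before the negative-to-zero rule), each female with the
configured offspring sex-ratio probability.  Offspring begin the next
season at the centre of the mother's
range.  Males are necessary for none of this machinery; mating is
implicit.

Each year animals are numbered geographically — north to south, ties west
first — and processed in that order every step, so results are independent
of input order.  The per-step pipeline for each disperser is fixed: (1)
bout check (resting animals just log), (2) modifier resolution at the
origin polygon, (3) vigilance draw, (4) activity-mode check, (5) movement
with boundary decisions, (6) energy cost, (7) foraging gain, (8)
starvation check, (9) predation draw, (10) perception and memory update,
(11) settlement attempt if triggered.  Death short-circuits the rest of
the pipeline.  Resident step-mortality precedes the dispersers each step
so freed ranges are available the same step.  A single global random
stream consumed in this fixed order makes every output byte a function of
(configuration, seed); the determinism tests run configurations twice and
compare logs and GeoJSON outputs byte for byte.

The clock counts minutes from midnight of day 1 of each season; a season
comprises `season_days * 1440 / step_minutes` steps starting at the
configured start hour, and years are concatenated season blocks (the
inter-dispersal event occupies no clock time).

## Synthetic landscapes and the packaged study scenarios

Real GIS case-study layers are rarely distributable, so the package
generates synthetic landscapes: a rectangular extent tessellated either as
a regular grid (exact areas — the default test fixture) or a Voronoi
diagram of random sites (irregular convex patches, built by half-plane
clipping), with habitat classes assigned to patches by a seeded weighted
draw and the four parameter maps built from a class attribute table.
Variant maps that reuse the tessellation but alter class attributes supply
the phases of swap schedules.  The generator emulates patchy mosaics with
class-constant attributes; it does not reproduce realistic patch shape,
autocorrelation, or fine-scale landscape structure, so passing tests
demonstrate the mechanics of the simulator, not calibration to any real
landscape.

Two packaged scenarios exercise the signature mechanisms at desk scale,
and their parameter choices are the package's standing study conditions:

* `scenario_food_pulse()`: a 4 × 4 km agriculture/forest mosaic (10 × 10
  grid), 20 nocturnal dispersers with energy 3750 (floor 1800, ceiling
  10 000), a 150-day season of 1-h steps, and a food-map swap to
  superabundant agricultural food on day 38 and back on day 114.  The
  distinct-sites trigger (25 suitable patches) spreads settlement times
  across the first swap, so the run itself contains settlers under both
  regimes; forest is the slight majority class so that minimum ranges of
  0.29 / 0.12 km² remain establishable.
* `scenario_forage_threshold()`: a 10 × 10 km forest/open mosaic, 8
  dispersers with energy 4548 (floor 3866, ceiling 5003), 4.5 h / 7.5 h
  activity bouts from 04:00 over a 60-day season, a 270-active-step
  trigger, minimum ranges 4.25 / 2.32 km², and an 8-fold foraging-state
  capture multiplier.  With the forage/search threshold enabled, reserves
  oscillate around it and settlers finish near it; with the threshold
  disabled the same configuration loses energy monotonically.  The bout
  SD is 0.8 h — large enough to desynchronise individuals, small relative
  to the bout means.

These sizes (tens of animals, seasons of 1440–3600 steps) were chosen so
that a full scenario completes in a couple of minutes in a single process
while still containing every mechanism.

## Numerical and design details

* Shared-edge containment ties break to the smallest feature id;
  tessellation coverage is validated by comparing summed feature area to
  the extent area within a $10^{-6}$ relative tolerance.
* Probabilities and tortuosity are clamped to $[0,1]$ after modifier
  multiplication; step lengths, prey sizes and bout durations truncate by
  clamping (not redrawing), keeping draw counts — and therefore the random
  stream — independent of the values drawn.
* All geometry is planar; inputs are assumed pre-projected to metres, and
  no geographic CRS computation is performed.
* Vector I/O is GeoJSON (text, diffable, deterministic with
  full-precision formatting); the step log is plain CSV, one row per
  animal per time-step, so determinism can be established with a file
  diff and summaries can be re-derived independently.
* The four maps need not share one tessellation; each is queried
  independently.

## Limitations

Movement is 2-D with no attraction toward remembered locations (memory
affects only home-range selection); food is not depleted by foraging;
breeding is aspatial and does not require male presence; home ranges do
not shift after establishment; unsettled animals do not survive between
seasons; and map swaps follow a fixed schedule rather than responding to
model state.  The simulator is best suited to solitary, territorial
species with a distinct natal-dispersal season.
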