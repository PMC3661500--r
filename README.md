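# dispersim

A spatially explicit, individual-based simulator of juvenile animal
dispersal and home-range establishment on polygon (vector-GIS) landscapes,
for spatial ecologists who want behaviourally rich dispersal models —
energy budgets, predation risk, behavioural state switching, memory-driven
habitat selection, and temporally dynamic landscapes — without raster
artefacts or a GIS runtime dependency.

## The model in brief

Virtual dispersers respond to four polygon parameter maps that tessellate
one planar extent (metres):

| map | per-polygon attributes |
|---|---|
| movement | wrapped-Cauchy turning concentration ρ, step length (mean ± SD, m), energy cost/step, permeability rank q, perception multiplier |
| food | capture probability/step, prey size (mean ± SD, energy units) |
| risk | predation probability/step |
| suitability | suitable {0,1}, occupied-by-male {0,1}, occupied-by-female {0,1} |

Each active time-step an animal turns by a wrapped-Cauchy angle (ρ = 0
uniform turning, ρ = 1 straight), draws a truncated-normal step length,
and crosses each habitat boundary it meets with probability
`q_to / (q_from + q_to)` (a refusal truncates the step; rank 0 is
impassable).  It pays the polygon's energy cost, forages, survives a
predation draw, and remembers the suitability and occupancy of every
patch inside its perceptual window (latest observation wins).  Below a
configurable energy threshold it switches from searching to foraging; a
stochastic risky/safe vigilance mode can modify any baseline parameter
via multiplicative modifier tables (sex, behavioural state, hour, date).
Once a trigger (active steps or distinct suitable sites) is passed, the
animal samples candidate home-range centres from memory with weight
`Q · exp(−d/w)` and settles where a generated range polygon finds enough
suitable area with zero same-sex overlap; residents then survive, breed,
and seed the next season's dispersers.  Any map can be swapped on a
schedule (seasonal food pulses, day/night risk).  Every run is a
deterministic function of (configuration, seed).

## Worked example

A seasonal food pulse: scarce agricultural food for 37 days, a
superabundant phase for 76 days (the food map is swapped on day 38 and
back on day 114), raccoon-like energetics (start 3750, starve below 1800,
ceiling 10 000):

```r
library(dispersim)

sc  <- scenario_food_pulse(seed = 101)       # landscape + config + swap schedule
res <- run_simulation(sc$cfg, sc$landscape)

an      <- res$animals
settled <- an[an$status == "settled", ]
swap_step <- (37 * 1440 - 18 * 60) / 60 + 1  # first step at/after the day-38 swap
wc <- settled$energy_final - settled$energy_init
split(round(wc), ifelse(settled$settled_step < swap_step, "pre_swap", "post_swap"))
#> $post_swap
#> [1] 3823 1215 6230 6246   33 5159 1902
#> $pre_swap
#> [1] -562 -594 -600 -474
```

Settlers that established while food was scarce lost ~500 units of body
mass; settlers that were still dispersing when the pulse arrived gained
up to the energy ceiling — the temporal food regime, not habitat quality,
splits the weight distribution.  `summarize_run(res)` reports mortality
by cause (predation / starvation / failure to settle), settlement times
and dispersal distances; `write_step_log()` and `write_vector_outputs()`
export the per-step log, the home-range polygons and the perception
corridors.

Landscapes can be built from your own GeoJSON layers
(`load_parameter_map()`, field names bound via `field_map`), or generated
synthetically (`synthetic_landscape()`, grid or Voronoi tessellations
with class attribute tables; `map_variant()` builds the paired maps of a
swap schedule).  A thin command-line front end for YAML-configured runs
is installed at `inst/cli/dispersim.R`.

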