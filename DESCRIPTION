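Package: dispersim
Title: Individual-Based Simulation of Animal Dispersal on Vector Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A spatially explicit, individual-based simulator of juvenile
    animal dispersal and home-range establishment on polygon (vector-GIS)
    landscapes. Virtual dispersers move by a correlated random walk with
    wrapped-Cauchy turning angles, respond to habitat-boundary permeability,
    forage and spend energy, face spatially varying predation risk, switch
    behavioural states (searching/foraging, risky/safe), remember the
    suitability and occupancy of areas they perceive, and settle into
    sex-exclusive home ranges. Landscapes are attribute-carrying polygon
    tessellations that can be swapped on a schedule to represent seasonal
    food pulses or day/night predation pressure. Includes a synthetic
    landscape generator, GeoJSON input/output, per-step logging, and
    population summaries (cause-specific mortality, settlement time,
    dispersal distance, weight change).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
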