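Package: skylarksim
Title: Agent-Based Simulation of Skylark Populations in Dynamic Farmed Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale agent-based model of skylark (Alauda arvensis)
    populations in dynamic agricultural landscapes: a raster landscape with
    polygon attributes, daily vegetation growth and insect food, probabilistic
    farm operations on crop rotations, and individual birds (clutches,
    nestlings, pre-fledglings, males, females) driven by behavioural state
    machines with habitat scoring, territory acquisition, energetics-limited
    foraging and degree-day egg development. Includes virtual-ecologist
    observation protocols (territory census, nest monitoring, seasonal series),
    pattern-oriented-modelling fit statistics with a one-at-a-time sensitivity
    harness, an incubation temperature-logger feeding-trip analysis, and
    seeded synthetic scenario generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
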