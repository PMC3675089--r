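---
title: "The skylarksim model: assumptions, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The skylarksim model: assumptions, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skylarksim)
```

# Overview

`skylarksim` is a desk-scale agent-based model of skylark (*Alauda
arvensis*) populations in dynamic farmed landscapes. Population dynamics are
not prescribed: they emerge from individual birds interacting daily with a
landscape whose vegetation, insect food and farm management change day by
day. The package couples four parts:

1. a **dynamic landscape**: a raster of cells grouped into polygons (fields,
   margins, hedgerows, ...), daily vegetation growth driven by temperature,
   a seasonal insect-food supply, and probabilistic farm operations on crop
   rotations;
2. **bird agents** in five life stages (clutch, nestlings, pre-fledglings,
   males, females) run as behavioural state machines: territory acquisition
   by habitat score, pairing, laying, trip-interrupted incubation with
   degree-day egg development, energetics-limited provisioning,
   probabilistic predation, nest leaving, independence, and overwinter
   return mortality;
3. a **virtual ecologist** that observes simulations exactly the way field
   protocols observe real populations (repeated territory mapping with
   centre-in-plot counting, daily nest monitoring, weekly seasonal series);
4. a **pattern-oriented fitting layer**: six scaled fit statistics, a
   weighted overall statistic, a scripted guided-fitting scan and a
   one-at-a-time sensitivity harness, plus the incubation temperature-logger
   trip analysis.

# The daily loop

Each simulated day proceeds landscape-first: weather, then farm operations,
then vegetation growth and insect food, then the birds. All stochastic
decisions draw from one RNG stream seeded at the start of a run, so a
scenario plus a seed reproduces its event log bit for bit.

## Vegetation and insect food

The sources this model descends from do not publish their growth equations,
so the growth submodel here is deliberately simple and explicit: biomass
follows a logistic, `dB = r * tf * B * (1 - B/k)`, with the temperature
factor `tf = max(0, T - T_base)/T_scale`; height and density are linear in
biomass up to crop-specific maxima. Ten parameterised curves stand in for
the ~70 vegetation types of a full system; road, building, water and bare
elements are inert.

Insect food is likewise a package-defined stand-in for an external
insect-biomass model: a triangular seasonal envelope (opening day 60,
peaking midsummer at 300 units/m², closing day 300) multiplied by an
element-type coefficient and a saturating function `B/(B + 100)` of
vegetation biomass. Insecticide sprays multiply food by 0.4 with linear
recovery over 10 days. These constants live in `skylark_params()` and are
scenario-overridable; their absolute scale is arbitrary (only the product
with `EXTRACTION_RATE` matters for the birds), and they were set so that an
incubating female needs on the order of 10–30 trips per day in mid-season
barley, matching the order of magnitude of observed off-bout counts.

## Habitat score and territories

Every polygon gets a per-m² habitat score from its vegetation structure:
the bare-earth value below 3 cm (`HQBAREEARTH = 3`), strong penalties for
hedgerows/woodland and vegetation above 3 m (`HQHEDGE = -250`) and for the
1.1–2 m and 2–3 m bands (`HQTALL`, `HQTALLVEG`), and in the 3 cm–1.1 m crop
band a baseline `q0` modulated by power laws in height and density with
thresholds `HEIGHTCONST_C = 38 cm` and `DENSITYCONST_C = 10`. Premiums are
added for patchy vegetation, open tramlines and skylark scrapes. `q0` is not
a published value; its default (40/m²) makes a hectare of good growing crop
comfortably exceed the acceptance threshold `MINFEMACCEPTSCORE = 300000`
while bare or senescent fields fall short — which is what produces the
characteristic mid-season abandonment of unrelieved tall crops.

Territories are fixed-area square blocks (1 ha by default) claimed
best-first on a candidate lattice with half-block spacing; occupied blocks
exclude overlaps, an occupied block scoring at least
`SPLIT_MULTIPLIER * MINFEMACCEPTSCORE` may split along its longer axis when
both halves remain acceptable, and males that fail to claim remain floaters
who retry daily. The grid-block simplification is acknowledged: real
territories are plastic in shape and season.

The scrape premium (`SKSCRAPESPREMIUM = 0.24/m²`) is applied per m² of
field carrying scrapes, not per m² of scrape; being orders of magnitude
smaller than the tramline premium, the scrape effect in practice flows
mostly through the foraging-accessibility relief (`TRAMLINE_FORAGING`) and
through scenario-level tramline handling, which matches how the two-field
experiment is specified (tramlines kept open on the scrape field).

## Energetics, incubation and nestlings

Foraging accessibility declines linearly above the height and density
thresholds (`HINDCONSTH_B`, `HINDCONSTD_B`), rain hindrance follows
`min(1, (r/MAXFEEDRAIN)^RAINHINDPOW)`, and intake per trip is
`food * EXTRACTION_RATE * accessibility * (1 - hindrance) * TRIPLENGTH`
on the territory's best cell. A female's requirement is maintenance (6
units/day) plus a cold-weather surcharge (0.4 units per °C below 10 °C)
plus her brood share; trips taken are the ceiling of requirement over
per-trip intake, capped at 45/day. Four consecutive days below half the
requirement abandon the nest ("other" mortality).

Egg development is a degree-day model: the requirement is
`MINDAYSTOHATCH * (EGGTEMP - MD_THRESHOLD)` °C·days; while incubated the
egg sits at `EGGTEMP = 36.1 °C`, and during each foraging off-bout it cools
exponentially toward ambient at `COOLING_RATE_EGGS = 3 h⁻¹`, integrated in
closed form per bout with instantaneous rewarming (sub-minute thermal
transients are below the model's resolution; the closed form is verified in
the tests against fine-step Euler integration). With zero trips the
incubation length is exactly 10.2 days for any ambient temperature; with
trips, hatching is delayed into days 11–17 counted inclusively.

Nestlings grow at `min(PEMAX, 0.5 * food delivered / brood size)` g/day
with both parents provisioning (50/50 by default); three consecutive days
below half of `PEMAX` kill the brood. From age 7 the brood leaves with
probability 23 %/day and is forced out at day 11; after leaving, chicks are
dependent pre-fledglings to 30 days post-hatch.

The bare-integer probability parameters are interpreted with explicit scale
factors: `ADULTRETURNMORT`, `JUVRETURNMORT` and `NESTLEAVECHANCE` as
percentages; `CLUTCH_MORT_PROB = 350` and `NEST_MORT_PROB = 23` as daily
probabilities × 10⁻⁴ (0.035 and 0.0023/day). The scales are themselves
parameters so alternative readings remain testable; the defaults put
predation and survival proportions in the plausible range for ground
nesters.

## Demography of desk-scale patches

The scenario fixtures are small single patches (25–60 ha), not 100 km²
landscapes. A closed population on such a patch is knife-edged between
extinction and saturation at territory capacity, neither of which describes
small farmland study sites. The generators therefore treat fixtures as
**open sink-like patches**: clutch size uniform on 3–5, pre-fledgling daily
survival 0.93 (≈ 0.2 survival over the ~3-week dependent period, in line
with field post-fledging estimates for ground-nesting larks), giving local
productivity slightly below replacement, plus Poisson spring immigration
with mean 2 birds/year. The result is a persistent population of roughly
5–15 pairs that neither dies out over 60 years nor saturates both fields of
the scrape experiment. These are design constants (`PREFLEDGE_SURVIVAL`,
`IMMIGRANTS_MEAN`), set once on these grounds and overridable per scenario.

# Observation protocols

`map_territories()` counts a pair for a plot on a visit date when a mated
territory's **centre** cell lies in the plot — the model-side metric, not
the field workers' nearest-25 % area apportioning. `monitor_nests()`
records incubation length (first incubation day and hatch day both
included) or fate (predated / other), and nestling period or fate, binned
over days 9–17 and 6–11 plus the two fate categories and normalised;
periods outside a bin range are counted in the nearest bin, while the raw
days remain available in the records. All statistics discard burn-in: by
default only the last 20 years of a 60-year run are used.
`seasonal_series()` averages per-date pair counts over the same window.

# Fit statistics and sensitivity

Pattern set 1 compares predicted and observed plot densities by regression
through the origin (`b = Σxy/Σx²`) with the general
`R² = 1 − SS_err/SS_tot` about the observed mean (so R² may be negative).
The slope statistic is `min(1, |1−b|/M)` and the R² statistic
`min(1, (M_r2 − R²)/M_r2)`; the published description of this scaling is
ambiguous, and this reading was chosen because it keeps both statistics in
[0,1], zero at the ideal value, with sensitivity concentrated near the best
fit. The `M` constants are recorded alongside the statistics. Pattern set 2
uses summed squared differences of the two proportion distributions, scaled
by the analytic maximum SSD of two proportion vectors (2). Pattern set 3
scales the per-date SSD by the score of an extinct population, clamped for
overshoot. The overall statistic is the weighted mean of per-set means with
weights (2, 2, 1) — sets 1 and 2 rest on much larger field datasets — and
the weights are arguments for anyone preferring the unweighted mean.

`sensitivity_scan()` perturbs each of the 30 calibration parameters one at
a time by ±5/10/20/40 % (small integers by ±1/2/4/8), keeps everything else
fitted, recomputes the six statistics and the overall fit per run with
weather and behavioural seeds held fixed, and classifies parameters
insensitive when no perturbation moves the overall statistic by more than
0.1. The bundled scan fixture (`make_miniature_patterns()`) uses miniature
versions of the three study designs — 3 census plots of 8–14 ha, the
minimum 25 ha all-barley block, and the two-field scrape layout, at 6 m
cells over 3 years with the last 2 scored — so the full 30 × 8 scan runs in
minutes on one CPU. Its "observed" patterns are synthetic: they come from a
baseline run at the fitted defaults under a different behavioural seed,
which is the appropriate target for harness mechanics (the real field
patterns are not deposited anywhere and the headline fits are not
reproducible at desk scale).

# Temperature-logger trip analysis

Nest loggers sample every 2 minutes at 0.1 °C resolution. An off-bout event
is a maximal run of at least two consecutive 2-minute drops of at least
0.2 °C (single-period drops are discarded as egg-turning; a run may not
contain a sub-threshold step). Events are binned by duration (4, 6, 8, ...
minutes) into daily rates; control-logger rates are subtracted per bin and
clamped at zero, and the mean trip length is the mean of the net discrete
distribution. `simulate_trace()` generates ground-truth traces from the
same thermal model (exponential cooling, instantaneous rewarming, daily
sinusoid, sensor noise, 0.1 °C quantisation); recovery is exact up to the
2-minute quantisation on clean traces and degrades gracefully with noise.

# Numerical and degenerate-input choices

* Within-bout cooling uses the closed-form integral with an explicit
  threshold-crossing time; `COOLING_RATE_EGGS = 0` falls back to full-rate
  development off nest.
* Fractional incubation lengths interpolate linearly within the hatch day.
* Candidate lattices always contain at least one block even when the block
  equals the grid; blocks are clipped to the grid edge.
* All-zero observed series make the extinct-population scaling undefined
  and raise an error rather than returning a silent 0/0.
* A degenerate net trip distribution (control ≥ nest in every bin) is
  flagged and its mean is `NA`, not 0.
* Weather uses 365-day model years on a contiguous date axis; leap days are
  not modelled.

# Problem sizes

The shipped scenarios are sized for routine desk use: the all-barley
fixture is 25 ha (60 years ≈ 15 s), the scrape experiment 57 ha (60 years
≈ 10–15 s), the 16-plot census landscape ≈ 700 ha (generated at 4 m cells),
and the miniature scan bundle runs a full 30-parameter one-at-a-time scan
in roughly 6–10 minutes on one CPU.

# Known limitations

* No wintering or migration behaviour beyond the two return-mortality
  parameters; no immigration structure beyond the Poisson floor.
* Territories are fixed-area axis-aligned blocks; no plastic boundaries,
  no gradual entry as conditions improve.
* Predation is a daily coin flip, not a predator model; brood loss is
  all-or-nothing (no partial brood reduction), which the pre-fledgling
  survival constant partly compensates.
* The insect and vegetation submodels are explicit stand-ins, adequate for
  the mechanisms they feed (accessibility, energetics, timing) but not for
  quantitative entomology.
* Synthetic weather is stationary; real warming trends or specific years
  are out of scope, though `simulate_skylarks()` accepts any weather series
  with the documented columns.
* Passing tests on these fixtures demonstrates internal consistency and
  mechanism fidelity, not agreement with the original field datasets, which
  are not publicly deposited.
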