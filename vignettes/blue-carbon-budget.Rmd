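---
title: "Methods: giant-iceberg blue-carbon budgets, scour simulation and depth-zoned analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: giant-iceberg blue-carbon budgets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bergcarbon)
```

This vignette is the package's account of its models: what each one
assumes, which parameters matter, how the numerical conventions were
chosen, what the synthetic generators do and do not emulate, and where the
known limitations lie.

## The accounting problem

Antarctic zoobenthos capture carbon into tissue and carbonate skeleton
(blue carbon); burial of that material is one of the few genuine
sequestration pathways in the Southern Ocean. Ice-shelf disintegration
creates giant icebergs (> 30 km²) and, behind them, newly open shelf water
that is rapidly colonized — a carbon gain. The same icebergs, when their
keels ground, crush benthic communities back to bare sediment — a carbon
loss. The package expresses both sides in a common currency
(tonnes of immobilized carbon per year) so the net effect of a calving
event can be stated, bounded, and stress-tested.

## Parameter registry

Every constant used anywhere in the package resolves through
`load_params()`: point value, `[low, high]` range, units, and a short
provenance anchor retrievable with `cite()`. Downstream code contains no
numeric literals for these quantities, so a config override (YAML/JSON file
or named list) propagates everywhere, including through the Monte-Carlo and
simulator modules. `strict = TRUE` rejects overrides outside the default
range; the lenient default accepts them, widens the range to keep
`low <= point <= high`, and flags the entry's provenance.

Choices worth stating:

* The fertilization multiplier's point value is the low end of its 5–10
  range, and the growth multiplier's point is 2.5 within 2–3, because those
  are the values the published chain itself multiplies; the ranges are kept
  for uncertainty propagation.
* Standing stock `rho` has point 16 t C km⁻² (the climax value used by the
  cost bound) within its observed 8–16 range; recovery time `t_rec` is 5 yr,
  the midpoint of the observed 4–6.
* The ×2 sea-ice multiplier and the ×5–10 fertilization multiplier are
  stored and sampled independently; no correlation information exists for
  them, which the Monte-Carlo results inherit as an assumption.

## Budget model and the reporting convention

Generation scales linearly in iceberg area from the single published point
(`g0 × area / 5000`); nothing is known about sub- or super-linearity, and
linearity keeps the per-iceberg and fleet-level figures consistent.

No rounding convention is stated for the published chains, but one is
implied by their arithmetic: rounding the raw per-iceberg product
8.75 × 10⁵ to one significant figure in a single pass gives 9 × 10⁵, not
the printed 10⁶. The chains only reproduce under *sequential*
one-significant-figure rounding (7 × 10⁴ × 2.5 → 2 × 10⁵; 2 × 10⁵ × 5 →
10⁶ exactly), so `report_round()` implements that as the reported branch,
and every result carries the exact raw branch alongside. The net budget
truncates to two significant figures (1.96 × 10⁶ → 1.9 × 10⁶), the
convention consistent with an "at least" bound. Truncation multiplies by
`1 + 1e-12` before dropping digits so values that are exact in decimal but
not in binary (1.9 × 10⁶ stored fractionally below 19 × 10⁵) do not lose a
figure. Multi-iceberg totals multiply the *rounded* per-iceberg figure
(2 × 10⁶ for two icebergs), matching the published doubling.

The cost side `q × A_g × rho` deliberately assumes every scoured km² holds
climax stock and is cleared once per year — an upper bound. The simulator
(below) is the tool that quantifies the overstatement; the budget model
does not correct for it.

## Circumpolar ladder

The unit identity 1 g C m⁻² yr⁻¹ = 1 t C km⁻² yr⁻¹ is exact and applied
silently. The depth-band production rates (13 / 5 / 1.5 g C m⁻² yr⁻¹) are
carried in the registry and surfaced in reports, but the ladder consumes
the published mean of 3 g C m⁻² yr⁻¹ directly: the area weights that would
turn the bands into that mean are not stated anywhere, and
reverse-engineering them would manufacture precision. Reported (rounded)
values propagate rung to rung — 3.4 → 6.8 → 30 → 60 → 80 → 160 — because
that is how the published chain proceeds; `circumpolar_estimate()` returns
the unrounded branch alongside (29.92 → 159.68), and the two never diverge
by more than one unit in the second significant figure. `replay_ladder()`
re-applies each recorded rung and errors on any tampered or inconsistent
ladder.

## Monte-Carlo propagation

Ranges are sampled independently and uniformly by default — the sources
give ranges with no shape information, and uniform is the maximum-entropy
choice on a bounded interval; a triangular option (peak at the point value)
is available where a user wants the point emphasized. Propagation always
uses the raw arithmetic branch: pushing draws through the reporting
rounding would quantize the envelopes into significant-figure bins.

Because the budget and ladder are monotone in every parameter, their
attainable extremes are corner products; `propagate()` evaluates all
low/high corners of the varying parameters and reports `bound_low` /
`bound_high` next to the sampled envelope. Two registry points sit exactly
on a range endpoint (`rho` at its high end, `g_new` at its low end), so the
point estimate can coincide with an attainable bound that a finite
continuous sample almost surely never reaches — containment statements are
therefore made against the corner bounds, and the sampled `[min, max]` is
checked to converge toward them (within 100 t of the cost corners at 4000
draws in the shipped tests).

## Scour–recovery simulator

State is a grid of seabed cells (default 25 km², configurable), each with a
depth, a climax stock, and a linear recovery ramp: stock =
`climax × min(1, years_since_scour / t_rec)`. The linear ramp was chosen
over a logistic because recovery observations support only a duration (4–6
years), not a shape, and the ramp gives closed forms the tests can pin
down: an annually re-scoured cell recycles exactly `climax / t_rec` =
16/5 = 3.2 t km⁻² per event — a fifth of what the static bound books for
it. A logistic alternative would change steady-state recycling by at most
the shape of the ramp's interior, not the endpoints.

Arrivals: groundings per year default to a fixed count of 8 (the point
estimate; Poisson arrivals are an option), each striking a centre cell
drawn with probability ∝ `exp(-depth / 150 m)` — scour frequency falls
rapidly with depth because few keels reach deep shelf bottoms; the
exponential form and its 150 m scale are this package's choice and are
isolated in `arrival_model()` for replacement. Each grounding scours
`round(q × iceberg_area / cell_area)` cells (minimum 1) as a contiguous
block of cell ids wrapping around the grid — the grid is a disturbance
budget, not a map, so adjacency is bookkeeping rather than geography.
Hotspot placement restricts strikes to a designated subset with the same
depth weighting. A fast-ice modulation hook scales the annual arrival rate
linearly in open-water days (`1 + coef × days`), calibrated only
qualitatively.

Carbon is conserved exactly and `check_conservation()` asserts it year by
year: cumulative recycled + current stock − initial stock = cumulative
growth. Two properties make the cost-overstatement argument quantitative:
steady-state recycled carbon never exceeds the static bound computed from
the same parameters, and hotspot placement recycles no more than uniform
placement under paired arrival sequences (repeatedly struck cells are
mid-recovery and hold less stock). The shipped comparison uses 200 paired
30-year replicates on a 100-cell grid — small enough to run in seconds,
large enough that the paired mean difference is stable.

## Synthetic generators and what passing tests mean

`gen_monitoring_series()` draws annual fast-ice durations uniformly on
30–310 days and applies
`scoured_proportion = clip(0.9 − b × days + N(0, 0.1), 0, 1)` with `b`
anchored so 300 ice days give 5 % scour. On the default 14-year record the
fitted correlation is r ≤ −0.7 in well over 95 % of seeds (median ≈ −0.92);
the observed −0.86 on real monitoring data is the qualitative reference
this emulates, not a number the generator is tuned to reproduce. The range
30–310 days keeps the noiseless rule strictly inside [0, 1], so zero noise
yields r = −1 exactly.

`gen_benthic_samples()` gives each zone a slope of blue carbon on sea-ice
duration of (+0.02, 0, −0.02, 0) t C km⁻² per ice-day for (A, B, C, D),
Gaussian noise of 0.5 t C km⁻², a gentle depth baseline (15 − 0.01 ×
depth), and no samples at 40–200 m, emulating the real sampling gap. The
slopes are not derivable from any published value — they are chosen so that
50 samples per zone detect the signed zones with near-certain power while
the null zones exercise type-I behaviour. One statistical property follows
directly and is worth stating: with two truly-null zones tested at an
uncorrected α = 0.05 (the analysis applies no multiple-testing correction,
matching its source), the probability that *all four* zone signs come out
correct is ≈ 0.95² ≈ 0.90 per dataset, so roughly one replicate in ten
shows a spurious sign in B or D even though each zone's error rate is
exactly controlled (empirically 5–6 % over 400 seeds, with uniform
p-values). Joint-recovery tallies over small seed sets inherit that
binomial noise; the per-zone error rates, not the joint tally, are the
stable calibration quantity.

`gen_iceberg_registry()` enforces its census as hard constraints — exactly
47 records, exactly 6 above 1000 km², exactly 4 grounded, at least half in
the 100–500 km² band — with log-uniform areas within bands, reflecting
heavy-tailed iceberg size distributions. Constraint satisfaction is exact
by construction, so registry tests check counts, not expectations.

What the generators do *not* emulate: spatial autocorrelation between
neighbouring samples, inter-annual autocorrelation in fast ice,
measurement error in stock conversion, and the confounding of sea-ice
duration with bloom length that the real depth-zone pattern integrates.
Passing the recovery tests therefore shows the analysis machinery detects
the assumed structure at the assumed noise — it does not validate the
ecological interpretation of any real dataset.

## Numerical and degenerate-input conventions

* `report_round()` rejects negative inputs; zero is a fixed point of every
  mode, and all modes are idempotent.
* A net budget whose cost exceeds generation reports 0 (truncation is only
  defined for the non-negative "at least" convention); the raw net stays
  negative and exact.
* `pearson()` flags zero-variance inputs as undefined instead of erroring;
  zones with fewer than 3 samples, the 40–200 m band, and undefined
  correlations all classify as `insufficient`.
* Depth zones use half-open intervals, lower bound inclusive, with 1000 m
  as an inclusive cap and anything deeper labelled out-of-range; all
  boundaries are overridable, since the 500 m and 1000 m cuts are read off
  a plotted axis rather than stated.
* All generators and the simulator save and restore the global RNG state,
  so library calls never perturb a caller's random stream.

## Problem sizes

The shipped tests and the results script run at desk scale by design: the
deterministic chains are single arithmetic evaluations; the simulator
properties use grids of 1–400 cells over 10–40 years (the closed forms make
small grids fully informative); the placement checks use 2 × 10⁴–5 × 10⁴
draws; envelope convergence uses 4000 draws; calibration sweeps use 100
seeds. The full suite completes in well under a minute.

## Known limitations

* The cost bound and simulator treat the scoured fraction `q = 0.25` as a
  per-event quantity; whether the observed "quarter of the grounded area"
  is per event or per iceberg lifetime is not stated, so the parameter is
  exposed rather than resolved.
* No geographic realism: no coastline, bathymetry map, currents or track
  data; regional statements (e.g. halved Amundsen Sea productivity) are
  available only as plain multipliers the user applies.
* The ladder's 10–20 % "iceberg share" of the biological carbon component
  and the one-fifth-grounded recycling figure are not implemented: the
  former's numerator and the latter's derivation are not reconstructible
  from printed inputs.
* Monte-Carlo independence between multipliers is an assumption, not a
  finding; correlated sampling would narrow or widen envelopes in ways the
  current data cannot constrain.
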