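# bergcarbon

Blue carbon — the carbon held in the tissues and skeletons of marine
organisms — is stored in globally significant quantities by the animals of
the Antarctic seabed (zoobenthos), where burial offers genuine long-term
sequestration. Giant icebergs (> 30 km²) calved from disintegrating ice
shelves cut both ways: the newly opened shelf water they leave behind hosts
rapid benthic colonization and carbon capture, while their keels, when they
ground, crush and recycle entire benthic communities. `bergcarbon` makes
that trade-off computable and testable: it is aimed at polar ecologists and
carbon-budget modellers who want the accounting chain, its uncertainty, and
the disturbance dynamics behind it in one reproducible package.

## What it computes

**Per-iceberg budget.** A newly calved iceberg of area $A$ (reference
5000 km²) generates immobilized benthic carbon at

$$G = G_0 \frac{A}{5000} \times g \times f \quad \text{(t C yr}^{-1}\text{)},$$

with base rate $G_0 = 7\times10^4$ t C yr⁻¹, post-collapse growth multiplier
$g = 2.5$ (range 2–3) and iceberg-fertilization multiplier $f = 5$ (range
5–10). Reported values follow the sequential significant-figure convention
of Fermi-style chains (each multiplication rounded to one significant
figure: $7\times10^4 \times 2.5 \to 2\times10^5$, $\times 5 \to 10^6$),
with exact raw values carried alongside. The annual scour cost is the upper
bound

$$C = q \times A_g \times \rho = 0.25 \times 10\,000 \times 16 = 4\times10^4 \ \text{t C yr}^{-1},$$

where $q$ is the scoured fraction of the grounded-iceberg area $A_g$ and
$\rho$ the climax standing stock. The net budget for two new 5000 km²
icebergs truncates to two significant figures:
$2\times10^6 - 4\times10^4 \to 1.9\times10^6$ t C yr⁻¹.

**Circumpolar scaling ladder.** Mean organic production of 3 g C m⁻² yr⁻¹
plus carbonate (12 % carbon) gives 3.4 t C km⁻² yr⁻¹; doubled for the
shallows (6.8), multiplied by the 4.4 × 10⁶ km² continental shelf (≈ 30
Mt C yr⁻¹), then × 2 for sea-ice losses (60), + 10 × 2 Mt for ice-shelf
losses (80), × 2 for sub-Antarctic shelves (≈ 160 Mt C yr⁻¹).

**Monte-Carlo envelopes.** Every parameter range propagates through the raw
branch of either model, with analytic corner bounds for the monotone chains.

**Scour–recovery simulator.** A seabed grid with linear stock recovery over
$T_{rec}$ (4–6 yr) under depth-weighted stochastic groundings quantifies how
far the static cost bound overstates recycled carbon when scour concentrates
in hotspots or repeats before recovery (an annually re-scoured cell yields
exactly $\rho / T_{rec}$ = 3.2 t per event instead of 16).

**Depth-zoned correlation analysis.** Pearson correlations of benthic blue
carbon on fast-ice duration within depth zones A (0–10 m, positive),
B (10–40 m, none), 40–200 m ("zone of ignorance", unsampled), C (200–500 m,
negative) and D (500–1000 m, none), plus the negative fast-ice vs
scour-frequency fit for shallow monitoring records. Seeded synthetic
generators emulate all of these structures so the full pipeline runs
without external data.

## Worked example

```r
library(bergcarbon)
params <- load_params()                      # the published constants + ranges
budget <- net_budget(iceberg_scenario(n_icebergs = 2, area_km2 = 5000), params)
print(budget)
#> Giant-iceberg blue-carbon budget (t C yr-1)
#>   icebergs: 2 x 5000 km2
#>   generation: raw 1.75e+06, reported 2e+06
#>   scour cost: raw 4e+04, reported 4e+04
#>   net:        raw 1.71e+06, reported 1.9e+06
budget$steps
#>                        label    raw reported
#> 1      base (new open water)  70000    7e+04
#> 2        x growth multiplier 175000    2e+05
#> 3 x fertilization multiplier 875000    1e+06
```

The reported generation chain reproduces the published sequential rounding
(2 × 10⁵ after growth, 10⁶ with fertilization, per iceberg); the raw column
shows the unrounded arithmetic (8.75 × 10⁵ per iceberg), and the reported
net is the "at least" figure 1.9 × 10⁶ t C yr⁻¹.

```r
est <- circumpolar_estimate(params)
as.data.frame(est$ladder)
#>                   label input operation result
#> 1        sea-ice losses    30       x 2     60
#> 2      ice-shelf losses    60  + 10 x 2     80
#> 3 sub-Antarctic shelves    80       x 2    160

zone_correlations(gen_benthic_samples(n_per_zone = 50, seed = 42))
#>        zone depth_min depth_max  n      r        p   sign_class
#> 1         A         0        10 50  0.955 6.88e-27     positive
#> 2         B        10        40 50  0.116 4.23e-01         none
#> 3 ignorance        40       200  0     NA       NA insufficient
#> 4         C       200       500 50 -0.850 5.88e-15     negative
#> 5         D       500      1000 50 -0.191 1.85e-01     none
```

The synthetic benthic samples recover the depth-zoned sign structure —
positive in the scour-shielded shallows, null at 10–40 m where shielding
and shortened blooms cancel, negative at shelf depths where keels rarely
reach, and no verdict in the unsampled 40–200 m band.

`run_pipeline()` drives any stage end to end (`"budget"`, `"scale"`,
`"mc"`, `"simulate"`, `"generate"`, `"analyze"`, `"report"`), writing its
outputs and a reproducibility manifest to a directory.

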