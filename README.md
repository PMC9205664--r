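# beescape

Bumblebee colony dynamics and pollination services on simulated
agricultural landscapes.

`beescape` is a weekly-timestep, spatially explicit simulator for a
generic early-active bumblebee (*Bombus* sp.) in agricultural landscapes.
It is aimed at pollination ecologists and ecological modellers who want to
explore how landscape composition (semi-natural habitat and early/late
mass-flowering crops) interacts with within-season resource shortages —
drought in particular — to shape colony growth, queen production and crop
pollination, without committing to a full agent-based model.

The model chains three parts every week *t*:

1. **Phenology.** A generalized seasonal progression (0–100, the sigmoid
   `100 Φ((day − 200)/65)` of day-of-year, a stand-in for cumulative
   growing degree days) drives per-habitat parabolic flowering curves,
   giving each raster cell *i* a floral value `F(t, i)`. Drought
   suppresses the weekly *growth* of `F` during a 1–4 week window
   (positive increments → ~0, negative increments × 1.5).
2. **Foraging.** Central-place foraging on a toroidal grid with an
   exponential distance kernel: the visitation rate from a nest in cell
   *i* to cell *j* is
   `VR_ij = X_i · F_j e^(−d_ij/γ) / Σ_u F_u e^(−d_iu/γ)`, giving the
   resources collected per nest `R(t)` (with optional shared-cell
   competition between nests) and the crop pollination potential
   `P_t = Σ_crop F (1 − e^(−κ V/F))`.
3. **Colony.** A five-stage within-season machine for the average colony
   (queen foraging → worker production → worker foraging → queen
   production → decline), with weekly production
   `w_t = α(1 − exp(−(R_{t−1}+R_{t−2})/2β))` and survival δ. Season
   outputs: `MaxW` (peak weekly worker production per nest), `TQ`
   (daughter queens produced per nest) and `PS` (seasonal pollination
   score).

A latin-hypercube experiment module runs paired drought/control seasons on
100 generated landscapes, and a sensitivity module computes one-at-a-time
±10% elasticities of the population parameters.

## Worked example

```r
library(beescape)

land   <- place_nests(generate_landscape(landscape_config(seed = 42)))
series <- build_floral_series(land)
ctrl   <- run_season(land, series)
dry    <- run_season(land, apply_drought(series), b3_ref_max_R = ctrl$max_R)

land
#> bee_landscape: 201x201 cells at 10 m (2.01 km side, toroidal)
#>   realized cover: SNH 10.0%, early MFC 25.0%, late MFC 25.0%, non-bee 40.0%
#>   nests: 49 (one queen each)

ctrl
#> season_result (49 nests)
#>   MaxW (peak weekly worker production/nest): 44.21
#>   total workers produced/nest:               584.93
#>   TQ (daughter queens produced/nest):        155.64
#>   PS (seasonal pollination score):           4326.78

dry
#> season_result (49 nests)
#>   MaxW (peak weekly worker production/nest): 18.14
#>   total workers produced/nest:               194.00
#>   TQ (daughter queens produced/nest):        53.87
#>   PS (seasonal pollination score):           651.17
```

A 10% semi-natural-habitat landscape receives 49 nests at the default
nest density (121 nests per km² of SNH). Without drought each colony
produces ≈585 workers over the season, peaking near the production
ceiling; the default 4-week early drought cuts the season total to ≈194
workers with a peak of ≈18 per week, and queen production and pollination
drop accordingly. `ctrl$trajectory` holds the weekly stage/R/W/Q/P series
behind these numbers.

The simulation experiment and sensitivity analysis:

```r
design <- lhs_design(seed = 1)          # 5 x 20 latin-hypercube draws
tab    <- run_experiment(design)        # 200 paired runs
case_control_summary(tab)               # paired drought effects
sens   <- local_sensitivity(n_landscapes = 20, seed = 1)
attr(sens, "ranking")                   # delta (survival) ranks first
```

A thin command-line front end with the same functionality is installed at
`inst/cli/beescape.R`
(`Rscript inst/cli/beescape.R experiment --config cfg.yaml --seed 1
--outdir out`); `inst/extdata/example-config.yaml` documents every
configuration key.

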