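# sealdive

Seasonal and oceanographic analysis of harbour-seal diving behaviour from
animal-borne CTD telemetry.

Harbour seals (*Phoca vitulina*) at the northern edge of the species' range
live on a shelf where cold, fresh Arctic Water meets warm, saline Atlantic
Water carried north by a slope current. Instrumented seals (CTD Satellite
Relay Data Loggers) transmit Argos positions, compressed dive records, 6-h
dive summaries and upcast CTD profiles — simultaneously sampling their own
behaviour and the water column they forage in. `sealdive` implements the
full analysis chain for such deployments:

* **Track processing** — speed-distance-angle filtering of Argos positions
  (speed threshold 2 m s⁻¹; spike rules (15°, 2.5 km) and (25°, 5 km)),
  then a continuous-time correlated random walk (integrated
  Ornstein–Uhlenbeck velocity) fitted by maximum likelihood with per-class
  measurement SDs and movement frozen during haul-outs, so every dive and
  cast can be geolocated from its timestamp.
* **Dive metrics** — bottom time (time deeper than 80 % of maximum depth on
  the broken-stick profile, with exact threshold crossings), per-animal
  standardized foraging-effort residuals from `bottom ~ depth + duration`,
  bathymetry-relative dive types (coastal < 50 m; benthic if
  depth/bathymetry > 0.95, else pelagic), diel bins, and time-spent-in-area
  grids whose top quartile defines high-usage cells.
* **Hydrography** — potential density σθ (UNESCO/EOS-80, verified against
  the published check values), mixed-layer depth by the density-profile
  method (reference at 6 m, threshold 0.03 kg m⁻³), a 3-D Gaussian-weighted
  running average (SDs 3 days / 25 km / 5 m) assigning temperature and
  salinity to every dive from all animals' casts, regional daily series and
  descriptive water-mass labels (AW / ArW / mixed).
* **Environment linkage** — the daily series MLD − mean dive depth with
  at-most-one-change mean-shift detection (exhaustive likelihood search,
  MBIC penalty), and lagged northerly / north-easterly wind covariates
  (1–7 days) as an upwelling proxy.
* **Statistical layer** — seasonal additive mixed models (per-year
  penalised splines, animal random intercept, AR(1) residuals), monthly
  diel mixed models, a multinomial dive-type model, and wind-lag model
  selection, all compared by BIC with BIC weights
  `exp(−ΔBIC/2)/Σexp(−ΔBIC/2)`.
* **Synthetic deployments** — a generator that emulates the full data
  structure (heterogeneous animals on a terraced shelf, a deepening mixed
  layer, a mid-winter divergence onset, wind-lagged Atlantic Water
  intrusions, Argos noise and outliers) with complete ground truth, so
  every estimator is validated end to end.

The methods vignette (`vignettes/sealdive-methods.Rmd`) documents the
models, parameter choices and the limits of the synthetic validation.

## Worked example

```r
library(sealdive)

sim <- simulate_deployment(sim_config(n_animals = 3, end = "2010-12-15",
                                      seed = 7))
sim
#> <sd_sim> 3 animals, 2010-09-01..2010-12-15: 6403 argos, 5010 dives,
#>          1260 summaries, 4247 cast levels

filt  <- sda_filter(sim$argos)
colSums(filt$report[, c("n_input", "n_removed_speed", "n_removed_spike")])
#>  n_input n_removed_speed n_removed_spike
#>     6403            1492             739

track <- fit_track(filt$locs, sim$haulouts)
dives <- sim$dives
loc   <- locate_events(track, data.frame(id = dives$id, time = dives$start))
dives$bathy <- raster_lookup(sim$bathy, loc$lon, loc$lat)$value
dives$class <- classify_dive(dives$max_depth_m, dives$bathy)
round(prop.table(table(dives$class)), 3)
#> coastal benthic pelagic
#>   0.257   0.012   0.732

mld <- mld_by_cast(sim$casts)
head(mld[!mld$bottom_limited, c("cast_id", "mld")], 3)
#>       cast_id      mld
#> 210 S02_c0005 41.20141
#> 211 S02_c0006 41.21612
#> 226 S02_c0021 41.17403
```

A quarter of the raw Argos fixes are removed by the speed rule and spikes
(the generator plants 2 % gross outliers, but dense class-A/B fixes also
violate the 2 m s⁻¹ rule against near-in-time neighbours, exactly as in
real Argos data). Early-autumn dives split into coastal and pelagic with
few benthic dives; the detected mixed-layer depths near 41 m match the
autumn stratification the generator imposes (truth 38 m plus the
box offset, detected at the top of the pycnocline).

## The analysis workflow

The numbered drivers under `analysis/` run the study end to end on a
synthetic deployment and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R        # raw data streams + ground truth
Rscript analysis/02_tracks.R          # SDA filter, CTCRW, geolocation
Rscript analysis/03_dive_metrics.R    # bottom time, effort, types, TSA
Rscript analysis/04_hydrography.R     # MLD, regional series, T/S per dive
Rscript analysis/05_link_upwelling.R  # divergence, change point, wind lags
Rscript analysis/06_seasonal_models.R # GAMMs, diel LMEs, multinomial
```

On the default conditions the pipeline recovers the injected structure:
the divergence change point lands on the generative onset date (27 Dec),
the best-BIC wind lag equals the injected 7 days for both bottom
temperature and salinity, monthly diel models select the diel term exactly
in the injected September–November window, and dive-type classification at
located positions agrees with ground truth for > 99 % of dives.

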