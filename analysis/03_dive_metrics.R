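#!/usr/bin/env Rscript
# Stage 3: per-dive and per-day behavioural metrics. Bottom time from the
# broken-stick profiles, per-animal foraging-effort residuals
# (bottom ~ depth + duration), bathymetry-relative dive types at the located
# positions, daily series from the 6-h summaries, and time-spent-in-area
# high-usage cells from the fitted tracks.

library(sealdive)

sim <- readRDS("results/sim.rds")
track <- readRDS("results/track.rds")
dive_loc <- read.csv("results/dive_locations.csv")

dives <- sim$dives
dives$lon <- dive_loc$lon; dives$lat <- dive_loc$lat
dives$bathy <- raster_lookup(sim$bathy, dives$lon, dives$lat)$value
dives$class <- classify_dive(dives$max_depth_m, dives$bathy)
dives$bottom_s <- bottom_time_df(dives)
er <- effort_residuals(dives)
dives$effort <- er$resid_std[match(paste(dives$id, dives$start),
                                   paste(er$id, er$start))]

tsa <- tsa_high_usage(track, cell_km = 5, step_min = 10)
dives$high_usage <- in_high_usage(tsa, dives)

daily <- daily_series(sim$summaries)

cat("dive type composition:\n")
print(round(prop.table(table(dives$class)), 3))
cat(sprintf("high-usage dives: %.1f%%; complete days: %d of %d\n",
            100 * mean(dives$high_usage), sum(daily$complete), nrow(daily)))
cat(sprintf("TSA time conservation: %.4f%%\n",
            100 * sum(tsa$cells$tsa_s) / sum(tsa$elapsed_s)))

out <- dives
out$start <- format(out$start, "%Y-%m-%dT%H:%M:%S")
write.csv(out, "results/dive_metrics.csv", row.names = FALSE)
write.csv(daily, "results/daily_series.csv", row.names = FALSE)
saveRDS(list(dives = dives, daily = daily, tsa = tsa),
        "results/metrics.rds")
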