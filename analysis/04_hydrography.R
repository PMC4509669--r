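#!/usr/bin/env Rscript
# Stage 4: hydrography from the seal-collected casts. Per-cast mixed-layer
# depth by the density-profile method (sigma-theta referenced at 6 m,
# 0.03 kg m-3 threshold), regional daily temperature series at fixed depth
# levels, and the 3-D Gaussian-weighted temperature/salinity assignment to
# every dive (3 days / 25 km / 5 m), with water-mass labels.

library(sealdive)

sim <- readRDS("results/sim.rds")
metrics <- readRDS("results/metrics.rds")
cast_loc <- read.csv("results/cast_locations.csv")

casts <- sim$casts
casts$lon <- cast_loc$lon[match(casts$cast_id, cast_loc$cast_id)]
casts$lat <- cast_loc$lat[match(casts$cast_id, cast_loc$cast_id)]

mld <- mld_by_cast(casts, dsigma = 0.03)
cat(sprintf("casts: %d; valid MLD: %d; bottom-limited: %d\n",
            nrow(mld), sum(mld$valid), sum(mld$bottom_limited)))

rs <- region_series(casts, var = "temp", depth_levels = c(6, 50, 100, 150))

dives <- metrics$dives
tg <- data.frame(time = dives$start, lon = dives$lon, lat = dives$lat,
                 depth_m = dives$max_depth_m)
hyd <- interpolate_ts(tg, casts, trunc_sd = 4)
dives$t_bottom <- hyd$temp
dives$s_bottom <- hyd$sal
dives$water_mass <- water_mass_label(dives$t_bottom, dives$s_bottom)

cat("water mass at dive bottom:\n")
print(round(prop.table(table(dives$water_mass)), 3))
deep_winter <- dives$max_depth_m > 100 &
  format(dives$start, "%m") %in% c("12", "01", "02", "03")
cat(sprintf("AW fraction among deep winter dives: %.1f%%\n",
            100 * mean(dives$water_mass[deep_winter] == "AW", na.rm = TRUE)))

mld_out <- mld
mld_out$time <- format(mld_out$time, "%Y-%m-%dT%H:%M:%S")
write.csv(mld_out, "results/mld_by_cast.csv", row.names = FALSE)
write.csv(rs, "results/region_series_temp.csv", row.names = FALSE)
saveRDS(list(mld = mld, dives = dives, casts = casts),
        "results/hydro.rds")
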