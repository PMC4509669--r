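#!/usr/bin/env Rscript
# Stage 2: clean the Argos tracks with the speed-distance-angle filter
# (2 m/s; spikes under the (15 deg, 2.5 km) and (25 deg, 5 km) rules), fit
# the continuous-time correlated random walk with haul-out stopping, and
# geolocate every dive and CTD cast from its transmitted timestamp.

library(sealdive)

sim <- readRDS("results/sim.rds")

filt <- sda_filter(sim$argos)
print(filt$report[, c("id", "n_input", "n_removed_speed", "n_removed_spike")])
cat(sprintf("kept %d of %d locations\n", nrow(filt$locs), nrow(sim$argos)))

track <- fit_track(filt$locs, sim$haulouts)
print(track)

dive_loc <- locate_events(track, data.frame(id = sim$dives$id,
                                            time = sim$dives$start))
cmeta <- sim$casts[!duplicated(sim$casts$cast_id),
                   c("cast_id", "id", "time")]
cast_loc <- locate_events(track, cmeta[c("id", "time")])
cast_loc$cast_id <- cmeta$cast_id

write_argos(filt$locs, "results/locations_filtered.csv")
write.csv(dive_loc, "results/dive_locations.csv", row.names = FALSE)
write.csv(cast_loc, "results/cast_locations.csv", row.names = FALSE)
saveRDS(track, "results/track.rds")

cat(sprintf("median location SE: %.2f km\n", median(dive_loc$se_km)))
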