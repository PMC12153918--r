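#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic bulk-tank population.
#
# Herds evolve over seven latent states under the published Walloon
# transition matrix; each state emits Gaussian trait profiles around the
# published per-cluster means, sampled every 1-3 days. Artifacts (missing
# traits, out-of-range fat/protein, negative fatty acids) are injected at
# 1 % each to exercise the cleaning stage. Spectra-like features and a
# station weather table round out the inputs.

suppressMessages(library(milkstate))
outdir <- "results/analysis"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

states <- make_state_models(walloon_state_means(), walloon_trait_sds(), 0.5)
cfg <- sim_config(n_herds = 60, horizon_days = 200,
                  artifact_rates = c(missing = 0.01, range = 0.01,
                                     negative_fa = 0.01),
                  seed = 20260901L)
pop <- simulate_population(states, cfg)
spectra <- simulate_spectra(pop$records, noise_sd = 0.1, seed = cfg$seed)

stations <- data.frame(station_id = paste0("s", 1:5),
                       x = c(0, 10, 20, 5, 15), y = c(0, 5, 0, 12, 10))
set.seed(cfg$seed)
herds <- data.frame(location_id = unique(pop$records$herd_id),
                    x = runif(cfg$n_herds, 0, 20),
                    y = runif(cfg$n_herds, 0, 12))
assignments <- assign_nearest_station(herds, stations)
weather <- simulate_weather(stations, unique(pop$records$date),
                            seed = cfg$seed,
                            heat_wave = list(start = "2021-06-20",
                                             end = "2021-07-05", delta = 12))

write.csv(pop$records, file.path(outdir, "records_raw.csv"), row.names = FALSE)
write.csv(pop$truth, file.path(outdir, "truth.csv"), row.names = FALSE)
write.csv(pop$artifact_log, file.path(outdir, "artifact_log.csv"),
          row.names = FALSE)
write.csv(spectra, file.path(outdir, "spectra.csv"), row.names = FALSE)
write.csv(assignments, file.path(outdir, "station_assignments.csv"),
          row.names = FALSE)
write.csv(weather, file.path(outdir, "weather.csv"), row.names = FALSE)

cat(sprintf("simulated %d records from %d herds over %d days\n",
            nrow(pop$records), cfg$n_herds, cfg$horizon_days))
cat(sprintf("injected artifacts on %d records (%.1f %%)\n",
            length(unique(pop$artifact_log$record_id)),
            100 * length(unique(pop$artifact_log$record_id)) / nrow(pop$records)))
cat("state occupancy (truth):\n")
print(round(100 * cluster_proportions(pop$truth$state_id, k = 7), 2))
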