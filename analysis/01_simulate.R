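#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic drought experiment.
#
# Emulates the main greenhouse trial: 8 tomato plants (4 stressed, 4 control),
# bioristor implanted at day 0, water withheld from day 1 for 16 d with one
# 50 cm^3 emergency irrigation at day 8, rewatered for 7 d; currents sampled
# every 15 min, imaging and physiology every 2 d. Writes the raw-data tables
# under results/run/ and the PNG image series under scratch/images/.

suppressMessages(library(phytosense))

seed <- 42L
design <- build_design("MAIN")
config <- generator_config(seed = seed)
dir.create("results/run", recursive = TRUE, showWarnings = FALSE)

traj <- simulate_latent_states(config, design)
write_design(design, "results/run/design.yaml")

trace <- synthesize_sensor_trace(traj)
write_table(trace, "results/run/sensor_trace.csv", "sensor_trace")
message(sprintf("sensor trace: %d samples from %d plants over %d d",
                nrow(trace), length(unique(trace$plant_id)),
                design$duration_days))

physio <- sample_physiology(traj)
write_table(physio, "results/run/physio.csv", "physio")

manifest <- render_plant_images(traj, "scratch/images")
write_table(manifest, "results/run/image_manifest.csv", "manifest")
message(sprintf("rendered %d images on %d imaging days (PNGs in scratch/images)",
                nrow(manifest), length(design$imaging_days)))
saveRDS(traj, "scratch/trajectories.rds")  # latent truth, for inspection only
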