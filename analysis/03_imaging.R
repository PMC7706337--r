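#!/usr/bin/env Rscript
# Stage 3 — image-based phenotyping.
#
# Segments every RGB/NIR view and computes the five indices per plant and
# imaging day: digital biovolume, height, compactness, green index and NIR
# hydration index.

suppressMessages(library(phytosense))

manifest <- read_table("results/run/image_manifest.csv", "manifest")
indices <- extract_indices_from_manifest(manifest, "scratch/images")
write_table(indices, "results/run/indices.csv", "indices")

g <- ifelse(substr(indices$plant_id, 1, 1) == "S", "stressed", "control")
d6 <- indices$day %in% c(6, 8)
hdef <- 1 - mean(indices$height_px[d6 & g == "stressed"]) /
  mean(indices$height_px[d6 & g == "control"])
message(sprintf("height of stressed plants %.0f%% lower around stress day 6",
                100 * hdef))
last <- indices$day == max(indices$day)
message(sprintf("final biovolume, stressed/control: %.2f (no recovery after rewatering)",
                mean(indices$biovolume[last & g == "stressed"]) /
                  mean(indices$biovolume[last & g == "control"])))
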