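#!/usr/bin/env Rscript
# Stage 2 — bioristor response analysis.
#
# Computes R = (Ids - Ids0)/Ids0 per sample, averages each 24 h cycle,
# normalizes stressed over control (NR), segments the NR trajectory into
# drought phases and detects stress onset. Key findings are printed; tables
# land in results/run/.

suppressMessages(library(phytosense))

design <- read_design("results/run/design.yaml")
trace <- read_table("results/run/sensor_trace.csv", "sensor_trace")

response <- compute_response(trace)
write_table(response[, c("plant_id", "time_min", "r")],
            "results/run/response.csv", "response")

daily <- daily_mean(response, design)
nr <- normalize_nr(daily[daily$group == "stressed", ],
                   daily[daily$group == "control", ])
write_table(nr, "results/run/daily_nr.csv", "daily_nr")

seg <- segment_phases(nr, design)
print(seg)
rec <- recovery_deficit(nr, seg)
message(sprintf("post-rewatering NR plateau reaches %.0f%% of the pre-stress baseline",
                100 * rec))

onset <- detect_onset(response_ratio_series(response), design)
if (onset$detected) {
  message(sprintf("stress onset detected %.1f h after water withholding (slope %.3f NR/day, p = %.2g)",
                  onset$onset_h, onset$window_slope, onset$p_slope))
} else {
  message("no stress onset detected within 72 h of water withholding")
}
jsonlite::write_json(c(onset, list(recovery_deficit = rec)),
                     "results/run/onset.json", auto_unbox = TRUE, digits = NA)
jsonlite::write_json(list(segments = seg$segments, breakpoints = seg$breakpoints),
                     "results/run/phases.json", auto_unbox = TRUE, digits = NA)
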