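#!/usr/bin/env Rscript
# Stage 4 — manual physiology.
#
# Stomatal conductance fold changes, relative water content from leaf weight
# triplets, and relative SPAD, summarized per day and group.

suppressMessages(library(phytosense))

physio <- read_table("results/run/physio.csv", "physio")
summ <- physio_summary(physio)

write.csv(summ$sc, "results/run/physio_sc.csv", row.names = FALSE)
write.csv(summ$rwc_group, "results/run/physio_rwc.csv", row.names = FALSE)
write.csv(summ$spad, "results/run/physio_spad.csv", row.names = FALSE)

peak <- summ$sc[summ$sc$day %in% 8:14, ]
message(sprintf("SC reduced %.1f-%.1f fold during peak stress (days 8-14)",
                min(peak$fold), max(peak$fold)))
rw <- summ$rwc_group
message(sprintf("RWC drop at peak stress: %.0f%%; after rewatering: %.1f%%",
                100 * max(rw$drop_frac), 100 * rw$drop_frac[nrow(rw)]))
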