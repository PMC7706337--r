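#!/usr/bin/env Rscript
# Stage 5 — integrative statistics.
#
# Joins sensor, image and physiology features over the stress-period imaging
# days, then computes the pairwise Pearson correlation matrix, the PCA biplot
# and per-timepoint ANOVA with star annotation.

suppressMessages(library(phytosense))

design <- read_design("results/run/design.yaml")
indices <- read_table("results/run/indices.csv", "indices")
physio <- read_table("results/run/physio.csv", "physio")
trace <- read_table("results/run/sensor_trace.csv", "sensor_trace")

daily <- daily_mean(compute_response(trace), design)
s0 <- stress_start_day(design)
features <- build_feature_table(indices[indices$day >= s0, ], daily, physio)
write.csv(features, "results/run/features.csv", row.names = FALSE)

cm <- correlation_matrix(features)
write.csv(as.data.frame(cm$r), "results/run/correlations.csv")
message(sprintf("r(R, SC) = %.2f (p = %.1g); r(R, DB) = %.2f (p = %.1g)",
                cm$r["R", "SC"], cm$p["R", "SC"],
                cm$r["R", "DB"], cm$p["R", "DB"]))

pca <- run_pca(features)
write.csv(data.frame(component = seq_along(pca$variance_explained),
                     variance_explained = pca$variance_explained),
          "results/run/variance_explained.csv", row.names = FALSE)
write.csv(as.data.frame(pca$scores), "results/run/pca_scores.csv")
write.csv(as.data.frame(pca$loadings), "results/run/pca_loadings.csv")
pc1 <- pca$scores[, 1]
sep <- abs(diff(tapply(pc1, pca$group, mean))) /
  sqrt(mean(tapply(pc1, pca$group, var)))
message(sprintf("PC1+PC2 explain %.1f%%; PC1 separates the groups by %.1f pooled SD",
                sum(pca$variance_explained[1:2]), sep))

long <- reshape(features[, c("group", "day", feature_variables)],
                varying = feature_variables, v.names = "value",
                timevar = "variable", times = feature_variables,
                direction = "long")
tests <- timepoint_tests(long, method = "anova")
write.csv(tests, "results/run/timepoint_tests.csv", row.names = FALSE)
message(sprintf("%d of %d day x variable tests significant at p <= 0.05",
                sum(tests$stars != ""), nrow(tests)))
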