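#!/usr/bin/env Rscript
# Stage 2: extract the 304-measure dysphonia battery from the
# demonstration cohort synthesized in stage 1 (re-synthesized here from
# the same seeds; waveforms are never stored on disk).
#
# Outputs under results/: feature_matrix_demo.csv, feature_manifest.txt

library(pdvoice)

dir.create("results", showWarnings = FALSE)
seed <- 20260923

demo_spec <- cohort_spec(n_pd_recordings = 8, n_control_recordings = 8,
                         n_pd_participants = 5, n_control_participants = 5,
                         duration = 4, seed = seed + 1)
demo <- generate_cohort(demo_spec, synthesize = TRUE,
                        channel = channel_spec())

message("Extracting 304 measures per phonation...")
t0 <- Sys.time()
ds <- extract_cohort_features(demo)
dt <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
message(sprintf("  %d x %d feature matrix in %.1f s (%.2f s/phonation)",
                nrow(ds$X), ncol(ds$X), dt, dt / nrow(ds$X)))

write_feature_matrix(ds, "results/feature_matrix_demo.csv")
mf <- feature_manifest()
writeLines(sprintf("%-28s %s", mf$name, mf$family),
           "results/feature_manifest.txt")

# headline group contrast on the demonstration cohort
for (feat in c("jitter.local_mean", "shimmer.local_mean", "hnr.hnr_mean")) {
  message(sprintf("  %-20s PD median %.4f | control median %.4f", feat,
                  median(ds$X[ds$y == 1, feat]),
                  median(ds$X[ds$y == 0, feat])))
}
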