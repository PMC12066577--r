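#!/usr/bin/env Rscript
# Stage 1 -- generate the synthetic experiment: Th17 and Treg micro-well
# populations at the study conditions (52 hr, 30-min frames; RORgt onsets
# 21.8 +/- 9.4 hr, Foxp3 onsets 39.3 +/- 8.2 hr; first divisions 38.8 /
# 36 hr), with pixel rendering for a subset of wells, and write the trace,
# pixel and metadata tables consumed by the later stages.

suppressPackageStartupMessages(library(clonefate))

seed <- 20260921
out <- "results"
dir.create(out, showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

cfg <- default_config(seed = seed)
pops <- lapply(seq_along(cfg$populations), function(i) {
  pc <- cfg$populations[[i]]
  spec <- population_spec(pc$condition, n_clones = pc$n_clones)
  simulate_population(spec, seed = stage_seed(seed, i),
                      render_pixels = TRUE,
                      n_pixel_wells = cfg$heterogeneity$n_pixel_wells)
})
names(pops) <- names(cfg$populations)

# long trace table: one row per well x frame
traces_df <- do.call(rbind, lapply(pops, function(p) {
  do.call(rbind, lapply(p$traces, function(tr) {
    data.frame(well_id = attr(tr, "well_id"), condition = attr(tr, "condition"),
               time_hr = tr$time_hr, total_G = tr$total_G, total_R = tr$total_R)
  }))
}))
write.csv(traces_df, file.path(out, "traces.csv"), row.names = FALSE)

metadata <- do.call(rbind, lapply(pops, `[[`, "metadata"))
rownames(metadata) <- NULL
write.csv(metadata, file.path(out, "wells.csv"), row.names = FALSE)

# pixel table for the rendered wells, last 5 frames only (the frames the
# heterogeneity analysis uses)
pixels_df <- do.call(rbind, lapply(pops, function(p) {
  do.call(rbind, lapply(p$frames, function(frames) {
    last5 <- frames[(length(frames) - 4):length(frames)]
    do.call(rbind, lapply(last5, function(f) {
      data.frame(well_id = f$well_id, frame_index = f$frame_index,
                 time_hr = f$time_hr, pixel_id = seq_along(f$G),
                 G = f$G, R = f$R)
    }))
  }))
}))
write.csv(pixels_df, file.path(out, "pixels_last5.csv"), row.names = FALSE)

saveRDS(pops, file.path("scratch", "populations.rds"))  # fast handoff for stages 2-4

cat(sprintf("simulated %d wells (%s)\n", nrow(metadata),
            paste(sprintf("%s: %d", names(pops),
                          vapply(pops, function(p) nrow(p$metadata), integer(1))),
                  collapse = ", ")))
cat("true fate mix:\n")
print(table(metadata$condition, metadata$true_fate))
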