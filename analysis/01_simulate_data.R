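#!/usr/bin/env Rscript
# Generate every synthetic input the downstream analyses consume, with
# ground truth saved alongside: a mixed-species droplet run, five-group
# planted counts, a reference panel, astrocyte skeletons with neurite
# evidence, and stimulus-locked calcium traces.

suppressMessages(library(xenofate))
seed <- 20240506L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("-- mixed-species droplet run (2,000 singlets + 2% doublets)")
barn <- simulate_barnyard(barnyard_config(
  n_human = 1000, n_mouse = 1000, n_doublets = 40,
  ambient_fraction = 0.01, mean_umis_per_cell = 5000, seed = seed))
write_10x_counts(barn$matrix, file.path(out, "barnyard"))
write.table(barn$truth, file.path(out, "barnyard_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message("-- five-group planted counts (D0, PFC/HIP x 2/4 MPT)")
grouped <- simulate_grouped_counts(planted_design(seed = seed))
write_10x_counts(grouped$matrix, file.path(out, "grouped"))
write.table(data.frame(barcode = colnames(grouped$matrix$counts),
                       group = grouped$matrix$cell_sample),
            file.path(out, "grouped_design.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(grouped$truth, file.path(out, "grouped_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_gmt(list(pfc_program = grouped$truth$gene[grouped$truth$axis ==
                                                  "region" &
                                                grouped$truth$effect > 0],
               hip_program = grouped$truth$gene[grouped$truth$axis ==
                                                  "region" &
                                                grouped$truth$effect < 0]),
          file.path(out, "region_programs.gmt"))

message("-- reference panel with known best matches")
panel <- simulate_reference_panel(n_refs = 5, n_samples = 10, n_genes = 500,
                                  noise_sd = 1, seed = seed)
write.table(panel$panel, file.path(out, "reference_panel.tsv"),
            sep = "\t", quote = FALSE)
write.table(panel$samples, file.path(out, "query_profiles.tsv"),
            sep = "\t", quote = FALSE)
write.table(panel$truth, file.path(out, "panel_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message("-- astrocyte skeletons + neurite evidence points")
for (cell in 1:3) {
  s <- simulate_skeleton(skeleton_config(seed = seed + cell))
  write_swc(s$skeleton, file.path(out, sprintf("astrocyte%02d.swc", cell)))
  np <- simulate_neurite_points(s$skeleton, coverage_fraction = 0.5,
                                offset = 0, seed = seed + cell)
  write.csv(np$points, file.path(out, sprintf("neurites%02d.csv", cell)),
            row.names = FALSE)
}

message("-- calcium traces (CONT / DA / ACh, administration at 10 s)")
# planted amplitudes put DA and ACh at 3.5x and 2.7x the control response;
# distinct rise dynamics let the correlation clustering tell them apart
traces <- simulate_traces(
  trace_config(dt = 0.1, duration = 60, stimulus_time = 10,
               noise_sd = 1, seed = seed),
  n_cells = 24,
  amplitude_fraction = rep(c(0.2, 0.7, 0.54), each = 8),
  rise_time = rep(c(1, 0.5, 6), each = 8),
  groups = rep(c("CONT", "DA", "ACh"), each = 8))
write_traces(traces, file.path(out, "calcium_traces.csv"),
             meta = file.path(out, "calcium_traces.yaml"))

message("done: inputs and ground truth under ", out)
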