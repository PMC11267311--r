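#!/usr/bin/env Rscript
# Calcium response analysis of the CONT / DA / ACh traces: dF/F0, the 10%
# response criterion, response times, fold activation vs control, and
# activity-correlation clustering.

suppressMessages(library(xenofate))
data_dir <- "results/data"
out <- "results"

traces <- read_traces(file.path(data_dir, "calcium_traces.csv"),
                      meta = file.path(data_dir, "calcium_traces.yaml"))
st <- dff(traces)
resp <- detect_response(st, theta = 0.10)
write.table(resp, file.path(out, "calcium_responses.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message(sprintf("%d/%d cells responded ((F/F0 - 1) > 10%%)",
                sum(resp$responded), nrow(resp)))
for (g in unique(resp$group)) {
  sel <- resp$group == g
  message(sprintf(
    "  %s: %d/%d responders, median response time %.1f s, mean max dF/F0 %.2f",
    g, sum(resp$responded[sel]), sum(sel),
    median(resp$response_time[sel], na.rm = TRUE),
    mean(resp$max_amplitude[sel])))
}

ga <- group_activation(resp, control = "CONT")
write.table(ga, file.path(out, "group_activation.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("fold activation: dF_DA/dF_CONT = %.1f; dF_ACh/dF_CONT = %.1f",
                ga$fold_vs_control[ga$group == "DA"],
                ga$fold_vs_control[ga$group == "ACh"]))

cl <- trace_correlation_cluster(st, k = 3)
clusters <- data.frame(cell = names(cl$clusters),
                       group = traces$groups,
                       cluster = unname(cl$clusters))
write.table(clusters, file.path(out, "calcium_clusters.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
tab <- table(clusters$group, clusters$cluster)
message("activity-correlation clusters (rows: group, cols: cluster):")
for (g in rownames(tab))
  message("  ", g, ": ", paste(tab[g, ], collapse = " "))
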