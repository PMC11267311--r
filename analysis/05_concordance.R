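#!/usr/bin/env Rscript
# Cross-comparison fate alignment: fold-change quadrant analysis between the
# two region contrasts, signed host-alignment scores of the region programs,
# and hypergeometric over-representation of the DEG list in the program
# gene sets.

suppressMessages(library(xenofate))
out <- "results"

deg_2m <- read.delim(file.path(out, "deg_PFC2_vs_HIP2.tsv"))
deg_4m <- read.delim(file.path(out, "deg_PFC4_vs_HIP4.tsv"))
programs <- read_gmt(file.path(out, "data", "region_programs.gmt"))

pair <- comparison_pair(deg_2m, deg_4m, mode = "union")
qa <- quadrant_analysis(pair$fc_x, pair$fc_y, genes = pair$genes)
write.table(data.frame(gene = names(qa$quadrant),
                       quadrant = as.character(qa$quadrant),
                       fc_2mpt = pair$fc_x, fc_4mpt = pair$fc_y),
            file.path(out, "quadrant_assignments.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf(
  "quadrant analysis over %d genes: I=%d II=%d III=%d IV=%d axis=%d; r = %.3f",
  sum(qa$counts), qa$counts["I"], qa$counts["II"], qa$counts["III"],
  qa$counts["IV"], qa$counts["axis"], qa$r))
message(sprintf("concordant (I+III) share: %.1f%%",
                100 * sum(qa$counts[c("I", "III")]) / sum(qa$counts)))

fc <- setNames(deg_4m$log2fc, deg_4m$gene)
align <- data.frame(
  gene_set = names(programs),
  score = sapply(programs, function(s) alignment_score(s, fc)$score),
  sign = sapply(programs, function(s) alignment_score(s, fc)$sign),
  n_genes = lengths(programs)
)
write.table(align, file.path(out, "alignment_scores.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("host-alignment scores on the PFC-vs-HIP (4MPT) contrast:")
for (i in seq_len(nrow(align)))
  message(sprintf("  %s: sum log2FC = %+.1f (sign %+d)",
                  align$gene_set[i], align$score[i], align$sign[i]))

universe <- deg_4m$gene
query <- deg_4m$gene[deg_4m$passes]
set.seed(1)
collection <- c(programs,
                setNames(lapply(1:20, function(i) sample(universe, 50)),
                         sprintf("random%02d", 1:20)))
ora <- ora_hypergeometric(query, collection, universe)
write.table(ora, file.path(out, "ora_results.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf(
  "ORA: top set '%s' (k=%d/K=%d, q = %.2e); planted programs rank %s",
  ora$set[1], ora$k[1], ora$K[1], ora$q[1],
  paste(which(ora$set %in% names(programs)), collapse = ",")))
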