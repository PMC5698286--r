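#!/usr/bin/env Rscript
# Quantify the repertoire: per-gene/per-J counts, normalization to the
# median-total replicate, median frequencies, binomial activity calls and
# the mappability filter. Writes results/quantify/.

suppressPackageStartupMessages(library(kappaseq))

sim <- "results/sim"
out <- "results/quantify"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

genes <- read.table(file.path(sim, "genes.tsv"), header = TRUE,
                    colClasses = c(id = "character"))
reference <- readLines(file.path(sim, "locus.fa"))[2]
events <- read.table("results/readproc/events.tsv", header = TRUE)
truth <- read.table(file.path(sim, "ground_truth.tsv"), header = TRUE)

windows <- gene_windows(genes, nchar(reference))
cnt <- count_events(events, genes, windows)
norm <- normalize_replicates(cnt, "J1_only")
cat("replicate scale factors:",
    sprintf("%.3f", attr(norm, "scale_factors")), "\n")

med <- median_frequency(norm[norm$j == "J1", ])
v_region_length <- (max(genes$end) + 500) - (min(genes$start) - 500)
calls <- call_active_genes(norm, v_region_length)
cat(sprintf("%d of %d genes called active (padj < 0.01)\n",
            sum(calls$active), nrow(calls)))
tab <- table(called = calls$active,
             truth = truth$active[match(calls$gene, truth$id)])
print(tab)

retained <- apply_mappability_filter(genes, reference, windows = windows)
cat(sprintf("mappability filter: %d of %d genes retained (>= 70%%)\n",
            nrow(retained), nrow(genes)))

write.table(norm, file.path(out, "counts_normalized.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(med, file.path(out, "median_frequency_J1.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(calls, file.path(out, "activity_calls.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(retained[, c("id", "mappability")],
            file.path(out, "mappability_retained.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote", out, "\n")
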