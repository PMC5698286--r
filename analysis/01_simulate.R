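#!/usr/bin/env Rscript
# Generate the synthetic study: locus, annotations, chromatin tracks, peak
# calls and three replicates of paired bait-capture reads, with ground truth.
# Outputs under results/sim/.

suppressPackageStartupMessages(library(kappaseq))

out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config()
loc <- simulate_locus(cfg)
chrom <- simulate_chromatin(loc)
rd <- simulate_reads(loc)

cat(sprintf("locus: %d bp, %d V genes (%.0f%% reverse strand), %d J genes\n",
            cfg$locus_length, nrow(loc$genes),
            100 * mean(loc$genes$strand == "-"), nrow(loc$jgenes)))
cat(sprintf("truth: %d active genes; %d read pairs over %d replicates\n",
            sum(loc$truth$active), length(rd$read1), cfg$n_replicates))

writeLines(c(">locus", loc$reference), file.path(out, "locus.fa"))
write.table(data.frame("locus", loc$genes$start, loc$genes$end,
                       loc$genes$id, 0, loc$genes$strand),
            file.path(out, "genes.bed"), sep = "\t", quote = FALSE,
            row.names = FALSE, col.names = FALSE)
write.table(loc$genes, file.path(out, "genes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(loc$jgenes, file.path(out, "jgenes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
truth <- data.frame(id = loc$genes$id, active = loc$truth$active,
                    log2_freq = loc$truth$log2_freq,
                    pu1_bind = loc$truth$pu1_bind,
                    e_rss = loc$truth$e_rss, e_prom = loc$truth$e_prom)
write.table(truth, file.path(out, "ground_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

dir.create(file.path(out, "tracks"), showWarnings = FALSE)
for (tr in names(chrom$tracks)) {
  write_bedgraph(chrom$tracks[[tr]],
                 file.path(out, "tracks", paste0(tr, ".bedGraph")))
}
dir.create(file.path(out, "peaks"), showWarnings = FALSE)
for (tf in names(chrom$peaks)) {
  write_narrowpeak(chrom$peaks[[tf]],
                   file.path(out, "peaks", paste0(tf, ".narrowPeak")))
}
write.table(chrom$segments, file.path(out, "true_segments.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

write_fastq(rd$read1, file.path(out, "reads_R1.fastq"))
write_fastq(rd$read2, file.path(out, "reads_R2.fastq"))
write.table(rd$labels, file.path(out, "read_labels.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("wrote", out, "\n")
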