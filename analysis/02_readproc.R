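#!/usr/bin/env Rscript
# Process the simulated paired reads into deduplicated recombination events:
# chimaera correction, bait assignment, filtering, unique alignment, UMI
# deduplication. Reads results/sim/, writes results/readproc/.

suppressPackageStartupMessages(library(kappaseq))

sim <- "results/sim"
out <- "results/readproc"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

reference <- readLines(file.path(sim, "locus.fa"))[2]
jgenes <- read.table(file.path(sim, "jgenes.tsv"), header = TRUE,
                     colClasses = c(id = "character"))
labels <- read.table(file.path(sim, "read_labels.tsv"), header = TRUE)
r1 <- read_fastq(file.path(sim, "reads_R1.fastq"))
r2 <- read_fastq(file.path(sim, "reads_R2.fastq"))
anchors <- sim_config()$anchor_sequences

pr <- process_reads(r1, r2, labels$replicate[match(names(r1), labels$read_id)],
                    jgenes, reference, anchors)
print(pr$stage_counts)
cat(sprintf("%d deduplicated events (%.1f%% of input pairs)\n",
            nrow(pr$events), 100 * nrow(pr$events) / length(r1)))

write.table(pr$events, file.path(out, "events.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(pr$stage_counts, file.path(out, "stage_counts.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote", out, "\n")
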