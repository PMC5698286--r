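#!/usr/bin/env Rscript
# Build the genes x 79 chromatin/genetic feature matrix and the peak
# co-localization summary. Writes results/features/.

suppressPackageStartupMessages(library(kappaseq))

sim <- "results/sim"
out <- "results/features"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

genes <- read.table(file.path(sim, "genes.tsv"), header = TRUE,
                    colClasses = c(id = "character"))
windows <- gene_windows(genes, max(genes$end) + 30000)

track_files <- list.files(file.path(sim, "tracks"), full.names = TRUE)
tracks <- lapply(track_files, function(f) {
  df <- read.table(f, col.names = c("chrom", "start", "end", "count"))
  df[, c("start", "end", "count")]
})
names(tracks) <- sub("\\.bedGraph$", "", basename(track_files))
# keep the configured dataset order so columns are deterministic
tracks <- tracks[intersect(sim_config()$tracks, names(tracks))]

fm <- build_feature_matrix(genes, tracks, windows)
cat(sprintf("feature matrix: %d genes x %d features\n", nrow(fm), ncol(fm)))
write.table(data.frame(id = rownames(fm), fm, check.names = FALSE),
            file.path(out, "feature_matrix.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

peak_files <- list.files(file.path(sim, "peaks"), full.names = TRUE)
assoc <- list()
for (f in peak_files) {
  tf <- sub("\\.narrowPeak$", "", basename(f))
  pk <- read.table(f, col.names = c("chrom", "start", "end", "name", "score",
                                    "strand", "signalValue", "pValue",
                                    "qValue", "peak"))
  if (nrow(pk) < 35) next   # distance analysis needs enough peaks
  d <- nearest_peak_distances(genes, pk)
  d$dataset <- tf
  assoc[[tf]] <- d
}
assoc <- do.call(rbind, assoc)
write.table(assoc, file.path(out, "peak_associations.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("peak association across %d datasets: %.0f%% of genes promoter-",
            length(unique(assoc$dataset)),
            100 * mean(tapply(assoc$promoter_associated, assoc$id, any))))
cat(sprintf("or RSS-associated\n"))
cat("wrote", out, "\n")
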