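#!/usr/bin/env Rscript
# Descriptive and inferential statistics on the quantified repertoire:
# replicate clustering, variance explained by the RIC score, state-activity
# association, and frequency tertiles of good-RIC active genes.
# Writes results/report/.

suppressPackageStartupMessages(library(kappaseq))

out <- "results/report"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

genes <- read.table("results/sim/genes.tsv", header = TRUE,
                    colClasses = c(id = "character"))
norm <- read.table("results/quantify/counts_normalized.tsv", header = TRUE,
                   colClasses = c(gene = "character"))
med <- read.table("results/quantify/median_frequency_J1.tsv", header = TRUE,
                  colClasses = c(gene = "character"))
calls <- read.table("results/quantify/activity_calls.tsv", header = TRUE,
                    colClasses = c(gene = "character"))
assign <- read.table("results/segmentation/gene_states.tsv", header = TRUE,
                     colClasses = c(id = "character"))
fm_df <- read.table("results/features/feature_matrix.tsv", header = TRUE,
                    check.names = FALSE, colClasses = c(id = "character"))

report <- list()

## Replicate agreement and clustering
cl <- repertoire_clustering(norm)
j1 <- grep("^J1", rownames(cl$cor))
report$min_J1_replicate_correlation <- min(cl$cor[j1, j1])
cat(sprintf("minimum Pearson r among J1 replicates: %.4f\n",
            report$min_J1_replicate_correlation))
write.table(round(cl$cor, 4), file.path(out, "replicate_correlations.tsv"),
            sep = "\t", quote = FALSE)

## Variance in usage explained by the RIC score (active genes)
act <- calls$gene[calls$active]
freq <- med$median_frequency[match(act, med$gene)]
ric <- genes$ric_score[match(act, genes$id)]
ok <- freq > 0
rve <- ric_variance_explained(log2(freq[ok]), ric[ok])
report$ric_r_squared <- rve$r_squared
cat(sprintf("RIC score explains %.1f%% of log2-frequency variance\n",
            100 * rve$r_squared))

## Chromatin state vs activity
sa <- state_activity_association(assign,
                                 calls$active[match(assign$id, calls$gene)])
report$state_activity_p <- sa$p_value
report$state_activity_odds_ratio <- sa$odds_ratio
cat(sprintf("state-activity Fisher test: OR %.2f, p %.3g\n",
            sa$odds_ratio, sa$p_value))

## Frequency tertiles of good-RIC active genes with feature comparisons
fm <- as.matrix(fm_df[, -1])
rownames(fm) <- fm_df$id
interesting <- intersect(c("H3K4me2_rss", "H3K4me3_rss", "IKAROS_rss",
                           "PU.1_rss", "MED1_promoter", "PAX5_upstream"),
                         colnames(fm))
tert <- frequency_tertiles(freq[ok], ric[ok],
                           features = fm[act[ok], interesting])
report$tertile_sizes <- as.list(tert$sizes)
cat("tertile sizes:", paste(tert$sizes, collapse = "/"), "\n")
sig <- tert$tests[tert$tests$padj < 0.05, ]
cat(sprintf("%d of %d tertile feature comparisons significant (padj < 0.05)\n",
            nrow(sig), nrow(tert$tests)))
write.table(tert$tests, file.path(out, "tertile_tests.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

jsonlite::write_json(report, file.path(out, "report.json"),
                     auto_unbox = TRUE, digits = NA)
cat("wrote", out, "\n")
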