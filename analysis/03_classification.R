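#!/usr/bin/env Rscript

# Stage 3 — MDS and KNN subtype classification.
#
# Euclidean distances over the 500 top-variance genes (logCPM) give the
# MDS map; the repeated-subsampling protocol (100 replicates, half the
# genes each, 3-NN leave-one-out) gives accuracy curves over growing
# top-variance gene sets, for all biotypes and separately for lncRNA and
# protein-coding genes, plus the class-balanced under-sampled variant.

suppressMessages(library(callsig))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L

counts <- read_counts("results/cohort/counts.tsv")
samples <- suppressWarnings(read_sample_table("results/cohort/samples.tsv"))
genes <- read_gene_models("results/cohort/genes.tsv")
cfg <- default_config()

expr <- log_cpm(counts, prior_count = cfg$prior_count)
tumor <- samples$group != "Control"
te <- expr[, tumor]
labels <- droplevels(factor(samples$group[tumor]))

top <- top_variance_genes(te, cfg$n_top_mds, genes,
                          exclude_biotypes = "pseudogene")
mds <- classical_mds(distance_matrix(te, top))
coords <- data.frame(id = colnames(te), subtype = as.character(labels),
                     dim1 = mds$points[, 1], dim2 = mds$points[, 2])
write.table(coords, "results/mds_coordinates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

grid <- c(2L, 5L, 10L, 20L, 50L, 100L, 200L, 500L)
reports <- list(
  accuracy_curve(te, labels, cfg, genes, gene_counts = grid,
                 seed = child_seed(seed, "curve_all")),
  accuracy_curve(te, labels, cfg, genes, gene_counts = grid,
                 restriction = "lncRNA",
                 seed = child_seed(seed, "curve_lnc")),
  accuracy_curve(te, labels, cfg, genes, gene_counts = grid,
                 restriction = "protein_coding",
                 seed = child_seed(seed, "curve_pc")),
  balanced_accuracy_curve(te, labels, cfg, genes,
                          gene_counts = grid[grid <= 50L],
                          seed = child_seed(seed, "curve_bal")))
report <- do.call(rbind, reports)
write.table(report, "results/classification_report.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

at50 <- function(r, cl) r$mean_acc[r$class == cl & r$n_genes == 50]
cat(sprintf("overall accuracy at 50 genes: %.1f%% (all) / %.1f%% (lncRNA) / %.1f%% (protein-coding)\n",
            100 * at50(reports[[1]], "overall"),
            100 * at50(reports[[2]], "overall"),
            100 * at50(reports[[3]], "overall")))
cat(sprintf("t(9;22) accuracy at 50 genes: %.1f%% unbalanced vs %.1f%% balanced\n",
            100 * at50(reports[[1]], "t(9;22)"),
            100 * at50(reports[[4]], "t(9;22)")))
cat("wrote results/mds_coordinates.tsv, results/classification_report.tsv\n")
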