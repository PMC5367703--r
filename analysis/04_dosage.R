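#!/usr/bin/env Rscript

# Stage 4 — gene dosage in the HeH subtype.
#
# Per autosome: median HeH/control fold change (genes > 30 CPM in both
# groups) against the chromosome's mean copy number in HeH, with an OLS
# fit; then the exclusion re-analysis, removing genes on the frequently
# gained chromosomes and re-running normalization, MDS and HeH
# classification to measure how much of the HeH signature is pure dosage.

suppressMessages(library(callsig))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L

counts <- read_counts("results/cohort/counts.tsv")
samples <- suppressWarnings(read_sample_table("results/cohort/samples.tsv"))
genes <- read_gene_models("results/cohort/genes.tsv")
cfg <- default_config()

rep <- dosage_report(counts, samples, genes, cfg)
write.table(rep$table, "results/dosage_per_chromosome.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("dosage regression: slope %.3f, intercept %.3f, r %.3f, R^2 %.3f over %d autosomes\n",
            rep$slope, rep$intercept, rep$pearson_r, rep$r_squared,
            rep$n_chromosomes))

excl <- exclusion_reanalysis(counts, samples, genes, cfg,
                             seed = child_seed(seed, "exclusion"))
jsonlite::write_json(
  list(distance_correlation = excl$distance_correlation,
       n_top_variance_genes_lost = excl$n_top_lost,
       heh_accuracy_all = excl$heh_accuracy_all,
       heh_accuracy_excluded = excl$heh_accuracy_excluded,
       slope = rep$slope, pearson_r = rep$pearson_r,
       r_squared = rep$r_squared),
  "results/dosage_summary.json", auto_unbox = TRUE, digits = NA)
cat(sprintf("exclusion of chr %s: distance r = %.3f, HeH accuracy %.1f%% -> %.1f%% (%d/%d top genes lost)\n",
            paste(cfg$heh_gained, collapse = ","),
            excl$distance_correlation, 100 * excl$heh_accuracy_all,
            100 * excl$heh_accuracy_excluded, excl$n_top_lost,
            cfg$n_top_mds))
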