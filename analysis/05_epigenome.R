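#!/usr/bin/env Rscript

# Stage 5 — promoter chromatin and TF binding on deregulated genes.
#
# TSS windows (+/-5 kb around the most-upstream TSS) are intersected with
# the histone-mark tracks: metagene coverage profiles per dysregulation
# category, the bivalency (H3K27me3 + H3K4me3) fractions with their fold
# enrichment in up-regulated genes, and per-TF hypergeometric peak
# enrichment crossed with the TF's own expression change.

suppressMessages(library(callsig))

counts <- read_counts("results/cohort/counts.tsv")
samples <- suppressWarnings(read_sample_table("results/cohort/samples.tsv"))
genes <- read_gene_models("results/cohort/genes.tsv")
de <- read_de_table("results/de_table.tsv")
calls <- read.delim("results/dysregulation_calls.tsv",
                    stringsAsFactors = FALSE)
cfg <- default_config()

k27 <- read_peaks("results/cohort/H3K27me3.bed", "H3K27me3")
k4 <- read_peaks("results/cohort/H3K4me3.bed", "H3K4me3")
k36 <- read_peaks("results/cohort/H3K36me3.bed", "H3K36me3")

windows <- tss_windows(genes, cfg$tss_window)
categories <- stats::setNames(calls$fig4_category, calls$gene)
windows <- windows[windows$gene %in% calls$gene, ]

## metagene profiles per category, one row per mark x category
profs <- list()
for (mark in list(k27, k4)) {
  for (cl in c("up", "down", "not_de")) {
    wcl <- windows[categories[windows$gene] == cl, ]
    profs[[length(profs) + 1L]] <- data.frame(
      mark = attr(mark, "peakset"), category = cl,
      bin = seq_len(50L), frac = metagene_profile(mark, wcl, bins = 50L))
  }
}
## gene-body windows for the transcription-coupled mark
body <- data.frame(chrom = genes$chromosome,
                   start = pmax(0L, genes$body_start - 2000L),
                   end = genes$body_end + 2000L, gene = genes$gene_id,
                   strand = genes$strand, stringsAsFactors = FALSE)
body <- body[body$gene %in% calls$gene, ]
for (cl in c("up", "down", "not_de")) {
  bcl <- body[categories[body$gene] == cl, ]
  profs[[length(profs) + 1L]] <- data.frame(
    mark = "H3K36me3", category = cl, bin = seq_len(100L),
    frac = metagene_profile(k36, bcl, bins = 100L))
}
write.table(do.call(rbind, profs), "results/metagene_profiles.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

biv <- bivalency_fractions(k27, k4, windows, categories)
write.table(biv$fractions, "results/bivalency_fractions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
up <- biv$fractions[biv$fractions$category == "up", ]
nd <- biv$fractions[biv$fractions$category == "not_de", ]
cat(sprintf("bivalency: %.1f%% of up-regulated vs %.1f%% of not-DE promoters (%.2f-fold)\n",
            100 * up$frac_bivalent, 100 * nd$frac_bivalent,
            biv$fold_enrichment))

## TF peak enrichment on leukemia-deregulated genes
tf_files <- list.files("results/cohort", pattern = "^TF_.*\\.bed$",
                       full.names = TRUE)
tfs <- lapply(tf_files, read_peaks)
names(tfs) <- sub("^TF_(.*)\\.bed$", "\\1", basename(tf_files))
targets <- calls$gene[calls$leukemia_status %in% c("up", "down")]
enr <- tf_enrichment(tfs, windows, targets, calls$gene, de, cfg)
write.table(enr, "results/tf_enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("TFs with significant enrichment and own deregulation (FDR<%.1f): %d of %d\n",
            cfg$fdr_enrich, sum(enr$significant), nrow(enr)))
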