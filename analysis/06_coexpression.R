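#!/usr/bin/env Rscript

# Stage 6 — co-expression modules over the top-variance genes.
#
# Unsigned soft-threshold adjacency (power 6) -> topological overlap ->
# Ward.D2 clustering of 1 - TOM -> eigengene merging at dissimilarity
# 0.25 -> module-subtype correlation, plus a hypergeometric enrichment of
# the planted leukemia gene sets within each module as a stand-in for GO
# term sets.

suppressMessages(library(callsig))

counts <- read_counts("results/cohort/counts.tsv")
samples <- suppressWarnings(read_sample_table("results/cohort/samples.tsv"))
genes <- read_gene_models("results/cohort/genes.tsv")
calls <- read.delim("results/dysregulation_calls.tsv",
                    stringsAsFactors = FALSE)
cfg <- default_config()

expr <- log_cpm(counts, prior_count = cfg$prior_count)
n_top <- min(cfg$n_top_wgcna, 2000L)  # network size used for this cohort
top <- top_variance_genes(expr, n_top, genes,
                          exclude_biotypes = "pseudogene")

adj <- soft_adjacency(expr, top, cfg$soft_power)
tom <- topological_overlap(adj)
mod <- detect_modules(1 - tom, expr, cfg)
assign <- data.frame(gene = names(mod$module), module = mod$module)
write.table(assign, "results/module_assignment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(id = rownames(mod$eigengenes), mod$eigengenes),
            "results/module_eigengenes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("modules: %d (sizes %s), %d genes unassigned\n",
            length(mod$sizes), paste(mod$sizes, collapse = ", "),
            sum(mod$module == 0)))

mt <- module_trait_correlation(mod$eigengenes, samples, cfg$fdr_enrich)
write.table(mt, "results/module_trait_correlation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
sig <- mt[mt$flagged, ]
if (nrow(sig)) {
  cat("subtype-associated modules (FDR < 0.1):\n")
  for (i in seq_len(nrow(sig)))
    cat(sprintf("  %s ~ %s: r = %.2f, FDR = %.2g\n", sig$module[i],
                sig$subtype[i], sig$r[i], sig$fdr[i]))
}

## enrichment of the dysregulation gene sets inside each module
sets <- list(
  leukemia_up = intersect(calls$gene[calls$leukemia_status == "up"], top),
  leukemia_down = intersect(calls$gene[calls$leukemia_status == "down"],
                            top),
  subtype_specific = intersect(calls$gene[!is.na(calls$specific_subtype)],
                               top))
sets <- sets[vapply(sets, length, 1L) > 0]
enr <- do.call(rbind, lapply(seq_along(mod$sizes), function(m) {
  e <- geneset_enrichment(names(mod$module)[mod$module == m], sets, top,
                          cfg$fdr_enrich)
  cbind(module = paste0("ME", m), e)
}))
write.table(enr, "results/module_set_enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote results/module_*.tsv\n")
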