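#!/usr/bin/env Rscript

# Stage 1 — generate the synthetic study cohort.
#
# Emulates the study design: 11 HeH, 22 t(12;21), 4 t(9;22) and 19 "Other"
# tumors plus 3 cord-blood controls; NB counts with planted leukemia-wide
# and subtype-specific signatures; trisomies of the frequently gained
# chromosomes in HeH; histone-mark and TF peak tracks with planted
# promoter bivalency on up-regulated genes. Everything downstream reads
# the files written here.

suppressMessages(library(callsig))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L

scfg <- sim_config(seed = seed)
sim <- simulate_counts(scfg, seed = child_seed(seed, "cohort"))
peaks <- simulate_peaks(sim$genes, sim$truth, scfg,
                        seed = child_seed(seed, "peaks"))

out <- "results/cohort"
write_cohort(sim, out, peaks)
dir.create("scratch", showWarnings = FALSE)
saveRDS(sim$truth, "scratch/truth.rds")  # ground-truth bookkeeping
write_manifest(file.path(out, "manifest.json"), default_config(), seed,
               extra = list(stage = "simulate",
                            n_genes = scfg$n_genes,
                            n_samples = sum(scfg$n_samples)))

cat(sprintf("cohort: %d genes x %d samples (%s)\n",
            nrow(sim$counts), ncol(sim$counts),
            paste(sprintf("%s=%d", names(scfg$n_samples), scfg$n_samples),
                  collapse = ", ")))
cat(sprintf("planted: %d leukemia-wide, %d subtype-specific genes\n",
            sum(sim$truth$category %in% c("leukemia_up", "leukemia_down")),
            sum(sim$truth$category == "specific")))
cat(sprintf("peaks: %s\n", paste(sprintf("%s=%d", names(peaks$marks),
                                         vapply(peaks$marks, nrow, 1L)),
                                 collapse = ", ")))
cat("wrote", out, "\n")
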