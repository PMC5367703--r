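# callsig — transcriptome signatures of pre-B childhood ALL subtypes

Pre-B childhood acute lymphoblastic leukemia (cALL) is stratified into
molecular subtypes — high hyperdiploidy (HeH, >50 chromosomes),
t(12;21)/*ETV6-RUNX1*, t(9;22)/*BCR-ABL1*, and a heterogeneous remainder —
that differ in prognosis and treatment. Karyotype- and fusion-based
assays miss subtypes without known rearrangements, which motivates
expression-based biomarkers, including the largely unexplored lncRNA
transcriptome. `callsig` is an R implementation of the full analysis
chain for this question, written for computational biologists who want
each step as a tested, reusable function rather than a one-off script:

* **Differential expression** — per-gene negative-binomial GLMs
  (log link, group + batch coefficients, log effective-library-size
  offsets from upper-quartile normalization), likelihood-ratio tests per
  subtype-vs-control contrast, BH FDR. Genes are categorized as
  leukemia-wide (same-sign significance in all four subtypes, FDR ≤
  1e-3) or subtype-specific (significant in exactly one), with a 4-fold
  specificity score on logCPM.
* **Classification** — classical MDS and leave-one-out 3-nearest-neighbor
  subtype prediction over top-variance genes, repeated on 100 random
  half-gene subsamples, with biotype restrictions (lncRNA vs
  protein-coding) and class-balanced under-sampling (4 per subtype).
* **Gene dosage** — per-autosome median HeH/control fold change (genes
  > 30 CPM in both groups) regressed on mean chromosomal copy number,
  and a re-analysis excluding the chromosomes frequently gained in HeH
  (4, 6, 10, 14, 17, 18, 21).
* **Promoter chromatin** — interval arithmetic in BED semantics, ±5 kb
  TSS windows, metagene coverage profiles, bivalent-promoter
  (H3K27me3 + H3K4me3) fractions by dysregulation category, and
  hypergeometric TF-peak enrichment crossed with each TF's own
  expression change.
* **Co-expression** — soft-threshold adjacency |cor|^6, topological
  overlap, Ward.D2 modules merged at eigengene dissimilarity 0.25,
  module eigengenes, module–subtype correlation, and hypergeometric
  gene-set enrichment.
* **Synthetic cohort** — a ground-truth generator
  (`simulate_counts()` / `simulate_peaks()`) emulating the study design
  (11 HeH / 22 t(12;21) / 4 t(9;22) / 19 Other / 3 controls, planted
  fold changes, trisomies, batch effects, planted bivalency and TF
  targeting), so the whole pipeline is testable without restricted
  patient data. The packaged cohort characteristics table is available
  via `table1_fixture()`.

The repository is organized as an analysis workflow: every computation
lives in the package (`R/`), and the numbered drivers under `analysis/`
run the stages in order, writing tables to `results/`.

## Worked example

```sh
Rscript analysis/01_simulate.R 1
Rscript analysis/02_differential_expression.R
Rscript analysis/03_classification.R 1
Rscript analysis/04_dosage.R 1
Rscript analysis/05_epigenome.R
Rscript analysis/06_coexpression.R
```

Output of the run above (seed 1):

```
cohort: 5000 genes x 59 samples (HeH=11, t(12;21)=22, t(9;22)=4, Other=19, Control=3)
planted: 375 leukemia-wide, 125 subtype-specific genes
...
tested 4999 genes (filtered 1 low-count)
DET (FDR<=0.001 in >=1 subtype): 470
leukemia-wide: 140 up, 156 down; subtype-specific: 120
...
overall accuracy at 50 genes: 100.0% (all) / 100.0% (lncRNA) / 100.0% (protein-coding)
...
dosage regression: slope 0.437, intercept 0.009, r 0.992, R^2 0.984 over 22 autosomes
exclusion of chr 4,6,10,14,17,18,21: distance r = 0.955, HeH accuracy 100.0% -> 100.0% (180/500 top genes lost)
...
bivalency: 14.3% of up-regulated vs 3.4% of not-DE promoters (4.22-fold)
TFs with significant enrichment and own deregulation (FDR<0.1): 7 of 15
...
modules: 3 (sizes 1598, 149, 126), 127 genes unassigned
subtype-associated modules (FDR < 0.1):
  ME1 ~ HeH: r = 0.96, FDR = 1.2e-32
```

Reading the numbers: the planted leukemia-wide and subtype-specific
signatures are recovered by the GLM at FDR ≤ 1e-3 (470 DETs against 500
planted); 50 top-variance genes suffice for essentially perfect subtype
classification under the default strong-signature regime; the dosage
regression tracks the copy-number line FC = copy/2 (the slope sits
slightly below 0.5 because renormalization absorbs part of the
trisomy-driven library inflation — see the methods vignette); excluding
the gained chromosomes leaves inter-sample geometry nearly unchanged
(distance r = 0.955), showing the HeH signature is not purely dosage;
and promoter bivalency concentrates in up-regulated genes as planted.
The deregulated-TF enrichments and the HeH-correlated co-expression
module mirror the planted TF targeting and the dosage-driven HeH
co-expression.

Thresholds (FDR 1e-3, 4-fold specificity, ±5 kb TSS windows, 30 CPM
dosage floor, gained-chromosome list, …) live in one place:
`default_config()`.

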