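#' Per-chromosome median fold change, HeH vs controls
#'
#' Per gene the fold change is mean CPM in the HeH group over mean CPM in
#' the control group (upper-quartile effective library sizes); genes are
#' kept only when mean CPM exceeds `cfg$cpm_min_dosage` in both groups, a
#' floor that avoids division by near-zero expression. The per-chromosome
#' median over kept genes is reported for autosomes only; chromosomes with
#' no kept gene get `NA` with a warning.
#'
#' @param counts count matrix.
#' @param samples sample table.
#' @param genes gene-model data.frame.
#' @param cfg [default_config()] list.
#' @return data.frame chromosome, median_fc, n_genes.
#' @export
chromosome_median_fc <- function(counts, samples, genes,
                                 cfg = default_config()) {
  heh <- samples$id[samples$group == "HeH"]
  ctl <- samples$id[samples$group == "Control"]
  if (!length(heh) || !length(ctl))
    stop("need >= 1 HeH and >= 1 Control sample")
  x <- cpm(counts, upper_quartile_factors(counts))
  m_heh <- rowMeans(x[, heh, drop = FALSE])
  m_ctl <- rowMeans(x[, ctl, drop = FALSE])
  keep <- m_heh > cfg$cpm_min_dosage & m_ctl > cfg$cpm_min_dosage
  chrom <- genes$chromosome[match(rownames(counts), genes$gene_id)]
  autosomes <- as.character(1:22)
  out <- data.frame(chromosome = autosomes, median_fc = NA_real_,
                    n_genes = 0L, stringsAsFactors = FALSE)
  for (i in seq_along(autosomes)) {
    g <- which(keep & chrom == autosomes[i])
    out$n_genes[i] <- length(g)
    if (length(g)) {
      out$median_fc[i] <- stats::median(m_heh[g] / m_ctl[g])
    } else {
      warning("no gene passed the CPM filter on chromosome ", autosomes[i])
    }
  }
  out
}

#' Mean copy number of a chromosome in the HeH group
#'
#' Gained chromosomes count 3 copies, all others 2; the mean is taken over
#' HeH samples.
#'
#' @param samples sample table with list-column karyotype_gains.
#' @param chromosome chromosome name.
#' @return mean copy number (numeric in [2, 3]).
#' @export
mean_copy_number <- function(samples, chromosome) {
  heh <- samples[samples$group == "HeH", ]
  if (!nrow(heh)) stop("no HeH samples")
  gained <- vapply(heh$karyotype_gains, function(g) chromosome %in% g,
                   logical(1L))
  mean(ifelse(gained, 3, 2))
}

#' Regress chromosome median fold change on mean copy number
#'
#' Ordinary least squares of the per-chromosome median HeH/control fold
#' change on the chromosome's mean copy number in the HeH group. Under a
#' pure dosage model the line is FC = copy/2: slope 0.5, intercept 0.
#'
#' @param median_fc data.frame from [chromosome_median_fc()].
#' @param samples sample table.
#' @return list of class `dosage_report`: per-chromosome table plus slope,
#'   intercept, pearson_r, r_squared.
#' @export
dosage_regression <- function(median_fc, samples) {
  tab <- median_fc
  tab$mean_copy_number <- vapply(tab$chromosome, function(ch)
    mean_copy_number(samples, ch), numeric(1L))
  ok <- !is.na(tab$median_fc)
  if (sum(ok) < 3L) stop("need >= 3 chromosomes with defined median FC")
  x <- tab$mean_copy_number[ok]; y <- tab$median_fc[ok]
  if (stats::sd(x) == 0) stop("zero variance in mean copy number")
  fit <- stats::lm(y ~ x)
  r <- stats::cor(x, y)
  structure(list(table = tab,
                 slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 pearson_r = r, r_squared = r^2,
                 n_chromosomes = sum(ok)),
            class = "dosage_report")
}

#' Full gene-dosage report for the HeH subtype
#'
#' @inheritParams chromosome_median_fc
#' @return `dosage_report` (see [dosage_regression()]).
#' @export
dosage_report <- function(counts, samples, genes, cfg = default_config()) {
  dosage_regression(chromosome_median_fc(counts, samples, genes, cfg),
                    samples)
}

#' Re-run MDS/KNN with frequently-gained chromosomes excluded
#'
#' Removes the rows of genes on `cfg$heh_gained` chromosomes (the
#' count-level analogue of discarding reads mapped to those chromosomes),
#' recomputes normalization and logCPM on the reduced matrix, and compares
#' the top-variance gene set, inter-sample distances and HeH
#' classification accuracy (at `n_genes_acc` genes) with the all-autosome
#' analysis. Tumor samples only are classified and used for the distance
#' comparison.
#'
#' @param counts count matrix.
#' @param samples sample table.
#' @param genes gene-model data.frame.
#' @param cfg [default_config()] list.
#' @param n_genes_acc gene count at which HeH accuracy is read (default 50).
#' @param seed random seed for the accuracy curves.
#' @return list: distance_correlation, n_top_lost (top-variance genes of
#'   the full analysis lost to exclusion), heh_accuracy_all,
#'   heh_accuracy_excluded, mds_all, mds_excluded.
#' @export
exclusion_reanalysis <- function(counts, samples, genes,
                                 cfg = default_config(),
                                 n_genes_acc = 50L, seed = cfg$seed) {
  tumor <- samples$group != "Control"
  excl <- cfg$heh_gained
  on_gained <- genes$chromosome[match(rownames(counts), genes$gene_id)] %in%
    excl
  counts_red <- counts[!on_gained, , drop = FALSE]

  expr_all <- log_cpm(counts, prior_count = cfg$prior_count)
  expr_red <- log_cpm(counts_red, prior_count = cfg$prior_count)

  top_all <- top_variance_genes(expr_all, cfg$n_top_mds, genes,
                                exclude_biotypes = "pseudogene")
  n_eligible_red <- sum(!on_gained)
  if (n_eligible_red < cfg$n_top_mds)
    stop("chromosome exclusion leaves fewer than n_top_mds genes")
  top_red <- top_variance_genes(expr_red, cfg$n_top_mds, genes,
                                exclude_biotypes = "pseudogene")

  te_all <- expr_all[, tumor, drop = FALSE]
  te_red <- expr_red[, tumor, drop = FALSE]
  d_all <- distance_matrix(te_all, top_all)
  d_red <- distance_matrix(te_red, top_red)
  labels <- droplevels(factor(samples$group[tumor]))

  acc_all <- accuracy_curve(te_all, labels, cfg, genes,
                            gene_counts = n_genes_acc, seed = seed)
  acc_red <- accuracy_curve(te_red, labels, cfg, genes,
                            gene_counts = n_genes_acc,
                            exclude_chromosomes = excl, seed = seed)
  heh_all <- acc_all$mean_acc[acc_all$class == "HeH"]
  heh_red <- acc_red$mean_acc[acc_red$class == "HeH"]

  list(distance_correlation = distance_correlation(d_all, d_red),
       n_top_lost = sum(top_all %in%
                          rownames(counts)[on_gained]),
       heh_accuracy_all = heh_all,
       heh_accuracy_excluded = heh_red,
       mds_all = classical_mds(d_all),
       mds_excluded = classical_mds(d_red))
}
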