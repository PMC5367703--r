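#' Upper-quartile normalization factors
#'
#' Per-sample scaling factors from the upper-quartile method: the 75th
#' percentile (linear interpolation) of each sample's counts over genes
#' with nonzero total count across samples, divided by the sample's
#' library size, then rescaled so the factors have geometric mean 1. The
#' effective library size of a sample is its library size times its factor.
#'
#' @param counts integer count matrix (genes x samples).
#' @return numeric vector of factors, one per sample, with attribute
#'   `effective_lib_size`.
#' @export
upper_quartile_factors <- function(counts) {
  lib <- colSums(counts)
  zero <- lib == 0
  if (any(zero))
    stop("all-zero sample(s): ", paste(colnames(counts)[zero], collapse = ", "))
  nz <- rowSums(counts) > 0
  q75 <- apply(counts[nz, , drop = FALSE], 2L, stats::quantile, probs = 0.75,
               names = FALSE)
  if (any(q75 == 0))
    stop("upper quartile is zero for sample(s): ",
         paste(colnames(counts)[q75 == 0], collapse = ", "))
  raw <- q75 / lib
  f <- raw / exp(mean(log(raw)))
  attr(f, "effective_lib_size") <- lib * f
  f
}

#' Log2 counts per million with a prior count
#'
#' logCPM = log2( (count + prior) / (effective library size + 2 * prior)
#' * 1e6 ), with effective library sizes from upper-quartile normalization.
#'
#' @param counts count matrix (genes x samples).
#' @param factors normalization factors from [upper_quartile_factors()];
#'   computed from `counts` when `NULL`.
#' @param prior_count prior count added to every observation (default 1).
#' @return numeric matrix of logCPM values with attributes `normalization`
#'   and `prior_count`.
#' @export
log_cpm <- function(counts, factors = NULL, prior_count = 1) {
  if (prior_count < 0) stop("prior_count must be non-negative")
  if (is.null(factors)) factors <- upper_quartile_factors(counts)
  eff <- attr(factors, "effective_lib_size")
  if (is.null(eff)) eff <- colSums(counts) * factors
  denom <- eff + 2 * prior_count
  x <- log2(sweep(counts + prior_count, 2L, denom, "/") * 1e6)
  attr(x, "normalization") <- "upper_quartile"
  attr(x, "prior_count") <- prior_count
  x
}

#' Counts per million (linear scale)
#'
#' @param counts count matrix.
#' @param factors optional upper-quartile factors; `NULL` uses raw library
#'   sizes.
#' @return CPM matrix.
#' @export
cpm <- function(counts, factors = NULL) {
  lib <- colSums(counts)
  eff <- if (is.null(factors)) lib else {
    e <- attr(factors, "effective_lib_size")
    if (is.null(e)) lib * factors else e
  }
  sweep(counts, 2L, eff, "/") * 1e6
}

row_vars <- function(x) {
  m <- rowMeans(x)
  rowSums((x - m)^2) / (ncol(x) - 1L)
}

#' Top-variance genes
#'
#' Genes ordered by decreasing logCPM variance across samples after
#' excluding the requested biotypes and chromosomes; ties broken by gene
#' id (lexicographic).
#'
#' @param expr logCPM matrix (genes x samples).
#' @param n number of genes to return.
#' @param genes optional gene-model data.frame (needed for exclusions).
#' @param exclude_biotypes biotypes to drop (e.g. "pseudogene").
#' @param exclude_chromosomes chromosomes to drop.
#' @return character vector of `n` gene ids, most variable first.
#' @export
top_variance_genes <- function(expr, n, genes = NULL,
                               exclude_biotypes = character(),
                               exclude_chromosomes = character()) {
  ids <- rownames(expr)
  if ((length(exclude_biotypes) || length(exclude_chromosomes)) &&
      is.null(genes))
    stop("gene models required for biotype/chromosome exclusions")
  if (!is.null(genes)) {
    gm <- genes[match(ids, genes$gene_id), ]
    keep <- !(gm$biotype %in% exclude_biotypes) &
      !(gm$chromosome %in% exclude_chromosomes)
    keep[is.na(keep)] <- TRUE
    ids <- ids[keep]
  }
  if (n > length(ids))
    stop(sprintf("requested %d genes but only %d are eligible", n, length(ids)))
  v <- row_vars(expr[ids, , drop = FALSE])
  ids[order(-v, ids)][seq_len(n)]
}
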