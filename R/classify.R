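#' Euclidean distance matrix over a gene set
#'
#' @param expr logCPM matrix (genes x samples).
#' @param genes character vector of gene ids to use.
#' @return symmetric distance matrix (samples x samples), zero diagonal.
#' @export
distance_matrix <- function(expr, genes) {
  if (!length(genes)) stop("empty gene list")
  missing <- setdiff(genes, rownames(expr))
  if (length(missing)) stop("gene(s) absent from expression matrix: ",
                            paste(utils::head(missing, 5L), collapse = ", "))
  as.matrix(stats::dist(t(expr[genes, , drop = FALSE])))
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared distance matrix and takes the top
#' eigenvectors. Axis signs are fixed so that the largest-magnitude
#' coordinate on each axis is positive, making the configuration
#' deterministic.
#'
#' @param d distance matrix.
#' @param dims number of output dimensions (default 2).
#' @return list of class `callsig_mds`: `points` (samples x dims, centered)
#'   and `eig` (all eigenvalues of the scaling solution).
#' @export
classical_mds <- function(d, dims = 2L) {
  d <- as.matrix(d)
  sol <- stats::cmdscale(d, k = min(dims, nrow(d) - 1L), eig = TRUE)
  n_pos <- sum(sol$eig > max(sol$eig) * 1e-9)
  if (dims > n_pos)
    stop(sprintf("requested %d dimensions but the solution has rank %d",
                 dims, n_pos))
  pts <- sol$points[, seq_len(dims), drop = FALSE]
  for (j in seq_len(ncol(pts))) {
    i <- which.max(abs(pts[, j]))
    if (pts[i, j] < 0) pts[, j] <- -pts[, j]
  }
  structure(list(points = pts, eig = sol$eig), class = "callsig_mds")
}

#' Leave-one-out k-nearest-neighbor classification
#'
#' Each sample is predicted by majority vote of its k nearest other
#' samples (Euclidean distance over the given genes' logCPM). Vote ties
#' are broken by the class of the single nearest neighbor among the tied
#' classes; residual distance ties by sample-id order.
#'
#' @param expr logCPM matrix (genes x samples).
#' @param labels factor of true classes, one per sample.
#' @param genes gene ids defining the feature space.
#' @param k number of neighbors.
#' @return list: `predicted` (factor), `per_class_accuracy`, `overall`.
#' @export
knn_loo <- function(expr, labels, genes, k = 3L) {
  if (!is.factor(labels)) labels <- factor(labels)
  n <- ncol(expr)
  if (k >= n) stop("k must be smaller than the number of samples")
  if (nlevels(droplevels(labels)) < 2L) stop("need >= 2 classes")
  empty <- levels(labels)[tabulate(labels, nlevels(labels)) == 0L]
  if (length(empty)) stop("class(es) with 0 samples: ",
                          paste(empty, collapse = ", "))
  D <- distance_matrix(expr, genes)
  ids <- colnames(expr)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  pred <- character(n)
  for (i in seq_len(n)) {
    j <- setdiff(seq_len(n), i)
    ord <- j[order(D[i, j], ids[j])]
    nn <- ord[seq_len(k)]
    votes <- table(factor(labels[nn], levels = levels(labels)))
    top <- names(votes)[votes == max(votes)]
    pred[i] <- if (length(top) == 1L) top else {
      as.character(labels[nn[which(as.character(labels[nn]) %in% top)[1L]]])
    }
  }
  pred <- factor(pred, levels = levels(labels))
  correct <- pred == labels
  per_class <- vapply(levels(labels), function(cl) {
    mean(correct[labels == cl])
  }, numeric(1L))
  list(predicted = pred, per_class_accuracy = per_class,
       overall = mean(correct))
}

# permutation baseline: P(correct) for a class equals its frequency
permutation_baseline <- function(labels) {
  labels <- droplevels(factor(labels))
  freq <- as.numeric(table(labels)) / length(labels)
  stats::setNames(c(freq, sum(freq^2)), c(levels(labels), "overall"))
}

eligible_genes <- function(expr, genes, restriction, exclude_chromosomes) {
  ids <- rownames(expr)
  if (!is.null(genes)) {
    gm <- genes[match(ids, genes$gene_id), ]
    keep <- !(gm$biotype %in% "pseudogene")
    if (restriction %in% c("lncRNA", "protein_coding"))
      keep <- keep & gm$biotype %in% restriction
    if (length(exclude_chromosomes))
      keep <- keep & !(gm$chromosome %in% exclude_chromosomes)
    keep[is.na(keep)] <- FALSE
    ids <- ids[keep]
  } else if (restriction != "all" || length(exclude_chromosomes)) {
    stop("gene models required for restriction '", restriction, "'")
  }
  ids
}

curve_engine <- function(expr, labels, cfg, gene_counts, pool, balanced,
                         seed) {
  set.seed(seed)
  labels <- droplevels(factor(labels))
  classes <- levels(labels)
  n_sub <- floor(cfg$gene_subsample_frac * length(pool))
  if (max(gene_counts) > n_sub)
    stop(sprintf("gene_counts up to %d exceed the per-replicate pool of %d",
                 max(gene_counts), n_sub))
  if (balanced) {
    small <- classes[tabulate(labels) < cfg$balanced_n]
    if (length(small))
      stop("class(es) smaller than balanced_n: ",
           paste(small, collapse = ", "))
  }
  acc <- array(NA_real_,
               c(cfg$replicates, length(gene_counts), length(classes) + 1L),
               dimnames = list(NULL, gene_counts, c(classes, "overall")))
  for (r in seq_len(cfg$replicates)) {
    cols <- if (balanced) {
      unlist(lapply(classes, function(cl)
        sample(which(labels == cl), cfg$balanced_n)))
    } else seq_along(labels)
    sub_expr <- expr[, cols, drop = FALSE]
    sub_lab <- labels[cols]
    gsub <- sample(pool, n_sub)
    v <- row_vars(sub_expr[gsub, , drop = FALSE])
    ranked <- gsub[order(-v, gsub)]
    for (ni in seq_along(gene_counts)) {
      res <- knn_loo(sub_expr, sub_lab, ranked[seq_len(gene_counts[ni])],
                     cfg$knn_k)
      acc[r, ni, classes] <- res$per_class_accuracy[classes]
      acc[r, ni, "overall"] <- res$overall
    }
  }
  base <- permutation_baseline(if (balanced) {
    factor(rep(classes, each = cfg$balanced_n), levels = classes)
  } else labels)
  report <- do.call(rbind, lapply(c(classes, "overall"), function(cl) {
    m <- matrix(acc[, , cl], nrow = cfg$replicates)
    data.frame(class = cl, n_genes = gene_counts,
               mean_acc = colMeans(m),
               sd_acc = apply(m, 2L, stats::sd),
               baseline = base[[cl]],
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  attr(report, "replicates") <- cfg$replicates
  report
}

#' Classification accuracy vs number of top-variance genes
#'
#' The repeated-subsampling protocol: in each of `cfg$replicates`
#' iterations, half of the eligible genes are drawn without replacement
#' and ranked by logCPM variance across samples; leave-one-out 3-NN
#' classification is then evaluated on growing prefixes of that ranking.
#' Pseudogenes are always excluded; a biotype restriction or chromosome
#' exclusion further narrows the pool. The baseline column is the
#' label-permutation expectation (class frequency per class).
#'
#' @param expr logCPM matrix restricted to the samples being classified.
#' @param labels factor of true subtypes, one per sample.
#' @param cfg [default_config()] list (replicates, knn_k,
#'   gene_subsample_frac).
#' @param genes gene-model data.frame (required to exclude pseudogenes and
#'   apply restrictions; optional when `restriction = "all"` and the
#'   matrix holds no pseudogenes).
#' @param gene_counts increasing gene-count grid (default 2, 5, 10, 20,
#'   50, 100, 200, 500).
#' @param restriction "all", "lncRNA" or "protein_coding".
#' @param exclude_chromosomes chromosomes removed from the pool.
#' @param seed random seed.
#' @return data.frame class x n_genes with mean_acc, sd_acc, baseline
#'   (attribute `replicates`).
#' @export
accuracy_curve <- function(expr, labels, cfg = default_config(),
                           genes = NULL,
                           gene_counts = c(2L, 5L, 10L, 20L, 50L, 100L,
                                           200L, 500L),
                           restriction = "all",
                           exclude_chromosomes = character(),
                           seed = cfg$seed) {
  if (cfg$replicates < 1L) stop("replicates must be >= 1")
  pool <- eligible_genes(expr, genes, restriction, exclude_chromosomes)
  rep <- curve_engine(expr, labels, cfg, gene_counts, pool,
                      balanced = FALSE, seed = seed)
  rep$restriction <- if (length(exclude_chromosomes)) {
    paste0(restriction, ";excl:",
           paste(exclude_chromosomes, collapse = ","))
  } else restriction
  rep
}

#' Class-balanced accuracy curve (under-sampling)
#'
#' As [accuracy_curve()], but each replicate first draws `cfg$balanced_n`
#' samples per class at random, removing class imbalance before
#' classification.
#'
#' @inheritParams accuracy_curve
#' @return data.frame as in [accuracy_curve()].
#' @export
balanced_accuracy_curve <- function(expr, labels, cfg = default_config(),
                                    genes = NULL,
                                    gene_counts = c(2L, 5L, 10L, 20L, 50L),
                                    restriction = "all",
                                    exclude_chromosomes = character(),
                                    seed = cfg$seed) {
  if (cfg$replicates < 1L) stop("replicates must be >= 1")
  pool <- eligible_genes(expr, genes, restriction, exclude_chromosomes)
  rep <- curve_engine(expr, labels, cfg, gene_counts, pool,
                      balanced = TRUE, seed = seed)
  rep$restriction <- paste0("balanced:", restriction)
  rep
}

#' Pearson correlation between two distance matrices
#'
#' Correlates the strictly-lower-triangle entries.
#'
#' @param dA,dB distance matrices of identical shape and sample order.
#' @return Pearson r.
#' @export
distance_correlation <- function(dA, dB) {
  dA <- as.matrix(dA); dB <- as.matrix(dB)
  if (!all(dim(dA) == dim(dB))) stop("distance matrices differ in shape")
  lt <- lower.tri(dA)
  stats::cor(dA[lt], dB[lt])
}
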