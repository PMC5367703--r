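#' Soft-threshold co-expression adjacency
#'
#' Unsigned adjacency a_ij = |cor(x_i, x_j)|^power over the given genes'
#' logCPM profiles, with zero diagonal.
#'
#' @param expr logCPM matrix.
#' @param genes gene ids (e.g. a top-variance list).
#' @param power soft-threshold exponent (>= 1, default 6).
#' @return symmetric adjacency matrix.
#' @export
soft_adjacency <- function(expr, genes, power = 6) {
  if (power < 1) stop("power must be >= 1")
  x <- expr[genes, , drop = FALSE]
  if (ncol(x) < 3L) stop("need >= 3 samples")
  v <- row_vars(x)
  if (any(v == 0))
    stop("zero-variance gene(s): ",
         paste(utils::head(genes[v == 0], 5L), collapse = ", "))
  a <- abs(stats::cor(t(x)))^power
  diag(a) <- 0
  a
}

#' Topological overlap matrix
#'
#' TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij) with
#' k the adjacency row sums; TOM_ii = 1. The dissimilarity used for
#' clustering is 1 - TOM.
#'
#' @param adjacency symmetric adjacency with zero diagonal.
#' @return TOM matrix (same dimnames).
#' @export
topological_overlap <- function(adjacency) {
  a <- as.matrix(adjacency)
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' First-principal-component module eigengene
#'
#' The eigengene is the first principal component of the standardized
#' module submatrix, scaled to unit variance, with its sign fixed so that
#' the mean gene-eigengene correlation is non-negative. A single-gene
#' module returns that gene's standardized profile.
#'
#' @param expr logCPM matrix.
#' @param module_genes gene ids of the module.
#' @return numeric vector, one score per sample (unit variance).
#' @export
module_eigengene <- function(expr, module_genes) {
  if (!length(module_genes)) stop("empty module")
  x <- expr[module_genes, , drop = FALSE]
  z <- t(scale(t(x)))
  if (nrow(z) == 1L) {
    e <- as.numeric(z)
  } else {
    sv <- svd(t(z), nu = 1L, nv = 0L)
    e <- sv$u[, 1L]
  }
  e <- as.numeric(scale(e))
  if (mean(stats::cor(t(x), e)) < 0) e <- -e
  stats::setNames(e, colnames(expr))
}

#' Detect co-expression modules from a TOM dissimilarity
#'
#' Agglomerative clustering (Ward.D2 by default) on the dissimilarity,
#' cut statically at the number of clusters that maximizes how many
#' clusters reach `min_size` genes; clusters below `min_size` are left
#' unassigned (module 0). Modules whose eigengenes are closer than
#' `cfg$merge_dissimilarity` (1 - correlation) are then merged
#' iteratively, closest pair first. Module ids are renumbered 1..M by
#' decreasing size.
#'
#' @param dissimilarity square matrix, typically 1 - TOM.
#' @param expr logCPM matrix (for eigengene-based merging).
#' @param cfg [default_config()] list (merge_dissimilarity,
#'   min_module_size).
#' @param method hclust linkage ("ward.D2" default, "average" available).
#' @param cut_height optional stringent static cut: the tree is cut at
#'   this fraction of the maximum merge height instead of the auto cut,
#'   so loose (noise-like) branches fall apart into unassigned singletons.
#' @return list of class `module_assignment`: `module` (named integer per
#'   gene, 0 = unassigned), `sizes`, `eigengenes` (samples x modules),
#'   `tree` (the hclust object).
#' @export
detect_modules <- function(dissimilarity, expr, cfg = default_config(),
                           method = "ward.D2", cut_height = NULL) {
  d <- as.matrix(dissimilarity)
  ids <- rownames(d)
  if (is.null(ids)) ids <- paste0("g", seq_len(nrow(d)))
  min_size <- cfg$min_module_size
  if (nrow(d) < min_size)
    stop("fewer genes than the minimum module size")
  tree <- stats::hclust(stats::as.dist(d), method = method)
  if (!is.null(cut_height)) {
    ct <- stats::cutree(tree, h = cut_height * max(tree$height))
  } else {
    kmax <- min(nrow(d) - 1L, 50L)
    best_k <- 2L; best_n <- -1L
    for (k in 2:kmax) {
      ctk <- stats::cutree(tree, k = k)
      n_ok <- sum(table(ctk) >= min_size)
      if (n_ok > best_n) { best_n <- n_ok; best_k <- k }
    }
    ct <- stats::cutree(tree, k = best_k)
  }
  sizes <- table(ct)
  keep <- as.integer(names(sizes)[sizes >= min_size])
  module <- integer(length(ct))
  for (j in seq_along(keep)) module[ct == keep[j]] <- j
  names(module) <- ids

  ## merge modules with close eigengenes
  repeat {
    mods <- sort(unique(module[module > 0L]))
    if (length(mods) < 2L) break
    eg <- vapply(mods, function(m)
      module_eigengene(expr, ids[module == m]), numeric(ncol(expr)))
    diss <- 1 - stats::cor(eg)
    diag(diss) <- Inf
    mn <- which(diss == min(diss), arr.ind = TRUE)[1L, ]
    if (diss[mn[1L], mn[2L]] >= cfg$merge_dissimilarity) break
    module[module == mods[mn[2L]]] <- mods[mn[1L]]
  }
  ## renumber by decreasing size
  mods <- sort(unique(module[module > 0L]))
  if (length(mods)) {
    sz <- vapply(mods, function(m) sum(module == m), integer(1L))
    newid <- integer(max(mods))
    newid[mods[order(-sz)]] <- seq_along(mods)
    module[module > 0L] <- newid[module[module > 0L]]
    mods <- sort(unique(module[module > 0L]))
    eigengenes <- vapply(mods, function(m)
      module_eigengene(expr, ids[module == m]), numeric(ncol(expr)))
    if (is.null(dim(eigengenes)))
      eigengenes <- matrix(eigengenes, ncol = 1L)
    colnames(eigengenes) <- paste0("ME", mods)
    rownames(eigengenes) <- colnames(expr)
  } else {
    eigengenes <- matrix(numeric(0), ncol(expr), 0,
                         dimnames = list(colnames(expr), NULL))
  }
  structure(list(module = module,
                 sizes = vapply(mods, function(m) sum(module == m),
                                integer(1L)),
                 eigengenes = eigengenes, tree = tree),
            class = "module_assignment")
}

#' Module-subtype correlation
#'
#' Pearson correlation of each module eigengene with the 0/1 membership
#' indicator of each tumor subtype, with t-distribution p-values and BH
#' FDR over all module x subtype cells; cells with FDR below `fdr_flag`
#' are flagged.
#'
#' @param eigengenes samples x modules matrix.
#' @param samples sample table (rows aligned with the eigengene rows).
#' @param fdr_flag flagging threshold (default 0.1).
#' @return data.frame module, subtype, r, pvalue, fdr, flagged.
#' @export
module_trait_correlation <- function(eigengenes, samples, fdr_flag = 0.1) {
  stopifnot(nrow(eigengenes) == nrow(samples))
  subtypes <- intersect(TUMOR_GROUPS, unique(as.character(samples$group)))
  n <- nrow(eigengenes)
  rows <- list()
  for (m in colnames(eigengenes)) {
    e <- eigengenes[, m]
    for (s in subtypes) {
      ind <- as.numeric(samples$group == s)
      if (length(unique(ind)) < 2L || stats::sd(e) == 0) {
        r <- NA_real_; p <- NA_real_
      } else {
        r <- stats::cor(e, ind)
        tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 1e-12))
        p <- 2 * stats::pt(-abs(tstat), df = n - 2)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        module = m, subtype = s, r = r, pvalue = p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$pvalue)
  out$flagged <- !is.na(out$fdr) & out$fdr < fdr_flag
  out
}

#' Hypergeometric gene-set enrichment for a module
#'
#' Plain upper-tail hypergeometric test of each term set against the
#' module, BH-corrected across terms. Term sets must lie inside the
#' universe.
#'
#' @param module_genes gene ids of the module.
#' @param term_sets named list of gene-id vectors.
#' @param universe background gene ids.
#' @param fdr_flag reporting threshold (default 0.1).
#' @return data.frame term, n_term, overlap, pvalue, fdr, flagged.
#' @export
geneset_enrichment <- function(module_genes, term_sets, universe,
                               fdr_flag = 0.1) {
  if (!length(universe)) stop("empty universe")
  bad <- names(term_sets)[!vapply(term_sets, function(s)
    all(s %in% universe), logical(1L))]
  if (length(bad))
    stop("term set(s) outside the universe: ", paste(bad, collapse = ", "))
  module_genes <- intersect(module_genes, universe)
  N <- length(universe); k <- length(module_genes)
  out <- do.call(rbind, lapply(names(term_sets), function(tm) {
    K <- length(term_sets[[tm]])
    q <- length(intersect(module_genes, term_sets[[tm]]))
    data.frame(term = tm, n_term = K, overlap = q,
               pvalue = hypergeom_upper(q, K, N, k),
               stringsAsFactors = FALSE)
  }))
  out$fdr <- bh_fdr(out$pvalue)
  out$flagged <- !is.na(out$fdr) & out$fdr < fdr_flag
  out[order(out$pvalue), ]
}
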