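#' Benjamini-Hochberg false discovery rates
#'
#' Step-up FDR adjustment with monotonicity enforcement. `NA` p-values are
#' carried through as `NA` and excluded from the denominator.
#'
#' @param pvalues numeric vector in [0, 1] (NAs allowed).
#' @return vector of adjusted values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(pvalues))
  out[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  out
}

# negative-binomial log-likelihood at fixed dispersion phi (size = 1/phi)
nb_loglik <- function(y, mu, phi) {
  if (phi <= 1e-12) return(sum(stats::dpois(y, mu, log = TRUE)))
  sum(stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
}

# Cox-Reid adjusted profile likelihood for phi, holding fitted means fixed
nb_apl <- function(y, mu, phi, X) {
  w <- mu / (1 + phi * mu)
  xtwx <- crossprod(X * sqrt(w))
  ld <- determinant(xtwx, logarithm = TRUE)$modulus
  nb_loglik(y, mu, phi) - 0.5 * as.numeric(ld)
}

fit_gene_nb <- function(y, X, offset, phi) {
  fam <- if (phi <= 1e-12) {
    stats::poisson(link = "log")
  } else {
    MASS::negative.binomial(theta = 1 / phi, link = "log")
  }
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = fam, offset = offset,
                   control = stats::glm.control(maxit = 50))
  )
  fit
}

#' Fit per-gene negative-binomial GLMs
#'
#' Log-linear NB models with one coefficient per tumor subtype (control
#' group as reference) plus batch indicators, offset by the log effective
#' library size from upper-quartile normalization. Genes with CPM > 1 in
#' fewer than 3 samples are filtered before fitting. Dispersion is
#' estimated by Cox-Reid adjusted profile likelihood per gene and shrunk
#' on the log scale toward the common (all-gene) estimate with a prior
#' weight of `dispersion_prior_df` residual degrees of freedom.
#'
#' @param counts integer count matrix (genes x samples).
#' @param samples sample table (needs columns id, group, batch).
#' @param cfg [default_config()] list.
#' @return object of class `nbglm_fit`: coefficients on the log2 scale,
#'   per-gene dispersions, log-likelihoods, design, offsets and bookkeeping
#'   used by [lrt_test()].
#' @export
fit_nb_glm <- function(counts, samples, cfg = default_config()) {
  stopifnot(ncol(counts) == nrow(samples))
  counts <- counts[, samples$id, drop = FALSE]
  group <- droplevels(factor(samples$group,
                             levels = c("Control", TUMOR_GROUPS)))
  if (!"Control" %in% group) stop("a Control group is required as reference")

  ## expression filter: CPM > 1 in >= 3 samples
  raw_cpm <- sweep(counts, 2L, colSums(counts), "/") * 1e6
  keep <- rowSums(raw_cpm > 1) >= 3L
  y_all <- counts[keep, , drop = FALSE]

  f <- upper_quartile_factors(counts)
  offset <- log(attr(f, "effective_lib_size"))

  batch <- factor(samples$batch)
  X <- if (nlevels(group) == 1L) {
    matrix(1, nrow(samples), 1L,
           dimnames = list(NULL, "(Intercept)"))
  } else if (nlevels(batch) > 1L) {
    stats::model.matrix(~ group + batch)
  } else {
    stats::model.matrix(~ group)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is not full rank; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }

  ng <- nrow(y_all)
  p <- ncol(X)
  n <- ncol(y_all)
  df_resid <- n - p

  ## initial fitted means under a moderate starting dispersion
  phi_init <- 0.1
  mu0 <- matrix(0, ng, n)
  for (g in seq_len(ng))
    mu0[g, ] <- fit_gene_nb(y_all[g, ], X, offset, phi_init)$fitted.values

  ## common dispersion: maximize summed CR-adjusted profile likelihood
  sub <- if (ng > 500L) {
    seq(1L, ng, length.out = 500L)
  } else seq_len(ng)
  common_obj <- function(lphi) {
    phi <- exp(lphi)
    sum(vapply(sub, function(g) nb_apl(y_all[g, ], mu0[g, ], phi, X),
               numeric(1L)))
  }
  phi_common <- exp(stats::optimize(common_obj, c(log(1e-5), log(5)),
                                    maximum = TRUE, tol = 1e-3)$maximum)

  ## per-gene estimates, shrunk toward the common value
  prior_df <- cfg$dispersion_prior_df
  w <- df_resid / (df_resid + prior_df)
  phi_gene <- numeric(ng)
  for (g in seq_len(ng)) {
    o <- stats::optimize(function(lphi) nb_apl(y_all[g, ], mu0[g, ],
                                               exp(lphi), X),
                         c(log(1e-6), log(5)), maximum = TRUE, tol = 1e-2)
    phi_gene[g] <- exp(w * o$maximum + (1 - w) * log(phi_common))
  }

  ## final fits at the shrunk dispersions
  coefs <- matrix(NA_real_, ng, p, dimnames = list(rownames(y_all),
                                                   colnames(X)))
  ll_full <- numeric(ng)
  converged <- logical(ng)
  for (g in seq_len(ng)) {
    fit <- fit_gene_nb(y_all[g, ], X, offset, phi_gene[g])
    coefs[g, ] <- fit$coefficients
    ll_full[g] <- nb_loglik(y_all[g, ], fit$fitted.values, phi_gene[g])
    converged[g] <- isTRUE(fit$converged)
  }

  group_cols <- paste0("group", setdiff(levels(group), "Control"))
  structure(list(
    counts = y_all, design = X, offset = offset,
    coefficients_log2 = coefs / log(2),
    phi = stats::setNames(phi_gene, rownames(y_all)),
    phi_common = phi_common,
    loglik_full = stats::setNames(ll_full, rownames(y_all)),
    converged = stats::setNames(converged, rownames(y_all)),
    group = group, group_cols = group_cols,
    contrasts = setdiff(levels(group), "Control"),
    mean_logcpm = rowMeans(log_cpm(counts, f,
                                   cfg$prior_count))[rownames(y_all)],
    n_filtered = sum(!keep)
  ), class = "nbglm_fit")
}

#' Likelihood-ratio test for one subtype-vs-control contrast
#'
#' Refits each gene's NB model with the contrast's coefficient dropped
#' (dispersion held fixed) and compares deviances; the statistic is
#' referred to chi-square with 1 df. Genes whose full fit did not converge
#' get `NA` p-values and are excluded from the FDR denominator.
#'
#' @param fit `nbglm_fit` from [fit_nb_glm()].
#' @param contrast subtype name (e.g. "HeH").
#' @return data.frame gene, contrast, log2fc, pvalue, fdr, mean_logcpm.
#' @export
lrt_test <- function(fit, contrast) {
  if (!contrast %in% fit$contrasts)
    stop("contrast '", contrast, "' has no samples; available: ",
         paste(fit$contrasts, collapse = ", "))
  col <- paste0("group", contrast)
  if (!col %in% colnames(fit$design)) stop("column not in design: ", col)
  Xr <- fit$design[, setdiff(colnames(fit$design), col), drop = FALSE]
  ng <- nrow(fit$counts)
  pval <- rep(NA_real_, ng)
  for (g in seq_len(ng)) {
    if (!fit$converged[g]) next
    rfit <- fit_gene_nb(fit$counts[g, ], Xr, fit$offset, fit$phi[g])
    ll_red <- nb_loglik(fit$counts[g, ], rfit$fitted.values, fit$phi[g])
    lr <- max(0, 2 * (fit$loglik_full[g] - ll_red))
    pval[g] <- stats::pchisq(lr, df = 1L, lower.tail = FALSE)
  }
  data.frame(
    gene = rownames(fit$counts),
    contrast = contrast,
    log2fc = fit$coefficients_log2[, col],
    pvalue = pval,
    fdr = bh_fdr(pval),
    mean_logcpm = fit$mean_logcpm,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Differential-expression table over all subtype contrasts
#'
#' @param fit `nbglm_fit`.
#' @return long data.frame, one block per contrast (see [lrt_test()]).
#' @export
de_table <- function(fit) {
  do.call(rbind, lapply(fit$contrasts, function(ct) lrt_test(fit, ct)))
}

de_wide <- function(de, value) {
  contrasts <- sort(unique(de$contrast))
  genes <- unique(de$gene)
  m <- matrix(NA_real_, length(genes), length(contrasts),
              dimnames = list(genes, contrasts))
  m[cbind(match(de$gene, genes), match(de$contrast, contrasts))] <- de[[value]]
  m
}

#' Call leukemia-wide and subtype-specific dysregulation
#'
#' A gene is a DET when FDR <= `fdr_de` in at least one subtype contrast;
#' leukemia-wide up/down when significant with the same sign in all four
#' subtypes (mixed when signs disagree); subtype-specific when significant
#' in exactly one. The promoter-analysis category is stricter: "up"
#' ("down") requires FDR < `fdr_de` and log2FC > `logfc_updown` (< -) in
#' all subtypes; "not_de" requires FDR > `fdr_notde` in all subtypes.
#'
#' @param de long DE table with all four subtype contrasts.
#' @param cfg [default_config()] list.
#' @return data.frame gene, n_sig, leukemia_status, specific_subtype,
#'   fig4_category.
#' @export
call_dysregulation <- function(de, cfg = default_config()) {
  fdr <- de_wide(de, "fdr")
  lfc <- de_wide(de, "log2fc")
  missing <- setdiff(TUMOR_GROUPS, colnames(fdr))
  if (length(missing))
    stop("missing contrast(s): ", paste(missing, collapse = ", "))
  fdr <- fdr[, TUMOR_GROUPS, drop = FALSE]
  lfc <- lfc[, TUMOR_GROUPS, drop = FALSE]
  sig <- !is.na(fdr) & fdr <= cfg$fdr_de
  n_sig <- rowSums(sig)
  all_sig <- n_sig == ncol(sig)
  pos <- rowSums(lfc > 0) == ncol(lfc)
  neg <- rowSums(lfc < 0) == ncol(lfc)
  leukemia_status <- ifelse(all_sig & pos, "up",
                     ifelse(all_sig & neg, "down",
                     ifelse(all_sig, "mixed", "none")))
  specific_subtype <- rep(NA_character_, nrow(sig))
  one <- which(n_sig == 1L)
  specific_subtype[one] <- colnames(sig)[apply(sig[one, , drop = FALSE],
                                               1L, which)]
  strict_up <- rowSums(!is.na(fdr) & fdr < cfg$fdr_de &
                         lfc > cfg$logfc_updown) == ncol(fdr)
  strict_dn <- rowSums(!is.na(fdr) & fdr < cfg$fdr_de &
                         lfc < -cfg$logfc_updown) == ncol(fdr)
  not_de <- rowSums(!is.na(fdr) & fdr > cfg$fdr_notde) == ncol(fdr)
  fig4 <- ifelse(strict_up, "up",
          ifelse(strict_dn, "down",
          ifelse(not_de, "not_de", "other")))
  data.frame(gene = rownames(sig), n_sig = n_sig,
             leukemia_status = leukemia_status,
             specific_subtype = specific_subtype,
             fig4_category = fig4,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Subtype specificity score and 4-fold specificity flag
#'
#' For each gene and focal tumor subtype: the score is the difference
#' between the gene's mean logCPM in the focal subtype and its mean in the
#' closest other tumor subtype (the one whose group mean is nearest); the
#' 4-fold flag marks genes whose focal mean differs from the pooled mean
#' of all other tumor samples by at least log2(`subtype_fold`). Controls
#' are not candidate "closest" groups.
#'
#' @param expr logCPM matrix.
#' @param samples sample table.
#' @param cfg [default_config()] list.
#' @return list with `score` and `flag` (gene x subtype matrices) and
#'   `summary` (per gene: focal subtype with the largest absolute score,
#'   that score, and its flag).
#' @export
specificity_score <- function(expr, samples, cfg = default_config()) {
  groups <- intersect(TUMOR_GROUPS, unique(as.character(samples$group)))
  if (length(groups) < 2L) stop("need >= 2 tumor subtypes")
  idx <- lapply(groups, function(g) which(samples$group == g))
  names(idx) <- groups
  empty <- groups[vapply(idx, length, 1L) == 0L]
  if (length(empty)) stop("subtype(s) with 0 samples: ",
                          paste(empty, collapse = ", "))
  gm <- vapply(idx, function(i) rowMeans(expr[, i, drop = FALSE]),
               numeric(nrow(expr)))
  score <- flag <- matrix(NA_real_, nrow(expr), length(groups),
                          dimnames = list(rownames(expr), groups))
  for (f in groups) {
    others <- setdiff(groups, f)
    d <- abs(gm[, others, drop = FALSE] - gm[, f])
    closest <- others[apply(d, 1L, which.min)]
    score[, f] <- gm[, f] - gm[cbind(seq_len(nrow(gm)), match(closest, groups))]
    pooled_idx <- unlist(idx[others])
    pooled <- rowMeans(expr[, pooled_idx, drop = FALSE])
    flag[, f] <- abs(gm[, f] - pooled) >= log2(cfg$subtype_fold)
  }
  focal_j <- apply(abs(score), 1L, which.max)
  summary <- data.frame(
    gene = rownames(expr),
    focal_subtype = groups[focal_j],
    specificity_score = score[cbind(seq_len(nrow(score)), focal_j)],
    specific_4fold = flag[cbind(seq_len(nrow(flag)), focal_j)] > 0,
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(score = score, flag = flag == 1, summary = summary)
}

#' Compare two differential-expression tables
#'
#' Intersects the gene universes, counts the overlap of significant sets,
#' compares it to the expectation under independent random draws
#' (nA * nB / N), and correlates log2 fold changes on the common
#' significant genes. This covers cross-platform comparisons where the
#' second table comes from an external analysis.
#'
#' @param deA,deB data.frames with columns gene, log2fc, fdr (single
#'   contrast each).
#' @param threshold significance cutoff on fdr (default 1e-3).
#' @return list: n_universe, nA, nB, observed, expected, fold_enrichment,
#'   pearson, spearman, sign_concordance.
#' @export
compare_de_tables <- function(deA, deB, threshold = 1e-3) {
  common <- intersect(deA$gene, deB$gene)
  if (!length(common)) stop("empty gene universe after intersection")
  a <- deA[match(common, deA$gene), ]
  b <- deB[match(common, deB$gene), ]
  sigA <- !is.na(a$fdr) & a$fdr <= threshold
  sigB <- !is.na(b$fdr) & b$fdr <= threshold
  both <- sigA & sigB
  nA <- sum(sigA); nB <- sum(sigB); N <- length(common)
  expected <- nA * nB / N
  lfcA <- a$log2fc[both]; lfcB <- b$log2fc[both]
  list(
    n_universe = N, nA = nA, nB = nB,
    observed = sum(both), expected = expected,
    fold_enrichment = if (expected > 0) sum(both) / expected else NA_real_,
    pearson = if (sum(both) >= 3) stats::cor(lfcA, lfcB) else NA_real_,
    spearman = if (sum(both) >= 3) {
      stats::cor(lfcA, lfcB, method = "spearman")
    } else NA_real_,
    sign_concordance = if (sum(both) > 0) {
      mean(sign(lfcA) == sign(lfcB))
    } else NA_real_
  )
}

#' Odds ratio and Fisher p from a 2x2 table
#'
#' Sample odds ratio (a/b)/(c/d) with Fisher's exact p-value.
#'
#' @param a,b,c,d cell counts (row 1 = a, b; row 2 = c, d).
#' @return list: odds_ratio, p_value, table.
#' @export
odds_from_counts <- function(a, b, c, d) {
  tab <- matrix(c(a, c, b, d), 2L)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin in 2x2 table: ", paste(c(a, b, c, d), collapse = ", "))
  list(odds_ratio = (a / b) / (c / d),
       p_value = stats::fisher.test(tab)$p.value,
       table = tab)
}

#' Are deregulated lncRNAs more often subtype-specific?
#'
#' Builds the 2x2 table (lncRNA vs non-lncRNA DET) x (subtype-specific vs
#' not) over differentially expressed genes and returns the sample odds
#' ratio with Fisher's exact p.
#'
#' @param calls output of [call_dysregulation()].
#' @param genes gene-model data.frame.
#' @return list: odds_ratio, p_value, table.
#' @export
biotype_specificity_odds <- function(calls, genes) {
  det <- calls[calls$n_sig >= 1L, ]
  if (!nrow(det)) stop("no differentially expressed genes")
  biotype <- genes$biotype[match(det$gene, genes$gene_id)]
  is_lnc <- biotype == "lncRNA"
  if (!any(is_lnc) || all(is_lnc))
    stop("need DETs of both lncRNA and non-lncRNA biotype")
  is_spec <- !is.na(det$specific_subtype)
  odds_from_counts(sum(is_lnc & is_spec), sum(is_lnc & !is_spec),
                   sum(!is_lnc & is_spec), sum(!is_lnc & !is_spec))
}
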