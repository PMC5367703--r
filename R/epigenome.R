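#' TSS windows around the most-upstream transcription start site
#'
#' One window per gene, `[TSS - flank, TSS + flank)` in BED semantics,
#' clipped at 0. "Most upstream" respects strand: the smallest TSS
#' coordinate on +, the largest on -. With `most_upstream = FALSE` every
#' TSS of the gene yields a window.
#'
#' @param genes gene-model data.frame.
#' @param flank half-window size in bp (> 0).
#' @param most_upstream use only the most-upstream TSS (default TRUE).
#' @return data.frame chrom, start, end, gene, strand.
#' @export
tss_windows <- function(genes, flank = 5000L, most_upstream = TRUE) {
  if (flank <= 0) stop("flank must be > 0")
  anchors <- lapply(seq_len(nrow(genes)), function(i) {
    t <- genes$tss[[i]]
    if (most_upstream) {
      if (genes$strand[i] == "-") max(t) else min(t)
    } else t
  })
  k <- lengths(anchors)
  idx <- rep(seq_len(nrow(genes)), k)
  a <- unlist(anchors)
  data.frame(chrom = genes$chromosome[idx],
             start = pmax(0L, as.integer(a - flank)),
             end = as.integer(a + flank),
             gene = genes$gene_id[idx],
             strand = genes$strand[idx],
             stringsAsFactors = FALSE)
}

#' Interval overlap test (BED semantics)
#'
#' For each query interval, whether it overlaps any subject interval by at
#' least 1 bp under the half-open convention ([0,10) and [10,20) do not
#' touch). Implemented per chromosome with a sorted sweep: subjects are
#' ordered by start and a running maximum of ends is kept, so each query
#' costs one binary search.
#'
#' @param a query data.frame (chrom, start, end).
#' @param b subject data.frame (chrom, start, end).
#' @return logical vector, one entry per row of `a`.
#' @export
overlaps <- function(a, b) {
  for (df in list(a, b)) {
    if (!all(c("chrom", "start", "end") %in% names(df)))
      stop("interval sets need chrom, start, end columns")
    if (nrow(df) && any(df$start >= df$end))
      stop("malformed interval: start >= end")
  }
  out <- logical(nrow(a))
  if (!nrow(a) || !nrow(b)) return(out)
  b_by <- split(seq_len(nrow(b)), b$chrom)
  a_by <- split(seq_len(nrow(a)), a$chrom)
  for (ch in names(a_by)) {
    bi <- b_by[[ch]]
    if (is.null(bi)) next
    ord <- bi[order(b$start[bi])]
    starts <- b$start[ord]
    max_end <- cummax(b$end[ord])
    ai <- a_by[[ch]]
    # subjects with start < query end: positions 1..k
    k <- findInterval(a$end[ai] - 1L, starts)
    hit <- k >= 1L
    hit[hit] <- max_end[k[hit]] > a$start[ai][hit]
    out[ai] <- hit
  }
  out
}

#' Metagene peak-coverage profile
#'
#' Splits every window into `bins` equal bins and reports, per bin, the
#' fraction of windows whose bin overlaps at least one peak. When the
#' window set carries a strand column, minus-strand windows are flipped so
#' that bins always run 5' to 3'.
#'
#' @param peaks peak data.frame (chrom, start, end).
#' @param windows window data.frame from [tss_windows()] (or any chrom /
#'   start / end [/ strand] table).
#' @param bins number of bins (>= 1).
#' @return numeric vector of length `bins` with values in [0, 1].
#' @export
metagene_profile <- function(peaks, windows, bins = 50L) {
  if (bins < 1L) stop("bins must be >= 1")
  n <- nrow(windows)
  if (!n) return(rep(NA_real_, bins))
  width <- windows$end - windows$start
  edges <- vapply(0:bins, function(k)
    windows$start + round(k * width / bins), numeric(n))
  qs <- as.vector(edges[, 1:bins, drop = FALSE])
  qe <- as.vector(edges[, 2:(bins + 1L), drop = FALSE])
  ok <- qe > qs
  q <- data.frame(chrom = rep(windows$chrom, bins),
                  start = qs, end = pmax(qe, qs + 1L),
                  stringsAsFactors = FALSE)
  hit <- matrix(overlaps(q, peaks) & ok, n, bins)
  if (!is.null(windows$strand)) {
    neg <- windows$strand == "-"
    hit[neg, ] <- hit[neg, bins:1, drop = FALSE]
  }
  colMeans(hit)
}

#' Bivalent-promoter fractions by dysregulation category
#'
#' Per promoter category (up / down / not_de / other): the fraction of
#' genes whose TSS window overlaps an H3K27me3 peak, and the fraction
#' overlapping both H3K27me3 and H3K4me3 (bivalent). The fold enrichment
#' is the bivalency fraction of the up category over that of not_de.
#'
#' @param k27,k4 peak data.frames for H3K27me3 and H3K4me3.
#' @param windows TSS windows with a `gene` column.
#' @param categories named character vector (or factor) of categories per
#'   gene, as in `fig4_category` of [call_dysregulation()].
#' @return list: `fractions` data.frame (category, n, frac_k27,
#'   frac_bivalent) and `fold_enrichment`.
#' @export
bivalency_fractions <- function(k27, k4, windows, categories) {
  cat <- as.character(categories[windows$gene])
  hit27 <- overlaps(windows, k27)
  hit4 <- overlaps(windows, k4)
  lv <- intersect(c("up", "down", "not_de", "other"), unique(cat))
  frac <- do.call(rbind, lapply(lv, function(cl) {
    i <- which(cat == cl)
    if (!length(i)) {
      warning("empty category: ", cl)
      return(data.frame(category = cl, n = 0L, frac_k27 = NA_real_,
                        frac_bivalent = NA_real_))
    }
    data.frame(category = cl, n = length(i),
               frac_k27 = mean(hit27[i]),
               frac_bivalent = mean(hit27[i] & hit4[i]),
               stringsAsFactors = FALSE)
  }))
  up <- frac$frac_bivalent[frac$category == "up"]
  ref <- frac$frac_bivalent[frac$category == "not_de"]
  fold <- if (length(up) && length(ref) && !is.na(ref) && ref > 0) {
    up / ref
  } else NA_real_
  list(fractions = frac, fold_enrichment = fold)
}

#' Hypergeometric upper-tail test for gene-set overlap
#'
#' P(X >= q) where X counts hits among `k` draws from a universe of `N`
#' genes containing `K` hits.
#'
#' @param q observed overlap.
#' @param K hits in the universe.
#' @param N universe size.
#' @param k draws (target-set size).
#' @return upper-tail p-value.
#' @export
hypergeom_upper <- function(q, K, N, k) {
  stats::phyper(q - 1L, K, N - K, k, lower.tail = FALSE)
}

#' Transcription-factor peak enrichment on deregulated genes
#'
#' For each TF peak set: genes of the background (expressed) universe are
#' scored as hit when their TSS window overlaps a peak; the upper-tail
#' hypergeometric p tests whether the target set (deregulated genes)
#' contains more hits than random draws from the background; the ratio is
#' the hit fraction in targets over the hit fraction in the background.
#' `min_subtype_log2fc` is the TF's own expression change in the subtype
#' contrast where it is smallest in magnitude (sign retained). A TF is
#' flagged significant when its enrichment FDR and its own DE FDR (the
#' minimum over subtype contrasts) are both below `cfg$fdr_enrich`.
#'
#' @param tfs named list of peak data.frames (names = TF gene ids).
#' @param windows TSS windows with a `gene` column.
#' @param target_genes deregulated gene ids (subset of background).
#' @param background_genes expressed gene ids (the universe).
#' @param de long DE table (for the TFs' own expression change).
#' @param cfg [default_config()] list.
#' @return data.frame, one row per TF: hit counts, enrichment ratio,
#'   p-value, fdr, min_subtype_log2fc, tf_de_fdr, significant.
#' @export
tf_enrichment <- function(tfs, windows, target_genes, background_genes,
                          de, cfg = default_config()) {
  if (!all(target_genes %in% background_genes))
    stop("target genes must be a subset of the background")
  windows <- windows[windows$gene %in% background_genes, , drop = FALSE]
  lfc <- de_wide(de, "log2fc")
  fdr <- de_wide(de, "fdr")
  N <- length(background_genes)
  k <- length(target_genes)
  is_target <- windows$gene %in% target_genes
  rows <- lapply(names(tfs), function(tf) {
    hit <- overlaps(windows, tfs[[tf]])
    hit_genes <- unique(windows$gene[hit])
    K <- length(hit_genes)
    q <- sum(target_genes %in% hit_genes)
    ratio <- if (K > 0) (q / k) / (K / N) else NA_real_
    p <- hypergeom_upper(q, K, N, k)
    if (tf %in% rownames(lfc)) {
      v <- lfc[tf, ]
      j <- which.min(abs(v))
      min_lfc <- v[j]
      tf_fdr <- min(fdr[tf, ], na.rm = TRUE)
    } else {
      min_lfc <- NA_real_; tf_fdr <- NA_real_
    }
    data.frame(tf = tf, n_target_hits = q, n_target = k,
               n_background_hits = K, n_background = N,
               enrichment_ratio = ratio, pvalue = p,
               min_subtype_log2fc = min_lfc, tf_de_fdr = tf_fdr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$fdr <- bh_fdr(out$pvalue)
  out$significant <- !is.na(out$tf_de_fdr) &
    out$fdr < cfg$fdr_enrich & out$tf_de_fdr < cfg$fdr_enrich
  out <- out[order(out$pvalue), ]
  rownames(out) <- NULL
  out
}
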