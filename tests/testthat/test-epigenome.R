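brute_overlap <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] & b$start < a$end[i] & a$start[i] < b$end)
  }, logical(1))
}

toy_genes <- function() {
  g <- data.frame(
    gene_id = c("gP", "gM"),
    biotype = "protein_coding",
    chromosome = c("1", "1"),
    strand = c("+", "-"),
    body_start = c(100L, 500L),
    body_end = c(10000L, 9000L),
    stringsAsFactors = FALSE)
  g$tss <- list(c(100L, 150L), c(100L, 150L))
  rownames(g) <- g$gene_id
  g
}

test_that("TSS windows use the most-upstream TSS and clip at zero", {
  g <- toy_genes()
  w <- tss_windows(g, flank = 5000)
  # + strand: most upstream is the smallest coordinate (100)
  expect_equal(w[w$gene == "gP", c("start", "end")],
               data.frame(start = 0L, end = 5100L), ignore_attr = TRUE)
  # - strand: most upstream is the largest coordinate (150)
  expect_equal(w$start[w$gene == "gM"], 0L)
  expect_equal(w$end[w$gene == "gM"], 5150L)
  expect_error(tss_windows(g, flank = 0), "flank")
  # all TSS when most_upstream = FALSE
  expect_equal(nrow(tss_windows(g, 10, most_upstream = FALSE)), 4L)
})

test_that("interval overlap respects half-open boundaries", {
  a <- data.frame(chrom = "1", start = 0L, end = 10L)
  expect_false(overlaps(a, data.frame(chrom = "1", start = 10L, end = 20L)))
  expect_true(overlaps(a, data.frame(chrom = "1", start = 9L, end = 20L)))
  expect_false(overlaps(a, data.frame(chrom = "2", start = 0L, end = 10L)))
  expect_error(overlaps(data.frame(chrom = "1", start = 5L, end = 5L), a),
               "malformed")
})

test_that("sweep-line overlap equals the all-pairs oracle on random cases", {
  set.seed(40)
  for (case in 1:40) {
    na <- sample(1:40, 1); nb <- sample(1:40, 1)
    mk <- function(n) {
      s <- sample.int(500, n, replace = TRUE)
      data.frame(chrom = sample(c("1", "2", "3"), n, replace = TRUE),
                 start = s, end = s + sample.int(60, n, replace = TRUE),
                 stringsAsFactors = FALSE)
    }
    a <- mk(na); b <- mk(nb)
    expect_identical(overlaps(a, b), brute_overlap(a, b))
  }
})

test_that("overlap results are independent of subject row order", {
  set.seed(41)
  s <- sample.int(300, 50, replace = TRUE)
  b <- data.frame(chrom = "1", start = s, end = s + 20L)
  a <- data.frame(chrom = "1", start = seq(0L, 290L, 10L),
                  end = seq(5L, 295L, 10L))
  expect_identical(overlaps(a, b), overlaps(a, b[sample(nrow(b)), ]))
})

test_that("metagene profiles localize coverage to the covered bins", {
  g <- toy_genes()
  w <- tss_windows(g, flank = 500)  # gP: [0,600), gM: [0,650)
  full <- data.frame(chrom = "1", start = 0L, end = 10000L)
  expect_equal(metagene_profile(full, w, bins = 5), rep(1, 5))
  none <- data.frame(chrom = "2", start = 0L, end = 10000L)
  expect_equal(metagene_profile(none, w, bins = 5), rep(0, 5))

  # a peak covering exactly the central bin of every window
  w2 <- data.frame(chrom = c("1", "1"), start = c(0L, 1000L),
                   end = c(500L, 1500L), gene = c("a", "b"),
                   strand = c("+", "+"), stringsAsFactors = FALSE)
  central <- data.frame(chrom = "1", start = c(200L, 1200L),
                        end = c(300L, 1300L))
  expect_equal(metagene_profile(central, w2, bins = 5),
               c(0, 0, 1, 0, 0))
  # minus-strand windows are flipped 5' -> 3'
  w3 <- w2; w3$strand <- "-"
  off <- data.frame(chrom = "1", start = c(0L, 1000L),
                    end = c(100L, 1100L))
  expect_equal(metagene_profile(off, w3, bins = 5), c(0, 0, 0, 0, 1))
})

test_that("bivalency fractions and fold enrichment match hand counts", {
  w <- data.frame(chrom = "1", start = (0:3) * 1000L,
                  end = (0:3) * 1000L + 500L,
                  gene = paste0("g", 1:4), strand = "+",
                  stringsAsFactors = FALSE)
  categories <- setNames(c("up", "up", "not_de", "not_de"), w$gene)
  # both up genes bivalent; one not_de gene has K27 only
  k27 <- data.frame(chrom = "1", start = c(0L, 1000L, 2000L),
                    end = c(100L, 1100L, 2100L))
  k4 <- data.frame(chrom = "1", start = c(0L, 1000L, 3000L),
                   end = c(100L, 1100L, 3100L))
  res <- bivalency_fractions(k27, k4, w, categories)
  up <- res$fractions[res$fractions$category == "up", ]
  nd <- res$fractions[res$fractions$category == "not_de", ]
  expect_equal(up$frac_bivalent, 1.0)
  expect_equal(up$frac_k27, 1.0)
  expect_equal(nd$frac_k27, 0.5)
  expect_equal(nd$frac_bivalent, 0)
  expect_true(is.na(res$fold_enrichment) || res$fold_enrichment == Inf)

  # 2/2 up vs 1/2 not_de bivalent -> fold 2
  k4b <- data.frame(chrom = "1", start = c(0L, 1000L, 2000L),
                    end = c(100L, 1100L, 2100L))
  res2 <- bivalency_fractions(k27, k4b, w, categories)
  expect_equal(res2$fold_enrichment, 2.0)

  # result unchanged under peak-row permutation
  res3 <- bivalency_fractions(k27[c(3, 1, 2), ], k4b[c(2, 3, 1), ], w,
                              categories)
  expect_equal(res3$fractions, res2$fractions)
})

test_that("hypergeometric p matches exhaustive enumeration", {
  # closed form vs enumeration over all subsets for small universes
  enum_p <- function(q, K, N, k) {
    hits <- seq(0, k)
    probs <- choose(K, hits) * choose(N - K, k - hits) / choose(N, k)
    sum(probs[hits >= q])
  }
  set.seed(42)
  for (i in 1:25) {
    N <- sample(4:12, 1)
    K <- sample(1:N, 1)
    k <- sample(1:N, 1)
    q <- sample(0:min(K, k), 1)
    expect_equal(hypergeom_upper(q, K, N, k), enum_p(q, K, N, k),
                 tolerance = 1e-12)
  }
  # worked example: universe 10, hits 5, draws 4, all 4 hit
  expect_equal(hypergeom_upper(4, 5, 10, 4), 5 / 210, tolerance = 1e-12)
})

test_that("TF enrichment reproduces ratio arithmetic and null behavior", {
  genes <- sprintf("g%02d", 1:10)
  w <- data.frame(chrom = "1", start = (0:9) * 1000L,
                  end = (0:9) * 1000L + 500L, gene = genes,
                  strand = "+", stringsAsFactors = FALSE)
  # TF peaks hit genes 1-5; targets are genes 1-4
  tf_peaks <- data.frame(chrom = "1", start = (0:4) * 1000L,
                         end = (0:4) * 1000L + 100L)
  de <- do.call(rbind, lapply(c("HeH", "t(12;21)", "t(9;22)", "Other"),
                              function(ct)
    data.frame(gene = genes, contrast = ct,
               log2fc = seq(-1, 0.8, length.out = 10),
               pvalue = 0.5, fdr = 0.5, stringsAsFactors = FALSE)))
  res <- tf_enrichment(list(g01 = tf_peaks), w,
                       target_genes = genes[1:4],
                       background_genes = genes, de = de)
  expect_equal(res$enrichment_ratio, (4 / 4) / (5 / 10))
  expect_equal(res$pvalue, 5 / 210, tolerance = 1e-12)
  expect_equal(res$min_subtype_log2fc, -1)  # identical across contrasts

  # targets = background: no enrichment possible
  res2 <- tf_enrichment(list(g01 = tf_peaks), w, genes, genes, de)
  expect_equal(res2$enrichment_ratio, 1)
  expect_equal(res2$pvalue, 1)

  # a TF absent from the DE table is kept but cannot be significant
  res3 <- tf_enrichment(list(missing_tf = tf_peaks), w, genes[1:4],
                        genes, de)
  expect_true(is.na(res3$min_subtype_log2fc))
  expect_false(res3$significant)

  expect_error(tf_enrichment(list(g01 = tf_peaks), w, "not_there",
                             genes, de), "subset")
})

test_that("planted TF targeting is detected end to end", {
  sim <- small_sim()
  scfg <- sim_config(n_genes = 1200)
  pk <- simulate_peaks(sim$genes, sim$truth, scfg, seed = 44)
  w <- tss_windows(sim$genes, 5000)
  de_cat <- sim$truth$category
  targets <- names(de_cat)[de_cat %in% c("leukemia_up", "leukemia_down")]
  de_stub <- do.call(rbind, lapply(c("HeH", "t(12;21)", "t(9;22)", "Other"),
                                   function(ct)
    data.frame(gene = sim$genes$gene_id, contrast = ct,
               log2fc = sim$truth$planted_log2fc[, ct], pvalue = 0.05,
               fdr = ifelse(de_cat == "null", 0.5, 0.01),
               stringsAsFactors = FALSE)))
  res <- tf_enrichment(pk$tfs, w, targets, sim$genes$gene_id, de_stub)
  # TFs whose targets were drawn from deregulated genes rank on top
  dereg_tfs <- names(pk$tf_targets)[vapply(pk$tf_targets, function(t)
    mean(t %in% targets) > 0.9, logical(1))]
  expect_gt(length(dereg_tfs), 0)
  top <- res$tf[seq_along(dereg_tfs)]
  expect_gt(mean(top %in% dereg_tfs), 0.7)
  expect_true(all(res$fdr[res$tf %in% dereg_tfs] < 0.1))
})
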