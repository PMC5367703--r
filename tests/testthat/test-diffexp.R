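null_de <- function() {
  cached("null_de", {
    sim <- null_sim()
    de_table(fit_nb_glm(sim$counts, sim$samples))
  })
}

test_that("BH adjustment matches the hand step-up and is monotone", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(4)
  p <- runif(50)
  f <- bh_fdr(p)
  expect_true(all(diff(f[order(p)]) >= -1e-12))
  expect_true(all(f >= p))
  # NAs carried through and excluded from the denominator
  f2 <- bh_fdr(c(0.01, NA, 0.02))
  expect_true(is.na(f2[2]))
  expect_equal(f2[c(1, 3)], bh_fdr(c(0.01, 0.02)))
})

test_that("a control-only cohort fits intercepts that match normalized means", {
  set.seed(5)
  m <- matrix(rnbinom(200 * 8, mu = 200, size = 10), 200,
              dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:8)))
  samples <- data.frame(id = colnames(m),
                        group = factor(rep("Control", 8),
                                       levels = c("HeH", "t(12;21)",
                                                  "t(9;22)", "Other",
                                                  "Control")),
                        batch = "b1", stringsAsFactors = FALSE)
  fit <- fit_nb_glm(m, samples)
  expect_length(fit$contrasts, 0)
  f <- upper_quartile_factors(m)
  eff <- attr(f, "effective_lib_size")
  norm_mean <- rowMeans(sweep(m, 2, eff, "/"))
  est <- 2^fit$coefficients_log2[, "(Intercept)"]
  expect_equal(unname(est), unname(norm_mean), tolerance = 0.02)
})

test_that("an exact 4-fold ratio is recovered in the Poisson limit", {
  # few, balanced up/down 4-fold genes so normalization stays anchored
  beta <- c(rep(2, 10), rep(-2, 10), rep(0, 200))
  tg <- two_group_counts(beta, n_per_group = 25, phi = 1e-4, seed = 6)
  fit <- fit_nb_glm(tg$counts, tg$samples)
  de <- lrt_test(fit, "HeH")
  b <- beta[match(de$gene, rownames(tg$counts))]
  expect_lt(abs(mean(de$log2fc[b == 2]) - 2), 0.05)
  expect_lt(abs(mean(de$log2fc[b == 0])), 0.05)
})

test_that("estimated log2FC tracks the planted grid with slope near 1", {
  beta <- rep(seq(-3, 3, 1), each = 20)
  tg <- two_group_counts(beta, n_per_group = 12, phi = 0.1, seed = 7)
  fit <- fit_nb_glm(tg$counts, tg$samples)
  de <- lrt_test(fit, "HeH")
  b <- beta[match(de$gene, rownames(tg$counts))]
  slope <- coef(lm(de$log2fc ~ b))[2]
  expect_lt(abs(slope - 1), 0.05)
  # power: a planted log2FC of 3 is detected overwhelmingly
  expect_lt(max(de$pvalue[b == 3]), 1e-6)
})

test_that("the GLM route agrees with an independent edgeR analysis", {
  skip_if_not_installed("edgeR")
  beta <- c(rep(2, 10), rep(-2, 10), rep(0, 200))
  tg <- two_group_counts(beta, n_per_group = 10, phi = 0.1, seed = 9)
  fit <- fit_nb_glm(tg$counts, tg$samples)
  de <- lrt_test(fit, "HeH")
  y <- edgeR::DGEList(tg$counts, group = tg$samples$group)
  y <- edgeR::calcNormFactors(y, method = "upperquartile")
  design <- model.matrix(~ factor(tg$samples$group,
                                  levels = c("Control", "HeH")))
  y <- edgeR::estimateDisp(y, design)
  ref <- edgeR::topTags(edgeR::glmLRT(edgeR::glmFit(y, design), coef = 2),
                        n = Inf, sort.by = "none")$table
  expect_gt(cor(de$log2fc, ref$logFC), 0.999)
  expect_lt(mean(abs(de$log2fc - ref$logFC)), 0.01)
  expect_gt(cor(-log10(de$pvalue + 1e-300), -log10(ref$PValue + 1e-300)),
            0.95)
  expect_gt(mean((de$fdr <= 1e-3) == (ref$FDR <= 1e-3)), 0.95)
})

test_that("null p-values are approximately uniform", {
  de <- null_de()
  p <- de$pvalue[de$contrast == "HeH"]
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("contrasts without samples and aliased designs are rejected", {
  tg <- two_group_counts(rep(0, 30), n_per_group = 5, seed = 8)
  fit <- fit_nb_glm(tg$counts, tg$samples)
  expect_error(lrt_test(fit, "t(9;22)"), "no samples")
  # batch perfectly confounded with group
  tg$samples$batch <- ifelse(tg$samples$group == "Control", "b1", "b2")
  expect_error(fit_nb_glm(tg$counts, tg$samples), "aliased.*batch")
})

test_that("dysregulation calls follow the threshold rules", {
  mk <- function(gene, fdrs, lfcs) {
    data.frame(gene = gene, contrast = c("HeH", "t(12;21)", "t(9;22)",
                                         "Other"),
               log2fc = lfcs, pvalue = fdrs, fdr = fdrs,
               stringsAsFactors = FALSE)
  }
  de <- rbind(
    mk("gAllUp", rep(1e-4, 4), rep(3, 4)),          # leukemia up, fig4 up
    mk("gHeH", c(1e-4, 0.9, 0.9, 0.9), c(3, 0, 0, 0)),  # specific HeH
    mk("gNone", rep(0.9, 4), rep(0.1, 4)),          # not DE
    mk("gMixed", rep(1e-4, 4), c(3, 3, -3, 3)),     # discordant signs
    mk("gWeakUp", rep(1e-4, 4), rep(1.5, 4)))       # significant, |lfc| < 2
  calls <- call_dysregulation(de, default_config())
  rownames(calls) <- calls$gene
  expect_equal(calls["gAllUp", "leukemia_status"], "up")
  expect_equal(calls["gAllUp", "fig4_category"], "up")
  expect_equal(calls["gHeH", "specific_subtype"], "HeH")
  expect_equal(calls["gNone", "fig4_category"], "not_de")
  expect_equal(calls["gMixed", "leukemia_status"], "mixed")
  expect_equal(calls["gWeakUp", "leukemia_status"], "up")
  expect_equal(calls["gWeakUp", "fig4_category"], "other")

  # invariant to row order
  calls2 <- call_dysregulation(de[sample(nrow(de)), ], default_config())
  rownames(calls2) <- calls2$gene
  expect_equal(calls2[rownames(calls), ], calls)

  expect_error(call_dysregulation(de[de$contrast != "Other", ]),
               "missing contrast")
})

test_that("calls on synthetic truth recover the planted categories", {
  sim <- small_sim()
  fit <- fit_nb_glm(sim$counts, sim$samples)
  calls <- call_dysregulation(de_table(fit))
  truth_cat <- sim$truth$category[calls$gene]
  up_called <- calls$gene[calls$leukemia_status == "up"]
  # the vast majority of leukemia-up calls are planted leukemia-up genes
  expect_gt(mean(truth_cat[calls$leukemia_status == "up"] == "leukemia_up"),
            0.9)
  # planted strong leukemia-up genes are mostly recovered
  strong <- names(sim$truth$category)[
    sim$truth$category == "leukemia_up" &
      apply(sim$truth$planted_log2fc, 1, min) >= 2]
  strong <- intersect(strong, calls$gene)
  expect_gt(mean(strong %in% up_called), 0.9)
})

test_that("specificity scores follow the closest-subtype definition", {
  groups <- rep(c("HeH", "t(12;21)", "t(9;22)"), each = 2)
  samples <- data.frame(id = paste0("s", 1:6),
                        group = factor(groups,
                                       levels = c("HeH", "t(12;21)",
                                                  "t(9;22)", "Other",
                                                  "Control")),
                        stringsAsFactors = FALSE)
  expr <- rbind(
    gFocal = rep(c(10, 2, 3), each = 2),   # closest other mean 3, score 7
    gFlat = rep(5, 6),                     # all equal: score 0, no flag
    gNear = rep(c(10, 8.0, 8.2), each = 2))  # pooled others 8.1, |d|=1.9
  colnames(expr) <- samples$id
  res <- specificity_score(expr, samples, default_config())
  expect_equal(res$score["gFocal", "HeH"], 7)
  expect_true(res$flag["gFocal", "HeH"])
  expect_equal(res$summary$specificity_score[
    res$summary$gene == "gFlat"], 0)
  expect_false(res$summary$specific_4fold[res$summary$gene == "gFlat"])
  expect_false(res$flag["gNear", "HeH"])  # 1.9 < log2(4)

  expect_error(specificity_score(expr[, 1:2, drop = FALSE],
                                 samples[1:2, ], default_config()),
               ">= 2 tumor subtypes")
})

test_that("DE-table comparison reports overlap enrichment and correlation", {
  set.seed(9)
  de <- data.frame(gene = sprintf("g%03d", 1:100),
                   log2fc = rnorm(100),
                   fdr = c(rep(1e-4, 10), runif(90, 0.2, 1)),
                   stringsAsFactors = FALSE)
  self <- compare_de_tables(de, de)
  expect_equal(self$observed, self$nA)
  expect_equal(self$pearson, 1)
  expect_equal(self$sign_concordance, 1)
  expect_equal(self$expected, 10 * 10 / 100)

  # independent random sets: mean observed overlap matches nA*nB/N
  N <- 100; nA <- 10; nB <- 20
  overlaps_mc <- replicate(400, {
    a <- sample(N, nA); b <- sample(N, nB)
    length(intersect(a, b))
  })
  expect_lt(abs(mean(overlaps_mc) - nA * nB / N), 0.3)

  expect_error(compare_de_tables(de, transform(de, gene = paste0("x", gene))),
               "empty gene universe")
})

test_that("odds ratios match hand arithmetic", {
  expect_equal(odds_from_counts(2, 8, 1, 9)$odds_ratio, 2.25)
  expect_equal(odds_from_counts(3, 6, 2, 4)$odds_ratio, 1)  # proportional
  expect_error(odds_from_counts(0, 0, 1, 2), "zero margin")

  calls <- data.frame(
    gene = paste0("g", 1:40), n_sig = 1L,
    specific_subtype = c(rep("HeH", 8), rep(NA, 32)),
    stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = paste0("g", 1:40),
                      biotype = rep(c("lncRNA", "protein_coding"), 20),
                      stringsAsFactors = FALSE)
  # lncRNA: 4 specific of 20; protein-coding: 4 of 20
  res <- biotype_specificity_odds(calls, genes)
  expect_equal(res$odds_ratio, 1)
})
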