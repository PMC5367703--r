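# independent naive KNN oracle implementing the documented tie-break rules
naive_knn <- function(expr, labels, genes, k) {
  labels <- factor(labels)
  D <- as.matrix(dist(t(expr[genes, , drop = FALSE])))
  ids <- colnames(expr)
  out <- character(ncol(expr))
  for (i in seq_len(ncol(expr))) {
    j <- setdiff(seq_len(ncol(expr)), i)
    nn <- j[order(D[i, j], ids[j])][seq_len(k)]
    votes <- table(factor(labels[nn], levels = levels(labels)))
    top <- names(votes)[votes == max(votes)]
    out[i] <- if (length(top) == 1L) top else {
      as.character(labels[nn[which(as.character(labels[nn]) %in% top)[1]]])
    }
  }
  factor(out, levels = levels(labels))
}

test_that("distance matrices match hand arithmetic and metric properties", {
  e <- matrix(c(0, 3, 4), 1, dimnames = list("g1", c("a", "b", "c")))
  D <- distance_matrix(e, "g1")
  expect_equal(D["a", "b"], 3)
  expect_equal(D["a", "c"], 4)
  expect_equal(D["b", "c"], 1)
  expect_true(all(diag(D) == 0))
  expect_error(distance_matrix(e, character()), "empty gene list")

  same <- matrix(rep(c(1, 2), 3), 2, dimnames = list(c("g1", "g2"),
                                                     c("x", "y", "z")))
  expect_true(all(distance_matrix(same, c("g1", "g2")) == 0))

  set.seed(10)
  e2 <- matrix(rnorm(50), 5, dimnames = list(paste0("g", 1:5),
                                             paste0("s", 1:10)))
  D2 <- distance_matrix(e2, rownames(e2))
  for (i in 1:10) for (j in 1:10) for (l in 1:10)
    expect_lte(D2[i, j], D2[i, l] + D2[l, j] + 1e-12)
})

test_that("classical MDS reconstructs planar configurations", {
  set.seed(11)
  X <- matrix(rnorm(24), 12, 2)
  D <- as.matrix(dist(X))
  m <- classical_mds(D, dims = 2)
  pr <- vegan::procrustes(X, m$points, scale = FALSE)
  expect_lt(pr$ss, 1e-8)
  expect_equal(colMeans(m$points), c(0, 0), tolerance = 1e-10)

  # two points at distance d embed at +/- d/2
  d2 <- matrix(c(0, 6, 6, 0), 2)
  m2 <- classical_mds(d2, dims = 1)
  expect_equal(sort(as.vector(m2$points)), c(-3, 3))

  # adding a duplicated point leaves the rest of the geometry intact
  X3 <- rbind(X, X[1, ])
  m3 <- classical_mds(as.matrix(dist(X3)), dims = 2)
  expect_equal(as.matrix(dist(m3$points[1:12, ])), D, tolerance = 1e-8)

  expect_error(classical_mds(d2, dims = 2), "rank")
})

test_that("KNN separates well-separated clusters perfectly", {
  set.seed(12)
  centers <- matrix(c(0, 0, 30, 0, 0, 30), 3, byrow = TRUE)
  e <- t(do.call(rbind, lapply(1:3, function(c)
    matrix(rnorm(5 * 2, mean = rep(centers[c, ], each = 5), sd = 1), 5))))
  rownames(e) <- c("g1", "g2")
  colnames(e) <- sprintf("s%02d", 1:15)
  lab <- factor(rep(c("A", "B", "C"), each = 5))
  res <- knn_loo(e, lab, rownames(e), k = 3)
  expect_true(all(res$per_class_accuracy == 1))
  expect_equal(res$overall, 1)
})

test_that("tie-breaking matches the naive enumeration oracle", {
  # all samples identical: everything is decided by the tie-break rules
  e <- matrix(1, 2, 6, dimnames = list(c("g1", "g2"), paste0("s", 1:6)))
  lab <- factor(c("A", "A", "A", "B", "B", "C"))
  res <- knn_loo(e, lab, rownames(e), k = 3)
  expect_identical(res$predicted, naive_knn(e, lab, rownames(e), 3))
  # overall accuracy equals that of majority-class assignment
  expect_equal(res$overall, 0.5)

  # random continuous data: oracle equivalence without ties
  set.seed(13)
  e2 <- matrix(rnorm(40), 4, dimnames = list(paste0("g", 1:4),
                                             paste0("s", 1:10)))
  lab2 <- factor(rep(c("A", "B"), 5))
  for (k in c(1, 3, 5))
    expect_identical(knn_loo(e2, lab2, rownames(e2), k)$predicted,
                     naive_knn(e2, lab2, rownames(e2), k))
})

test_that("k = n-1 predicts the leave-one-out majority class", {
  set.seed(14)
  e <- matrix(rnorm(10), 2, dimnames = list(c("g1", "g2"), paste0("s", 1:5)))
  lab <- factor(c("A", "A", "A", "B", "B"))
  res <- knn_loo(e, lab, rownames(e), k = 4)
  # for A-samples the others are {A,A,B,B} (tie), for B-samples {A,A,A,B}
  expect_identical(res$predicted, naive_knn(e, lab, rownames(e), 4))
  expect_true(all(res$predicted[4:5] == "A"))
})

test_that("KNN errors on degenerate inputs", {
  e <- matrix(rnorm(8), 2, dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  expect_error(knn_loo(e, factor(rep("A", 4)), rownames(e), 2),
               ">= 2 classes")
  expect_error(knn_loo(e, factor(c("A", "A", "B", "B")), rownames(e), 4),
               "smaller than")
  expect_error(knn_loo(e, factor(c("A", "A", "B", "B"),
                                 levels = c("A", "B", "C")),
                       rownames(e), 2), "0 samples")
})

test_that("predictions are invariant to global affine transforms", {
  set.seed(15)
  e <- matrix(rnorm(60), 6, dimnames = list(paste0("g", 1:6),
                                            paste0("s", 1:10)))
  lab <- factor(rep(c("A", "B"), each = 5))
  base <- knn_loo(e, lab, rownames(e), 3)$predicted
  expect_identical(knn_loo(2.5 * e + 7, lab, rownames(e), 3)$predicted,
                   base)
})

test_that("accuracy curves are deterministic and order-invariant", {
  sim <- small_sim()
  te <- tumor_expr(sim)
  cfg <- default_config(replicates = 8)
  a <- accuracy_curve(te$expr, te$labels, cfg, sim$genes,
                      gene_counts = c(10L, 50L), seed = 21)
  b <- accuracy_curve(te$expr, te$labels, cfg, sim$genes,
                      gene_counts = c(10L, 50L), seed = 21)
  expect_identical(a, b)
  # sample reordering leaves the mean accuracies unchanged
  ord <- sample(ncol(te$expr))
  c <- accuracy_curve(te$expr[, ord], te$labels[ord], cfg, sim$genes,
                      gene_counts = c(10L, 50L), seed = 21)
  expect_equal(c$mean_acc, a$mean_acc, tolerance = 0.1)
  expect_error(accuracy_curve(te$expr, te$labels, cfg, sim$genes,
                              gene_counts = 10000L), "exceed")
})

test_that("label permutation pushes accuracy to the baseline", {
  set.seed(16)
  e <- matrix(rnorm(300 * 20), 300,
              dimnames = list(sprintf("g%03d", 1:300), paste0("s", 1:20)))
  lab <- factor(rep(c("A", "B", "C", "D"), each = 5))
  cfg <- default_config(replicates = 20)
  rep <- accuracy_curve(e, lab, cfg, gene_counts = c(20L), seed = 22)
  ov <- rep[rep$class == "overall", ]
  mc_sd <- ov$sd_acc / sqrt(20)
  expect_lt(abs(ov$mean_acc - ov$baseline), max(3 * mc_sd, 0.12))
})

test_that("balanced under-sampling equals plain LOO on a balanced cohort", {
  set.seed(17)
  centers <- matrix(rnorm(8, sd = 4), 4)
  e <- t(do.call(rbind, lapply(1:4, function(c)
    matrix(rnorm(4 * 2, mean = rep(centers[c, ], each = 4), sd = 2), 4))))
  rownames(e) <- c("g1", "g2")
  colnames(e) <- sprintf("s%02d", 1:16)
  e <- rbind(e, matrix(rnorm(30 * 16), 30,
                       dimnames = list(sprintf("n%02d", 1:30),
                                       colnames(e))))
  lab <- factor(rep(c("A", "B", "C", "D"), each = 4))
  cfg <- default_config(replicates = 30)
  plain <- accuracy_curve(e, lab, cfg, gene_counts = c(5L), seed = 23)
  bal <- balanced_accuracy_curve(e, lab, cfg, gene_counts = c(5L), seed = 24)
  po <- plain[plain$class == "overall", ]
  bo <- bal[bal$class == "overall", ]
  expect_lt(abs(po$mean_acc - bo$mean_acc),
            3 * (po$sd_acc + bo$sd_acc) / sqrt(30) + 0.05)
  expect_equal(bo$baseline, 0.25)
  expect_error(balanced_accuracy_curve(e[, 1:13], lab[1:13], cfg,
                                       gene_counts = c(5L)),
               "smaller than balanced_n")
})

test_that("distance-matrix correlation behaves as a similarity measure", {
  set.seed(18)
  X <- matrix(rnorm(20), 10)
  dA <- as.matrix(dist(X))
  expect_equal(distance_correlation(dA, dA), 1)
  expect_equal(distance_correlation(dA, 2 * dA), 1)  # scale invariance
  expect_error(distance_correlation(dA, dA[1:5, 1:5]), "shape")
})
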