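# Shared fixtures: small simulated cohorts, cached so several test files
# can reuse them without re-simulating.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# moderate-size cohort with the default strong signal
small_sim <- function() {
  cached("small_sim", simulate_counts(sim_config(n_genes = 1200), seed = 101))
}

# pure-null cohort: no DE, no trisomies, no batch effects
null_sim <- function(n_genes = 800) {
  cached(paste0("null_sim", n_genes),
         simulate_counts(sim_config(n_genes = n_genes, frac_de = 0,
                                    trisomy_prob = 0, batch_sd = 0),
                         seed = 102))
}

tumor_expr <- function(sim) {
  e <- log_cpm(sim$counts)
  tumor <- sim$samples$group != "Control"
  list(expr = e[, tumor, drop = FALSE],
       labels = droplevels(factor(sim$samples$group[tumor])))
}

# two-group cohort (Control vs one subtype) with exact planted log2 fold
# changes; used as a consistency oracle for the GLM fits
two_group_counts <- function(beta, n_per_group = 15, phi = 0.1,
                             lib = 2e6, seed = 1, group = "HeH") {
  set.seed(seed)
  ng <- length(beta)
  q <- exp(stats::rnorm(ng, 0, 1)); q <- q / sum(q)
  mu_c <- lib * q
  counts <- cbind(
    matrix(stats::rnbinom(ng * n_per_group, mu = mu_c, size = 1 / phi), ng),
    matrix(stats::rnbinom(ng * n_per_group, mu = rep(mu_c * 2^beta,
                                                     n_per_group),
                          size = 1 / phi), ng))
  rownames(counts) <- sprintf("G%04d", seq_len(ng))
  colnames(counts) <- sprintf("S%03d", seq_len(2L * n_per_group))
  samples <- data.frame(
    id = colnames(counts),
    group = factor(rep(c("Control", group), each = n_per_group),
                   levels = c("HeH", "t(12;21)", "t(9;22)", "Other",
                              "Control")),
    batch = "b1", stringsAsFactors = FALSE)
  list(counts = counts, samples = samples)
}

# literal triple-loop implementation of the topological overlap formula
brute_tom <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  tom <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { tom[i, j] <- 1; next }
    s <- 0
    for (u in seq_len(n)) s <- s + a[i, u] * a[u, j]
    tom[i, j] <- (s + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tom
}

# adjusted Rand index between two partitions (closed form over the
# contingency table); independent of any clustering code under test
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
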