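#' Synthetic cohort configuration
#'
#' Defaults mirror the study cohort: 11 HeH, 22 t(12;21), 4 t(9;22) and 19
#' "Other" tumors plus 3 cord-blood controls; negative-binomial counts with
#' common dispersion 0.1; ~10% of genes differentially expressed in
#' leukemia with planted |log2FC| centered on 2, a quarter of them
#' subtype-specific; trisomies of the frequently-gained chromosomes in HeH
#' samples (probability 0.8 per chromosome per sample) acting
#' multiplicatively on the mean; two protocol-era batches with mild
#' log-scale effects; and promoter bivalency planted on leukemia-up genes
#' at 3.3x the 3.3% baseline.
#'
#' @param ... named overrides of any default field.
#' @return list of class `callsig_simconfig`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_genes = 5000L,
    biotype_proportions = c(protein_coding = 0.6, lncRNA = 0.3,
                            pseudogene = 0.1),
    n_samples = c("HeH" = 11L, "t(12;21)" = 22L, "t(9;22)" = 4L,
                  "Other" = 19L, "Control" = 3L),
    frac_de = 0.10,
    frac_specific = 0.25,
    log2fc_mean = 2,
    log2fc_sd = 0.5,
    phi = 0.1,
    phi_gene_sdlog = 0,
    libsize_meanlog = log(3e6),
    libsize_sdlog = 0.25,
    batch_sd = 0.1,
    batches = c("2000-01", "2005-01"),
    trisomy_prob = 0.8,
    heh_gained = c("4", "6", "10", "14", "17", "18", "21"),
    de_chrom_pool = NULL,
    bivalency_baseline = 0.033,
    bivalency_enrichment = 3.3,
    k27_baseline = 0.05,
    k27_enrichment = 3,
    k4_baseline = 0.5,
    k36_baseline = 0.2,
    k36_down = 0.7,
    tf_n = 15L,
    tf_peak_baseline = 0.10,
    tf_enrichment = 3,
    tf_n_targets = 150L,
    seed = 1L
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown sim config field(s): ",
                          paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  if (abs(sum(cfg$biotype_proportions) - 1) > 1e-8)
    stop("biotype_proportions must sum to 1")
  if (cfg$phi < 0) stop("dispersion phi must be >= 0")
  if (cfg$n_genes < 1 || sum(cfg$n_samples) < 2)
    stop("degenerate sim config: need >= 1 gene and >= 2 samples")
  structure(cfg, class = "callsig_simconfig")
}

TUMOR_GROUPS <- c("HeH", "t(12;21)", "t(9;22)", "Other")

#' Simulate a leukemia cohort with known ground truth
#'
#' Draws counts K_gs ~ NB(mean = L_s * q_g * 2^beta_{g,group(s)} *
#' (c_{s,chr(g)}/2) * 2^{b_{g,batch(s)}}, dispersion phi): library size
#' L_s log-normal, relative abundance q_g log-normal, planted log2 fold
#' changes beta per subtype-vs-control contrast, chromosomal copy number c
#' (3 for gained chromosomes in HeH samples, else 2) acting
#' multiplicatively, and per-gene batch effects b. Gene categories (null /
#' leukemia_up / leukemia_down / specific) and all planted parameters are
#' recorded in the returned truth object.
#'
#' @param cfg [sim_config()] list.
#' @param seed random seed (default `cfg$seed`).
#' @return list with elements `counts` (integer matrix), `samples`
#'   (sample table data.frame), `genes` (gene models) and `truth` (list:
#'   per-gene category, specific_subtype, planted_log2fc matrix with one
#'   column per tumor subtype, per-sample copy_number matrix, phi).
#' @export
simulate_counts <- function(cfg = sim_config(), seed = cfg$seed) {
  set.seed(seed)
  n <- as.integer(cfg$n_genes)
  ns <- cfg$n_samples
  if (n < 1L || sum(ns) < 2L) stop("degenerate sim config")

  ## gene models -------------------------------------------------------
  gene_id <- sprintf("G%05d", seq_len(n))
  biotype <- sample(names(cfg$biotype_proportions), n, replace = TRUE,
                    prob = cfg$biotype_proportions)
  chromosome <- sample(as.character(1:22), n, replace = TRUE)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  body_start <- sample.int(1e8L, n)
  body_len <- pmax(2000L, as.integer(round(stats::rlnorm(n, log(2e4), 0.8))))
  body_end <- body_start + body_len
  n_tss <- sample(1:3, n, replace = TRUE)
  tss <- lapply(seq_len(n), function(i) {
    anchor <- if (strand[i] == "-") body_end[i] - 1L else body_start[i]
    extra <- if (n_tss[i] > 1L) {
      off <- sample.int(max(2L, body_len[i] %/% 5L), n_tss[i] - 1L)
      if (strand[i] == "-") anchor - off else anchor + off
    } else integer()
    sort(unique(as.integer(c(anchor, extra))))
  })
  genes <- data.frame(gene_id = gene_id, biotype = biotype,
                      chromosome = chromosome, strand = strand,
                      body_start = body_start, body_end = body_end,
                      stringsAsFactors = FALSE)
  genes$tss <- tss
  rownames(genes) <- gene_id

  ## truth: categories and planted fold changes ------------------------
  n_de <- round(cfg$frac_de * n)
  de_idx <- sample.int(n, n_de)
  n_spec <- round(cfg$frac_specific * n_de)
  spec_idx <- if (n_spec > 0) de_idx[seq_len(n_spec)] else integer()
  leuk_idx <- setdiff(de_idx, spec_idx)
  category <- rep("null", n)
  specific_subtype <- rep(NA_character_, n)
  beta <- matrix(0, n, length(TUMOR_GROUPS),
                 dimnames = list(gene_id, TUMOR_GROUPS))
  if (length(leuk_idx)) {
    sgn <- sample(c(-1, 1), length(leuk_idx), replace = TRUE)
    mag <- abs(stats::rnorm(length(leuk_idx), cfg$log2fc_mean, cfg$log2fc_sd))
    beta[leuk_idx, ] <- sgn * mag
    category[leuk_idx] <- ifelse(sgn > 0, "leukemia_up", "leukemia_down")
  }
  if (length(spec_idx)) {
    sub <- rep(TUMOR_GROUPS, length.out = length(spec_idx))
    sgn <- sample(c(-1, 1), length(spec_idx), replace = TRUE)
    mag <- abs(stats::rnorm(length(spec_idx), cfg$log2fc_mean, cfg$log2fc_sd))
    for (j in seq_along(spec_idx))
      beta[spec_idx[j], sub[j]] <- sgn[j] * mag[j]
    category[spec_idx] <- "specific"
    specific_subtype[spec_idx] <- sub
  }
  if (!is.null(cfg$de_chrom_pool) && length(de_idx)) {
    pool <- as.character(cfg$de_chrom_pool)
    genes$chromosome[de_idx] <- sample(pool, length(de_idx), replace = TRUE)
  }

  ## samples ------------------------------------------------------------
  group <- factor(rep(names(ns), times = ns),
                  levels = c(TUMOR_GROUPS, "Control"))
  n_tot <- length(group)
  id <- sprintf("S%03d", seq_len(n_tot))
  batch <- sample(cfg$batches, n_tot, replace = TRUE)
  copy_number <- matrix(2L, n_tot, 22,
                        dimnames = list(id, as.character(1:22)))
  for (i in which(group == "HeH")) {
    gained <- cfg$heh_gained[stats::runif(length(cfg$heh_gained)) <
                               cfg$trisomy_prob]
    copy_number[i, gained] <- 3L
  }
  karyotype_gains <- lapply(seq_len(n_tot), function(i)
    colnames(copy_number)[copy_number[i, ] > 2L])
  is_tumor <- group != "Control"
  relapse <- is_tumor & stats::runif(n_tot) < 0.2
  death <- relapse & stats::runif(n_tot) < 0.5
  samples <- data.frame(
    id = id, group = group,
    sex = sample(c("F", "M"), n_tot, replace = TRUE),
    blast_rate = ifelse(is_tumor, round(stats::runif(n_tot, 70, 100), 1), NA),
    age_months = ifelse(is_tumor,
                        round(stats::rlnorm(n_tot, log(60), 0.5)), 0),
    dna_index = ifelse(group == "HeH",
                       round(1 + rowSums(copy_number - 2L) / 46, 2), 1),
    risk_group = ifelse(is_tumor,
                        sample(c("Standard", "High"), n_tot, replace = TRUE),
                        NA),
    batch = batch, stringsAsFactors = FALSE
  )
  samples$karyotype_gains <- karyotype_gains
  samples$events <- lapply(seq_len(n_tot), function(i)
    c(if (relapse[i]) "R", if (death[i]) "D"))

  ## counts --------------------------------------------------------------
  q <- exp(stats::rnorm(n, 0, 1.25)); q <- q / sum(q)
  L <- stats::rlnorm(n_tot, cfg$libsize_meanlog, cfg$libsize_sdlog)
  batch_eff <- matrix(0, n, length(cfg$batches),
                      dimnames = list(gene_id, cfg$batches))
  if (length(cfg$batches) > 1L && cfg$batch_sd > 0)
    batch_eff[, -1L] <- stats::rnorm(n * (length(cfg$batches) - 1L),
                                     0, cfg$batch_sd)
  phi_g <- if (cfg$phi_gene_sdlog > 0) {
    cfg$phi * exp(stats::rnorm(n, 0, cfg$phi_gene_sdlog) -
                    cfg$phi_gene_sdlog^2 / 2)
  } else rep(cfg$phi, n)
  chrom_idx <- match(genes$chromosome, as.character(1:22))
  counts <- matrix(0L, n, n_tot, dimnames = list(gene_id, id))
  for (s in seq_len(n_tot)) {
    b <- if (group[s] == "Control") 0 else beta[, as.character(group[s])]
    dose <- copy_number[s, chrom_idx] / 2
    mu <- L[s] * q * 2^(b + batch_eff[, match(batch[s], cfg$batches)]) * dose
    counts[, s] <- if (cfg$phi <= 1e-12 && cfg$phi_gene_sdlog == 0) {
      stats::rpois(n, mu)
    } else {
      stats::rnbinom(n, mu = mu, size = 1 / phi_g)
    }
  }

  truth <- list(category = stats::setNames(category, gene_id),
                specific_subtype = stats::setNames(specific_subtype, gene_id),
                planted_log2fc = beta,
                copy_number = copy_number,
                phi = stats::setNames(phi_g, gene_id),
                batch_effect = batch_eff,
                lib_size = stats::setNames(L, id))
  list(counts = counts, samples = samples, genes = genes, truth = truth)
}

place_peak <- function(chrom, anchor, half_width = 750L, jitter = 1000L) {
  center <- anchor + sample.int(2L * jitter + 1L, length(anchor),
                                replace = TRUE) - jitter - 1L
  start <- pmax(0L, as.integer(center - half_width))
  data.frame(chrom = chrom, start = start,
             end = as.integer(start + 2L * half_width),
             stringsAsFactors = FALSE)
}

#' Simulate histone-mark and transcription-factor peak tracks
#'
#' Plants the promoter chromatin structure the downstream enrichment
#' analyses look for: leukemia-up genes carry co-occurring H3K27me3 and
#' H3K4me3 TSS peaks (bivalency) at `bivalency_baseline *
#' bivalency_enrichment`, all other genes at the baseline rate;
#' leukemia-down genes carry H3K36me3 gene-body peaks at an elevated rate
#' (actively transcribed in the normal comparator); each simulated TF gets
#' TSS-window peaks at `tf_peak_baseline`, boosted `tf_enrichment`-fold on
#' its designated target genes. TFs are named after genes of the simulated
#' matrix so their own expression change is defined; roughly half are drawn
#' from leukemia-deregulated genes with deregulated targets.
#'
#' @param genes gene models from [simulate_counts()].
#' @param truth truth object from [simulate_counts()].
#' @param cfg [sim_config()] list.
#' @param seed random seed.
#' @return list with `marks` (named list of H3K27me3 / H3K4me3 / H3K36me3
#'   peak data.frames), `tfs` (named list of TF peak data.frames, names =
#'   TF gene ids), `bivalent` (named logical per gene) and `tf_targets`
#'   (named list of target gene-id vectors).
#' @export
simulate_peaks <- function(genes, truth, cfg = sim_config(),
                           seed = cfg$seed + 1L) {
  set.seed(seed)
  n <- nrow(genes)
  anchor <- vapply(seq_len(n), function(i) {
    t <- genes$tss[[i]]
    if (genes$strand[i] == "-") max(t) else min(t)
  }, integer(1L))
  up <- truth$category == "leukemia_up"
  down <- truth$category == "leukemia_down"

  p_biv <- ifelse(up, pmin(1, cfg$bivalency_baseline * cfg$bivalency_enrichment),
                  cfg$bivalency_baseline)
  bivalent <- stats::runif(n) < p_biv
  p_k27 <- ifelse(up, pmin(1, cfg$k27_baseline * cfg$k27_enrichment),
                  cfg$k27_baseline)
  k27_only <- !bivalent & stats::runif(n) < p_k27
  k4_only <- !bivalent & !k27_only & stats::runif(n) < cfg$k4_baseline

  k27_idx <- which(bivalent | k27_only)
  k4_idx <- which(bivalent | k4_only)
  marks <- list(
    H3K27me3 = place_peak(genes$chromosome[k27_idx], anchor[k27_idx]),
    H3K4me3 = place_peak(genes$chromosome[k4_idx], anchor[k4_idx])
  )
  p_k36 <- ifelse(down, cfg$k36_down, cfg$k36_baseline)
  k36_idx <- which(stats::runif(n) < p_k36)
  body_mid <- (genes$body_start[k36_idx] + genes$body_end[k36_idx]) %/% 2L
  marks$H3K36me3 <- data.frame(
    chrom = genes$chromosome[k36_idx],
    start = pmax(0L, body_mid - 1000L),
    end = body_mid + 1000L, stringsAsFactors = FALSE)

  de_ids <- names(truth$category)[up | down]
  tf_n <- min(cfg$tf_n, n)
  n_de_tf <- min(length(de_ids), ceiling(tf_n / 2))
  tf_ids <- c(sample(de_ids, n_de_tf),
              sample(setdiff(genes$gene_id, de_ids), tf_n - n_de_tf))
  tf_targets <- stats::setNames(vector("list", tf_n), tf_ids)
  tfs <- stats::setNames(vector("list", tf_n), tf_ids)
  for (j in seq_len(tf_n)) {
    deregulated_tf <- tf_ids[j] %in% de_ids
    pool <- if (deregulated_tf && length(de_ids) > 0) {
      de_ids
    } else genes$gene_id
    targ <- sample(pool, min(cfg$tf_n_targets, length(pool)))
    tf_targets[[j]] <- targ
    p <- ifelse(genes$gene_id %in% targ,
                pmin(1, cfg$tf_peak_baseline * cfg$tf_enrichment),
                cfg$tf_peak_baseline)
    idx <- which(stats::runif(n) < p)
    pk <- place_peak(genes$chromosome[idx], anchor[idx], half_width = 300L,
                     jitter = 2000L)
    pk$name <- tf_ids[j]
    pk$cells <- "SIMULATED"
    tfs[[j]] <- pk[order(pk$chrom, pk$start), ]
  }
  marks <- lapply(marks, function(p) {
    p <- p[order(p$chrom, p$start), ]; rownames(p) <- NULL; p
  })
  list(marks = marks, tfs = tfs,
       bivalent = stats::setNames(bivalent, genes$gene_id),
       tf_targets = tf_targets)
}

#' The packaged cohort characteristics table
#'
#' Returns the 56-patient cohort metadata table (subtype, sex, blast rate,
#' age, DNA index, karyotype gains, risk group, events, protocol era)
#' shipped with the package. Clinical shorthand in the karyotype column
#' that is not a chromosome name is silently dropped during parsing.
#'
#' @return sample-table data.frame (see [read_sample_table()]).
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1_cohort.tsv", package = "callsig")
  suppressWarnings(read_sample_table(path))
}

#' Write a simulated cohort to disk
#'
#' Writes counts (TSV), sample table (TSV), gene models (BED-like dialect)
#' and, when peaks are supplied, one BED per histone mark and TF, in the
#' same dialects the readers accept.
#'
#' @param sim result of [simulate_counts()].
#' @param dir output directory (created if needed).
#' @param peaks optional result of [simulate_peaks()].
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir, peaks = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(sim$counts, file.path(dir, "counts.tsv"))
  write_sample_table(sim$samples, file.path(dir, "samples.tsv"))
  write_gene_models(sim$genes, file.path(dir, "genes.tsv"))
  if (!is.null(peaks)) {
    for (m in names(peaks$marks))
      write_peaks(peaks$marks[[m]], file.path(dir, paste0(m, ".bed")))
    for (tf in names(peaks$tfs))
      write_peaks(peaks$tfs[[tf]], file.path(dir, paste0("TF_", tf, ".bed")))
  }
  invisible(dir)
}
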