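#' Default run configuration
#'
#' Returns the list of analysis thresholds and protocol parameters used
#' throughout the pipeline, with the study's defaults: FDR cutoff 1e-3 for
#' differential expression, log2FC cutoff 2 for the up/down promoter
#' categories, FDR > 0.5 defining "not DE", a 4-fold rule for subtype
#' specificity, 3-nearest-neighbor classification over 100 half-gene
#' subsamples, 500 top-variance genes for MDS, 5000 for co-expression,
#' a +/-5 kb TSS window, a 30 CPM floor for the dosage analysis, and the
#' chromosomes frequently gained in high-hyperdiploid (HeH) leukemia
#' (4, 6, 10, 14, 17, 18 and 21).
#'
#' @param ... named overrides of any default field.
#' @return A validated list of class `callsig_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    fdr_de = 1e-3,
    fdr_enrich = 0.1,
    logfc_updown = 2,
    fdr_notde = 0.5,
    subtype_fold = 4,
    knn_k = 3L,
    n_top_mds = 500L,
    n_top_wgcna = 5000L,
    replicates = 100L,
    gene_subsample_frac = 0.5,
    balanced_n = 4L,
    tss_window = 5000L,
    cpm_min_dosage = 30,
    heh_gained = c("4", "6", "10", "14", "17", "18", "21"),
    prior_count = 1,
    merge_dissimilarity = 0.25,
    soft_power = 6,
    min_module_size = 30L,
    dispersion_prior_df = 10
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  validate_config(cfg)
}

#' Validate a run configuration
#'
#' @param cfg a list as returned by [default_config()].
#' @return the config, invisibly classed `callsig_config`.
#' @export
validate_config <- function(cfg) {
  probs <- c("fdr_de", "fdr_enrich", "fdr_notde")
  for (p in probs) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v > 1)
      stop(p, " must be a probability in (0, 1]")
  }
  counts <- c("knn_k", "n_top_mds", "n_top_wgcna", "replicates", "balanced_n",
              "tss_window", "min_module_size")
  for (p in counts) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || v < 1)
      stop(p, " must be a count >= 1")
  }
  if (cfg$gene_subsample_frac <= 0 || cfg$gene_subsample_frac > 1)
    stop("gene_subsample_frac must be in (0, 1]")
  if (cfg$prior_count < 0) stop("prior_count must be non-negative")
  if (!all(cfg$heh_gained %in% as.character(1:22)))
    stop("heh_gained must be a subset of the autosome names 1..22")
  structure(cfg, class = "callsig_config")
}

#' Read a run configuration from YAML
#'
#' Fields present in the file override the defaults; everything else keeps
#' its default value.
#'
#' @param path YAML file.
#' @return validated `callsig_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  over <- yaml::read_yaml(path)
  if (is.null(over)) over <- list()
  do.call(default_config, over)
}

#' Derive a stage-specific child seed from a master seed
#'
#' One master seed drives the whole pipeline; each stage draws from its own
#' deterministic child so that re-running one stage does not perturb the
#' random streams of the others. The child is a fixed hash of the master
#' seed and the stage name, kept below 2^31.
#'
#' @param seed master seed (integer).
#' @param stage character stage name.
#' @return integer seed.
#' @export
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 1000003
  as.integer((abs(seed) %% 1000003) * 1009 + h * 7 + 1) %% 2147483647L
}

#' Write a JSON run manifest
#'
#' Records the configuration, seed, package version and R version of a run
#' so that outputs can be traced to their inputs.
#'
#' @param path output JSON file.
#' @param cfg `callsig_config` list.
#' @param seed master seed used.
#' @param extra optional named list of additional fields.
#' @export
write_manifest <- function(path, cfg, seed, extra = list()) {
  man <- c(list(
    package = "callsig",
    version = as.character(utils::packageVersion("callsig")),
    r_version = R.version.string,
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(cfg)
  ), extra)
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
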