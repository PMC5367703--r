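#' @importFrom utils read.delim write.table head packageVersion
NULL

GROUP_LEVELS <- c("HeH", "t(12;21)", "t(9;22)", "Other", "Control")
CHROM_NAMES <- c(as.character(1:22), "X", "Y")

# write a TSV with leading '#'-prefixed metadata lines
write_tsv_meta <- function(df, path, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta)) writeLines(paste0("# ", meta), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_meta <- function(path) {
  read.delim(path, comment.char = "#", check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' Read a gene-level count matrix from TSV
#'
#' First column holds gene ids, the header row holds sample ids, all other
#' cells are non-negative integer counts.
#'
#' @param path TSV file.
#' @return integer matrix, genes in rows (rownames = gene ids), samples in
#'   columns.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("count file not found: ", path)
  df <- read.delim(path, comment.char = "#", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("count matrix needs a gene-id column plus >=1 sample")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicated gene id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  for (j in seq_len(ncol(m))) {
    v <- suppressWarnings(as.numeric(m[, j]))
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad))
      stop(sprintf("non-integer count at row '%s', column '%s'",
                   ids[bad[1L]], colnames(m)[j]))
  }
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  m
}

#' Write a count matrix as TSV
#'
#' @param counts integer matrix with gene rownames and sample colnames.
#' @param path output file.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

parse_karyotype <- function(x) {
  lapply(x, function(cell) {
    if (is.na(cell)) return(character())
    cell <- trimws(cell)
    if (cell %in% c("", "-", "None", "none", "NA") ||
        grepl("^Not enough", cell, ignore.case = TRUE)) return(character())
    toks <- trimws(strsplit(cell, "[,; ]+")[[1L]])
    toks <- toks[nzchar(toks)]
    keep <- toks %in% CHROM_NAMES
    if (any(!keep))
      warning("dropping unparseable karyotype token(s): ",
              paste(toks[!keep], collapse = ", "), call. = FALSE)
    unique(toks[keep])
  })
}

normalize_group <- function(x) {
  x <- trimws(as.character(x))
  x[x %in% c("HHD", "HD", "HeH")] <- "HeH"
  bad <- setdiff(unique(x), GROUP_LEVELS)
  if (length(bad))
    stop("unknown subtype label(s): ", paste(bad, collapse = ", "),
         "; accepted: ", paste(c(GROUP_LEVELS, "HHD (alias of HeH)"),
                               collapse = ", "))
  factor(x, levels = GROUP_LEVELS)
}

#' Read a cohort sample table
#'
#' Expects the column layout of the study's cohort table: subtype, id, sex,
#' blast rate, age (months), DNA index, karyotype (comma-separated gained
#' chromosomes), prognostic risk group, events and treatment protocol. The
#' protocol era doubles as the batch factor. Karyotype tokens that are not
#' chromosome names (clinical shorthand such as "3?" or "21c") are dropped
#' with a warning. "HHD" is accepted as an alias of "HeH".
#'
#' @param path TSV file.
#' @return data.frame with columns id, group (factor), sex, blast_rate,
#'   age_months, dna_index, karyotype_gains (list of character vectors),
#'   risk_group, events (list of character vectors), batch.
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop("sample table not found: ", path)
  df <- read.delim(path, comment.char = "#", check.names = FALSE,
                   stringsAsFactors = FALSE, na.strings = c("NA", "-", ""))
  names(df) <- tolower(gsub("[^A-Za-z0-9]+", "_", names(df)))
  pick <- function(cands) {
    hit <- intersect(cands, names(df))
    if (length(hit)) df[[hit[1L]]] else rep(NA, nrow(df))
  }
  out <- data.frame(
    id = as.character(pick(c("id", "sample", "sample_id"))),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$id))
    stop("duplicated sample id(s): ",
         paste(unique(out$id[duplicated(out$id)]), collapse = ", "))
  out$group <- normalize_group(pick(c("subtype", "group")))
  sex <- toupper(trimws(as.character(pick(c("sex")))))
  sex[!sex %in% c("F", "M")] <- "unknown"
  out$sex <- sex
  out$blast_rate <- suppressWarnings(as.numeric(pick(c(
    "blast_rate", "blast_rate_", "blast_rate_percent"))))
  out$age_months <- suppressWarnings(as.numeric(pick(c(
    "age_months", "age"))))
  out$dna_index <- suppressWarnings(as.numeric(pick(c("dna_index"))))
  if (any(!is.na(out$dna_index) & out$dna_index <= 0))
    stop("dna_index must be positive where present")
  out$karyotype_gains <- parse_karyotype(as.character(pick(c("karyotype"))))
  out$risk_group <- as.character(pick(c(
    "prognostic_risk_group", "risk_group", "risk")))
  ev <- as.character(pick(c("events", "event")))
  out$events <- lapply(ev, function(e) {
    if (is.na(e)) return(character())
    toks <- trimws(strsplit(e, "[,; ]+")[[1L]])
    intersect(toks, c("R", "D"))
  })
  out$batch <- as.character(pick(c("dfci_protocol", "protocol", "batch")))
  out$batch[is.na(out$batch)] <- "unknown"
  ctrl_gain <- out$group == "Control" &
    vapply(out$karyotype_gains, length, 1L) > 0
  if (any(ctrl_gain))
    stop("Control samples must have empty karyotype gains: ",
         paste(out$id[ctrl_gain], collapse = ", "))
  out
}

#' Write a cohort sample table as TSV
#'
#' Inverse of [read_sample_table()] (column layout of the cohort table).
#'
#' @param samples data.frame as returned by [read_sample_table()].
#' @param path output file.
#' @export
write_sample_table <- function(samples, path) {
  df <- data.frame(
    Subtype = as.character(samples$group),
    ID = samples$id,
    Sex = samples$sex,
    `Blast Rate (%)` = samples$blast_rate,
    `Age (months)` = samples$age_months,
    `DNA Index` = samples$dna_index,
    Karyotype = vapply(samples$karyotype_gains, paste, "", collapse = ","),
    `Prognostic Risk Group` = samples$risk_group,
    Events = vapply(samples$events, paste, "", collapse = ","),
    `DFCI Protocol` = samples$batch,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read gene models from GTF or the package's BED-like dialect
#'
#' GTF input (1-based, closed intervals) is read through rtracklayer and
#' converted to the internal BED convention (0-based, half-open). TSS are
#' the 5' ends of transcript records, respecting strand; genes without a
#' biotype attribute are classified "other" with a warning. The BED-like
#' dialect has columns chrom, start, end, gene_id, biotype, strand,
#' tss_list (comma-separated 0-based positions).
#'
#' @param path `.gtf` file or BED-like TSV.
#' @return data.frame with columns gene_id, biotype, chromosome, strand,
#'   tss (list of integer positions, 0-based), body_start, body_end
#'   (0-based half-open).
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("gene model file not found: ", path)
  if (grepl("\\.(gtf|gff2?)$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "gtf")
    meta <- S4Vectors::mcols(gr)
    is_gene <- as.character(meta$type) == "gene"
    is_tx <- as.character(meta$type) == "transcript"
    g <- gr[is_gene]
    gm <- S4Vectors::mcols(g)
    biotype <- if ("gene_biotype" %in% names(gm)) {
      as.character(gm$gene_biotype)
    } else rep(NA_character_, length(g))
    if (anyNA(biotype)) {
      warning("gene(s) without biotype attribute classified as 'other'")
      biotype[is.na(biotype)] <- "other"
    }
    strand_g <- as.character(BiocGenerics::strand(g))
    out <- data.frame(
      gene_id = as.character(gm$gene_id),
      biotype = biotype,
      chromosome = as.character(GenomicRanges::seqnames(g)),
      strand = strand_g,
      body_start = BiocGenerics::start(g) - 1L,  # GTF 1-based -> BED
      body_end = BiocGenerics::end(g),
      stringsAsFactors = FALSE
    )
    tx <- gr[is_tx]
    txm <- S4Vectors::mcols(tx)
    tss1 <- ifelse(as.character(BiocGenerics::strand(tx)) == "-",
                   BiocGenerics::end(tx) - 1L,   # 0-based position of 5' base
                   BiocGenerics::start(tx) - 1L)
    tss_by_gene <- split(as.integer(tss1), as.character(txm$gene_id))
    out$tss <- lapply(out$gene_id, function(id) {
      v <- tss_by_gene[[id]]
      if (is.null(v)) {
        # no transcript record: gene 5' end stands in
        g1 <- out[out$gene_id == id, ]
        v <- if (g1$strand == "-") g1$body_end - 1L else g1$body_start
      }
      sort(unique(as.integer(v)))
    })
  } else {
    df <- read.delim(path, comment.char = "#", check.names = FALSE,
                     stringsAsFactors = FALSE)
    need <- c("chrom", "start", "end", "gene_id", "biotype", "strand")
    if (!all(need %in% names(df)))
      stop("BED-like gene model file needs columns: ",
           paste(need, collapse = ", "))
    out <- data.frame(
      gene_id = as.character(df$gene_id),
      biotype = as.character(df$biotype),
      chromosome = as.character(df$chrom),
      strand = as.character(df$strand),
      body_start = as.integer(df$start),
      body_end = as.integer(df$end),
      stringsAsFactors = FALSE
    )
    out$tss <- if ("tss_list" %in% names(df)) {
      lapply(strsplit(as.character(df$tss_list), ","),
             function(v) sort(unique(as.integer(v))))
    } else {
      lapply(seq_len(nrow(out)), function(i)
        if (out$strand[i] == "-") out$body_end[i] - 1L else out$body_start[i])
    }
  }
  if (anyDuplicated(out$gene_id))
    stop("duplicated gene id(s) in gene models")
  if (any(out$body_start >= out$body_end))
    stop("gene body intervals must satisfy start < end")
  if (any(vapply(out$tss, length, 1L) == 0L))
    stop("every gene needs at least one TSS")
  rownames(out) <- out$gene_id
  out
}

#' Write gene models in the BED-like dialect
#'
#' @param genes data.frame as returned by [read_gene_models()].
#' @param path output TSV.
#' @export
write_gene_models <- function(genes, path) {
  df <- data.frame(
    chrom = genes$chromosome,
    start = genes$body_start,
    end = genes$body_end,
    gene_id = genes$gene_id,
    biotype = genes$biotype,
    strand = genes$strand,
    tss_list = vapply(genes$tss, paste, "", collapse = ","),
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write gene models as GTF
#'
#' Emits one `gene` record per gene plus one `transcript` record per TSS
#' (transcript body spanning TSS to gene 3' end), converting the internal
#' 0-based half-open intervals to GTF's 1-based closed convention.
#'
#' @param genes gene model data.frame.
#' @param path output `.gtf`.
#' @export
write_gene_models_gtf <- function(genes, path) {
  recs <- list()
  n_tss <- vapply(genes$tss, length, 1L)
  gidx <- rep(seq_len(nrow(genes)), 1L + n_tss)
  type <- unlist(lapply(n_tss, function(k) c("gene", rep("transcript", k))))
  start0 <- integer(length(gidx)); end0 <- integer(length(gidx))
  tx_id <- rep(NA_character_, length(gidx))
  pos <- 1L
  for (i in seq_len(nrow(genes))) {
    start0[pos] <- genes$body_start[i]; end0[pos] <- genes$body_end[i]
    pos <- pos + 1L
    tss <- genes$tss[[i]]
    for (j in seq_along(tss)) {
      if (genes$strand[i] == "-") {
        start0[pos] <- genes$body_start[i]; end0[pos] <- tss[j] + 1L
      } else {
        start0[pos] <- tss[j]; end0[pos] <- genes$body_end[i]
      }
      tx_id[pos] <- paste0(genes$gene_id[i], ".t", j)
      pos <- pos + 1L
    }
  }
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chromosome[gidx],
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    strand = genes$strand[gidx]
  )
  S4Vectors::mcols(gr)$type <- type
  S4Vectors::mcols(gr)$gene_id <- genes$gene_id[gidx]
  S4Vectors::mcols(gr)$transcript_id <- tx_id
  S4Vectors::mcols(gr)$gene_biotype <- genes$biotype[gidx]
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read a peak file (BED, optionally with name and cell-type columns)
#'
#' Plain 3+-column BED gives unnamed intervals; a 5-column dialect
#' chrom/start/end/name/cells mirrors the UCSC clustered-TFBS-with-cells
#' layout (cells is a comma-separated list, carried but not interpreted).
#' Coordinates are kept in BED semantics (0-based, half-open).
#'
#' @param path BED file.
#' @param name optional peak-set name (mark or TF id) attached as attribute.
#' @return data.frame with columns chrom, start, end and optionally name,
#'   cells; sorted by chrom then start.
#' @export
read_peaks <- function(path, name = NULL) {
  if (!file.exists(path)) stop("peak file not found: ", path)
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("BED file needs >= 3 columns: ", path)
  out <- data.frame(chrom = as.character(df[[1L]]),
                    start = as.integer(df[[2L]]),
                    end = as.integer(df[[3L]]),
                    stringsAsFactors = FALSE)
  if (ncol(df) >= 4L) out$name <- as.character(df[[4L]])
  if (ncol(df) >= 5L) out$cells <- as.character(df[[5L]])
  if (any(out$start >= out$end)) stop("malformed interval (start >= end) in ", path)
  if (any(out$start < 0)) stop("negative coordinate in ", path)
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "peakset") <- name
  out
}

#' Write a peak set as BED
#'
#' @param peaks data.frame with chrom, start, end and optional name, cells.
#' @param path output file.
#' @export
write_peaks <- function(peaks, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "cells"), names(peaks))
  write.table(peaks[, cols, drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a differential-expression table as TSV
#'
#' @param de data.frame with columns gene, contrast, log2fc, pvalue, fdr
#'   (and optionally mean_logcpm).
#' @param path output file.
#' @param meta character vector of metadata lines (written '#'-prefixed).
#' @export
write_de_table <- function(de, path, meta = character()) {
  write_tsv_meta(de, path, meta)
}

#' Read a differential-expression table
#'
#' Accepts the package's own DE table layout or a minimal external table
#' with columns gene, log2fc, fdr (as used for cross-dataset comparison).
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_de_table <- function(path) {
  df <- read_tsv_meta(path)
  if (!all(c("gene", "log2fc") %in% names(df)))
    stop("DE table needs at least columns gene and log2fc")
  df
}
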