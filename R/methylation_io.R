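#' Read a per-CpG methylation matrix
#'
#' Two on-disk layouts are supported:
#' * `metilene_tsv` — a single TSV with header `chrom`, `pos`, then one
#'   beta column per sample; missing values written as `"."`.
#' * `bedgraph_dir` — a directory of per-sample bedGraph files
#'   (`chrom start end beta_percent [meth unmeth]`, methylation as a
#'   percentage); the sample id is the file name without extension and the
#'   CpG position is `start + 1`.
#'
#' Site order is normalized to sorted (chromosome, position) regardless of
#' input order.
#'
#' @param path File (metilene_tsv) or directory (bedgraph_dir).
#' @param fmt Input layout.
#' @return A [meth_matrix()].
#' @export
read_methylation_table <- function(path, fmt = c("metilene_tsv", "bedgraph_dir")) {
  fmt <- match.arg(fmt)
  if (!file.exists(path))
    epr_format_error("no such file or directory: %s", path)
  if (fmt == "metilene_tsv") read_metilene_tsv(path) else read_bedgraph_dir(path)
}

read_metilene_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = NULL)
  nm <- names(dt)
  if (length(nm) < 3L)
    epr_format_error("matrix TSV needs chrom, pos and >=1 sample column")
  if (nm[1] != "chrom")
    epr_format_error("malformed header: first column is '%s', expected 'chrom'", nm[1])
  if (nm[2] != "pos")
    epr_format_error("malformed header: second column is '%s', expected 'pos'", nm[2])
  pos <- suppressWarnings(as.integer(dt[[2]]))
  if (anyNA(pos))
    epr_format_error("non-integer position on line %d", which(is.na(pos))[1] + 1L)
  samples <- nm[-(1:2)]
  beta <- matrix(NA_real_, nrow(dt), length(samples),
                 dimnames = list(NULL, samples))
  for (j in seq_along(samples)) {
    raw <- dt[[j + 2L]]
    miss <- raw == "."
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(!miss & is.na(v))
    if (length(bad))
      epr_format_error("non-numeric value '%s' in column '%s' on line %d",
                       raw[bad[1]], samples[j], bad[1] + 1L)
    out <- which(!is.na(v) & (v < 0 | v > 1))
    if (length(out))
      epr_value_error("beta %s outside [0,1] in column '%s' on line %d",
                      raw[out[1]], samples[j], out[1] + 1L)
    v[miss] <- NA_real_
    beta[, j] <- v
  }
  key <- paste(dt[[1]], pos)
  if (anyDuplicated(key))
    epr_integrity_error("duplicate site %s", key[duplicated(key)][1])
  meth_matrix(dt[[1]], pos, beta)
}

read_bedgraph_dir <- function(path) {
  files <- list.files(path, pattern = "\\.(bedGraph|bedgraph|bg)(\\.gz)?$",
                      full.names = TRUE)
  if (!length(files))
    epr_format_error("no bedGraph files found in %s", path)
  per <- lapply(files, function(f) {
    dt <- data.table::fread(f, header = FALSE)
    if (ncol(dt) < 4L)
      epr_format_error("bedGraph %s has fewer than 4 columns", basename(f))
    names(dt)[1:4] <- c("chrom", "start", "end", "pct")
    if (any(dt$pct < 0 | dt$pct > 100))
      epr_value_error("methylation percentage outside [0,100] in %s", basename(f))
    out <- data.table::data.table(chrom = as.character(dt$chrom),
                                  pos = as.integer(dt$start) + 1L,
                                  beta = dt$pct / 100)
    if (ncol(dt) >= 6L) out$cov <- as.integer(dt[[5]]) + as.integer(dt[[6]])
    out
  })
  ids <- sub("\\.(bedGraph|bedgraph|bg)(\\.gz)?$", "", basename(files))
  sites <- unique(data.table::rbindlist(
    lapply(per, function(d) d[, c("chrom", "pos")])))
  data.table::setorder(sites, chrom, pos)
  key <- paste(sites$chrom, sites$pos)
  beta <- matrix(NA_real_, nrow(sites), length(ids),
                 dimnames = list(NULL, ids))
  has_cov <- all(vapply(per, function(d) "cov" %in% names(d), logical(1)))
  coverage <- if (has_cov) matrix(0L, nrow(sites), length(ids),
                                  dimnames = list(NULL, ids))
  for (j in seq_along(per)) {
    i <- match(paste(per[[j]]$chrom, per[[j]]$pos), key)
    beta[i, j] <- per[[j]]$beta
    if (has_cov) coverage[i, j] <- per[[j]]$cov
  }
  meth_matrix(sites$chrom, sites$pos, beta, coverage)
}

#' Write a methylation matrix as metilene-style TSV
#'
#' @param mat A [meth_matrix()].
#' @param path Output file; missing cells are written as `"."`.
#' @export
write_methylation_table <- function(mat, path) {
  dt <- data.table::data.table(chrom = mat$sites$chrom, pos = mat$sites$pos)
  dt <- cbind(dt, data.table::as.data.table(mat$beta))
  data.table::fwrite(dt, path, sep = "\t", na = ".", quote = FALSE)
  invisible(path)
}

#' Read / write BED region sets
#'
#' Standard BED3/BED4, 0-based half-open; `read_region_bed(write_region_bed(rs))`
#' is the identity (name-preserving for BED4). Parsing goes through
#' `rtracklayer`; a light pre-scan classifies the common failure modes
#' (non-numeric coordinates, start >= end).
#'
#' @param rs A [region_set()].
#' @param path BED file path.
#' @return `read_region_bed` returns a [region_set()].
#' @export
read_region_bed <- function(path) {
  if (!file.exists(path)) epr_format_error("no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  if (!length(lines)) return(region_set())
  fields <- strsplit(lines, "[ \t]+")
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 3L)
      epr_format_error("BED line %d has fewer than 3 fields", i)
    if (!grepl("^[0-9]+$", f[2]) || !grepl("^[0-9]+$", f[3]))
      epr_format_error("non-numeric coordinates on BED line %d", i)
    if (as.numeric(f[2]) >= as.numeric(f[3]))
      epr_integrity_error("BED line %d has start >= end", i)
  }
  gr <- rtracklayer::import(path, format = "BED")
  nm <- gr$name
  region_set(as.character(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
             name = if (!is.null(nm) && !all(is.na(nm))) nm)
}

#' @rdname read_region_bed
#' @export
write_region_bed <- function(rs, path) {
  rs <- as_region_set(rs)
  if (nrow(rs) == 0L) { file.create(path); return(invisible(path)) }
  gr <- regions_granges(rs)
  if ("name" %in% names(rs)) names(gr) <- rs$name
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read / write DMR tables
#'
#' TSV with columns `chrom`, `start`, `end`, `n_cpg`, `mean_delta_beta`,
#' `p_value`, `direction`, ordered by (chrom, start). [call_dmrs()] output
#' carries additional group-mean columns which are not persisted.
#'
#' @param dmrs A data.frame of DMRs (as returned by [call_dmrs()]).
#' @param path TSV file path.
#' @return `read_dmr_table` returns a data.frame with the seven columns.
#' @export
write_dmr_table <- function(dmrs, path) {
  cols <- c("chrom", "start", "end", "n_cpg", "mean_delta_beta",
            "p_value", "direction")
  dmrs <- as.data.frame(dmrs)
  missing_cols <- setdiff(cols, names(dmrs))
  if (length(missing_cols))
    epr_format_error("DMR table lacks column(s): %s",
                     paste(missing_cols, collapse = ", "))
  out <- dmrs[order(dmrs$chrom, dmrs$start), cols, drop = FALSE]
  ok <- tryCatch({
    data.table::fwrite(out, path, sep = "\t", quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    epr_format_error("failed writing DMR table to %s: %s",
                     path, conditionMessage(ok))
  invisible(path)
}

#' @rdname write_dmr_table
#' @export
read_dmr_table <- function(path) {
  if (!file.exists(path)) epr_format_error("no such file: %s", path)
  df <- data.table::setDF(data.table::fread(path, sep = "\t", header = TRUE))
  need <- c("chrom", "start", "end", "n_cpg", "mean_delta_beta",
            "p_value", "direction")
  if (!all(need %in% names(df)))
    epr_format_error("DMR table %s lacks required columns", path)
  df[order(df$chrom, df$start), need, drop = FALSE]
}

#' Read / write sample metadata tables
#'
#' TSV with columns `sample_id`, `sex` (female/male), `timepoint`
#' (postnatal day), `group` (sham/low/high/untreated), `tissue`
#' (retina/superior_colliculus/cfdna) and `pool_n` (1 for single animals,
#' 3-4 for pooled cfDNA libraries).
#'
#' @param meta A data.frame of per-sample annotations.
#' @param path TSV file path.
#' @return `read_sample_meta` returns a validated data.frame.
#' @export
read_sample_meta <- function(path) {
  if (!file.exists(path)) epr_format_error("no such file: %s", path)
  df <- data.table::setDF(data.table::fread(path, sep = "\t", header = TRUE))
  validate_sample_meta(df)
}

#' @rdname read_sample_meta
#' @export
write_sample_meta <- function(meta, path) {
  data.table::fwrite(validate_sample_meta(meta), path, sep = "\t",
                     quote = FALSE)
  invisible(path)
}

validate_sample_meta <- function(df) {
  df <- as.data.frame(df)
  need <- c("sample_id", "sex", "timepoint", "group", "tissue", "pool_n")
  if (!all(need %in% names(df)))
    epr_format_error("metadata lacks column(s): %s",
                     paste(setdiff(need, names(df)), collapse = ", "))
  if (anyDuplicated(df$sample_id))
    epr_integrity_error("duplicate sample_id in metadata")
  if (!all(df$sex %in% c("female", "male")))
    epr_value_error("sex must be 'female' or 'male'")
  if (!all(df$group %in% c("sham", "low", "high", "untreated")))
    epr_value_error("group must be sham/low/high/untreated")
  if (!all(df$tissue %in% c("retina", "superior_colliculus", "cfdna")))
    epr_value_error("tissue must be retina/superior_colliculus/cfdna")
  if (any(df$pool_n < 1))
    epr_value_error("pool_n must be a positive integer")
  df$timepoint <- as.integer(df$timepoint)
  df$pool_n <- as.integer(df$pool_n)
  df
}

#' Write a score report
#'
#' @param report A data.frame from [score_samples()] / [score_cfdna()].
#' @param path TSV file path.
#' @export
write_score_table <- function(report, path) {
  data.table::fwrite(as.data.frame(report)[, c("sample_id", "score",
                                               "n_regions_used")],
                     path, sep = "\t", quote = FALSE)
  invisible(path)
}
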