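#' Construct a per-CpG methylation matrix
#'
#' The central container: beta values (fraction methylated, in \[0,1\]) at a
#' set of genome-positioned CpG sites for a set of samples. Sites are
#' strand-collapsed single 1-based positions, stored sorted by
#' (chromosome, position) with no duplicates. Missing observations are `NA`;
#' if a coverage matrix is supplied, cells with zero coverage are forced
#' missing.
#'
#' @param chrom Character vector of chromosome names, one per site.
#' @param pos Integer vector of 1-based CpG positions.
#' @param beta Numeric matrix, sites x samples, values in \[0,1\] or `NA`.
#'   Column names are the sample ids.
#' @param coverage Optional non-negative integer matrix of the same shape.
#' @return An object of class `meth_matrix`: a list with elements `sites`
#'   (data.frame `chrom`, `pos`), `beta`, `coverage` (or `NULL`) and
#'   `samples`.
#' @export
meth_matrix <- function(chrom, pos, beta, coverage = NULL) {
  beta <- as.matrix(beta)
  if (is.null(colnames(beta)))
    epr_format_error("beta matrix must have sample ids as column names")
  if (length(chrom) != nrow(beta) || length(pos) != nrow(beta))
    epr_integrity_error("site vectors and beta matrix disagree on site count")
  sites <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                      stringsAsFactors = FALSE)
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  beta <- beta[ord, , drop = FALSE]
  if (!is.null(coverage)) {
    coverage <- as.matrix(coverage)[ord, , drop = FALSE]
    if (!identical(dim(coverage), dim(beta)))
      epr_integrity_error("coverage matrix shape differs from beta matrix")
    if (any(coverage < 0, na.rm = TRUE))
      epr_value_error("coverage must be non-negative")
    beta[!is.na(coverage) & coverage == 0] <- NA_real_
  }
  rownames(sites) <- NULL
  if (anyDuplicated(sites))
    epr_integrity_error("duplicate (chromosome, position) site")
  bad <- which(!is.na(beta) & (beta < 0 | beta > 1))
  if (length(bad))
    epr_value_error("beta value outside [0,1] at site row %d",
                    ((bad[1] - 1) %% nrow(beta)) + 1)
  structure(
    list(sites = sites, beta = beta, coverage = coverage,
         samples = colnames(beta)),
    class = "meth_matrix"
  )
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat(sprintf("meth_matrix: %d CpG sites x %d samples (%s)\n",
              nrow(x$sites), length(x$samples),
              if (is.null(x$coverage)) "no coverage" else "with coverage"))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(x$sites$chrom), collapse = ", ")))
  cat(sprintf("  missing cells: %.1f%%\n", 100 * mean(is.na(x$beta))))
  invisible(x)
}

#' @export
dim.meth_matrix <- function(x) dim(x$beta)

# GRanges of the CpG sites (1-bp ranges, harmonized seqlevels optional)
sites_granges <- function(mat, seqlevels = NULL) {
  lv <- if (is.null(seqlevels)) unique(mat$sites$chrom) else seqlevels
  GenomicRanges::GRanges(factor(mat$sites$chrom, levels = lv),
                         IRanges::IRanges(mat$sites$pos, mat$sites$pos))
}

sample_index <- function(mat, ids) {
  idx <- match(ids, mat$samples)
  if (anyNA(idx))
    epr_lookup_error("unknown sample id(s): %s",
                     paste(ids[is.na(idx)], collapse = ", "))
  idx
}

# beta with cells below min_coverage masked out
masked_beta <- function(mat, min_coverage = 1L) {
  b <- mat$beta
  if (!is.null(mat$coverage) && min_coverage > 0)
    b[mat$coverage < min_coverage] <- NA_real_
  b
}

#' Per-region, per-sample mean beta values
#'
#' For each region, the unweighted mean beta over the region's CpGs (a CpG
#' at 1-based position p belongs to a 0-based half-open region \[s,e) iff
#' s <= p-1 < e), per sample, skipping missing cells. Regions with no
#' retained CpG for a sample yield `NA`.
#'
#' @param mat A [meth_matrix()].
#' @param regions A [region_set()] or data.frame with `chrom`, `start`,
#'   `end` (0-based half-open).
#' @param samples Optional character vector restricting the columns.
#' @param min_coverage Cells below this coverage are treated as missing
#'   (ignored when `mat` has no coverage).
#' @return Numeric matrix, regions x samples.
#' @export
compute_region_means <- function(mat, regions, samples = NULL,
                                 min_coverage = 1L) {
  regions <- as.data.frame(regions)
  cols <- if (is.null(samples)) seq_along(mat$samples)
          else sample_index(mat, samples)
  b <- masked_beta(mat, min_coverage)[, cols, drop = FALSE]
  out <- matrix(NA_real_, nrow(regions), ncol(b),
                dimnames = list(NULL, mat$samples[cols]))
  if (nrow(regions) == 0L) return(out)
  lv <- union(unique(mat$sites$chrom), unique(regions$chrom))
  gr_sites <- sites_granges(mat, lv)
  gr_reg <- GenomicRanges::GRanges(
    factor(regions$chrom, levels = lv),
    IRanges::IRanges(regions$start + 1L, regions$end))
  ov <- GenomicRanges::findOverlaps(gr_reg, gr_sites)
  if (length(ov) == 0L) return(out)
  q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
  for (j in seq_len(ncol(b))) {
    v <- b[s, j]
    keep <- !is.na(v)
    if (!any(keep)) next
    sums <- rowsum(v[keep], q[keep])
    ns <- rowsum(rep(1, sum(keep)), q[keep])
    out[as.integer(rownames(sums)), j] <- sums / ns
  }
  out
}
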