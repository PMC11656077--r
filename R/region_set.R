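#' Construct a genomic region set
#'
#' A sorted set of 0-based half-open genomic intervals (the BED convention),
#' optionally named. Used for CpG islands, truth regions, signatures and
#' any other BED-backed content.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors, 0-based half-open (`start < end`).
#' @param name Optional character vector of region names.
#' @return A data.frame of class `region_set` with columns `chrom`,
#'   `start`, `end` and (if named) `name`, sorted by (chrom, start, end).
#' @export
region_set <- function(chrom = character(), start = integer(),
                       end = integer(), name = NULL) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- as.character(name)
  as_region_set(df)
}

#' Coerce a data.frame to a region_set
#'
#' Validates coordinates (`start < end`), sorts canonically and stamps the
#' `region_set` class. Extra columns (e.g. `direction`) are preserved.
#'
#' @param df A data.frame with at least `chrom`, `start`, `end`.
#' @return A `region_set`.
#' @export
as_region_set <- function(df) {
  df <- as.data.frame(df)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(df)))
    epr_format_error("region set requires columns chrom, start, end")
  if (nrow(df)) {
    if (any(!is.finite(df$start)) || any(!is.finite(df$end)))
      epr_format_error("non-numeric region coordinates")
    if (any(df$start >= df$end))
      epr_integrity_error("region with start >= end (row %d)",
                          which(df$start >= df$end)[1])
  }
  df$chrom <- as.character(df$chrom)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("region_set", "data.frame")
  df
}

# region_set (or compatible df) -> GRanges (1-based closed, as GRanges wants)
regions_granges <- function(rs, seqlevels = NULL) {
  rs <- as.data.frame(rs)
  lv <- if (is.null(seqlevels)) unique(rs$chrom) else seqlevels
  GenomicRanges::GRanges(factor(rs$chrom, levels = lv),
                         IRanges::IRanges(rs$start + 1L, rs$end))
}

# Two GRanges on a harmonized seqlevel set (avoids seqlevel warnings)
granges_pair <- function(a, b) {
  a <- as.data.frame(a); b <- as.data.frame(b)
  lv <- union(unique(a$chrom), unique(b$chrom))
  list(regions_granges(a, lv), regions_granges(b, lv))
}
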