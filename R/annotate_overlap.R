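#' Overlap between two region sets
#'
#' Region-wise overlap: the statistics count distinct regions with at
#' least one partner (the convention behind "x% of DMRs were also found
#' in ..."), not overlapping base pairs. The search is the sorted
#' interval-tree overlap of `GenomicRanges`.
#'
#' @param a,b [region_set()]s (or data.frames with `chrom`, `start`, `end`).
#' @param min_overlap_bp Minimum shared base pairs (default 1).
#' @return A list with `pairs` (data.frame of overlapping index pairs
#'   `a_idx`, `b_idx` plus coordinates) and `stats`, an `overlap_stats`
#'   list: `n_a`, `n_b`, `n_shared_a`, `n_shared_b`, `pct_a_shared`,
#'   `pct_b_shared`, `jaccard` (shared regions over the union of regions).
#'   Percentages are exact; rounding to one decimal happens only in
#'   printing/reporting.
#' @export
intersect_regions <- function(a, b, min_overlap_bp = 1L) {
  a <- as.data.frame(a); b <- as.data.frame(b)
  gp <- granges_pair(a, b)
  ov <- GenomicRanges::findOverlaps(gp[[1]], gp[[2]],
                                    minoverlap = min_overlap_bp)
  q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
  pairs <- data.frame(a_idx = q, b_idx = s,
                      a_chrom = a$chrom[q], a_start = a$start[q],
                      a_end = a$end[q], b_start = b$start[s],
                      b_end = b$end[s], stringsAsFactors = FALSE)
  n_sa <- length(unique(q)); n_sb <- length(unique(s))
  stats <- structure(list(
    n_a = nrow(a), n_b = nrow(b),
    n_shared_a = n_sa, n_shared_b = n_sb,
    pct_a_shared = if (nrow(a)) 100 * n_sa / nrow(a) else 0,
    pct_b_shared = if (nrow(b)) 100 * n_sb / nrow(b) else 0,
    jaccard = if (nrow(a) + nrow(b)) (n_sa + n_sb) / (nrow(a) + nrow(b))
              else 0), class = "overlap_stats")
  list(pairs = pairs, stats = stats)
}

#' @export
print.overlap_stats <- function(x, ...) {
  cat(sprintf("overlap: %d/%d A regions (%.1f%%), %d/%d B regions (%.1f%%), jaccard %.3f\n",
              x$n_shared_a, x$n_a, x$pct_a_shared,
              x$n_shared_b, x$n_b, x$pct_b_shared, x$jaccard))
  invisible(x)
}

#' CpG-context annotation of regions
#'
#' Labels each region `island` (>= 1 bp overlap with a CpG island),
#' `shore` (within `shore_bp` of an island), `shelf` (within
#' `shore_bp + shelf_bp`) or `open_sea`, with that precedence, so every
#' region gets exactly one label. `collapse = TRUE` folds shores and
#' shelves into `open_sea`, reproducing a two-bucket island/open-sea
#' summary.
#'
#' @param regions A [region_set()] of regions (e.g. DMRs).
#' @param islands A [region_set()] of CpG islands (any genome build).
#' @param shore_bp,shelf_bp Flank widths, default the conventional 2 kb
#'   each.
#' @param collapse Collapse shore/shelf into open_sea.
#' @return A list with `context` (character vector, one label per region)
#'   and `summary` (named fractions per label).
#' @export
annotate_cpg_context <- function(regions, islands, shore_bp = 2000L,
                                 shelf_bp = 2000L, collapse = FALSE) {
  regions <- as.data.frame(regions); islands <- as.data.frame(islands)
  labels <- rep("open_sea", nrow(regions))
  if (!nrow(islands)) {
    warning("empty island set: all regions labeled open_sea")
  } else if (nrow(regions)) {
    gp <- granges_pair(regions, islands)
    d <- GenomicRanges::distanceToNearest(gp[[1]], gp[[2]])
    dist <- rep(NA_real_, nrow(regions))
    dist[S4Vectors::queryHits(d)] <- as.data.frame(d)$distance
    labels[!is.na(dist) & dist <= shore_bp + shelf_bp] <- "shelf"
    labels[!is.na(dist) & dist <= shore_bp] <- "shore"
    labels[!is.na(dist) & dist == 0 &
             GenomicRanges::countOverlaps(gp[[1]], gp[[2]]) > 0] <- "island"
  }
  if (collapse) labels[labels %in% c("shore", "shelf")] <- "open_sea"
  lvls <- if (collapse) c("island", "open_sea")
          else c("island", "shore", "shelf", "open_sea")
  summary <- if (nrow(regions))
    table(factor(labels, levels = lvls)) / nrow(regions)
  else setNames(rep(0, length(lvls)), lvls)
  list(context = labels, summary = c(summary))
}

#' Overlap statistics for two name sets
#'
#' Exact Venn arithmetic on, for example, pathway name lists. Names are
#' case-normalized (lower-cased, trimmed) and deduplicated before the
#' intersection. Percentages are exact; one-decimal rounding is a
#' reporting convention only.
#'
#' @param list_a,list_b Character vectors of names.
#' @return An `overlap_stats` list as in [intersect_regions()], where
#'   `n_shared_a == n_shared_b == |A` \eqn{\cap} `B|` and `jaccard` is the
#'   usual set Jaccard index.
#' @export
set_overlap_stats <- function(list_a, list_b) {
  a <- unique(trimws(tolower(as.character(list_a))))
  b <- unique(trimws(tolower(as.character(list_b))))
  shared <- length(intersect(a, b))
  structure(list(
    n_a = length(a), n_b = length(b),
    n_shared_a = shared, n_shared_b = shared,
    pct_a_shared = if (length(a)) 100 * shared / length(a) else 0,
    pct_b_shared = if (length(b)) 100 * shared / length(b) else 0,
    jaccard = if (length(union(a, b))) shared / length(union(a, b)) else 0),
    class = "overlap_stats")
}

#' Hierarchical clustering of samples
#'
#' Manhattan distance with Ward linkage (`hclust` method `"ward.D2"`), the
#' combination used for the methylation heatmaps. Missing cells are
#' handled pairwise-complete: `stats::dist` sums |differences| over the
#' sites both samples observe and rescales to the full site count. A pair
#' of samples with no commonly observed site has no defined distance and
#' is reported as an error.
#'
#' @param x A [meth_matrix()], or a numeric matrix with samples as
#'   columns (e.g. a delta-beta table).
#' @param k Optional number of flat clusters to cut.
#' @return A list with `hclust` (the dendrogram), `dist`, and `labels`
#'   (named cluster assignment, `NULL` when `k` is missing).
#' @export
cluster_samples <- function(x, k = NULL) {
  m <- if (inherits(x, "meth_matrix")) x$beta else as.matrix(x)
  if (ncol(m) < 2L) epr_config_error("need at least two samples to cluster")
  d <- stats::dist(t(m), method = "manhattan")
  if (anyNA(d)) {
    dm <- as.matrix(d)
    bad <- which(is.na(dm) & upper.tri(dm), arr.ind = TRUE)
    epr_integrity_error(
      "no commonly observed sites for sample pair(s): %s",
      paste(sprintf("%s/%s", rownames(dm)[bad[, 1]],
                    colnames(dm)[bad[, 2]]), collapse = ", "))
  }
  hc <- stats::hclust(d, method = "ward.D2")
  list(hclust = hc, dist = d,
       labels = if (!is.null(k)) stats::cutree(hc, k = k))
}
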