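#' Parameters for DMR calling
#'
#' Defaults follow common practice for metilene-style callers: regions of
#' at least 10 CpGs with consecutive CpGs at most 300 bp apart, an absolute
#' mean delta-beta of at least 0.1, and a raw Mann-Whitney p-value below
#' 0.05. No multiple-testing correction is applied by default (the
#' significance filter is a raw p < alpha gate); Benjamini-Hochberg
#' adjustment across candidates is available via `adjust = "BH"`.
#'
#' @param min_cpgs Minimum CpGs per DMR.
#' @param max_gap Maximum distance (bp) between consecutive CpGs in a run.
#' @param min_abs_delta Minimum |mean delta-beta| of an emitted region.
#' @param alpha Significance level of the Mann-Whitney gate.
#' @param min_coverage Per-cell coverage below which a beta is treated as
#'   missing.
#' @param min_samples_per_group Minimum non-missing samples per group for a
#'   CpG to be retained.
#' @param adjust `"none"` (raw p, the default) or `"BH"`.
#' @return A list of class `dmr_params`.
#' @export
dmr_params <- function(min_cpgs = 10L, max_gap = 300L, min_abs_delta = 0.1,
                       alpha = 0.05, min_coverage = 1L,
                       min_samples_per_group = 2L,
                       adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (alpha <= 0 || alpha >= 1) epr_config_error("alpha must lie in (0,1)")
  if (min_cpgs < 2L) epr_config_error("min_cpgs must be >= 2")
  structure(list(min_cpgs = as.integer(min_cpgs),
                 max_gap = as.integer(max_gap),
                 min_abs_delta = min_abs_delta, alpha = alpha,
                 min_coverage = as.integer(min_coverage),
                 min_samples_per_group = as.integer(min_samples_per_group),
                 adjust = adjust),
            class = "dmr_params")
}

# Per-CpG group means and the retained-site filter shared by the caller.
group_cpg_means <- function(mat, group_a, group_b, params) {
  ia <- sample_index(mat, group_a)
  ib <- sample_index(mat, group_b)
  if (length(intersect(ia, ib)))
    epr_config_error("groups must be disjoint")
  if (!length(ia) || !length(ib))
    epr_config_error("both groups must be non-empty")
  b <- masked_beta(mat, params$min_coverage)
  ba <- b[, ia, drop = FALSE]; bb <- b[, ib, drop = FALSE]
  na <- rowSums(!is.na(ba)); nb <- rowSums(!is.na(bb))
  keep <- na >= params$min_samples_per_group &
          nb >= params$min_samples_per_group
  list(mean_a = rowMeans(ba, na.rm = TRUE),
       mean_b = rowMeans(bb, na.rm = TRUE),
       keep = keep)
}

#' Segment candidate regions between two groups
#'
#' A documented greedy segmentation standing in for metilene's internal
#' pre-segmentation. CpGs are filtered (coverage, minimum non-missing
#' samples per group), then grouped into maximal runs in which consecutive
#' retained CpGs are at most `max_gap` bp apart. Within a run, maximal
#' stretches of CpGs whose per-CpG group-mean difference shares one sign
#' form the candidate seeds; each seed is trimmed from whichever edge has
#' the weaker |delta| while its |mean delta-beta| is below `min_abs_delta`,
#' and emitted if at least `min_cpgs` CpGs survive with |mean delta-beta|
#' at or above the threshold. With `min_abs_delta = 0` every same-sign
#' stretch of sufficient length is emitted. Candidates are non-overlapping
#' and produced deterministically left to right; the procedure is
#' antisymmetric under swapping the groups.
#'
#' @param mat A [meth_matrix()].
#' @param group_a,group_b Disjoint character vectors of sample ids
#'   (`group_a` is the reference).
#' @param params A [dmr_params()].
#' @return A data.frame with one row per candidate (`chrom`, `start`,
#'   `end`, `n_cpg`, `mean_beta_a`, `mean_beta_b`, `mean_delta_beta`) and a
#'   list attribute `"cpg_means"` holding, per candidate, the per-CpG group
#'   mean vectors used downstream by the rank test.
#' @export
segment_candidates <- function(mat, group_a, group_b, params = dmr_params()) {
  gm <- group_cpg_means(mat, group_a, group_b, params)
  idx <- which(gm$keep)
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_cpg = integer(),
                      mean_beta_a = numeric(), mean_beta_b = numeric(),
                      mean_delta_beta = numeric())
  attr(empty, "cpg_means") <- list()
  if (!length(idx)) return(empty)

  chrom <- mat$sites$chrom[idx]; pos <- mat$sites$pos[idx]
  d <- gm$mean_b[idx] - gm$mean_a[idx]
  new_run <- c(TRUE, chrom[-1] != chrom[-length(chrom)] |
                      diff(pos) > params$max_gap)
  run_id <- cumsum(new_run)

  cands <- list(); means <- list()
  for (r in unique(run_id)) {
    w <- which(run_id == r)
    s <- sign(d[w])
    rl <- rle(s)
    stop_at <- cumsum(rl$lengths); start_at <- c(1L, head(stop_at, -1) + 1L)
    for (k in seq_along(rl$lengths)) {
      if (rl$values[k] == 0 && params$min_abs_delta > 0) next
      win <- w[start_at[k]:stop_at[k]]
      # trim the weaker edge while the window mean is under the threshold
      while (length(win) >= params$min_cpgs &&
             abs(mean(d[win])) < params$min_abs_delta) {
        if (abs(d[win[1]]) < abs(d[win[length(win)]]))
          win <- win[-1]
        else win <- win[-length(win)]
      }
      if (length(win) < params$min_cpgs) next
      if (abs(mean(d[win])) < params$min_abs_delta) next
      cands[[length(cands) + 1L]] <- data.frame(
        chrom = chrom[win[1]],
        start = pos[win[1]] - 1L, end = pos[win[length(win)]],
        n_cpg = length(win),
        mean_beta_a = mean(gm$mean_a[idx][win]),
        mean_beta_b = mean(gm$mean_b[idx][win]),
        mean_delta_beta = mean(d[win]), stringsAsFactors = FALSE)
      means[[length(means) + 1L]] <- list(a = gm$mean_a[idx][win],
                                          b = gm$mean_b[idx][win])
    }
  }
  if (!length(cands)) return(empty)
  out <- do.call(rbind, cands)
  ord <- order(out$chrom, out$start)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cpg_means") <- means[ord]
  out
}

# Two-sided Mann-Whitney U on two numeric vectors: exact enumeration for
# combined n <= exact_max_n without ties, otherwise the normal
# approximation with midrank tie correction and no continuity correction.
mwu_p <- function(x, y, exact_max_n = 12L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) return(NA_real_)
  use_exact <- (length(x) + length(y)) <= exact_max_n &&
    !anyDuplicated(c(x, y))
  p <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = use_exact, correct = FALSE)$p.value)
  if (!is.finite(p)) p <- 1 # degenerate: zero rank variance (all values tied)
  min(p, 1)
}

#' Mann-Whitney U test over a region's CpGs
#'
#' Compares the vector of per-CpG `group_a` means against the vector of
#' per-CpG `group_b` means over the CpGs of `region`, two-sided. The exact
#' null distribution is used for combined n of at most 12 without ties;
#' otherwise the normal approximation with tie correction.
#'
#' @param mat A [meth_matrix()].
#' @param region A one-row data.frame (or list) with `chrom`, `start`,
#'   `end` (0-based half-open).
#' @param group_a,group_b Disjoint sample-id vectors.
#' @param params A [dmr_params()] (coverage / retention filters).
#' @return The two-sided p-value, or `NA` if the region has no testable
#'   CpG in one of the groups.
#' @export
test_region_mwu <- function(mat, region, group_a, group_b,
                            params = dmr_params()) {
  gm <- group_cpg_means(mat, group_a, group_b, params)
  in_reg <- mat$sites$chrom == region$chrom &
    mat$sites$pos - 1L >= region$start & mat$sites$pos - 1L < region$end
  idx <- which(in_reg & gm$keep)
  if (!length(idx)) return(NA_real_)
  mwu_p(gm$mean_a[idx], gm$mean_b[idx])
}

#' Call differentially methylated regions between two groups
#'
#' Runs [segment_candidates()], applies the two-sided Mann-Whitney U test
#' to each candidate's per-CpG group-mean vectors, and retains candidates
#' with `p < alpha` and `|mean delta-beta| >= min_abs_delta`. Direction is
#' `"hyper"` when `group_b` is more methylated than the reference
#' `group_a`, `"hypo"` otherwise.
#'
#' @inheritParams segment_candidates
#' @return A data.frame sorted by (chrom, start) with columns `chrom`,
#'   `start`, `end`, `n_cpg`, `mean_beta_a`, `mean_beta_b`,
#'   `mean_delta_beta`, `p_value`, `direction`.
#' @export
call_dmrs <- function(mat, group_a, group_b, params = dmr_params()) {
  cand <- segment_candidates(mat, group_a, group_b, params)
  means <- attr(cand, "cpg_means")
  if (!nrow(cand)) {
    cand$p_value <- numeric(); cand$direction <- character()
    return(cand)
  }
  cand$p_value <- vapply(means, function(m) mwu_p(m$a, m$b), numeric(1))
  drop_untestable <- is.na(cand$p_value)
  if (any(drop_untestable))
    message(sprintf("dropping %d untestable candidate region(s)",
                    sum(drop_untestable)))
  cand <- cand[!drop_untestable, , drop = FALSE]
  p_gate <- if (params$adjust == "BH")
    stats::p.adjust(cand$p_value, "BH") else cand$p_value
  keep <- p_gate < params$alpha &
    abs(cand$mean_delta_beta) >= params$min_abs_delta
  out <- cand[keep, , drop = FALSE]
  out$direction <- ifelse(out$mean_delta_beta > 0, "hyper", "hypo")
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  attr(out, "cpg_means") <- NULL
  rownames(out) <- NULL
  out
}
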