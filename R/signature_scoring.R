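#' Derive the disease/treatment DMR signature
#'
#' The signature is the set of disease-progression DMRs (reference P21 vs
#' degenerate P60, untreated animals) that are also touched by treatment:
#' a degeneration DMR is retained iff it overlaps at least one treatment
#' DMR by `min_overlap_bp` or more. Coordinates and the hyper/hypo label
#' (direction of the P21 to P60 change) come from the degeneration DMR.
#' Signatures are sex-specific: both DMR sets must come from the same sex.
#'
#' @param degeneration_dmrs DMR data.frame from the P21-vs-P60 untreated
#'   comparison ([call_dmrs()] output).
#' @param treatment_dmrs DMR data.frame from a sham-vs-treated comparison.
#' @param sex Optional sex label ("female"/"male") stamped on the result.
#' @param min_overlap_bp Minimum overlap in bp (default 1).
#' @return A [region_set()] with a `direction` column and attribute `sex`;
#'   empty (with a warning) when the DMR sets do not intersect.
#' @export
derive_signature <- function(degeneration_dmrs, treatment_dmrs, sex = NULL,
                             min_overlap_bp = 1L) {
  deg <- as.data.frame(degeneration_dmrs)
  trt <- as.data.frame(treatment_dmrs)
  if (!nrow(deg) || !nrow(trt)) {
    warning("empty signature: one of the DMR sets is empty")
    out <- region_set()
    out$direction <- character(0)
    attr(out, "sex") <- sex
    return(out)
  }
  gp <- granges_pair(deg, trt)
  ov <- GenomicRanges::findOverlaps(gp[[1]], gp[[2]],
                                    minoverlap = min_overlap_bp)
  hit <- sort(unique(S4Vectors::queryHits(ov)))
  if (!length(hit)) warning("empty signature: no overlapping DMRs")
  out <- deg[hit, c("chrom", "start", "end", "direction"), drop = FALSE]
  out <- unique(out)
  out <- as_region_set(out)
  attr(out, "sex") <- sex
  out
}

#' Compute P21/P60 anchor means for a signature
#'
#' For each signature region the anchors are the unweighted mean beta over
#' the region's CpGs, then over the anchor samples: `anchor_p21` from the
#' pre-degenerate untreated group and `anchor_p60` from the degenerate
#' untreated group. Regions whose computed anchors contradict their
#' direction label, or whose anchor span `|anchor_p60 - anchor_p21|` is
#' below `min_anchor_span`, are dropped with a message (never silently
#' imputed).
#'
#' @param regions Signature regions ([derive_signature()] output, or any
#'   region data.frame with a `direction` column).
#' @param mat A [meth_matrix()].
#' @param p21_samples,p60_samples Non-empty sample-id vectors of the
#'   untreated anchor cohorts.
#' @param min_coverage Coverage filter for region means.
#' @param min_anchor_span Minimum |anchor difference| (default 0.01), a
#'   guard against near-degenerate normalization denominators.
#' @return A data.frame of class `epi_signature` with columns `chrom`,
#'   `start`, `end`, `direction`, `anchor_p21`, `anchor_p60`; attributes
#'   `sex` (carried over) and `dropped` (data.frame of removed regions and
#'   reasons).
#' @export
compute_anchors <- function(regions, mat, p21_samples, p60_samples,
                            min_coverage = 1L, min_anchor_span = 0.01) {
  if (!length(p21_samples) || !length(p60_samples))
    epr_config_error("both anchor groups must be non-empty")
  regions <- as.data.frame(regions)
  if (!"direction" %in% names(regions))
    epr_format_error("signature regions need a 'direction' column")
  rm21 <- compute_region_means(mat, regions, p21_samples, min_coverage)
  rm60 <- compute_region_means(mat, regions, p60_samples, min_coverage)
  a21 <- rowMeans(rm21, na.rm = TRUE)
  a60 <- rowMeans(rm60, na.rm = TRUE)
  span <- a60 - a21
  reason <- rep(NA_character_, nrow(regions))
  reason[is.nan(a21) | is.nan(a60)] <- "no retained CpG in an anchor group"
  consistent <- ifelse(regions$direction == "hyper", span > 0, span < 0)
  reason[is.na(reason) & !consistent] <- "anchors contradict direction label"
  reason[is.na(reason) & abs(span) < min_anchor_span] <-
    sprintf("anchor span below %g", min_anchor_span)
  drop <- !is.na(reason)
  if (any(drop))
    message(sprintf("compute_anchors: dropping %d region(s): %s",
                    sum(drop),
                    paste(unique(reason[drop]), collapse = "; ")))
  out <- regions[!drop, c("chrom", "start", "end", "direction"), drop = FALSE]
  out$anchor_p21 <- a21[!drop]
  out$anchor_p60 <- a60[!drop]
  rownames(out) <- NULL
  structure(out,
            class = c("epi_signature", "data.frame"),
            sex = attr(regions, "sex", exact = TRUE),
            dropped = cbind(regions[drop, c("chrom", "start", "end"),
                                    drop = FALSE],
                            reason = reason[drop]))
}

#' Per-sample epigenomic scores
#'
#' For sample `j` and signature region `i` with region-mean beta `b_ij`,
#' the normalized value is
#' `r_ij = (b_ij - anchor_p21_i) / (anchor_p60_i - anchor_p21_i)`;
#' the denominator is negative for hypomethylated regions, which is
#' exactly the "reversal" of the min-max normalization. The score is the
#' mean of `r_ij` over the regions computable for that sample
#' (`method = "per_region"`, the primary definition), or the normalization
#' of stratum-aggregated betas (`method = "stratum"`: betas are averaged
#' over the hyper and hypo regions separately, each stratum normalized
#' against its aggregated anchors, and the two values combined weighted by
#' region count). Scores are 0 at the P21 anchors, 1 at the P60 anchors,
#' and deliberately not clipped: treated samples may fall below 0 and
#' degenerated ones above 1.
#'
#' @param mat A [meth_matrix()] of the samples to score.
#' @param signature An `epi_signature` from [compute_anchors()].
#' @param samples Optional sample-id subset (default: all columns).
#' @param meta Optional metadata; when given and the signature carries a
#'   sex label, scoring samples of the other sex is refused unless
#'   `force_sex = TRUE` (the signature is sex-specific).
#' @param min_coverage Coverage filter for region means.
#' @param method `"per_region"` or `"stratum"` (see above).
#' @param force_sex Allow cross-sex scoring.
#' @return A data.frame (class `score_report`) with `sample_id`, `score`
#'   and `n_regions_used`; attribute `region_values` holds the per-region
#'   normalized values (regions x samples) for audit. Samples with no
#'   computable region get `NA` with a warning.
#' @export
score_samples <- function(mat, signature, samples = NULL, meta = NULL,
                          min_coverage = 1L,
                          method = c("per_region", "stratum"),
                          force_sex = FALSE) {
  method <- match.arg(method)
  sig <- as.data.frame(signature)
  if (!nrow(sig))
    epr_config_error("cannot score against an empty signature")
  if (is.null(samples)) samples <- mat$samples
  sig_sex <- attr(signature, "sex", exact = TRUE)
  if (!is.null(meta) && !is.null(sig_sex) && !force_sex) {
    other <- meta$sample_id[meta$sex != sig_sex]
    bad <- intersect(samples, other)
    if (length(bad))
      epr_config_error(
        "signature is %s-specific; refusing to score %s (use force_sex = TRUE)",
        sig_sex, paste(bad, collapse = ", "))
  }
  b <- compute_region_means(mat, sig, samples, min_coverage)
  denom <- sig$anchor_p60 - sig$anchor_p21
  rv <- sweep(sweep(b, 1, sig$anchor_p21, "-"), 1, denom, "/")
  n_used <- as.integer(colSums(!is.na(rv)))
  if (method == "per_region") {
    score <- colMeans(rv, na.rm = TRUE)
    score[n_used == 0] <- NA_real_
  } else {
    score <- vapply(seq_along(samples), function(j) {
      ok <- !is.na(b[, j])
      if (!any(ok)) return(NA_real_)
      parts <- vapply(c("hyper", "hypo"), function(dd) {
        i <- ok & sig$direction == dd
        if (!any(i)) return(c(NA_real_, 0))
        c((mean(b[i, j]) - mean(sig$anchor_p21[i])) /
            (mean(sig$anchor_p60[i]) - mean(sig$anchor_p21[i])), sum(i))
      }, numeric(2))
      sum(parts[1, ] * parts[2, ], na.rm = TRUE) / sum(parts[2, ])
    }, numeric(1))
  }
  if (any(n_used == 0))
    warning(sprintf("no computable signature region for sample(s): %s",
                    paste(samples[n_used == 0], collapse = ", ")))
  structure(data.frame(sample_id = samples, score = unname(score),
                       n_regions_used = unname(n_used),
                       stringsAsFactors = FALSE),
            class = c("score_report", "data.frame"),
            region_values = rv)
}

#' Epigenomic scores for cell-free DNA
#'
#' cfDNA does not detect every signature region, so scoring is restricted
#' to the signature regions that overlap the tissue-detectable set (e.g.
#' DMRs callable in cfDNA, or any externally determined detectable-region
#' BED); within that subset, a region contributes to a pool's score only
#' if it has at least one covered CpG, exactly as in [score_samples()].
#'
#' @param cfdna_mat A [meth_matrix()] of cfDNA pools.
#' @param signature An `epi_signature`.
#' @param tissue_detectable_regions Optional [region_set()]; `NULL` keeps
#'   the whole signature.
#' @param min_overlap_bp Overlap threshold for the restriction.
#' @inheritParams score_samples
#' @return A `score_report` as in [score_samples()]; `n_regions_used`
#'   reports the per-pool subset size actually used.
#' @export
score_cfdna <- function(cfdna_mat, signature,
                        tissue_detectable_regions = NULL,
                        samples = NULL, meta = NULL, min_coverage = 1L,
                        method = c("per_region", "stratum"),
                        force_sex = FALSE, min_overlap_bp = 1L) {
  sig <- signature
  if (!is.null(tissue_detectable_regions) &&
      nrow(as.data.frame(tissue_detectable_regions))) {
    gp <- granges_pair(as.data.frame(sig),
                       as.data.frame(tissue_detectable_regions))
    hit <- sort(unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(gp[[1]], gp[[2]],
                                  minoverlap = min_overlap_bp))))
    sex <- attr(sig, "sex", exact = TRUE)
    sig <- sig[hit, , drop = FALSE]
    attr(sig, "sex") <- sex
    if (!nrow(sig))
      epr_config_error("no signature region is tissue-detectable")
  }
  score_samples(cfdna_mat, sig, samples = samples, meta = meta,
                min_coverage = min_coverage, method = method,
                force_sex = force_sex)
}
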