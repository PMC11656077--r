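#' Disease-progression analysis
#'
#' Calls DMRs between the pre-degenerate reference timepoint (first
#' untreated day, normally P21) and every later untreated timepoint of one
#' sex, and — when a treatment DMR table is supplied — derives the
#' signature from the final comparison (P21 vs P60) intersected with the
#' treatment DMRs, with anchors computed on the untreated P21/P60 animals.
#'
#' @param mat A [meth_matrix()].
#' @param meta Sample metadata (see [read_sample_meta()]).
#' @param sex Which sex to analyze ("female"/"male"); DMR calling is
#'   sex-stratified.
#' @param params A [dmr_params()].
#' @param treatment_dmrs Optional DMR data.frame from a sham-vs-treated
#'   comparison of the same sex.
#' @param min_overlap_bp Overlap threshold for the signature intersection.
#' @param min_anchor_span,anchor_min_coverage Passed to [compute_anchors()].
#' @return A list with `dmr_tables` (named `"P<t>"` per comparison),
#'   `counts` (data.frame timepoint / n_dmr / n_hyper / n_hypo),
#'   `signature_regions` and `signature` (NULL without `treatment_dmrs`).
#' @export
run_progression_analysis <- function(mat, meta, sex, params = dmr_params(),
                                     treatment_dmrs = NULL,
                                     min_overlap_bp = 1L,
                                     min_anchor_span = 0.01,
                                     anchor_min_coverage = 1L) {
  um <- meta[meta$group == "untreated" & meta$sex == sex, , drop = FALSE]
  tps <- sort(unique(um$timepoint))
  if (length(tps) < 2L)
    epr_config_error("need untreated samples at >= 2 timepoints for sex %s", sex)
  t0 <- tps[1]; t1 <- tps[length(tps)]
  ref <- um$sample_id[um$timepoint == t0]
  dmr_tables <- list()
  for (t in tps[-1]) {
    grp <- um$sample_id[um$timepoint == t]
    dmr_tables[[paste0("P", t)]] <- call_dmrs(mat, ref, grp, params)
  }
  counts <- data.frame(
    timepoint = tps[-1],
    n_dmr = vapply(dmr_tables, nrow, integer(1)),
    n_hyper = vapply(dmr_tables, function(d) sum(d$direction == "hyper"),
                     integer(1)),
    n_hypo = vapply(dmr_tables, function(d) sum(d$direction == "hypo"),
                    integer(1)), row.names = NULL)
  signature_regions <- NULL; signature <- NULL
  if (!is.null(treatment_dmrs)) {
    signature_regions <- derive_signature(dmr_tables[[paste0("P", t1)]],
                                          treatment_dmrs, sex = sex,
                                          min_overlap_bp = min_overlap_bp)
    if (nrow(signature_regions))
      signature <- compute_anchors(signature_regions, mat,
                                   p21_samples = ref,
                                   p60_samples = um$sample_id[um$timepoint == t1],
                                   min_coverage = anchor_min_coverage,
                                   min_anchor_span = min_anchor_span)
  }
  list(dmr_tables = dmr_tables, counts = counts,
       signature_regions = signature_regions, signature = signature)
}

#' Treatment-arm analysis
#'
#' Calls DMRs between the sham arm and each treated arm at the final
#' timepoint, scores every arm (including untreated animals at that
#' timepoint, if present) against a signature, and compares each treated
#' arm's scores with the reference arm. Both Welch's and Student's
#' two-sample t-test p-values are reported (group sizes are typically
#' unequal). Arms with fewer than two scored samples skip the test with a
#' warning.
#'
#' @param mat A [meth_matrix()].
#' @param meta Sample metadata.
#' @param signature An `epi_signature` from [compute_anchors()].
#' @param sex Which sex to analyze.
#' @param params A [dmr_params()] for the sham-vs-treated DMR tables
#'   (set `call_treatment_dmrs = FALSE` to skip).
#' @param reference_group Reference arm (default "sham").
#' @param treated_groups Treated arms to compare against the reference.
#' @param timepoint Day of the treatment comparison (default: max in meta).
#' @param call_treatment_dmrs Whether to (re)call sham-vs-treated DMRs.
#' @param method Scoring variant, see [score_samples()].
#' @return A list with `dmr_tables` (per treated arm, possibly NULL),
#'   `scores` (per-sample score_report with `group` attached),
#'   `arm_summary` (group / n / mean_score) and `tests`
#'   (group / p_welch / p_student).
#' @export
run_treatment_analysis <- function(mat, meta, signature, sex,
                                   params = dmr_params(),
                                   reference_group = "sham",
                                   treated_groups = c("low", "high"),
                                   timepoint = NULL,
                                   call_treatment_dmrs = TRUE,
                                   method = "per_region") {
  mm <- meta[meta$sex == sex, , drop = FALSE]
  if (is.null(timepoint)) timepoint <- max(mm$timepoint)
  arms <- mm[mm$timepoint == timepoint &
               mm$group %in% c(reference_group, treated_groups, "untreated"), ,
             drop = FALSE]
  if (!nrow(arms[arms$group == reference_group, ]))
    epr_config_error("no %s samples at P%d for sex %s",
                     reference_group, timepoint, sex)
  ref_ids <- arms$sample_id[arms$group == reference_group]
  dmr_tables <- NULL
  if (call_treatment_dmrs) {
    dmr_tables <- lapply(setNames(treated_groups, treated_groups),
                         function(g) {
      ids <- arms$sample_id[arms$group == g]
      if (!length(ids)) return(NULL)
      call_dmrs(mat, ref_ids, ids, params)
    })
  }
  scores <- score_samples(mat, signature, samples = arms$sample_id,
                          meta = meta, method = method)
  scores$group <- arms$group[match(scores$sample_id, arms$sample_id)]
  arm_summary <- do.call(rbind, lapply(split(scores, scores$group),
    function(s) data.frame(group = s$group[1], n = nrow(s),
                           mean_score = mean(s$score, na.rm = TRUE))))
  rownames(arm_summary) <- NULL
  ref_scores <- scores$score[scores$group == reference_group]
  tests <- do.call(rbind, lapply(treated_groups, function(g) {
    x <- scores$score[scores$group == g]
    if (length(x) < 2L || length(ref_scores) < 2L) {
      warning(sprintf("arm '%s': fewer than 2 samples, t-test skipped", g))
      return(data.frame(group = g, p_welch = NA_real_,
                        p_student = NA_real_))
    }
    safe_t <- function(...) tryCatch(stats::t.test(...)$p.value,
                                     error = function(e) NA_real_)
    data.frame(group = g,
               p_welch = safe_t(x, ref_scores),
               p_student = safe_t(x, ref_scores, var.equal = TRUE))
  }))
  list(dmr_tables = dmr_tables, scores = scores,
       arm_summary = arm_summary, tests = tests)
}
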