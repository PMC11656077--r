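# Small in-code fixtures shared across test files.

# A meth_matrix with two groups separated by a uniform delta over a run of
# CpGs; group A at beta_a, group B at beta_a + delta, two samples each.
two_group_matrix <- function(n_cpg = 20L, spacing = 100L, beta_a = 0.3,
                             delta = 0.3, jitter = 0.01,
                             gap_after = NULL, gap_bp = 1000L) {
  pos <- cumsum(rep(spacing, n_cpg))
  if (!is.null(gap_after)) pos[(gap_after + 1):n_cpg] <-
    pos[(gap_after + 1):n_cpg] + gap_bp
  # small deterministic jitter so per-CpG values are distinct (no ties)
  jit <- jitter * sin(seq_len(n_cpg))
  beta <- cbind(a1 = beta_a + jit, a2 = beta_a + jit / 2,
                b1 = beta_a + delta + jit, b2 = beta_a + delta + jit / 3)
  beta <- pmin(pmax(beta, 0), 1)
  meth_matrix(rep("chr1", n_cpg), pos, beta)
}

# compact simulated cohort for pipeline-level tests
small_sim <- function(seed = 1L, ...) {
  simulate_cohort(sim_config(n_chrom = 1L, cpgs_per_chrom = 300L,
                             n_true_regions = 8L, n_per_group_per_sex = 4L,
                             seed = seed, ...))
}

untreated_ids <- function(meta, sex, tp) {
  meta$sample_id[meta$group == "untreated" & meta$sex == sex &
                   meta$timepoint == tp]
}

group_ids <- function(meta, sex, grp, tp = NULL) {
  keep <- meta$group == grp & meta$sex == sex
  if (!is.null(tp)) keep <- keep & meta$timepoint == tp
  meta$sample_id[keep]
}

# signature + anchors from a simulated cohort, one sex
sim_signature <- function(sim, sex = "female", params = dmr_params()) {
  meta <- sim$meta
  p21 <- untreated_ids(meta, sex, min(meta$timepoint))
  p60 <- untreated_ids(meta, sex, max(meta$timepoint))
  deg <- call_dmrs(sim$matrix, p21, p60, params)
  trt <- call_dmrs(sim$matrix, group_ids(meta, sex, "sham"),
                   group_ids(meta, sex, "high"), params)
  sig_regions <- derive_signature(deg, trt, sex = sex)
  compute_anchors(sig_regions, sim$matrix, p21, p60)
}
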