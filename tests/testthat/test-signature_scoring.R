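# a hand-built signature with known anchors
manual_signature <- function() {
  structure(
    data.frame(chrom = c("chr1", "chr1"), start = c(0L, 1000L),
               end = c(500L, 1500L), direction = c("hyper", "hypo"),
               anchor_p21 = c(0.2, 0.7), anchor_p60 = c(0.6, 0.3)),
    class = c("epi_signature", "data.frame"))
}

# one CpG per signature region at given betas
profile_matrix <- function(betas, ids = names(betas)) {
  b <- do.call(cbind, lapply(betas, function(v) v))
  colnames(b) <- ids
  meth_matrix(c("chr1", "chr1"), c(100L, 1100L), b)
}

test_that("signature derivation keeps overlapping degeneration DMRs, deduplicated", {
  deg <- data.frame(chrom = "chr1", start = 100L, end = 300L,
                    direction = "hyper")
  trt <- data.frame(chrom = "chr1", start = c(250L, 290L),
                    end = c(400L, 600L), direction = c("hypo", "hyper"))
  sig <- derive_signature(deg, trt, sex = "female")
  expect_equal(nrow(sig), 1L) # overlapped twice, emitted once
  expect_equal(sig$start, 100L)
  expect_equal(sig$end, 300L)
  expect_equal(sig$direction, "hyper") # direction from the degeneration DMR
  expect_equal(attr(sig, "sex"), "female")

  far <- data.frame(chrom = "chr1", start = 5000L, end = 5100L,
                    direction = "hyper")
  expect_warning(empty <- derive_signature(deg, far), "empty signature")
  expect_equal(nrow(empty), 0L)

  # min_overlap_bp boundary: [100,300) vs [299,400) share exactly 1 bp
  edge <- data.frame(chrom = "chr1", start = 299L, end = 400L,
                     direction = "hyper")
  expect_equal(nrow(derive_signature(deg, edge, min_overlap_bp = 1L)), 1L)
  expect_warning(
    expect_equal(nrow(derive_signature(deg, edge, min_overlap_bp = 2L)), 0L))
})

test_that("anchors: span and direction-consistency filters drop regions with a message", {
  # region 1: hyper 0.2 -> 0.6 (kept); region 2: labeled hypo but rises (dropped);
  # region 3: span 0.005 below min_anchor_span (dropped)
  m <- meth_matrix(rep("chr1", 3), c(100L, 1100L, 2100L),
                   cbind(p21a = c(0.2, 0.40, 0.500),
                         p21b = c(0.2, 0.40, 0.500),
                         p60a = c(0.6, 0.45, 0.505),
                         p60b = c(0.6, 0.45, 0.505)))
  regions <- data.frame(chrom = "chr1", start = c(0L, 1000L, 2000L),
                        end = c(500L, 1500L, 2500L),
                        direction = c("hyper", "hypo", "hyper"))
  expect_message(
    sig <- compute_anchors(regions, m, c("p21a", "p21b"), c("p60a", "p60b")),
    "dropping 2")
  expect_equal(nrow(sig), 1L)
  expect_equal(sig$anchor_p21, 0.2)
  expect_equal(sig$anchor_p60, 0.6)
  expect_equal(nrow(attr(sig, "dropped")), 2L)
  expect_error(compute_anchors(regions, m, character(0), c("p60a")),
               class = "epr_config_error")
})

test_that("score formula: anchor identities, midpoint, and no clipping", {
  sig <- manual_signature()
  m <- profile_matrix(list(at21 = c(0.2, 0.7), at60 = c(0.6, 0.3),
                           mid = c(0.4, 0.5), beyond = c(0.7, 0.2)))
  sc <- score_samples(m, sig)
  expect_equal(sc$score[sc$sample_id == "at21"], 0)
  expect_equal(sc$score[sc$sample_id == "at60"], 1)
  expect_equal(sc$score[sc$sample_id == "mid"], 0.5) # r = (0.5, 0.5)
  expect_gt(sc$score[sc$sample_id == "beyond"], 1)   # unclipped
  expect_equal(sc$n_regions_used, rep(2L, 4))
  rv <- attr(sc, "region_values")
  expect_equal(unname(rv[, "mid"]), c(0.5, 0.5))

  # stratum-aggregate variant satisfies the same anchor identities
  sc2 <- score_samples(m, sig, method = "stratum")
  expect_equal(sc2$score[sc2$sample_id == "at21"], 0)
  expect_equal(sc2$score[sc2$sample_id == "at60"], 1)
})

test_that("direction-flip invariance: b -> 1-b with flipped labels leaves scores unchanged", {
  sig <- manual_signature()
  m <- profile_matrix(list(s1 = c(0.35, 0.62), s2 = c(0.55, 0.41)))
  flipped_sig <- sig
  flipped_sig$direction <- ifelse(sig$direction == "hyper", "hypo", "hyper")
  flipped_sig$anchor_p21 <- 1 - sig$anchor_p21
  flipped_sig$anchor_p60 <- 1 - sig$anchor_p60
  m_flip <- profile_matrix(list(s1 = 1 - c(0.35, 0.62), s2 = 1 - c(0.55, 0.41)))
  a <- score_samples(m, sig)
  b <- score_samples(m_flip, flipped_sig)
  expect_equal(a$score, b$score, tolerance = 1e-12)
  expect_equal(attr(a, "region_values"), attr(b, "region_values"),
               tolerance = 1e-12)
})

test_that("score is invariant to signature region order and refuses cross-sex scoring", {
  sig <- manual_signature()
  attr(sig, "sex") <- "female"
  m <- profile_matrix(list(s1 = c(0.35, 0.62), s2 = c(0.55, 0.41)))
  sig_rev <- sig[2:1, ]
  attr(sig_rev, "sex") <- "female"
  expect_equal(score_samples(m, sig)$score, score_samples(m, sig_rev)$score)

  meta <- data.frame(sample_id = c("s1", "s2"), sex = c("female", "male"),
                     timepoint = 60L, group = "sham", tissue = "retina",
                     pool_n = 1L)
  expect_error(score_samples(m, sig, meta = meta), class = "epr_config_error")
  forced <- score_samples(m, sig, meta = meta, force_sex = TRUE)
  expect_equal(nrow(forced), 2L)
  # scoring only the matching sex is fine
  ok <- score_samples(m, sig, samples = "s1", meta = meta)
  expect_equal(nrow(ok), 1L)
})

test_that("samples with no computable region get NA with a warning", {
  sig <- manual_signature()
  b <- cbind(s1 = c(0.4, NA), s2 = c(NA_real_, NA_real_))
  m <- meth_matrix(c("chr1", "chr1"), c(100L, 1100L), b)
  expect_warning(sc <- score_samples(m, sig), "s2")
  expect_true(is.na(sc$score[sc$sample_id == "s2"]))
  expect_equal(sc$n_regions_used, c(1L, 0L))
  expect_equal(sc$score[1], (0.4 - 0.2) / 0.4)
})

test_that("noise-free untreated scores increase strictly with day; treated recovery is centered", {
  cfg0 <- sim_config(n_chrom = 1L, cpgs_per_chrom = 300L, n_true_regions = 8L,
                     noise_kappa = Inf, mean_coverage = Inf, seed = 17L)
  sim0 <- simulate_cohort(cfg0)
  sig <- sim_signature(sim0, "female")
  sc <- score_samples(sim0$matrix, sig,
                      samples = sim0$meta$sample_id[
                        sim0$meta$group == "untreated" &
                          sim0$meta$sex == "female"],
                      meta = sim0$meta)
  sc$day <- sim0$meta$timepoint[match(sc$sample_id, sim0$meta$sample_id)]
  by_day <- aggregate(score ~ day, sc, mean)
  expect_true(all(diff(by_day$score[order(by_day$day)]) > 0))
  expect_equal(by_day$score, (by_day$day - 21) / 39, tolerance = 1e-9)

  # with noise: mean treated-P60 score within +-0.05 of the reversal target
  treated_means <- vapply(1:20, function(s) {
    sim <- simulate_cohort(sim_config(
      n_chrom = 1L, cpgs_per_chrom = 200L, n_true_regions = 6L,
      timepoints = c(21L, 60L), sex_overlap = 1, seed = 800L + s))
    sig_s <- sim_signature(sim, "female")
    mean(score_samples(sim$matrix, sig_s,
                       samples = group_ids(sim$meta, "female", "high"),
                       meta = sim$meta)$score)
  }, numeric(1))
  expect_lt(abs(mean(treated_means) - 0.5), 0.05)
})

test_that("cfDNA scoring: identity pools reproduce tissue scores; subset restriction applies", {
  sim <- small_sim(seed = 23L)
  sig <- sim_signature(sim, "female")
  fem60 <- group_ids(sim$meta, "female", "untreated", 60L)
  pools <- setNames(as.list(fem60), paste0("pool_", seq_along(fem60)))
  cf <- simulate_cfdna(sim$matrix, tissue_fraction = 1, dropout = 0,
                       pool = pools, meta = sim$meta, noise_kappa = Inf,
                       mean_coverage = Inf, seed = 2L)
  tissue_sc <- score_samples(sim$matrix, sig, samples = fem60,
                             meta = sim$meta)
  cf_sc <- score_cfdna(cf$matrix, sig, tissue_detectable_regions = sig)
  expect_equal(cf_sc$score, tissue_sc$score, tolerance = 1e-12)
  expect_equal(cf_sc$n_regions_used, tissue_sc$n_regions_used)

  # restriction to a detectable subset shrinks n_regions_used
  sub <- as.data.frame(sig)[1, , drop = FALSE]
  cf_sub <- score_cfdna(cf$matrix, sig, tissue_detectable_regions = sub)
  expect_true(all(cf_sub$n_regions_used == 1L))
  off <- data.frame(chrom = "chrZ", start = 0L, end = 10L)
  expect_error(score_cfdna(cf$matrix, sig, tissue_detectable_regions = off),
               class = "epr_config_error")
})
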