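test_that("noise-free construction: anchors at baseline and baseline +/- drift, full reversal", {
  cfg <- sim_config(n_chrom = 1L, cpgs_per_chrom = 200L, n_true_regions = 6L,
                    timepoints = c(21L, 60L), noise_kappa = Inf,
                    mean_coverage = Inf,
                    treatment_effect = c(sham = 0, high = 1), seed = 11L)
  sim <- simulate_cohort(cfg)
  truth <- sim$truth
  exp_tab <- truth$expected

  for (sex in c("female", "male")) {
    act <- truth$regions$sex %in% c(sex, "both")
    for (tp in c(21L, 60L)) {
      rm <- compute_region_means(sim$matrix, truth$regions,
                                 untreated_ids(sim$meta, sex, tp))
      want <- exp_tab$expected_beta[exp_tab$group == "untreated" &
                                      exp_tab$timepoint == tp]
      expect_equal(unname(rowMeans(rm))[act], want[act], tolerance = 1e-12)
    }
    # drift magnitude is drift_max at the final day
    rm21 <- rowMeans(compute_region_means(sim$matrix, truth$regions,
                                          untreated_ids(sim$meta, sex, 21L)))
    rm60 <- rowMeans(compute_region_means(sim$matrix, truth$regions,
                                          untreated_ids(sim$meta, sex, 60L)))
    sgn <- ifelse(truth$regions$direction == "hyper", 1, -1)
    expect_equal(unname(rm60 - rm21)[act], (sgn * cfg$drift_max)[act],
                 tolerance = 1e-12)
    # treatment_effect = 1: treated P60 equals P21
    rm_high <- rowMeans(compute_region_means(sim$matrix, truth$regions,
                                             group_ids(sim$meta, sex, "high")))
    expect_equal(unname(rm_high)[act], unname(rm21)[act], tolerance = 1e-12)
  }
})

test_that("simulation is seed-deterministic and betas stay in [0,1]", {
  cfg <- sim_config(n_chrom = 1L, cpgs_per_chrom = 100L, n_true_regions = 3L,
                    timepoints = c(21L, 60L), n_per_group_per_sex = 2L,
                    seed = 5L)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$matrix$beta, b$matrix$beta)
  expect_identical(a$matrix$coverage, b$matrix$coverage)
  expect_identical(a$truth$regions, b$truth$regions)

  cfg2 <- sim_config(n_chrom = 1L, cpgs_per_chrom = 100L, n_true_regions = 3L,
                     timepoints = c(21L, 60L), n_per_group_per_sex = 2L,
                     seed = 6L)
  c <- simulate_cohort(cfg2)
  expect_false(identical(a$matrix$beta, c$matrix$beta))

  expect_true(all(a$matrix$beta >= 0 & a$matrix$beta <= 1, na.rm = TRUE))
  # zero-coverage cells are missing
  expect_true(all(is.na(a$matrix$beta[a$matrix$coverage == 0])))
})

test_that("truth trajectories are monotone in the labeled direction", {
  sim <- small_sim(seed = 9L)
  exp_tab <- sim$truth$expected
  for (r in sim$truth$regions$name) {
    tr <- exp_tab[exp_tab$region == r & exp_tab$group == "untreated", ]
    tr <- tr[order(tr$timepoint), ]
    dir_r <- sim$truth$regions$direction[sim$truth$regions$name == r]
    if (dir_r == "hyper") expect_true(all(diff(tr$expected_beta) >= 0))
    else expect_true(all(diff(tr$expected_beta) <= 0))
  }
  expect_true(all(exp_tab$expected_beta >= 0 & exp_tab$expected_beta <= 1))
})

test_that("noisy cells converge in mean to the expected beta (3 SE)", {
  n_seeds <- 150L
  devs <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    cfg <- sim_config(n_chrom = 1L, cpgs_per_chrom = 30L, n_true_regions = 1L,
                      cpgs_per_region = 5L, timepoints = c(21L, 60L),
                      n_per_group_per_sex = 1L, noise_kappa = 50,
                      mean_coverage = Inf, sex_overlap = 1, seed = 1000L + s)
    sim <- simulate_cohort(cfg)
    reg <- sim$truth$regions[1, ]
    site <- which(sim$matrix$sites$pos - 1L >= reg$start &
                    sim$matrix$sites$pos - 1L < reg$end)[1]
    samp <- untreated_ids(sim$meta, "female", 60L)[1]
    expected_s <- sim$truth$expected$expected_beta[
      sim$truth$expected$region == reg$name &
        sim$truth$expected$group == "untreated" &
        sim$truth$expected$timepoint == 60L]
    devs[s] <- sim$matrix$beta[site, samp] - expected_s
  }
  # Beta(m*kappa, (1-m)*kappa) has mean m and variance <= 1/(4*(kappa+1))
  se <- sqrt(0.25 / 51) / sqrt(n_seeds)
  expect_lt(abs(mean(devs)), 3 * se)
})

test_that("infeasible drift configurations are rejected before sampling", {
  expect_error(sim_config(drift_max = 0.95), class = "epr_config_error")
  expect_error(sim_config(frac_hyper = 1.2), class = "epr_config_error")
  expect_error(sim_config(n_true_regions = 500L, cpgs_per_chrom = 100L),
               class = "epr_config_error")
})

test_that("cfDNA mixture: identity at f=1, background at f=0, midpoint at f=0.5", {
  m <- meth_matrix(rep("chr1", 4), c(100L, 200L, 300L, 400L),
                   cbind(t1 = c(0.8, 0.6, 0.8, 0.8),
                         t2 = c(0.8, 1.0, 0.8, 0.8)))
  pool <- list(p1 = c("t1", "t2"))
  id <- simulate_cfdna(m, tissue_fraction = 1, dropout = 0, pool = pool,
                       noise_kappa = Inf, mean_coverage = Inf, seed = 1)
  expect_equal(unname(id$matrix$beta[, "p1"]), c(0.8, 0.8, 0.8, 0.8))
  expect_equal(id$meta$pool_n, 2L)

  bg <- simulate_cfdna(m, tissue_fraction = 0, background_beta = 0.25,
                       dropout = 0, pool = pool, noise_kappa = Inf,
                       mean_coverage = Inf, seed = 1)
  expect_equal(unname(bg$matrix$beta[, "p1"]), rep(0.25, 4))

  mid <- simulate_cfdna(m, tissue_fraction = 0.5, background_beta = 0.2,
                        dropout = 0, pool = pool, noise_kappa = Inf,
                        mean_coverage = Inf, seed = 1)
  expect_equal(unname(mid$matrix$beta[1, "p1"]), 0.5 * 0.8 + 0.5 * 0.2)
})

test_that("cfDNA dropout and pooling are validated", {
  m <- meth_matrix(rep("chr1", 2), c(100L, 200L),
                   cbind(t1 = c(0.5, 0.5), t2 = c(0.5, 0.5)))
  expect_error(simulate_cfdna(m, 1, pool = list(character(0)), seed = 1),
               class = "epr_config_error")
  expect_error(simulate_cfdna(m, 1, pool = list(a = "t1", b = "t1"), seed = 1),
               class = "epr_config_error")
  expect_error(simulate_cfdna(m, 1.4, pool = list(a = "t1"), seed = 1),
               class = "epr_config_error")
  expect_error(simulate_cfdna(m, 1, pool = list(a = "nope"), seed = 1),
               class = "epr_lookup_error")
  # dropout removes roughly the requested fraction of sites (block = 1 CpG)
  big <- meth_matrix(rep("chr1", 2000), seq_len(2000) * 10L,
                     cbind(t1 = rep(0.5, 2000)))
  dr <- simulate_cfdna(big, 1, dropout = 0.3, pool = list(a = "t1"),
                       noise_kappa = Inf, mean_coverage = Inf,
                       dropout_block_cpgs = 1L, seed = 3)
  frac <- mean(is.na(dr$matrix$beta))
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / 2000))
})
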