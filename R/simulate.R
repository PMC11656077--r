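#' Configuration for the synthetic-cohort generator
#'
#' Describes an RRBS-like study of progressive retinal degeneration:
#' untreated animals sampled at several postnatal days between P21
#' (pre-degenerate) and P60 (degenerate), plus treatment arms at the final
#' day whose stimulation reverses a fraction of the age drift. A designated
#' set of "true" regions drifts hyper- or hypomethylated linearly with age;
#' all other CpGs hold a constant baseline. Baselines of null CpGs are
#' piecewise-constant over blocks of consecutive CpGs, mimicking the local
#' correlation of real methylomes.
#'
#' @param n_chrom Number of chromosomes.
#' @param cpgs_per_chrom CpGs per chromosome, evenly spaced `cpg_spacing`
#'   bp apart.
#' @param n_true_regions Number of drifting regions (across chromosomes).
#' @param cpgs_per_region Consecutive CpGs per true region.
#' @param frac_hyper Fraction of true regions drifting hypermethylated.
#' @param timepoints Postnatal days of the untreated arm; the first/last
#'   define the drift anchors.
#' @param n_per_group_per_sex Animals per (group, timepoint, sex) cell.
#' @param drift_max Delta-beta reached at the final timepoint.
#' @param treatment_effect Named fractions of drift reversed per treated
#'   group (treated arms are generated at the final timepoint only).
#' @param sex_overlap Fraction of true regions active in both sexes; the
#'   remainder is split evenly into female-only and male-only regions.
#' @param noise_kappa Beta-distribution precision; observed betas are
#'   `Beta(m*kappa, (1-m)*kappa)` around the expected value `m`. `Inf`
#'   disables noise.
#' @param mean_coverage Mean of the Poisson per-cell coverage; `Inf`
#'   disables the coverage layer.
#' @param cpg_spacing Distance in bp between consecutive CpGs.
#' @param seed Integer seed; identical configs and seeds give identical
#'   output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_chrom = 2L, cpgs_per_chrom = 1500L,
                       n_true_regions = 40L, cpgs_per_region = 10L,
                       frac_hyper = 0.6,
                       timepoints = c(21L, 35L, 42L, 49L, 60L),
                       n_per_group_per_sex = 4L, drift_max = 0.3,
                       treatment_effect = c(sham = 0, low = 0.25, high = 0.5),
                       sex_overlap = 0.2, noise_kappa = 50,
                       mean_coverage = 30, cpg_spacing = 150L, seed = 1L) {
  cfg <- list(n_chrom = as.integer(n_chrom),
              cpgs_per_chrom = as.integer(cpgs_per_chrom),
              n_true_regions = as.integer(n_true_regions),
              cpgs_per_region = as.integer(cpgs_per_region),
              frac_hyper = frac_hyper, timepoints = sort(as.integer(timepoints)),
              n_per_group_per_sex = as.integer(n_per_group_per_sex),
              drift_max = drift_max, treatment_effect = treatment_effect,
              sex_overlap = sex_overlap, noise_kappa = noise_kappa,
              mean_coverage = mean_coverage,
              cpg_spacing = as.integer(cpg_spacing), seed = as.integer(seed))
  for (f in c("frac_hyper", "sex_overlap"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      epr_config_error("%s must lie in [0,1]", f)
  if (cfg$drift_max < 0 || cfg$drift_max > 1)
    epr_config_error("drift_max must lie in [0,1]")
  if (cfg$drift_max > 0.8)
    epr_config_error(
      "drift_max %.2f leaves no feasible baseline range within [0,1]",
      cfg$drift_max)
  if (length(cfg$timepoints) < 2L)
    epr_config_error("need at least two timepoints")
  if (is.null(names(cfg$treatment_effect)) ||
      any(cfg$treatment_effect < 0 | cfg$treatment_effect > 1))
    epr_config_error("treatment_effect must be a named vector of fractions in [0,1]")
  if (cfg$n_true_regions > 0) {
    per_chrom <- ceiling(cfg$n_true_regions / cfg$n_chrom)
    need <- per_chrom * (cfg$cpgs_per_region + 4L) + 4L
    if (need > cfg$cpgs_per_chrom)
      epr_config_error("chromosomes too short for %d regions of %d CpGs",
                       cfg$n_true_regions, cfg$cpgs_per_region)
  }
  structure(cfg, class = "sim_config")
}

# Deterministic region layout: regions spread evenly along chromosomes,
# separated by >= 4 null CpGs so segmentation boundaries are identifiable.
place_regions <- function(cfg) {
  if (cfg$n_true_regions == 0L)
    return(data.frame(chrom = character(), first = integer(),
                      last = integer()))
  chrom_of <- rep(seq_len(cfg$n_chrom), length.out = cfg$n_true_regions)
  out <- lapply(seq_len(cfg$n_chrom), function(cc) {
    k <- sum(chrom_of == cc)
    if (k == 0L) return(NULL)
    gap <- (cfg$cpgs_per_chrom - k * cfg$cpgs_per_region) %/% (k + 1L)
    first <- gap * seq_len(k) + cfg$cpgs_per_region * (seq_len(k) - 1L) + 1L
    data.frame(chrom = paste0("chr", cc), first = first,
               last = first + cfg$cpgs_per_region - 1L)
  })
  do.call(rbind, out)
}

#' Simulate a tissue methylation cohort
#'
#' Generates a [meth_matrix()], matching metadata and a ground-truth object.
#' For a true region active in a sample's sex, the expected beta of a
#' sample in group `g` at day `t` is
#' `baseline + dir * drift_max * (t - t0)/(t1 - t0) * (1 - treatment_effect[g])`
#' with `dir = +1` (hyper) or `-1` (hypo) and `t0`/`t1` the first/last
#' timepoints. Null CpGs keep their baseline in every group. Observed betas
#' are beta-distributed around the expectation with precision
#' `noise_kappa`; per-cell coverage is Poisson with mean `mean_coverage`
#' and zero-coverage cells are missing.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `sim_cohort`: `matrix` (meth_matrix), `meta`
#'   (sample metadata data.frame) and `truth` (list with `regions` — a
#'   [region_set()] with `name`, `direction`, `sex` columns — and
#'   `expected`, the long table of expected group-mean betas per region,
#'   group and timepoint).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, simulate_cohort_impl(cfg))
}

simulate_cohort_impl <- function(cfg) {
  t0 <- cfg$timepoints[1]; t1 <- cfg$timepoints[length(cfg$timepoints)]
  n_sites <- cfg$n_chrom * cfg$cpgs_per_chrom
  chrom <- rep(paste0("chr", seq_len(cfg$n_chrom)), each = cfg$cpgs_per_chrom)
  pos <- rep(seq_len(cfg$cpgs_per_chrom) * cfg$cpg_spacing, cfg$n_chrom)

  lay <- place_regions(cfg)
  n_reg <- nrow(lay)
  site_region <- rep(NA_integer_, n_sites)
  if (n_reg) {
    chrom_offset <- (match(lay$chrom, paste0("chr", seq_len(cfg$n_chrom))) - 1L) *
      cfg$cpgs_per_chrom
    for (r in seq_len(n_reg))
      site_region[chrom_offset[r] + (lay$first[r]:lay$last[r])] <- r
  }

  # direction and sex labels for true regions
  n_hyper <- round(cfg$frac_hyper * n_reg)
  direction <- rep("hypo", n_reg)
  if (n_reg) direction[sample.int(n_reg, n_hyper)] <- "hyper"
  n_both <- round(cfg$sex_overlap * n_reg)
  sex_lab <- rep(c("female", "male"), length.out = max(n_reg - n_both, 0))
  sex_lab <- c(rep("both", n_both), sex_lab)[seq_len(n_reg)]
  if (n_reg) sex_lab <- sample(sex_lab)

  # baselines: per true region, and per block of null CpGs
  base_reg <- numeric(n_reg)
  if (n_reg) {
    hyper <- direction == "hyper"
    base_reg[hyper] <- runif(sum(hyper), 0.15, 1 - cfg$drift_max - 0.05)
    base_reg[!hyper] <- runif(sum(!hyper), cfg$drift_max + 0.05, 0.85)
  }
  block <- ceiling(seq_len(cfg$cpgs_per_chrom) / cfg$cpgs_per_region)
  block_id <- rep(block, cfg$n_chrom) +
    rep((seq_len(cfg$n_chrom) - 1L) * max(block), each = cfg$cpgs_per_chrom)
  base_block <- runif(max(block_id), 0.1, 0.9)
  baseline <- base_block[block_id]
  in_reg <- !is.na(site_region)
  baseline[in_reg] <- base_reg[site_region[in_reg]]

  # sample grid
  treated <- setdiff(names(cfg$treatment_effect), "untreated")
  grid <- rbind(
    expand.grid(sex = c("female", "male"), group = "untreated",
                timepoint = cfg$timepoints, rep = seq_len(cfg$n_per_group_per_sex),
                stringsAsFactors = FALSE),
    expand.grid(sex = c("female", "male"), group = treated,
                timepoint = t1, rep = seq_len(cfg$n_per_group_per_sex),
                stringsAsFactors = FALSE))
  meta <- data.frame(
    sample_id = sprintf("%s_%s_P%d_%d", ifelse(grid$sex == "female", "F", "M"),
                        grid$group, grid$timepoint, grid$rep),
    sex = grid$sex, timepoint = as.integer(grid$timepoint),
    group = grid$group, tissue = "retina", pool_n = 1L,
    stringsAsFactors = FALSE)
  meta <- meta[order(meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL

  effect_of <- function(g) if (g == "untreated") 0 else cfg$treatment_effect[[g]]
  dirsign <- ifelse(direction == "hyper", 1, -1)

  beta <- matrix(NA_real_, n_sites, nrow(meta),
                 dimnames = list(NULL, meta$sample_id))
  for (j in seq_len(nrow(meta))) {
    m <- baseline
    if (n_reg) {
      active <- in_reg & (sex_lab[site_region] %in% c("both", meta$sex[j]))
      r <- site_region[active]
      prog <- (meta$timepoint[j] - t0) / (t1 - t0)
      m[active] <- base_reg[r] + dirsign[r] * cfg$drift_max * prog *
        (1 - effect_of(meta$group[j]))
    }
    beta[, j] <- draw_beta(m, cfg$noise_kappa)
  }
  coverage <- NULL
  if (is.finite(cfg$mean_coverage))
    coverage <- matrix(rpois(length(beta), cfg$mean_coverage),
                       n_sites, ncol(beta), dimnames = dimnames(beta))

  mat <- meth_matrix(chrom, pos, beta, coverage)

  truth <- make_truth(cfg, lay, direction, sex_lab, base_reg, pos, t0, t1)
  structure(list(matrix = mat, meta = meta, truth = truth),
            class = "sim_cohort")
}

draw_beta <- function(m, kappa) {
  if (!is.finite(kappa)) return(m)
  v <- m
  inner <- m > 0 & m < 1
  v[inner] <- rbeta(sum(inner), m[inner] * kappa, (1 - m[inner]) * kappa)
  v
}

make_truth <- function(cfg, lay, direction, sex_lab, base_reg, pos, t0, t1) {
  n_reg <- nrow(lay)
  if (n_reg == 0L) {
    return(list(regions = region_set(), expected = data.frame()))
  }
  # BED coordinates covering exactly the region's CpGs
  start <- (lay$first * cfg$cpg_spacing) - 1L
  end <- lay$last * cfg$cpg_spacing
  rs <- region_set(lay$chrom, start, end,
                   name = sprintf("reg_%03d", seq_len(n_reg)))
  # region_set() sorts; carry the labels over in sorted order
  ord <- order(lay$chrom, start, end)
  rs$direction <- direction[ord]
  rs$sex <- sex_lab[ord]
  base_sorted <- base_reg[ord]
  dirsign <- ifelse(rs$direction == "hyper", 1, -1)

  groups <- c("untreated", setdiff(names(cfg$treatment_effect), "untreated"))
  rows <- list()
  for (g in groups) {
    tps <- if (g == "untreated") cfg$timepoints else t1
    eff <- if (g == "untreated") 0 else cfg$treatment_effect[[g]]
    for (t in tps) {
      prog <- (t - t0) / (t1 - t0)
      rows[[length(rows) + 1L]] <- data.frame(
        region = rs$name, group = g, timepoint = t,
        expected_beta = base_sorted + dirsign * cfg$drift_max * prog * (1 - eff),
        stringsAsFactors = FALSE)
    }
  }
  expected <- do.call(rbind, rows)
  if (any(expected$expected_beta < 0 | expected$expected_beta > 1))
    epr_config_error("expected beta escapes [0,1]; infeasible configuration")
  # monotonicity of the untreated trajectory, by construction
  for (r in rs$name) {
    tr <- expected[expected$region == r & expected$group == "untreated", ]
    tr <- tr[order(tr$timepoint), ]
    d <- diff(tr$expected_beta)
    dir_r <- rs$direction[rs$name == r]
    stopifnot(all(if (dir_r == "hyper") d >= 0 else d <= 0))
  }
  list(regions = rs, expected = expected)
}

#' Simulate pooled plasma cell-free DNA from a tissue matrix
#'
#' Each cfDNA pool is a two-component mixture: at a retained site,
#' `beta = f * mean(tissue beta over the pool) + (1 - f) * background`,
#' then beta-distributed noise. A fraction `dropout` of the genome is lost
#' per pool, in blocks of `dropout_block_cpgs` consecutive CpGs (shallow
#' whole-genome bisulfite coverage drops contiguous stretches, not
#' independent sites).
#'
#' @param tissue A [meth_matrix()] of tissue samples.
#' @param tissue_fraction Mixing fraction `f` of tissue-derived signal.
#' @param background_beta Scalar or per-site vector of background
#'   methylation of the non-tissue cfDNA compartment.
#' @param dropout Expected fraction of sites lost per pool.
#' @param pool Named list of character vectors; each element gives the
#'   tissue sample ids pooled into one cfDNA library.
#' @param meta Optional tissue metadata used to annotate the pools
#'   (sex/group/timepoint are taken from the pooled members).
#' @param noise_kappa Beta precision of the measurement noise (`Inf` = none).
#' @param mean_coverage Poisson mean of the cfDNA coverage layer
#'   (`Inf` = no coverage matrix).
#' @param dropout_block_cpgs Size of the contiguous dropout unit, in CpGs.
#' @param seed Integer seed.
#' @return A list of class `cfdna_sim` with `matrix` (the cfDNA
#'   [meth_matrix()], one column per pool) and `meta`.
#' @export
simulate_cfdna <- function(tissue, tissue_fraction, background_beta = 0.5,
                           dropout = 0, pool, meta = NULL,
                           noise_kappa = 200, mean_coverage = 10,
                           dropout_block_cpgs = 50L, seed = 1L) {
  stopifnot(inherits(tissue, "meth_matrix"))
  if (tissue_fraction < 0 || tissue_fraction > 1)
    epr_config_error("tissue_fraction must lie in [0,1]")
  if (dropout < 0 || dropout > 1)
    epr_config_error("dropout must lie in [0,1]")
  if (!length(pool) || any(lengths(pool) == 0L))
    epr_config_error("every pool group must contain at least one sample")
  if (is.null(names(pool)) || any(!nzchar(names(pool))))
    names(pool) <- sprintf("pool_%02d", seq_along(pool))
  all_ids <- unlist(pool)
  if (anyDuplicated(all_ids))
    epr_config_error("pool groups must be disjoint")
  sample_index(tissue, all_ids) # errors on unknown ids

  withr::with_seed(as.integer(seed), {
    n_sites <- nrow(tissue$sites)
    bg <- rep_len(background_beta, n_sites)
    beta <- matrix(NA_real_, n_sites, length(pool),
                   dimnames = list(NULL, names(pool)))
    # contiguous dropout blocks per chromosome
    block_id <- integer(n_sites)
    off <- 0L
    for (cc in unique(tissue$sites$chrom)) {
      i <- which(tissue$sites$chrom == cc)
      block_id[i] <- off + ceiling(seq_along(i) / dropout_block_cpgs)
      off <- max(block_id[i])
    }
    n_block <- off
    for (j in seq_along(pool)) {
      cols <- sample_index(tissue, pool[[j]])
      tm <- rowMeans(tissue$beta[, cols, drop = FALSE], na.rm = TRUE)
      tm[is.nan(tm)] <- NA_real_
      m <- if (tissue_fraction == 0) bg
           else tissue_fraction * tm + (1 - tissue_fraction) * bg
      if (dropout > 0) {
        dropped <- rbinom(n_block, 1L, dropout) == 1L
        m[dropped[block_id]] <- NA_real_
      }
      ok <- !is.na(m)
      v <- rep(NA_real_, n_sites)
      v[ok] <- draw_beta(m[ok], noise_kappa)
      beta[, j] <- v
    }
    coverage <- NULL
    if (is.finite(mean_coverage)) {
      coverage <- matrix(rpois(length(beta), mean_coverage),
                         n_sites, ncol(beta), dimnames = dimnames(beta))
      coverage[is.na(beta)] <- 0L
    }
    mat <- meth_matrix(tissue$sites$chrom, tissue$sites$pos, beta, coverage)
    pool_meta <- data.frame(
      sample_id = names(pool), sex = NA_character_,
      timepoint = NA_integer_, group = NA_character_,
      tissue = "cfdna", pool_n = lengths(pool), stringsAsFactors = FALSE)
    if (!is.null(meta)) {
      for (j in seq_along(pool)) {
        mm <- meta[meta$sample_id %in% pool[[j]], , drop = FALSE]
        one <- function(v) if (length(unique(v)) == 1L) unique(v) else NA
        pool_meta$sex[j] <- one(mm$sex)
        pool_meta$group[j] <- one(mm$group)
        pool_meta$timepoint[j] <- one(mm$timepoint)
      }
    }
    structure(list(matrix = mat, meta = pool_meta), class = "cfdna_sim")
  })
}
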