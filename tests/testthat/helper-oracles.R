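# Independent oracles used to freeze expected values. These deliberately
# avoid the code paths they check.

# Exhaustive-enumeration two-sided Mann-Whitney p: over all C(n+m, n)
# assignments of the pooled values to group A, the proportion whose U is
# at least as extreme (two-sided, around the null mean nm/2) as observed.
oracle_mwu_exact <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  u_of <- function(a_idx) {
    a <- pooled[a_idx]; b <- pooled[-a_idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_of(seq_len(n))
  centre <- n * m / 2
  assignments <- utils::combn(n + m, n)
  us <- apply(assignments, 2, u_of)
  mean(abs(us - centre) >= abs(u_obs - centre) - 1e-12)
}

# Quadratic brute-force interval overlap: every pair of regions sharing at
# least min_overlap_bp base pairs (0-based half-open coordinates).
oracle_overlap_pairs <- function(a, b, min_overlap_bp = 1L) {
  out <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
      if (ov >= min_overlap_bp)
        out[[length(out) + 1L]] <- c(i, j)
    }
  }
  if (!length(out))
    return(data.frame(a_idx = integer(), b_idx = integer()))
  m <- do.call(rbind, out)
  data.frame(a_idx = m[, 1], b_idx = m[, 2])
}

random_region_set <- function(n, chroms = c("chr1", "chr2"),
                              max_pos = 5000L, max_len = 400L) {
  start <- sample.int(max_pos, n, replace = TRUE)
  df <- data.frame(chrom = sample(chroms, n, replace = TRUE),
                   start = start,
                   end = start + sample.int(max_len, n, replace = TRUE))
  # brute-force oracle and region_set both tolerate duplicates, but the
  # canonical container sorts, so sort here to keep indices comparable
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}
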