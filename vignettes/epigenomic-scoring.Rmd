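---
title: "Methods: DMR calling and epigenomic scoring of retinal degeneration"
author: "epiretscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DMR calling and epigenomic scoring of retinal degeneration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiretscore)
```

## The problem

In rodent models of inherited retinal degeneration such as the Royal College
of Surgeons (RCS) rat, the retina degenerates on a stereotyped clock: the
tissue is essentially pre-degenerate at postnatal day 21 (P21) and blind by
P60. DNA methylation changes progressively over that window, and a therapy —
here, transcorneal electrical stimulation (TES) delivered weekly between P21
and P56 at low or high current, with zero-current sham controls — partially
reverses those changes. `epiretscore` turns this into a quantitative,
per-sample readout:

1. call differentially methylated regions (DMRs) between sample groups from
   a per-CpG beta-value matrix;
2. derive a **signature**: the disease-progression DMRs (P21 vs P60,
   untreated) that are also perturbed by treatment;
3. compute a per-sample **epigenomic score** anchored so that the untreated
   P21 state scores 0 and the untreated P60 state scores 1;
4. apply the same score to plasma cell-free DNA (cfDNA), restricted to
   regions detectable in both tissue and plasma.

All stages are exercised end to end on synthetic cohorts with known ground
truth, generated by the package itself.

## DMR calling

The input is a matrix of beta values (fraction methylated, in $[0,1]$) at
strand-collapsed CpG positions. DMR calling between a reference group $A$
and a test group $B$ proceeds as:

1. **Filtering.** Cells under `min_coverage` (default 1 read) are treated
   as missing; a CpG is retained only if at least `min_samples_per_group`
   (default 2) samples per group observe it. Missing values are excluded
   from all means, never imputed — bisulfite coverage is sparse and
   imputation would manufacture signal.
2. **Runs.** Retained CpGs are grouped into maximal runs in which
   consecutive CpGs are at most `max_gap` (default 300 bp) apart.
3. **Candidates.** Within a run, per-CpG differences
   $d_i = \bar\beta_{B,i} - \bar\beta_{A,i}$ are computed from unweighted
   group means. Maximal stretches of CpGs sharing the sign of $d_i$ seed
   candidates; a seed is trimmed from whichever edge carries the smaller
   $|d_i|$ (right edge on ties) while its $|\overline{\Delta\beta}|$ is
   below `min_abs_delta` (default 0.1), and emitted if at least `min_cpgs`
   (default 10) CpGs survive above threshold. This greedy, deterministic
   segmentation replaces the binary-segmentation pre-step of established
   callers; the package's contract is the significance gate, not a
   particular segmentation heuristic. The procedure is antisymmetric:
   swapping $A$ and $B$ yields the same regions with negated effect sizes.
4. **Significance.** Each candidate is tested with a two-sided
   Mann-Whitney U comparing the vector of per-CpG $A$-means against the
   vector of per-CpG $B$-means over the region's CpGs. Candidates with
   $p < \alpha$ (default 0.05, raw — no multiple-testing correction, with
   an optional Benjamini-Hochberg flag) and
   $|\overline{\Delta\beta}| \ge$ `min_abs_delta` are reported, labeled
   `hyper` when $B$ is more methylated than $A$.

### Numerical behavior of the rank test

For combined $n \le 12$ without ties the exact permutation null is used;
otherwise the normal approximation with midrank tie correction and **no
continuity correction**. Two facts about this choice are worth recording:

* The exact two-sided $p$ at 6 vs 6 is a step function with jumps of up to
  ~0.06, so no continuous approximation can track it within less than
  roughly half a step. The branch-agreement property test asserts
  $|\Delta p| < 0.07$, the discreteness bound. At the significance
  boundary the two branches agree much more closely, and the uncorrected
  approximation keeps the empirical type-I rate of 10-CpG windows at the
  nominal $\alpha$ (the continuity-corrected variant is conservative,
  ~0.043 at $\alpha = 0.05$).
* The test assumes per-CpG means within a tested region are exchangeable,
  i.e. the region is internally homogeneous. On a window whose CpGs sit at
  wildly different baselines, the cross-CpG rank comparisons are fixed by
  the baselines and the test becomes extremely conservative. Segmentation
  aims to produce homogeneous regions; the type-I calibration is
  accordingly evaluated on windows aligned with the simulator's
  homogeneous baseline blocks.

## The epigenomic score

For each signature region the **anchors** are the unweighted region-mean
betas of the untreated P21 and untreated P60 cohorts (the
natural-progression arm — not sham-treated animals, since the signature
quantifies disease progression). For sample $j$ and region $i$ with
region-mean beta $\beta_{ij}$:

$$ r_{ij} = \frac{\beta_{ij} - a^{21}_i}{a^{60}_i - a^{21}_i}, \qquad
   \mathrm{score}_j = \frac{1}{|R_j|}\sum_{i \in R_j} r_{ij} $$

where $R_j$ is the set of regions with at least one covered CpG for sample
$j$. The denominator is negative for hypomethylated regions, so the single
formula implements the "reversal" of the min-max normalization for hypo
regions. By construction the P21 anchor profile scores exactly 0 and the
P60 profile exactly 1; scores are deliberately **not clipped** to $[0,1]$
(a successfully treated retina can be "younger" than the P21 anchors, and
clipping would destroy monotonicity diagnostics).

Two aggregation granularities are implemented because the verbal definition
of "min-max normalization on the average beta values across the regions of
interest" admits both readings:

* `method = "per_region"` (default): normalize each region, then average.
  Robust to between-region baseline differences.
* `method = "stratum"`: average betas over the hyper and hypo strata
  first, normalize each stratum against its aggregated anchors, combine
  weighted by region count.

Both satisfy the anchor identities; neither is claimed to be *the*
published computation.

Guards: regions whose computed anchors contradict their direction label,
or whose anchor span is below `min_anchor_span` (default 0.01, preventing
near-zero denominators), are dropped with a logged reason. Signatures are
sex-specific; scoring samples of the other sex is refused unless forced.

### cfDNA scoring

Plasma cfDNA detects only a subset of tissue regions. `score_cfdna()`
restricts the signature to regions overlapping a tissue-detectable set and
then scores exactly as above. One consequence of anchor normalization is
worth noting: each region contributes its own offset
$(\,f\cdot a - a^{21}_i + \dots)/(a^{60}_i - a^{21}_i)$ under a mixture, so
scores computed over *different* region subsets are not directly
comparable — this is precisely why the cfDNA analysis fixes a common
retina/plasma subset before scoring, and why the rank-order validation
below compares treatment arms under a fixed subset.

## The synthetic-cohort generator

`simulate_cohort()` emulates the study design, not sequencing chemistry:

* **Design.** Untreated animals at P21/P35/P42/P49/P60 and sham/low/high
  arms at P60, `n_per_group_per_sex = 4` per cell per sex (the study used
  3-4); cfDNA pools of 2-4 tissue samples mirror the pooling forced by
  plasma volume.
* **Drift.** A designated set of true regions (default 40 of 10 CpGs)
  drifts linearly from its baseline by `drift_max` (default 0.3) at P60:
  $m(t) = \beta_0 + \mathrm{dir}\cdot\Delta_{\max}\cdot\frac{t-21}{39}
  \cdot (1 - e_g)$, where $e_g$ is the fraction of drift reversed by
  treatment. Real progression is progressive but not necessarily linear;
  linearity is chosen so the expected score has the closed form
  $(t-21)/39$ for untreated samples, giving exact acceptance checks.
  Defaults `frac_hyper = 0.6` (hypermethylation predominates in the
  degenerating retina, ~57-61%), `sex_overlap = 0.2` (the DMR overlap
  between sexes is reported around 17%), and treatment effects
  sham 0 / low 0.25 / high 0.5 are artifact choices: effect magnitudes are
  published only graphically, so "high current reverses half the drift" is
  a calibration of this simulator, not a measured quantity.
* **Noise.** Observed betas are $\mathrm{Beta}(m\kappa, (1-m)\kappa)$
  around the expectation (respects $[0,1]$; one interpretable precision
  knob, default $\kappa = 50$, i.e. a per-cell SD of ~0.07 at $m = 0.5$).
  Coverage is Poisson (`mean_coverage = 30`); zero-coverage cells are
  missing.
* **Local correlation.** Null-CpG baselines are piecewise-constant over
  blocks of consecutive CpGs, as neighboring CpGs in real methylomes share
  methylation state. True regions have a constant within-region baseline.
* **cfDNA.** A pool's beta at a retained site is
  $f \cdot \overline{\beta}_{\mathrm{pool}} + (1-f)\cdot\beta_{\mathrm{bg}}$
  plus noise. Dropout removes blocks of `dropout_block_cpgs` consecutive
  CpGs (default 50) independently per pool with probability `dropout`:
  shallow whole-genome bisulfite coverage loses contiguous stretches, and
  block dropout makes the expected fraction of *usable regions* equal
  $1 - \mathrm{dropout}$ (site-i.i.d. dropout would almost never silence a
  whole 10-CpG region).

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: read-level sampling and conversion errors,
non-linear or region-specific drift kinetics, cell-type composition shifts
in the degenerating retina (bulk methylation confounds proportions with
within-cell-type change), genomic structure beyond two chromosomes of
evenly spaced CpGs, and any genome-specific CpG island landscape.

## Validation layout

The test suite (fixed seeds throughout) checks, among others:

* exact Mann-Whitney p-values against exhaustive enumeration (complete
  separation at 3v3 and 5v5: $p = 0.1$ and $2/252$);
* type-I calibration of the region test on 2,000 null 10-CpG windows
  (within $3\cdot$ binomial SE of $\alpha$);
* recovery of planted $\Delta\beta = 0.3$ regions at $n = 4$ vs 4,
  $\kappa = 50$ ($\ge 90\%$ at $\ge 50\%$ reciprocal overlap), with
  recovery non-decreasing in effect size;
* the closed-form score $(t - 21)/39$ to $10^{-9}$ on noise-free cohorts
  and the exact anchor identities;
* Spearman correlation of score with age $\ge 0.9$ at $\kappa = 50$;
* cfDNA: exact tissue-score reproduction for identity mixtures, region
  usage near $1 - \mathrm{dropout}$ (binomial tolerance with a straddle
  allowance for 100-CpG dropout blocks), and preservation of treatment-arm
  rank order at $f = 0.2$;
* interval overlap against a quadratic brute-force oracle on 100 random
  instances.

Simulated problem sizes (2 chromosomes × 1,500 CpGs, 64 samples; null
calibration on 10 × 2,000-CpG cohorts) were chosen so the full suite runs
in well under a minute while leaving Monte-Carlo tolerances meaningful.
`scripts/acceptance.R` recomputes the same quantities from scratch for any
seed.

## Known limitations

* The segmentation is a greedy stand-in; boundaries can differ from
  2D-KS-style callers near weak region edges (one or two flanking null
  CpGs may attach before trimming).
* Raw $p < 0.05$ with no correction follows the published filter; at
  genome scale this admits false positives by design. Use `adjust = "BH"`
  for exploratory work beyond reproducing the published behavior.
* Scores from different region subsets are not comparable (see cfDNA note
  above); compare samples only on a fixed signature and subset.
* DMR-to-gene assignment and pathway analysis are out of scope: pathway
  lists enter only as name sets for overlap arithmetic
  (`set_overlap_stats()`), since the upstream assignment used proprietary
  tooling.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 7)
sim <- simulate_cohort(cfg)
meta <- sim$meta
fem <- function(g, tp = NULL) {
  keep <- meta$sex == "female" & meta$group == g
  if (!is.null(tp)) keep <- keep & meta$timepoint == tp
  meta$sample_id[keep]
}

deg <- call_dmrs(sim$matrix, fem("untreated", 21), fem("untreated", 60))
trt <- call_dmrs(sim$matrix, fem("sham"), fem("high"))
sig <- compute_anchors(derive_signature(deg, trt, sex = "female"),
                       sim$matrix, fem("untreated", 21), fem("untreated", 60))
scores <- score_samples(sim$matrix, sig, samples = fem("untreated"),
                        meta = meta)
```
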