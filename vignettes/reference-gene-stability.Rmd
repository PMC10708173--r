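---
title: "Screening and ranking reference genes for RT-qPCR normalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening and ranking reference genes for RT-qPCR normalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Relative RT-qPCR quantification stands or falls with the reference
(housekeeping) genes used for normalization: a reference that itself
responds to the experimental treatment biases every fold change computed
against it.  `refstab` implements a two-stage computational procedure for
choosing references in a crop-plant setting (the motivating system is
rice seedlings under salt and drought stress): first, candidate genes are
mined from multi-dataset RNA-seq FPKM matrices by a cascade of stability
filters; second, the candidates measured by RT-qPCR are ranked by four
classical stability algorithms whose ranks are merged into a
geometric-mean comprehensive rank; finally, the consequence of the choice
is demonstrated by quantifying a target gene under contrasting
normalization schemes.  Because the motivating study's raw data are not
deposited, the package carries a synthetic-data generator with planted
ground truth, and every stage is validated against it.

```{r, eval = FALSE}
library(refstab)
design <- simulation_design(seed = 1)
panel  <- simulate_fpkm_panel(design)
screen <- screen_candidates(panel$panel)
cq     <- simulate_cq_experiment(design)
rank_stability(cq$table, tissue = "leaf")
```

# The screening cascade

The mining substrate is an `expression_panel`: a genes x samples FPKM
matrix plus per-sample metadata (dataset, variety, tissue, treatment,
biological replicate).  Candidates must survive five stages, with
defaults in `screen_criteria()`:

1. **Abundance** — within each dataset, the gene's mean FPKM must exceed
   70% of the grand mean FPKM over all genes and samples of that
   dataset.  We read "the whole sample's average FPKM" as this grand
   mean; the alternative per-sample-percentile reading would make the
   threshold depend on single samples and is not implemented.
2. **Ratio window** — every condition group's mean FPKM, divided by the
   gene's dataset-wide mean, must lie in 0.75–1.25.  Group means, not
   individual replicates, are compared: replicate-level ratios would
   conflate measurement noise with treatment response.  A condition
   group is the cross of the varying design factors (variety, tissue,
   treatment).
3. **ANOVA** — one-way ANOVA of the gene's FPKM across the dataset's
   condition groups must give p > 0.05; the filter *keeps*
   non-significant genes.  No multiple-testing correction is applied —
   correction would enlarge p-values and loosen, not tighten, a filter
   that retains non-significance.  Degenerate layouts follow fixed
   conventions: zero within-group variance with equal means is p = 1
   (pass), with differing means p = 0 (fail).  Datasets that cannot
   support ANOVA (fewer than two groups, or any group with one
   replicate) are excluded from this filter with a warning.
4. **Presence** — a gene must pass all three filters simultaneously in
   at least two datasets.  Datasets excluded from ANOVA contribute
   nothing to the count.
5. **Correlation** — each kept gene's profile is its mean log2(FPKM + 1)
   per (dataset, tissue, treatment) cell; the log transform stabilizes
   the variance of skewed FPKM values and the +1 keeps zero observable.
   Pairwise Pearson correlations are computed between profiles, and a
   gene's score aggregates the r² of its positively correlated partners
   (negative correlations contribute 0 — anti-correlated genes are not
   co-stable).  The default aggregate is the median (robust to one
   aberrant partner; mean and max are available and the choice is logged
   in the report header).  Selection requires score ≥ 0.95 with the best
   partner's correlation p < 0.01.  A zero-variance profile scores 0
   with a reason flag rather than erroring.

One caveat worth stating plainly: loosening any single threshold
monotonically grows the *kept* set, but not necessarily the final
*selected* set, because enlarging the kept set changes every gene's
correlation-partner pool.  The tests assert the stage-wise property,
which is the one that actually holds.

# The four stability algorithms

The ranking substrate is a `cq_table` of long-format quantification
cycles.  Technical replicates are averaged arithmetically (no outlier
rejection — the convention for triplicate designs; any other policy
would be a guess).  Cq values at or beyond the 44-cycle ceiling of the
amplification program mean "not detected" and are rejected: a reference
gene must be expressed in every sample.  Ranking is per tissue, pooling
varieties and treatments, the way per-tissue stability panels are read.

With relative quantities $Q_{gs} = E_g^{\,\min_s C_q(g) - C_q(g,s)}$
(efficiency $E = 2$ unless per-gene standard-curve fits are supplied;
reported efficiencies exist in such studies but are not stated to feed
the stability analysis, so 2 is the default):

* **geNorm** — pairwise variation $V_{jk} = \mathrm{SD}_s\,
  \log_2(Q_{js}/Q_{ks})$; $M_j$ is the mean of $V_{jk}$ over partners,
  lower = more stable.  At $E = 2$, $V_{jk}$ equals the SD of the
  per-sample Cq difference exactly (asserted to 1e-12), so $M$ coincides
  with the comparative dCt statistic.  The classical iterative mode
  (drop the highest-M gene, recompute, until two remain) is implemented
  and reported, but the *rank* used by default is the full-panel M
  ordering: the per-tissue M charts order genes this way, and the
  comprehensive-ranking service the field uses reimplements geNorm as a
  one-shot M ranking.  The exclusion order (`genorm_rank_basis =
  "exclusion"`) has a documented pathology that our simulations
  reproduce: genes co-responding to the same treatments form clusters
  whose mutual pairwise variation is small, and with enough of them the
  endgame retains a co-regulated pair instead of the truly stable genes.
  The companion statistic $V_{n/n+1}$ (`genorm_pairwise_v()`) supports
  the how-many-references decision.
* **NormFinder** — a variance-components model on $y = \log_2 Q$.  Each
  sample is centered by its across-gene mean, which removes the shared
  loading component; per gene and treatment group the mean and variance
  of the centered values are estimated.  Centering mixes residuals
  across the $k$ genes, so the naive per-gene variance is corrected:
  $\hat\sigma^2_{ig} = \frac{k}{k-2}\left(s^2_{ig} - \frac{\sum_l
  s^2_{lg}}{k(k-1)}\right)$, clamped at 0 — the $k - 2$ denominator is
  why at least three genes are required.  Inter-group differences
  $d_{ig}$ (doubly centered, hence $(k-1)(G-1)$ free entries) are
  shrunken toward zero in proportion to their sampling variance
  $c_{ig} = \hat\sigma^2_{ig}/n_g$, with scale $\hat\gamma^2 =
  \max(0, \sum d^2/((k-1)(G-1)) - \bar c)$.  The stability value is the
  mean over groups of $|\tilde d_{ig}| + \sqrt{c_{ig}}$.  With a single
  group it degenerates to the SD of the gene's centered values, the
  case the oracle tests pin down exactly; the multi-group corrections
  are validated by simulation recovery, not by matching an external
  binary.
* **BestKeeper** — descriptive statistics of raw Cq: the sample SD (the
  ranking statistic), CV% = 100·SD/mean, and the Pearson correlation
  with the BestKeeper index (per-sample geometric mean of all
  candidates' Cq), which is reported but not ranked on.  The original
  tool's mean-absolute-deviation variant sits behind `stat = "mad"`.
  BestKeeper is deliberately *not* invariant to per-sample loading
  shifts — it is the one method that sees them, and the tests assert
  that difference.
* **Comparative dCt** — mean over partners of the SD of per-sample Cq
  differences; identical to geNorm M at $E = 2$.

**Comprehensive rank.**  A gene's comprehensive value is the geometric
mean of its ranks across the methods run (all four by default; ranks are
tie-averaged and consumed as-is).  Final ordering breaks ties by the
mean z-score of the raw stability values, then by gene id, so reports
are deterministic.

# Quantification

`fit_standard_curve()` regresses Cq on log10(dilution); the efficiency
in percent is $100\,(10^{-1/\text{slope}} - 1)$, so a slope of −3.3219
is 100% (E = 2).  A positive slope aborts with "inverted dilution
axis?".

`relative_expression()` computes efficiency-corrected ratios per
biological replicate, $E_t^{\Delta C_{q,t}} / \prod_r
(E_r^{\Delta C_{q,r}})^{1/|\text{refs}|}$, against a calibrator defined
as the arithmetic mean Cq of the tissue's mock (CK) replicates — the
exact calibrator is a convention; per-tissue CK mean is the simplest one
that makes the control's geometric-mean fold change exactly 1.  With all
E = 2 this is plain $2^{-\Delta\Delta C_q}$, the default; per-gene
fitted efficiencies are opt-in (`use_efficiencies = TRUE`).
Replicate statistics are computed on log2 fold changes (symmetric
errors) and reported back on the linear scale, so `mean_fc` is a
geometric mean.  `compare_normalizations()` contrasts schemes (each
top-ranked reference singly, the top three combined, the bottom-ranked
references) and summarizes divergence as the maximum over conditions of
the absolute log2 fold-change difference from the first scheme.

# The synthetic-data generator

`simulation_design()` holds the study conditions; the defaults are the
emulated design: six RNA-seq datasets; two varieties; leaf, shoot and
root; mock (CK), salt and drought treatments; three biological and three
technical replicates.  Noise is Normal on log2-FPKM and on Cq — both are
log-scale quantities, and no noise model is stated for the original
data.  Parameter choices, fixed once:

* `stable_noise_sd = 0.15` cycles (or log2-FPKM units): replicate noise
  of a well-behaved assay.
* `treatment_effect = 1.5`: planted condition shifts, in cycles (Cq) or
  log2-fold (FPKM).  Cq magnitudes are jittered ±10% per gene and cell
  (no two real genes share an identical response), keeping every planted
  shift at ≥ 1 cycle; FPKM group shifts draw magnitudes uniformly up to
  the effect.
* `sample_loading_sd = 0.3` cycles: a shared per-sample loading effect
  added to *all* genes of a sample.  It is included deliberately — the
  four methods differ precisely in how they cancel it (ratio methods and
  sample-centering do; raw-Cq descriptive statistics do not); without it
  they would be indistinguishable.
* `tech_rep_sd = 0.1` cycles; base Cq uniform in 24–34, inside the
  window such assays report.
* FPKM panels: one global baseline per gene, with candidate baselines
  from a normal (mean 6, SD 0.75 log2) truncated below at mean − 1 — a
  candidate reference gene is by definition abundantly expressed, and
  the truncation is what makes "planted genes constructed to pass the
  criteria" literally true.  Each dataset adds a shared log2 offset
  (SD 1.0) to all genes: global expression-level differences between
  sequencing experiments.  This shared component is what makes co-stable
  housekeeping genes correlate across datasets; with independent
  per-dataset baselines the correlation screen could never fire.  Half
  of the background genes form a low-expression stratum for the
  abundance filter to remove; all background genes carry condition
  shifts, as genuinely condition-responsive transcripts do.

What the generator does *not* emulate: count-based sampling noise and
its mean–variance relation, zero inflation/dropout, gene–gene
correlation beyond the shared dataset and loading effects, amplification
inhibitors, plate effects, or technical-replicate outliers.  Passing
tests therefore show that the algorithms recover a planted signal of the
stated size under log-normal noise — not that any particular biological
dataset satisfies those assumptions.

# Numerical conventions and degenerate inputs

Cq ceiling 44 (the cycling program length); Cq at the ceiling or ≤ 0
rejected.  Missing (gene, sample) cells are a hard error — every
stability algorithm needs a complete grid — with an explicit
`drop_incomplete_samples` opt-in that removes the sample from all genes.
geNorm exclusion ties break toward the alphabetically first gene id; the
final pair shares rank 1.5.  Zero-variance correlation profiles score 0
with a reason flag.  All generators route their randomness through one
seed and restore the caller's RNG state.

# Problem sizes used by the test suite

Oracle tests run on ≥ 100 random instances of at most 8 genes × 12
samples; identity and invariance tests on 10–50 random matrices;
recovery simulations on 200 replicates of the 12-gene single-tissue
design (stability, quantification bias) and 100 replicates of the
six-dataset panel (screening); null calibration pools 1,440 ANOVA
decisions.  These sizes make the stochastic checks reproducible in
minutes on one CPU while keeping binomial error on estimated rates
around one percentage point.

# Known limitations

* The comprehensive rank weights geNorm and dCt as separate methods
  although they coincide at E = 2; with all-default efficiencies the
  geometric mean effectively double-weights that statistic, as the
  four-method convention does.
* Under the planted-shift model, unstable genes whose salt and drought
  responses are concordant are partially invisible to ratio-based
  statistics (the pairwise SD shrinks common shifts); recovery
  simulations show geNorm-M/dCt placing the stable trio in their top 4
  in about 93–95% of replicates, against ~98–100% for NormFinder and
  BestKeeper.  This is a property of the statistics, not an
  implementation artifact.
* Screening cannot reproduce the absolute candidate counts of any real
  dataset collection; with undeposited raw data the cascade is validated
  on recovery of planted truth only.
* Two-way ANOVA, instrument-native file parsing, per-well
  amplification-curve efficiencies and plate-layout modeling are out of
  scope.
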