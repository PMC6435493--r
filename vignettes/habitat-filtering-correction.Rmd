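---
title: "Correcting habitat filtering in microbial correlation networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting habitat filtering in microbial correlation networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfnet)
```

## The problem

Co-occurrence networks built from amplicon data (16S, ITS, 18S) are a
standard way to generate hypotheses about microbial interactions. When the
samples going into one analysis come from several habitats — different
soils, body sites, host genotypes, or even sequencing centers — taxa whose
abundances track the habitat will appear correlated with each other even if
they never interact. This *habitat filtering* (HF) can dominate the network:
nodes cluster by habitat preference, and edges mostly say "these two taxa
like the same soil", masking the within-habitat associations of actual
biological interest.

## The correction

`hf_correct()` removes the habitat signal by centering each feature on its
within-habitat mean. For an abundance matrix $A$ (samples $\times$
features) and habitat assignment $H$, the corrected matrix is

$$C_{ij} = A_{ij} - \frac{1}{n}\sum_{k \in H_i} A_{kj},$$

where $H_i$ is the set of samples from sample $i$'s habitat and
$n = |H_i|$. Any per-habitat constant offset of a feature — precisely the
HF effect — is removed exactly, while covariation within habitats is left
untouched. Correlations (we use Spearman after correction) are then
computed on $C$.

The correction is linear and exact, which gives it three properties the
test suite asserts directly: per-habitat feature means of the output are
zero; the operation is idempotent; and adding arbitrary per-habitat
constants to any feature leaves the output unchanged. It assumes monotone
associations (rank or linear correlation downstream), discrete habitat
labels known in advance, and reasonably balanced habitat sizes — with very
unequal groups the pooled correlations are dominated by the larger habitat.
A habitat with a single sample is permitted (the formula is well defined;
its residuals are identically zero) but triggers a warning, since it
contributes nothing but noise reduction in the denominator of downstream
tests.

## Recommended real-data pipeline

`run_network()` wires the standard order: read counts, optionally rarefy to
the minimum depth, keep features present in at least 50% of samples
(inclusive boundary, presence meaning a strictly positive value), close to
relative abundances, centered log-ratio (CLR) transform, HF-correct,
correlate, threshold. CLR comes *before* the correction: compositional
artifacts are a property of the raw relative abundances, and the correction
is scale-agnostic — it centers whatever matrix it is given.

Tunable parameters, with defaults chosen for a multi-habitat amplicon
study:

| parameter | default | meaning |
|---|---|---|
| `prevalence` | 0.5 | minimum fraction of samples a feature is detected in |
| `pseudocount` | 1 | added before the CLR log (counts scale); the zero-handling strategy is deliberately explicit and logged in the manifest |
| `p_max` | 0.01 | edge significance cutoff, strict inequality |
| `r_min` | 0.75 | edge strength cutoff on \|r\|, strict inequality |
| `positive_only` | TRUE | keep only positive correlations in real-data networks |
| `rarefy_depth` | off | subsampling depth; samples below it are an error, not silently dropped |

P-values for both Pearson and Spearman come from the t approximation
$t = r\sqrt{(n-2)/(1-r^2)}$ with $n-2$ degrees of freedom, applied
uniformly at every sample size. At $n = 6$ an exact Spearman permutation
p-value would differ; we accept that inexactness so that every cell of the
benchmark grid uses the same machinery, and document it as a limitation.
Edge p-values are used raw (the cutoff is $p < 0.01$, not an adjusted
rate); a Benjamini–Hochberg option exists but is off by default. Constant
features get an undefined correlation recorded as `NA` with p-value 1, so
they can never form edges.

## The simulator

`simulation_truth()` + `simulate_dataset()` emulate a two-habitat community
of 50 features:

1. **Design** — each unordered feature pair is independently "perfectly
   correlated" ($\pm 1$, fair-coin sign) with probability 0.1, else 0.
2. **Projection** — the $\pm 1/0$ design is generally inconsistent (A~B and
   B~C perfect but A~C absent), so it is projected to the nearest valid
   correlation matrix in Frobenius norm (`Matrix::nearPD`, unit-diagonal
   constraint, eigenvalue floor 0) and scaled to a covariance with every
   log-scale standard deviation equal to 0.1. That projected matrix
   $R^\ast$, not the raw design, is the truth against which detected
   correlation matrices are scored by RMSE; the raw design $T$ is the truth
   for edge-level proportion-correct. The projection tolerance is $10^{-8}$
   on the minimum eigenvalue.
3. **Draws** — samples are multivariate normal on the log scale,
   exponentiated to lognormal abundances.
4. **HF injection** — each feature is independently HF-affected with
   probability 0.1, preferring habitat B (+1) or A (−1) with equal
   probability. An affected feature gains `hf_strength` times its own
   empirical abundance standard deviation, added on the abundance scale to
   every sample of its preferred habitat. Applying the shift after
   exponentiation keeps abundances non-negative even at strength 10, and
   "times the abundance standard deviation" then holds on the scale where
   the shift acts; `scale = "log"` is available as the alternative reading.
5. **Closure** — each sample is divided by its total *after* the shift, so
   the habitat effect survives into the observed compositions.

Defaults are the study conditions throughout: 50 features, 10% correlated
pairs, 10% HF-affected features, log-scale sd 0.1, HF strengths 0–10, 6–60
total samples split evenly over habitats "A" and "B".

What the simulator does **not** emulate: sequencing noise (multinomial
resampling, depth variation), zero inflation (lognormal draws are strictly
positive, which is also why the benchmark can run CLR with pseudocount 0),
more than two habitats, and taxonomic structure. Passing benchmarks
therefore show that the correction removes additive habitat shifts from
compositional lognormal data — not that it is robust to sparse, noisy real
counts, where the CLR pseudocount and prevalence filter carry more weight.

## The benchmark

`benchmark_grid()` scores three methods per replicate dataset — Spearman
and Pearson on the raw relative abundances, and Spearman after correction —
with two metrics: RMSE of the full detected correlation matrix against
$R^\ast$ (no p-thresholding, `NA` scored as 0), and the proportion of edges
in the $p < 0.01$ network (both signs) that are true design pairs with
matching sign. Edgeless networks contribute a missing proportion, excluded
from cell means and counted in the summary. Methods are compared per cell
with a paired two-sided Wilcoxon signed-rank test across replicates — the
same datasets are scored by every method, so pairing is natural, and the
rank test avoids a normality assumption on bounded proportions. When every
paired difference is zero the p-value is defined as 1.

The package's own reference configuration, used by its acceptance checks,
is one mid-grid condition — 30 samples, HF strengths 0 and 5, 50
replicates — which runs in seconds and reproduces the qualitative findings:
all methods agree at strength 0 (mean proportion-correct within 0.1 of each
other); under HF the corrected method is better on both metrics with
signed-rank $p \ll 0.05$; and the corrected method's performance is stable
across strengths (difference under 0.1) while uncorrected Spearman drops by
more than 0.1.

## Bias diagnostics for real data

Without ground truth, residual HF bias is quantified through habitat
preference: `assign_habitat_preference()` labels each feature with the
habitat(s) where it is significantly more abundant (pairwise Wilcoxon
rank-sum tests, BH-adjusted across all feature × pair tests, adjusted
$p \le 0.05$, a feature must beat every other habitat to earn a label).
This is a deliberately simple nonparametric stand-in; for fidelity to a
negative-binomial differential-abundance analysis, labels can instead be
supplied from file (`read_preference_labels()`).
`shared_preference_proportion()` then reports the fraction of edges joining
two nodes with overlapping label sets (edges touching unlabeled nodes count
in the denominator only), `random_baseline_proportion()` gives the value
expected of a random graph over the same nodes (analytic pair enumeration,
or Monte Carlo), and `proportions_chisq()` compares two networks' shared
proportions (Pearson chi-square, 1 df, no continuity correction).
`pcoa_braycurtis()` provides the look-before-you-correct ordination:
habitat separation in the leading Bray–Curtis principal coordinates is the
signal that correction is warranted.

## Numerical and design choices

- **Seeds.** One base seed per run; every randomized stage derives its own
  seed by hashing the base seed with stage/replicate tags (`derive_seed`),
  so adding a stage never reshuffles earlier randomness, and every grid
  cell × replicate is independently reproducible. All derived seeds stay
  below $2^{31}$.
- **Degenerate inputs.** Zero-sum samples, all-features-removed filters,
  samples below rarefaction depth, and missing habitat assignments are
  errors naming the offending rows; constant features and edgeless
  networks are representable results (`NA`), not errors; an all-identical
  ordination returns zero coordinates.
- **Mode detection.** A table whose rows sum to 1 within $10^{-6}$ is
  treated as relative; the stricter $10^{-9}$ closure tolerance applies to
  tables the package itself constructs.
- **Ties.** Spearman uses mid-ranks, so it equals Pearson on ranks exactly
  (asserted to $10^{-12}$).
- **Strict cutoffs.** $p < p_{max}$ and $|r| > r_{min}$, matching the usual
  reading of "p < 0.01" and "r > 0.75"; the strength cutoff applies to
  $|r|$, with `positive_only` as a separate, explicit switch.

## Limitations

The correction handles discrete, pre-specified habitats only — continuous
environmental gradients need regression-style approaches. It assumes
monotone associations and does not address conditional independence (two
taxa sharing a partner will still correlate) or severe compositionality in
low-diversity data, where a dedicated compositional method is more
appropriate. The built-in preference labeling is not a differential
abundance model; treat its labels as a screening diagnostic.
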