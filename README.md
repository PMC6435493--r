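# hfnet — habitat-filtering correction for microbial correlation networks

Co-occurrence network analysis of amplicon data (16S/ITS/18S) infers
putative microbial interactions from correlated abundances. When one
analysis pools samples from several *habitats* — different soils, body
sites, host genotypes, sequencing batches — taxa that merely share a
habitat preference become strongly correlated, and the network ends up
describing habitat structure instead of microbial associations. This
package is for microbial ecologists who want consensus networks across
related habitats without that bias.

The core is a one-line correction: center every feature on its
within-habitat mean before detecting correlations. For an abundance matrix
*A* (samples × features) and habitat assignment *H*,

&nbsp;&nbsp;&nbsp;&nbsp;*C<sub>ij</sub> = A<sub>ij</sub> − (1/n) Σ<sub>k∈H<sub>i</sub></sub> A<sub>kj</sub>*,

where *H<sub>i</sub>* is the set of samples from sample *i*'s habitat and
*n = |H<sub>i</sub>|*. Per-habitat mean shifts — the habitat-filtering
signal — are removed exactly; within-habitat covariation is untouched.
Spearman correlations on *C* then yield the network.

Around the correction the package provides the full workflow:
compositional preprocessing (rarefaction, prevalence filter, centered
log-ratio transform), correlation + p-value matrices and thresholded
networks (TSV/GraphML export), a correlated-lognormal simulator with a
tunable habitat-filtering effect, benchmark scoring against simulation
truth, and habitat-preference bias diagnostics (shared-preference edge
proportion with analytic/Monte-Carlo random baselines, chi-square
comparison, Bray-Curtis PCoA).

## Worked example

The defining toy: one feature over two habitats, values (2, 4) in habitat
A and (1, 3) in B. Centering each habitat removes the between-habitat
shift and keeps the within-habitat variation:

```r
library(hfnet)
x <- abundance_table(matrix(c(2, 4, 1, 3), 4, 1), mode = "counts")
h <- c(S1 = "A", S2 = "A", S3 = "B", S4 = "B")
unclass(hf_correct(x, h))[, 1]
#> S1 S2 S3 S4
#> -1  1 -1  1
```

At simulation scale — 50 features, 10% truly correlated pairs, 10%
habitat-affected features, 30 samples over two habitats, habitat shift of
5 abundance standard deviations, 20 replicate datasets:

```r
b <- benchmark_grid(hf_strengths = c(0, 5), n_samples_list = 30, n_reps = 20,
                    methods = c("spearman", "hf_corrected"), base_seed = 1)
b$summary
#>   hf_strength n_samples       method rmse_mean rmse_sd prop_correct_mean
#> 1           0        30 hf_corrected     0.188 0.00726             0.740
#> 2           0        30     spearman     0.185 0.00632             0.763
#> 3           5        30 hf_corrected     0.186 0.00926             0.757
#> 4           5        30     spearman     0.207 0.01303             0.629
```

Reading the numbers: `prop_correct_mean` is the fraction of detected
network edges (p < 0.01) that are true design correlations with the right
sign; `rmse_mean` is the error of the full detected correlation matrix
against the simulated one. With no habitat effect (strength 0) the two
methods are equivalent. Under a strong habitat effect, uncorrected
Spearman degrades (0.763 → 0.629 correct; RMSE up 12%) while the corrected
method is unaffected (0.740 → 0.757), and the paired signed-rank
comparison of the 20 replicates gives p ≈ 1e-4:

```r
subset(b$comparisons, hf_strength == 5)
#>   hf_strength n_samples method_a     method_b   p_rmse p_prop_correct
#> 2           5        30 spearman hf_corrected 0.000151        0.00013
```

For real data, `run_network()` wires the recommended order (rarefy →
prevalence ≥ 50% → relative abundance → CLR → HF-correct → Spearman →
p < 0.01, r > 0.75, positive edges), and a thin CLI wraps the same
pipeline functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "hfnet.R", package = "hfnet"))') \
  network --abundance counts.tsv --habitats habitats.tsv --out_dir net/
```

A tiny synthetic example table ships in `inst/extdata/`
(`synthetic_abundance.tsv`, `synthetic_habitats.tsv`). See the vignette
(`vignettes/habitat-filtering-correction.Rmd`) for the model, the
simulator's assumptions, and every tunable parameter.

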