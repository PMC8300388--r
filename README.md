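# panelprune

How you thin a dense SNP chip changes what genomic prediction can do with
it. `panelprune` is an R package for quantifying that: it builds SNP panels
from high-density genotype data by three pruning strategies — minimum
physical distance between adjacent markers (**PhyD**), pairwise linkage
disequilibrium (**GenD**, sliding-window r² pruning) and uniform random
sampling (**RanD**) — and relates four *marker-density measurements* of each
panel to its cross-validated genomic prediction accuracy. It is aimed at
animal and plant breeders deciding how to design low- and moderate-density
panels, and at anyone estimating SNP heritability who prunes markers by LD
out of habit.

## The statistics at the core

For a panel whose adjacent within-chromosome markers are separated by
physical gaps d and adjacent-pair squared dosage correlations r², the four
density measurements are d̄, σ²_d, r̄² and σ²_r² (means and sample
variances). Genomic prediction uses GBLUP:

    y = 1μ + Zg + e,   g ~ N(0, G σ²_g),   e ~ N(0, I σ²_e)

with VanRaden's genomic relationship matrix

    G = WW′ / (2 Σₖ pₖ(1 − pₖ)),   W = M − 2P,

where M is the 0/1/2 dosage matrix and pₖ the allele frequency of marker k.
Variance components are estimated by AI-REML (average-information updates
with step-halving and an EM-REML fallback); GEBVs for phenotyped and
unphenotyped individuals come from the joint mixed-model equations. Panel
accuracy is the Pearson correlation between phenotype and pooled held-out
GEBVs in repeated k-fold cross-validation.

To ask whether a density measurement drives accuracy *at a fixed panel
size*, measurements and accuracies are z-standardized within each SNP-number
level (mean 0, sample SD 1 across the three methods) and pooled across
levels and traits; the Pearson correlation of the pooled pairs is tested
with t = r·√((n−2)/(1−r²)).

The package ships a 33-row reference summary table (11 SNP-number levels ×
3 methods, with measurements and 10×10-fold CV accuracies for three dairy
traits from a German Holstein population) and a seedable genotype/trait
simulator — haplotypes from a first-order Markov chain whose allele
correlation decays as exp(−d/λ) in physical distance — so the entire
pipeline runs and is testable without any external data.

## Worked example

```r
library(panelprune)

# simulate a small dense-chip dataset: 2 chromosomes x 25 Mb, 4,000 SNPs
cfg <- sim_config(n_individuals = 300, n_markers = 4000,
                  chromosome_lengths_bp = rep(2.5e7, 2),
                  spacing_model = "clustered", ld_decay_lambda_bp = 2e5,
                  seed = 11)
geno <- simulate_genotypes(simulate_marker_map(cfg), cfg)
trait <- simulate_trait(geno, trait_architecture("SCS_like", h2 = 0.5),
                        seed = 12)

# three 800-SNP panels, one per pruning strategy
phyd <- prune_to_count(geno, "PhyD", 800, seed = 1)
gend <- prune_to_count(geno, "GenD", 800, seed = 1)
rand <- prune_rand(geno$map, 800, seed = 1)

density_measures(subset_markers(geno, phyd))
#> density_measures: d_mean 62632.9 bp, d_var 5.329e+08 bp^2, r2_mean 0.5353, r2_var 0.01138 (798 gaps)
density_measures(subset_markers(geno, rand))
#> density_measures: d_mean 62283.8 bp, d_var 4.043e+09 bp^2, r2_mean 0.6089, r2_var 0.06644 (798 gaps)

for (p in list(phyd, gend, rand)) {
  cv <- cv_accuracy(geno, trait$phenotypes, panel = p,
                    n_folds = 5, n_repeats = 2, seed = 3)
  cat(sprintf("%s: mean accuracy %.3f\n", p$method, cv$mean_accuracy))
}
#> PhyD: mean accuracy 0.448
#> GenD: mean accuracy 0.414
#> RanD: mean accuracy 0.416
```

At the same panel size PhyD produces a gap variance roughly an order of
magnitude below RanD's and the highest prediction accuracy — equally spaced
markers leave no long untagged stretches of genome, while random and
LD-based panels leave gaps that orphan the QTL inside them.

The packaged reference table reproduces the same relationship at full
scale:

```r
rt <- reproduce_table1()
rt$sigma_d2_all
#> correlation_test: sigma_d2 vs accuracy(FP,MY,SCS) over levels {1,2,3,4,5,7,10,15,20,30,50}
#>   r = -0.8338, t = -14.875, p = 9.09e-27 (n = 99 pairs)
rt$sigma_d2_scs_mod
#> correlation_test: sigma_d2 vs accuracy(SCS) over levels {15,20,30,50}
#>   r = -0.5532, t = -2.100, p = 0.06208 (n = 12 pairs)
```

A negative pooled correlation of −0.83 between the adjacent-gap variance
σ²_d and GEBV accuracy over all 99 standardized pairs: the more variable
the spacing, the worse the prediction. Restricted to moderate densities and
the purely polygenic trait, σ²_d matters less (−0.55) while the adjacent-r²
measurements take over (≈ −0.8, see `rt$r2_mean_scs_mod`).

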