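---
title: "Marker-density measurements, panel pruning and GBLUP accuracy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-density measurements, panel pruning and GBLUP accuracy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelprune)
```

## The question the package addresses

"Marker density" in genomic prediction is usually equated with the number
of SNPs on a panel. But two panels with the same SNP count can distribute
those SNPs very differently: one evenly along the genome, one in clumps
separated by long empty stretches. `panelprune` operationalizes four
measurements that separate these situations — the mean $\bar d$ and sample
variance $\sigma^2_d$ of the physical distance (bp) between adjacent
within-chromosome SNPs, and the mean $\bar{r^2}$ and sample variance
$\sigma^2_{r^2}$ of the squared dosage correlation between adjacent SNPs —
and provides the machinery to test which of them predicts GBLUP accuracy
when the SNP count is held fixed.

At a fixed panel size $\bar d$ is essentially determined by the genome
length, so the informative measurements are $\sigma^2_d$ (spacing
unevenness) and the two $r^2$ statistics (local LD retained on the panel).

## Panel construction

Three strategies build a panel from a dense marker set:

* **PhyD** — greedy left-to-right scan per chromosome keeping the next
  marker at least `min_gap_bp` beyond the last kept one. This approximately
  minimizes $\sigma^2_d$ at a given size.
* **GenD** — sliding-window pairwise-$r^2$ pruning: within each 50 kb
  window, while any surviving pair has $r^2$ above the threshold, one
  member is removed; the window advances 5 kb and the process repeats.
  Windows never span chromosome boundaries.
* **RanD** — uniform sampling without replacement.

When a GenD pair violates the threshold, the member with the smaller minor
allele frequency is removed (ties: the later position). The choice of
victim is not dictated by the algorithm's usual description, which says
only that one of the pair is dropped; preferring to discard the rarer
allele retains more informative markers and, crucially, makes the output
deterministic so that pruning is exactly reproducible.

`prune_to_count()` hits an exact panel size by bisecting the threshold
(PhyD size is non-increasing in the gap threshold, GenD size
non-decreasing in the $r^2$ threshold) and then removing surplus markers
from the larger bracketing panel by a seeded uniform draw. The bisection
for GenD is capped at $r^2 = 0.999$: with a strict "greater than" removal
rule a cap of exactly 1 would never prune perfect duplicates, and no
panel-size ceiling would exist. With the cap, duplicated markers always
collapse, so there is a largest achievable GenD panel and targets above it
raise a `"target unreachable"` error — on real dense chips the LD-pruning
route simply cannot produce the largest panels, and the pipeline records
such grid cells as skipped.

Two properties of the stepped window are worth knowing. First, a pair of
markers separated by slightly less than the window span (within one step
of it) may never share a window position and can survive above the
threshold; this is inherent to every stepped-window pruner, not a defect
of this one. Second, the final verification pass rescans the *same* window
grid the pruner walked (anchored at each chromosome's first marker), so
"no surviving pair within any window position exceeds the threshold" is
checked exactly.

`scenario_gap_sample()` builds panels by walking marker *ranks*: start at
marker 1 and advance by a gap drawn from
$\mathcal N(\text{mean\_gap}, \sqrt{\text{gap\_variance}})$, rounded to
the nearest integer and truncated below at 1 (the constant mean gap when
the variance is 0). Panels so built share $\bar d$ but differ in
$\sigma^2_d$, isolating the spacing-variance effect from panel size.
Rounding and truncation conventions are the package's own choice; with a
mean gap of 67 and variances up to 80 the truncation is a $7.5\sigma$
event and numerically irrelevant.

## The GBLUP engine

The prediction model is $y = 1\mu + Zg + e$ with
$g \sim N(0, G\sigma^2_g)$, $e \sim N(0, I\sigma^2_e)$ and VanRaden's
$G = WW'/(2\sum_k p_k(1-p_k))$, $W = M - 2P$. Allele frequencies come from
the data themselves; missing dosages are mean-imputed to $2p_k$ (zero
after centering) and monomorphic markers contribute zero to numerator and
denominator alike. No reliability weighting is applied to the phenotypes:
$R = I\sigma^2_e$ exactly, because the intended phenotypes are
high-reliability EBV-like pseudo-records with one observation per
individual and no fixed effects beyond the mean.

`ai_reml()` estimates $(\sigma^2_g, \sigma^2_e)$ directly (not as ratios)
by average-information REML. Implementation choices, stated explicitly
because the algorithm's users rarely see them:

* One eigendecomposition $G = U\,\mathrm{diag}(d)\,U'$ turns every
  iteration into $O(n)$ vector arithmetic in the rotated basis.
* Newton steps use the average-information matrix
  $\mathrm{AI}_{ij} = \tfrac12 y'PV_iPV_jPy$ with step-halving on the
  restricted log-likelihood; a step that would leave the parameter space,
  or an ill-conditioned AI system, falls back to an exact EM-REML update.
  With $G = I$ only the total variance is identifiable, the AI matrix is
  singular by construction, and the EM path estimates the total — the
  package's tests assert the sum, never the split, in that limit.
* Components are floored at $10^{-8}\,\mathrm{var}(y)$; convergence
  requires the parameter change (scaled by $\mathrm{var}(y)$, so boundary
  solutions can converge) and the log-likelihood change both below
  $10^{-8}$, with at most 100 iterations. Starting values are
  $\sigma^2_g = \sigma^2_e = \mathrm{var}(y)/2$. Non-convergence is a
  flag on the result, not an exception; cross-validation excludes flagged
  folds from pooling and warns.

`solve_mme()` solves the joint mean-and-GEBV system
$(Z'Z/\sigma^2_e + (G\sigma^2_g)^{-1})\hat g = Z'(y-\hat\mu 1)/\sigma^2_e$
with validation individuals present in $G$ but absent from $Z$ — one code
path for training and prediction, algebraically equal to the direct
$V^{-1}$-based BLUP (asserted to $10^{-8}$ against that oracle in the
tests). If $G$ is numerically singular (reciprocal condition below
$10^{-12}$, common for small panels), a ridge of
$10^{-8}\overline{\mathrm{diag}}$ is added and logged as a warning. When
$\sigma^2_g \le 10^{-10}\sigma^2_e$ the full-shrinkage limit is returned
directly ($\hat g = 0$, $\hat\mu$ the training mean) rather than inverting
a numerically meaningless system.

## Cross-validation and the pooled correlation test

`cv_accuracy()` re-estimates variance components per training fold — the
fold's model is fit entirely from its own training data — and pools each
repeat's held-out GEBVs into a single Pearson correlation with the
phenotype, one accuracy per repeat. Per-fold variance components are
retained on the result for inspection. Accuracy is invariant to affine
rescaling of the phenotype, which is why EBV-like pseudo-phenotypes on an
arbitrary scale are acceptable inputs.

`pooled_correlation()` implements the within-level standardization
$z_i = (x_i - \overline x)/\mathrm{sd}(x)$ applied separately to the three
method values of a measurement at each SNP-number level, and equally to
each trait's three accuracies; every standardized measurement is then
paired with its row's standardized accuracies and pooled across levels and
traits. The sample SD ($n-1$, here over $n=3$) is fixed by convention —
the pooled correlation is invariant to any common per-level scale factor,
so the $n$ vs $n-1$ choice cannot change $r$; it is pinned only so that
standardized values themselves are reproducible. The $t$-test treats all
pairs as independent (pairs sharing a row share their measurement value);
no repeated-measures correction is applied, deliberately, because the
packaged reference analysis defines the statistic this way and the package
reproduces it exactly. The packaged 33-row reference table is
checksum-verified on load; from it, `reproduce_table1()` computes the
all-level correlations of each measurement with accuracy (99 standardized
pairs) and the moderate-density (15–50 k) SCS-only correlations (12
pairs).

## What the simulator emulates — and what it does not

`simulate_genotypes()` draws two independent haplotypes per individual
from a first-order Markov chain along each chromosome: the allele at
marker $j$ has marginal frequency $p_j$ and targets correlation
$\rho_j = e^{-\mathrm{gap}_j/\lambda}$ with marker $j-1$, so correlation
between any two markers decays as $e^{-D/\lambda}$ in their distance $D$
(correlations multiply along a Markov chain). Allele frequencies follow a
reflected random walk within `[maf_low, maf_high]` whose step SD grows
with $\sqrt{\mathrm{gap}/\lambda}$ — real allele frequencies are spatially
autocorrelated through shared genealogy, and without this smoothness the
binary chain's transition probabilities clip at 0/1 and long-range LD
collapses. Allele labels are then flipped at random markers so the
counted-allele spectrum is two-sided. Clustered maps draw gaps log-normal
(`spacing_log_sd`, default 1), giving the heavy right tail of real dense
chips; uniform maps give exactly equal gaps.

`simulate_trait()` implements three architectures named for contrasting
dairy traits: `FP_like` (2 major QTL at 10× the small-effect SD plus 300
small), `MY_like` (20 moderate at 3× plus 300 small) and `SCS_like` (500
small only), with default heritabilities 0.5, 0.4 and 0.3. The QTL counts
and effect-size ratios are declared package defaults — chosen as plausible
for a major-gene, an oligogenic and a polygenic dairy trait — not
estimates from any dataset. Phenotypes are
$y = g - \bar g + e$ with $e$ scaled so
$\mathrm{var}(g)/\mathrm{var}(y)$ hits the target $h^2$
($h^2 = 1$ means noise-free).

The simulator deliberately omits population history: no pedigree or
family structure, no selection, no mutation model, and LD purely local
(exponential decay, no long-range admixture LD). Consequently simulated
accuracies are driven by LD tagging alone and sit well below what a real
half-sib-structured cattle population shows at the same $n$ — relatedness
between training and validation animals, which inflates real-data
accuracy, is absent by design. Passing simulation-based tests therefore
demonstrates the *mechanisms* (density effects, estimator calibration),
not real-data accuracy levels, which require the original genotypes.

## Problem sizes used by the test suite

The suite exercises every mechanism at sizes a desk machine handles in
about a minute:

* BLUP oracle equivalence: 200 random mixed-model instances, $n \le 20$.
* REML calibration: 20 simulated polygenic datasets, $n = 800$, 2,000
  SNPs, target $h^2 = 0.5$; the mean estimate must land within $\pm 0.05$.
* Spacing-variance mechanism: 10 simulated clustered-map datasets
  ($n = 500$, 50,000 markers on 5 × 50 Mb, $\lambda = 200$ kb — long-range
  LD typical of small-$N_e$ livestock at these distances), rank-gap panels
  at variances {0, 20, 40, 80} and mean gap 67, scored by paired 5-fold
  2-repeat CV sharing folds across scenarios; the Spearman correlation of
  the four mean accuracies with the gap variance must be non-positive.
  The decision to pair data and folds across scenarios removes most
  between-run noise and is what makes the weak single-seed effect visible
  in aggregate.

## Known limitations

* The GenD implementation is the pairwise windowed pruner; the one-line
  description of LD pruning as "the multiple correlation coefficient of
  one SNP regressed on all others" would be a VIF-style criterion, which
  is *not* what the windowed algorithm computes. The pairwise algorithm is
  implemented because that is the algorithm actually specified
  step-by-step; the discrepancy in wording is documented here and the
  VIF variant is out of scope.
* Which member of a high-LD pair is removed is a convention (smaller MAF
  here); other implementations remove the other member, so panels can
  differ marker-by-marker even at identical thresholds.
* The Hardy–Weinberg QC test is the plain 1-df chi-square on observed vs
  expected genotype counts, not an exact or mid-p test. For the intended
  post-imputation data with large $n$ the distinction is minor, but users
  filtering small samples at stringent thresholds should be aware.
* Variances of density measurements use the $n-1$ denominator throughout;
  with thousands of gaps this is indistinguishable from $n$, but the
  convention is fixed for test determinism.
* Single trait, single random effect, mean-only fixed effects. Multi-trait
  models, additional fixed effects, weighted or LD-adjusted relationship
  matrices and Bayesian whole-genome regressions are out of scope.
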