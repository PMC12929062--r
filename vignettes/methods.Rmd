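---
title: "Models and methods behind rhizogwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rhizogwas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`rhizogwas` implements a host-microbiome quantitative-genetics pipeline: it
screens rhizosphere amplicon sequence variants (ASVs) for host-genetic
control, maps that control to loci with a mixed-linear-model association
engine, characterises the regulatory architecture of root gene expression
(local and distant eQTL, trans hotspots), predicts plant nutritional traits
from combinations of omics similarity kernels, and assembles the resulting
evidence into a regulatory network. This vignette explains each model, the
parameters that matter, and the design choices made where the methodology was
genuinely open.

## 1. Plot-level variance components and heritability

ASV abundances from a replicated field trial are modelled per environment as

$$y_{ijk} = \mu + g_i + r_j + b_{jk} + e_{ijk},$$

with genotype ($g_i$), replicate ($r_j$), block nested within replicate
($b_{jk}$) and residual all random and mutually independent normal. The fit
is REML via `lme4` (`fit_plot_lmm()`); when the data contain no block
structure beyond replicates the block term is dropped automatically.
Broad-sense heritability on an entry-mean basis is

$$H^2 = \frac{\sigma_g^2}{\sigma_g^2 + \sigma_e^2 / R},$$

where $R$ is the number of replications (`estimate_h2()`). Features with
$H^2 > 0.15$ (the default screen in `h2_screen()`) are considered under
host-genetic control. Genotype means for downstream association work are
BLUEs: the model is refitted with genotype fixed and the remaining terms
random (`compute_blues()`); in a balanced design these reduce exactly to
arithmetic genotype means, and in unbalanced designs they are the GLS
estimates under the fitted random structure.

Before any of this, counts are filtered (total reads >= 10,000 and detection
in >= 80% of samples) and transformed to log relative abundance. Zeros force
a pseudocount; we use `1e-6` on the relative-abundance scale, small enough
not to compress genuine low abundances yet bounded away from `log(0)`. The
choice matters mainly for sparsely observed ASVs, which the prevalence filter
is designed to remove first.

## 2. The mixed-model association engine

GWAS, eGWAS and TWAS all share one engine, the standard "Q + K" mixed linear
model

$$\mathbf{y} = X\boldsymbol\beta + \mathbf{m}a + \mathbf{g} + \mathbf{e},
\qquad \mathbf{g} \sim N(0, G\sigma_g^2),\quad
\mathbf{e} \sim N(0, I\sigma_e^2),$$

where $\mathbf{m}$ holds minor-allele dosages (GWAS/eGWAS) or standardized
expression values (TWAS) and $G$ is a similarity kernel: the VanRaden genomic
relationship matrix $ZZ'/(2\sum_k p_k(1-p_k))$ for marker data
(`vanraden_grm()`), or the feature kinship $MM'/c$ with $M$ the standardized
feature matrix and $c$ the mean diagonal of $MM'$ (`feature_kinship()`, mean
diagonal exactly 1 by construction).

Variance components are estimated once per trait (`reml_null_fit()`) by
eigendecomposing $G$ and profiling the restricted likelihood over the
variance ratio $\lambda = \sigma_g^2/\sigma_e^2$ on a log grid spanning
$[10^{-5}, 10^5]$, refined by one-dimensional optimization — the EMMA
rotation. The rotation is cached and reused for the scan, and for eGWAS the
eigendecomposition itself is shared across all expression traits.

The scan (`p3d_wald_scan()`) holds the variance ratio fixed at the null
estimate ("population parameters previously determined") and computes, per
feature, the GLS effect estimate $\hat a$ and its Wald statistic
$W = \hat a^2 / \mathrm{var}(\hat a)$, referred to $\chi^2_1$. One detail is
deliberately different from the strictest P3D variant: the residual *scale*
is re-estimated per feature from the augmented-model weighted residual sum of
squares with $n - p - 1$ degrees of freedom, while only the variance *ratio*
stays fixed. This makes the statistic reduce exactly to the squared OLS
t-statistic when the kinship is the identity — a sharp correctness oracle —
at negligible cost, since the quantity is available in closed form from the
same projections. A consequence worth knowing: because $W$ is t-squared
distributed in finite samples, the $\chi^2_1$ reference is mildly
anticonservative in its far tail (at $n \approx 150$ the per-marker rate at
$p \approx 2.5\times10^{-4}$ is about 1.4x nominal), so family-wise null
discovery rates after FDR sit nearer 8% than 5% at that sample size. At the
nominal 0.05 level calibration is tight (type-I error within [0.04, 0.06],
genomic inflation $\lambda_{GC} \approx 1$ on 10,000 null markers).

Fixed covariates default to an intercept; leading principal components of the
kinship can be added as "Q" (`n_pcs` in `study_spec()`), since published
Q + K analyses rarely state how Q was built. Multiple testing follows the
study design: BH FDR at 5% within each response trait for GWAS and TWAS, and
Bonferroni-Holm across the marker panel for eGWAS (`adjust_pvalues()`
reports the first-step threshold $\alpha/m$; with $m = 239{,}172$ and
$m = 292{,}839$ markers at $\alpha = 0.05$ this gives $2.09\times10^{-7}$ and
$1.71\times10^{-7}$).

## 3. LD intervals, eQTL classes, hotspots

LD between markers is the squared Pearson correlation of dosage codes
(composite LD, allele-flip invariant). LD decay (`ld_decay_profile()`) is
the distance at which the monotone-smoothed mean $r^2$ within a 500-kb window
first falls below 0.1.

Each significant SNP is assigned an interval by scanning outward to the
position where $r^2$ with the focal SNP *first* drops below 0.1
(`ld_boundaries()`); the scan is one-pass by design — LD recovering above
threshold further out does not re-open the interval, a literal reading of
"first dropped below". Intervals that overlap, or whose peak SNPs are less
than 50 kb apart (strict inequality), are merged by single linkage into
independent QTL regions, each represented by its most significant member
(ties broken by position; `merge_qtl_intervals()`). Merging is idempotent
and order-invariant.

An eQTL is *local* to its gene if both are on one chromosome and either
overlap or lie within 50 kb (inclusive) of each other, measured between the
facing interval ends; otherwise *distant* (`classify_eqtl()`). Distant-eQTL
lead positions are scanned for hotspots with sliding 100-kb windows (step
half a window): each window's event count is tested against a Poisson null
at the genome-wide event density, window p values are BH-adjusted, and
adjacent significant windows merge into maximal regions
(`detect_hotspots()`, significance 0.01). This windowed Poisson scan is our
own statistic honouring the published window and significance settings; it is
not a re-implementation of any specific scan package's internals. It detects
a planted 50-event hub over 50 background events with essentially unit power
and stays quiet on uniform nulls in >= 95% of runs.

## 4. Multi-kernel prediction

Ionome traits and ASV abundances are predicted by

$$\mathbf{y} = 1_n\mu + \sum_{i=1}^{k}\mathbf{m}_i + \mathbf{e},\qquad
\mathbf{m}_i \sim N(0, V_i\sigma_{m_i}^2),$$

with up to four kernels $V_i$ (VanRaden for SNP layers, feature kinship for
expression and ASV layers). `fit_multikernel()` estimates the variance
components by REML — a single kernel reuses the eigen-rotation exactly; for
several kernels the restricted likelihood is optimized over log-variances
with dense Cholesky solves, comfortable at panel sizes of a few hundred. A
Gibbs sampler with scaled-inverse-$\chi^2$ priors (5,000 iterations, 1,000
burn-in by default) is available as `method = "gibbs"` for fidelity to
Bayesian variance estimation; REML is the default because it is deterministic
and the downstream BLUP mechanics are identical.

Held-out genotypes are predicted through the BLUP cross-covariance
$\hat{\mathbf{y}}_{test} = \hat\mu + \sum_i \hat\sigma_{m_i}^2
V_i[test,train] V_{train}^{-1}(\mathbf{y}_{train} - \hat\mu)$; kernels are
built once on all genotypes, as is standard for precomputed similarity
matrices. `kernel_cv_predict()` runs repeated 5-fold cross-validation with
fold shuffles derived from a single seed by a per-repeat counter, so results
are bitwise reproducible; accuracy is the Pearson correlation between
observed and pooled predicted values. `enumerate_scenarios()` spans all
non-empty kernel subsets — 15 scenarios for four omics layers, 7 for three.

Expected accuracy follows $r \approx \sqrt{h^2\, n/(n + M_e)}$ with $M_e$ the
effective number of independent chromosome segments. The acceptance-level
check that a trait generated from the genomic kernel at $h^2 = 0.5$ is
predicted with $r \approx \sqrt{h^2} \approx 0.7$ therefore uses a panel in
the low-$M_e$ regime: whole-chromosome founder mosaics (5 chromosomes, 3
founders, $M_e \approx 10\text{-}15$), with component variances rescaled to
their targets exactly so the realized signal-to-noise is $h^2$ rather than a
draw around it. On high-$M_e$ panels (thousands of weakly linked segments)
the same machinery is correct but accuracy is intrinsically far below
$\sqrt{h^2}$ — that is biology, not a defect.

## 5. Mantel tests and the network

`mantel_test()` correlates the upper triangles of two distance matrices and
permutes rows and columns of the second jointly;
$p = (1 + \#\{r_{perm} \ge r_{obs}\})/(1 + \text{permutations})$, one-sided
upper tail, 1,999 permutations by default (so identical matrices give
$p = 1/2000 = 0.0005$). Pearson is the default statistic with Spearman as an
option. `assemble_network()` turns significant GWAS QTL (ASV-QTL edges),
significant TWAS genes (ASV-gene edges) and hotspot-resident distant eQTL
(gene-hotspot edges) into a deduplicated edge list with a node degree table.

## 6. What the synthetic data emulate — and what they do not

`simulate_genotypes()` uses a founder-mosaic model: chromosomes are tiled
into LD blocks; within a block each individual inherits two of a few founder
haplotypes, so within-block $r^2$ far exceeds between-block $r^2$ and the
block length is the knob controlling LD decay. Marker columns are drawn so
realized MAF >= 0.05. `simulate_field_trial()` draws plots from exactly the
variance-component model of section 1. `simulate_asv_counts()` plants causal
SNP effects on latent log-abundances scaled to a target plot-level $H^2$,
then samples counts from a multinomial with log-normal library sizes (median
30,000 reads), so the data are deliberately compositional: one consequence is
that strong genetic signal in some ASVs leaks weak apparent heritability into
others through the closure constraint, and multinomial sampling adds residual
noise, so realized $H^2$ after the count pipeline sits slightly below the
latent target. `simulate_expression()` gives a fraction of genes a cis effect
from their nearest SNP and a set of hub targets a shared trans effect — the
architecture behind a distant-eQTL hotspot. `simulate_ionome()` draws traits
as sums of kernel-distributed genetic values plus noise, recording realized
variance fractions as ground truth; `exact = TRUE` rescales each component to
its target variance.

All generators are pure functions of their configuration and seed. They do
not emulate: sequencing error, taxonomy, coalescent-realistic haplotype
structure, genotype-by-environment interaction, or spatial field trends.
Passing tests on these data therefore demonstrate statistical correctness of
the machinery under the assumed model, not robustness to those unmodelled
features of real field data.

## 7. Numerical choices and limitations

* Missing genotype calls are mean-imputed per marker at load time, with the
  imputed fraction recorded; upstream imputation tools are out of scope.
* Minor-allele recoding happens once at load; frequency ties (0.5) keep the
  ALT allele deterministically.
* Variance clamps: $\sigma_e^2$ is floored at $10^{-8}\times\mathrm{var}(y)$;
  the $\lambda$ grid spans $[10^{-5}, 10^5]$.
* Rank-normal (QQ-normal) expression transform uses Blom's offset
  $(r - 3/8)/(n + 1/4)$ with tied values receiving the mean normal score of
  their rank span.
* Constant explanatory features are flagged and reported with effect 0 and
  $p = 1$ rather than dropped, keeping scan output aligned with input.
* Desk-scale problem sizes used throughout the examples and checks (175-200
  genotypes, 300-2,000 markers for LD-structured panels plus 10,000 unlinked
  null markers for calibration, 120-300 features per omics layer, 10-20 CV
  repeats) were chosen so each analysis completes in seconds to a couple of
  minutes while keeping every estimator in its well-behaved regime; repeat
  counts and panel sizes are plain function arguments for scaling up.
* Per-environment analysis only: no cross-environment mixed model, no
  narrow-sense heritability, no dominance or epistasis kernels, no
  fine-mapping or colocalization.
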