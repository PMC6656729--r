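---
title: "Methods: Pst-Fst comparison of trait syndromes in a selfing plant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Pst-Fst comparison of trait syndromes in a selfing plant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Natural lineages of a widespread selfing annual such as *Arabidopsis
thaliana* differ both in their genomes and in their resource-use
phenotypes: leaf-economics traits (mass-based assimilation rate A_mass,
leaf mass per area LMA, leaf lifespan LLS) and whole-plant slow-fast traits
(plant-level A_mass and LMA, age at maturity AM, relative growth rate RGR).
The question this package addresses is whether the *phenotypic*
differentiation of those trait syndromes among genetic lineages exceeds
what drift alone would produce — the classical Qst-Fst comparison, with
phenotypic Pst standing in for Qst because the available data are phenotypes
of natural inbred accessions rather than a crossing design.

`slowfast` implements the whole chain on plain data structures: SNP
genotypes and ancestry fractions in, verdicts and sensitivity curves out,
with seeded simulators so that every stage can be calibrated on data whose
truth is known.

## Population structure and the neutral benchmark

Accessions are fully homozygous, so each one is treated as a haploid
genome. Per SNP, the Weir-Cockerham estimator reduces to the one-way ANOVA
of allele indicators across populations: with non-missing sample sizes
$n_i$, frequencies $p_i$, $r$ populations and $N$ haploid calls,

$$MS_B = \frac{\sum_i n_i(p_i-\bar p)^2}{r-1},\qquad
  MS_W = \frac{\sum_i n_i p_i(1-p_i)}{N-r},\qquad
  n_c = \frac{N-\sum_i n_i^2/N}{r-1},$$

and $\hat\theta = a/(a+b)$ with $a=(MS_B-MS_W)/n_c$, $b=MS_W$. Negative
estimates are retained — clamping them would bias every downstream median
and null distribution. Multilocus summaries report both the ratio-of-sums
$\sum a/\sum(a+b)$ (the primary statistic, lower variance) and the
unweighted mean of per-SNP $\hat\theta$, because genome-wide means are the
common summary in the literature and the two can differ noticeably when the
per-SNP distribution is skewed.

Accessions are assigned to lineages by the majority-ancestry rule: strictly
more than 50% of the genome from one cluster, otherwise "Admixed" and
excluded from all differentiation statistics. The strictness matters at the
boundary: a 0.5/0.5 accession is admixed.

Significance is permutation-based: population labels are shuffled across
accessions (jointly for all SNPs, preserving between-SNP dependence and the
per-population sample sizes), 1000 times by default, and a SNP is
significant when its observed $\hat\theta$ exceeds the 95th quantile of its
own null. The *neutral Fst* benchmark is the median of significant
intergenic $\hat\theta$ values — intergenic SNPs being the ones assumed to
drift freely. Note a subtlety our simulations expose: this conditioned
median generally sits slightly *below* the ratio-of-sums multilocus
estimate, because the per-SNP $\hat\theta$ distribution is right-skewed
(its mean exceeds its median) while the significance filter only removes
the lower tail. The guaranteed direction, which the test suite asserts, is
that conditioning on significance can only raise the median relative to
the unconditioned intergenic median.

LD pruning follows the standard greedy windowed scheme (r² threshold 0.1,
50 kb windows stepping by 50 SNPs); the kinship matrix is the realized
relationship matrix of standardized dosages with pairwise-complete missing
handling.

## Pst for an autogamous species

For genotype means decomposed into between- and within-population variance
components $\sigma^2_B$ and $\sigma^2_W$ (one-way random-effects method of
moments, unbalanced coefficient $n_0$, negative estimates truncated at zero
and flagged),

$$P_{ST} = \frac{c\,\sigma^2_B}{c\,\sigma^2_B + h^2\,\sigma^2_W},$$

where $c$ is the among-population heritability and $h^2$ the heritability.
The within-population term carries **no factor 2**: in an outcrossing
species the additive within-population variance would be doubled, but a
predominantly autogamous, fully homozygous species transmits genotypes
whole. Under the null assumption $c = h^2 = 1$ the statistic reduces
machine-exactly to $\sigma^2_B/(\sigma^2_B+\sigma^2_W)$.

Two levels of variance are deliberately kept apart: $\sigma^2_W$ in the
formula is the within-population variance of *genotype means* (phenotypic),
while the replicate-level residual enters only the heritability estimate
$h^2 = \sigma^2_G/(\sigma^2_G+\sigma^2_E)$ from the one-way ANOVA of
replicates within genotypes. With inbred lines this replicate design
estimates broad-sense heritability, which we treat as equivalent to the
narrow-sense value under full homozygosity. No information on how $h^2$
"should" be estimated survives in typical datasets beyond replication, so
replicate ANOVA is the package's declared choice.

Confidence intervals are parametric bootstrap: each iteration redraws
population effects $\sim N(0,\hat\sigma^2_B)$ and genotype deviations
$\sim N(0,\hat\sigma^2_W)$ under the observed design, re-estimates the
components and recomputes Pst; the interval is the 2.5/97.5 percentile
range of 10,000 iterations by default. The sensitivity analysis sweeps the
ratio $\rho = c/h^2$ over a grid (default 0.05–2.00 by 0.05; only the ratio
matters, since $P_{ST}(\rho h^2, h^2)$ is free of $h^2$), reusing one set
of bootstrap component draws across the grid — valid because only the
multiplier changes, and it makes the curve smooth in $\rho$ by
construction. The *critical ratio* is the smallest grid $\rho$ whose CI
lower bound clears the neutral Fst; a low critical ratio means the
diversifying-selection verdict does not lean on optimistic assumptions
about $c$ and $h^2$. The verdict itself compares the H0 CI lower bound with
neutral Fst.

### A known limitation: few populations make wide, undercovering intervals

With five populations the between-population mean square has four degrees
of freedom. The percentile bootstrap of a variance-ratio with so few groups
is known to undercover, and our own calibration test measures roughly 84%
coverage where 95% is nominal at the study-like design (5 populations x 60
genotypes). The same heavy lower tail means that even a trait with plug-in
Pst = 0.35 rarely has its CI lower bound clear a neutral Fst of 0.10 — the
CI lower bound sits near 0.05–0.08, which is exactly the order of the
published intervals for such designs. Users should read the verdict as
conservative: "diversifying" is trustworthy, "not-distinguishable" may
simply reflect the small number of lineages. We deliberately did not switch
to basic/BCa intervals or clamp the bootstrap, because the percentile
parametric bootstrap is the declared contract of the method.

## Growth curves and RGR

Rosette growth is fitted with the 3-parameter logistic
$A(t)=K/(1+e^{-r(t-t_0)})$ by Levenberg-Marquardt least squares, with
starting values from the observed maximum (K), the half-maximum time (t0)
and the early log-linear slope (r). "Sigmoid" families differ; the logistic
is the package's choice because the relative growth rate at the inflection
has the closed form $r/2$ — the absolute slope there is $rK/4$ and the area
is $K/2$ — which matches the dimensionless-per-day units (mm² mm⁻² d⁻¹) in
which RGR is reported. An absolute-slope reading would carry units of
mm² d⁻¹ and change under area rescaling; $r/2$ is invariant, and the test
suite asserts that invariance. A fit is flagged unconverged when the
optimizer fails, the fitted asymptote exceeds ten times the largest
observed area, or the logistic cannot outperform a straight line (a series
still in its linear phase contains no information about $K$ or $t_0$).

## Trait axes, scaling, kinship regression

Axes are first principal components of the correlation matrix of
log10-transformed genotype means (RGR excepted — it is already a relative
rate). The correlation matrix is the only defensible choice for traits in
incommensurable units, and it buys invariance to affine rescaling of the
transformed traits. PC1 orientation is pinned so the LMA-type loading is
positive: high score = conservative/slow. Complete cases only; dropped
genotypes are reported, not imputed.

Leaf-to-plant scaling uses standardized major axis regression — symmetric
in x and y, appropriate when both traits carry sampling variance — with the
standard correlation-based 95% slope interval
$b\,(\sqrt{B+1}\pm\sqrt B)$, $B = F_{0.95;1,n-2}(1-r^2)/(n-2)$. The
interval degenerates to the point estimate at $|r|=1$ and respects the
reciprocal symmetry $|b_{xy} b_{yx}| = 1$.

The kinship-aware check refits the axis-axis slope by GLS with covariance
proportional to the realized relationship matrix (Cholesky solve, with an
escalating ridge only if the factorization fails) and reports whether the
GLS and OLS slopes differ beyond their combined standard errors. With an
identity kinship the GLS slope equals OLS exactly, which the tests assert.

## Climate association

The screen is plain Pearson correlation per climate variable, uncorrected
for multiplicity (matching how such tables are usually presented; the count
of nominally significant variables is attached). Model selection is
bidirectional stepwise AIC from the full model (the "formal" model is the
full 19-variable regression, the "reduced" model the stepwise-selected
one). Predictive accuracy is repeated k-fold cross-validation — 10 folds,
10 repetitions by default, both configurable and seeded — where stepwise
selection, when requested, is **re-run inside every training fold**. The
no-leakage property is enforced by a regression test: on pure-noise
responses the cross-validated r² stays near zero, whereas selecting
variables before splitting would inflate it. Two metrics are reported
(squared correlation of pooled out-of-fold predictions, and pooled
1 − SSE/SST) because the field uses both; the correlation version is
primary. Grid prediction applies the selected linear model row-wise and
flags extrapolation whenever a selected variable leaves its training range.

## What the simulators emulate — and what they do not

`simulate_genotypes` draws Balding-Nichols island-model SNPs: ancestral
frequency uniform on an interval, population frequencies Beta-distributed
around it with spread set by the target F, haploid Bernoulli dosages.
Admixed accessions are equal two-population mixtures, which places their
ancestry rows exactly at the 0.5 boundary of the strict majority rule.
Defaults (5 populations x 60, F target ~0.1, ~50% intergenic, ~20% admixed
when requested) mirror a European-scale selfing panel. There is no linkage,
no mutation model, no selection at the sequence level — LD pruning is
exercised by duplicated-column fixtures instead.

`simulate_phenotypes` realizes the Pst variance decomposition directly:
population effects with variance $\sigma^2_B$ (split $c$ : $1-c$ into
genetic and environmental parts), within-population deviations with
variance $\sigma^2_W$ (split by $h^2$), and replicate noise scaled so the
replicate-ANOVA repeatability targets $h^2$. `simulate_growth_series` adds
truncated Gaussian noise to an exact logistic (truncation at zero makes the
early-day noise slightly non-Gaussian — areas cannot be negative).
`simulate_climate` couples one causal variable to the score (either by
slope or by a target population correlation) against independent Gaussian
background variables.

What passing tests on these simulators show is that the *estimators are
calibrated under their own assumptions* at study-like designs. They do not
show robustness to real-data features the generators omit: genotyping
error, LD between causal and neutral variants, non-normal trait
distributions, spatially structured climate noise, or environmental
covariance between sites and phenotypes.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: monomorphic SNPs get `NA` theta
(never 0); SNPs with fewer than two populations of two non-missing calls
are undefined; zero-variance columns correlate with nothing in LD pruning
unless exactly duplicated; negative variance components truncate to zero
with a flag; an all-zero between-component with positive within-component
gives Pst = 0; ties in the majority rule go to "Admixed" by strictness.
Quantiles are R's default type-7 throughout.

The test suite runs the calibration experiments at the sizes the method is
meant for — 5 populations x 60 genotypes, 5000 SNPs, 1000 permutations,
2000-iteration bootstraps, 200-seed Monte-Carlo loops — chosen so the whole
suite completes in about ten minutes on a single core. The acceptance
script runs one full pipeline pass at the same scale (about half a minute).
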