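---
title: "Comparing phenotypic and neutral genetic differentiation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing phenotypic and neutral genetic differentiation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparrowdiv)
```

sparrowdiv implements the quantitative chain used to ask whether phenotypic
divergence among wild populations exceeds what neutral processes alone would
produce: microsatellite diversity and differentiation statistics, bottleneck
and isolation-by-distance tests, trait scoring for color and behavior,
Bayesian variance-component estimation, and the Pst–Fst decision framework.
This vignette documents the models, the tunable parameters, the numerical
choices, and what the synthetic-data generators do and do not emulate.

## The Pst–Fst framework

Neutral differentiation is measured by $F_{ST}$; differentiation of a
quantitative trait is summarised by its phenotypic analog

$$P_{ST} \;=\; \frac{\frac{c}{h^2}\,\sigma^2_B}
{\frac{c}{h^2}\,\sigma^2_B + 2\,\sigma^2_W},$$

where $\sigma^2_B$ and $\sigma^2_W$ are the between- and within-population
variance components of the trait, $h^2$ is narrow-sense heritability and $c$
the share of the between-population variance that is additive genetic. Since
neither $c$ nor $h^2$ is observable without a common-garden design, the
point estimate assumes $c = h^2$ (`phi = 1`), and robustness is expressed
through the *critical* $c/h^2$: the smallest ratio at which the lower 95%
bound of $P_{ST}$ still clears the upper 95% bound of $F_{ST}$. Inverting
the $P_{ST}$ formula gives the closed form

$$\left(\frac{c}{h^2}\right)^{*} = \frac{F}{1-F}\cdot\frac{1-P}{P},$$

with $F$ the $F_{ST}$ upper bound and $P$ the $P_{ST}$ lower bound at
$c/h^2 = 1$. `critical_c_over_h2()` also offers a `"grid"` mode that
recomputes the $P_{ST}$ lower bound from the posterior draws on a grid of
ratios and bisects for the crossing; the two agree to the Monte Carlo error
of the draw quantiles, and both are reported by `pst_fst_table()`. Verdicts
are assigned per trait: `Pst = Fst` when the intervals overlap, `Pst > Fst`
otherwise, upgraded to `Pst >> Fst` when the critical ratio is at most
`strong_threshold`. The default threshold of 0.125 separates the two
published label groups (critical values 0.046–0.124 versus 0.131–0.959) and
is exposed as a configuration knob, since the boundary itself is a
convention rather than a statistic.

### Variance components

`fit_variance_components()` fits the Gaussian random-intercept model
$y = X\beta + u_{pop} + e$, $u \sim N(0, \sigma^2_B)$,
$e \sim N(0, \sigma^2_W)$, by single-chain conjugate Gibbs sampling with
flat priors on $\beta$ and weakly informative inverse-gamma priors
IG$(\nu/2,\ \nu V/2)$ with $V = 1$, $\nu = 0.002$ on both variances — the
defaults of the mixed-model package this analysis standardises on. The
default chain (65,000 iterations, 15,000 burn-in, thinning interval 50)
retains 1,000 draws. Sex enters as a fixed effect for morphological traits
and sampling year for color traits, matching how those data are collected
(plumage is scored on males only). Convergence is summarised by effective
sample sizes and a split-chain $\widehat R$; $\widehat R > 1.1$ flags the
fit. Because $P_{ST}$ is a monotone transform of
$\sigma^2_B / 2\sigma^2_W$, the posterior of $P_{ST}$ is obtained by
applying the formula draw-by-draw; the point estimate is the posterior
median (the published analyses do not state which location summary was
used; the median is invariant under the monotone transform and is the
default, with mean available from the draws).

The test suite fits shorter chains (6,000–12,000 iterations, thinning 5)
so that twenty-seed recovery studies complete in seconds each; recovery of
$\sigma^2_B = \sigma^2_W = 1$ on a 14 × 20 design and agreement with REML
on balanced data are both checked at those sizes.

## Differentiation statistics

`weir_cockerham_theta()` implements the Weir–Cockerham estimator with
unequal sample sizes: per-allele variance components $a$ (among
populations), $b$ (among individuals within populations) and $c$ (within
individuals), summed over alleles and loci, with the multilocus estimate
the ratio of summed components — never the mean of per-locus ratios, a
property asserted by test on fixtures where the two differ. Negative
estimates are reported as computed; truncating them at zero would bias
every downstream comparison. The 95% CI is a percentile bootstrap over
loci. Pairwise significance permutes individuals between the two
populations (10,000 permutations by default, always seeded); the published
analysis flags significant pairs without stating its procedure, so the
permutation scheme is documented here as this package's choice.

`amova()` partitions gene-copy variance under the 0/1 allele metric into
among-group, among-population-within-group and within-population
components (an $F_{ST}$-analog AMOVA, not the allele-size $R_{ST}$ form),
with expected-mean-square coefficients for unequal sizes, summation over
loci, and permutation tests at the population and group levels. Groups
holding a single population leave the middle level with zero degrees of
freedom; the component is then reported `NA` rather than silently dropped.

## Diversity, rarefaction, locus QC

Expected heterozygosity uses Nei's unbiased form
$(2n/(2n-1))(1 - \sum p_i^2)$; $F_{IS}$ is the multilocus Weir–Cockerham
small-$f$ with a bootstrap-over-loci CI. Rarefied allelic richness is the
exact combinatorial expectation
$A_R(g) = \sum_i [1 - \binom{N-N_i}{g}/\binom{N}{g}]$, evaluated in the
log domain; private allelic richness multiplies each allele's presence
probability in the focal population's rarefied sample by its absence
probabilities in all others. The default rarefaction size is the smallest
per-locus copy count across populations. Both quantities are tested
against exhaustive enumeration of subsamples on small pools.

Hardy–Weinberg deviation is tested by a Monte Carlo exact test whose
statistic is the conditional probability of the genotype array given the
allele counts; the null is generated by re-pairing shuffled gene copies.
Null alleles are screened with the moment estimator
$r = (H_E - H_O)/(H_E + H_O)$, whose expectation under a null allele at
frequency $q$ is $q/(1+q)$; the pipeline flags a locus when its mean
estimate across populations exceeds 0.15, and excludes loci failing
Bonferroni-corrected HWE screening, mirroring the marker-exclusion step of
the original workflow.

## The bottleneck test

A recent bottleneck leaves expected heterozygosity transiently above the
equilibrium value implied by the observed allele count $k$. For each locus
the conditional null of $H_{eq} \mid k$ is simulated: under the
infinite-alleles model by Ewens (Chinese-restaurant) configurations —
where the conditional law is exactly independent of the mutation rate —
and under the stepwise and two-phase models by coalescent genealogies with
integer-valued mutations, retaining genealogies whose allele count equals
$k$. The mutation rate is centred at the Ewens solution of
$E[k \mid \theta, n] = k$ and scanned over $\theta \times \{0.5, 1, 2\}$
to blunt the residual $\theta$-dependence of the stepwise conditional.
The two-phase model defaults to 90% single-step mutations and a geometric
multi-step variance of 12, the conventional settings of the reference
bottleneck software, since the original analysis states only that the
two-phase model was used; `p_ss = 1` degenerates to the strict stepwise
model, and the conditional means order IAM < TPM < SMM at fixed $(k, n)$,
as asserted by test.

One numerical decision deserves emphasis. The raw locus excess
$H_{E,obs} - \overline{H}_{eq}$ has mean zero at equilibrium but a skewed
distribution (the conditional law of $H \mid k$ is left-skewed), so a
one-tailed signed-rank test on raw excesses rejects far above its nominal
size — we measured roughly 10–11% at a nominal 5% across equilibrium
simulations. The population-level Wilcoxon is therefore computed on the
probability-scale residual $0.5 - p_{mid}$, where $p_{mid}$ is the mid-p
tail probability of the observed heterozygosity under the simulated
conditional null. This residual is symmetric under the null by
construction, and the test holds its size (measured 4.5% over 200
equilibrium seeds); the raw excess is still reported per locus. The
mode-shift indicator bins pooled allele frequencies into ten classes of
width 0.1 and flags the loss of the L-shape (lowest class no longer
modal).

## Spatial analysis

Distances are great-circle kilometres on a sphere of radius 6371.0 km.
The source study used an unspecified web calculator; reproduction of its
printed pairwise distances is checked at 0.5% tolerance, which absorbs any
difference of Earth model. Merged populations use the coordinate of the
first-listed locality of the merge — the convention that matches the
printed matrix where it can be checked — and the mapping is configurable.
`mantel()` reports the cross-product statistic $Z = \sum_{i<j} X_{ij}
Y_{ij}$, the Pearson correlation $r$ over unordered pairs, and a one-tailed
permutation p (positive association being the isolation-by-distance
alternative), with the identity permutation counted in numerator and
denominator. Calibration of the permutation p and agreement of $r$ with an
independent implementation are tested.

## Trait construction

**Color.** Reflectance spectra on the 380–730 nm, 10 nm grid are converted
to brightness through a pinned colorimetric chain: D65 illuminant, CIE 1931
2° observer (normalised so a perfect reflector has $Y = 1$), the standard
XYZ→linear-sRGB matrix, sRGB gamma companding, clipping to [0, 1], and the
green channel as the brightness score (0 = black, 1 = white). The exact
settings of the original spectrophotometer software are unpublished, so
these constants are fixed and documented; for the flat spectra the
generator produces, the conversion is exactly linear up to companding,
which is what the anchor tests (black, white, 18% grey) pin down.

**Behavior.** Exploration is scored from five assay variables — distinct
quarters visited (of 4), distinct perches used (of 6), location changes,
hops, flight incidents — each converted to a per-minute rate, divided by
the best rate in the cohort (0 when the cohort best is 0), and summed to a
total in [0, 5]. Quarters and perches count distinct entities, not visit
events. Neophobia is the unweighted mean of two proportions: time on
decorated perches out of total perched time (a bird is on a perch from a
landing until its next event), and center time out of assay duration;
higher values mean a reduced neophobic response. The original description
lists the two components without a combination rule; the mean keeps the
score in [0, 1] and weighs the components equally, and the choice is
config-exposed. A bird that never perched contributes zero and is flagged
rather than dropped.

**Region comparisons.** Shapiro–Wilk on ANOVA residuals and Levene's test
(both at $\alpha = 0.05$) route each trait to either one-way ANOVA with
Tukey HSD or to Welch's ANOVA plus Kruskal–Wallis with Dunn's post-hocs;
raw p-values are Bonferroni-corrected across the traits analysed in one
run (the published correction does not state its family size; the trait
set of the run is the natural family). Pairwise outcomes are summarised as
a compact letter display whose consistency with the pairwise significance
matrix is property-tested.

## Synthetic data: what it emulates, what it does not

The generators exist so that every stage has a parameter-recovery test
with known truth. `simulate_genotypes()` uses the Balding–Nichols
construction for the island model — population allele frequencies drawn
from a Dirichlet with parameters $\bar p (1-F)/F$ — because the target
differentiation is then an explicit parameter; the defaults (14
populations × 20 diploids, 8 loci, 4–28 alleles per locus, $F = 0.008$, 2%
missing calls) reproduce the scale and the low-differentiation regime of
the study system. The stepping-stone variant draws each population from a
Dirichlet centred on its neighbour with per-step variance
$\delta p(1-p)$, clipping frequencies to [0.001, 0.999] before
renormalising to avoid absorbing states in short chains — an approximation
that produces the intended distance-correlated divergence, verified by
Mantel tests against line position. `simulate_phenotypes()` adds
population effects $N(0, \sigma^2_B)$, residuals $N(0, \sigma^2_W)$, and
optional sex, year and latitudinal-trend effects.

What the generators do *not* emulate: mutation within the sampled
generations, coalescent ancestry with migration (drift is parametric, not
genealogical), linkage between loci, genotyping artifacts other than
uniformly missing calls (null alleles are constructed explicitly in the
tests that need them), measurement error structure in traits beyond
Gaussian residuals, and observer effects in assay scoring. Passing
recovery tests on these data therefore demonstrates correctness of the
estimators under their own assumptions, not robustness to the full
messiness of field data.

All generators take one integer seed; per-component streams are derived
deterministically from it, and every simulation is bit-reproducible.

## Problem sizes and numerical choices

Test and calibration studies use sizes chosen to make the suite a
routine run: twenty-seed recovery studies for differentiation
($F = 0.10$, 50 loci, 10 × 30) and for $P_{ST}$ (14 × 20, chains of 8,000
iterations), 200-seed calibration of the bottleneck Wilcoxon, the exact
Hardy–Weinberg test and the Mantel permutation p, and enumeration oracles
at $n \le 8$ gene copies. Rarefaction uses log-domain binomial
coefficients; the Gibbs sampler initialises at the method-of-moments
split of the total variance; permutation p-values use the
$(\text{hits}+1)/(B+1)$ convention so they are never zero; ties in the
exact HWE test statistic are accepted within $10^{-9}$ of the observed
log-probability.

## Known limitations

$P_{ST}$ inherits every caveat of its definition: it cannot separate
plasticity from genetic divergence, and the $c = h^2$ assumption is a
convention whose sensitivity the critical ratio only partially summarises.
The AMOVA is frequency-based and ignores allele size information. The
bottleneck conditional null for the stepwise models retains a mild
dependence on the mutation-rate grid. Eight microsatellite loci — the
scale this package mirrors — give wide bootstrap intervals for global
$F_{ST}$, which propagates directly into the Pst–Fst verdicts; that width
is a property of the design, not of the estimator.
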