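# sparrowdiv

Tools for asking a classic question in evolutionary biology: is the
phenotypic divergence observed among wild populations greater than what
genetic drift alone would produce? The package implements the full
quantitative chain used in microsatellite-based studies of structured bird
populations — here modelled on house sparrow (*Passer domesticus*)
populations sampled along a steep climatic gradient — from raw genotype,
reflectance and behavioral-assay files to the Pst–Fst decision table.

## The core comparison

Neutral differentiation is estimated by Weir & Cockerham's θ (the F_ST
estimator). Phenotypic differentiation for a trait with between- and
within-population variance components σ²B and σ²W is

    Pst = (c/h² · σ²B) / (c/h² · σ²B + 2 σ²W)

evaluated at c/h² = 1 (additive share of the between-population variance
equal to heritability), with the variance components estimated by a Gibbs
sampler for a Gaussian random-intercept model (population as random effect,
sex or sampling year as fixed effect). A trait diverges more than neutrally
when the lower 95% bound of Pst exceeds the upper 95% bound of F_ST; the
*critical c/h²* — the smallest ratio at which that still holds,
`[F/(1−F)]·[(1−P)/P]` — measures how robust the signal is to the unknown
genetic architecture. Small critical values upgrade the verdict from
`Pst > Fst` to `Pst >> Fst`.

Around that core the package provides: unbiased heterozygosity, F_IS with
bootstrap CIs, rarefied allelic and private allelic richness (exact
combinatorics), Monte Carlo exact Hardy–Weinberg tests, null-allele
screening, hierarchical AMOVA on gene copies with permutation tests, a
heterozygosity-excess bottleneck test under IAM/TPM/SMM mutation models
(coalescent simulation conditional on the observed allele count), Mantel
tests for isolation by distance, great-circle distance matrices, spectral
reflectance → brightness conversion (D65 / CIE 1931 / sRGB), behavioral
assay scoring (exploration and neophobia), region comparisons with
assumption-guided test choice, and synthetic-data generators with known
ground truth for every stage. `run_pipeline()` sequences everything from a
YAML config into TSV tables and a deterministic JSON report.

## Worked example

Simulate a study-scale dataset (14 populations × 20 birds, 8 microsatellite
loci, true F = 0.008) and a trait with true Pst = 1/3, then run the
comparison:

```r
library(sparrowdiv)

geno <- simulate_genotypes(geno_sim_spec(F = 0.008, seed = 42))
geno
#> microsat_dataset: 280 individuals, 14 populations, 8 loci
#>   missing calls: 1.7%

fst <- weir_cockerham_theta(geno, seed = 42)
round(c(theta = fst$theta, lower = fst$ci[1], upper = fst$ci[2]), 4)
#>  theta  lower  upper
#> 0.0049 0.0028 0.0074

pheno <- simulate_phenotypes(pheno_sim_spec(sigma2_B = 1, sigma2_W = 1,
                                            sex_effect = 0.5, seed = 42),
                             dataset = geno)
tab <- pst_fst_table(pheno, fst_upper = fst$ci[2],
                     iterations = 20000, burn_in = 5000, thin = 15, seed = 1)
print(tab[, c("trait", "pst", "lower", "upper", "critical_c_h2", "verdict")],
      digits = 3)
#>    trait  pst lower upper critical_c_h2    verdict
#> 1 trait1 0.29 0.155 0.523        0.0408 Pst >> Fst
```

Reading the output: the multilocus θ of 0.0049 (bootstrap CI over loci
0.0028–0.0074) recovers the low simulated differentiation; the posterior
median Pst of 0.29 brackets the true value 1/3; and the critical c/h² of
0.041 says the divergence verdict would survive even if only ~4% of the
between-population trait variance were additive genetic relative to
heritability — hence `Pst >> Fst`.

The methods vignette (`vignettes/pst-fst-methods.Rmd`) documents every
model, default and numerical decision.

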