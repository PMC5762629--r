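test_that("complete divergence gives theta = 1", {
  ds <- make_dataset(c("A", "A", "B", "B"),
                     cbind(c(1L, 1L, 2L, 2L)), cbind(c(1L, 1L, 2L, 2L)))
  expect_equal(weir_cockerham_theta(ds, n_boot = 0)$theta, 1)
})

test_that("theta equals an independent brute-force transcription", {
  # 3-population, 2-locus toy with unequal sizes and missing data
  set.seed(5)
  ds <- simulate_genotypes(geno_sim_spec(n_pops = 3, n_per_pop = 7,
                                         n_loci = 2, F = 0.2,
                                         alleles_per_locus = c(3, 5),
                                         missing_rate = 0.1, seed = 5))
  got <- weir_cockerham_theta(ds, n_boot = 0)$theta
  expect_equal(got, wc_theta_bruteforce(ds), tolerance = 1e-12)
  # and on a 2-population subset
  got2 <- weir_cockerham_theta(ds, pops = c("P01", "P03"), n_boot = 0)$theta
  expect_equal(got2, wc_theta_bruteforce(ds, c("P01", "P03")),
               tolerance = 1e-12)
})

test_that("multilocus theta is the ratio of sums, not the mean of ratios", {
  ds <- simulate_genotypes(geno_sim_spec(n_pops = 4, n_per_pop = 10,
                                         n_loci = 6, F = 0.1, seed = 8))
  f <- weir_cockerham_theta(ds, n_boot = 0)
  pl <- f$per_locus[is.finite(f$per_locus$theta), ]
  ratio_of_sums <- sum(pl$a) / sum(pl$a + pl$b + pl$c)
  expect_equal(f$theta, ratio_of_sums)
  expect_false(isTRUE(all.equal(f$theta, mean(pl$theta))))
})

test_that("negative estimates are reported as computed", {
  # near-identical small samples routinely give slightly negative theta
  found_negative <- FALSE
  for (s in 1:10) {
    ds <- simulate_genotypes(geno_sim_spec(n_pops = 2, n_per_pop = 8,
                                           n_loci = 4, panmictic = TRUE,
                                           missing_rate = 0, seed = s))
    th <- suppressWarnings(weir_cockerham_theta(ds, n_boot = 0)$theta)
    if (!is.na(th) && th < 0) found_negative <- TRUE
  }
  expect_true(found_negative)
})

test_that("pairwise matrix is symmetric with seed-reproducible p-values", {
  ds <- simulate_genotypes(geno_sim_spec(n_pops = 3, n_per_pop = 8,
                                         n_loci = 3, F = 0.1, seed = 4))
  f1 <- weir_cockerham_theta(ds, pairwise = TRUE, n_perm = 99, seed = 7)
  f2 <- weir_cockerham_theta(ds, pairwise = TRUE, n_perm = 99, seed = 7)
  expect_identical(f1$pairwise, f2$pairwise)
  expect_identical(f1$pairwise_p, f2$pairwise_p)
  expect_equal(f1$pairwise, t(f1$pairwise))
  expect_equal(diag(f1$pairwise), setNames(rep(0, 3), populations(ds)))
  expect_true(all(f1$pairwise_p[upper.tri(f1$pairwise_p)] > 0))
})

test_that("monomorphic loci are excluded with a warning", {
  a <- cbind(c(1L, 1L, 1L, 1L), c(1L, 2L, 1L, 2L))
  ds <- make_dataset(c("A", "A", "B", "B"), a, a)
  expect_warning(f <- weir_cockerham_theta(ds, n_boot = 0), "monomorphic")
  expect_true(is.finite(f$theta))
})

test_that("AMOVA percentages sum to 100 and components nest correctly", {
  ds <- simulate_genotypes(geno_sim_spec(n_pops = 8, n_per_pop = 10,
                                         n_loci = 5, F = 0.05, seed = 6))
  am <- amova(ds, n_perm = 0)
  expect_equal(sum(am$components$percent), 100, tolerance = 1e-9)
  expect_equal(am$components$level,
               c("among_groups", "among_pops_within_groups", "within_pops"))
  # dropping the grouping reduces to the two-level decomposition
  am2 <- amova(ds, groups = NULL, n_perm = 0)
  expect_true(is.na(am2$components$sigma2[1]))
  expect_equal(sum(am2$components$percent, na.rm = TRUE), 100,
               tolerance = 1e-9)
})

test_that("two fixed groups with no within-group variation give 100% among groups", {
  a <- cbind(c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L))
  ds <- make_dataset(rep(c("A1", "A2", "B1", "B2"), each = 2), a, a,
                     region = c(A1 = "G1", A2 = "G1", B1 = "G2", B2 = "G2"))
  am <- amova(ds, n_perm = 0)
  expect_equal(am$components$percent[1], 100, tolerance = 1e-9)
  expect_equal(am$phi[["F_CT"]], 1, tolerance = 1e-9)
})

test_that("two-level AMOVA agrees with the theta-consistent component ratio", {
  # with no missing data and random union of gametes the gene-copy AMOVA
  # Phi_ST tracks Weir-Cockerham theta closely
  ds <- simulate_genotypes(geno_sim_spec(n_pops = 2, n_per_pop = 30,
                                         n_loci = 10, F = 0.1,
                                         missing_rate = 0, seed = 9))
  am <- amova(ds, groups = NULL, n_perm = 0)
  th <- weir_cockerham_theta(ds, n_boot = 0)$theta
  expect_equal(am$phi[["F_ST"]], th, tolerance = 0.02)
})

test_that("panmictic data put essentially all variation within populations", {
  pcts <- vapply(1:8, function(s) {
    ds <- simulate_genotypes(geno_sim_spec(n_pops = 8, n_per_pop = 15,
                                           n_loci = 6, panmictic = TRUE,
                                           missing_rate = 0, seed = s))
    am <- amova(ds, n_perm = 0)
    am$components$percent[3]
  }, 0)
  expect_gte(mean(pcts), 99)
})

test_that("AMOVA permutation p-values are reproducible and significant when they should be", {
  ds <- simulate_genotypes(geno_sim_spec(n_pops = 8, n_per_pop = 15,
                                         n_loci = 5, F = 0.15,
                                         missing_rate = 0, seed = 3))
  am1 <- amova(ds, n_perm = 99, seed = 5)
  am2 <- amova(ds, n_perm = 99, seed = 5)
  expect_identical(am1$p, am2$p)
  expect_lt(am1$p[["F_ST"]], 0.05)
})
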