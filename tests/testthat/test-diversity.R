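test_that("heterozygosity matches hand enumeration", {
  # monomorphic: both zero
  ds <- make_dataset(rep("P", 3), cbind(c(1L, 1L, 1L)), cbind(c(1L, 1L, 1L)))
  h <- heterozygosity(ds, "P", "L1")
  expect_equal(h$H_O, 0)
  expect_equal(h$H_E, 0)
  # two heterozygotes {A,B},{A,B}: H_O = 1, H_E = (4/3) * 0.5
  ds2 <- make_dataset(rep("P", 2), cbind(c(1L, 1L)), cbind(c(2L, 2L)))
  h2 <- heterozygosity(ds2, "P", "L1")
  expect_equal(h2$H_O, 1)
  expect_equal(h2$H_E, 4 / 3 * 0.5)
  # all-missing locus flagged NA, not zero
  ds3 <- make_dataset(rep("P", 2), cbind(c(NA, NA), c(1L, 2L)),
                      cbind(c(NA, NA), c(1L, 2L)))
  expect_true(is.na(heterozygosity(ds3, "P", "L1")$H_O))
})

test_that("unbiased H_E matches its Monte Carlo expectation", {
  p <- c(0.5, 0.3, 0.2)
  n <- 12
  set.seed(42)
  he <- replicate(3000, {
    g <- matrix(sample.int(3, 2 * n, replace = TRUE, prob = p), n, 2)
    ds <- make_dataset(rep("P", n), g[, 1, drop = FALSE], g[, 2, drop = FALSE])
    heterozygosity(ds, "P", "L1")$H_E
  })
  expect_lt(abs(mean(he) - (1 - sum(p^2))), 0.01)
})

test_that("F_IS has the right sign structure and fixation limit", {
  # every individual heterozygous at every locus -> excess, F_IS < 0
  ds <- make_dataset(rep("P", 6),
                     matrix(1L, 6, 2), matrix(2L, 6, 2))
  expect_lt(fis(ds, "P")$F_IS, 0)
  # fully selfed: all homozygotes from a polymorphic pool -> F_IS = 1
  ds2 <- make_dataset(rep("P", 6),
                      cbind(rep(c(1L, 2L, 3L), 2), rep(c(2L, 3L, 4L), 2)),
                      cbind(rep(c(1L, 2L, 3L), 2), rep(c(2L, 3L, 4L), 2)))
  expect_equal(fis(ds2, "P")$F_IS, 1)
})

test_that("F_IS bootstrap CI covers 0 under Hardy-Weinberg", {
  hits <- 0L
  for (s in 1:20) {
    ds <- make_equilibrium_pop(n_ind = 30, n_loci = 25, theta = 4, seed = s)
    ci <- fis(ds, "P1", n_boot = 500, seed = s)$ci
    hits <- hits + (ci[1] <= 0 && ci[2] >= 0)
  }
  expect_gte(hits, 18L)
})

test_that("rarefied allelic richness equals exhaustive enumeration", {
  # 4 copies, counts {2, 2}, g = 2: enumerate all C(4,2) = 6 subsamples
  ds <- make_dataset(rep("P", 2), cbind(c(1L, 2L)), cbind(c(1L, 2L)))
  expect_equal(allelic_richness(ds, "P", "L1", 2), 5 / 3)
  expect_equal(rarefaction_enumerate(c(1, 1, 2, 2), 2), 5 / 3)
  # g = N returns the observed allele count
  expect_equal(allelic_richness(ds, "P", "L1", 4), 2)
  # random fixtures: equality with enumeration and monotonicity in g
  set.seed(7)
  for (rep in 1:5) {
    copies <- sample.int(4, 8, replace = TRUE)
    ds2 <- make_dataset(rep("P", 4), cbind(copies[1:4]), cbind(copies[5:8]))
    ar <- vapply(1:8, function(g) allelic_richness(ds2, "P", "L1", g), 0)
    expect_true(all(diff(ar) >= -1e-12))
    expect_equal(ar[3], rarefaction_enumerate(copies, 3))
  }
  expect_error(allelic_richness(ds, "P", "L1", 5), "exceeds")
  expect_error(allelic_richness(ds, "P", "L1", 0), ">= 1")
})

test_that("private allelic richness matches its brute-force oracle", {
  # disjoint allele sets: everything private, A_PR = A_R
  ds <- make_dataset(c("A", "A", "B", "B"),
                     cbind(c(1L, 2L, 5L, 6L)), cbind(c(1L, 2L, 5L, 6L)))
  g <- 3
  expect_equal(private_allelic_richness(ds, "A", "L1", g),
               allelic_richness(ds, "A", "L1", g))
  # identical counts in both populations: nothing private at large g
  ds2 <- make_dataset(c("A", "A", "B", "B"),
                      cbind(c(1L, 2L, 1L, 2L)), cbind(c(1L, 2L, 1L, 2L)))
  expect_lt(private_allelic_richness(ds2, "A", "L1", 4), 0.1)
  # 2-pop toy {A:3, B:1} vs {A:4}, g = 2: exhaustive over subsample pairs
  ds3 <- make_dataset(c("p1", "p1", "p2", "p2"),
                      cbind(c(1L, 1L, 1L, 1L)), cbind(c(1L, 2L, 1L, 1L)))
  pool1 <- c(1, 1, 1, 2); pool2 <- c(1, 1, 1, 1)
  s1 <- utils::combn(4, 2); s2 <- utils::combn(4, 2)
  tot <- 0
  for (i in seq_len(ncol(s1))) for (j in seq_len(ncol(s2))) {
    al1 <- unique(pool1[s1[, i]]); al2 <- unique(pool2[s2[, j]])
    tot <- tot + length(setdiff(al1, al2))
  }
  oracle <- tot / (ncol(s1) * ncol(s2))
  expect_equal(private_allelic_richness(ds3, "p1", "L1", 2), oracle)
  # bound chain: 0 <= A_PR <= A_R <= min(g, k)
  apr <- private_allelic_richness(ds3, "p1", "L1", 2)
  ar <- allelic_richness(ds3, "p1", "L1", 2)
  expect_true(apr >= 0 && apr <= ar && ar <= 2)
})

test_that("the exact HWE test behaves at both extremes and is calibrated", {
  # perfect HW proportions: p high
  g1 <- c(rep(1L, 4), rep(1L, 4), rep(2L, 1))
  g2 <- c(rep(1L, 4), rep(2L, 4), rep(2L, 1))
  ds <- make_dataset(rep("P", 9), cbind(g1), cbind(g2))
  expect_gt(hwe_test(ds, "P", "L1", n_perm = 500, seed = 1)$p, 0.5)
  # all heterozygotes, n = 20: extreme excess
  ds2 <- make_dataset(rep("P", 20), matrix(1L, 20, 1), matrix(2L, 20, 1))
  expect_lt(hwe_test(ds2, "P", "L1", n_perm = 2000, seed = 1)$p, 0.01)
  # fewer than 2 alleles: p = 1 flagged by k
  ds3 <- make_dataset(rep("P", 4), matrix(1L, 4, 1), matrix(1L, 4, 1))
  res <- hwe_test(ds3, "P", "L1")
  expect_equal(res$p, 1)
  expect_lt(res$k, 2)
  # approximate uniformity of p under HW pairing (200 seeds)
  ps <- vapply(1:200, function(s) {
    ds <- make_equilibrium_pop(n_ind = 15, n_loci = 1, theta = 3, seed = s)
    hwe_test(ds, "P1", "L1", n_perm = 199, seed = s)$p
  }, 0)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.001)
  expect_lte(mean(ps < 0.05), 0.09)
})

test_that("null-allele moment estimator has its analytic expectation", {
  # trivial identities
  ds <- make_dataset(rep("P", 4), cbind(c(1L, 1L, 2L, 2L)),
                     cbind(c(2L, 2L, 3L, 3L)))
  h <- heterozygosity(ds, "P", "L1")
  expect_equal(null_allele_estimate(ds, "P", "L1"),
               (h$H_E - h$H_O) / (h$H_E + h$H_O))
  all_hom <- make_dataset(rep("P", 4), cbind(c(1L, 1L, 2L, 2L)),
                          cbind(c(1L, 1L, 2L, 2L)))
  expect_equal(null_allele_estimate(all_hom, "P", "L1"), 1)
  # true null allele at frequency 0.2 under HW: E[r] ~ 0.2 / 1.2
  set.seed(31)
  rs <- replicate(50, {
    n <- 40
    p_vis <- c(0.3, 0.3, 0.2)  # visible alleles; null freq 0.2
    draw <- function() sample.int(4, 1, prob = c(p_vis, 0.2))
    g <- t(replicate(n, c(draw(), draw())))
    # null allele 4: het with null looks homozygous, null homozygote missing
    a1 <- g[, 1]; a2 <- g[, 2]
    both_null <- a1 == 4 & a2 == 4
    a1[a1 == 4] <- a2[a1 == 4]; a2[a2 == 4] <- a1[a2 == 4]
    a1[both_null] <- NA; a2[both_null] <- NA
    ds <- make_dataset(rep("P", n), cbind(a1), cbind(a2))
    null_allele_estimate(ds, "P", "L1")
  })
  expect_lt(abs(mean(rs) - 0.2 / 1.2), 0.07)
})

test_that("the screening rule flags only high-null-rate loci", {
  ds <- make_equilibrium_pop(n_ind = 25, n_loci = 3, theta = 4, seed = 3)
  scr <- null_allele_screen(ds, threshold = 0.15)
  expect_equal(nrow(scr), 3L)
  expect_type(scr$flagged, "logical")
})

test_that("diversity summary assembles one row per population", {
  ds <- simulate_genotypes(geno_sim_spec(n_pops = 3, n_per_pop = 10,
                                         n_loci = 4, F = 0.05, seed = 2))
  div <- diversity_summary(ds)
  expect_equal(nrow(div), 3L)
  expect_true(all(div$H_E >= 0 & div$H_E <= 1))
  expect_true(all(div$A_R >= 1))
  expect_true(all(div$N == 10))
})
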