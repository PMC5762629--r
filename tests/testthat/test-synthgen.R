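test_that("generators are bit-reproducible under a fixed seed", {
  s <- geno_sim_spec(n_pops = 4, n_per_pop = 6, n_loci = 3, seed = 11)
  expect_identical(simulate_genotypes(s), simulate_genotypes(s))
  p <- pheno_sim_spec(n_pops = 4, n_per_pop = 6, seed = 11)
  expect_identical(simulate_phenotypes(p), simulate_phenotypes(p))
  expect_identical(simulate_assay(3, seed = 4), simulate_assay(3, seed = 4))
  expect_identical(simulate_spectra(5, seed = 4), simulate_spectra(5, seed = 4))
})

test_that("generated datasets satisfy the container invariants", {
  for (s in 1:5) {
    ds <- simulate_genotypes(geno_sim_spec(n_pops = 3, n_per_pop = 8,
                                           n_loci = 4, missing_rate = 0.2,
                                           seed = s))
    expect_true(all(ds$a1 > 0, na.rm = TRUE))
    expect_true(all(ds$a1 <= ds$a2, na.rm = TRUE))
    expect_identical(is.na(ds$a1), is.na(ds$a2))
    expect_false(anyDuplicated(unique(ds$ind[, c("pop", "region")])$pop) > 0)
  }
})

test_that("panmictic simulation shows no differentiation (CI covers 0)", {
  ds <- simulate_genotypes(geno_sim_spec(n_pops = 8, n_per_pop = 25,
                                         n_loci = 12, panmictic = TRUE,
                                         missing_rate = 0, seed = 2))
  f <- weir_cockerham_theta(ds, n_boot = 500, seed = 2)
  expect_lt(f$ci[1], 0)
  expect_gt(f$ci[2], -0.02)
  expect_lt(abs(f$theta), 0.02)
})

test_that("island model F = 0 is rejected in favour of the panmictic flag", {
  expect_error(geno_sim_spec(F = 0), "panmictic")
})

test_that("stepping-stone drift produces isolation by distance", {
  hits <- 0L
  for (s in 1:20) {
    ds <- simulate_genotypes(geno_sim_spec(
      n_pops = 14, n_per_pop = 20, n_loci = 8, model = "stepping_stone",
      delta = 0.01, missing_rate = 0, seed = s))
    f <- weir_cockerham_theta(ds, pairwise = TRUE, n_perm = 0, n_boot = 0)
    pops <- populations(ds)
    idx <- abs(outer(seq_along(pops), seq_along(pops), "-"))
    dimnames(idx) <- dimnames(f$pairwise)
    diag(idx) <- 0
    mt <- mantel(pairwise_matrix(idx), pairwise_matrix(f$pairwise),
                 n_perm = 500, seed = s)
    hits <- hits + (mt$p < 0.05)
  }
  expect_gte(hits, 18L)  # >= 90% of 20 seeds
})

test_that("null phenotypes give calibrated ANOVA type-I error at 5%", {
  ps <- vapply(1:40, function(s) {
    ph <- simulate_phenotypes(pheno_sim_spec(n_pops = 8, n_per_pop = 10,
                                             sigma2_B = 0, seed = s))
    anova(aov(value ~ population, data = ph))[1, "Pr(>F)"]
  }, 0)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  expect_lte(mean(ps < 0.05), 0.2)
})

test_that("a simulated sex effect is recovered by the posterior", {
  ph <- simulate_phenotypes(pheno_sim_spec(sigma2_B = 1, sigma2_W = 1,
                                           sex_effect = 2, seed = 9))
  post <- fit_variance_components(ph, "trait1", iterations = 6000,
                                  burn_in = 1000, thin = 5, seed = 1)
  expect_lt(abs(mean(post$beta[, "sexM"]) - 2), 0.3)
})

test_that("assay simulation respects its behavioral dials", {
  quiet <- simulate_assay(3, rates = c(hop = 0, flight = 0, move = 0,
                                       quarter = 0, perch = 0),
                          center_time = 0, seed = 1)
  sc <- exploration_score(quiet)
  expect_equal(sc$exploration, rep(0, 3))
  bold <- simulate_assay(5, rates = c(perch = 2), neophobia_bias = 1,
                         center_time = 0, seed = 2)
  for (l in bold) {
    ns <- neophobia_score(l)
    if (!ns$never_perched) expect_equal(ns$decorated_prop, 1)
  }
})

test_that("neophobia cohorts with distinct bias separate under Kruskal-Wallis", {
  hits <- 0L
  for (s in 1:20) {
    shy <- simulate_assay(15, rates = c(perch = 1.5), neophobia_bias = 0.2,
                          center_time = 0.1, seed = s)
    bold <- simulate_assay(15, rates = c(perch = 1.5), neophobia_bias = 0.8,
                           center_time = 0.3, seed = s + 1000)
    neo <- c(vapply(shy, function(l) neophobia_score(l)$score, 0),
             vapply(bold, function(l) neophobia_score(l)$score, 0))
    grp <- rep(c("shy", "bold"), each = 15)
    hits <- hits + (kruskal.test(neo, factor(grp))$p.value < 0.05)
  }
  expect_gte(hits, 18L)
})

test_that("spectral gradient is recovered as a brightness trend", {
  sp0 <- simulate_spectra(3, gradient = c(0, 0), noise_sd = 0, seed = 1)
  expect_equal(spectrum_to_brightness(sp0), rep(0, 3))
  sp <- simulate_spectra(40, gradient = c(0.2, 0.8), noise_sd = 0.03, seed = 5)
  b <- spectrum_to_brightness(sp)
  pos <- attr(sp, "position")
  expect_lt(mean(b[pos < 0.5]), mean(b[pos >= 0.5]))
  fit <- summary(lm(b ~ pos))
  expect_gt(coef(fit)["pos", "Estimate"], 0)
  expect_lt(coef(fit)["pos", "Pr(>|t|)"], 0.05)
})
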