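test_that("the Pst formula evaluates its anchor points exactly", {
  expect_equal(pst(0, 1, 1), 0)
  expect_equal(pst(0, 1, 17), 0)
  expect_equal(pst(2, 1, 1), 0.5)
  expect_equal(pst(4, 1, 0.5), 0.5)
  expect_error(pst(1, 0), "sigma2_W")
  expect_error(pst(1, 1, 0), "phi")
})

test_that("Pst is strictly increasing in phi and sigma2_B with limit 1", {
  phis <- c(0.01, 0.1, 1, 10, 1000)
  vals <- pst(1.5, 1, phis)
  expect_true(all(diff(vals) > 0))
  expect_lt(abs(pst(1, 1, 1e9) - 1), 1e-8)
  expect_true(all(diff(pst(c(0.5, 1, 2, 4), 1, 1)) > 0))
})

test_that("posterior Pst quantiles are the monotone transform of the ratio quantiles", {
  set.seed(8)
  sB <- rgamma(500, 3, 2); sW <- rgamma(500, 4, 2)
  # order-statistic quantiles commute exactly with monotone transforms
  ratio_q <- quantile(sB / (2 * sW), c(0.025, 0.5, 0.975), type = 1)
  direct_q <- quantile(pst(sB, sW, 1), c(0.025, 0.5, 0.975), type = 1)
  expect_equal(unname(direct_q), unname(ratio_q / (1 + ratio_q)),
               tolerance = 1e-12)
})

test_that("the Gibbs sampler recovers known variance components", {
  hits <- 0L
  for (s in 1:10) {
    ph <- simulate_phenotypes(pheno_sim_spec(sigma2_B = 1, sigma2_W = 1,
                                             seed = s))
    post <- fit_variance_components(ph, "trait1", iterations = 6000,
                                    burn_in = 1000, thin = 5, seed = s)
    ok_B <- abs(median(post$sigma2_B) - 1) < 0.6
    ok_W <- abs(median(post$sigma2_W) - 1) < 0.3
    hits <- hits + (ok_B && ok_W)
  }
  expect_gte(hits, 9L)
})

test_that("a null between-population variance concentrates near zero", {
  ph <- simulate_phenotypes(pheno_sim_spec(sigma2_B = 0.0001, sigma2_W = 1,
                                           seed = 21))
  post <- fit_variance_components(ph, "trait1", iterations = 6000,
                                  burn_in = 1000, thin = 5, seed = 2)
  expect_lt(median(post$sigma2_B), 0.1 * median(post$sigma2_W))
})

test_that("posterior medians agree with REML on a balanced design", {
  skip_if_not_installed("lme4")
  ph <- simulate_phenotypes(pheno_sim_spec(n_pops = 14, n_per_pop = 20,
                                           sigma2_B = 1.5, sigma2_W = 1,
                                           seed = 12))
  post <- fit_variance_components(ph, "trait1", fixed_effects = character(0),
                                  iterations = 12000, burn_in = 2000,
                                  thin = 5, seed = 3)
  fit <- lme4::lmer(value ~ 1 + (1 | population), data = ph, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  expect_lt(abs(median(post$sigma2_B) - vc$vcov[1]),
            0.25 * vc$vcov[1] + 0.1)
  expect_lt(abs(median(post$sigma2_W) - vc$vcov[2]), 0.1 * vc$vcov[2])
  expect_true(post$converged)
  expect_equal(length(post$sigma2_B), (12000 - 2000) / 5)
})

test_that("the critical c/h2 closed form inverts the Pst formula exactly", {
  # fixed point: P_low = F
  expect_equal(critical_c_over_h2(0.3, 0.3 + 1e-9), NA_real_)
  expect_equal(critical_c_over_h2(0.3000001, 0.3), 1, tolerance = 1e-4)
  # machine-precision identity: Pst(phi*, rho_low) = F
  for (P in c(0.05, 0.176, 0.5)) for (F in c(0.016, 0.024, 0.2)) {
    if (P <= F) next
    phi_star <- critical_c_over_h2(P, F)
    rho <- P / (1 - P)
    expect_equal(phi_star * rho / (phi_star * rho + 1), F, tolerance = 1e-12)
  }
  # worked values: right-cheek row exactly, body-mass closed form
  expect_equal(critical_c_over_h2(0.025, 0.024), 0.959, tolerance = 5e-4)
  expect_equal(critical_c_over_h2(0.176, 0.016), 0.0761, tolerance = 5e-4)
})

test_that("grid mode agrees with the closed form on the draw scale", {
  ph <- simulate_phenotypes(pheno_sim_spec(sigma2_B = 2, sigma2_W = 1,
                                           seed = 6))
  post <- fit_variance_components(ph, "trait1", iterations = 8000,
                                  burn_in = 2000, thin = 5, seed = 4)
  P_low <- pst_posterior(post)$lower
  F_up <- 0.016
  phi_cf <- critical_c_over_h2(P_low, F_up)
  phi_grid <- critical_c_over_h2(P_low, F_up, mode = "grid", post = post)
  expect_equal(phi_grid, phi_cf, tolerance = 0.02)
})

test_that("verdicts reproduce the published decision table", {
  t3 <- read.csv(extdata("study_pstfst_summary.csv"))
  for (i in seq_len(nrow(t3))) {
    v <- verdict(t3$lower[i], t3$fst_upper[i], t3$critical[i])
    want <- c(">>" = "Pst >> Fst", ">" = "Pst > Fst", "=" = "Pst = Fst")
    expect_equal(v, unname(want[t3$verdict[i]]), info = t3$trait[i])
  }
})

test_that("the end-to-end table classifies simulated effect sizes correctly", {
  # true Pst = 0.3 -> sigma2_B = 2 * 0.3 / 0.7 with sigma2_W = 1
  ph <- simulate_phenotypes(pheno_sim_spec(sigma2_B = 2 * 0.3 / 0.7,
                                           sigma2_W = 1, seed = 17))
  tab <- pst_fst_table(ph, fst_upper = 0.016, iterations = 8000,
                       burn_in = 2000, thin = 5, seed = 5)
  expect_true(tab$verdict %in% c("Pst > Fst", "Pst >> Fst"))
  # true Pst below Fst -> "="
  ph0 <- simulate_phenotypes(pheno_sim_spec(sigma2_B = 0.001, sigma2_W = 1,
                                            seed = 18))
  tab0 <- pst_fst_table(ph0, fst_upper = 0.016, iterations = 8000,
                        burn_in = 2000, thin = 5, seed = 5)
  expect_equal(tab0$verdict, "Pst = Fst")
})
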