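#' Observed and unbiased expected heterozygosity
#'
#' For one population at one locus: `H_O` is the fraction of heterozygous
#' genotypes among non-missing individuals; `H_E` is Nei's unbiased
#' estimator `(2n / (2n - 1)) * (1 - sum p_i^2)` with `n` the number of
#' non-missing individuals.
#'
#' @param x a [microsat_dataset()].
#' @param pop population name.
#' @param locus locus name.
#' @return List `(H_O, H_E, n)`; both heterozygosities are `NA` (flagged,
#'   not zero) when every call is missing.
#' @export
heterozygosity <- function(x, pop, locus) {
  g <- genotypes_of(x, pop, locus)
  n <- nrow(g)
  if (n == 0) {
    return(list(H_O = NA_real_, H_E = NA_real_, n = 0L))
  }
  ho <- mean(g[, 1] != g[, 2])
  p <- allele_counts(x, pop, locus) / (2 * n)
  he <- (2 * n / (2 * n - 1)) * (1 - sum(p^2))
  list(H_O = ho, H_E = he, n = n)
}

## Weir-Cockerham within-population component sums for one population:
## for r = 1 the among-population component vanishes and small-f reduces to
## f = 1 - sum(c) / sum(b + c) over alleles and loci, with
## b = (n/(n-1)) * (p(1-p) - (2n-1)/(4n) * hbar), c = hbar / 2.
fis_components <- function(x, pop, locus) {
  g <- genotypes_of(x, pop, locus)
  n <- nrow(g)
  if (n < 2) return(c(b = 0, c = 0))
  alleles <- sort(unique(c(g)))
  b <- 0; cc <- 0
  for (a in alleles) {
    p <- mean(c(g) == a)
    h <- mean((g[, 1] == a) != (g[, 2] == a))
    b <- b + (n / (n - 1)) * (p * (1 - p) - (2 * n - 1) / (4 * n) * h)
    cc <- cc + h / 2
  }
  c(b = b, c = cc)
}

#' Multilocus inbreeding coefficient with bootstrap CI
#'
#' Weir-Cockerham small-f for a single population: ratio-of-sums over loci
#' of the within-individual variance components, `f = 1 - sum(c) /
#' sum(b + c)`. The 95% CI is a percentile bootstrap over loci.
#'
#' @param x a [microsat_dataset()].
#' @param pop population name.
#' @param n_boot bootstrap replicates (over loci).
#' @param seed integer seed for the bootstrap.
#' @return List `(F_IS, ci, n_loci)`; `ci` is `c(lower, upper)` and is
#'   `NA` (with a warning) when only one informative locus is available.
#' @export
fis <- function(x, pop, n_boot = 1000, seed = 1) {
  comp <- t(vapply(x$loci, function(l) fis_components(x, pop, l), c(b = 0, c = 0)))
  use <- rowSums(abs(comp)) > 0
  comp <- comp[use, , drop = FALSE]
  if (!nrow(comp)) return(list(F_IS = NA_real_, ci = c(NA, NA), n_loci = 0L))
  f_of <- function(m) 1 - sum(m[, "c"]) / sum(m[, "b"] + m[, "c"])
  est <- f_of(comp)
  if (nrow(comp) < 2) {
    warning("single informative locus: F_IS CI is degenerate")
    return(list(F_IS = est, ci = c(NA_real_, NA_real_), n_loci = nrow(comp)))
  }
  boots <- with_seed(derive_seed(seed, "fis"), {
    vapply(seq_len(n_boot), function(b) {
      f_of(comp[sample.int(nrow(comp), replace = TRUE), , drop = FALSE])
    }, 0)
  })
  list(F_IS = est,
       ci = unname(quantile(boots, c(0.025, 0.975), na.rm = TRUE)),
       n_loci = nrow(comp))
}

## log-domain ratio C(N - Ni, g) / C(N, g); 0 when N - Ni < g
choose_ratio <- function(N, Ni, g) {
  if (N - Ni < g) return(0)
  exp(lchoose(N - Ni, g) - lchoose(N, g))
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a random subsample of `g` gene
#' copies: `A_R(g) = sum_i [1 - C(N - N_i, g) / C(N, g)]` where `N_i` is
#' the count of allele i among the `N` sampled copies. Exact combinatorics,
#' evaluated in the log domain.
#'
#' @param x a [microsat_dataset()].
#' @param pop population name.
#' @param locus locus name.
#' @param g rarefaction size in gene copies, `1 <= g <= N`.
#' @return The rarefied richness, in `[1, g]`.
#' @export
allelic_richness <- function(x, pop, locus, g) {
  cnt <- allele_counts(x, pop, locus)
  N <- sum(cnt)
  if (g < 1) stop("g must be >= 1")
  if (g > N) stop(sprintf("g = %d exceeds available gene copies (%d)", g, N))
  sum(vapply(cnt, function(Ni) 1 - choose_ratio(N, Ni, g), 0))
}

#' Rarefied private allelic richness
#'
#' Expected number of alleles present in a rarefied sample of `g` copies
#' from the focal population but absent from rarefied samples of `g` copies
#' from every other population:
#' `A_PR(g) = sum_i Q_ij(g) * prod_{k != j} (1 - Q_ik(g))`, with
#' `Q_ik(g) = 1 - C(N_k - N_ik, g) / C(N_k, g)` the probability that allele
#' i appears in the rarefied sample from population k.
#'
#' @inheritParams allelic_richness
#' @param g rarefaction size; every population must hold at least `g`
#'   copies at the locus (else an error — callers building summaries skip
#'   and report such loci).
#' @return The rarefied private richness, `0 <= A_PR(g) <= A_R(g)`.
#' @export
private_allelic_richness <- function(x, pop, locus, g) {
  pops <- populations(x)
  cnts <- lapply(pops, function(p) allele_counts(x, p, locus))
  names(cnts) <- pops
  Ns <- vapply(cnts, sum, 0L)
  if (any(Ns < g)) {
    stop(sprintf("population(s) %s hold fewer than g = %d copies at %s",
                 paste(pops[Ns < g], collapse = ", "), g, locus))
  }
  alleles <- sort(unique(as.integer(unlist(lapply(cnts, names)))))
  Q <- function(k, a) {
    Nik <- unname(cnts[[k]][as.character(a)])
    if (is.na(Nik)) Nik <- 0L
    1 - choose_ratio(unname(Ns[[k]]), Nik, g)
  }
  total <- 0
  for (a in alleles) {
    term <- Q(pop, a)
    for (k in setdiff(pops, pop)) term <- term * (1 - Q(k, a))
    total <- total + term
  }
  total
}

## Levene's conditional probability of a genotype array given allele counts
log_hw_prob <- function(g) {
  n <- nrow(g)
  lo <- pmin(g[, 1], g[, 2]); hi <- pmax(g[, 1], g[, 2])
  cnt <- table(c(g))
  h <- sum(lo != hi)
  lfactorial(n) - sum(lfactorial(table(paste(lo, hi)))) +
    h * log(2) + sum(lfactorial(cnt)) - lfactorial(2 * n)
}

#' Monte Carlo exact test of Hardy-Weinberg proportions
#'
#' The test statistic is the conditional probability of the observed
#' genotype array given the allele counts (Levene's distribution); the
#' p-value is the share of allele-shuffled genotype arrays whose probability
#' is no greater than the observed one, with the observed array counted in
#' both numerator and denominator.
#'
#' @param x a [microsat_dataset()].
#' @param pop population name.
#' @param locus locus name.
#' @param n_perm Monte Carlo shuffles.
#' @param seed integer seed.
#' @return List `(p, n, k)`; `p = 1` (flagged via `k < 2`) for loci with
#'   fewer than two alleles in the population.
#' @export
hwe_test <- function(x, pop, locus, n_perm = 1000, seed = 1) {
  g <- genotypes_of(x, pop, locus)
  k <- length(unique(c(g)))
  if (k < 2) return(list(p = 1, n = nrow(g), k = k))
  obs <- log_hw_prob(g)
  copies <- c(g)
  hits <- with_seed(derive_seed(seed, "hwe"), {
    sum(vapply(seq_len(n_perm), function(b) {
      s <- sample(copies)
      log_hw_prob(cbind(s[seq_len(nrow(g))], s[-seq_len(nrow(g))])) <=
        obs + 1e-9
    }, NA))
  })
  list(p = (hits + 1) / (n_perm + 1), n = nrow(g), k = k)
}

#' Moment estimate of null-allele frequency
#'
#' Chakraborty's estimator `r = (H_E - H_O) / (H_E + H_O)`, which under
#' Hardy-Weinberg with a null allele at frequency `q` has expectation
#' `q / (1 + q)`.
#'
#' @inheritParams heterozygosity
#' @return The estimate, or `NA` (flagged) when `H_E + H_O = 0`.
#' @export
null_allele_estimate <- function(x, pop, locus) {
  h <- heterozygosity(x, pop, locus)
  if (is.na(h$H_E) || h$H_E + h$H_O == 0) return(NA_real_)
  (h$H_E - h$H_O) / (h$H_E + h$H_O)
}

#' Locus screening for null alleles
#'
#' Flags loci whose mean Chakraborty estimate across populations exceeds a
#' threshold, the screening rule used to drop compromised markers before
#' differentiation analyses.
#'
#' @param x a [microsat_dataset()].
#' @param threshold mean-estimate threshold (default 0.15).
#' @return data.frame with locus, mean estimate and `flagged`.
#' @export
null_allele_screen <- function(x, threshold = 0.15) {
  pops <- populations(x)
  mean_r <- vapply(x$loci, function(l) {
    mean(vapply(pops, function(p) null_allele_estimate(x, p, l), 0),
         na.rm = TRUE)
  }, 0)
  data.frame(locus = x$loci, null_allele_r = unname(mean_r),
             flagged = unname(mean_r > threshold),
             stringsAsFactors = FALSE)
}

#' Per-population diversity summary table
#'
#' One row per population: sample size, mean unbiased expected and observed
#' heterozygosity over loci, multilocus F_IS with bootstrap CI, rarefied
#' allelic and private allelic richness (mean over loci at a common
#' rarefaction size), and the heterozygosity-excess bottleneck Wilcoxon p
#' with the mode-shift flag.
#'
#' @param x a [microsat_dataset()].
#' @param g rarefaction size in gene copies; default (`NULL`) is the
#'   smallest per-locus copy count across populations.
#' @param bottleneck if `TRUE` run [bottleneck_test()] per population.
#' @param model mutation model for the bottleneck test.
#' @param n_sim,seed bottleneck simulation settings.
#' @return data.frame, one row per population.
#' @export
diversity_summary <- function(x, g = NULL, bottleneck = FALSE,
                              model = tpm_model(), n_sim = 1000, seed = 1) {
  pops <- populations(x)
  if (is.null(g)) {
    g <- min(vapply(x$loci, function(l) {
      min(vapply(pops, function(p) sum(allele_counts(x, p, l)), 0L))
    }, 0L))
  }
  rows <- lapply(pops, function(p) {
    hs <- lapply(x$loci, function(l) heterozygosity(x, p, l))
    he <- mean(vapply(hs, `[[`, 0, "H_E"), na.rm = TRUE)
    ho <- mean(vapply(hs, `[[`, 0, "H_O"), na.rm = TRUE)
    fi <- fis(x, p, seed = seed)
    ar <- mean(vapply(x$loci, function(l) {
      if (sum(allele_counts(x, p, l)) >= g) allelic_richness(x, p, l, g)
      else NA_real_
    }, 0), na.rm = TRUE)
    apr <- mean(vapply(x$loci, function(l) {
      tryCatch(private_allelic_richness(x, p, l, g), error = function(e) NA_real_)
    }, 0), na.rm = TRUE)
    bt_p <- NA_real_; ms <- NA
    if (bottleneck) {
      bt <- bottleneck_test(x, p, model = model, n_sim = n_sim,
                            seed = derive_seed(seed, p))
      bt_p <- bt$p_wilcoxon; ms <- bt$mode_shift
    }
    data.frame(population = p, N = sum(x$ind$pop == p), H_E = he, H_O = ho,
               F_IS = fi$F_IS, F_IS_lo = fi$ci[1], F_IS_hi = fi$ci[2],
               A_R = ar, A_PR = apr, bottleneck_p = bt_p, mode_shift = ms,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "g") <- g
  out
}
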