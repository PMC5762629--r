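#' Specification for a synthetic genotype dataset
#'
#' Defaults emulate the study system: 14 populations of 20 diploid
#' individuals typed at 8 microsatellite loci carrying 4-28 alleles each,
#' with very low global differentiation (the empirical regime is
#' theta ~ 0.008) and an isolation-by-distance gradient available through
#' the stepping-stone model.
#'
#' @param n_pops number of populations.
#' @param n_per_pop diploid individuals per population (>= 2).
#' @param n_loci number of loci.
#' @param alleles_per_locus integer range (length 2) of allele counts per
#'   locus; each locus draws its count uniformly from this range.
#' @param dirichlet_conc concentration of the symmetric Dirichlet from which
#'   ancestral allele frequencies are drawn.
#' @param model `"island"` (Balding-Nichols, differentiation parameter `F`)
#'   or `"stepping_stone"` (per-step drift `delta` along a line of
#'   populations).
#' @param F island-model differentiation parameter, in (0, 1); set
#'   `panmictic = TRUE` instead of `F = 0`.
#' @param delta stepping-stone per-step drift variance scale, in (0, 1).
#' @param panmictic if `TRUE` all populations share the ancestral
#'   frequencies exactly (no drift).
#' @param missing_rate per-call missing probability.
#' @param seed integer seed.
#' @return A `geno_sim_spec` list.
#' @export
geno_sim_spec <- function(n_pops = 14, n_per_pop = 20, n_loci = 8,
                          alleles_per_locus = c(4, 28), dirichlet_conc = 1,
                          model = c("island", "stepping_stone"),
                          F = 0.008, delta = 0.01, panmictic = FALSE,
                          missing_rate = 0.02, seed = 1) {
  model <- match.arg(model)
  if (n_per_pop < 2) stop("n_per_pop must be >= 2")
  if (!panmictic && model == "island" && (F <= 0 || F >= 1)) {
    stop("island model requires F in (0, 1); use panmictic = TRUE for F = 0")
  }
  if (model == "stepping_stone" && (delta <= 0 || delta >= 1)) {
    stop("delta must be in (0, 1)")
  }
  structure(list(n_pops = n_pops, n_per_pop = n_per_pop, n_loci = n_loci,
                 alleles_per_locus = alleles_per_locus,
                 dirichlet_conc = dirichlet_conc, model = model, F = F,
                 delta = delta, panmictic = panmictic,
                 missing_rate = missing_rate, seed = seed),
            class = "geno_sim_spec")
}

rdirichlet1 <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(x == 0)) x[which.max(alpha)] <- 1
  x / sum(x)
}

#' Simulate microsatellite genotypes with known differentiation
#'
#' Island model: per-locus population allele frequencies are drawn from a
#' Dirichlet with parameters `p_anc * (1 - F) / F` (Balding-Nichols), so the
#' expected Wright fixation index equals `F` by construction. Stepping
#' stone: population j+1 frequencies are drawn from a Dirichlet centred on
#' population j's frequencies with per-step variance ~ `delta * p * (1 - p)`
#' (concentration `(1 - delta) / delta`), frequencies clipped to
#' \[0.001, 0.999\] and renormalised to avoid absorbing states; divergence
#' then accumulates with position along the line, producing isolation by
#' distance. Genotypes are two independent allele draws per individual.
#'
#' @param spec a [geno_sim_spec()].
#' @return A [microsat_dataset()] with populations `P01 ...`, regions
#'   assigned by quartile of the population line (`R1`-`R4`), sexes
#'   alternating M/F; the spec is attached as attribute `"sim_spec"`.
#' @export
simulate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "geno_sim_spec"))
  with_seed(derive_seed(spec$seed, "geno"), {
    np <- spec$n_pops; ni <- spec$n_per_pop; nl <- spec$n_loci
    pops <- sprintf("P%02d", seq_len(np))
    region_of <- paste0("R", cut(seq_len(np), 4, labels = FALSE))
    k_locus <- sample(seq(spec$alleles_per_locus[1], spec$alleles_per_locus[2]),
                      nl, replace = TRUE)
    n <- np * ni
    a1 <- matrix(NA_integer_, n, nl); a2 <- matrix(NA_integer_, n, nl)
    for (l in seq_len(nl)) {
      k <- k_locus[l]
      panc <- rdirichlet1(rep(spec$dirichlet_conc, k))
      freqs <- matrix(0, np, k)
      if (spec$panmictic) {
        freqs <- matrix(panc, np, k, byrow = TRUE)
      } else if (spec$model == "island") {
        conc <- panc * (1 - spec$F) / spec$F
        for (j in seq_len(np)) freqs[j, ] <- rdirichlet1(conc)
      } else {
        cur <- panc
        for (j in seq_len(np)) {
          cur <- rdirichlet1(cur * (1 - spec$delta) / spec$delta)
          cur <- pmin(pmax(cur, 0.001), 0.999)
          cur <- cur / sum(cur)
          freqs[j, ] <- cur
        }
      }
      for (j in seq_len(np)) {
        rows <- ((j - 1) * ni + 1):(j * ni)
        a1[rows, l] <- sample.int(k, ni, replace = TRUE, prob = freqs[j, ])
        a2[rows, l] <- sample.int(k, ni, replace = TRUE, prob = freqs[j, ])
      }
    }
    if (spec$missing_rate > 0) {
      miss <- matrix(runif(n * nl) < spec$missing_rate, n, nl)
      a1[miss] <- NA; a2[miss] <- NA
    }
    ind <- data.frame(
      id = paste0(rep(pops, each = ni), "_", rep(seq_len(ni), np)),
      pop = rep(pops, each = ni),
      region = rep(region_of, each = ni),
      sex = rep_len(c("M", "F"), n),
      stringsAsFactors = FALSE)
    ds <- microsat_dataset(ind, sprintf("L%02d", seq_len(nl)), a1, a2)
    attr(ds, "sim_spec") <- spec
    ds
  })
}

#' Specification for synthetic phenotypes
#'
#' Houses the two variances of the Pst formula: `sigma2_B` (between
#' populations) and `sigma2_W` (within). Defaults mirror the study design
#' scale: 14 populations x 20 individuals.
#'
#' @param n_pops,n_per_pop design size.
#' @param sigma2_B between-population variance (>= 0).
#' @param sigma2_W within-population (residual) variance (> 0).
#' @param sex_effect additive fixed effect of being male, trait units.
#' @param year_effect additive fixed effect per year since the first.
#' @param lat_slope latitudinal trend added to the population means, per
#'   index step along the population line (Bergmann/Gloger-style gradients).
#' @param grand_mean intercept.
#' @param trait trait name.
#' @param seed integer seed.
#' @return A `pheno_sim_spec` list.
#' @export
pheno_sim_spec <- function(n_pops = 14, n_per_pop = 20, sigma2_B = 1,
                           sigma2_W = 1, sex_effect = 0, year_effect = 0,
                           lat_slope = 0, grand_mean = 0,
                           trait = "trait1", seed = 1) {
  if (sigma2_B < 0 || sigma2_W <= 0) {
    stop("sigma2_B must be >= 0 and sigma2_W > 0")
  }
  structure(list(n_pops = n_pops, n_per_pop = n_per_pop,
                 sigma2_B = sigma2_B, sigma2_W = sigma2_W,
                 sex_effect = sex_effect, year_effect = year_effect,
                 lat_slope = lat_slope, grand_mean = grand_mean,
                 trait = trait, seed = seed),
            class = "pheno_sim_spec")
}

#' Simulate a phenotype table with known variance components
#'
#' `value = grand_mean + u_pop + sex_effect * male + year_effect * (year -
#' year0) + lat_slope * pop_index + e`, with `u_pop ~ N(0, sigma2_B)` and
#' `e ~ N(0, sigma2_W)`. If a genotype dataset is supplied, individual ids,
#' population, region and sex labels are taken from it so phenotype and
#' genotype records match one-to-one.
#'
#' @param spec a [pheno_sim_spec()].
#' @param dataset optional [microsat_dataset()] supplying the individuals.
#' @return A `phenotype_table` with attribute `"sim_spec"` (and
#'   `"pop_effects"`, the realised population effects).
#' @export
simulate_phenotypes <- function(spec, dataset = NULL) {
  stopifnot(inherits(spec, "pheno_sim_spec"))
  with_seed(derive_seed(spec$seed, "pheno"), {
    if (is.null(dataset)) {
      pops <- sprintf("P%02d", seq_len(spec$n_pops))
      ind <- data.frame(
        id = paste0(rep(pops, each = spec$n_per_pop), "_",
                    rep(seq_len(spec$n_per_pop), spec$n_pops)),
        pop = rep(pops, each = spec$n_per_pop),
        region = paste0("R", cut(match(rep(pops, each = spec$n_per_pop), pops),
                                 4, labels = FALSE)),
        sex = rep_len(c("M", "F"), spec$n_pops * spec$n_per_pop),
        stringsAsFactors = FALSE)
    } else {
      ind <- dataset$ind
    }
    pops <- unique(ind$pop)
    u <- rnorm(length(pops), 0, sqrt(spec$sigma2_B))
    names(u) <- pops
    year <- sample(0:2, nrow(ind), replace = TRUE)
    pidx <- match(ind$pop, pops)
    val <- spec$grand_mean + u[ind$pop] +
      spec$sex_effect * (ind$sex == "M") +
      spec$year_effect * year +
      spec$lat_slope * pidx +
      rnorm(nrow(ind), 0, sqrt(spec$sigma2_W))
    out <- data.frame(individual = ind$id, population = ind$pop,
                      region = ind$region, sex = ind$sex,
                      year = 2013 + year, trait = spec$trait,
                      value = unname(val), stringsAsFactors = FALSE)
    class(out) <- c("phenotype_table", "data.frame")
    attr(out, "sim_spec") <- spec
    attr(out, "pop_effects") <- u
    out
  })
}

#' Simulate behavioral assay event logs
#'
#' Event counts are Poisson at the given per-minute rates with timestamps
#' uniform over the assay; perch landings choose a decorated perch with
#' probability `neophobia_bias` (1 = always the novel perches, i.e. no
#' neophobia); a fraction `center_time` of the assay is spent in the center
#' of the arena, encoded as an `enter_center`/`leave_center` pair.
#'
#' @param n_birds number of birds (one log each).
#' @param rates named per-minute rates for `hop`, `flight`, `move`,
#'   `quarter` (quarter entries) and `perch` (perch landings).
#' @param neophobia_bias probability in \[0, 1\] that a landing picks a
#'   decorated perch.
#' @param center_time fraction of the assay spent in the center.
#' @param duration assay duration in minutes (> 0).
#' @param population population label for all birds.
#' @param seed integer seed.
#' @return List of [assay_log()] objects.
#' @export
simulate_assay <- function(n_birds,
                           rates = c(hop = 3, flight = 0.6, move = 1,
                                     quarter = 0.3, perch = 0.4),
                           neophobia_bias = 0.5, center_time = 0.2,
                           duration = 15, population = "P01", seed = 1) {
  if (duration <= 0) stop("duration must be > 0")
  defaults <- c(hop = 0, flight = 0, move = 0, quarter = 0, perch = 0)
  rates <- c(rates, defaults[setdiff(names(defaults), names(rates))])
  with_seed(derive_seed(seed, "assay"), {
    decorated <- 1:3
    lapply(seq_len(n_birds), function(b) {
      ev <- list()
      for (kind in c("hop", "flight", "move")) {
        nk <- rpois(1, rates[[kind]] * duration)
        if (nk) ev[[kind]] <- data.frame(time = sort(runif(nk, 0, duration)),
                                         event = kind, arg = NA_integer_)
      }
      nq <- rpois(1, rates[["quarter"]] * duration)
      if (nq) ev$quarter <- data.frame(time = sort(runif(nq, 0, duration)),
                                       event = "enter_quarter",
                                       arg = sample.int(4, nq, replace = TRUE))
      np <- rpois(1, rates[["perch"]] * duration)
      if (np) {
        dec <- runif(np) < neophobia_bias
        perch <- ifelse(dec, sample(decorated, np, replace = TRUE),
                        sample(4:6, np, replace = TRUE))
        ev$perch <- data.frame(time = sort(runif(np, 0, duration)),
                               event = "land_perch", arg = as.integer(perch))
      }
      if (center_time > 0) {
        len <- center_time * duration
        t0 <- runif(1, 0, duration - len)
        ev$center <- data.frame(time = c(t0, t0 + len),
                                event = c("enter_center", "leave_center"),
                                arg = NA_integer_)
      }
      events <- do.call(rbind, ev)
      if (is.null(events)) {
        events <- data.frame(time = numeric(0), event = character(0),
                             arg = integer(0))
      }
      events <- events[order(events$time), , drop = FALSE]
      assay_log(sprintf("A%03d", b), sprintf("bird%03d", b), population,
                duration, events, decorated = decorated)
    })
  })
}

#' Simulate flat reflectance spectra along a brightness gradient
#'
#' Sample i receives a flat spectrum at a level interpolated linearly
#' between the two gradient endpoints, plus Gaussian noise, clipped at 0.
#'
#' @param n number of samples.
#' @param gradient length-2 numeric, reflectance level of the first and last
#'   sample.
#' @param noise_sd per-wavelength Gaussian noise standard deviation.
#' @param seed integer seed.
#' @return A [spectrum_table()] with attribute `"position"` (the gradient
#'   coordinate of each sample, in \[0, 1\]).
#' @export
simulate_spectra <- function(n, gradient = c(0.2, 0.8), noise_sd = 0.02,
                             seed = 1) {
  with_seed(derive_seed(seed, "spectra"), {
    pos <- if (n == 1) 0 else (seq_len(n) - 1) / (n - 1)
    level <- gradient[1] + pos * (gradient[2] - gradient[1])
    wl <- spectrum_wavelengths()
    m <- matrix(rep(level, each = length(wl)), n, length(wl), byrow = TRUE)
    m <- pmax(m + matrix(rnorm(n * length(wl), 0, noise_sd), n), 0)
    out <- spectrum_table(m)
    attr(out, "position") <- pos
    out
  })
}
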