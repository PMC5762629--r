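## Weir-Cockerham (1984) variance components for one locus across r
## populations with unequal sample sizes. Returns the per-locus sums over
## alleles of the among-population (a), among-individual-within-population
## (b) and within-individual (c) components. Loci monomorphic across the
## subset give a = b = c = 0 and are excluded upstream.
wc_components_locus <- function(glist) {
  glist <- glist[vapply(glist, nrow, 0L) > 0]
  r <- length(glist)
  if (r < 2) return(c(a = 0, b = 0, c = 0))
  ns <- vapply(glist, nrow, 0L)
  nbar <- mean(ns)
  nc <- (r * nbar - sum(ns^2) / (r * nbar)) / (r - 1)
  alleles <- sort(unique(unlist(glist)))
  if (length(alleles) < 2) return(c(a = 0, b = 0, c = 0))
  a <- b <- cc <- 0
  for (al in alleles) {
    p_i <- vapply(glist, function(g) mean(c(g) == al), 0)
    h_i <- vapply(glist, function(g) mean((g[, 1] == al) != (g[, 2] == al)), 0)
    pbar <- sum(ns * p_i) / (r * nbar)
    s2 <- sum(ns * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ns * h_i) / (r * nbar)
    a <- a + (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- b + (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- cc + hbar / 2
  }
  c(a = a, b = b, c = cc)
}

wc_theta_from_components <- function(comp) {
  tot <- sum(comp[, "a"] + comp[, "b"] + comp[, "c"])
  if (tot == 0) return(NA_real_)
  sum(comp[, "a"]) / tot
}

#' Weir-Cockerham theta (multilocus F_ST)
#'
#' Estimates among-population differentiation with Weir and Cockerham's
#' theta: per-allele variance components with unequal sample sizes, the
#' multilocus estimate being the ratio of summed components (never the mean
#' of per-locus ratios). Negative estimates are reported as computed. A 95%
#' CI is obtained by bootstrap over loci; pairwise theta significance by
#' permuting individuals between the two populations.
#'
#' @param x a [microsat_dataset()].
#' @param pops populations to include (default all; at least 2).
#' @param n_boot bootstrap replicates over loci for the CI (0 disables).
#' @param pairwise if `TRUE` also compute the pairwise theta matrix with
#'   permutation p-values.
#' @param n_perm permutations per population pair.
#' @param seed integer seed.
#' @return An `fst_result` list: `theta` (multilocus), `ci`, `per_locus`
#'   (data.frame of components and per-locus theta; monomorphic loci
#'   excluded with a warning), and when requested `pairwise` / `pairwise_p`
#'   matrices.
#' @export
weir_cockerham_theta <- function(x, pops = NULL, n_boot = 1000,
                                 pairwise = FALSE, n_perm = 10000, seed = 1) {
  pops <- pops %||% populations(x)
  if (length(pops) < 2) stop("need at least 2 populations")
  comp <- t(vapply(x$loci, function(l) {
    wc_components_locus(lapply(pops, function(p) genotypes_of(x, p, l)))
  }, c(a = 0, b = 0, c = 0)))
  poly <- rowSums(abs(comp)) > 0
  if (any(!poly)) {
    warning(sprintf("monomorphic locus excluded: %s",
                    paste(x$loci[!poly], collapse = ", ")))
  }
  comp_use <- comp[poly, , drop = FALSE]
  theta <- wc_theta_from_components(comp_use)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0 && nrow(comp_use) > 1) {
    boots <- with_seed(derive_seed(seed, "fstboot"), {
      vapply(seq_len(n_boot), function(b) {
        wc_theta_from_components(
          comp_use[sample.int(nrow(comp_use), replace = TRUE), , drop = FALSE])
      }, 0)
    })
    ci <- unname(quantile(boots, c(0.025, 0.975), na.rm = TRUE))
  }
  per_locus <- data.frame(locus = x$loci, comp,
                          theta = ifelse(rowSums(abs(comp)) > 0,
                                         comp[, "a"] / rowSums(comp), NA),
                          stringsAsFactors = FALSE)
  out <- list(theta = theta, ci = ci, per_locus = per_locus, pops = pops)
  if (pairwise) {
    np <- length(pops)
    pm <- matrix(0, np, np, dimnames = list(pops, pops))
    pp <- matrix(NA_real_, np, np, dimnames = list(pops, pops))
    for (i in seq_len(np - 1)) for (j in (i + 1):np) {
      pr <- pairwise_theta_perm(x, pops[i], pops[j], n_perm,
                                derive_seed(seed, i * 1000 + j))
      pm[i, j] <- pm[j, i] <- pr$theta
      pp[i, j] <- pp[j, i] <- pr$p
    }
    out$pairwise <- pm
    out$pairwise_p <- pp
  }
  class(out) <- "fst_result"
  out
}

## two-population theta + permutation p (individuals shuffled between pops)
pairwise_theta_perm <- function(x, p1, p2, n_perm, seed) {
  theta_of <- function(g1, g2) {
    comp <- t(vapply(seq_along(x$loci), function(li) {
      wc_components_locus(list(g1[[li]], g2[[li]]))
    }, c(a = 0, b = 0, c = 0)))
    wc_theta_from_components(comp[rowSums(abs(comp)) > 0, , drop = FALSE])
  }
  i1 <- which(x$ind$pop == p1); i2 <- which(x$ind$pop == p2)
  grab <- function(rows) lapply(seq_along(x$loci), function(li) {
    g <- cbind(x$a1[rows, li], x$a2[rows, li])
    g[!is.na(g[, 1]), , drop = FALSE]
  })
  obs <- theta_of(grab(i1), grab(i2))
  if (n_perm <= 0 || is.na(obs)) return(list(theta = obs, p = NA_real_))
  all_i <- c(i1, i2)
  hits <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(b) {
      s <- sample(all_i)
      t_b <- theta_of(grab(s[seq_along(i1)]), grab(s[-seq_along(i1)]))
      !is.na(t_b) && t_b >= obs - 1e-12
    }, NA))
  })
  list(theta = obs, p = (hits + 1) / (n_perm + 1))
}

## sum of squared differences among gene copies under the 0/1 allele metric:
## for counts c_a over m copies, SSD = (m^2 - sum c_a^2) / (2 m)
ssd_copies <- function(counts) {
  m <- sum(counts)
  if (m == 0) return(0)
  (m^2 - sum(counts^2)) / (2 * m)
}

amova_locus <- function(cnts, groups_of) {
  ## cnts: list pop -> named allele count vector; groups_of: pop -> group
  pops <- names(cnts)
  m_p <- vapply(cnts, sum, 0)
  keep <- m_p > 0
  cnts <- cnts[keep]; pops <- pops[keep]; m_p <- m_p[keep]
  grp <- groups_of[pops]
  groups <- unique(grp)
  M <- sum(m_p)
  pool <- function(lst) {
    all_a <- sort(unique(unlist(lapply(lst, names))))
    colSums(do.call(rbind, lapply(lst, function(v) {
      out <- setNames(numeric(length(all_a)), all_a)
      out[names(v)] <- v
      out
    })), na.rm = TRUE)
  }
  ssd_total <- ssd_copies(pool(cnts))
  ssd_wp <- sum(vapply(cnts, ssd_copies, 0))
  ssd_group <- vapply(groups, function(g) ssd_copies(pool(cnts[grp == g])), 0)
  ssd_ap <- sum(ssd_group) - ssd_wp
  ssd_ag <- ssd_total - sum(ssd_group)
  G <- length(groups); P <- length(pops)
  m_g <- vapply(groups, function(g) sum(m_p[grp == g]), 0)
  df <- c(ag = G - 1, ap = P - G, wp = M - P)
  ## expected-mean-square coefficients (unequal sizes)
  n1 <- (M - sum(vapply(groups, function(g) sum(m_p[grp == g]^2) / m_g[g], 0))) /
    max(P - G, 1)
  n2 <- (sum(vapply(groups, function(g) sum(m_p[grp == g]^2) / m_g[g], 0)) -
           sum(m_p^2) / M) / max(G - 1, 1)
  n3 <- (M - sum(m_g^2) / M) / max(G - 1, 1)
  list(ssd = c(ag = ssd_ag, ap = ssd_ap, wp = ssd_wp), df = df,
       n = c(n1 = n1, n2 = n2, n3 = n3))
}

#' Hierarchical AMOVA on gene copies
#'
#' Allele-frequency-based analysis of molecular variance: nested sums of
#' squares of gene copies under the 0/1 allele distance, partitioned among
#' groups (regions), among populations within groups, and within
#' populations; summed over loci. Negative variance components are reported
#' as computed; percentages always sum to 100. Significance is assessed by
#' permutation: gene copies among populations (within-population level /
#' Phi_ST), populations among groups (F_CT).
#'
#' @param x a [microsat_dataset()].
#' @param groups named character vector `pop -> group`; default the
#'   dataset's region labels. Pass `NULL` to fit the two-level
#'   (no-grouping) decomposition.
#' @param n_perm permutations for the significance tests (0 disables).
#' @param seed integer seed.
#' @return An `amova_result`: data.frame `components` (sigma2, percent, df),
#'   `phi` (`F_CT`, `F_SC`, `F_ST`), `p` (permutation p-values).
#' @export
amova <- function(x, groups = "region", n_perm = 1000, seed = 1) {
  pops <- populations(x)
  if (identical(groups, "region")) {
    map <- unique(x$ind[, c("pop", "region")])
    groups <- setNames(map$region, map$pop)
  } else if (is.null(groups)) {
    groups <- setNames(pops, pops)  # each pop its own group: two-level fit
  }
  fit <- function(ds) {
    per <- lapply(ds$loci, function(l) {
      amova_locus(setNames(lapply(pops, function(p) allele_counts(ds, p, l)),
                           pops), groups)
    })
    ssd <- Reduce(`+`, lapply(per, `[[`, "ssd"))
    df <- per[[1]]$df
    n <- colMeans(do.call(rbind, lapply(per, `[[`, "n")))
    ms <- ssd / pmax(df, 1)
    s2_c <- ms[["wp"]]
    two_level <- all(groups[pops] == pops)
    if (two_level) {
      ## among-population and within-population only
      s2_b <- (ms[["ag"]] - s2_c) / n[["n3"]]
      comps <- c(among_groups = NA, among_pops = s2_b, within_pops = s2_c)
    } else if (df[["ap"]] == 0) {
      ## every group holds a single population: the among-populations-
      ## within-groups level is undefined and reported as NA
      s2_a <- (ms[["ag"]] - s2_c) / n[["n3"]]
      comps <- c(among_groups = s2_a, among_pops = NA, within_pops = s2_c)
    } else {
      s2_b <- (ms[["ap"]] - s2_c) / n[["n1"]]
      s2_a <- (ms[["ag"]] - s2_c - n[["n2"]] * s2_b) / n[["n3"]]
      comps <- c(among_groups = s2_a, among_pops = s2_b, within_pops = s2_c)
    }
    comps
  }
  comps <- fit(x)
  used <- comps[!is.na(comps)]
  total <- sum(used)
  pct <- 100 * comps / total
  two_level <- all(groups[pops] == pops)
  phi <- if (two_level) {
    c(F_CT = NA,
      F_SC = NA,
      F_ST = comps[["among_pops"]] / total)
  } else {
    c(F_CT = comps[["among_groups"]] / total,
      F_SC = if (is.na(comps[["among_pops"]])) NA else
        comps[["among_pops"]] /
          (comps[["among_pops"]] + comps[["within_pops"]]),
      F_ST = (total - comps[["within_pops"]]) / total)
  }
  p <- c(F_CT = NA_real_, F_ST = NA_real_)
  if (n_perm > 0) {
    obs_fst <- phi[["F_ST"]]
    hits_fst <- with_seed(derive_seed(seed, "amova1"), {
      sum(vapply(seq_len(n_perm), function(b) {
        xp <- x
        xp$ind$pop <- sample(x$ind$pop)
        cb <- fit(xp)
        fstb <- sum(cb[!is.na(cb)][-length(cb[!is.na(cb)])]) / sum(cb[!is.na(cb)])
        fstb >= obs_fst - 1e-12
      }, NA))
    })
    p[["F_ST"]] <- (hits_fst + 1) / (n_perm + 1)
    if (!two_level) {
      obs_fct <- phi[["F_CT"]]
      hits <- with_seed(derive_seed(seed, "amova2"), {
        sum(vapply(seq_len(n_perm), function(b) {
          ## permute group membership of populations
          g2 <- setNames(sample(unname(groups[pops])), pops)
          permfit <- {
            per <- lapply(x$loci, function(l) {
              amova_locus(setNames(lapply(pops, function(p)
                allele_counts(x, p, l)), pops), g2)
            })
            ssd <- Reduce(`+`, lapply(per, `[[`, "ssd"))
            df <- per[[1]]$df
            n <- colMeans(do.call(rbind, lapply(per, `[[`, "n")))
            ms <- ssd / pmax(df, 1)
            s2_c <- ms[["wp"]]
            if (df[["ap"]] == 0) {
              s2_a <- (ms[["ag"]] - s2_c) / n[["n3"]]
              s2_a / (s2_a + s2_c)
            } else {
              s2_b <- (ms[["ap"]] - s2_c) / n[["n1"]]
              s2_a <- (ms[["ag"]] - s2_c - n[["n2"]] * s2_b) / n[["n3"]]
              s2_a / (s2_a + s2_b + s2_c)
            }
          }
          permfit >= obs_fct - 1e-12
        }, NA))
      })
      p[["F_CT"]] <- (hits + 1) / (n_perm + 1)
    }
  }
  structure(list(
    components = data.frame(
      level = c("among_groups", "among_pops_within_groups", "within_pops"),
      sigma2 = unname(comps), percent = unname(pct)),
    phi = phi, p = p, groups = groups),
    class = "amova_result")
}
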