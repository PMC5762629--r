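## Dunn's post-hoc test on ranks (z statistics with a tie correction),
## two-sided p-values, Bonferroni-adjusted over the pairs.
dunn_test <- function(value, group) {
  group <- factor(group)
  N <- length(value)
  rk <- rank(value)
  ties <- table(rk)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(rk, group, mean)
  ns <- tapply(rk, group, length)
  lv <- levels(group)
  pairs <- utils::combn(lv, 2)
  res <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / ns[[i]] + 1 / ns[[j]]))
    z <- (rbar[[i]] - rbar[[j]]) / se
    c(z = z, p = 2 * pnorm(-abs(z)))
  })
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
             z = res["z", ], p = res["p", ],
             p_adj = pmin(res["p", ] * ncol(pairs), 1),
             stringsAsFactors = FALSE, row.names = NULL)
}

## compact letter display from a pairwise significance matrix
## (TRUE = significantly different). Insert-and-absorb algorithm.
compact_letters <- function(groups, sig) {
  sets <- list(groups)  # candidate letters: sets of mutually non-different groups
  for (i in seq_along(groups)) for (j in seq_along(groups)) {
    if (i < j && sig[i, j]) {
      for (s in seq_along(sets)) {
        st <- sets[[s]]
        if (all(c(groups[i], groups[j]) %in% st)) {
          sets[[s]] <- setdiff(st, groups[j])
          sets[[length(sets) + 1]] <- setdiff(st, groups[i])
        }
      }
      # absorb duplicates / subsets
      keep <- rep(TRUE, length(sets))
      for (a in seq_along(sets)) for (b in seq_along(sets)) {
        if (a != b && keep[a] && keep[b] &&
            all(sets[[a]] %in% sets[[b]])) keep[a] <- FALSE
      }
      sets <- sets[keep]
    }
  }
  sets <- sets[order(vapply(sets, function(s) match(s[1], groups), 0))]
  letters_of <- setNames(rep("", length(groups)), groups)
  for (s in seq_along(sets)) {
    for (g in sets[[s]]) letters_of[g] <- paste0(letters_of[g], letters[s])
  }
  letters_of
}

#' Compare a trait among regions
#'
#' Assumption-guided one-way comparison: Shapiro-Wilk on the ANOVA
#' residuals and Levene's test route the analysis. When both assumptions
#' hold, a one-way ANOVA with Tukey HSD post-hocs is used; otherwise
#' Welch's ANOVA and a Kruskal-Wallis test with Dunn's post-hocs. The raw
#' p-value is Bonferroni-adjusted across the trait family, and pairwise
#' results are summarised as a compact letter display at `alpha` (regions
#' sharing a letter do not differ).
#'
#' @param phenotypes a `phenotype_table`.
#' @param trait trait name to analyse.
#' @param alpha significance level for assumption checks and the letter
#'   display.
#' @param n_traits Bonferroni family size (default: number of distinct
#'   traits present in `phenotypes`).
#' @return A `region_comparison` list: `test` used, `statistic`, `df`,
#'   `p`, `p_adj`, `posthoc` (pairwise table) and `letters`.
#' @export
compare_regions <- function(phenotypes, trait, alpha = 0.05,
                            n_traits = NULL) {
  d <- phenotypes[phenotypes$trait == trait, ]
  if (!nrow(d)) stop("no rows for trait ", trait)
  small <- table(d$region)
  if (any(small < 2)) {
    stop("region(s) with fewer than 2 observations: ",
         paste(names(small)[small < 2], collapse = ", "))
  }
  n_traits <- n_traits %||% length(unique(phenotypes$trait))
  d$region <- factor(d$region)
  fit <- aov(value ~ region, data = d)
  normal_ok <- tryCatch(shapiro.test(stats::residuals(fit))$p.value > alpha,
                        error = function(e) TRUE)
  homosk_ok <- car::leveneTest(value ~ region, data = d)[1, "Pr(>F)"] > alpha
  lv <- levels(d$region)
  np <- length(lv)
  sig <- matrix(FALSE, np, np, dimnames = list(lv, lv))
  if (normal_ok && homosk_ok) {
    an <- anova(fit)
    stat <- an[1, "F value"]; df <- unname(an$Df); p <- an[1, "Pr(>F)"]
    tk <- TukeyHSD(fit)$region
    ph <- data.frame(pair = rownames(tk), p_adj = tk[, "p adj"],
                     stringsAsFactors = FALSE, row.names = NULL)
    for (k in seq_len(nrow(ph))) {
      gs <- strsplit(ph$pair[k], "-")[[1]]
      sig[gs[1], gs[2]] <- sig[gs[2], gs[1]] <- ph$p_adj[k] < alpha
    }
    test <- "ANOVA"
  } else {
    w <- oneway.test(value ~ region, data = d, var.equal = FALSE)
    kw <- kruskal.test(value ~ region, data = d)
    stat <- unname(kw$statistic); df <- unname(kw$parameter)
    p <- kw$p.value
    dn <- dunn_test(d$value, d$region)
    ph <- data.frame(pair = paste(dn$group2, dn$group1, sep = "-"),
                     p_adj = dn$p_adj, stringsAsFactors = FALSE)
    for (k in seq_len(nrow(dn))) {
      sig[dn$group1[k], dn$group2[k]] <-
        sig[dn$group2[k], dn$group1[k]] <- dn$p_adj[k] < alpha
    }
    test <- "Kruskal-Wallis"
    attr(test, "welch") <- c(F = unname(w$statistic), p = w$p.value)
  }
  structure(list(trait = trait, test = test, statistic = stat, df = df,
                 p = p, p_adj = min(p * n_traits, 1),
                 posthoc = ph,
                 letters = compact_letters(lv, sig)),
            class = "region_comparison")
}

#' Ordinary least squares of a trait on latitude
#'
#' @param phenotypes a `phenotype_table`.
#' @param trait trait name.
#' @param localities a `locality_table`; latitude is joined on
#'   `population -> name`, or supply `pop_latitude` directly.
#' @param pop_latitude optional named vector `population -> latitude`.
#' @param sqrt_transform if `TRUE`, regress `sqrt(value)` (used for traits
#'   whose residuals deviate from normality).
#' @return List `(slope, r2, F, p, n)`.
#' @export
latitude_regression <- function(phenotypes, trait, localities = NULL,
                                pop_latitude = NULL, sqrt_transform = FALSE) {
  d <- phenotypes[phenotypes$trait == trait, ]
  if (is.null(pop_latitude)) {
    if (is.null(localities)) stop("supply localities or pop_latitude")
    pop_latitude <- setNames(localities$latitude, localities$name)
  }
  d$latitude <- unname(pop_latitude[d$population])
  d <- d[is.finite(d$latitude), ]
  if (length(unique(d$latitude)) < 3) {
    stop("need at least 3 distinct latitudes")
  }
  y <- if (sqrt_transform) sqrt(d$value) else d$value
  fit <- lm(y ~ latitude, data = d)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]), r2 = sm$r.squared,
       F = unname(sm$fstatistic[1]),
       p = unname(pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                     lower.tail = FALSE)),
       n = nrow(d))
}

#' @importFrom stats pf residuals
NULL
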