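## Builders for small in-code fixtures and independent oracle
## implementations used across the test files.

make_dataset <- function(pop, a1, a2, region = NULL, sex = NULL,
                         loci = NULL) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  n <- nrow(a1)
  region <- region %||% setNames(unique(pop), unique(pop))
  microsat_dataset(
    data.frame(id = paste0("i", seq_len(n)), pop = pop,
               region = unname(region[pop]),
               sex = sex %||% rep("U", n), stringsAsFactors = FALSE),
    loci %||% paste0("L", seq_len(ncol(a1))), a1, a2)
}

`%||%` <- function(a, b) if (is.null(b)) a else if (is.null(a)) b else a

## equilibrium population at mutation-drift balance: Ewens configurations
## (infinite-alleles) per locus, gene copies randomly paired into diploids
make_equilibrium_pop <- function(n_ind = 20, n_loci = 8, theta = 3,
                                 seed = 1) {
  set.seed(seed)
  a1 <- matrix(NA_integer_, n_ind, n_loci)
  a2 <- matrix(NA_integer_, n_ind, n_loci)
  for (l in seq_len(n_loci)) {
    cnt <- sparrowdiv:::.crp_counts(2 * n_ind, theta)
    copies <- sample(rep(seq_along(cnt), cnt))
    a1[, l] <- copies[seq_len(n_ind)]
    a2[, l] <- copies[n_ind + seq_len(n_ind)]
  }
  make_dataset(rep("P1", n_ind), a1, a2)
}

## Independent brute-force transcription of the Weir-Cockerham (1984)
## per-allele component formulas, written as literal term-by-term algebra
## over explicit population summaries; used only as an oracle.
wc_theta_bruteforce <- function(ds, pops = NULL) {
  pops <- if (is.null(pops)) unique(ds$ind$pop) else pops
  A_sum <- 0; ABC_sum <- 0
  for (locus in ds$loci) {
    li <- match(locus, ds$loci)
    glist <- lapply(pops, function(p) {
      rows <- ds$ind$pop == p
      g <- cbind(ds$a1[rows, li], ds$a2[rows, li])
      g[!is.na(g[, 1]), , drop = FALSE]
    })
    glist <- glist[sapply(glist, nrow) > 0]
    r <- length(glist)
    if (r < 2) next
    n_i <- sapply(glist, nrow)
    n_bar <- sum(n_i) / r
    n_c <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
    alleles <- sort(unique(unlist(lapply(glist, c))))
    if (length(alleles) < 2) next
    for (al in alleles) {
      p_i <- sapply(glist, function(g) sum(g == al) / (2 * nrow(g)))
      h_i <- sapply(glist, function(g) {
        sum((g[, 1] == al & g[, 2] != al) | (g[, 2] == al & g[, 1] != al)) /
          nrow(g)
      })
      p_bar <- sum(n_i * p_i) / sum(n_i)
      s2 <- sum(n_i * (p_i - p_bar)^2) / ((r - 1) * n_bar)
      h_bar <- sum(n_i * h_i) / sum(n_i)
      a <- (n_bar / n_c) * (s2 - (1 / (n_bar - 1)) *
             (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - h_bar / 4))
      b <- (n_bar / (n_bar - 1)) * (p_bar * (1 - p_bar) -
             ((r - 1) / r) * s2 - ((2 * n_bar - 1) / (4 * n_bar)) * h_bar)
      cc <- h_bar / 2
      A_sum <- A_sum + a
      ABC_sum <- ABC_sum + a + b + cc
    }
  }
  A_sum / ABC_sum
}

## exhaustive rarefaction oracle: average distinct-allele count over all
## C(N, g) subsamples of the gene-copy pool
rarefaction_enumerate <- function(copies, g) {
  subs <- utils::combn(length(copies), g)
  mean(apply(subs, 2, function(ix) length(unique(copies[ix]))))
}

## Ewens sampling formula: exact probability of an allele configuration
## (partition of n given as counts) at mutation rate theta
ewens_prob <- function(counts, theta) {
  n <- sum(counts)
  k <- length(counts)
  mult <- table(counts)
  log_p <- k * log(theta) - sum(log(theta + 0:(n - 1))) +
    lfactorial(n) - sum(log(counts)) - sum(lfactorial(mult))
  exp(log_p)
}

## all partitions of n (as count vectors), smallest-first recursion
partitions_of <- function(n, max_part = n) {
  if (n == 0) return(list(integer(0)))
  out <- list()
  for (p in seq_len(min(n, max_part))) {
    for (rest in partitions_of(n - p, p)) {
      out[[length(out) + 1]] <- c(p, rest)
    }
  }
  out
}

extdata <- function(f) system.file("extdata", f, package = "sparrowdiv")

read_table2_matrix <- function(which = c("dist", "fst")) {
  which <- match.arg(which)
  f <- if (which == "dist") "study_pairwise_distances_km.tsv" else "study_pairwise_fst.tsv"
  m <- as.matrix(read.table(extdata(f), sep = "\t", header = TRUE,
                            row.names = 1, check.names = FALSE))
  colnames(m) <- rownames(m)
  pairwise_matrix(m)
}
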