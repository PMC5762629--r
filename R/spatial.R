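#' Great-circle distance in km
#'
#' Haversine distance on a sphere of radius 6371.0 km.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (vectorised).
#' @return Distance(s) in km.
#' @export
great_circle_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180)) {
    stop("coordinates out of range")
  }
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371)
}

#' Construct a labelled symmetric pairwise matrix
#'
#' @param m square numeric matrix (symmetric, zero diagonal).
#' @param labels population names, in a fixed order shared between paired
#'   matrices.
#' @return A `pairwise_matrix`.
#' @export
pairwise_matrix <- function(m, labels = rownames(m)) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("matrix must be square")
  if (max(abs(m - t(m))) > 1e-8) stop("matrix must be symmetric")
  if (any(abs(diag(m)) > 1e-12)) stop("diagonal must be zero")
  dimnames(m) <- list(labels, labels)
  class(m) <- c("pairwise_matrix", "matrix", "array")
  m
}

#' Pairwise geographic distance matrix for populations
#'
#' Each population is mapped to one locality; merged populations use the
#' coordinate of a designated representative locality (by convention the
#' first-listed locality of the merge).
#'
#' @param localities a `locality_table` (see [read_table()]).
#' @param pop_to_locality named character vector `population -> locality
#'   name`; default maps each locality name to itself.
#' @return A [pairwise_matrix()] of great-circle km.
#' @export
distance_matrix <- function(localities, pop_to_locality = NULL) {
  if (is.null(pop_to_locality)) {
    pop_to_locality <- setNames(localities$name, localities$name)
  }
  miss <- setdiff(unname(pop_to_locality), localities$name)
  if (length(miss)) {
    stop("unmapped locality name(s): ", paste(miss, collapse = ", "))
  }
  pops <- names(pop_to_locality)
  idx <- match(pop_to_locality, localities$name)
  lat <- localities$latitude[idx]; lon <- localities$longitude[idx]
  n <- length(pops)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j) m[i, j] <- m[j, i] <- great_circle_km(lat[i], lon[i],
                                                     lat[j], lon[j])
  }
  pairwise_matrix(m, pops)
}

#' Mantel test for matrix correlation
#'
#' `Z = sum_{i<j} X_ij * Y_ij` and `r` the Pearson correlation over the
#' `n(n-1)/2` unordered off-diagonal pairs. The permutation p-value is
#' one-tailed for positive association: joint row/column permutations of
#' one matrix, the identity permutation included in both numerator and
#' denominator.
#'
#' @param X,Y [pairwise_matrix()] objects (or plain symmetric matrices)
#'   with identical labels in identical order.
#' @param n_perm number of random permutations.
#' @param seed integer seed.
#' @return A `mantel_result` list `(Z, r, p, n_perm, seed)`.
#' @export
mantel <- function(X, Y, n_perm = 10000, seed = 1) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!identical(dim(X), dim(Y))) stop("matrices must have identical dimensions")
  if (!is.null(rownames(X)) && !is.null(rownames(Y)) &&
      !identical(rownames(X), rownames(Y))) {
    stop("matrices must share labels in identical order")
  }
  n <- nrow(X)
  if (n < 3) stop("need at least 3 populations")
  ut <- upper.tri(X)
  x <- X[ut]; y <- Y[ut]
  if (sd(x) == 0 || sd(y) == 0) {
    stop("zero variance in off-diagonal entries: r undefined")
  }
  Z <- sum(x * y)
  r <- cor(x, y)
  hits <- with_seed(derive_seed(seed, "mantel"), {
    sum(vapply(seq_len(n_perm), function(b) {
      s <- sample.int(n)
      cor(X[s, s][ut], y) >= r - 1e-12
    }, NA))
  })
  structure(list(Z = Z, r = r, p = (hits + 1) / (n_perm + 1),
                 n_perm = n_perm, seed = seed),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: Z = %.4g, r = %.4f, one-tailed p = %.4g (%d permutations)\n",
              x$Z, x$r, x$p, x$n_perm))
  invisible(x)
}
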