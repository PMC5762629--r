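#' Construct a microsatellite dataset
#'
#' The central genotype container: diploid allele calls for a set of
#' individuals at a set of microsatellite loci, with population / region /
#' sex labels. Allele calls are stored as two integer matrices (`a1`, `a2`)
#' of dimension individuals x loci, canonicalised so that `a1 <= a2`
#' (genotypes are unordered pairs); missing calls are `NA` in both.
#'
#' @param ind data.frame with columns `id`, `pop`, `region`, `sex`
#'   (`"M"`, `"F"` or `"U"` for unknown).
#' @param loci character vector of locus names.
#' @param a1,a2 integer matrices (individuals x loci) of allele codes
#'   (strictly positive), `NA` for missing.
#' @return An object of class `microsat_dataset`.
#' @export
microsat_dataset <- function(ind, loci, a1, a2) {
  ind <- as.data.frame(ind, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "pop", "region", "sex") %in% names(ind)))
  ind$sex <- as.character(ind$sex)
  if (!all(ind$sex %in% c("M", "F", "U"))) {
    stop("sex must be one of 'M', 'F', 'U'")
  }
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (nrow(a1) != nrow(ind) || ncol(a1) != length(loci) ||
      !identical(dim(a1), dim(a2))) {
    stop("allele matrices must be individuals x loci")
  }
  if (any(xor(is.na(a1), is.na(a2)))) {
    stop("half-missing genotypes are not representable: both alleles or neither")
  }
  if (any(a1 <= 0, na.rm = TRUE) || any(a2 <= 0, na.rm = TRUE)) {
    stop("allele codes must be strictly positive")
  }
  # one region per population
  map <- unique(ind[, c("pop", "region")])
  if (anyDuplicated(map$pop)) {
    stop("each population must map to exactly one region")
  }
  swap <- !is.na(a1) & a1 > a2
  tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  dimnames(a1) <- dimnames(a2) <- list(ind$id, loci)
  structure(list(ind = ind, loci = as.character(loci), a1 = a1, a2 = a2),
            class = "microsat_dataset")
}

#' @export
print.microsat_dataset <- function(x, ...) {
  cat(sprintf("microsat_dataset: %d individuals, %d populations, %d loci\n",
              nrow(x$ind), length(unique(x$ind$pop)), length(x$loci)))
  cat(sprintf("  missing calls: %.1f%%\n", 100 * mean(is.na(x$a1))))
  invisible(x)
}

#' Population names of a microsatellite dataset
#' @param x a `microsat_dataset`.
#' @return Character vector of population names in order of first appearance.
#' @export
populations <- function(x) unique(x$ind$pop)

#' Subset a microsatellite dataset
#'
#' @param x a `microsat_dataset`.
#' @param pops populations to keep (default all).
#' @param loci loci to keep (default all).
#' @param sex keep only this sex (`"M"`/`"F"`), default both.
#' @return A `microsat_dataset`.
#' @export
subset_dataset <- function(x, pops = NULL, loci = NULL, sex = NULL) {
  keep <- rep(TRUE, nrow(x$ind))
  if (!is.null(pops)) keep <- keep & x$ind$pop %in% pops
  if (!is.null(sex)) keep <- keep & x$ind$sex %in% sex
  lkeep <- if (is.null(loci)) x$loci else intersect(x$loci, loci)
  li <- match(lkeep, x$loci)
  microsat_dataset(x$ind[keep, , drop = FALSE], lkeep,
                   x$a1[keep, li, drop = FALSE], x$a2[keep, li, drop = FALSE])
}

## allele count table for one population x locus: named integer vector
allele_counts <- function(x, pop, locus) {
  i <- x$ind$pop == pop
  li <- match(locus, x$loci)
  a <- c(x$a1[i, li], x$a2[i, li])
  a <- a[!is.na(a)]
  if (!length(a)) return(integer(0))
  tab <- table(a)
  setNames(as.integer(tab), names(tab))
}

## genotype matrix rows (a1,a2) for one population x locus, missing dropped
genotypes_of <- function(x, pop, locus) {
  i <- x$ind$pop == pop
  li <- match(locus, x$loci)
  g <- cbind(x$a1[i, li], x$a2[i, li])
  g[!is.na(g[, 1]), , drop = FALSE]
}

#' Read a GenePop file
#'
#' Parses the standard GenePop dialect used for diploid microsatellite data:
#' a title line, one locus name per line (or a single comma-separated line),
#' and `Pop` blocks of individual lines `label , 001002 003003 ...`. Both
#' 2- and 3-digit allele widths are accepted; `00`/`000` encodes a missing
#' allele. The population name is the first whitespace-delimited token of
#' the first label in each block; the remainder of the label (if any) is the
#' individual id.
#'
#' @param path path to a GenePop file, or a character vector of lines
#'   (anything containing a newline is treated as literal text).
#' @param regions optional named character vector mapping population name
#'   to region; defaults to region = population.
#' @return A [microsat_dataset()].
#' @export
read_genepop <- function(path, regions = NULL) {
  lines <- if (length(path) > 1 || grepl("\n", path[1])) {
    unlist(strsplit(paste(path, collapse = "\n"), "\n"))
  } else readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  if (length(lines) < 3) stop_parse(length(lines), "truncated GenePop file")
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop_parse(length(lines), "no 'Pop' line found")
  header <- lines[2:(first_pop - 1)]
  loci <- trimws(unlist(strsplit(header, ",")))
  loci <- loci[nzchar(loci)]
  if (!length(loci)) stop_parse(2, "no locus names before first Pop")
  nl <- length(loci)

  recs <- list(); block <- 0L; pop_name <- NA_character_
  block_sizes <- integer(0)
  for (k in seq(first_pop, length(lines))) {
    ln <- trimws(lines[k])
    if (!nzchar(ln)) next
    if (toupper(ln) == "POP") {
      if (block > 0L && block_sizes[block] == 0L) {
        stop_parse(k, "empty Pop block")
      }
      block <- block + 1L
      block_sizes[block] <- 0L
      pop_name <- NA_character_
      next
    }
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2) stop_parse(k, "expected 'label , genotypes'")
    label <- trimws(parts[1])
    toks <- strsplit(label, "[[:space:]]+")[[1]]
    if (is.na(pop_name)) pop_name <- toks[1]
    id <- if (length(toks) > 1) paste(toks[-1], collapse = " ") else NA_character_
    gt <- strsplit(trimws(paste(parts[-1], collapse = ",")), "[[:space:]]+")[[1]]
    gt <- gt[nzchar(gt)]
    if (length(gt) != nl) {
      stop_parse(k, sprintf("individual has %d loci, expected %d",
                            length(gt), nl))
    }
    w <- unique(nchar(gt))
    if (length(w) != 1 || !w %in% c(4L, 6L)) {
      stop_parse(k, "malformed allele width (expect 2x2 or 2x3 digits)")
    }
    half <- w / 2
    a1 <- as.integer(substr(gt, 1, half))
    a2 <- as.integer(substr(gt, half + 1, w))
    if (anyNA(a1) || anyNA(a2)) stop_parse(k, "non-numeric allele code")
    a1[a1 == 0L] <- NA; a2[a2 == 0L] <- NA
    # one zero allele in a diploid call is treated as a fully missing call
    miss <- is.na(a1) | is.na(a2)
    a1[miss] <- NA; a2[miss] <- NA
    block_sizes[block] <- block_sizes[block] + 1L
    recs[[length(recs) + 1L]] <- list(pop = pop_name, id = id, a1 = a1, a2 = a2)
  }
  if (block > 0L && block_sizes[block] == 0L) {
    stop_parse(length(lines), "empty Pop block")
  }
  if (!length(recs)) stop_parse(length(lines), "no individuals")
  pops <- vapply(recs, `[[`, "", "pop")
  ids <- vapply(recs, function(r) r$id %||% NA_character_, "")
  # generated ids where the label carried none
  for (p in unique(pops)) {
    sel <- which(pops == p & is.na(ids))
    ids[sel] <- paste0(p, "_", seq_along(sel))
  }
  reg <- if (is.null(regions)) setNames(unique(pops), unique(pops)) else regions
  ind <- data.frame(id = ids, pop = pops,
                    region = unname(reg[pops]), sex = "U",
                    stringsAsFactors = FALSE)
  a1 <- do.call(rbind, lapply(recs, `[[`, "a1"))
  a2 <- do.call(rbind, lapply(recs, `[[`, "a2"))
  microsat_dataset(ind, loci, a1, a2)
}

#' Write a GenePop file
#'
#' Emits the canonical 3-digit-per-allele encoding with one `Pop` block per
#' population (dataset order) and labels `"<pop> <id>"`, so that
#' `read_genepop(write_genepop(x))` reproduces `x`'s populations and calls.
#'
#' @param x a [microsat_dataset()].
#' @param path output path; if `NULL` the lines are returned invisibly.
#' @param title title line (first line of the file).
#' @return Invisibly, the character vector of file lines.
#' @export
write_genepop <- function(x, path = NULL, title = "sparrowdiv export") {
  if (!length(x$loci)) stop("cannot write a dataset with no loci")
  if (any(x$a2 >= 1000L, na.rm = TRUE)) {
    stop("allele code >= 1000 cannot be encoded in 3 digits")
  }
  enc <- function(a) ifelse(is.na(a), "000", formatC(a, width = 3, flag = "0"))
  out <- c(title, x$loci)
  for (p in populations(x)) {
    out <- c(out, "Pop")
    sel <- which(x$ind$pop == p)
    for (i in sel) {
      g <- paste0(enc(x$a1[i, ]), enc(x$a2[i, ]))
      out <- c(out, paste0(p, " ", x$ind$id[i], " ,  ", paste(g, collapse = " ")))
    }
  }
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}
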