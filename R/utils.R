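#' @useDynLib sparrowdiv, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aov anova aggregate coef cor dist kruskal.test lm
#'   median na.omit oneway.test p.adjust pchisq pnorm predict pt qnorm
#'   quantile rbeta rbinom rgamma rmultinom rnorm rpois runif sd setNames
#'   shapiro.test var wilcox.test TukeyHSD rexp
#' @importFrom utils read.table write.table head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child RNG seed from a master seed
#'
#' All stochastic stages of the package take an explicit integer seed.
#' Components that need several independent streams derive them from one
#' master seed with this helper, keeping every derived seed a valid 32-bit
#' integer.
#'
#' @param seed master integer seed.
#' @param stream stream index (1, 2, ...) or a short character tag.
#' @return An integer seed, deterministic in `(seed, stream)`.
#' @export
derive_seed <- function(seed, stream) {
  if (is.character(stream)) {
    stream <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  }
  as.integer((as.numeric(seed) * 69069 + as.numeric(stream) * 2654435) %%
               2147483399) + 1L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stop_parse <- function(line, msg) {
  stop(sprintf("parse error at line %d: %s", line, msg), call. = FALSE)
}
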