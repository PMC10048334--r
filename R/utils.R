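#' @importFrom methods new validObject is slot
#' @importFrom stats rbinom rpois rnbinom runif dpois dnbinom pbinom
#'   t.test wilcox.test chisq.test ks.test prop.test qpois setNames
#' @importFrom utils read.delim write.table packageVersion
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL evaluates in the current stream.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

.isFraction <- function(x) is.numeric(x) && length(x) == 1L &&
  is.finite(x) && x >= 0 && x <= 1

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Draw per-site read depths: Poisson(mean) or, when dispersion is finite,
# negative binomial with size = dispersion (variance = m + m^2/size).
.drawDepth <- function(n, meanDepth, dispersion = Inf) {
  if (is.finite(dispersion)) rnbinom(n, size = dispersion, mu = meanDepth)
  else rpois(n, meanDepth)
}

.depthPmf <- function(meanDepth, dispersion = Inf, tail = 1e-12) {
  xmax <- if (is.finite(dispersion))
    max(20, ceiling(meanDepth + 40 * sqrt(meanDepth + meanDepth^2 / dispersion)))
  else qpois(1 - tail, meanDepth)
  x <- 0:xmax
  p <- if (is.finite(dispersion)) dnbinom(x, size = dispersion, mu = meanDepth)
  else dpois(x, meanDepth)
  list(x = x, p = p)
}

.BASES <- c("A", "C", "G", "T")
.COMP <- c(A = "T", C = "G", G = "C", T = "A")
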