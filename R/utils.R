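#' @useDynLib sepstab, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats anova aov ave coef cor density lm median model.matrix
#'   pf pnorm predict pt quantile rbinom rnorm runif sd setNames var kmeans
#' @importFrom utils head read.csv write.csv
NULL

# Round half away from zero (base round() is banker's rounding).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Derive a 32-bit child seed from a parent seed and context tags, so every
# stochastic step in a run is reproducible from one master seed.
child_seed <- function(seed, ...) {
  tags <- vapply(list(...), function(t) {
    if (is.character(t)) sum(utf8ToInt(t) * seq_along(utf8ToInt(t))) else as.numeric(t)
  }, numeric(1))
  x <- (as.numeric(seed) %% 2147483647)
  for (t in tags) x <- (x * 48271 + t * 8191 + 1) %% 2147483647
  as.integer(x)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# standardize columns; constant columns become 0 rather than NaN
zscore_cols <- function(X) {
  mu <- colMeans(X)
  s <- apply(X, 2, sd)
  s[s == 0 | !is.finite(s)] <- 1
  sweep(sweep(X, 2, mu, "-"), 2, s, "/")
}
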