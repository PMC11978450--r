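#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx lm coef median quantile rnorm rpois runif sd
#'   setNames plogis qnorm pchisq vcov as.formula complete.cases ave
#'   contrasts<-
#' @importFrom utils head tail write.csv read.csv packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Trapezoid integral of y(x) on an irregular grid.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1L] - x[-n]) * (y[-1L] + y[-n])) / 2
}

# Derive a reproducible sub-seed from a base seed and a stream name, so that
# draws from one named stream (e.g. measurement noise) do not shift draws from
# another (e.g. event times) generated under the same base seed.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  (as.integer(seed) %% 1000003L) * 2017L + (h %% 104729L)
}

# Evaluate `expr` under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

stop_nirtherm <- function(...) stop(..., call. = FALSE)
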