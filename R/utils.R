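#' @keywords internal
"_PACKAGE"

#' @import EBImage
#' @importFrom stats rnorm runif rpois rbinom rexp coef lm predict sd cor
#'   quantile median residuals setNames
#' @importFrom utils head tail write.csv read.csv modifyList
NULL

# Boltzmann constant, J/K
.kB <- 1.380649e-23

# Default global seed used by all preset constructors
.default_seed <- 20211220L

`%||%` <- function(a, b) if (is.null(a)) b else a

logistic <- function(x) 1 / (1 + exp(-x))

# Evaluate expr with a locally-set RNG state; restores the caller's state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         closed_lower = TRUE, closed_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stopf("'%s' must be a single number", name)
  lo_ok <- if (closed_lower) x >= lower else x > lower
  hi_ok <- if (closed_upper) x <= upper else x < upper
  if (!lo_ok || !hi_ok)
    stopf("'%s' = %g out of range %s%g, %g%s", name, x,
          if (closed_lower) "[" else "(", lower, upper,
          if (closed_upper) "]" else ")")
  x
}

# clamp to [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
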