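# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a master seed and a stream name
#'
#' All randomness in the package flows from a single integer seed through
#' named substreams, so that individual components (block order, deviant
#' positions, timing jitter, noise) are independently reproducible.
#'
#' @param seed Master integer seed.
#' @param name Character stream name.
#' @return An integer in `[0, 2^31 - 2]`.
#' @keywords internal
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  m <- 2147483647  # 2^31 - 1, Mersenne prime used by Lehmer generators
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% m
  as.integer((abs(seed) %% m * 48271 + h) %% m)
}

#' Evaluate code with a locally seeded RNG
#'
#' Restores the caller's RNG state on exit so that library code never
#' perturbs the global random stream.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Draw from a truncated normal distribution by inverse-CDF sampling
#'
#' @param n Number of draws.
#' @param mean,sd Location and scale of the parent normal.
#' @param lower,upper Truncation bounds; must satisfy `lower < upper`.
#' @return Numeric vector of draws, all inside `[lower, upper]`.
#' @keywords internal
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (!(lower < upper)) {
    stop("invalid truncation bounds: lower (", lower,
         ") must be strictly below upper (", upper, ")")
  }
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  pmin(pmax(stats::qnorm(u, mean, sd), lower), upper)
}

# Cohen's d with pooled standard deviation (n - 1 weights).
pooled_cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  if (!is.finite(sp2) || sp2 <= 0) {
    stop("degenerate input: combined variance is zero, Cohen's d undefined")
  }
  (mean(x) - mean(y)) / sqrt(sp2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
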