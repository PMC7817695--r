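#' Round half away from zero
#'
#' Rounding used throughout for bin assignment and ROI/VOI dimensioning:
#' halves round up (towards +Inf for the positive quantities handled here),
#' unlike base [round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
round_half_up <- function(x) floor(x + 0.5)

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state so that
#' generator calls never perturb an enclosing simulation stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive an independent sub-stream seed
#'
#' A single user-facing seed drives every generator through a splittable
#' counter: `split_seed(seed, k)` gives the seed of sub-stream `k`, so adding
#' one generator call never shifts another call's stream.
#'
#' @param seed integer master seed.
#' @param k non-negative integer sub-stream index.
#' @return an integer seed below 2^31.
#' @export
split_seed <- function(seed, k = 0L) {
  # multiplier kept small enough that the product is exact in double precision
  as.integer((as.double(abs(seed)) * 65539 + as.double(k) * 2654435 + 11) %%
               2147483647)
}

# separable 3-tap convolution along rows/cols of a matrix, replicated edges
conv3_matrix <- function(x, w) {
  stopifnot(length(w) == 3)
  n <- nrow(x); m <- ncol(x)
  up <- x[c(1, seq_len(n - 1)), , drop = FALSE]
  dn <- x[c(seq_len(n - 1) + 1, n), , drop = FALSE]
  y <- w[1] * up + w[2] * x + w[3] * dn
  lf <- y[, c(1, seq_len(m - 1)), drop = FALSE]
  rt <- y[, c(seq_len(m - 1) + 1, m), drop = FALSE]
  w[1] * lf + w[2] * y + w[3] * rt
}

# smooth gaussian-ish random field, sd-normalised then scaled to `amplitude`
smooth_noise_field <- function(shape, amplitude, n_pass = 4) {
  z <- matrix(rnorm(prod(shape)), shape[1], shape[2])
  w <- c(0.25, 0.5, 0.25)
  for (i in seq_len(n_pass)) z <- conv3_matrix(z, w)
  s <- sd(z)
  if (s == 0) return(matrix(0, shape[1], shape[2]))
  z / s * amplitude
}
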