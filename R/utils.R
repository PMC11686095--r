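# Small numerical helpers shared across the package.

#' Rectified linear activation
#' @param x numeric vector or matrix.
#' @return elementwise max(x, 0).
#' @keywords internal
relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' Column-wise softmax
#'
#' Normalises each column of a matrix (or a single vector) to a probability
#' simplex, with the usual max-subtraction for numerical stability.
#'
#' @param x numeric vector or matrix (classes in rows, samples in columns).
#' @return object of the same shape with non-negative columns summing to 1.
#' @export
softmax <- function(x) {
  if (is.null(dim(x))) {
    e <- exp(x - max(x))
    return(e / sum(e))
  }
  e <- exp(sweep(x, 2, apply(x, 2, max), "-"))
  sweep(e, 2, colSums(e), "/")
}

#' Cosine similarity between two vectors
#' @param a,b numeric vectors of equal length.
#' @return scalar in [-1, 1]; NA if either vector is all-zero.
#' @export
cosine_similarity <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}

# Run an expression under a local RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so package functions never perturb it.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a child seed from a master seed and a stream index, kept within
# 32-bit integer range.
child_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + 7919 * as.double(index)) %% 2147483587L) + 1L
}

#' Savitzky-Golay smoothing of an error trace
#'
#' Convenience wrapper used to smooth per-trial error curves of the cognitive
#' tasks (window length 25, polynomial order 3 by default). Traces shorter
#' than the window are returned unchanged.
#'
#' @param x numeric vector.
#' @param window odd filter length (default 25).
#' @param order polynomial order (default 3).
#' @return smoothed numeric vector of the same length.
#' @export
smooth_error_trace <- function(x, window = 25, order = 3) {
  if (length(x) < window) return(x)
  as.numeric(signal::sgolayfilt(x, p = order, n = window))
}
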