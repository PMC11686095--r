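# Small fixtures built in code: tiny parameter sets with controllable weights
# and a minimal hand-rolled batch constructor.

toy_params <- function(n_rnn = 3, n_input = 2, n_out = 2, n_granule = 4,
                       alpha = 0.5, variant = "cerebellar_feedback",
                       tau_windows = 1L, feedback_softmax = FALSE,
                       seed = 42, zero_weights = FALSE, ...) {
  p <- init_params(n_rnn = n_rnn, n_input = n_input, n_out = n_out,
                   n_granule = n_granule, alpha = alpha, variant = variant,
                   tau_windows = tau_windows,
                   feedback_softmax = feedback_softmax, seed = seed, ...)
  if (zero_weights) {
    for (nm in c("W_ih", "W_hh", "W_rdt", "W_MF", "W_PF", "W_Ch", "W_zh"))
      if (!is.null(p[[nm]])) p[[nm]][] <- 0
    p$b_rdt[] <- 0
  }
  p
}

# A hand-built batch: x and y given as [dim, batch, T] arrays.
toy_batch <- function(x, y, mask = NULL, loss_kind = "mse", labels = NULL) {
  if (is.null(mask)) mask <- rep(TRUE, dim(x)[3])
  meta <- list()
  if (!is.null(labels)) meta$label <- labels
  structure(list(x = x, y = y, loss_mask = mask, meta = meta,
                 T = dim(x)[3], n_input = dim(x)[1], n_out = dim(y)[1],
                 task = "toy", loss_kind = loss_kind),
            class = "ccl_batch")
}

# Central finite-difference gradient of a scalar function of a matrix.
fd_gradient <- function(fn, M, h = 1e-6) {
  G <- M * 0
  for (i in seq_along(M)) {
    Mp <- M; Mp[i] <- Mp[i] + h
    Mm <- M; Mm[i] <- Mm[i] - h
    G[i] <- (fn(Mp) - fn(Mm)) / (2 * h)
  }
  G
}
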