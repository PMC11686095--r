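# Forward dynamics of the cortico-cerebellar loop.
#
# States are stored as matrices with units in rows and batch examples in
# columns; trajectories as 3-d arrays [units, batch, timestep]. Timesteps are
# 1-based in all user-facing interfaces.

#' Cerebellar feedforward pass
#'
#' Computes the cerebellar prediction from the previous cortical state:
#' `c = W_PF %*% relu(W_MF %*% tanh(h))`. A context mask restricts the
#' parallel-fibre columns that contribute (masked columns contribute zero);
#' the granule activity is returned alongside for use by the parallel-fibre
#' plasticity rule.
#'
#' @param h_prev cortical state, `n_rnn` vector or `n_rnn x batch` matrix.
#' @param params a [init_params()] object.
#' @param context_mask optional logical vector over granule cells selecting
#'   the active parallel-fibre columns.
#' @return list with `c` (`n_feedback x batch`) and `g` (`n_granule x batch`).
#' @export
cerebellar_forward <- function(h_prev, params, context_mask = NULL) {
  h_prev <- as.matrix(h_prev)
  if (nrow(h_prev) != params$n_rnn)
    stop("`h_prev` must have n_rnn rows")
  g <- relu(params$W_MF %*% tanh(h_prev))
  if (is.null(context_mask)) {
    cfb <- params$W_PF %*% g
  } else {
    if (length(context_mask) != params$n_granule)
      stop("`context_mask` must have one entry per granule cell")
    if (!any(context_mask)) {
      cfb <- matrix(0, params$n_feedback, ncol(g))
    } else {
      cfb <- params$W_PF[, context_mask, drop = FALSE] %*%
        g[context_mask, , drop = FALSE]
    }
  }
  list(c = cfb, g = g)
}

#' Thalamic relay pass
#'
#' Projects the concatenated cortical activity and cerebellar output through
#' a small fixed random feedforward network:
#' `theta = gain * W_th %*% relu(W_in %*% c(tanh(h), c))`. The result replaces
#' the cerebellar feedback in the cortical update.
#'
#' @param h cortical state matrix (`n_rnn x batch`).
#' @param c_t cerebellar output (`n_feedback x batch`).
#' @param thalamus the `thalamus` element of a [init_params()] object.
#' @return `n_feedback x batch` thalamic feedback.
#' @export
thalamic_forward <- function(h, c_t, thalamus) {
  if (is.null(thalamus)) stop("no thalamic relay configured")
  z_in <- rbind(tanh(as.matrix(h)), as.matrix(c_t))
  thalamus$gain * (thalamus$W_th %*% relu(thalamus$W_in %*% z_in))
}

# Apply the per-window softmax used when feedback is bounded to [0, 1]
# for the cognitive tasks. Each n_out slice of the feedback is normalised
# independently.
feedback_transform <- function(fb, params) {
  if (!params$feedback_softmax) return(fb)
  n_out <- params$n_out
  for (i in seq_along(params$tau_windows)) {
    rows <- ((i - 1) * n_out + 1):(i * n_out)
    fb[rows, ] <- softmax(fb[rows, , drop = FALSE])
  }
  fb
}

#' Single cortical update step
#'
#' Applies one step of the leaky-rate dynamics
#' `h_t = alpha * h_prev + W_hh tanh(h_prev) + W_ih x_t + <feedback term>`,
#' where the feedback term is `W_Ch c_t` (cerebellar feedback, or the
#' thalamic output in its place), `W_zh z_{t-1}` (readout feedback) or absent.
#' `feedback` must already be on the feedback scale expected by the variant
#' (i.e. post-softmax when that is configured).
#'
#' @param h_prev state matrix `n_rnn x batch`.
#' @param x_t input matrix `n_input x batch`.
#' @param feedback feedback matrix or NULL.
#' @param params a [init_params()] object.
#' @return the next state, `n_rnn x batch`.
#' @export
rnn_step <- function(h_prev, x_t, feedback, params) {
  h_prev <- as.matrix(h_prev); x_t <- as.matrix(x_t)
  h <- params$alpha * h_prev + params$W_hh %*% tanh(h_prev) +
    params$W_ih %*% x_t
  if (params$variant %in% c("no_feedback", "cerebellar_readout")) {
    if (!is.null(feedback))
      stop(sprintf("variant '%s' accepts no feedback", params$variant))
    return(h)
  }
  if (is.null(feedback)) return(h)
  if (params$variant == "cerebellar_feedback")
    h + params$W_Ch %*% as.matrix(feedback)
  else
    h + params$W_zh %*% as.matrix(feedback)
}

#' Linear or softmax readout of the cortical state
#'
#' @param h state matrix `n_rnn x batch`.
#' @param params a [init_params()] object.
#' @param mode `"linear"` returns `W_rdt tanh(h) + b`; `"softmax"`
#'   additionally normalises each column to class probabilities.
#' @return `n_out x batch` matrix.
#' @export
readout <- function(h, params, mode = c("linear", "softmax")) {
  mode <- match.arg(mode)
  z <- params$W_rdt %*% tanh(as.matrix(h)) + params$b_rdt
  if (mode == "softmax") z <- softmax(z)
  z
}

#' Run a full trial rollout
#'
#' Simulates the variant's dynamics over all timesteps of a batch, starting
#' from `h_0 = 0`, optionally applying an [ablation_schedule()]. For the
#' `cerebellar_readout` variant the model output is the cerebellar prediction
#' computed from the current state (first window slice) instead of the linear
#' readout.
#'
#' @param params a [init_params()] object.
#' @param batch a task batch (see [make_line_batch()] and friends).
#' @param ablation optional [ablation_schedule()].
#' @param context_mask optional logical parallel-fibre mask (task switching).
#' @param seed integer seed; used only to draw the silenced subset for
#'   partial cortical ablation.
#' @param record_granule keep the granule activity in the trajectory (needed
#'   for learning; switch off to save memory in long analysis runs).
#' @return an object of class `ccl_traj` with arrays `h`, `fh`, `z`, and for
#'   cerebellar variants `c` (raw output), `fed` (feedback as injected,
#'   post-softmax/thalamus) and `g`.
#' @export
run_trial <- function(params, batch, ablation = NULL, context_mask = NULL,
                      seed = NULL, record_granule = TRUE) {
  stopifnot(inherits(batch, "ccl_batch"))
  if (dim(batch$x)[1] != params$n_input)
    stop("batch input dimension does not match params")
  T <- batch$T
  nb <- dim(batch$x)[2]
  has_cereb <- params$variant %in% c("cerebellar_feedback", "cerebellar_readout")

  abl_active <- rep(FALSE, T)
  cortex_idx <- NULL
  if (!is.null(ablation)) {
    abl_active <- ablation_active(ablation, T)
    if (ablation$target == "cortex_partial") {
      n_sil <- max(1L, round(ablation$fraction * params$n_rnn))
      cortex_idx <- with_seed(seed, sample.int(params$n_rnn, n_sil))
    }
    if (ablation$target == "thalamus" && is.null(params$thalamus))
      stop("thalamic ablation requires a configured thalamic relay")
  }

  h <- array(0, c(params$n_rnn, nb, T))
  fh <- array(0, c(params$n_rnn, nb, T))
  z <- array(0, c(params$n_out, nb, T))
  cc <- if (has_cereb) array(0, c(params$n_feedback, nb, T)) else NULL
  fed <- if (params$variant %in% c("cerebellar_feedback", "readout_feedback"))
    array(0, c(if (params$variant == "cerebellar_feedback") params$n_feedback
               else params$n_out, nb, T)) else NULL
  g <- if (has_cereb && record_granule) array(0, c(params$n_granule, nb, T)) else NULL

  h_prev <- matrix(0, params$n_rnn, nb)
  z_prev <- matrix(0, params$n_out, nb)
  for (t in seq_len(T)) {
    fb <- NULL
    if (params$variant == "cerebellar_feedback") {
      cb <- cerebellar_forward(h_prev, params, context_mask)
      c_t <- cb$c
      if (!is.null(ablation) && ablation$target == "cerebellum" && abl_active[t])
        c_t[] <- 0
      cc[, , t] <- c_t
      if (!is.null(g)) g[, , t] <- cb$g
      fb <- feedback_transform(c_t, params)
      if (!is.null(params$thalamus)) {
        fb <- thalamic_forward(h_prev, fb, params$thalamus)
        if (!is.null(ablation) && ablation$target == "thalamus" && abl_active[t])
          fb[] <- 0
      }
      fed[, , t] <- fb
    } else if (params$variant == "readout_feedback") {
      fb <- if (params$feedback_softmax) softmax(z_prev) else z_prev
      fed[, , t] <- fb
    }
    x_t <- matrix(batch$x[, , t], params$n_input, nb)
    h_t <- rnn_step(h_prev, x_t, fb, params)
    if (!is.null(cortex_idx) && abl_active[t]) h_t[cortex_idx, ] <- 0
    h[, , t] <- h_t
    fh_t <- tanh(h_t)
    fh[, , t] <- fh_t
    if (params$variant == "cerebellar_readout") {
      cb <- cerebellar_forward(h_t, params, context_mask)
      cc[, , t] <- cb$c
      if (!is.null(g)) g[, , t] <- cb$g
      z[, , t] <- cb$c[seq_len(params$n_out), , drop = FALSE]
    } else {
      z[, , t] <- params$W_rdt %*% fh_t + params$b_rdt
    }
    h_prev <- h_t
    z_prev <- z[, , t]
    if (!is.matrix(z_prev)) z_prev <- matrix(z_prev, params$n_out, nb)
  }

  structure(list(h = h, fh = fh, z = z, c = cc, fed = fed, g = g,
                 x = batch$x, batch = batch, variant = params$variant),
            class = "ccl_traj")
}

#' @export
print.ccl_traj <- function(x, ...) {
  d <- dim(x$h)
  cat(sprintf("<ccl_traj> %s: %d units x %d examples x %d timesteps%s\n",
              x$variant, d[1], d[2], d[3],
              if (!is.null(x$c)) sprintf(", cerebellar dim %d", dim(x$c)[1]) else ""))
  invisible(x)
}
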