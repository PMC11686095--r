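#' Leak factor from continuous-time constants
#'
#' The discrete leak of the rate network is obtained from the membrane time
#' constant and the simulation timestep as \eqn{\alpha = \exp(-\Delta t / \tau_M)}.
#' The leak is exposed directly as the primary configured parameter of
#' [init_params()]; this helper documents the correspondence with the
#' underlying continuous dynamics (the membrane-resistance factor is dropped,
#' which only rescales the weights).
#'
#' @param tau_M membrane time constant in ms (> 0).
#' @param dt simulation timestep in ms (>= 0).
#' @return the dimensionless leak factor `exp(-dt / tau_M)` in (0, 1].
#' @examples
#' compute_alpha(20, 50)   # ~0.082
#' compute_alpha(90, 200)  # ~0.108
#' @export
compute_alpha <- function(tau_M, dt) {
  if (!is.numeric(tau_M) || length(tau_M) != 1 || !is.finite(tau_M) || tau_M <= 0)
    stop("`tau_M` must be a positive scalar (ms)")
  if (!is.numeric(dt) || length(dt) != 1 || !is.finite(dt) || dt < 0)
    stop("`dt` must be a non-negative scalar (ms)")
  exp(-dt / tau_M)
}

# Uniform fan-in bound used for the feedforward layers (readout, mossy and
# parallel fibres). This is the "kaiming" uniform bound with slope s = sqrt(5):
#   sqrt(6 / ((1 + s^2) * fan_in)) = sqrt(6 / (6 * fan_in)) = 1 / sqrt(fan_in).
kaiming_bound <- function(fan_in) 1 / sqrt(fan_in)

runif_mat <- function(nrow, ncol, bound) {
  matrix(stats::runif(nrow * ncol, -bound, bound), nrow, ncol)
}

model_variants <- c("no_feedback", "readout_feedback",
                    "cerebellar_feedback", "cerebellar_readout")

#' Initialise cortico-cerebellar loop parameters
#'
#' Builds the full parameter set of a model variant: a leaky cortical RNN
#' (`n_rnn` tanh units, leak `alpha`), a feedforward cerebellar module with a
#' divergent granule layer (`n_granule` ReLU units; 1:20 expansion at the
#' defaults) and plastic parallel fibres, plus the readout. The cerebellar
#' output dimension is `n_out * length(tau_windows)`: with a single predictive
#' window it mirrors the task outcome, with a temporal basis it concatenates
#' one prediction per window.
#'
#' Recurrent, input and feedback weights are drawn from
#' U(-1/sqrt(n_rnn), 1/sqrt(n_rnn)); readout, mossy-fibre and parallel-fibre
#' weights use the uniform fan-in bound 1/sqrt(fan_in); readout biases are
#' U(-1/sqrt(n_rnn), 1/sqrt(n_rnn)). Only the cortical readout carries a bias,
#' so the zero state is an exact fixed point of the undriven loop.
#'
#' @param n_rnn number of cortical units (default 50).
#' @param n_input input dimensionality.
#' @param n_out readout dimensionality (2 for drawing and delayed association,
#'   3 for evidence accumulation).
#' @param n_granule number of cerebellar granule cells (default 1000).
#' @param alpha leak factor in [0, 1) (default 0.1).
#' @param variant one of `"no_feedback"`, `"readout_feedback"`,
#'   `"cerebellar_feedback"`, `"cerebellar_readout"`.
#' @param tau_windows integer vector of cerebellar predictive windows in
#'   timesteps (default 3; `0:5` gives the 0-250 ms temporal basis at a 50 ms
#'   timestep).
#' @param feedback_softmax apply a softmax to each feedback slice before it is
#'   injected into the RNN (used for the cognitive/classification tasks).
#' @param n_thal if non-NULL, adds a feedforward thalamic relay of this many
#'   hidden units between the cerebellum and cortex.
#' @param thal_gain scaling of the thalamic output (1 = intact, 0.25 =
#'   weakened).
#' @param tau_M,dt continuous-time constants recorded as metadata (ms); the
#'   configured `alpha` is authoritative (see [compute_alpha()]).
#' @param seed integer seed fixing the initialisation.
#' @return an object of class `ccl_params`.
#' @examples
#' p <- init_params(n_input = 10, n_out = 2, seed = 1)
#' p
#' @export
init_params <- function(n_rnn = 50, n_input, n_out, n_granule = 1000,
                        alpha = 0.1, variant = "cerebellar_feedback",
                        tau_windows = 3L, feedback_softmax = FALSE,
                        n_thal = NULL, thal_gain = 1.0,
                        tau_M = 20, dt = 50, seed = NULL) {
  variant <- match.arg(variant, model_variants)
  if (alpha < 0 || alpha >= 1) stop("`alpha` must lie in [0, 1)")
  tau_windows <- as.integer(tau_windows)
  if (any(tau_windows < 0)) stop("all cerebellar windows must be >= 0")
  if (anyDuplicated(tau_windows)) stop("cerebellar windows must be distinct")
  n_feedback <- n_out * length(tau_windows)

  p <- with_seed(seed, {
    a <- 1 / sqrt(n_rnn)
    out <- list(
      n_rnn = n_rnn, n_input = n_input, n_out = n_out,
      n_granule = n_granule, n_feedback = n_feedback,
      alpha = alpha, variant = variant,
      tau_windows = tau_windows, feedback_softmax = feedback_softmax,
      tau_M = tau_M, dt = dt, R_m = 1,
      W_ih = runif_mat(n_rnn, n_input, a),
      W_hh = runif_mat(n_rnn, n_rnn, a),
      W_rdt = runif_mat(n_out, n_rnn, kaiming_bound(n_rnn)),
      b_rdt = stats::runif(n_out, -a, a),
      W_MF = runif_mat(n_granule, n_rnn, kaiming_bound(n_rnn)),
      W_PF = runif_mat(n_feedback, n_granule, kaiming_bound(n_granule)),
      W_Ch = NULL, W_zh = NULL, thalamus = NULL
    )
    if (variant == "cerebellar_feedback")
      out$W_Ch <- runif_mat(n_rnn, n_feedback, a)
    if (variant == "readout_feedback")
      out$W_zh <- runif_mat(n_rnn, n_out, a)
    if (!is.null(n_thal)) {
      if (variant != "cerebellar_feedback")
        stop("a thalamic relay requires the cerebellar_feedback variant")
      out$thalamus <- list(
        n_thal = n_thal,
        W_in = runif_mat(n_thal, n_rnn + n_feedback,
                         kaiming_bound(n_rnn + n_feedback)),
        W_th = runif_mat(n_feedback, n_thal, kaiming_bound(n_thal)),
        gain = thal_gain
      )
    }
    out
  })
  class(p) <- "ccl_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  stopifnot(
    inherits(p, "ccl_params"),
    p$alpha >= 0, p$alpha < 1,
    all(dim(p$W_hh) == c(p$n_rnn, p$n_rnn)),
    all(dim(p$W_ih) == c(p$n_rnn, p$n_input)),
    all(dim(p$W_rdt) == c(p$n_out, p$n_rnn)),
    length(p$b_rdt) == p$n_out,
    all(dim(p$W_MF) == c(p$n_granule, p$n_rnn)),
    all(dim(p$W_PF) == c(p$n_feedback, p$n_granule)),
    p$n_feedback == p$n_out * length(p$tau_windows)
  )
  if (!is.null(p$W_Ch))
    stopifnot(all(dim(p$W_Ch) == c(p$n_rnn, p$n_feedback)))
  if (!is.null(p$W_zh))
    stopifnot(all(dim(p$W_zh) == c(p$n_rnn, p$n_out)))
  if (!is.null(p$thalamus)) {
    th <- p$thalamus
    stopifnot(all(dim(th$W_in) == c(th$n_thal, p$n_rnn + p$n_feedback)),
              all(dim(th$W_th) == c(p$n_feedback, th$n_thal)))
  }
  invisible(p)
}

#' @export
print.ccl_params <- function(x, ...) {
  cat(sprintf("<ccl_params> variant=%s\n", x$variant))
  cat(sprintf("  cortex: %d units, alpha=%.3g | cerebellum: %d granule cells -> %d outputs\n",
              x$n_rnn, x$alpha, x$n_granule, x$n_feedback))
  cat(sprintf("  input dim %d, readout dim %d, windows tau={%s}%s%s\n",
              x$n_input, x$n_out, paste(x$tau_windows, collapse = ","),
              if (x$feedback_softmax) ", softmax feedback" else "",
              if (!is.null(x$thalamus))
                sprintf(", thalamic relay (%d units, gain %.2g)",
                        x$thalamus$n_thal, x$thalamus$gain) else ""))
  invisible(x)
}

#' Ablation schedule
#'
#' Describes transient silencing applied during a trial rollout: the
#' cerebellar output (`c_t = 0` within the window), a random fraction of
#' cortical units (zeroed after the state update), or the thalamic relay.
#' Windows are 1-based inclusive timestep intervals, matching how trial
#' timesteps are indexed in logs and presets.
#'
#' @param target `"cerebellum"`, `"cortex_partial"` or `"thalamus"`.
#' @param windows a list of length-2 integer vectors `c(start, end)` (a single
#'   vector is accepted).
#' @param fraction proportion of units silenced (`cortex_partial` only;
#'   1 = all).
#' @return an object of class `ccl_ablation`.
#' @export
ablation_schedule <- function(target = c("cerebellum", "cortex_partial", "thalamus"),
                              windows, fraction = 1.0) {
  target <- match.arg(target)
  if (!is.list(windows)) windows <- list(windows)
  for (w in windows) {
    if (length(w) != 2 || w[1] < 1 || w[2] < w[1])
      stop("each ablation window must be c(start, end) with 1 <= start <= end")
  }
  if (fraction <= 0 || fraction > 1) stop("`fraction` must lie in (0, 1]")
  structure(list(target = target, windows = windows, fraction = fraction),
            class = "ccl_ablation")
}

# TRUE for the (1-based) timesteps covered by the schedule's windows.
ablation_active <- function(ablation, T) {
  act <- rep(FALSE, T)
  for (w in ablation$windows) {
    if (w[2] > T) stop("ablation window exceeds trial length")
    act[w[1]:w[2]] <- TRUE
  }
  act
}
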