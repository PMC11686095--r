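# Cerebellar-to-cortical systems consolidation: the cerebellar drive is
# gradually written into the recurrent cortical weights while the feedback
# weights decay to zero. Targets are never used - the rules are unsupervised.

#' Consolidation configuration
#'
#' @param rule `"optimal"` (least-squares fit of the cerebellar drive by a
#'   recurrent-weight change) or `"biological"` (ratio of cerebellar input to
#'   total population activity).
#' @param eta_rnn recurrent-weight consolidation rate (0.1 for the optimal
#'   rule; 0.3 for the biological rule, which is stabler when three times the
#'   decay rate).
#' @param eta_Ch decay rate of the cerebellar-to-cortical weights (0.1).
#' @param n_trials number of consolidation trials (batch size 10 each).
#' @param ridge ridge term added when solving the least-squares problem on
#'   rank-deficient state matrices (0 = minimum-norm pseudo-inverse).
#' @param denom_guard biological rule only: timesteps where the absolute
#'   population activity falls below this threshold are skipped.
#' @param batch_size examples per consolidation trial.
#' @param n_test test examples evaluated after each trial.
#' @return an object of class `ccl_consolidation_config`.
#' @export
consolidation_config <- function(rule = c("optimal", "biological"),
                                 eta_rnn = NULL, eta_Ch = 0.1,
                                 n_trials = 50, ridge = 0,
                                 denom_guard = 1e-8, batch_size = 10,
                                 n_test = 1000) {
  rule <- match.arg(rule)
  if (is.null(eta_rnn)) eta_rnn <- if (rule == "optimal") 0.1 else 0.3
  stopifnot(eta_rnn >= 0, eta_Ch >= 0, eta_Ch <= 1)
  structure(list(rule = rule, eta_rnn = eta_rnn, eta_Ch = eta_Ch,
                 n_trials = n_trials, ridge = ridge,
                 denom_guard = denom_guard, batch_size = batch_size,
                 n_test = n_test),
            class = "ccl_consolidation_config")
}

#' Decay of the cerebellar-to-cortical weights
#'
#' `W_Ch <- (1 - eta_Ch) * W_Ch`; applied once per consolidation trial so the
#' feedback strength decays geometrically to zero.
#'
#' @param W_Ch cerebellar-to-cortical weight matrix.
#' @param eta_Ch decay rate in [0, 1].
#' @return the decayed matrix.
#' @export
feedback_decay <- function(W_Ch, eta_Ch) {
  stopifnot(eta_Ch >= 0, eta_Ch <= 1)
  (1 - eta_Ch) * W_Ch
}

# Concatenate the cortical activity f(h) and the injected cerebellar drive
# W_Ch %*% fed (post-softmax when configured - consolidation mimics the drive
# the RNN actually received) over all timesteps and batch examples.
consolidation_design <- function(traj, params) {
  n <- params$n_rnn; nb <- dim(traj$h)[2]; T <- dim(traj$h)[3]
  X <- matrix(traj$fh, n, nb * T)
  fed <- matrix(traj$fed, params$n_feedback, nb * T)
  list(X = X, drive = params$W_Ch %*% fed)
}

#' Optimal (least-squares) consolidation step
#'
#' Finds the recurrent-weight change whose action on the visited cortical
#' activity best reproduces the cerebellar drive: `F` minimising
#' `||F f(H) - W_Ch C||` over all timesteps and examples of the trajectory
#' (minimum-norm pseudo-inverse on rank deficiency, optionally ridge
#' regularised), scaled by the consolidation rate.
#'
#' @param traj a [run_trial()] trajectory from a cerebellar-feedback model.
#' @param params the [init_params()] object that produced it.
#' @param cfg a [consolidation_config()].
#' @return the `n_rnn x n_rnn` recurrent-weight change.
#' @export
consolidation_step_optimal <- function(traj, params, cfg) {
  if (is.null(traj$c)) stop("trajectory has no cerebellar output")
  if (dim(traj$h)[3] == 0) stop("empty trajectory")
  d <- consolidation_design(traj, params)
  X <- d$X; M <- d$drive
  if (cfg$ridge > 0) {
    XtX <- tcrossprod(X) + cfg$ridge * diag(nrow(X))
    F_lsq <- M %*% crossprod(X, solve(XtX))
  } else {
    F_lsq <- M %*% MASS::ginv(X)
  }
  cfg$eta_rnn * F_lsq
}

#' Biological (ratio) consolidation step
#'
#' Per-synapse rule: the change of every recurrent weight onto neuron `j` is
#' the cerebellar input to `j` divided by the total population activity,
#' `dw_ij = eta * (W_Ch[j, ] %*% c_t) / sum_k f(h_kt)`, accumulated over the
#' whole sequence (and averaged over the batch). By construction the induced
#' change in recurrent input, `dW_hh %*% f(h_t)`, equals the cerebellar input
#' `W_Ch %*% c_t` exactly at each accumulated timestep (up to the rate
#' factor). Timesteps with near-zero population activity are skipped with a
#' warning.
#'
#' @inheritParams consolidation_step_optimal
#' @return the `n_rnn x n_rnn` recurrent-weight change.
#' @export
consolidation_step_bio <- function(traj, params, cfg) {
  if (is.null(traj$c)) stop("trajectory has no cerebellar output")
  n <- params$n_rnn; nb <- dim(traj$h)[2]; T <- dim(traj$h)[3]
  delta <- matrix(0, n, n)
  skipped <- 0L
  for (t in seq_len(T)) {
    fed_t <- matrix(if (is.null(traj$fed)) traj$c[, , t] else traj$fed[, , t],
                    ncol = nb)
    drive <- params$W_Ch %*% fed_t            # n x nb cerebellar input
    denom <- colSums(matrix(traj$fh[, , t], n, nb))
    ok <- abs(denom) >= cfg$denom_guard
    if (!all(ok)) skipped <- skipped + sum(!ok)
    if (!any(ok)) next
    # dw_ij is independent of the presynaptic index i: each row j of the
    # update is the scalar drive_j / denom replicated across columns.
    scal <- drive[, ok, drop = FALSE] /
      matrix(denom[ok], n, sum(ok), byrow = TRUE)
    delta <- delta + rowMeans(scal) %o% rep(1, n)
  }
  if (skipped > 0)
    warning(sprintf("skipped %d timestep(s) with near-zero population activity",
                    skipped))
  cfg$eta_rnn * delta
}

#' Run a consolidation phase
#'
#' Presents further task trials *without using their targets*: per trial the
#' model is rolled forward, the recurrent weights are updated by the selected
#' rule (no optimizer), and the cerebellar-to-cortical weights decay. After
#' each trial the model is evaluated on a fresh test set with and without
#' full cerebellar ablation, and similarity diagnostics to the
#' pre-consolidation network are recorded: the cosine similarity of the
#' concatenated RNN + granule activity to its pre-consolidation value (with a
#' shuffled-activity baseline averaged over `n_shuffle` permutations), and the
#' cosine similarity between the current recurrent input `W_hh f(h)` and the
#' pre-consolidation total input `W_hh^pre f(h) + W_Ch^pre c`.
#'
#' @param params a trained cerebellar-feedback [init_params()] object.
#' @param task a [ccl_task()].
#' @param cfg a [consolidation_config()].
#' @param seed integer seed.
#' @param n_shuffle permutations for the shuffled-similarity baseline.
#' @return list with final `params`, per-trial data frame `trace` (columns
#'   `trial`, `error`, `error_ablated`, `w_ch_norm`, `w_hh_norm`,
#'   `act_similarity`, `act_similarity_shuffled`, `input_similarity`) and the
#'   pre-consolidation weights.
#' @export
run_consolidation <- function(params, task, cfg, seed = NULL, n_shuffle = 100) {
  stopifnot(params$variant == "cerebellar_feedback",
            inherits(cfg, "ccl_consolidation_config"))
  W_hh_pre <- params$W_hh
  W_Ch_pre <- params$W_Ch

  probe_batch <- task$generate(min(cfg$n_test, 200), child_seed(seed, 0L))
  ref_traj <- run_trial(params, probe_batch, record_granule = TRUE)
  ref_act <- c(as.numeric(ref_traj$fh), as.numeric(ref_traj$g))
  shuf_sim <- with_seed(child_seed(seed, 1L), {
    mean(vapply(seq_len(n_shuffle), function(i)
      cosine_similarity(ref_act, sample(ref_act)), numeric(1)))
  })

  full_abl <- ablation_schedule("cerebellum", list(c(1, task$T)))
  trace <- vector("list", cfg$n_trials)
  for (k in seq_len(cfg$n_trials)) {
    batch <- task$generate(cfg$batch_size, child_seed(seed, 100L + k))
    traj <- run_trial(params, batch, record_granule = FALSE)
    delta <- if (cfg$rule == "optimal")
      consolidation_step_optimal(traj, params, cfg)
    else
      consolidation_step_bio(traj, params, cfg)
    params$W_hh <- params$W_hh + delta
    params$W_Ch <- feedback_decay(params$W_Ch, cfg$eta_Ch)
    if (!all(is.finite(params$W_hh)))
      stop(sprintf("consolidation diverged at trial %d", k))

    ev <- evaluate_model(params, task, cfg$n_test,
                         seed = child_seed(seed, 0L))
    ev_abl <- evaluate_model(params, task, cfg$n_test,
                             seed = child_seed(seed, 0L),
                             ablation = full_abl)
    cur_traj <- run_trial(params, probe_batch, record_granule = TRUE)
    act_sim <- cosine_similarity(
      c(as.numeric(cur_traj$fh), as.numeric(cur_traj$g)), ref_act)
    # recurrent input now vs total (recurrent + cerebellar) input before
    nb <- dim(cur_traj$h)[2]; TT <- dim(cur_traj$h)[3]
    fh_flat <- matrix(cur_traj$fh, params$n_rnn, nb * TT)
    fed_flat <- matrix(cur_traj$fed, params$n_feedback, nb * TT)
    input_sim <- cosine_similarity(
      params$W_hh %*% fh_flat,
      W_hh_pre %*% fh_flat + W_Ch_pre %*% fed_flat)

    trace[[k]] <- data.frame(
      trial = k, error = ev$loss, error_ablated = ev_abl$loss,
      accuracy = if (is.null(ev$accuracy)) NA_real_ else ev$accuracy,
      accuracy_ablated = if (is.null(ev_abl$accuracy)) NA_real_ else ev_abl$accuracy,
      w_ch_norm = sqrt(sum(params$W_Ch^2)),
      w_hh_norm = sqrt(sum(params$W_hh^2)),
      act_similarity = act_sim,
      act_similarity_shuffled = shuf_sim,
      input_similarity = input_sim)
  }
  list(params = params, trace = do.call(rbind, trace),
       W_hh_pre = W_hh_pre, W_Ch_pre = W_Ch_pre)
}
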