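# Learning rules: masked task losses, the delayed-target cerebellar delta
# rule, e-prop gradients for the cortical weights, and the Adam optimizer.
#
# Convention: `task_loss()` returns the exact gradient of its scalar loss
# (mean over supervised timesteps, batch and - for MSE - output dimensions),
# and every weight-gradient function below returns the exact gradient of that
# scalar. Learning rates are applied by the optimizer, and gradients are
# accumulated over all timesteps of a trial before one optimizer step.

#' Learning configuration
#'
#' @param eta learning rate for the readout and parallel fibres
#'   (default 0.001).
#' @param eta_rnn learning rate for the cortical input/feedback/recurrent
#'   weights when plastic (defaults to `eta`; 0.0025 is used for the delayed
#'   association task).
#' @param regime plasticity regime: `"fixed_rnn"` (readout only),
#'   `"input_plastic"` (adds input and feedback weights) or `"fully_plastic"`
#'   (adds the recurrent weights). The parallel fibres always learn; the mossy
#'   fibres never do.
#' @param batch_size examples per trial (default 10).
#' @param n_train training examples per session (default 1000, i.e. 100
#'   trials).
#' @param n_test test examples used to evaluate a session (default 1000).
#' @return an object of class `ccl_learning_config`.
#' @export
learning_config <- function(eta = 0.001, eta_rnn = NULL,
                            regime = c("fixed_rnn", "input_plastic",
                                       "fully_plastic"),
                            batch_size = 10, n_train = 1000, n_test = 1000) {
  regime <- match.arg(regime)
  structure(list(eta = eta, eta_rnn = if (is.null(eta_rnn)) eta else eta_rnn,
                 regime = regime, batch_size = batch_size,
                 n_train = n_train, n_test = n_test),
            class = "ccl_learning_config")
}

#' Masked task loss and output gradient
#'
#' Mean squared error for regression tasks, softmax cross-entropy for
#' classification, computed over the supervised timesteps only. MSE is the
#' mean of squared residuals over masked timesteps, batch and output
#' dimensions; cross-entropy is the mean over masked timesteps and batch of
#' `-sum(y * log softmax(z))`, with `z` treated as logits.
#'
#' @param z model outputs, `n_out x batch x T` array.
#' @param y targets of the same shape (one-hot class labels for
#'   cross-entropy).
#' @param mask logical vector of length `T` marking supervised timesteps.
#' @param loss_kind `"mse"` or `"cross_entropy"`.
#' @return list with `loss` (scalar) and `dz` (gradient of `loss` w.r.t. `z`,
#'   zero outside the mask).
#' @export
task_loss <- function(z, y, mask, loss_kind = c("mse", "cross_entropy")) {
  loss_kind <- match.arg(loss_kind)
  stopifnot(identical(dim(z), dim(y)), length(mask) == dim(z)[3])
  steps <- which(mask)
  if (length(steps) == 0) stop("loss mask selects no timesteps")
  n_out <- dim(z)[1]; nb <- dim(z)[2]
  dz <- array(0, dim(z))
  if (loss_kind == "mse") {
    denom <- length(steps) * nb * n_out
    resid <- z[, , steps, drop = FALSE] - y[, , steps, drop = FALSE]
    loss <- sum(resid^2) / denom
    dz[, , steps] <- 2 * resid / denom
  } else {
    ysub <- y[, , steps, drop = FALSE]
    colsums <- apply(ysub, c(2, 3), sum)
    if (any(ysub < 0) || any(abs(colsums - 1) > 1e-8))
      stop("cross-entropy targets must be one-hot / probability columns")
    denom <- length(steps) * nb
    loss <- 0
    for (t in steps) {
      p <- softmax(matrix(z[, , t], n_out, nb))
      loss <- loss - sum(y[, , t] * log(pmax(p, 1e-12)))
      dz[, , t] <- (p - matrix(y[, , t], n_out, nb)) / denom
    }
    loss <- loss / denom
  }
  list(loss = loss, dz = dz)
}

#' Readout delta rule
#'
#' Accumulates the exact gradient of the task loss for the readout weights
#' and bias: the outer product of the per-step output gradient with the
#' cortical activity, summed over timesteps (`dE/dz_t %*% t(f(h_t))`).
#'
#' @param dz output-gradient array from [task_loss()].
#' @param fh cortical activity array `tanh(h)`, `n_rnn x batch x T`.
#' @return list with `W_rdt` (`n_out x n_rnn`) and `b_rdt` (`n_out`) gradient
#'   accumulations.
#' @export
delta_readout <- function(dz, fh) {
  n_out <- dim(dz)[1]; nb <- dim(dz)[2]; T <- dim(dz)[3]
  gW <- matrix(0, n_out, dim(fh)[1])
  gb <- numeric(n_out)
  for (t in seq_len(T)) {
    dzt <- matrix(dz[, , t], n_out, nb)
    if (all(dzt == 0)) next
    gW <- gW + tcrossprod(dzt, matrix(fh[, , t], dim(fh)[1], nb))
    gb <- gb + rowSums(dzt)
  }
  list(W_rdt = gW, b_rdt = gb)
}

#' Behavioural timing-specific parallel-fibre rule
#'
#' The cerebellar output learns against *future* targets: for each predictive
#' window `tau_i`, the window's slice of the cerebellar output at `t - tau_i`
#' is paired with the target at `t`, for every supervised timestep `t` with
#' `t - tau_i >= 1`, and the resulting error gradient is paired with the
#' granule activity at `t - tau_i`. The cerebellar loss mirrors the task loss
#' (MSE, or softmax cross-entropy when the feedback is softmax-bounded) and
#' is averaged over windows, valid pairs and batch. Updates are restricted to
#' the parallel-fibre columns active under the context mask.
#'
#' @param traj a [run_trial()] trajectory (with granule activity recorded).
#' @param y target array `n_out x batch x T`.
#' @param mask logical supervised-timestep mask of length `T`.
#' @param tau_windows integer vector of predictive windows (timesteps).
#' @param loss_kind `"mse"` or `"cross_entropy"`.
#' @param context_mask optional logical mask over parallel-fibre columns.
#' @return `n_feedback x n_granule` gradient accumulation for the
#'   parallel-fibre weights.
#' @export
delta_parallel_fibres <- function(traj, y, mask, tau_windows,
                                  loss_kind = c("mse", "cross_entropy"),
                                  context_mask = NULL) {
  loss_kind <- match.arg(loss_kind)
  if (is.null(traj$c) || is.null(traj$g))
    stop("trajectory has no cerebellar record (run with record_granule = TRUE)")
  n_out <- dim(y)[1]; nb <- dim(y)[2]; T <- dim(y)[3]
  n_fb <- dim(traj$c)[1]; n_g <- dim(traj$g)[1]
  grad <- matrix(0, n_fb, n_g)
  steps <- which(mask)
  cols <- if (is.null(context_mask)) rep(TRUE, n_g) else context_mask
  any_pair <- FALSE
  for (i in seq_along(tau_windows)) {
    tau <- tau_windows[i]
    rows <- ((i - 1) * n_out + 1):(i * n_out)
    valid <- steps[steps - tau >= 1]
    if (length(valid) == 0) next
    any_pair <- TRUE
    denom <- length(tau_windows) * length(valid) * nb *
      (if (loss_kind == "mse") n_out else 1)
    for (t in valid) {
      cs <- matrix(traj$c[rows, , t - tau], n_out, nb)
      yt <- matrix(y[, , t], n_out, nb)
      dc <- if (loss_kind == "mse") 2 * (cs - yt) / denom
            else (softmax(cs) - yt) / denom
      gt <- matrix(traj$g[, , t - tau], n_g, nb)
      grad[rows, cols] <- grad[rows, cols] +
        tcrossprod(dc, gt[cols, , drop = FALSE])
    }
  }
  if (!any_pair)
    warning("all cerebellar windows exceed the trial length; zero update")
  grad
}

#' Eligibility trace update
#'
#' The per-synapse eligibility trace of the leaky dynamics reduces to a leaky
#' accumulation of presynaptic activity, `eps_t = alpha * eps_{t-1} + a_t`,
#' shared across postsynaptic targets (the trace depends only on the leak and
#' the presynaptic unit, so it is stored once per presynaptic unit).
#'
#' @param eps_prev previous trace (vector or matrix).
#' @param a presynaptic activity of matching shape.
#' @param alpha leak factor.
#' @return the updated trace.
#' @export
eligibility_update <- function(eps_prev, a, alpha) {
  alpha * eps_prev + a
}

# Which cortical weight matrices a regime allows to learn, given the variant.
regime_targets <- function(regime, variant) {
  fb <- switch(variant, cerebellar_feedback = "W_Ch",
               readout_feedback = "W_zh", NULL)
  switch(regime,
    fixed_rnn = character(0),
    input_plastic = c("W_ih", fb),
    fully_plastic = c("W_ih", fb, "W_hh"),
    stop(sprintf("unknown plasticity regime '%s'", regime))
  )
}

#' e-prop gradients for the cortical weights
#'
#' Approximates backpropagation through time with the product of an
#' instantaneous learning signal and locally-computed eligibility traces:
#' `dw_ji = sum_t L_j^t * eps_ji^t`. The learning signal is one-step
#' backpropagation through space, `L_t = t(W_rdt) %*% dE/dz_t * f'(h_t)` (for
#' the cerebellar-readout variant the signal is instead backpropagated one
#' step through the cerebellar network). Traces use the presynaptic activity
#' feeding each matrix: the input `x_t` for `W_ih`, the injected feedback for
#' `W_Ch`/`W_zh`, and `tanh(h_{t-1})` for `W_hh`.
#'
#' @param traj a [run_trial()] trajectory.
#' @param dz output-gradient array from [task_loss()].
#' @param params a [init_params()] object.
#' @param regime plasticity regime (see [learning_config()]).
#' @return named list of gradient accumulations for the weights the regime
#'   permits (empty for `"fixed_rnn"`).
#' @export
eprop_gradient <- function(traj, dz, params, regime) {
  targets <- regime_targets(regime, params$variant)
  if (length(targets) == 0) return(list())
  n <- params$n_rnn; nb <- dim(traj$h)[2]; T <- dim(traj$h)[3]
  grads <- list()
  eps <- list()
  if ("W_ih" %in% targets) {
    grads$W_ih <- matrix(0, n, params$n_input)
    eps$x <- matrix(0, params$n_input, nb)
  }
  fb_name <- intersect(c("W_Ch", "W_zh"), targets)
  if (length(fb_name) == 1) {
    grads[[fb_name]] <- matrix(0, n, dim(traj$fed)[1])
    eps$fed <- matrix(0, dim(traj$fed)[1], nb)
  }
  if ("W_hh" %in% targets) {
    grads$W_hh <- matrix(0, n, n)
    eps$h <- matrix(0, n, nb)
  }
  cereb_readout <- params$variant == "cerebellar_readout"
  W_PF_out <- if (cereb_readout)
    params$W_PF[seq_len(params$n_out), , drop = FALSE] else NULL

  for (t in seq_len(T)) {
    if (!is.null(eps$x))
      eps$x <- eligibility_update(eps$x, matrix(traj$x[, , t],
                                                params$n_input, nb),
                                  params$alpha)
    if (!is.null(eps$fed))
      eps$fed <- eligibility_update(eps$fed, matrix(traj$fed[, , t],
                                                    dim(traj$fed)[1], nb),
                                    params$alpha)
    if (!is.null(eps$h)) {
      fh_prev <- if (t == 1) matrix(0, n, nb) else matrix(traj$fh[, , t - 1], n, nb)
      eps$h <- eligibility_update(eps$h, fh_prev, params$alpha)
    }
    dzt <- matrix(dz[, , t], params$n_out, nb)
    if (all(dzt == 0)) next
    fh_t <- matrix(traj$fh[, , t], n, nb)
    if (cereb_readout) {
      gt <- matrix(traj$g[, , t], params$n_granule, nb)
      dg <- crossprod(W_PF_out, dzt) * (gt > 0)
      L <- crossprod(params$W_MF, dg) * (1 - fh_t^2)
    } else {
      L <- crossprod(params$W_rdt, dzt) * (1 - fh_t^2)
    }
    if (!is.null(grads$W_ih)) grads$W_ih <- grads$W_ih + tcrossprod(L, eps$x)
    if (length(fb_name) == 1)
      grads[[fb_name]] <- grads[[fb_name]] + tcrossprod(L, eps$fed)
    if (!is.null(grads$W_hh)) grads$W_hh <- grads$W_hh + tcrossprod(L, eps$h)
  }
  grads
}

#' Adam optimizer step
#'
#' Standard bias-corrected adaptive-moment update for a single parameter.
#'
#' @param opt optimizer state for this parameter (NULL to initialise).
#' @param param current parameter value (vector or matrix).
#' @param grad gradient accumulation of matching shape.
#' @param eta learning rate.
#' @param beta1,beta2 moment decay rates (defaults 0.9, 0.999).
#' @param eps_hat numerical stabiliser (default 1e-8).
#' @return list with the updated `param` and `opt` state.
#' @export
adam_step <- function(opt, param, grad, eta, beta1 = 0.9, beta2 = 0.999,
                      eps_hat = 1e-8) {
  if (is.null(opt))
    opt <- list(m = param * 0, v = param * 0, t = 0L)
  opt$t <- opt$t + 1L
  opt$m <- beta1 * opt$m + (1 - beta1) * grad
  opt$v <- beta2 * opt$v + (1 - beta2) * grad^2
  m_hat <- opt$m / (1 - beta1^opt$t)
  v_hat <- opt$v / (1 - beta2^opt$t)
  list(param = param - eta * m_hat / (sqrt(v_hat) + eps_hat), opt = opt)
}

# Apply one Adam step to every named gradient in `grads`. `etas` maps
# parameter names to learning rates. Thalamic W_in and mossy fibres never
# appear here (they are fixed by construction).
apply_gradients <- function(params, opt, grads, etas) {
  for (nm in names(grads)) {
    st <- adam_step(opt[[nm]], params[[nm]], grads[[nm]], etas[[nm]])
    params[[nm]] <- st$param
    opt[[nm]] <- st$opt
  }
  list(params = params, opt = opt)
}

# Per-trial losses on a fresh batch; for classification also the end-of-trial
# accuracy (argmax of the readout at the last supervised step).
#' Evaluate a model on freshly generated examples
#'
#' @param params a [init_params()] object.
#' @param task a [ccl_task()].
#' @param n_test number of examples.
#' @param seed integer seed for the test batch.
#' @param ablation optional [ablation_schedule()] applied during evaluation.
#' @param context_mask optional parallel-fibre mask.
#' @return list with `loss`, and for classification tasks `accuracy`.
#' @export
evaluate_model <- function(params, task, n_test = 1000, seed = NULL,
                           ablation = NULL, context_mask = NULL) {
  batch <- task$generate(n_test, seed)
  traj <- run_trial(params, batch, ablation = ablation,
                    context_mask = context_mask, seed = seed,
                    record_granule = FALSE)
  loss <- task_loss(traj$z, batch$y, batch$loss_mask, task$loss_kind)
  out <- list(loss = loss$loss)
  if (task$loss_kind == "cross_entropy") {
    t_end <- max(which(batch$loss_mask))
    pred <- apply(matrix(traj$z[, , t_end], batch$n_out, n_test), 2, which.max)
    out$accuracy <- mean(pred == batch$meta$label)
  }
  out
}

#' Train for one session
#'
#' Runs `n_train / batch_size` trials: forward rollout, masked loss, readout
#' delta rule, parallel-fibre rule, e-prop gradients for the weights the
#' regime permits, and one Adam step per trial. Mossy fibres are never
#' updated. Aborts with a diagnostic if the loss diverges.
#'
#' @param params a [init_params()] object.
#' @param task a [ccl_task()].
#' @param cfg a [learning_config()].
#' @param seed integer seed; per-trial batches use independent child streams.
#' @param opt optimizer state carried across sessions (NULL to start fresh).
#' @param context_mask optional parallel-fibre mask (task switching).
#' @return list with updated `params`, `opt`, the per-trial `trial_errors`,
#'   and the session's `test` evaluation.
#' @export
train_session <- function(params, task, cfg, seed = NULL, opt = NULL,
                          context_mask = NULL) {
  stopifnot(inherits(task, "ccl_task"), inherits(cfg, "ccl_learning_config"))
  n_trials <- ceiling(cfg$n_train / cfg$batch_size)
  errors <- numeric(n_trials)
  has_cereb <- params$variant %in% c("cerebellar_feedback", "cerebellar_readout")
  etas <- list(W_rdt = cfg$eta, b_rdt = cfg$eta, W_PF = cfg$eta,
               W_ih = cfg$eta_rnn, W_Ch = cfg$eta_rnn, W_zh = cfg$eta_rnn,
               W_hh = cfg$eta_rnn)
  for (k in seq_len(n_trials)) {
    batch <- task$generate(cfg$batch_size, child_seed(seed, k))
    traj <- run_trial(params, batch, context_mask = context_mask)
    loss <- task_loss(traj$z, batch$y, batch$loss_mask, task$loss_kind)
    if (!is.finite(loss$loss))
      stop(sprintf("training diverged at trial %d (loss = %g)", k, loss$loss))
    errors[k] <- loss$loss
    grads <- list()
    if (params$variant != "cerebellar_readout") {
      gr <- delta_readout(loss$dz, traj$fh)
      grads$W_rdt <- gr$W_rdt
      grads$b_rdt <- gr$b_rdt
    }
    if (has_cereb) {
      grads$W_PF <- delta_parallel_fibres(
        traj, batch$y, batch$loss_mask, params$tau_windows,
        loss_kind = task$loss_kind, context_mask = context_mask)
    }
    ep <- eprop_gradient(traj, loss$dz, params, cfg$regime)
    grads[names(ep)] <- ep
    st <- apply_gradients(params, opt, grads, etas)
    params <- st$params
    opt <- st$opt
  }
  test <- evaluate_model(params, task, cfg$n_test,
                         seed = child_seed(seed, 0L),
                         context_mask = context_mask)
  list(params = params, opt = opt, trial_errors = errors, test = test)
}

#' Train a model over multiple sessions
#'
#' Repeats [train_session()], carrying the optimizer state across sessions,
#' and tracks the parameters with the best session test error (used for all
#' post-hoc analyses).
#'
#' @inheritParams train_session
#' @param n_sessions number of training sessions (1000 examples each by
#'   default).
#' @return list with final `params`, `best_params`, per-trial `trial_errors`
#'   across all sessions, per-session `test_errors` (and `test_accuracy` for
#'   classification), and the optimizer state.
#' @export
train_model <- function(params, task, cfg, n_sessions, seed = NULL,
                        context_mask = NULL, opt = NULL) {
  trial_errors <- numeric(0)
  test_errors <- numeric(n_sessions)
  test_acc <- rep(NA_real_, n_sessions)
  best <- list(err = Inf, params = params)
  for (s in seq_len(n_sessions)) {
    res <- train_session(params, task, cfg, seed = child_seed(seed, 1000L + s),
                         opt = opt, context_mask = context_mask)
    params <- res$params
    opt <- res$opt
    trial_errors <- c(trial_errors, res$trial_errors)
    test_errors[s] <- res$test$loss
    if (!is.null(res$test$accuracy)) test_acc[s] <- res$test$accuracy
    if (res$test$loss < best$err)
      best <- list(err = res$test$loss, params = params)
  }
  list(params = params, best_params = best$params, opt = opt,
       trial_errors = trial_errors, test_errors = test_errors,
       test_accuracy = test_acc)
}
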