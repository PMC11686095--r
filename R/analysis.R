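# Quantitative readouts on simulated trajectories: selectivity traces, choice
# regression, activity/covariance change, controllability energy, SNR
# decomposition and the predictive-lead curve.

#' Cue selectivity trace
#'
#' The readout logit at the dimension of the correct class (pre-softmax), per
#' timestep, averaged over the examples of each class.
#'
#' @param traj a [run_trial()] trajectory from a classification task.
#' @param labels integer class labels per example (defaults to the batch's).
#' @return a `T x n_class` matrix of per-timestep mean correct-class logits,
#'   with an attribute `overall` holding the class-averaged trace.
#' @export
selectivity <- function(traj, labels = NULL) {
  if (is.null(labels)) labels <- traj$batch$meta$label
  n_out <- dim(traj$z)[1]; nb <- dim(traj$z)[2]; T <- dim(traj$z)[3]
  stopifnot(length(labels) == nb)
  classes <- sort(unique(labels))
  out <- matrix(NA_real_, T, length(classes),
                dimnames = list(NULL, paste0("class", classes)))
  for (j in seq_along(classes)) {
    idx <- which(labels == classes[j])
    for (t in seq_len(T))
      out[t, j] <- mean(traj$z[classes[j], idx, t])
  }
  attr(out, "overall") <- rowMeans(out)
  out
}

# Per-window evidence differences (#channel-2 - #channel-1 pulses) for the
# three equal windows of the presentation period.
evidence_window_counts <- function(batch) {
  pulses <- batch$meta$pulses
  T_pres <- batch$meta$T_pres
  edges <- round(seq(0, T_pres, length.out = 4))
  E <- matrix(0, dim(pulses)[2], 3)
  for (i in 1:3) {
    win <- (edges[i] + 1):edges[i + 1]
    E[, i] <- apply(pulses[2, , win, drop = FALSE], 2, sum) -
      apply(pulses[1, , win, drop = FALSE], 2, sum)
  }
  colnames(E) <- paste0("E", 1:3)
  E
}

#' Temporal choice regression
#'
#' Fits the model's binary left/right choices with a logistic model on the
#' per-window evidence differences, `P(right) = S(b1 E1 + b2 E2 + b3 E3)`,
#' where `E_i` is the pulse-count difference (right minus left) in the i-th
#' third of the presentation period. Tie ("equal") choices are excluded.
#' Weights are normalised by their sum. On perfect separation the fit is
#' ridge-regularised with a warning.
#'
#' @param batch an evidence-accumulation `ccl_batch` (or a list of them).
#' @param choices integer model choices per example (1 = channel 1 / left,
#'   2 = channel 2 / right, 3 = tie).
#' @param ridge ridge penalty used on separable data (default 1e-3).
#' @return list with `beta`, `beta_normalized` and the number of fitted
#'   trials `n`.
#' @export
fit_choice_regression <- function(batch, choices, ridge = 1e-3) {
  if (inherits(batch, "ccl_batch")) { batch <- list(batch); choices <- list(choices) }
  E <- do.call(rbind, lapply(batch, evidence_window_counts))
  ch <- unlist(choices)
  stopifnot(length(ch) == nrow(E))
  keep <- ch %in% c(1L, 2L)
  E <- E[keep, , drop = FALSE]
  resp <- as.integer(ch[keep] == 2L)
  if (length(resp) < 10) stop("too few binary choices to fit the regression")
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(resp ~ 0 + E, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- unname(stats::coef(fit))
  if (sep || any(!is.finite(beta)) || max(abs(beta)) > 25) {
    warning("choices are (near-)separable; using a ridge-regularised fit")
    nll <- function(b) {
      eta <- as.numeric(E %*% b)
      sum(log1p(exp(eta))) - sum(resp * eta) + ridge * sum(b^2)
    }
    beta <- stats::optim(rep(0, 3), nll, method = "BFGS")$par
  }
  list(beta = beta, beta_normalized = beta / sum(beta), n = length(resp))
}

#' Per-neuron activity change between two periods
#'
#' Mean absolute activity difference per neuron between matched recordings of
#' two periods, normalised by each neuron's baseline standard deviation.
#' Neurons with zero baseline deviation are excluded with a warning.
#'
#' @param act_P1,act_P2 activity arrays `n x batch x T` (post-nonlinearity),
#'   matched in examples and timesteps.
#' @param baseline_std per-neuron standard deviations from the start of the
#'   baseline period (defaults to the std of `act_P1`).
#' @return list with `per_neuron` change scores and their `mean`.
#' @export
activity_change <- function(act_P1, act_P2, baseline_std = NULL) {
  stopifnot(identical(dim(act_P1), dim(act_P2)))
  n <- dim(act_P1)[1]
  flat1 <- matrix(act_P1, n); flat2 <- matrix(act_P2, n)
  if (is.null(baseline_std)) baseline_std <- apply(flat1, 1, stats::sd)
  stopifnot(length(baseline_std) == n)
  keep <- baseline_std > 0
  if (!all(keep))
    warning(sprintf("excluding %d neuron(s) with zero baseline std", sum(!keep)))
  score <- rep(NA_real_, n)
  score[keep] <- rowMeans(abs(flat2 - flat1))[keep] / baseline_std[keep]
  list(per_neuron = score, mean = mean(score[keep]))
}

#' Covariance change between two periods
#'
#' One minus the Pearson correlation between the neuron-by-neuron covariance
#' matrices of two periods (covariance taken over timesteps and examples).
#' Ranges over [0, 2]; 0 for identical (or positively proportional)
#' covariance structure, 2 for perfectly anti-correlated structure.
#'
#' @param act_P1,act_P2 activity arrays `n x batch x T` for the two periods.
#' @return scalar in [0, 2].
#' @export
covariance_change <- function(act_P1, act_P2) {
  n <- dim(act_P1)[1]
  cov_matrix_change(stats::cov(t(matrix(act_P1, n))),
                    stats::cov(t(matrix(act_P2, n))))
}

# 1 - Pearson correlation between two flattened covariance matrices.
cov_matrix_change <- function(c1, c2) {
  if (stats::sd(c1) == 0 || stats::sd(c2) == 0)
    stop("constant activity: covariance correlation undefined")
  1 - stats::cor(as.numeric(c1), as.numeric(c2))
}

#' Controllability energy of the cerebellar feedback direction
#'
#' Generalises the controllability Gramian to the nonlinear loop: the state
#' covariance `Sigma` is estimated from `n_samples` noise-driven rollouts of
#' the input-free dynamics (`h_t = alpha h_{t-1} + W_hh f(h_{t-1}) +
#' W_Ch c_t + xi_t`, with i.i.d. Gaussian increments `xi_t` standing in for a
#' Wiener process), time-averaged after a burn-in. The energy of a unit
#' direction `v` is `v' Sigma v`; energies are reported normalised by the top
#' eigenvalue of `Sigma` (the highest attainable energy), for the cerebellar
#' feedback direction `W_Ch c / ||W_Ch c||` probed at `probe_step` and for
#' random standard-normal unit directions.
#'
#' @param params a [init_params()] object (any variant; the cerebellar
#'   direction requires cerebellar feedback).
#' @param n_samples number of rollouts (default 500).
#' @param n_steps simulated timesteps per rollout (default 50).
#' @param burn_in initial timesteps discarded from the covariance (default 5).
#' @param probe_step timestep at which the cerebellar direction is read
#'   (default 10).
#' @param noise_sd standard deviation of the per-step noise increments
#'   (default 1).
#' @param n_directions random comparison directions (default 100).
#' @param seed integer seed.
#' @return list with `Sigma`, `max_energy`, `energy_cereb` (normalised),
#'   `energy_random` (vector of normalised energies) and the probe direction.
#' @export
controllability_energy <- function(params, n_samples = 500, n_steps = 50,
                                   burn_in = 5, probe_step = 10,
                                   noise_sd = 1, n_directions = 100,
                                   seed = NULL) {
  stopifnot(n_steps > burn_in, probe_step <= n_steps)
  n <- params$n_rnn
  has_fb <- params$variant == "cerebellar_feedback"
  with_seed(seed, {
    h <- matrix(0, n, n_samples)
    Sigma <- matrix(0, n, n)
    kept <- 0L
    h_dir <- NULL
    for (t in seq_len(n_steps)) {
      fb <- NULL
      if (has_fb) {
        cb <- cerebellar_forward(h, params)
        fb <- feedback_transform(cb$c, params)
        if (!is.null(params$thalamus))
          fb <- thalamic_forward(h, fb, params$thalamus)
      }
      h <- params$alpha * h + params$W_hh %*% tanh(h) +
        (if (has_fb) params$W_Ch %*% fb else 0) +
        matrix(stats::rnorm(n * n_samples, 0, noise_sd), n, n_samples)
      if (!all(is.finite(h))) stop("noise-driven dynamics diverged")
      if (t == probe_step && has_fb) {
        drive <- rowMeans(params$W_Ch %*% fb)
        h_dir <- drive / sqrt(sum(drive^2))
      }
      if (t > burn_in) {
        Sigma <- Sigma + stats::cov(t(h))
        kept <- kept + 1L
      }
    }
    Sigma <- Sigma / kept
    max_energy <- max(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values)
    vs <- matrix(stats::rnorm(n * n_directions), n, n_directions)
    vs <- sweep(vs, 2, sqrt(colSums(vs^2)), "/")
    e_rand <- colSums(vs * (Sigma %*% vs)) / max_energy
    e_cereb <- if (is.null(h_dir)) NA_real_
      else as.numeric(t(h_dir) %*% Sigma %*% h_dir) / max_energy
    list(Sigma = Sigma, max_energy = max_energy,
         energy_cereb = e_cereb, energy_random = e_rand,
         cereb_direction = h_dir, n_samples = n_samples)
  })
}

#' Signal-to-noise decomposition of cortical activity
#'
#' Splits the population activity variance into a task-conditioned (signal)
#' and a within-condition (noise) component: the noise variance is the
#' average per-neuron variance within each stimulus condition (expectation
#' over conditions), the total variance is taken across all examples, and the
#' task variance is their difference. SNR is the ratio of task to noise
#' variance.
#'
#' @param act activity matrix `n x examples` (e.g. `tanh(h)` at a chosen
#'   timestep) or array `n x batch x T` with `timestep` selecting a slice.
#' @param conditions condition label per example.
#' @param timestep slice used when `act` is a 3-d array (default: last).
#' @return list with `var_task`, `var_noise`, `var_total` and `snr`.
#' @export
snr_report <- function(act, conditions, timestep = NULL) {
  if (length(dim(act)) == 3) {
    if (is.null(timestep)) timestep <- dim(act)[3]
    act <- matrix(act[, , timestep], dim(act)[1])
  }
  stopifnot(length(conditions) == ncol(act))
  conds <- unique(conditions)
  if (length(conds) < 2) stop("SNR needs at least two stimulus conditions")
  neuron_var <- function(m) mean(apply(m, 1, stats::var))
  var_total <- neuron_var(act)
  props <- table(conditions)[as.character(conds)] / length(conditions)
  var_noise <- sum(vapply(seq_along(conds), function(i)
    props[i] * neuron_var(act[, conditions == conds[i], drop = FALSE]),
    numeric(1)))
  var_task <- var_total - var_noise
  list(var_task = var_task, var_noise = var_noise, var_total = var_total,
       snr = var_task / var_noise)
}

#' Minimum granule count needed to decode the stimulus
#'
#' For each candidate granule-cell count, trains only a cerebellar decoder
#' (a `cerebellar_readout` model with a fixed, randomly initialised cortical
#' RNN; only the parallel fibres learn) to classify the stimulus, over
#' `n_sessions` sessions and `length(seeds)` initialisations. A count
#' succeeds when the mean classification error over the last `last_k`
#' sessions is below `threshold` for at least `min_seeds` seeds.
#'
#' @param task a classification [ccl_task()].
#' @param granule_grid increasing vector of granule-cell counts.
#' @param seeds integer seeds (default 1:5).
#' @param n_sessions training sessions per run (default 40).
#' @param cfg a [learning_config()] (regime is forced to `fixed_rnn`).
#' @param n_rnn,alpha cortical network size and leak of the encoder RNN.
#' @param threshold error criterion (default 0.05).
#' @param last_k sessions averaged for the criterion (default 4).
#' @param min_seeds required successful seeds (default 4).
#' @return list with `min_granules` (NA if no count succeeds) and the
#'   per-count error table.
#' @export
min_granules <- function(task, granule_grid, seeds = 1:5, n_sessions = 40,
                         cfg = learning_config(), n_rnn = 50, alpha = 0.1,
                         threshold = 0.05, last_k = 4, min_seeds = 4) {
  cfg$regime <- "fixed_rnn"
  rows <- list()
  result <- NA_integer_
  for (gcount in sort(granule_grid)) {
    err <- matrix(NA_real_, length(seeds), n_sessions)
    for (i in seq_along(seeds)) {
      p <- init_params(n_rnn = n_rnn, n_input = task$n_input,
                       n_out = task$n_out, n_granule = gcount,
                       alpha = alpha, variant = "cerebellar_readout",
                       tau_windows = 0L, seed = seeds[i])
      fit <- train_model(p, task, cfg, n_sessions, seed = seeds[i])
      err[i, ] <- 1 - fit$test_accuracy
    }
    tail_err <- rowMeans(err[, max(1, n_sessions - last_k + 1):n_sessions,
                             drop = FALSE])
    ok <- sum(tail_err < threshold) >= min_seeds
    rows[[length(rows) + 1]] <- data.frame(
      n_granule = gcount, mean_error = mean(tail_err), success = ok)
    if (ok && is.na(result)) result <- gcount
  }
  list(min_granules = result, table = do.call(rbind, rows))
}

#' SNR decomposition plus minimum decodable granule count
#'
#' Convenience wrapper combining [snr_report()] on per-condition trajectories
#' with the [min_granules()] decoding sweep.
#'
#' @param act,conditions,timestep passed to [snr_report()].
#' @param task,granule_grid,seeds,... passed to [min_granules()].
#' @return list with elements `snr` and `decoding`.
#' @export
snr_and_min_granules <- function(act, conditions, timestep = NULL,
                                 task, granule_grid, seeds = 1:5, ...) {
  list(snr = snr_report(act, conditions, timestep),
       decoding = min_granules(task, granule_grid, seeds, ...))
}

#' Prediction error versus temporal delay
#'
#' For each delay `d`, the cue/time-averaged Euclidean distance between the
#' cerebellar prediction at `t` and the readout at `t + d` (first-window
#' slice of the cerebellar output), together with the readout's
#' self-prediction baseline `||z_t - z_{t+d}||`. A trained predictive
#' cerebellum minimises the curve at `d = tau`.
#'
#' @param traj a [run_trial()] trajectory with cerebellar output.
#' @param delays integer delays to evaluate (default 0:5).
#' @return data frame with columns `delay`, `cereb_error`, `self_error`.
#' @export
prediction_delay_error <- function(traj, delays = 0:5) {
  if (is.null(traj$c)) stop("trajectory has no cerebellar output")
  n_out <- dim(traj$z)[1]; nb <- dim(traj$z)[2]; T <- dim(traj$z)[3]
  cs <- traj$c[seq_len(n_out), , , drop = FALSE]
  res <- lapply(delays, function(d) {
    ts <- seq_len(T - d)
    ce <- se <- 0
    for (t in ts) {
      dc <- matrix(cs[, , t], n_out, nb) - matrix(traj$z[, , t + d], n_out, nb)
      dz <- matrix(traj$z[, , t], n_out, nb) - matrix(traj$z[, , t + d], n_out, nb)
      ce <- ce + mean(sqrt(colSums(dc^2)))
      se <- se + mean(sqrt(colSums(dz^2)))
    }
    data.frame(delay = d, cereb_error = ce / length(ts),
               self_error = se / length(ts))
  })
  do.call(rbind, res)
}
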