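# Experiment drivers: reproducible multi-seed training runs, the task-switch
# protocol with context-specific parallel fibres, and plain-text config /
# logging so a stored config + seed reproduces a run exactly.

#' Read / write an experiment configuration
#'
#' Configurations are plain YAML key/value files. Missing fields fall back to
#' the defaults of [experiment_config()].
#'
#' @param path file path.
#' @return a config list (class `ccl_experiment_config`).
#' @export
read_experiment_config <- function(path) {
  do.call(experiment_config, yaml::read_yaml(path))
}

#' @rdname read_experiment_config
#' @param config a config list.
#' @export
write_experiment_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Experiment configuration
#'
#' Collects every knob of a training experiment. `task_args` are forwarded to
#' the task generator (e.g. `T_pres`, `rho`); `mode` selects plain training,
#' the task-switch protocol or a consolidation phase.
#'
#' @param task task name (see [ccl_task()]).
#' @param variant model variant (see [init_params()]).
#' @param regime plasticity regime (see [learning_config()]).
#' @param alpha cortical leak.
#' @param tau_windows cerebellar predictive window(s), timesteps.
#' @param n_rnn,n_granule network sizes.
#' @param eta,eta_rnn learning rates.
#' @param n_sessions training sessions per run.
#' @param seeds integer vector of initial conditions (default 1:5).
#' @param batch_size,n_train,n_test see [learning_config()].
#' @param mode `"train"`, `"switch"` or `"consolidate"`.
#' @param task_args named list of generator overrides.
#' @param switch_overlap,switch_sessions task-switch options: parallel-fibre
#'   overlap fraction and sessions per phase `c(task1, task2)`.
#' @param consolidation named list passed to [consolidation_config()].
#' @param out_dir optional output directory for logs.
#' @return a config list (class `ccl_experiment_config`).
#' @export
experiment_config <- function(task = "line", variant = "cerebellar_feedback",
                              regime = "fixed_rnn", alpha = 0.1,
                              tau_windows = 3L, n_rnn = 50, n_granule = 1000,
                              eta = 0.001, eta_rnn = NULL, n_sessions = 10,
                              seeds = 1:5, batch_size = 10, n_train = 1000,
                              n_test = 1000, mode = "train",
                              task_args = list(), switch_overlap = 0,
                              switch_sessions = c(10, 10),
                              consolidation = list(), out_dir = NULL) {
  structure(as.list(environment()), class = "ccl_experiment_config")
}

config_task <- function(config) {
  do.call(ccl_task, c(list(name = config$task), config$task_args))
}

config_params <- function(config, seed, n_granule = NULL) {
  task <- config_task(config)
  init_params(n_rnn = config$n_rnn, n_input = task$n_input,
              n_out = task$n_out,
              n_granule = if (is.null(n_granule)) config$n_granule else n_granule,
              alpha = config$alpha, variant = config$variant,
              tau_windows = config$tau_windows,
              feedback_softmax = task$feedback_softmax, seed = seed)
}

config_learning <- function(config) {
  learning_config(eta = config$eta, eta_rnn = config$eta_rnn,
                  regime = config$regime, batch_size = config$batch_size,
                  n_train = config$n_train, n_test = config$n_test)
}

#' Retention score after switching back
#'
#' Baseline task error divided by the error on the first trial after the
#' original task is reintroduced; 1 means the switch back is immediate and
#' lossless, values below 1 mean the original task was (partly) forgotten.
#'
#' @param baseline_error task error during the baseline period.
#' @param first_error error on the first trial after switching back.
#' @return scalar retention score.
#' @export
retention_score <- function(baseline_error, first_error) {
  baseline_error / first_error
}

#' Task-switch protocol with context-specific parallel fibres
#'
#' Trains a cerebellar-feedback model on `task1`, switches to `task2` using a
#' second parallel-fibre context (sharing a fraction `overlap` of columns),
#' then reintroduces `task1` and measures the retention score and the
#' activity / covariance changes of the cortical population across periods
#' (changes are normalised by the within-baseline change).
#'
#' @param config an [experiment_config()] (fields `switch_overlap`,
#'   `switch_sessions` control the protocol).
#' @param seed integer initial condition.
#' @param n_probe examples used for the activity probes (default 200).
#' @return list with `retention`, `baseline_error`, `first_error_back`,
#'   `activity_change`, `covariance_change` (both baseline-normalised),
#'   per-phase test errors and the final parameters.
#' @export
run_switching <- function(config, seed, n_probe = 200) {
  task1 <- config_task(config)
  task2_name <- if (config$task == "line") "curl" else config$task
  task2 <- do.call(ccl_task, c(list(name = task2_name), config$task_args))
  masks <- make_context_masks(config$n_granule, 2, config$switch_overlap)
  n_total <- attr(masks, "n_total")
  params <- config_params(config, seed, n_granule = n_total)
  cfg <- config_learning(config)

  fit1 <- train_model(params, task1, cfg, config$switch_sessions[1],
                      seed = child_seed(seed, 1L), context_mask = masks[[1]])
  params <- fit1$params
  baseline_error <- utils::tail(fit1$test_errors, 1)

  probe <- function(p, mask, probe_seed) {
    b <- task1$generate(n_probe, probe_seed)
    run_trial(p, b, context_mask = mask, record_granule = FALSE)$fh
  }
  act_B1 <- probe(params, masks[[1]], child_seed(seed, 51L))
  act_B2 <- probe(params, masks[[1]], child_seed(seed, 52L))

  fit2 <- train_model(params, task2, cfg, config$switch_sessions[2],
                      seed = child_seed(seed, 2L), context_mask = masks[[2]])
  params <- fit2$params
  act_T2 <- probe(params, masks[[2]], child_seed(seed, 51L))

  # first trial back on task 1: error before any retraining
  back <- task1$generate(cfg$batch_size, child_seed(seed, 3L))
  traj_back <- run_trial(params, back, context_mask = masks[[1]])
  first_error <- task_loss(traj_back$z, back$y, back$loss_mask,
                           task1$loss_kind)$loss

  std_B1 <- apply(matrix(act_B1, config$n_rnn), 1, stats::sd)
  dact <- activity_change(act_B1, act_T2, std_B1)$mean -
    activity_change(act_B1, act_B2, std_B1)$mean
  dcov <- covariance_change(act_B1, act_T2) - covariance_change(act_B1, act_B2)

  list(retention = retention_score(baseline_error, first_error),
       baseline_error = baseline_error, first_error_back = first_error,
       task1_test_errors = fit1$test_errors,
       task2_test_errors = fit2$test_errors,
       activity_change = dact, covariance_change = dcov,
       params = params, masks = masks)
}

#' Run a configured experiment over all seeds
#'
#' Dispatches on the config's `mode`: `"train"` trains a model per seed and
#' evaluates it (with per-preset ablation errors for the task's standard
#' windows), `"switch"` runs the task-switch protocol, `"consolidate"` trains
#' and then runs a consolidation phase. If `out_dir` is set, writes the
#' config, a per-trial error log (`errors.tsv`: seed, trial, train_error) and
#' a `manifest.tsv` with checksums.
#'
#' @param config an [experiment_config()].
#' @return list of per-seed results plus a `summary` data frame.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "ccl_experiment_config"))
  task <- config_task(config)
  cfg <- config_learning(config)
  results <- list()
  log_rows <- list()

  for (seed in config$seeds) {
    key <- paste0("seed", seed)
    if (config$mode == "switch") {
      results[[key]] <- run_switching(config, seed)
      next
    }
    params <- config_params(config, seed)
    fit <- train_model(params, task, cfg, config$n_sessions, seed = seed)
    res <- list(fit = fit, test_error = utils::tail(fit$test_errors, 1))
    if (config$variant %in% c("cerebellar_feedback", "cerebellar_readout")) {
      presets <- ablation_presets(config$task)
      res$ablation_errors <- vapply(presets, function(ab)
        evaluate_model(fit$best_params, task, cfg$n_test,
                       seed = child_seed(seed, 0L), ablation = ab)$loss,
        numeric(1))
    }
    if (config$mode == "consolidate") {
      ccfg <- do.call(consolidation_config, config$consolidation)
      res$consolidation <- run_consolidation(fit$best_params, task, ccfg,
                                             seed = child_seed(seed, 7L))
    }
    log_rows[[key]] <- data.frame(seed = seed,
                                  trial = seq_along(fit$trial_errors),
                                  train_error = fit$trial_errors)
    results[[key]] <- res
  }

  if (config$mode == "switch") {
    summary <- data.frame(
      seed = config$seeds,
      retention = vapply(results, `[[`, numeric(1), "retention"),
      covariance_change = vapply(results, `[[`, numeric(1), "covariance_change"))
  } else {
    summary <- data.frame(
      seed = config$seeds,
      test_error = vapply(results, `[[`, numeric(1), "test_error"))
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_experiment_config(config, file.path(config$out_dir, "config.yaml"))
    if (length(log_rows) > 0)
      utils::write.table(do.call(rbind, log_rows),
                         file.path(config$out_dir, "errors.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(summary, file.path(config$out_dir, "summary.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    files <- list.files(config$out_dir, full.names = TRUE)
    manifest <- data.frame(file = basename(files),
                           md5 = as.character(tools::md5sum(files)))
    utils::write.table(manifest, file.path(config$out_dir, "manifest.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  list(results = results, summary = summary, config = config)
}
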