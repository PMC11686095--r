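# Synthetic task generators. All generators are pure functions of their
# arguments and the seed: the same (config, seed) pair yields an identical
# batch. Inputs carry zero-mean Gaussian noise (sd 0.1) at every timestep,
# including the cue step.

new_batch <- function(x, y, loss_mask, meta, task, loss_kind) {
  structure(list(x = x, y = y, loss_mask = loss_mask, meta = meta,
                 T = dim(x)[3], n_input = dim(x)[1], n_out = dim(y)[1],
                 task = task, loss_kind = loss_kind),
            class = "ccl_batch")
}

#' @export
print.ccl_batch <- function(x, ...) {
  cat(sprintf("<ccl_batch> task=%s: %d examples x %d timesteps, input dim %d, target dim %d (%s loss, %d supervised steps)\n",
              x$task, dim(x$x)[2], x$T, x$n_input, x$n_out, x$loss_kind,
              sum(x$loss_mask)))
  invisible(x)
}

# Endpoints of the five "go" lines, evenly spaced on the unit circle.
line_endpoints <- function() {
  ang <- 2 * pi * (0:4) / 5
  rbind(cos(ang), sin(ang))
}

drawing_inputs <- function(cues, T, noise_sd) {
  nb <- length(cues)
  x <- array(stats::rnorm(10 * nb * T, 0, noise_sd), c(10, nb, T))
  for (b in seq_len(nb)) x[cues[b], b, 1] <- x[cues[b], b, 1] + 1
  x
}

#' Line drawing task batch
#'
#' One of six 10-dimensional binary cues is shown at timestep 1 (one-hot on
#' the first six channels); five cues map to straight 2-d lines from the
#' origin to endpoints evenly spaced on the unit circle, drawn over 20 steps
#' with evenly spaced intermediate targets `y_t = (t-1)/19 * y_end`; the sixth
#' cue is a "no-go" whose target stays at the origin. Every input timestep
#' carries Gaussian noise (sd `noise_sd`).
#'
#' @param batch number of examples.
#' @param seed integer seed.
#' @param noise_sd input noise standard deviation (default 0.1).
#' @param T trial length in timesteps (default 20).
#' @param curl use the curl-field (semi-elliptical) targets of the task-switch
#'   context instead of straight lines.
#' @return a `ccl_batch` (mean-squared-error loss, all timesteps supervised).
#' @export
make_line_batch <- function(batch = 10, seed = NULL, noise_sd = 0.1, T = 20,
                            curl = FALSE) {
  with_seed(seed, {
    cues <- sample.int(6, batch, replace = TRUE)
    x <- drawing_inputs(cues, T, noise_sd)
    ends <- line_endpoints()
    y <- array(0, c(2, batch, T))
    for (b in seq_len(batch)) {
      if (cues[b] == 6) next  # no-go: remain at the origin
      y_end <- ends[, cues[b]]
      y[, b, ] <- if (curl) make_curl_targets(y_end, T)
                  else outer(y_end, (seq_len(T) - 1) / (T - 1))
    }
    new_batch(x, y, rep(TRUE, T), list(cue = cues),
              task = if (curl) "curl" else "line", loss_kind = "mse")
  })
}

#' Curl-field drawing target
#'
#' Semi-elliptical path from the origin to `y_end`: with
#' `theta = atan2(y_end[2], y_end[1])` and `t` running uniformly from `pi` to
#' `2*pi`,
#' `y(t) = y_end/2 + R(theta) %*% c(cos(t), sin(t)) / 2`
#' where `R` is the rotation by `theta`. The path starts at the origin
#' (`t = pi`), ends at `y_end` (`t = 2*pi`) and deviates laterally by 1/2 from
#' the chord at its midpoint. A zero endpoint (the no-go cue) yields a target
#' fixed at the origin.
#'
#' @param y_end length-2 endpoint on the unit circle (or `c(0, 0)`).
#' @param T number of sampled points (default 20).
#' @return `2 x T` matrix of target positions.
#' @export
make_curl_targets <- function(y_end, T = 20) {
  stopifnot(length(y_end) == 2)
  if (all(y_end == 0)) return(matrix(0, 2, T))
  theta <- atan2(y_end[2], y_end[1])
  tt <- seq(pi, 2 * pi, length.out = T)
  rbind(y_end[1] / 2 + cos(theta) * cos(tt) / 2 - sin(theta) * sin(tt) / 2,
        y_end[2] / 2 + sin(theta) * cos(tt) / 2 + cos(theta) * sin(tt) / 2)
}

digit_template_cache <- new.env(parent = emptyenv())

#' Digit drawing templates
#'
#' Six fixed 20-point piecewise-linear templates resembling the digits 0-5,
#' constructed within the unit square and shipped as a versioned delimited
#' text fixture (`inst/extdata/digit_templates_v1.csv`).
#'
#' @return a list of six `2 x 20` matrices, one per digit 0-5.
#' @export
digit_templates <- function() {
  if (!is.null(digit_template_cache$templates))
    return(digit_template_cache$templates)
  path <- system.file("extdata", "digit_templates_v1.csv", package = "ccloop")
  if (path == "") stop("digit template fixture not found")
  tab <- utils::read.csv(path)
  out <- lapply(0:5, function(d) {
    sub <- tab[tab$digit == d, ]
    sub <- sub[order(sub$step), ]
    rbind(sub$x, sub$y)
  })
  digit_template_cache$templates <- out
  out
}

#' Digit drawing task batch
#'
#' Same cue scheme as [make_line_batch()], but each of the six cues maps to a
#' fixed 20-point digit-shaped trajectory in the unit square (digits 0-5).
#' This task produces non-linear, varied future targets and is the setting
#' where a cerebellar temporal basis (multiple predictive windows) pays off.
#'
#' @inheritParams make_line_batch
#' @return a `ccl_batch` (mean-squared-error loss, all timesteps supervised).
#' @export
make_digit_batch <- function(batch = 10, seed = NULL, noise_sd = 0.1, T = 20) {
  templates <- digit_templates()
  with_seed(seed, {
    cues <- sample.int(6, batch, replace = TRUE)
    x <- drawing_inputs(cues, T, noise_sd)
    y <- array(0, c(2, batch, T))
    for (b in seq_len(batch)) y[, b, ] <- templates[[cues[b]]]
    new_batch(x, y, rep(TRUE, T), list(cue = cues),
              task = "digit", loss_kind = "mse")
  })
}

evidence_label <- function(n_left, n_right) {
  if (n_left > n_right) 1L else if (n_right > n_left) 2L else 3L
}

#' Evidence accumulation task batch
#'
#' Binary pulses ("air puffs") arrive on one of two channels over a
#' presentation period: per timestep the input is zero with probability `rho`
#' (sparsity), otherwise a single pulse on channel 1 or 2 with equal
#' probability. After a delay the model must report which channel received
#' more pulses (class 1 or 2) or whether the counts tied (class 3); the target
#' is supervised only at the final timestep. An example is flagged
#' *history-centric* when classifying from the final third of the
#' presentation period alone would give strictly the wrong answer.
#'
#' @param batch number of examples.
#' @param seed integer seed.
#' @param T_pres presentation period length (default 45 timesteps).
#' @param T_del delay period length (default 5; the sub-second variant uses 0).
#' @param rho zero-input rate in [0, 1] (default 0.7).
#' @param noise_sd input noise standard deviation (default 0.1).
#' @return a `ccl_batch` (cross-entropy loss, 3 classes) with
#'   `meta$label`, `meta$counts` and `meta$history_centric`.
#' @export
make_evidence_batch <- function(batch = 10, seed = NULL, T_pres = 45,
                                T_del = 5, rho = 0.7, noise_sd = 0.1) {
  stopifnot(rho >= 0, rho <= 1)
  T <- T_pres + T_del
  with_seed(seed, {
    pulses <- array(0, c(2, batch, T))
    draw <- matrix(stats::runif(batch * T_pres), batch, T_pres)
    side <- matrix(stats::runif(batch * T_pres) < 0.5, batch, T_pres)
    labels <- integer(batch)
    history <- logical(batch)
    counts <- matrix(0L, 2, batch)
    final_third <- (T_pres - floor(T_pres / 3) + 1):T_pres
    for (b in seq_len(batch)) {
      on <- draw[b, ] >= rho
      ch <- ifelse(side[b, ], 1L, 2L)
      for (t in which(on)) pulses[ch[t], b, t] <- 1
      n1 <- sum(on & ch == 1L); n2 <- sum(on & ch == 2L)
      counts[, b] <- c(n1, n2)
      labels[b] <- evidence_label(n1, n2)
      ft <- intersect(which(on), final_third)
      lab_ft <- evidence_label(sum(ch[ft] == 1L), sum(ch[ft] == 2L))
      history[b] <- lab_ft != labels[b]
    }
    x <- pulses + array(stats::rnorm(2 * batch * T, 0, noise_sd), c(2, batch, T))
    y <- array(0, c(3, batch, T))
    for (b in seq_len(batch)) y[labels[b], b, ] <- 1
    mask <- rep(FALSE, T); mask[T] <- TRUE
    new_batch(x, y, mask,
              list(label = labels, counts = counts, history_centric = history,
                   pulses = pulses, T_pres = T_pres),
              task = "evidence", loss_kind = "cross_entropy")
  })
}

# The two fixed 10-dimensional binary cue vectors of the delayed association
# task: disjoint 5-hot patterns.
delayed_assoc_cues <- function() {
  cbind(c(rep(1, 5), rep(0, 5)), c(rep(0, 5), rep(1, 5)))
}

#' Delayed association task batch
#'
#' One of two fixed 10-dimensional binary cues is presented at timestep 1,
#' followed by a delay with no input (noise only); the model must report the
#' associated binary class at the end of the trial. The output is supervised
#' over the final six timesteps (timestep `T - 5` onwards, i.e. 10..15 at the
#' default `T = 15`).
#'
#' @param batch number of examples.
#' @param seed integer seed.
#' @param T trial length in timesteps (>= 6; default 15).
#' @param noise_sd input noise standard deviation (default 0.1).
#' @return a `ccl_batch` (cross-entropy loss, 2 classes) with `meta$label`.
#' @export
make_delayed_assoc_batch <- function(batch = 10, seed = NULL, T = 15,
                                     noise_sd = 0.1) {
  stopifnot(T >= 6)
  cues <- delayed_assoc_cues()
  with_seed(seed, {
    labels <- sample.int(2, batch, replace = TRUE)
    x <- array(stats::rnorm(10 * batch * T, 0, noise_sd), c(10, batch, T))
    for (b in seq_len(batch)) x[, b, 1] <- x[, b, 1] + cues[, labels[b]]
    y <- array(0, c(2, batch, T))
    for (b in seq_len(batch)) y[labels[b], b, ] <- 1
    mask <- rep(FALSE, T); mask[(T - 5):T] <- TRUE
    new_batch(x, y, mask, list(label = labels),
              task = "delayed_association", loss_kind = "cross_entropy")
  })
}

#' Context-specific parallel-fibre masks
#'
#' Splits the parallel-fibre columns among task contexts: each context's
#' active set is the union of a shared block (a fraction `overlap` of its
#' columns) and a private block disjoint from every other context's. With
#' zero overlap each context uses fully private cerebellar weights; with
#' overlap 1 all contexts share the same columns.
#'
#' @param n_pf_columns number of active parallel-fibre columns per context.
#' @param n_contexts number of task contexts.
#' @param overlap fraction of each context's columns that are shared.
#' @param n_total total number of granule cells / parallel-fibre columns
#'   available (defaults to the minimum required).
#' @return list of logical masks (length `n_total`), one per context, with
#'   attributes `overlap` and `n_total`.
#' @export
make_context_masks <- function(n_pf_columns, n_contexts, overlap,
                               n_total = NULL) {
  stopifnot(overlap >= 0, overlap <= 1, n_contexts >= 1)
  n_shared <- round(overlap * n_pf_columns)
  n_private <- n_pf_columns - n_shared
  required <- n_shared + n_contexts * n_private
  if (is.null(n_total)) n_total <- required
  if (n_total < required)
    stop(sprintf("need %d parallel-fibre columns for %d contexts, have %d",
                 required, n_contexts, n_total))
  masks <- vector("list", n_contexts)
  for (i in seq_len(n_contexts)) {
    m <- rep(FALSE, n_total)
    if (n_shared > 0) m[seq_len(n_shared)] <- TRUE
    if (n_private > 0)
      m[n_shared + (i - 1) * n_private + seq_len(n_private)] <- TRUE
    masks[[i]] <- m
  }
  attr(masks, "overlap") <- overlap
  attr(masks, "n_total") <- n_total
  masks
}

#' Ablation window presets per task
#'
#' The transient cerebellar silencing windows used in the task analyses,
#' as 1-based inclusive timestep intervals: start/middle/end thirds for the
#' drawing tasks (`[1-6], [8-13], [15-20]`) and evidence accumulation
#' (`[1-15], [15-30], [30-45]`, plus `full` = the whole trial), and for the
#' delayed association task the mid-delay window `[8-12]` (`main`) plus
#' `[1-5], [6-10], [11-15]`.
#'
#' @param task `"line"`, `"curl"`, `"digit"`, `"evidence"` or
#'   `"delayed_association"`.
#' @return named list of [ablation_schedule()] objects.
#' @export
ablation_presets <- function(task) {
  switch(task,
    line = , curl = , digit = list(
      start = ablation_schedule("cerebellum", list(c(1, 6))),
      mid = ablation_schedule("cerebellum", list(c(8, 13))),
      end = ablation_schedule("cerebellum", list(c(15, 20)))),
    evidence = list(
      full = ablation_schedule("cerebellum", list(c(1, 50))),
      early = ablation_schedule("cerebellum", list(c(1, 15))),
      mid = ablation_schedule("cerebellum", list(c(15, 30))),
      late = ablation_schedule("cerebellum", list(c(30, 45)))),
    delayed_association = list(
      main = ablation_schedule("cerebellum", list(c(8, 12))),
      early = ablation_schedule("cerebellum", list(c(1, 5))),
      mid = ablation_schedule("cerebellum", list(c(6, 10))),
      late = ablation_schedule("cerebellum", list(c(11, 15)))),
    stop(sprintf("unknown task '%s'", task))
  )
}

#' Task specification for training
#'
#' Bundles a batch generator with the task's structural constants so that
#' [train_session()] and [run_experiment()] can be task-agnostic. Extra
#' arguments are forwarded to the generator (e.g. `T_pres`, `rho` for the
#' evidence task).
#'
#' @param name task name (see [ablation_presets()] for the list).
#' @param ... overrides passed to the batch generator.
#' @return an object of class `ccl_task`.
#' @export
ccl_task <- function(name = c("line", "curl", "digit", "evidence",
                              "delayed_association"), ...) {
  name <- match.arg(name)
  args <- list(...)
  info <- switch(name,
    line = list(gen = make_line_batch, n_input = 10, n_out = 2, T = 20,
                loss_kind = "mse", feedback_softmax = FALSE),
    curl = list(gen = function(batch, seed, ...)
                  make_line_batch(batch, seed, curl = TRUE, ...),
                n_input = 10, n_out = 2, T = 20,
                loss_kind = "mse", feedback_softmax = FALSE),
    digit = list(gen = make_digit_batch, n_input = 10, n_out = 2, T = 20,
                 loss_kind = "mse", feedback_softmax = FALSE),
    evidence = list(gen = make_evidence_batch, n_input = 2, n_out = 3, T = 50,
                    loss_kind = "cross_entropy", feedback_softmax = TRUE),
    delayed_association = list(gen = make_delayed_assoc_batch, n_input = 10,
                               n_out = 2, T = 15,
                               loss_kind = "cross_entropy",
                               feedback_softmax = TRUE)
  )
  if (name == "evidence") {
    T_pres <- if (!is.null(args$T_pres)) args$T_pres else 45
    T_del <- if (!is.null(args$T_del)) args$T_del else 5
    info$T <- T_pres + T_del
  }
  if (name == "delayed_association" && !is.null(args$T)) info$T <- args$T
  gen <- info$gen
  structure(list(
    name = name, n_input = info$n_input, n_out = info$n_out, T = info$T,
    loss_kind = info$loss_kind, feedback_softmax = info$feedback_softmax,
    generate = function(batch, seed = NULL)
      do.call(gen, c(list(batch = batch, seed = seed), args))
  ), class = "ccl_task")
}

#' @export
print.ccl_task <- function(x, ...) {
  cat(sprintf("<ccl_task> %s: input dim %d, %d outputs, T=%d, %s loss%s\n",
              x$name, x$n_input, x$n_out, x$T, x$loss_kind,
              if (x$feedback_softmax) ", softmax feedback" else ""))
  invisible(x)
}
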