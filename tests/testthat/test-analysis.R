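test_that("selectivity is the correct-class logit averaged per condition", {
  p <- toy_params(n_rnn = 4, n_input = 3, n_out = 2, n_granule = 5,
                  zero_weights = TRUE)
  x <- array(rnorm(3 * 6 * 4), c(3, 6, 4))
  y <- array(0, c(2, 6, 4))
  labels <- rep(1:2, 3)
  b <- toy_batch(x, y, loss_kind = "cross_entropy", labels = labels)
  tr <- run_trial(p, b)
  # zero readout weights: flat zero trace
  s <- selectivity(tr)
  expect_true(all(s == 0))

  # untrained symmetric network: traces carry the right shape and classes
  p2 <- toy_params(n_rnn = 4, n_input = 3, n_out = 2, n_granule = 5, seed = 6)
  tr2 <- run_trial(p2, b)
  s2 <- selectivity(tr2)
  expect_equal(dim(s2), c(4, 2))
  expect_equal(unname(s2[2, 1]), mean(tr2$z[1, labels == 1, 2]))
  expect_length(attr(s2, "overall"), 4)
})

test_that("choice regression recovers generating window weights", {
  # simulate choices from known beta over evidence windows
  gen_choices <- function(beta, n, seed) {
    b <- make_evidence_batch(n, seed = seed, rho = 0.5)
    E <- cbind(
      apply(b$meta$pulses[2, , 1:15], 1, sum) - apply(b$meta$pulses[1, , 1:15], 1, sum),
      apply(b$meta$pulses[2, , 16:30], 1, sum) - apply(b$meta$pulses[1, , 16:30], 1, sum),
      apply(b$meta$pulses[2, , 31:45], 1, sum) - apply(b$meta$pulses[1, , 31:45], 1, sum))
    pr <- 1 / (1 + exp(-as.numeric(E %*% beta)))
    set.seed(seed + 1)
    choices <- ifelse(runif(n) < pr, 2L, 1L)
    list(batch = b, choices = choices)
  }

  # equal weights recover ~ (1/3, 1/3, 1/3)
  d <- gen_choices(c(1, 1, 1), 5000, 10)
  fit <- fit_choice_regression(d$batch, d$choices)
  expect_equal(fit$beta_normalized, rep(1 / 3, 3), tolerance = 0.05)

  # weight only on the final window recovers ~ (0, 0, 1)
  d3 <- gen_choices(c(0, 0, 1.5), 5000, 20)
  fit3 <- fit_choice_regression(d3$batch, d3$choices)
  expect_equal(fit3$beta_normalized, c(0, 0, 1), tolerance = 0.05)

  # normalised weights are invariant to the scale of beta (strong weights
  # make the choices near-separable, which triggers the ridge fallback)
  d2 <- gen_choices(c(2, 2, 2), 5000, 10)
  fit2 <- suppressWarnings(fit_choice_regression(d2$batch, d2$choices))
  expect_equal(sum(fit2$beta_normalized), 1, tolerance = 1e-12)
  expect_equal(fit2$beta_normalized, rep(1 / 3, 3), tolerance = 0.05)
})

test_that("activity change scores are normalised mean absolute differences", {
  set.seed(2)
  a1 <- array(rnorm(5 * 4 * 3), c(5, 4, 3))
  # identical periods score zero
  expect_equal(activity_change(a1, a1)$mean, 0)
  # shifting each neuron by its baseline std scores exactly 1
  sdv <- apply(matrix(a1, 5), 1, sd)
  a2 <- a1 + array(rep(sdv, 12), c(5, 4, 3))
  res <- activity_change(a1, a2, sdv)
  expect_equal(res$per_neuron, rep(1, 5), tolerance = 1e-12)
  # population mean is invariant to neuron permutation
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(activity_change(a1[perm, , , drop = FALSE],
                               a2[perm, , , drop = FALSE])$mean,
               activity_change(a1, a2)$mean, tolerance = 1e-12)
  # zero-variance neurons are excluded with a warning
  a1z <- a1; a1z[1, , ] <- 0
  expect_warning(rz <- activity_change(a1z, a2), "zero baseline")
  expect_true(is.na(rz$per_neuron[1]))
})

test_that("covariance change spans [0, 2] with the expected landmarks", {
  set.seed(3)
  a <- array(rnorm(4 * 10 * 5), c(4, 10, 5))
  expect_equal(covariance_change(a, a), 0, tolerance = 1e-12)
  # positive scaling leaves the correlation of covariances at 1
  expect_equal(covariance_change(a, a * 3), 0, tolerance = 1e-12)
  # unrelated periods stay within the [0, 2] bound
  b <- array(rnorm(4 * 10 * 5), c(4, 10, 5))
  v <- covariance_change(a, b)
  expect_gte(v, 0); expect_lte(v, 2)
  expect_error(covariance_change(a * 0, a), "constant")

  # anti-correlated toy covariance structure reaches the upper landmark 2
  # (tested on the matrix-level step: r = -1 requires structures that no
  # positive-definite pair can attain, e.g. a sign flip)
  c1 <- matrix(c(1, 0.9, 0.9, 1), 2)
  expect_equal(ccloop:::cov_matrix_change(c1, -c1), 2, tolerance = 1e-12)
})

test_that("noise-driven covariance matches the Lyapunov solution in the linear limit", {
  # A 10-unit contraction with tiny weights keeps tanh ~ identity; the
  # stationary covariance then solves Sigma = A Sigma A' + Q.
  set.seed(5)
  n <- 10
  W <- matrix(rnorm(n * n, 0, 0.05 / sqrt(n)), n, n)
  p <- init_params(n_rnn = n, n_input = 1, n_out = 1, n_granule = 2,
                   alpha = 0.3, variant = "no_feedback", seed = 1)
  p$W_hh <- W
  noise_sd <- 0.02   # small noise keeps states in the linear range of tanh
  est <- controllability_energy(p, n_samples = 500, n_steps = 60,
                                burn_in = 10, probe_step = 20,
                                noise_sd = noise_sd, seed = 2)
  A <- p$alpha * diag(n) + W
  Q <- noise_sd^2 * diag(n)
  # solve the discrete Lyapunov equation by fixed-point iteration (oracle)
  S <- Q
  for (i in 1:500) S <- A %*% S %*% t(A) + Q
  # Monte-Carlo s.e. of a covariance entry ~ sigma^2 * sqrt(2/N)
  tol <- 3 * max(diag(S)) * sqrt(2 / 500)
  expect_lt(max(abs(est$Sigma - S)), tol)
  # normalised energies live in [0, 1]; the top eigenvector attains 1
  expect_true(all(est$energy_random >= 0 & est$energy_random <= 1 + 1e-12))
  u <- eigen(est$Sigma, symmetric = TRUE)$vectors[, 1]
  expect_equal(as.numeric(t(u) %*% est$Sigma %*% u) / est$max_energy, 1,
               tolerance = 1e-12)
})

test_that("SNR decomposition recovers known signal and noise variances", {
  set.seed(6)
  n <- 30; m <- 4000
  sig_sd <- 0.8; noise_sd <- 0.5
  cond <- rep(1:2, each = m / 2)
  mu <- matrix(rnorm(n * 2, 0, sig_sd), n, 2)
  act <- mu[, cond] + matrix(rnorm(n * m, 0, noise_sd), n, m)
  rep_ <- snr_report(act, cond)
  # two equiprobable condition means drawn i.i.d.: between-condition variance
  # per neuron is (mu1 - mu2)^2 / 4; average over neurons
  expected_task <- mean((mu[, 1] - mu[, 2])^2 / 4)
  expect_equal(rep_$var_noise, noise_sd^2, tolerance = 0.05)
  expect_equal(rep_$var_task, expected_task, tolerance = 0.05)
  expect_equal(rep_$snr, expected_task / noise_sd^2, tolerance = 0.15)
  expect_gte(rep_$var_task, -1e-6)

  # identical condition distributions give SNR ~ 0
  act0 <- matrix(rnorm(n * m, 0, noise_sd), n, m)
  expect_lt(abs(snr_report(act0, cond)$snr), 0.05)
  expect_error(snr_report(act0, rep(1, m)), "two stimulus conditions")
})

test_that("prediction-delay curve has exact landmarks", {
  # c identical to z: zero error at delay 0
  p <- toy_params(n_rnn = 3, n_input = 2, n_out = 2, n_granule = 4,
                  tau_windows = 0L, seed = 51)
  x <- array(rnorm(2 * 3 * 6), c(2, 3, 6))
  b <- toy_batch(x, array(0, c(2, 3, 6)))
  tr <- run_trial(p, b)
  tr$c <- tr$z
  pe <- prediction_delay_error(tr, 0:3)
  expect_equal(pe$cereb_error[1], 0, tolerance = 1e-12)
  expect_equal(pe$cereb_error, pe$self_error, tolerance = 1e-12)

  # constant trajectories give a flat zero curve
  trc <- tr
  trc$z[] <- 1; trc$c[] <- 1
  pec <- prediction_delay_error(trc, 0:3)
  expect_true(all(pec$cereb_error == 0))
  expect_true(all(pec$self_error == 0))
})

test_that("granule decoding sweep returns the smallest sufficient count", {
  # tiny sweep: a 2-class task decodable with enough granule cells
  task <- ccl_task("delayed_association", T = 6)
  res <- min_granules(task, granule_grid = c(2, 60), seeds = 1:2,
                      n_sessions = 3, n_rnn = 12,
                      cfg = learning_config(n_train = 200, n_test = 100),
                      threshold = 0.35, last_k = 2, min_seeds = 2)
  expect_s3_class(res$table, "data.frame")
  expect_equal(nrow(res$table), 2)
  # monotone benefit: more granule cells never decode worse here
  expect_lte(res$table$mean_error[2], res$table$mean_error[1] + 0.05)
})
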