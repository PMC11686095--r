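test_that("masked losses and their output gradients are exact", {
  z <- array(0, c(2, 1, 1)); y <- array(c(1, 0), c(2, 1, 1))
  # single-step MSE: loss = mean((z-y)^2) = 1/2, grad = 2(z-y)/denom
  l <- task_loss(z, y, TRUE, "mse")
  expect_equal(l$loss, 0.5)
  expect_equal(as.numeric(l$dz), c(-1, 0))

  # perfect prediction: zero loss, zero gradient
  l0 <- task_loss(y, y, TRUE, "mse")
  expect_equal(l0$loss, 0)
  expect_true(all(l0$dz == 0))

  # uniform 2-class softmax vs one-hot: loss = ln 2
  lce <- task_loss(array(0, c(2, 1, 1)), y, TRUE, "cross_entropy")
  expect_equal(lce$loss, log(2))
  expect_error(task_loss(z, array(c(2, 1), c(2, 1, 1)), TRUE, "cross_entropy"),
               "one-hot")

  # gradients match central finite differences for both losses
  set.seed(1)
  zr <- array(rnorm(2 * 3 * 4), c(2, 3, 4))
  yr <- array(0, c(2, 3, 4)); yr[1, , ] <- 1
  mask <- c(FALSE, TRUE, TRUE, TRUE)
  for (kind in c("mse", "cross_entropy")) {
    l <- task_loss(zr, yr, mask, kind)
    fd <- fd_gradient(function(zz) task_loss(zz, yr, mask, kind)$loss, zr)
    expect_equal(as.numeric(l$dz), as.numeric(fd), tolerance = 1e-6)
  }
})

test_that("readout delta rule equals the analytic loss gradient", {
  # 1-D toy: dE/dz = 2 paired with activities (0.5, -0.5)
  dz <- array(2, c(1, 1, 2))
  fh <- array(c(0.5, -0.5), c(1, 1, 2))
  g <- delta_readout(dz, fh)
  expect_equal(as.numeric(g$W_rdt), 2 * 0.5 + 2 * (-0.5))
  expect_equal(as.numeric(g$b_rdt), 4)
  expect_true(all(delta_readout(dz * 0, fh)$W_rdt == 0))
  expect_true(all(delta_readout(dz, fh * 0)$W_rdt == 0))

  # finite differences through the full rollout on a 5-unit toy
  p <- toy_params(n_rnn = 5, n_input = 2, n_out = 2, n_granule = 4, seed = 21)
  x <- array(rnorm(2 * 3 * 4), c(2, 3, 4))
  y <- array(rnorm(2 * 3 * 4), c(2, 3, 4))
  b <- toy_batch(x, y)
  traj <- run_trial(p, b)
  l <- task_loss(traj$z, y, b$loss_mask, "mse")
  got <- delta_readout(l$dz, traj$fh)
  fd <- fd_gradient(function(W) {
    p2 <- p; p2$W_rdt <- W
    task_loss(run_trial(p2, b)$z, y, b$loss_mask, "mse")$loss
  }, p$W_rdt)
  expect_equal(got$W_rdt, fd, tolerance = 1e-5)
})

test_that("parallel-fibre rule pairs past output with current target", {
  # T = 3, tau = 1, scalar-ish toy with a hand-computed accumulation
  p <- toy_params(n_rnn = 2, n_input = 1, n_out = 1, n_granule = 2,
                  tau_windows = 1L, seed = 31)
  x <- array(rnorm(1 * 1 * 3), c(1, 1, 3))
  y <- array(c(0.3, -0.2, 0.5), c(1, 1, 3))
  b <- toy_batch(x, y)
  traj <- run_trial(p, b)
  got <- delta_parallel_fibres(traj, y, b$loss_mask, 1L, "mse")
  # oracle: explicit sum over t = 2..3 under the mean convention
  denom <- 1 * 2 * 1 * 1   # windows * pairs * batch * dims
  oracle <- matrix(0, 1, 2)
  for (t in 2:3) {
    dc <- 2 * (traj$c[1, 1, t - 1] - y[1, 1, t]) / denom
    oracle <- oracle + dc * traj$g[, 1, t - 1]
  }
  expect_equal(got, oracle, tolerance = 1e-12)

  # tau = 0 reduces to the standard delta rule pairing c_t with y_t
  got0 <- delta_parallel_fibres(traj, y, b$loss_mask, 0L, "mse")
  oracle0 <- matrix(0, 1, 2)
  for (t in 1:3)
    oracle0 <- oracle0 + (2 * (traj$c[1, 1, t] - y[1, 1, t]) / 3) * traj$g[, 1, t]
  expect_equal(got0, oracle0, tolerance = 1e-12)

  # a perfect predictor receives no update
  traj_perfect <- traj
  for (t in 2:3) traj_perfect$c[1, , t - 1] <- y[1, , t]
  upd <- delta_parallel_fibres(traj_perfect, y, b$loss_mask, 1L, "mse")
  expect_true(all(abs(upd) < 1e-12))

  # window longer than the trial: zero update with a warning
  expect_warning(
    z <- delta_parallel_fibres(traj, y, b$loss_mask, 5L, "mse"),
    "exceed")
  expect_true(all(z == 0))

  # context mask restricts updated columns
  m <- c(TRUE, FALSE)
  gm <- delta_parallel_fibres(traj, y, b$loss_mask, 1L, "mse",
                              context_mask = m)
  expect_true(all(gm[, !m] == 0))
  expect_false(all(gm[, m] == 0))
})

test_that("eligibility trace follows the leaky recursion", {
  # sequence (1, 0, 1) at alpha = 0.5 gives traces (1, 0.5, 1.25)
  eps <- 0
  out <- numeric(3)
  for (t in 1:3) {
    eps <- eligibility_update(eps, c(1, 0, 1)[t], 0.5)
    out[t] <- eps
  }
  expect_equal(out, c(1, 0.5, 1.25))
  # alpha = 0: trace equals current activity
  expect_equal(eligibility_update(99, 0.7, 0), 0.7)
  # constant input converges to a / (1 - alpha)
  eps <- 0
  for (t in 1:200) eps <- eligibility_update(eps, 2, 0.8)
  expect_equal(eps, 2 / (1 - 0.8), tolerance = 1e-8)
})

test_that("e-prop gradients respect the regime and match exact gradients", {
  p <- toy_params(n_rnn = 5, n_input = 3, n_out = 2, n_granule = 4,
                  tau_windows = 0L, seed = 11)
  x1 <- array(rnorm(3 * 2 * 1), c(3, 2, 1))
  y1 <- array(rnorm(2 * 2 * 1), c(2, 2, 1))
  b1 <- toy_batch(x1, y1)
  traj1 <- run_trial(p, b1)
  l1 <- task_loss(traj1$z, y1, b1$loss_mask, "mse")

  expect_identical(eprop_gradient(traj1, l1$dz, p, "fixed_rnn"), list())
  expect_error(eprop_gradient(traj1, l1$dz, p, "everything"), "regime")

  # single-timestep trial: e-prop is the exact gradient (finite differences)
  got <- eprop_gradient(traj1, l1$dz, p, "fully_plastic")
  for (nm in c("W_ih", "W_Ch")) {
    fd <- fd_gradient(function(W) {
      p2 <- p; p2[[nm]] <- W
      task_loss(run_trial(p2, b1)$z, y1, b1$loss_mask, "mse")$loss
    }, p[[nm]])
    expect_equal(got[[nm]], fd, tolerance = 1e-5, label = nm)
  }

  # linear limit, T = 3: equals the truncated-BPTT-with-frozen-future oracle
  # computed by explicit unrolling with traces eps^t = sum_s alpha^(t-s) a^s.
  pl <- toy_params(n_rnn = 3, n_input = 2, n_out = 2, n_granule = 3,
                   tau_windows = 0L, seed = 13, alpha = 0.6)
  x <- array(rnorm(2 * 1 * 3), c(2, 1, 3))
  y <- array(rnorm(2 * 1 * 3), c(2, 1, 3))
  b <- toy_batch(x, y)
  traj <- run_trial(pl, b)
  l <- task_loss(traj$z, y, b$loss_mask, "mse")
  got <- eprop_gradient(traj, l$dz, pl, "fully_plastic")
  oracle <- matrix(0, 3, 2)
  for (t in 1:3) {
    eps_t <- Reduce(`+`, lapply(1:t, function(s) pl$alpha^(t - s) * x[, 1, s]))
    L_t <- (t(pl$W_rdt) %*% l$dz[, , t]) * (1 - traj$fh[, 1, t]^2)
    oracle <- oracle + L_t %*% t(eps_t)
  }
  expect_equal(got$W_ih, oracle, tolerance = 1e-10)
})

test_that("adam follows the bias-corrected recursion", {
  # zero gradient leaves the parameter unchanged
  st <- adam_step(NULL, 1.5, 0, eta = 0.1)
  expect_equal(st$param, 1.5)
  # constant gradient: first step is ~ -eta * sign(g)
  st <- adam_step(NULL, 0, 3, eta = 0.01)
  expect_equal(st$param, -0.01 * 3 / (sqrt(9) + 1e-8), tolerance = 1e-9)
  # two steps with known gradients match a hand-evaluated recursion
  g1 <- 2; g2 <- -1; eta <- 0.05
  st <- adam_step(NULL, 0, g1, eta)
  st <- adam_step(st$opt, st$param, g2, eta)
  m <- 0.9 * (0.1 * g1) + 0.1 * g2
  v <- 0.999 * (0.001 * g1^2) + 0.001 * g2^2
  m_hat <- m / (1 - 0.9^2); v_hat <- v / (1 - 0.999^2)
  expected <- (-eta * (0.1 * g1) / (1 - 0.9)) /
    (sqrt((0.001 * g1^2) / (1 - 0.999)) + 1e-8)
  expected <- expected - eta * m_hat / (sqrt(v_hat) + 1e-8)
  expect_equal(st$param, expected, tolerance = 1e-9)
})

test_that("a training session leaves frozen weights bitwise unchanged", {
  task <- ccl_task("line")
  p <- init_params(n_rnn = 10, n_input = 10, n_out = 2, n_granule = 30,
                   seed = 2)
  cfg <- learning_config(regime = "input_plastic", n_train = 50, n_test = 50)
  res <- train_session(p, task, cfg, seed = 5)
  # regime containment: W_hh and W_MF untouched, learned weights changed
  expect_identical(res$params$W_hh, p$W_hh)
  expect_identical(res$params$W_MF, p$W_MF)
  expect_false(identical(res$params$W_ih, p$W_ih))
  expect_false(identical(res$params$W_Ch, p$W_Ch))
  expect_false(identical(res$params$W_PF, p$W_PF))

  # eta = 0 changes nothing and the error trace is flat across repeats
  cfg0 <- learning_config(eta = 0, eta_rnn = 0, regime = "fully_plastic",
                          n_train = 30, n_test = 30)
  res0 <- train_session(p, task, cfg0, seed = 5)
  expect_equal(res0$params$W_PF, p$W_PF, tolerance = 1e-14)
  expect_equal(res0$params$W_ih, p$W_ih, tolerance = 1e-14)
  res0b <- train_session(p, task, cfg0, seed = 5)
  expect_identical(res0$trial_errors, res0b$trial_errors)
})
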