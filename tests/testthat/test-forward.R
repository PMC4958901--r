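spec4 <- model_spec("fwd", family = "D", linearity = "nonlinear",
                    gating_source = "preSMA")

test_that("zero input at rest is an exact fixed point of neural and BOLD states", {
  acq <- test_acq(n_volumes = 30)
  nb <- acq$n_volumes * acq$microtime_bins
  inp <- dcm_inputs(matrix(0, nb, 2, dimnames = list(NULL, c("task", "stop"))),
                    acq$dt)
  cp <- diag_coupling(spec4)
  z <- simulate_neural(spec4, cp, inp)
  expect_identical(max(abs(z)), 0)
  y <- simulate_bold(z, hemodynamic_params(4), acq)
  expect_identical(max(abs(y)), 0)
})

test_that("a decoupled region follows the scalar linear ODE closed form", {
  acq <- test_acq(n_volumes = 60, microtime_bins = 16)
  inp <- impulse_inputs(acq, bin = 40L)
  cp <- diag_coupling(spec4, self = -0.5, drive = "preSMA", gain = 1)
  z <- simulate_neural(spec4, cp, inp)
  # post-impulse state decays as exp(-0.5 t)
  z0 <- z[41, "preSMA"]
  expect_gt(z0, 0)
  idx <- 41:nrow(z)
  t_rel <- (idx - 41) * acq$dt
  expect_lt(max(abs(z[idx, "preSMA"] - z0 * exp(-0.5 * t_rel))), 1e-4)
  # untouched regions remain identically zero
  expect_identical(max(abs(z[, c("IFG", "STN", "M1")])), 0)
})

test_that("with B = D = 0 the propagator matches the matrix-exponential solution", {
  skip_if_not_installed("Matrix")
  acq <- test_acq(n_volumes = 40, microtime_bins = 8)
  nb <- acq$n_volumes * acq$microtime_bins
  u <- matrix(0, nb, 2, dimnames = list(NULL, c("task", "stop")))
  u[nb %/% 4 + seq_len(16), "task"] <- 1     # a 16-bin boxcar
  inp <- dcm_inputs(u, acq$dt)
  nm <- spec4$regions$names
  A <- matrix(0, 4, 4, dimnames = list(nm, nm))
  diag(A) <- -0.5
  A["STN", "IFG"] <- 0.4; A["STN", "preSMA"] <- 0.3; A["M1", "STN"] <- 0.35
  A["IFG", "preSMA"] <- 0.3; A["preSMA", "IFG"] <- 0.2
  C <- matrix(0, 4, 2, dimnames = list(nm, c("task", "stop")))
  C[c("preSMA", "IFG"), "task"] <- 1
  cp <- coupling_params(A, C = C, spec = spec4)
  z <- simulate_neural(spec4, cp, inp)
  # oracle: exact discrete propagation with expm on each constant-input bin
  Ainv <- solve(A)
  eAdt <- as.matrix(Matrix::expm(A * acq$dt))
  gain <- Ainv %*% (eAdt - diag(4))
  zk <- numeric(4)
  zora <- matrix(0, nb, 4)
  for (t in seq_len(nb)) {
    zora[t, ] <- zk
    zk <- as.numeric(eAdt %*% zk + gain %*% (C %*% u[t, ]))
  }
  expect_lt(max(abs(z - zora)), 1e-5)
})

test_that("silencing the gating source reproduces the bilinear-only trajectory bit for bit", {
  spec <- model_spec("gate", family = "A", linearity = "nonlinear",
                     gating_source = "preSMA")
  acq <- test_acq(n_volumes = 40)
  nb <- acq$n_volumes * acq$microtime_bins
  u <- matrix(0, nb, 2, dimnames = list(NULL, c("task", "stop")))
  u[seq(10, nb, 60), "task"] <- 1
  inp <- dcm_inputs(u, acq$dt)
  nm <- spec$regions$names
  A <- diag(-0.5, 4); dimnames(A) <- list(nm, nm)
  A["STN", "IFG"] <- 0.4
  C <- matrix(0, 4, 2, dimnames = list(nm, c("task", "stop")))
  C["IFG", "task"] <- 1          # nothing ever drives preSMA
  D <- array(0, c(4, 4, 4), dimnames = list(nm, nm, nm))
  D["STN", "IFG", "preSMA"] <- 0.7
  with_gate <- simulate_neural(spec, coupling_params(A, C = C, D = D), inp)
  without <- simulate_neural(spec, coupling_params(A, C = C), inp)
  expect_identical(with_gate, without)
})

test_that("a brief neural burst yields a single-peaked BOLD response with a 3-7 s lag", {
  acq <- test_acq(n_volumes = 30, microtime_bins = 16)
  nb <- acq$n_volumes * acq$microtime_bins
  z <- matrix(0, nb, 1)
  burst <- seq(1, 1 + round(1 / acq$dt))      # ~1 s unit burst at t = 0
  z[burst, 1] <- 1
  fine_acq <- acquisition(TR = acq$TR / 10, n_volumes = acq$n_volumes * 10,
                          microtime_bins = acq$microtime_bins)
  y <- simulate_bold(z, hemodynamic_params(1), acq)
  peak_vol <- which.max(y[, 1])
  peak_t <- (peak_vol - 1) * acq$TR
  expect_gt(peak_t, 3); expect_lt(peak_t, 7)
  # the response returns toward baseline
  expect_lt(abs(y[nrow(y), 1]), 0.1 * max(y[, 1]))

  # oracle: independent fine-step integration of the same balloon equations
  skip_if_not_installed("deSolve")
  cs <- balloon_constants()
  zfun <- stats::approxfun(seq(0, by = acq$dt, length.out = nb), z[, 1],
                           method = "linear", rule = 2)
  rhs <- function(t, x, p) {
    fv <- x[3]^(1 / cs$alpha)
    Ef <- 1 - (1 - cs$E0)^(1 / x[2])
    list(c(zfun(t) - 0.64 * x[1] - cs$gamma * (x[2] - 1),
           x[1],
           (x[2] - fv) / 2,
           (x[2] * Ef / cs$E0 - fv * x[4] / x[3]) / 2))
  }
  times <- seq(0, (acq$n_volumes - 1) * acq$TR, by = acq$TR)
  sol <- deSolve::lsoda(c(s = 0, f = 1, v = 1, q = 1), times, rhs, NULL,
                        rtol = 1e-9, atol = 1e-9)
  k1 <- 4.3 * cs$theta0 * cs$E0 * cs$TE
  k2 <- 1 * cs$r0 * cs$E0 * cs$TE
  k3 <- 1 - 1
  y_ref <- 100 * cs$V0 * (k1 * (1 - sol[, "q"]) +
                          k2 * (1 - sol[, "q"] / sol[, "v"]) +
                          k3 * (1 - sol[, "v"]))
  expect_lt(max(abs(y[, 1] - y_ref)), 1e-3 * max(abs(y_ref)))
})

test_that("doubling epsilon rescales the response without moving its peak", {
  acq <- test_acq(n_volumes = 30, microtime_bins = 16)
  nb <- acq$n_volumes * acq$microtime_bins
  z <- matrix(0, nb, 1)
  z[1:16, 1] <- 1
  y1 <- simulate_bold(z, hemodynamic_params(1, epsilon = 1), acq)
  y2 <- simulate_bold(z, hemodynamic_params(1, epsilon = 2), acq)
  expect_gt(abs(max(y2) - max(y1)), 0.01 * max(y1))
  t1 <- which.max(y1[, 1]); t2 <- which.max(y2[, 1])
  expect_lte(abs(t1 - t2) * acq$TR, acq$TR)   # within one volume
})

test_that("halving the microtime step changes predicted BOLD by < 1e-3 relative", {
  spec <- enumerate_models()[["NCp"]]
  pr <- default_priors(spec)
  theta <- setNames(numeric(nrow(pr$table)), pr$table$name)
  theta[c("A.IFG->STN", "C.task->preSMA", "C.task->IFG",
          "D.preSMA.IFG->STN", "C.stop->preSMA")] <- c(0.4, 0.6, 0.6, 0.5, 0.4)
  ys <- lapply(c(16, 32), function(mtb) {
    acq <- acquisition(TR = 2, n_volumes = 40, microtime_bins = mtb)
    nb <- acq$n_volumes * acq$microtime_bins
    u <- matrix(0, nb, 2)
    onsets <- seq(2.5, 70, by = 2.5)
    for (o in onsets) {
      b <- floor(o / acq$dt) + 1
      u[b:(b + round(1 / acq$dt) - 1), 1] <- 1
      if ((o %% 10) == 0) u[b:(b + round(1 / acq$dt) - 1), 2] <- 1
    }
    stopdcm:::fast_predict(spec, theta, pr$table, u, acq$dt,
                           stopdcm:::volume_sample_bins(acq),
                           balloon_constants(), 16)
  })
  rel <- max(abs(ys[[1]] - ys[[2]])) / max(abs(ys[[2]]))
  expect_lt(rel, 1e-3)
})

test_that("more negative self-connections never amplify the impulse response", {
  acq <- test_acq(n_volumes = 40)
  inp <- impulse_inputs(acq, bin = 3L)
  norms <- vapply(c(-0.4, -0.6, -0.9, -1.5), function(s) {
    cp <- diag_coupling(spec4, self = s)
    sqrt(sum(simulate_neural(spec4, cp, inp)^2))
  }, 0)
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("predict_timeseries is the exact composition of the two simulators and is deterministic", {
  acq <- test_acq(n_volumes = 30)
  inp <- impulse_inputs(acq, bin = 8L)
  cp <- diag_coupling(spec4)
  hemo <- hemodynamic_params(4)
  y1 <- predict_timeseries(spec4, cp, hemo, inp, acq)
  y2 <- simulate_bold(simulate_neural(spec4, cp, inp), hemo, acq, dt = inp$dt)
  expect_identical(y1, y2)
  expect_identical(y1, predict_timeseries(spec4, cp, hemo, inp, acq))
})

test_that("noise averaging converges to the noiseless prediction as draws grow", {
  acq <- test_acq(n_volumes = 30)
  inp <- impulse_inputs(acq, bin = 8L, value = 5)
  cp <- diag_coupling(spec4)
  y <- predict_timeseries(spec4, cp, hemodynamic_params(4), inp, acq)
  sd_n <- sd(y[, "preSMA"])      # SNR 1 on the driven region
  set.seed(99)
  noisy_mean <- function(ndraw) {
    acc <- 0
    for (i in seq_len(ndraw)) acc <- acc + (y + rnorm(length(y), sd = sd_n))
    acc / ndraw
  }
  dev50 <- max(abs(noisy_mean(50) - y))
  dev800 <- max(abs(noisy_mean(800) - y))
  expect_lt(dev800, dev50)           # shrinking deviation
  expect_lt(dev800, 4 * sd_n / sqrt(800) * sqrt(2 * log(length(y))))
})

test_that("unstable parameters raise an instability error naming the diagonal", {
  acq <- test_acq(n_volumes = 30)
  inp <- impulse_inputs(acq, bin = 2L)
  nm <- spec4$regions$names
  A <- diag(-0.5, 4); dimnames(A) <- list(nm, nm)
  A["IFG", "preSMA"] <- 3; A["preSMA", "IFG"] <- 3    # unstable frontal loop
  C <- matrix(0, 4, 2, dimnames = list(nm, c("task", "stop")))
  C["preSMA", "task"] <- 1
  cp <- coupling_params(A, C = C, spec = spec4)
  expect_error(simulate_neural(spec4, cp, inp), "diverged")
})

test_that("parameter containers validate their invariants", {
  expect_error(hemodynamic_params(2, decay = -1), "positive")
  expect_error(coupling_params(diag(0.1, 2), C = matrix(0, 2, 1)), "negative")
  spec <- enumerate_models()[["NAp"]]
  nm <- spec$regions$names
  A <- diag(-0.5, 4); dimnames(A) <- list(nm, nm)
  A["IFG", "preSMA"] <- 0.3      # outside family-A mask
  C <- matrix(0, 4, 2, dimnames = list(nm, c("task", "stop")))
  expect_error(coupling_params(A, C = C, spec = spec), "outside the model mask")
})
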