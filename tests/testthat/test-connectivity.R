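test_that("hilbert phase of a sinusoid advances at the carrier rate", {
  fs <- 256
  tt <- (0:1023) / fs
  ph <- hilbert_phase(cos(2 * pi * 10 * tt))
  d <- wrap_angle(diff(ph))[100:900]
  slope_hz <- mean(d) * fs / (2 * pi)
  expect_lt(abs(slope_hz - 10) / 10, 0.01)
})

test_that("cos/sin quadrature pair has a pi/2 circular-mean lag", {
  fs <- 256
  tt <- (0:1023) / fs
  p1 <- hilbert_phase(cos(2 * pi * 8 * tt))
  p2 <- hilbert_phase(sin(2 * pi * 8 * tt))
  d <- (p1 - p2)[100:900]
  cm <- Arg(mean(exp(1i * d)))
  expect_lt(abs(cm - pi / 2), 0.01)
})

test_that("analytic phase matches an independent direct-DFT construction", {
  set.seed(11)
  x <- bandpass_fir_zero_phase(rnorm(256), 8, 10, 256)
  ph <- hilbert_phase(x)
  zo <- oracle_analytic_dft(x)
  expect_lt(max(abs(wrap_angle(ph[20:230] - Arg(zo[20:230])))), 1e-6)
})

test_that("degenerate phase inputs are rejected", {
  expect_error(hilbert_phase(numeric(128)), "all-zero")
  expect_error(hilbert_phase(rnorm(32)), "64 samples")
})

test_that("PLV closed forms and the quadrature identity hold", {
  # constant lag of any size -> exactly 1
  phi <- runif(64, -pi, pi)
  expect_equal(compute_plv(phi, phi - 1.234), 1)
  # evenly spread phasors cancel
  k <- 0:7
  expect_lt(compute_plv(2 * pi * k / 8, numeric(8)), 1e-12)
  # complex-mean form equals the sin/cos quadrature form
  set.seed(2)
  d <- runif(1024, -pi, pi)
  quad <- sqrt(mean(sin(d))^2 + mean(cos(d))^2)
  expect_lt(abs(compute_plv(d, numeric(1024)) - quad), 1e-12)
  expect_error(compute_plv(1:4, 1:5), "lengths differ")
})

test_that("PLV is invariant to common phase offsets and amplitude", {
  fs <- 256
  tt <- (0:1023) / fs
  set.seed(3)
  x1 <- bandpass_fir_zero_phase(rnorm(1024), 8, 10, fs)
  x2 <- bandpass_fir_zero_phase(rnorm(1024), 8, 10, fs)
  base <- compute_plv(hilbert_phase(x1), hilbert_phase(x2))
  off <- compute_plv(hilbert_phase(x1) + 0.7, hilbert_phase(x2) + 0.7)
  expect_equal(off, base, tolerance = 1e-12)
  scaled <- compute_plv(hilbert_phase(5 * x1), hilbert_phase(0.1 * x2))
  expect_equal(scaled, base, tolerance = 1e-9)
})

test_that("epoch averaging is the arithmetic mean of per-epoch PLV", {
  # epoch 1: constant lag (PLV 1); epoch 2: full turn (PLV 0)
  ph <- array(0, dim = c(2, 8, 2))
  ph[1, , 1] <- 0.3; ph[2, , 1] <- 0.9
  ph[1, , 2] <- 2 * pi * (0:7) / 8; ph[2, , 2] <- 0
  P <- epoch_averaged_plv(ph)
  expect_equal(P$values[1, 2], 0.5, tolerance = 1e-12)
  expect_equal(P$n_epochs_averaged, 2)
  # identical coupling in every epoch: average equals single epoch
  ph1 <- array(rep(ph[, , 1], 3), dim = c(2, 8, 3))
  expect_equal(epoch_averaged_plv(ph1)$values,
               epoch_averaged_plv(ph[, , 1, drop = FALSE])$values)
})

test_that("surrogate pruning keeps locked pairs and drops null ones", {
  set.seed(8)
  phi <- runif(1024, -pi, pi)
  ph <- array(0, dim = c(2, 1024, 1))   # identical series on both channels
  ph[1, , 1] <- phi
  ph[2, , 1] <- phi
  obs <- epoch_averaged_plv(ph)
  pr <- surrogate_prune(obs, ph, M = 100, alpha = 0.05, seed = 4)
  expect_equal(pr$values[1, 2], obs$values[1, 2])  # retained, unscaled
  expect_lt(pr$p_surrogate[1, 2], 0.05)
  expect_equal(pr$p_surrogate[1, 2], 1 / 101)
  # observed PLV below every surrogate -> p = 1, zeroed
  fake <- obs; fake$values[] <- 0
  pr0 <- surrogate_prune(fake, ph, M = 100, alpha = 0.05, seed = 4)
  expect_equal(pr0$p_surrogate[1, 2], 1)
  expect_equal(pr0$values[1, 2], 0)
})

test_that("pruned entries are a subset of observed entries", {
  m <- demo_montage()
  plan <- coupling_plan(m, bands = "theta")
  rec <- generate_subject(plan, n_epochs = 3, seed = 6,
                          bands = eeg_bands("theta"),
                          return_phases = TRUE)
  ph <- band_phases(rec, "theta", "phases")
  obs <- epoch_averaged_plv(ph)
  pr <- surrogate_prune(obs, ph, M = 30, alpha = 0.05, seed = 2)
  kept <- pr$values != 0
  expect_true(all(pr$values[kept] == obs$values[kept]))
  expect_true(all(pr$values %in% c(0, obs$values)))
  expect_all_equal(pr$values, t(pr$values))
})

test_that("surrogate parameters are validated", {
  ph <- array(runif(2 * 128 * 1, -pi, pi), dim = c(2, 128, 1))
  obs <- epoch_averaged_plv(ph)
  expect_error(surrogate_prune(obs, ph, M = 10), "at least 20")
  expect_error(surrogate_prune(obs, ph, M = 20, alpha = 0.01),
               "cannot resolve")
  expect_error(surrogate_prune(obs, ph, M = 100, alpha = 0.7),
               "alpha")
})

test_that("edge tables carry labels, PLV and surrogate p-values", {
  ph <- array(runif(3 * 128, -pi, pi), dim = c(3, 128, 1),
              dimnames = list(c("A", "B", "C"), NULL, NULL))
  obs <- epoch_averaged_plv(ph)
  pr <- surrogate_prune(obs, ph, M = 20, alpha = 0.049, seed = 1)
  tab <- edge_table(pr)
  expect_equal(nrow(tab), 3)
  expect_named(tab, c("channel_i", "channel_j", "plv", "p_surrogate"))
  expect_equal(tab$channel_i, c("A", "A", "B"))
})
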