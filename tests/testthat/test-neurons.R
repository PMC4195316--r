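test_that("analytic membrane constants follow from the printed parameters", {
  p <- lif_params()
  expect_equal(membrane_time_constant(p), 5227 * 3 / 1000)
  expect_equal(rheobase(p), 1000 * (-41.8 + 71.5) / 5227)
})

test_that("subthreshold constant current produces no spikes", {
  p <- lif_params()
  tr <- simulate_neuron(p, const_drive(5.0))
  expect_length(tr$times, 0)
  expect_equal(measure_rates(tr)$mean, 0)
})

test_that("non-finite drive samples are rejected", {
  p <- lif_params()
  bad <- continuous_signal(c(rep(8, 100), NA, rep(8, 100)), 0.025, "pA")
  expect_error(simulate_neuron(p, bad), "non-finite")
  expect_error(measure_rates(spike_train(5, 0.025, 500), warmup = 1000),
               "warm-up")
})

test_that("a constant inhibitory conductance hyperpolarizes and lowers the rate", {
  p <- lif_params()
  r0 <- measure_rates(simulate_neuron(p, const_drive(9, dur = 5000)))$mean
  ri <- measure_rates(simulate_neuron(p, const_drive(9, dur = 5000),
                                      g_I = 0.1, E_I = -65))$mean
  expect_lt(ri, r0)
  expect_gt(ri, 0)
})

test_that("LIF constant-current ISIs match the closed form within one step", {
  p <- lif_params()
  dt <- 0.025
  for (I in c(6.5, 8, 12)) {
    tr <- simulate_neuron(p, const_drive(I, dur = 5000))
    isi <- diff(tr$times)
    # closed form computed independently from the membrane equation
    tau <- p$R * p$C / 1000
    T0 <- tau * log((I * p$R / 1000) / (I * p$R / 1000 - (p$V_th - p$E_R)))
    expect_lt(max(abs(isi - T0)), dt + 1e-9)
  }
})

test_that("LIF steady-state rate matches the closed-form f-I curve within 2%", {
  p <- lif_params()
  I_grid <- c(6, 8, 12, 16, 20)
  rates <- fI_curve(p, I_grid, duration = 5000)
  tau <- p$R * p$C / 1000
  closed <- 1000 / (tau * log((I_grid * p$R / 1000) /
                                (I_grid * p$R / 1000 - (p$V_th - p$E_R))))
  expect_lt(max(abs(rates - closed) / closed), 0.02)
  expect_true(all(diff(rates) >= 0))
  # just below rheobase: silent
  expect_equal(fI_curve(p, 5.6, duration = 3000), 0)
})

test_that("the spike delay is a pure shift of recorded spike times", {
  drive <- const_drive(9, dur = 3000)
  pd <- neuron_params("rif", delta_s = 4.85)
  p0 <- neuron_params("rif", delta_s = 0)
  t1 <- simulate_neuron(pd, drive)$times
  t0 <- simulate_neuron(p0, drive)$times
  k <- min(length(t0), length(t1))
  expect_equal(t1[1:k], t0[1:k] + 4.85)
})

test_that("rIF with g_b = 0 and no delay reproduces the LIF bit-identically", {
  x <- gen_bandlimited_gaussian(20, 10000, 0.025, seed = 2)
  drive <- continuous_signal(7.1 + 0.6 * x$samples, 0.025, "pA")
  p_lif <- lif_params()
  p_rif0 <- neuron_params("rif", g_b = 0, delta_s = 0)
  expect_identical(simulate_neuron(p_lif, drive)$times,
                   simulate_neuron(p_rif0, drive)$times)
})

test_that("splitting a drive into segments with carried-over state is exact", {
  x <- gen_bandlimited_gaussian(20, 6000, 0.025, seed = 9)
  drive <- continuous_signal(7.2 + 0.8 * x$samples, 0.025, "pA")
  p <- rif_params()
  whole <- simulate_neuron(p, drive)$times
  n <- length(drive$samples)
  d1 <- continuous_signal(drive$samples[1:(n / 2)], 0.025, "pA")
  d2 <- continuous_signal(drive$samples[(n / 2 + 1):n], 0.025, "pA")
  s1 <- simulate_neuron(p, d1, return_state = TRUE)
  s2 <- simulate_neuron(p, d2, state = s1$state)
  stitched <- c(s1$train$times, s2$times + n / 2 * 0.025)
  expect_equal(stitched, whole, tolerance = 1e-12)
})

test_that("spike times converge first-order in dt", {
  p <- rif_params()
  f <- 5
  devs <- vapply(c(0.05, 0.025), function(dt) {
    d1 <- continuous_signal(7 + 1.5 * gen_sinusoid(f, 1000, dt)$samples,
                            dt, "pA")
    d2 <- continuous_signal(7 + 1.5 * gen_sinusoid(f, 1000, dt / 2)$samples,
                            dt / 2, "pA")
    t1 <- simulate_neuron(p, d1)$times
    t2 <- simulate_neuron(p, d2)$times
    k <- min(length(t1), length(t2))
    c(first = abs(t1[1] - t2[1]), max = max(abs(t1[1:k] - t2[1:k])))
  }, numeric(2))
  # the first spike moves by less than one coarse step; the accumulated
  # deviation over the train scales down linearly with dt
  expect_lt(devs["first", 1], 0.05)
  expect_lt(devs["first", 2], 0.025)
  expect_lt(devs["max", 2], 0.75 * devs["max", 1])
})

test_that("the ideal encoder integrates rate exactly", {
  r <- continuous_signal(rep(40, 400000), 0.025, "spikes/s")
  tr <- simulate_ideal(r)
  expect_length(tr$times, 400)
  expect_equal(unique(round(diff(tr$times), 6)), 25)

  # spike count conserves the integrated rate for an arbitrary trace
  x <- short_noise(dur = 20000, dt = 0.025, seed = 12)
  R <- make_rate_signal(x, 40, 1)
  tr2 <- simulate_ideal(R)
  expected <- sum(pmax(R$samples, 0)) * R$dt / 1000
  expect_lt(abs(length(tr2$times) - floor(expected)), 2)
})

test_that("the ideal encoder recovers a slow sinusoidal rate", {
  dt <- 0.025
  n <- round(10000 / dt)
  t_ms <- (seq_len(n) - 1) * dt
  R <- continuous_signal(40 * (1 + sin(2 * pi * 1 * t_ms / 1000)), dt,
                         "spikes/s")
  tr <- simulate_ideal(R)
  binned <- bin_spikes(tr, 100)$samples * 10          # counts/100ms -> rate
  ref <- colMeans(matrix(R$samples[1:(4000 * 100)], nrow = 4000))
  expect_gt(cor(binned, ref), 0.95)
})

test_that("tonic-current calibration round-trips through the f-I curve", {
  p <- lif_params()
  for (F0 in c(20, 40, 80)) {
    I0 <- calibrate_tonic_current(p, F0)
    expect_gt(I0, rheobase(p))
    expect_rel_equal(fI_curve(p, I0), F0, 0.005)
  }
  expect_error(calibrate_tonic_current(p, 0), "positive")
})

test_that("modulation-amplitude calibration obeys its defining property", {
  p <- lif_params()
  I0 <- calibrate_tonic_current(p, 40)
  A1 <- calibrate_modulation_amplitude(p, I0, 0.1, 40)
  expect_rel_equal(fI_curve(p, I0 + A1), 44, 0.005)
  A2 <- calibrate_modulation_amplitude(p, I0, 1, 40)
  expect_gt(A2, A1)
  expect_error(calibrate_modulation_amplitude(p, I0, 0, 40), "positive")
})

test_that("measure_rates counts spikes per time after warm-up", {
  tr <- spike_train(seq(25, 10000, by = 25), 0.025, 10000)
  expect_equal(measure_rates(tr, warmup = 0)$mean, 40)
  expect_equal(measure_rates(spike_train(numeric(0), 0.025, 5000))$mean, 0)
})

test_that("low-rate population calibration hits the target F_eff distribution", {
  p <- lif_params()
  x <- gen_bandlimited_gaussian(20, 30000, 0.025, seed = 21)
  cal <- calibrate_population_lowrate(p, 12, 4, 2, A_I = 2, x,
                                      seed = 3, calib_duration = 30000,
                                      tol = 0.05)
  expect_true(all(cal$targets >= 0))
  ok <- cal$targets > 0.5
  expect_lt(max(abs(cal$realized[ok] - cal$targets[ok]) / cal$targets[ok]),
            0.1)
  expect_lt(abs(mean(cal$realized) - 4), 0.5)
  expect_error(calibrate_population_lowrate(p, 4, -1, 2, 2, x),
               "unreachable")
})
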