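test_that("the sampling-rate filter conserves spikes and handles edge cases", {
  tr <- spike_train(c(10, 20, 30), 0.025, 100)
  y <- sampling_rate_filter(tr)
  expect_equal(sum(y$samples), 3)
  expect_true(all(y$samples %in% c(0, 1)))
  expect_equal(sum(sampling_rate_filter(spike_train(numeric(0), 0.025,
                                                    100))$samples), 0)
  # two spikes in one (coarse) bin cap at 1 with a warning
  expect_warning(yc <- sampling_rate_filter(spike_train(c(10.1, 10.4), 0.025,
                                                        100), dt = 1),
                 "capped")
  expect_equal(max(yc$samples), 1)
})

test_that("the alpha filter peaks at tau, is linear, and has unit integral", {
  tr <- spike_train(500, 1, 3000)
  y <- alpha_filter(tr, tau_alpha = 100, dt = 1)
  expect_equal(which.max(y$samples) - 500, 100, tolerance = 0.02)
  expect_equal(sum(y$samples) * y$dt, 1, tolerance = 0.01)

  a <- spike_train(c(100, 300), 1, 3000)
  b <- spike_train(c(200, 700), 1, 3000)
  ab <- spike_train(sort(c(a$times, b$times)), 1, 3000)
  expect_equal(alpha_filter(ab)$samples,
               alpha_filter(a)$samples + alpha_filter(b)$samples,
               tolerance = 1e-10)
})

test_that("instantaneous rate is 1/ISI attached at the later spike", {
  tr <- spike_train(seq(25, 1000, by = 25), 0.025, 1000)
  ir <- instantaneous_rate(tr)
  expect_true(all(abs(ir$rate - 40) < 1e-9))
  expect_equal(nrow(instantaneous_rate(spike_train(25, 0.025, 100))), 0)
  expect_true(all(ir$rate > 0 & is.finite(ir$rate)))
})

test_that("welch_csd satisfies the self-coherence and independence identities", {
  x <- short_noise(cutoff = 100, dur = 60000, seed = 13)
  sp <- welch_csd(x, x)
  expect_equal(Mod(sp$Pxy)^2, sp$Pxx * sp$Pyy, tolerance = 1e-10)
  expect_true(all(sp$Pxx >= 0))

  y <- short_noise(cutoff = 100, dur = 60000, seed = 14)
  spi <- welch_csd(x, y)
  coh <- Mod(spi$Pxy)^2 / (spi$Pxx * spi$Pyy)
  expect_lt(mean(coh[spi$freq <= 100]), 0.05)

  # white-ish input: flat auto-spectrum at coarse resolution
  spf <- welch_csd(x, x, spectral_settings(seg_s = 0.2))
  keep <- spf$freq > 5 & spf$freq < 95
  expect_lt(max(abs(10 * log10(spf$Pxx[keep] / mean(spf$Pxx[keep])))), 1)
})

test_that("a scaled identity system has flat gain and zero phase", {
  x <- short_noise(cutoff = 50, dur = 40000, seed = 15)
  y <- continuous_signal(2 * x$samples, x$dt, x$units)
  tf <- direct_transfer_function(x, y, spectral_settings(band = c(0.5, 50)))
  expect_lt(max(abs(tf$gain_db)), 1e-8)
  expect_lt(max(abs(tf$phase_deg)), 1e-6)
  expect_equal(mean(tf$raw_gain), 2, tolerance = 1e-9)
})

test_that("a known one-pole filter is recovered within 0.5 dB and 3 degrees", {
  fx <- make_fixture("lti_known")
  x <- fx$results$signals$x
  y <- fx$results$signals$y
  st <- spectral_settings(band = c(0.5, 80))
  tf <- direct_transfer_function(x, y, st)
  H <- fx$results$b0 / (1 - fx$results$a1 *
                          exp(-2i * pi * tf$freq * x$dt / 1000))
  gain_true_db <- 20 * log10(Mod(H) / Mod(H)[1])
  phase_true <- mfrsim:::unwrap_phase(Arg(H)) * 180 / pi
  expect_lt(max(abs(tf$gain_db - gain_true_db)), 0.5)
  expect_lt(max(abs(tf$phase_deg - phase_true)), 3)
})

test_that("sinusoid fit matches the analytic LIF response at low frequency", {
  p <- lif_params()
  F0 <- 40
  f <- 5
  I0 <- calibrate_tonic_current(p, F0)
  A_I <- calibrate_modulation_amplitude(p, I0, 0.1, F0)
  drive <- continuous_signal(I0 + A_I * gen_sinusoid(f, 60000)$samples,
                             0.025, "pA")
  tr <- simulate_neuron(p, drive)
  fit <- sinusoid_fit_transfer(tr, f, A_I)
  an <- analytic_lif_transfer(p, F0, c(0.5, f))
  expect_rel_equal(fit$gain, an$raw_gain[2], 0.05)
  expect_lt(abs(fit$phase_deg - an$phase_deg[2]), 6)
  expect_rel_equal(fit$offset, F0, 0.02)
})

test_that("sinusoid fit returns ~zero amplitude for an unmodulated train", {
  p <- lif_params()
  tr <- simulate_neuron(p, const_drive(7.13, dur = 30000))
  fit <- sinusoid_fit_transfer(tr, 5, A_I = 1)
  expect_lt(fit$amplitude, 0.1)
  expect_warning(sinusoid_fit_transfer(spike_train(c(1, 2), 0.025, 100), 5, 1),
                 "too few")
})

test_that("the quasi-static limit of the sinusoid fit equals the f-I slope", {
  p <- lif_params()
  F0 <- 40
  I0 <- calibrate_tonic_current(p, F0)
  A_I <- calibrate_modulation_amplitude(p, I0, 0.1, F0)
  drive <- continuous_signal(I0 + A_I * gen_sinusoid(0.5, 40000)$samples,
                             0.025, "pA")
  fit <- sinusoid_fit_transfer(simulate_neuron(p, drive), 0.5, A_I)
  dc <- (fI_curve(p, I0 + 0.1, duration = 8000) -
           fI_curve(p, I0 - 0.1, duration = 8000)) / 0.2
  expect_rel_equal(fit$gain, dc, 0.1)
})

test_that("analytic LIF transfer has DC normalization and carrier resonances", {
  p <- lif_params()
  tf <- analytic_lif_transfer(p, 40, c(0.5, 1, 2, 5, 10, 20, 39.9, 40.5))
  expect_lt(abs(tf$gain_db[1]), 0.1)
  # resonance lobe near the carrier rate dwarfs the low-frequency gain
  expect_gt(tf$raw_gain[7], 10 * tf$raw_gain[1])
})

test_that("direct estimate agrees with the analytic LIF response below 20 Hz", {
  p <- lif_params()
  F0 <- 40
  dt <- 0.025
  x <- gen_bandlimited_gaussian(20, 90000, dt, seed = 16)
  I0 <- calibrate_tonic_current(p, F0)
  A_I <- calibrate_modulation_amplitude(p, I0, 0.1, F0)
  tr <- mfrsim:::sim_if_raw(p, x$samples, 0, A_I, 0, I0,
                            length(x$samples), dt)
  xa <- decimate_signal(x, 4)
  ya <- bin_spikes(tr, 0.1)
  tf <- direct_transfer_function(xa, ya, spectral_settings(band = c(0.5, 18)))
  an <- analytic_lif_transfer(p, F0, tf$freq)
  expect_lt(max(abs(tf$gain_db - an$gain_db)), 1)
})

test_that("sinusoid fitting still returns finite gain above Nyquist where VAF collapses", {
  p <- lif_params()
  F0 <- 40
  f <- 35
  I0 <- calibrate_tonic_current(p, F0)
  A_I <- calibrate_modulation_amplitude(p, I0, 0.1, F0)
  drive <- continuous_signal(I0 + A_I * gen_sinusoid(f, 60000)$samples,
                             0.025, "pA")
  tr <- simulate_neuron(p, drive)
  fit <- sinusoid_fit_transfer(tr, f, A_I)
  expect_true(is.finite(fit$gain) && fit$gain > 0)

  # ...whereas the coherence-based VAF at 35 Hz under broadband drive is ~0
  x <- gen_bandlimited_gaussian(450, 60000, 1, seed = 17)
  trn <- mfrsim:::sim_if_raw(p, x$samples, 0, A_I, 0, I0,
                             length(x$samples), 1)
  v <- vaf_spectrum(x, bin_spikes(trn, 1), band = c(30, 40))
  expect_lt(v$vaf[v$freq == 35], 10)
})
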