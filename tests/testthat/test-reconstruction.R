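test_that("the Wiener filter is the identity for y = x and inverts a pure delay", {
  x <- short_noise(cutoff = 40, dur = 60000, seed = 18)
  K <- wiener_filter(x, x, spectral_settings(band = c(0.5, 45)))
  expect_lt(max(Mod(K$K[K$in_band] - 1)), 1e-6)
  expect_true(all(K$K[!K$in_band] == 0))

  fx <- make_fixture("delay_pair")
  xd <- fx$results$signals$x
  yd <- fx$results$signals$y
  Kd <- wiener_filter(xd, yd, spectral_settings(band = c(0.5, 95)))
  f <- Kd$freq[Kd$in_band]
  ph <- mfrsim:::unwrap_phase(Arg(Kd$K[Kd$in_band]))
  # phase advance 2*pi*f*d compensates the delay
  slope_ms <- 1000 * stats::coef(stats::lm(ph ~ f))[2] / (2 * pi)
  expect_rel_equal(slope_ms, fx$results$delay_ms, 0.02)
  expect_lt(max(abs(Mod(Kd$K[Kd$in_band]) - 1)), 0.05)
})

test_that("the band-limited Wiener kernel is sinc-like with finite support", {
  dt <- 1
  x <- gen_bandlimited_gaussian(20, 120000, dt, seed = 19)
  tr <- simulate_ideal(make_rate_signal(x, 40, 1))
  y <- bin_spikes(tr, dt)
  K <- wiener_filter(x, y, spectral_settings(band = c(0.5, 25)))
  kern <- wiener_kernel(K, span_s = 8)
  # energy concentrated within +/- 2 s of lag zero
  inside <- abs(kern$lag_ms) <= 2000
  expect_lt(sum(kern$kernel[!inside]^2) / sum(kern$kernel^2), 0.01)
  # oscillation at the cutoff frequency: first zero crossing near 1/(2*cutoff)
  core <- kern[kern$lag_ms >= 0 & kern$lag_ms <= 100, ]
  first_zero <- core$lag_ms[which(diff(sign(core$kernel)) != 0)[1]]
  expect_lt(abs(first_zero - 25), 6)
})

test_that("reconstruction with the identity filter returns the band-passed input", {
  x <- short_noise(cutoff = 30, dur = 60000, seed = 20)
  K <- wiener_filter(x, x, spectral_settings(band = c(0.5, 35)))
  xe <- reconstruct(x, K)
  # reference: x brick-wall filtered to the reconstruction band
  n <- length(x$samples)
  f <- (seq_len(n) - 1) * 1000 / n
  f <- pmin(f, 1000 - f)
  X <- stats::fft(x$samples)
  X[f < 0.5 | f > 35] <- 0
  xb <- Re(stats::fft(X, inverse = TRUE)) / n
  core <- 2001:(n - 2000)
  expect_gt(cor(xe$samples[core], xb[core]), 0.999)
})

test_that("reconstruction error variance matches the Wiener identity", {
  # output = input + independent in-band noise: VAF and the realized
  # reconstruction error must agree through (1 - VAF) * var(x)
  x <- short_noise(cutoff = 30, dur = 120000, seed = 22)
  ns <- short_noise(cutoff = 30, dur = 120000, seed = 23)
  y <- continuous_signal(x$samples + 0.7 * ns$samples, x$dt, x$units)
  st <- spectral_settings(band = c(0.5, 30))
  v <- vaf_spectrum(x, y, st, band = c(0.5, 30))
  K <- wiener_filter(x, y, st)
  xe <- reconstruct(y, K)
  core <- 4001:(length(x$samples) - 4000)
  err <- stats::var(xe$samples[core] - x$samples[core])
  expect_rel_equal(err, (1 - v$mean_vaf / 100) * stats::var(x$samples[core]),
                   0.1)
  # and the analytic coherence of signal-plus-noise: 1/(1 + 0.49)
  expect_rel_equal(v$mean_vaf / 100, 1 / 1.49, 0.05)
})

test_that("VAF is 100% for identical signals and ~0 for independent ones", {
  x <- short_noise(cutoff = 20, dur = 120000, seed = 24)
  v1 <- vaf_spectrum(x, x, band = c(0.5, 20))
  expect_true(all(v1$vaf > 99.999))
  y <- short_noise(cutoff = 20, dur = 120000, seed = 25)
  v0 <- vaf_spectrum(x, y, band = c(0.5, 20))
  expect_lt(v0$mean_vaf, 5)
})

test_that("VAF is invariant to scaling and to linear filtering of the output", {
  dt <- 1
  x <- gen_bandlimited_gaussian(20, 120000, dt, seed = 26)
  tr <- simulate_ideal(make_rate_signal(x, 40, 1))
  y <- bin_spikes(tr, dt)
  v <- vaf_spectrum(x, y, band = c(0.5, 20))

  ys <- continuous_signal(3.7 * y$samples, dt, y$units)
  xs <- continuous_signal(0.2 * x$samples, dt, x$units)
  expect_equal(vaf_spectrum(xs, ys, band = c(0.5, 20))$vaf, v$vaf,
               tolerance = 1e-10)
  ya <- alpha_filter(tr, tau_alpha = 100, dt = dt)

  # coherence invariance under the alpha filter (an LTI map of y); the
  # filter's ~200-ms group delay requires segments long enough that the
  # delay is a negligible fraction of the window
  st <- spectral_settings(seg_s = 16)
  v16 <- vaf_spectrum(x, y, st, band = c(0.5, 20))
  va <- vaf_spectrum(x, ya, st, band = c(0.5, 20))
  expect_lt(max(abs(va$vaf - v16$vaf)), 1)
})

test_that("population output is linear and antisymmetric under sub-population swap", {
  tr <- spike_train(c(10, 30, 50), 1, 100)
  trains <- list(tr, tr, tr)
  y3 <- population_output(trains, signs = 1)
  expect_equal(y3$samples, 3 * population_output(tr)$samples)

  t2 <- spike_train(c(20, 40), 1, 100)
  ypp <- population_output(list(tr, t2), signs = c(1, -1))
  yswap <- population_output(list(tr, t2), signs = c(-1, 1))
  expect_equal(ypp$samples, -yswap$samples)
})

test_that("a single encoder transmits nothing above its carrier rate (Nyquist property)", {
  dt <- 1
  # broadband input; 240 s so the coherence-estimator tail is small
  x <- gen_bandlimited_gaussian(450, 240000, dt, seed = 27)
  tr <- simulate_ideal(make_rate_signal(x, 40, 1))
  v <- vaf_spectrum(x, bin_spikes(tr, dt), band = c(40.5, 200))
  expect_lt(max(v$vaf), 10)
})

test_that("mean VAF is non-decreasing in population size for the encoder", {
  vals <- vapply(c(1, 10, 40), function(N) {
    cfg <- experiment_config("encoder", N = N, F0in = 40, a = 1, cutoff = 20,
                             duration_s = 40)
    run_experiment(cfg, 5)$mean_vaf
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})
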