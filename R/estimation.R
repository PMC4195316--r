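#' Spectral estimation settings
#'
#' Welch's average-periodogram settings: Hann-windowed segments of
#' `seg_s` seconds with fractional overlap `overlap`, per-segment mean
#' removal, giving a frequency resolution of `1/seg_s` Hz.  The default 2-s
#' segments give the 0.5-Hz resolution at which transfer functions and VAF
#' spectra are evaluated, over the analysis band 0.5-200 Hz.
#'
#' @param seg_s segment length in seconds.
#' @param overlap fractional overlap between consecutive segments.
#' @param band analysis band `c(f_min, f_max)` in Hz.
#' @export
spectral_settings <- function(seg_s = 2, overlap = 0.5, band = c(0.5, 200)) {
  stopifnot(seg_s > 0, overlap >= 0, overlap < 1, length(band) == 2,
            band[1] > 0, band[2] > band[1])
  structure(list(seg_s = seg_s, overlap = overlap, band = band),
            class = "spectral_settings")
}

#' Sampling-rate filter: spike train to binary signal on the simulation grid
#'
#' The discrete approximation of a delta-function filter: a rectangular
#' window of one simulation step, so each bin containing a spike is 1 and all
#' others are 0.  This is the assumption-free conversion used for direct
#' transfer-function estimation.
#'
#' @param train a [spike_train()].
#' @param dt grid step (ms); defaults to the train's producing step.
#' @return a `continuous_signal` of 0/1 values.
#' @export
sampling_rate_filter <- function(train, dt = train$dt) {
  stopifnot(inherits(train, "spike_train"))
  n <- round(train$duration / dt)
  y <- numeric(n)
  if (length(train$times)) {
    idx <- pmin(pmax(ceiling(train$times / dt), 1), n)
    if (anyDuplicated(idx)) {
      warning("multiple spikes fell into one bin; bin value capped at 1")
      idx <- unique(idx)
    }
    y[idx] <- 1
  }
  continuous_signal(y, dt, "dimensionless")
}

#' Bin spike counts onto a coarser analysis grid
#'
#' Spike counts per bin of width `bin_ms`; the bin-summed equivalent of the
#' sampling-rate filter, used to bring spike outputs onto the spectral
#' analysis grid (all content below the analysis band is preserved).
#'
#' @param train a [spike_train()].
#' @param bin_ms bin width (ms).
#' @export
bin_spikes <- function(train, bin_ms = 1) {
  stopifnot(inherits(train, "spike_train"))
  n <- round(train$duration / bin_ms)
  cnt <- tabulate(pmin(pmax(ceiling(train$times / bin_ms), 1), n), nbins = n)
  continuous_signal(as.numeric(cnt), bin_ms, "dimensionless")
}

#' Alpha-function synaptic filter
#'
#' Convolves the spike train with the alpha function
#' `(t/tau^2) exp(-t/tau)` for `t >= 0`, normalized so that the integral per
#' spike equals 1; a model of the conversion of spikes into postsynaptic
#' potential changes.
#'
#' @param train a [spike_train()].
#' @param tau_alpha alpha-function time constant (ms).
#' @param dt output grid step (ms); defaults to 1 ms.
#' @return a `continuous_signal`.
#' @export
alpha_filter <- function(train, tau_alpha = 100, dt = 1) {
  stopifnot(inherits(train, "spike_train"), tau_alpha > 0)
  y <- bin_spikes(train, dt)$samples
  # 20 tau support: the truncation discontinuity otherwise leaves a spectral
  # floor that masks the filter's genuine high-frequency response
  tk <- seq(0, 20 * tau_alpha, by = dt)
  k <- (tk / tau_alpha^2) * exp(-tk / tau_alpha)
  k <- k / (sum(k) * dt)                     # exact unit integral per spike
  out <- convolve_open(y, k) * dt
  continuous_signal(out[seq_along(y)], dt, "dimensionless")
}

# Linear ("open") convolution via FFT.
#' @noRd
convolve_open <- function(x, k) {
  n <- length(x) + length(k) - 1
  nf <- stats::nextn(n, c(2, 3, 5))
  Re(stats::fft(stats::fft(c(x, numeric(nf - length(x)))) *
                  stats::fft(c(k, numeric(nf - length(k)))),
                inverse = TRUE))[seq_len(n)] / nf
}

#' Instantaneous firing rate from inter-spike intervals
#'
#' Attaches the rate `1/(t_i - t_{i-1})` (spikes/s) at each spike time `t_i`.
#'
#' @param train a [spike_train()].
#' @return data frame with columns `time` (ms) and `rate` (spikes/s).
#' @export
instantaneous_rate <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  tt <- train$times
  if (length(tt) < 2)
    return(data.frame(time = numeric(0), rate = numeric(0)))
  data.frame(time = tt[-1], rate = 1000 / diff(tt))
}

#' Transfer-function estimate by sinusoidal fitting
#'
#' The classical single-frequency method: a least-squares fit of
#' `c + A sin(2 pi f t + phi)` to the instantaneous-rate points, with the
#' fit frequency fixed at the known input modulation frequency.  Its defining
#' assumption -- prior knowledge of `f` -- is also its weakness: above the
#' Nyquist frequency of the spike code the fit still returns a finite gain
#' although no observer without that prior could reconstruct the signal.
#'
#' The rate sample `1/ISI` is attached at the midpoint of its interval for
#' the fit (attaching at the closing spike would bias the phase by half an
#' ISI).
#'
#' @param train a [spike_train()] from a sinusoidally modulated run.
#' @param f input modulation frequency (Hz).
#' @param A_I input modulation amplitude (pA).
#' @param warmup initial interval discarded (ms).
#' @return list with `gain` (spikes/s per pA), `phase_deg` (degrees, lags
#'   negative), `amplitude` (spikes/s) and `offset` (spikes/s).
#' @export
sinusoid_fit_transfer <- function(train, f, A_I, warmup = 1000) {
  ir <- instantaneous_rate(train)
  ir$time <- ir$time - 500 / ir$rate           # midpoint of the ISI (ms)
  ir <- ir[ir$time > warmup, ]
  if (nrow(ir) < 3) {
    warning("too few spikes for a sinusoid fit; returning NA")
    return(list(gain = NA_real_, phase_deg = NA_real_,
                amplitude = NA_real_, offset = NA_real_))
  }
  w <- 2 * pi * f * ir$time / 1000
  fit <- stats::lm.fit(cbind(1, sin(w), cos(w)), ir$rate)
  cf <- fit$coefficients
  A <- sqrt(cf[2]^2 + cf[3]^2)
  phi <- atan2(cf[3], cf[2]) * 180 / pi      # relative to sin(2 pi f t)
  phi <- ((phi + 180) %% 360) - 180
  list(gain = unname(A / A_I), phase_deg = unname(phi),
       amplitude = unname(A), offset = unname(cf[1]))
}

#' Welch auto- and cross-spectral densities
#'
#' Averaged periodograms over Hann-windowed, mean-removed, overlapping
#' segments.  `Pxy` uses the convention `conj(X) * Y`, so `Pxy/Pxx` is the
#' transfer function from `x` to `y`; `Pyx = conj(Pxy)`.
#'
#' @param x,y `continuous_signal`s on the same grid.
#' @param settings a [spectral_settings()] object.
#' @return list with `freq` (Hz, DC excluded), `Pxx`, `Pyy` (real),
#'   `Pxy` (complex), number of segments `K` and the grid step `dt`.
#' @export
welch_csd <- function(x, y, settings = spectral_settings()) {
  stopifnot(inherits(x, "continuous_signal"), inherits(y, "continuous_signal"))
  if (abs(x$dt - y$dt) > 1e-12 || length(x$samples) != length(y$samples))
    stop("'x' and 'y' must share one grid")
  fs <- 1000 / x$dt
  L <- round(settings$seg_s * fs)
  n <- length(x$samples)
  if (n < L) stop("signal shorter than one segment")
  step <- max(1, round(L * (1 - settings$overlap)))
  starts <- seq(1, n - L + 1, by = step)
  if (length(starts) < 2)
    warning("fewer than 2 Welch segments; spectral estimates are degenerate")
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(L) - 1) / L)
  U <- sum(w^2) * fs                          # density normalization
  nf <- L %/% 2
  Pxx <- Pyy <- numeric(nf)
  Pxy <- complex(nf)
  for (s in starts) {
    xs <- x$samples[s:(s + L - 1)]
    ys <- y$samples[s:(s + L - 1)]
    X <- stats::fft((xs - mean(xs)) * w)[2:(nf + 1)]
    Y <- stats::fft((ys - mean(ys)) * w)[2:(nf + 1)]
    Pxx <- Pxx + Re(X * Conj(X))
    Pyy <- Pyy + Re(Y * Conj(Y))
    Pxy <- Pxy + Conj(X) * Y
  }
  K <- length(starts)
  list(freq = (seq_len(nf)) * fs / L,
       Pxx = Pxx / (K * U), Pyy = Pyy / (K * U), Pxy = Pxy / (K * U),
       K = K, dt = x$dt)
}

# Phase unwrapping (radians).
#' @noRd
unwrap_phase <- function(p) {
  d <- diff(p)
  p + c(0, cumsum(-2 * pi * round(d / (2 * pi))))
}

# Transfer function from precomputed Welch spectra.
#' @noRd
tf_from_spectra <- function(sp, band, power_tol = 1e-12) {
  keep <- sp$freq >= band[1] & sp$freq <= band[2] &
    sp$Pxx > power_tol * max(sp$Pxx)
  f <- sp$freq[keep]
  Tf <- sp$Pxy[keep] / sp$Pxx[keep]
  gain <- Mod(Tf)
  structure(list(freq = f, T = Tf,
                 gain_db = 20 * log10(gain / gain[1]),
                 phase_deg = unwrap_phase(Arg(Tf)) * 180 / pi,
                 raw_gain = gain),
            class = "transfer_function")
}

#' Direct transfer-function estimate from input and spiking output
#'
#' `T(f) = Pxy(f) / Pxx(f)` on the analysis band, from Welch spectra of the
#' input signal and the (sampling-rate-filtered) spiking output.  Gain is
#' normalized to unity (0 dB) at the lowest analysis frequency and reported
#' in dB; phase is unwrapped and reported in degrees with lags negative.
#'
#' @param x input `continuous_signal`.
#' @param y output `continuous_signal` on the same grid.
#' @param settings a [spectral_settings()] object.
#' @return object of class `transfer_function` with `freq`, `T` (complex),
#'   `gain_db` (normalized), `phase_deg`, `raw_gain`.
#' @export
direct_transfer_function <- function(x, y, settings = spectral_settings()) {
  tf_from_spectra(welch_csd(x, y, settings), settings$band)
}

#' @export
print.transfer_function <- function(x, ...) {
  cat(sprintf("<transfer_function> %d bins, %.2f-%.2f Hz\n",
              length(x$freq), min(x$freq), max(x$freq)))
  invisible(x)
}

#' @export
plot.transfer_function <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$freq, x$gain_db, type = "l", log = "x",
                 xlab = "frequency (Hz)", ylab = "gain (dB)", ...)
  graphics::plot(x$freq, x$phase_deg, type = "l", log = "x",
                 xlab = "frequency (Hz)", ylab = "phase (deg)", ...)
  invisible(x)
}

#' Export a transfer function as CSV
#' @param tf a `transfer_function`.
#' @param path file path.
#' @export
write_transfer_csv <- function(tf, path) {
  utils::write.csv(data.frame(frequency_hz = tf$freq, gain_db = tf$gain_db,
                              phase_deg = tf$phase_deg), path,
                   row.names = FALSE)
  invisible(path)
}

#' Analytic rate-modulation transfer function of the noise-free LIF
#'
#' Closed-form linear response of the instantaneous ensemble rate of a
#' deterministic leaky integrate-and-fire neuron to small sinusoidal current
#' modulation around the tonic current that gives carrier rate `F0`
#' (the classical ensemble-density derivation).  With `theta = V_th - E_R`,
#' `tau = RC`, unperturbed period `T0 = 1/F0`, supra-rheobase current
#' `alpha = I0 - theta/R` and `beta = I0 exp(-T0/tau)`:
#' \deqn{T(\omega) = \frac{i\omega r_0}{\alpha e^{i\omega T_0} - \beta}\cdot
#'       \frac{e^{i\omega T_0} - e^{-T_0/\tau}}{1/\tau + i\omega}}
#' It has infinite resonance peaks at multiples of the carrier rate and tends
#' to the slope of the f-I curve as `f -> 0`.  Used as an independent oracle
#' for the estimation methods.
#'
#' @param params a `neuron_params` object (LIF).
#' @param F0 carrier rate (spikes/s).
#' @param f_grid frequencies at which to evaluate (Hz).
#' @return object of class `transfer_function` (raw gain in
#'   spikes/s per pA before normalization).
#' @export
analytic_lif_transfer <- function(params, F0, f_grid) {
  stopifnot(params$model == "lif")
  tau <- membrane_time_constant(params)       # ms
  theta <- params$V_th - params$E_R           # mV
  T0 <- 1000 / F0                             # ms
  I0 <- 1000 * theta / params$R / (1 - exp(-T0 / tau))  # pA
  alpha <- I0 - rheobase(params)              # pA
  beta <- I0 * exp(-T0 / tau)
  w <- 2 * pi * f_grid / 1000                 # rad/ms
  j0 <- (exp(1i * w * T0) - exp(-T0 / tau)) / (1 / tau + 1i * w)
  Tf <- (1i * w * (1 / T0) * j0) / (alpha * exp(1i * w * T0) - beta)
  Tf <- Tf * 1000                             # spikes/ms -> spikes/s per pA
  # f -> 0 limit (0/0 above): slope of the rate-current relation
  dc <- tau * (1 - exp(-T0 / tau)) / (T0^2 * alpha) * 1000
  Tf[w == 0] <- dc
  gain <- Mod(Tf)
  structure(list(freq = f_grid, T = Tf,
                 gain_db = 20 * log10(gain / gain[1]),
                 phase_deg = unwrap_phase(Arg(Tf)) * 180 / pi,
                 raw_gain = gain, I0 = I0),
            class = "transfer_function")
}
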