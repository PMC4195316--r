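#' Ideal-observer Wiener reconstruction filter
#'
#' The non-causal linear filter `K(f) = Pyx(f)/Pyy(f)` that minimizes the
#' mean-squared error of reconstructing the input `x` from the output `y`.
#' `K` is set to zero at frequencies where the input has (numerically) no
#' power -- outside the input band there is nothing to reconstruct and the
#' division would amplify estimation noise.
#'
#' @param x input `continuous_signal`.
#' @param y output `continuous_signal` on the same grid.
#' @param settings a [spectral_settings()] object.
#' @param power_tol bins with `Pxx < power_tol * max(Pxx)` are zeroed.
#' @return object of class `wiener_filter`: `freq`, complex `K`, logical
#'   `in_band`, and the spectra used.
#' @export
wiener_filter <- function(x, y, settings = spectral_settings(),
                          power_tol = 1e-12) {
  sp <- welch_csd(x, y, settings)
  in_band <- sp$freq >= settings$band[1] & sp$freq <= settings$band[2] &
    sp$Pxx > power_tol * max(sp$Pxx)
  K <- Conj(sp$Pxy) / sp$Pyy
  K[!in_band] <- 0
  structure(list(freq = sp$freq, K = K, in_band = in_band, spectra = sp),
            class = "wiener_filter")
}

#' Time-domain kernel of a Wiener filter
#'
#' Inverse transform of `K(f)` (Hermitian completion), centred at lag zero.
#' For band-limited input the kernel approaches a sinc band-pass
#' reconstruction function with finite temporal support, so a causal variant
#' exists by delaying.
#'
#' @param K a `wiener_filter`.
#' @param span_s half-width of the lag range (s); the frequency grid is
#'   refined so the inverse transform covers `c(-span_s, span_s)`.
#' @return data frame with `lag_ms` and `kernel`, centred at lag zero.
#' @export
wiener_kernel <- function(K, span_s = 8) {
  df0 <- K$freq[1]
  df <- 1 / (2 * span_s)                      # Hz, gives a 2*span_s window
  fmax <- max(K$freq)
  fq <- seq(df, fmax, by = df)
  ReK <- stats::approx(K$freq, Re(K$K), xout = fq, rule = 2)$y
  ImK <- stats::approx(K$freq, Im(K$K), xout = fq, rule = 2)$y
  inb <- stats::approx(K$freq, as.numeric(K$in_band), xout = fq,
                       rule = 2)$y >= 0.5
  ReK[!inb] <- 0
  ImK[!inb] <- 0
  nf <- length(fq)
  n <- 2 * (nf + 1)
  spec <- complex(real = numeric(n), imaginary = numeric(n))
  spec[2:(nf + 1)] <- complex(real = ReK, imaginary = ImK)
  spec[n:(n - nf + 1)] <- Conj(spec[2:(nf + 1)])
  kern <- Re(stats::fft(spec, inverse = TRUE)) / n * n * df  # density scaling
  dt_ms <- 1000 / (n * df)
  half <- n %/% 2
  idx <- c((half + 1):n, 1:half)              # fftshift
  data.frame(lag_ms = ((1:n) - half - 1) * dt_ms, kernel = kern[idx])
}

#' Reconstruct the input from the output with a Wiener filter
#'
#' Non-causal frequency-domain application of `K(f)` to `y`: the filter is
#' interpolated onto the FFT grid of `y`, applied with Hermitian symmetry and
#' inverse-transformed.  Returns the time-domain estimate `x_est = K * y` on
#' the grid of `y`.
#'
#' @param y output `continuous_signal`.
#' @param K a [wiener_filter()].
#' @return a `continuous_signal` (the reconstruction `x_est`).
#' @export
reconstruct <- function(y, K) {
  stopifnot(inherits(y, "continuous_signal"), inherits(K, "wiener_filter"))
  n <- length(y$samples)
  fs <- 1000 / y$dt
  fgrid <- (seq_len(n) - 1) * fs / n
  fpos <- pmin(fgrid, fs - fgrid)              # |f| with aliasing symmetry
  bandf <- K$freq[K$in_band]
  ReK <- ImK <- numeric(n)
  sel <- fpos >= min(bandf) & fpos <= max(bandf)
  ReK[sel] <- stats::approx(K$freq, Re(K$K), xout = fpos[sel], rule = 2)$y
  ImK[sel] <- stats::approx(K$freq, Im(K$K), xout = fpos[sel], rule = 2)$y
  ImK[fgrid > fs / 2] <- -ImK[fgrid > fs / 2]  # Hermitian: K(-f) = conj(K(f))
  Kf <- complex(real = ReK, imaginary = ImK)
  Y <- stats::fft(y$samples - mean(y$samples))
  continuous_signal(Re(stats::fft(Kf * Y, inverse = TRUE)) / n, y$dt,
                    "dimensionless")
}

#' Variance-accounted-for (VAF) spectrum
#'
#' The headline fidelity statistic: the magnitude-squared coherence
#' `VAF(f) = |Pxy|^2 / (Pxx Pyy)` expressed in percent.  `VAF(f) = 100`
#' implies perfect linear reconstruction at that frequency.  The band mean is
#' the unweighted average over the bins of the input band (`f_min` up to the
#' input cutoff); bins with negligible input power are excluded.
#'
#' @param x input `continuous_signal`.
#' @param y output `continuous_signal` on the same grid.
#' @param settings a [spectral_settings()] object.
#' @param band averaging band `c(f_min, cutoff)` in Hz; defaults to
#'   `settings$band[1]` up to the settings band maximum.
#' @param power_tol input-power floor relative to peak `Pxx`.
#' @return object of class `vaf_spectrum`: `freq`, `vaf` (percent),
#'   `mean_vaf`, `band`.
#' @export
vaf_spectrum <- function(x, y, settings = spectral_settings(), band = NULL,
                         power_tol = 1e-12) {
  sp <- welch_csd(x, y, settings)
  if (is.null(band)) band <- settings$band
  vaf_from_spectra(sp, band, power_tol)
}

# VAF spectrum from precomputed Welch spectra.
#' @noRd
vaf_from_spectra <- function(sp, band, power_tol = 1e-12) {
  keep <- sp$freq >= band[1] & sp$freq <= band[2] &
    sp$Pxx > power_tol * max(sp$Pxx)
  f <- sp$freq[keep]
  vaf <- 100 * Mod(sp$Pxy[keep])^2 / (sp$Pxx[keep] * sp$Pyy[keep])
  vaf <- pmin(pmax(vaf, 0), 100)
  structure(list(freq = f, vaf = vaf, mean_vaf = mean(vaf), band = band,
                 n_segments = sp$K),
            class = "vaf_spectrum")
}

#' @export
print.vaf_spectrum <- function(x, ...) {
  cat(sprintf("<vaf_spectrum> mean VAF = %.1f%% over %.2f-%.1f Hz (%d bins)\n",
              x$mean_vaf, x$band[1], x$band[2], length(x$freq)))
  invisible(x)
}

#' @export
plot.vaf_spectrum <- function(x, ...) {
  graphics::plot(x$freq, x$vaf, type = "l", ylim = c(0, 100),
                 xlab = "frequency (Hz)", ylab = "VAF (%)", ...)
  graphics::abline(h = 90, lty = 3)
  invisible(x)
}

#' Export a VAF spectrum as CSV
#' @param v a `vaf_spectrum`.
#' @param path file path.
#' @export
write_vaf_csv <- function(v, path) {
  utils::write.csv(data.frame(frequency_hz = v$freq, vaf_percent = v$vaf),
                   path, row.names = FALSE)
  invisible(path)
}

#' Population output signal
#'
#' Sum of the sampling-rate-filtered trains of all cells on a common grid;
#' under push-pull coding the sign-negative sub-population is subtracted:
#' `y(t) = y_plus(t) - y_minus(t)`.
#'
#' @param trains list of [spike_train()] objects.
#' @param signs per-cell signs (+1/-1), recycled to the number of cells.
#' @param bin_ms output grid step (ms); defaults to the simulation step of
#'   the first train (the sampling-rate filter grid).
#' @return a `continuous_signal` of signed spike counts per bin.
#' @export
population_output <- function(trains, signs = 1, bin_ms = NULL) {
  if (inherits(trains, "spike_train")) trains <- list(trains)
  stopifnot(length(trains) >= 1)
  signs <- rep_len(signs, length(trains))
  if (is.null(bin_ms)) bin_ms <- trains[[1]]$dt
  duration <- trains[[1]]$duration
  n <- round(duration / bin_ms)
  out <- numeric(n)
  for (i in seq_along(trains)) {
    stopifnot(abs(trains[[i]]$duration - duration) < 1e-9)
    add_spikes_cpp(out, trains[[i]]$times, bin_ms, signs[i])
  }
  continuous_signal(out, bin_ms, "dimensionless")
}
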