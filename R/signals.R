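#' Uniformly sampled continuous signal
#'
#' Light container used for all stimulus, noise and analysis waveforms:
#' a numeric sample vector on a regular time grid with step `dt` (ms) and a
#' units tag. Signals tagged `"normalized"` follow the convention
#' 2*sd = 1 (sample standard deviation 0.5) so that an amplitude factor
#' carries all magnitude information.
#'
#' @param samples numeric vector of samples (length >= 2).
#' @param dt time step in ms (> 0).
#' @param units one of `"pA"`, `"spikes/s"`, `"normalized"`, `"dimensionless"`.
#' @return an object of class `continuous_signal`.
#' @export
continuous_signal <- function(samples, dt,
                              units = c("dimensionless", "pA", "spikes/s",
                                        "normalized")) {
  units <- match.arg(units)
  samples <- as.numeric(samples)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a single positive number (ms)")
  if (length(samples) < 2L)
    stop("a continuous signal needs at least 2 samples")
  structure(list(samples = samples, dt = dt, units = units),
            class = "continuous_signal")
}

#' @export
print.continuous_signal <- function(x, ...) {
  cat(sprintf("<continuous_signal> %d samples, dt = %g ms (%.3f s), units = %s\n",
              length(x$samples), x$dt,
              length(x$samples) * x$dt / 1000, x$units))
  invisible(x)
}

#' @export
length.continuous_signal <- function(x) length(x$samples)

# Evaluate expr under a temporary RNG state seeded with `seed`,
# restoring the caller's state afterwards.
#' @noRd
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-cell seed stream, kept below 2^31.
#' @noRd
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 7919 + 12345) %%
               2147483647)
}

#' Unit-amplitude sinusoid
#'
#' Generates sin(2*pi*f*t) on a regular grid; the caller scales by the
#' modulation amplitude and adds the tonic offset.
#'
#' @param f modulation frequency in Hz (0 < f <= Nyquist of the grid).
#' @param duration duration in ms.
#' @param dt time step in ms.
#' @return a `continuous_signal` (dimensionless).
#' @export
gen_sinusoid <- function(f, duration, dt = 0.025) {
  if (f <= 0) stop("'f' must be positive")
  nyq <- 1000 / (2 * dt)
  if (f > nyq)
    stop(sprintf("frequency %g Hz exceeds the grid Nyquist frequency %g Hz",
                 f, nyq))
  n <- round(duration / dt)
  t_ms <- (seq_len(n) - 1) * dt
  continuous_signal(sin(2 * pi * f * t_ms / 1000), dt, "dimensionless")
}

#' Band-limited Gaussian noise (flat spectrum up to a hard cutoff)
#'
#' Constructed in the frequency domain: independent complex Gaussian Fourier
#' coefficients for 0 < f <= cutoff, exactly zero beyond, inverse transform,
#' then empirical normalization to sd = 0.5 (the 2*sd = 1 convention).
#' A time-domain filter would have spectral roll-off; the frequency-domain
#' construction gives a brick-wall spectrum.
#'
#' @param cutoff low-pass cutoff frequency in Hz.
#' @param duration duration in ms.
#' @param dt time step in ms.
#' @param seed integer seed; same seed gives byte-identical output.
#' @return a `continuous_signal` with units `"normalized"` (sd = 0.5).
#' @export
gen_bandlimited_gaussian <- function(cutoff, duration, dt = 0.025, seed = 1) {
  nyq <- 1000 / (2 * dt)
  if (cutoff <= 0 || cutoff > nyq)
    stop(sprintf("'cutoff' must lie in (0, %g] Hz for dt = %g ms", nyq, dt))
  n <- round(duration / dt)
  if (n < 2) stop("duration too short")
  df <- 1000 / (n * dt)                      # frequency resolution, Hz
  if (cutoff < 2 * df)
    stop("duration too short to resolve the cutoff frequency ",
         "(fewer than 2 periods of the lowest analysis frequency)")
  # highest populated bin with f <= cutoff; the (real-valued) Nyquist bin is
  # left empty so the Hermitian fill below stays consistent
  kmax <- min(floor(cutoff / df), floor((n - 1) / 2))
  co <- with_local_seed(seed, {
    complex(real = stats::rnorm(kmax), imaginary = stats::rnorm(kmax))
  })
  spec <- complex(real = numeric(n), imaginary = numeric(n))
  spec[2:(kmax + 1)] <- co
  spec[n - (0:(kmax - 1))] <- Conj(co)       # Hermitian symmetry -> real signal
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x <- x - mean(x)
  x <- x * (0.5 / stats::sd(x))
  continuous_signal(x, dt, "normalized")
}

#' Ornstein-Uhlenbeck noise process
#'
#' Stationary OU process with correlation time `tau_n`, generated with the
#' exact discretization `x[k+1] = x[k] exp(-dt/tau) + sqrt(1 - exp(-2 dt/tau)) xi`
#' so that its statistics do not depend on the step size, then empirically
#' normalized to zero mean and sd = 0.5 (same 2*sd = 1 convention as the
#' signal, so the amplitude factor A_IN carries all magnitude information).
#'
#' @param tau_n correlation time constant in ms.
#' @param duration duration in ms.
#' @param dt time step in ms.
#' @param seed integer seed.
#' @return a `continuous_signal` with units `"normalized"`.
#' @export
gen_ou_noise <- function(tau_n, duration, dt = 0.025, seed = 1) {
  if (tau_n <= 0) stop("'tau_n' must be positive")
  n <- round(duration / dt)
  if (n < 2) stop("duration too short")
  phi <- exp(-dt / tau_n)
  x <- with_local_seed(seed, {
    innov <- stats::rnorm(n) * sqrt(1 - phi^2)
    innov[1] <- stats::rnorm(1)              # stationary start, unit sd
    as.numeric(stats::filter(innov, phi, method = "recursive"))
  })
  x <- x - mean(x)
  x <- x * (0.5 / stats::sd(x))
  continuous_signal(x, dt, "normalized")
}

#' Sign-invert a signal
#'
#' Returns -x on the same grid with the same units; used for the push-pull
#' sub-population that receives the inverted signal.
#'
#' @param x a `continuous_signal`.
#' @export
invert_signal <- function(x) {
  stopifnot(inherits(x, "continuous_signal"))
  continuous_signal(-x$samples, x$dt, x$units)
}

#' Bin-average a signal onto a coarser grid
#'
#' Downsamples by averaging consecutive blocks of `factor` samples; used to
#' bring stimulus traces onto the spectral-analysis grid. Content above the
#' new Nyquist frequency must be negligible (true for the band-limited
#' stimuli used here).
#'
#' @param x a `continuous_signal`.
#' @param factor integer decimation factor.
#' @export
decimate_signal <- function(x, factor) {
  stopifnot(inherits(x, "continuous_signal"))
  factor <- as.integer(factor)
  if (factor == 1L) return(x)
  n <- (length(x$samples) %/% factor) * factor
  m <- matrix(x$samples[seq_len(n)], nrow = factor)
  continuous_signal(colMeans(m), x$dt * factor, x$units)
}

#' Write / read a signal as two-column CSV (time_ms, value)
#'
#' @param x a `continuous_signal`.
#' @param path file path.
#' @export
write_signal_csv <- function(x, path) {
  stopifnot(inherits(x, "continuous_signal"))
  d <- data.frame(time_ms = (seq_along(x$samples) - 1) * x$dt,
                  value = x$samples)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signal_csv
#' @param units units tag to attach on read.
#' @export
read_signal_csv <- function(path, units = "dimensionless") {
  d <- utils::read.csv(path)
  continuous_signal(d$value, d$time_ms[2] - d$time_ms[1], units)
}
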