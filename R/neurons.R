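#' Integrate-and-fire neuron parameters
#'
#' Membrane, threshold, resonant-conductance and spike-delay constants for
#' the three model kinds:
#' \describe{
#'   \item{lif}{leaky integrate-and-fire: `C dV/dt = -(V - E_R)/R + I_E`,
#'     reset to `E_R` at threshold `V_th`.}
#'   \item{rif}{resonant IF: the LIF augmented with a spike-triggered leak
#'     conductance `I_B = g_b b (V - E_R)` where `b` jumps by 1 at each spike
#'     and decays with time constant `tau_b`, plus a pure output spike delay
#'     `delta_s` that shifts recorded spike times without affecting the
#'     membrane dynamics.}
#'   \item{ideal}{no-leak integrator with rest/reset 0 and threshold 1 that
#'     converts a nonnegative rate signal into spikes (see
#'     [simulate_ideal()]).}
#' }
#' The rIF defaults are the published granule-cell fit: `C` = 3 pF,
#' `R` = 5227 MOhm, `E_R` = -71.5 mV, `V_th` = -41.8 mV, `g_b` = 55.6 pS,
#' `tau_b` = 19.6 ms, `delta_s` = 4.85 ms.  The LIF uses the same membrane
#' constants with `g_b = 0`, `delta_s = 0`.
#'
#' @param model one of `"lif"`, `"rif"`, `"ideal"`.
#' @param C capacitance (pF).
#' @param R resistance (MOhm).
#' @param E_R resting and reset potential (mV).
#' @param V_th spike threshold (mV).
#' @param g_b resonant conductance increment per spike (pS).
#' @param tau_b resonant-state time constant (ms).
#' @param delta_s output spike delay (ms).
#' @return an object of class `neuron_params`.
#' @export
neuron_params <- function(model = c("lif", "rif", "ideal"),
                          C = 3, R = 5227, E_R = -71.5, V_th = -41.8,
                          g_b = if (model == "rif") 55.6 else 0,
                          tau_b = 19.6,
                          delta_s = if (model == "rif") 4.85 else 0) {
  model <- match.arg(model)
  if (model != "ideal") {
    stopifnot(C > 0, R > 0, V_th > E_R, g_b >= 0, tau_b > 0, delta_s >= 0)
    if (model == "lif" && (g_b != 0 || delta_s != 0))
      stop("a LIF has g_b = 0 and delta_s = 0; use model = 'rif'")
  }
  structure(list(model = model, C = C, R = R, E_R = E_R, V_th = V_th,
                 g_b = g_b, tau_b = tau_b, delta_s = delta_s),
            class = "neuron_params")
}

#' @rdname neuron_params
#' @param ... passed on to [neuron_params()].
#' @export
lif_params <- function(...) neuron_params("lif", ...)

#' @rdname neuron_params
#' @export
rif_params <- function(...) neuron_params("rif", ...)

#' @export
print.neuron_params <- function(x, ...) {
  cat(sprintf("<neuron_params> %s: C=%g pF, R=%g MOhm, E_R=%g mV, V_th=%g mV",
              x$model, x$C, x$R, x$E_R, x$V_th))
  if (x$model == "rif")
    cat(sprintf(", g_b=%g pS, tau_b=%g ms, delta_s=%g ms",
                x$g_b, x$tau_b, x$delta_s))
  cat("\n")
  invisible(x)
}

#' Membrane time constant and rheobase
#'
#' `membrane_time_constant` returns tau = R*C in ms; `rheobase` returns the
#' minimum constant current for sustained spiking, (V_th - E_R)/R, in pA.
#'
#' @param params a `neuron_params` object.
#' @export
membrane_time_constant <- function(params) params$R * params$C / 1000

#' @rdname membrane_time_constant
#' @export
rheobase <- function(params) 1000 * (params$V_th - params$E_R) / params$R

# Closed-form LIF inter-spike interval under constant current (ms).
#' @noRd
lif_isi_closed_form <- function(params, I) {
  tau <- membrane_time_constant(params)
  IR <- I * params$R / 1000                      # pA * MOhm -> mV
  theta <- params$V_th - params$E_R
  ifelse(IR > theta, tau * log(IR / (IR - theta)), Inf)
}

# Low-level simulation: drive I_E(t) = scale_x*x + scale_n*noise + I0 (pA).
# x, noise: numeric vectors (length 1 = constant). Returns a spike_train.
#' @noRd
sim_if_raw <- function(params, x, noise, scale_x, scale_n, I0, n_steps, dt,
                       g_I = 0, E_I = -65, state = NULL,
                       return_state = FALSE) {
  V0 <- if (is.null(state)) params$E_R else state$V
  b0 <- if (is.null(state)) 0 else state$b
  res <- sim_if_cpp(x, noise, scale_x, scale_n, I0, as.double(n_steps), dt,
                    params$C, params$R, params$E_R, params$V_th,
                    params$g_b * 1e-3, params$tau_b, params$delta_s,
                    g_I, E_I, V0, b0)
  duration <- n_steps * dt
  tr <- spike_train(res$times[res$times <= duration], dt, duration)
  if (return_state) list(train = tr, state = list(V = res$V, b = res$b))
  else tr
}

#' Simulate a leaky or resonant integrate-and-fire neuron
#'
#' Integrates the membrane equation with an exponential-Euler step and exact
#' exponential decay of the resonant state.  Threshold crossing is detected
#' at end-of-step; the reset is applied immediately and the output delay
#' `delta_s` shifts only the recorded spike time.  An optional constant
#' inhibitory current `g_I (V - E_I)` is included in the dynamics.
#'
#' @param params a `neuron_params` object (`"lif"` or `"rif"`).
#' @param drive input current as a `continuous_signal` in pA.
#' @param I_offset constant current added to the drive (pA).
#' @param g_I constant inhibitory conductance (nS).
#' @param E_I inhibitory reversal potential (mV), default -65 mV.
#' @param state optional carried-over state `list(V, b)` from a previous
#'   segment; `return_state = TRUE` returns the end state alongside the train
#'   so a drive can be split into concatenated segments.
#' @param return_state return `list(train, state)` instead of the bare train.
#' @return a [spike_train()] (or `list(train, state)`).
#' @export
simulate_neuron <- function(params, drive, I_offset = 0, g_I = 0, E_I = -65,
                            state = NULL, return_state = FALSE) {
  stopifnot(inherits(params, "neuron_params"), params$model != "ideal",
            inherits(drive, "continuous_signal"))
  if (anyNA(drive$samples) || any(!is.finite(drive$samples)))
    stop("drive contains non-finite samples")
  sim_if_raw(params, drive$samples, 0, 1, 0, I_offset,
             length(drive$samples), drive$dt, g_I, E_I, state, return_state)
}

#' Simulate the ideal integrate-and-fire rate encoder
#'
#' A no-leak integrator with rest/reset 0 and threshold 1: it accumulates
#' `rate(t) dt` (rate in spikes/s) and emits a spike, subtracting 1, whenever
#' the accumulator reaches 1.  Negative instantaneous rates are clipped to
#' zero; this clipping is the rectification mechanism that push-pull coding
#' counteracts.  The encoder has a flat transfer function, which is why it is
#' used to turn continuous rate signals into input spike trains.
#'
#' @param rate_signal a `continuous_signal` in spikes/s.
#' @param phase initial accumulator value in `[0, 1)`.
#' @return a [spike_train()].
#' @export
simulate_ideal <- function(rate_signal, phase = 0) {
  stopifnot(inherits(rate_signal, "continuous_signal"))
  res <- sim_ideal_cpp(rate_signal$samples, 1, 0,
                       as.double(length(rate_signal$samples)),
                       rate_signal$dt, phase)
  spike_train(res$times, rate_signal$dt,
              length(rate_signal$samples) * rate_signal$dt)
}

# Steady-state rate under constant current, measured precisely from the mean
# inter-spike interval after the warm-up discard (constant-current trains are
# periodic, so this avoids the count/duration quantization).
#' @noRd
steady_rate <- function(params, I, duration = 10000, warmup = 1000,
                        dt = 0.025, g_I = 0, E_I = -65) {
  tr <- sim_if_raw(params, 0, 0, 0, 0, I, round(duration / dt), dt, g_I, E_I)
  tt <- tr$times[tr$times > warmup]
  if (length(tt) < 2) return(1000 * length(tt) / (duration - warmup))
  1000 * (length(tt) - 1) / (tt[length(tt)] - tt[1])
}

#' Steady-state f-I curve
#'
#' Steady-state firing rate for each current in `I_grid`, from constant-current
#' simulations of `duration` ms with the first `warmup` ms discarded.
#'
#' @param params a `neuron_params` object.
#' @param I_grid sorted currents (pA).
#' @param duration,warmup simulation and discard lengths (ms).
#' @param dt step size (ms).
#' @return numeric vector of rates (spikes/s).
#' @export
fI_curve <- function(params, I_grid, duration = 10000, warmup = 1000,
                     dt = 0.025) {
  if (is.unsorted(I_grid)) stop("'I_grid' must be sorted")
  vapply(I_grid, function(I) steady_rate(params, I, duration, warmup, dt),
         numeric(1))
}

#' Calibrate the tonic current for a target carrier rate
#'
#' Bisection on the steady-state f-I relation until the simulated tonic rate
#' is within `tol` (relative) of the target `F0`.
#'
#' @param params a `neuron_params` object.
#' @param F0 target tonic firing rate (spikes/s), > 0.
#' @param tol relative tolerance on the realized rate.
#' @param dt step size (ms).
#' @param duration,warmup simulation and discard lengths (ms).
#' @return the tonic current `I0` in pA.
#' @export
calibrate_tonic_current <- function(params, F0, tol = 0.005, dt = 0.025,
                                    duration = 10000, warmup = 1000) {
  if (F0 <= 0)
    stop("'F0' must be positive (any subthreshold current gives 0 spikes/s)")
  rb <- rheobase(params)
  lo <- rb * 1.0001
  hi <- rb + 5
  while (steady_rate(params, hi, duration, warmup, dt) < F0) hi <- rb + (hi - rb) * 2
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    r <- steady_rate(params, mid, duration, warmup, dt)
    if (abs(r - F0) <= tol * F0) return(mid)
    if (r < F0) lo <- mid else hi <- mid
  }
  stop(sprintf("calibration did not converge to %g spikes/s", F0))
}

#' Calibrate the modulation amplitude for a relative modulation a
#'
#' The amplitude convention: a tonic input `I0 + A_I` produces the tonic rate
#' `(1 + a) F0`, i.e. `A_I = calibrate_tonic_current((1+a) F0) - I0`.  The
#' same rule with `a_n` in place of `a` gives the noise amplitude `A_IN`.
#'
#' @param params a `neuron_params` object.
#' @param I0 calibrated tonic current (pA).
#' @param a relative modulation amplitude (> 0).
#' @param F0 carrier rate the tonic current was calibrated for (spikes/s).
#' @param ... passed to [calibrate_tonic_current()].
#' @return the amplitude `A_I` in pA.
#' @export
calibrate_modulation_amplitude <- function(params, I0, a, F0, ...) {
  if (a <= 0) stop("'a' must be positive")
  calibrate_tonic_current(params, (1 + a) * F0, ...) - I0
}

#' Calibrate a low-rate population to a target effective-rate distribution
#'
#' Per-cell targets for the effective firing rate F_eff are drawn from a
#' normal distribution truncated at zero, and each cell's tonic current is
#' bisected -- with the modulation (fixed amplitude `A_I`) and any per-cell
#' noise current active -- until its measured F_eff is within `tol` of its
#' target.  This reproduces populations whose activity is set by subthreshold
#' tonic currents, where F0 and F_eff differ.
#'
#' @param params a `neuron_params` object.
#' @param N population size.
#' @param target_mean,target_sd mean and sd of the F_eff targets (spikes/s).
#' @param A_I fixed modulation amplitude (pA).
#' @param x modulation signal (`continuous_signal`, 2*sd = 1 convention).
#' @param signs per-cell signs (+1/-1, push-pull); default all +1.
#' @param noise list of per-cell noise `continuous_signal`s (or `NULL`).
#' @param A_IN noise amplitude (pA) applied to each noise trace.
#' @param seed seed for the target draws.
#' @param calib_duration length of the calibration window (ms); the first
#'   `warmup` ms are discarded when measuring F_eff.
#' @param warmup warm-up discard (ms).
#' @param tol relative tolerance on each cell's F_eff.
#' @return list with `I0` (per-cell currents), `targets`, `realized`
#'   (F_eff measured on the calibration window), `A_I`, `A_IN`.
#' @export
calibrate_population_lowrate <- function(params, N, target_mean, target_sd,
                                         A_I, x, signs = rep(1, N),
                                         noise = NULL, A_IN = 0, seed = 1,
                                         calib_duration = 60000,
                                         warmup = 1000, tol = 0.03) {
  if (target_mean <= 0 || target_sd < 0)
    stop("unreachable target rate distribution")
  stopifnot(inherits(x, "continuous_signal"), length(signs) == N)
  targets <- draw_feff_targets(N, target_mean, target_sd, seed)
  I0 <- realized <- numeric(N)
  for (i in seq_len(N)) {
    nz <- if (is.null(noise)) 0 else noise[[i]]$samples
    cal <- calibrate_cell_feff(params, targets[i], A_I * signs[i], x$samples,
                               nz, A_IN, x$dt, calib_duration, warmup, tol)
    I0[i] <- cal$I0
    realized[i] <- cal$realized
  }
  list(I0 = I0, targets = targets, realized = realized, A_I = A_I, A_IN = A_IN)
}

# Per-cell F_eff targets: standard-normal draws rescaled to the exact sample
# mean and sd (the published condition states the realized population
# moments), then truncated at zero.
#' @noRd
draw_feff_targets <- function(N, target_mean, target_sd, seed) {
  z <- with_local_seed(seed, stats::rnorm(N))
  if (N > 1) z <- (z - mean(z)) / stats::sd(z)
  pmax(target_mean + target_sd * z, 0)
}

# Bisection on the tonic current of one cell until its effective rate
# (modulation scale_x and noise active, frozen realizations) matches the
# target within a relative tolerance.
#' @noRd
calibrate_cell_feff <- function(params, target, scale_x, x_samples, nz, A_IN,
                                dt, calib_duration = 60000, warmup = 1000,
                                tol = 0.03, max_iter = 40) {
  n_cal <- min(round(calib_duration / dt), length(x_samples))
  win_s <- (n_cal * dt - warmup) / 1000
  feff <- function(I) {
    tr <- sim_if_raw(params, x_samples, nz, scale_x, A_IN, I, n_cal, dt)
    sum(tr$times > warmup) / win_s
  }
  rb <- rheobase(params)
  lo <- rb - 12
  hi <- rb + 1
  while (feff(hi) < target) hi <- hi + 2
  mid <- hi
  r <- NA_real_
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    r <- feff(mid)
    # stop on the rate criterion, or once the current interval is below the
    # measurement quantization of the rate (1 spike per window)
    if (target > 0 && abs(r - target) <= tol * max(target, 0.5)) break
    if (hi - lo < 0.004) break
    if (r < target) lo <- mid else hi <- mid
  }
  list(I0 = mid, realized = r)
}
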