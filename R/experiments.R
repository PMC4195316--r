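#' Experiment configuration
#'
#' Declarative description of one simulation-and-analysis run.  A config plus
#' a seed determines a run exactly.  Three kinds are supported:
#' \describe{
#'   \item{current}{N membrane-model cells (LIF or rIF) driven by a tonic
#'     current calibrated to carrier rate `F0`, modulated by band-limited
#'     Gaussian noise with relative amplitude `a`, optionally with per-cell
#'     additive Ornstein-Uhlenbeck noise currents.}
#'   \item{encoder}{N ideal integrate-and-fire rate encoders converting
#'     `R(t) = a F0in x(t) + F0in`, with per-cell carrier rates either fixed
#'     or drawn with relative variance `carrier_v`.}
#'   \item{lowrate}{N membrane-model cells with fixed modulation amplitude
#'     `A_I` (pA) and per-cell subthreshold tonic currents calibrated so the
#'     effective rates F_eff match a truncated-normal target distribution.}
#' }
#'
#' @param kind `"current"`, `"encoder"`, or `"lowrate"`.
#' @param model `"lif"`, `"rif"` or `"ideal"` (encoder runs force `"ideal"`).
#' @param N population size.
#' @param F0 carrier rate for current runs (spikes/s).
#' @param F0in mean input carrier rate for encoder runs (spikes/s).
#' @param carrier_v relative variance of encoder carrier rates
#'   (`2 sd = carrier_v * mean`; 0 = homogeneous).
#' @param a relative modulation amplitude.
#' @param cutoff input-noise cutoff frequency (Hz).
#' @param noise `"none"`, `"fast"` (OU tau 1 ms) or `"slow"` (OU tau 100 ms).
#' @param a_n relative noise amplitude (same calibration convention as `a`);
#'   defaults to 4 for fast and 2 for slow noise.
#' @param push_pull split the population into +x / -x halves and reconstruct
#'   from the difference of sub-population outputs.
#' @param lowrate_mean,lowrate_sd target F_eff distribution for lowrate runs
#'   (spikes/s).
#' @param A_I fixed modulation amplitude for lowrate runs (pA).
#' @param A_IN noise-current amplitude for lowrate runs (pA).
#' @param duration_s run length per seed (s).
#' @param dt simulation step (ms).
#' @param analysis_bin_ms spectral-analysis grid (ms).
#' @param warmup_s warm-up discard (s).
#' @return an `experiment_config` object.
#' @export
experiment_config <- function(kind = c("current", "encoder", "lowrate"),
                              model = c("lif", "rif", "ideal"),
                              N = 1, F0 = 40, F0in = 40, carrier_v = 0.5,
                              a = 0.1, cutoff = 20,
                              noise = c("none", "fast", "slow"), a_n = NULL,
                              push_pull = FALSE,
                              lowrate_mean = 4, lowrate_sd = 2,
                              A_I = 2, A_IN = 2,
                              duration_s = 120, dt = 0.025,
                              analysis_bin_ms = 0.1, warmup_s = 1) {
  kind <- match.arg(kind)
  model <- match.arg(model)
  noise <- match.arg(noise)
  if (kind == "encoder") model <- "ideal"
  if (is.null(a_n)) a_n <- switch(noise, none = 0, fast = 4, slow = 2)
  cfg <- list(kind = kind, model = model, N = N, F0 = F0, F0in = F0in,
              carrier_v = carrier_v, a = a, cutoff = cutoff, noise = noise,
              a_n = a_n, push_pull = push_pull, lowrate_mean = lowrate_mean,
              lowrate_sd = lowrate_sd, A_I = A_I, A_IN = A_IN,
              duration_s = duration_s, dt = dt,
              analysis_bin_ms = analysis_bin_ms, warmup_s = warmup_s,
              schema_version = 1L)
  class(cfg) <- "experiment_config"
  cfg
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf(
    "<experiment_config> %s/%s: N=%d, a=%g, cutoff=%g Hz, noise=%s%s, %gs @ dt=%g ms\n",
    x$kind, x$model, x$N, x$a, x$cutoff, x$noise,
    if (x$push_pull) ", push-pull" else "", x$duration_s, x$dt))
  invisible(x)
}

# OU time constants for the named noise kinds (ms).
#' @noRd
noise_tau <- function(noise) switch(noise, fast = 1, slow = 100,
                                    stop("no noise kind"))

# Analysis shared by all runners: bring x onto the analysis grid, trim the
# warm-up, then one Welch pass feeding both the transfer function and the
# VAF spectrum.  The analysis bin must be fine (default 0.1 ms): coarse
# binning of the spike output aliases carrier-harmonic sidebands into the
# signal band and biases VAF down.
#' @noRd
analyze_run <- function(x, y_pop, cfg) {
  bin <- cfg$analysis_bin_ms
  xa <- decimate_signal(x, round(bin / x$dt))
  drop <- round(cfg$warmup_s * 1000 / bin)
  xa <- continuous_signal(xa$samples[-seq_len(drop)], bin, xa$units)
  ya <- continuous_signal(y_pop$samples[-seq_len(drop)], bin, y_pop$units)
  sp <- welch_csd(xa, ya, spectral_settings())
  list(
    vaf = vaf_from_spectra(sp, band = c(0.5, cfg$cutoff)),
    transfer = tf_from_spectra(sp, band = c(0.5, min(200, cfg$cutoff))),
    x_analysis = xa, y_analysis = ya
  )
}

#' Run one experiment for one seed
#'
#' Dispatches on the config kind; see [run_current_experiment()],
#' [run_encoder_experiment()] and [run_lowrate_experiment()].
#'
#' @param config an [experiment_config()].
#' @param seed integer seed.
#' @export
run_experiment <- function(config, seed = 1) {
  stopifnot(inherits(config, "experiment_config"))
  switch(config$kind,
         current = run_current_experiment(config, seed),
         encoder = run_encoder_experiment(config, seed),
         lowrate = run_lowrate_experiment(config, seed))
}

# Assemble the common result object.
#' @noRd
experiment_result <- function(cfg, seed, an, feff, f0 = NULL, extra = list()) {
  structure(c(list(
    config = cfg, seed = seed,
    transfer = an$transfer, vaf = an$vaf, mean_vaf = an$vaf$mean_vaf,
    F_eff = list(mean = feff$mean, sd = feff$sd, per_cell = feff$per_cell),
    F0 = f0), extra), class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %s/%s N=%d seed=%d: mean VAF = %.1f%%, F_eff = %.1f +/- %.1f spikes/s\n",
              x$config$kind, x$config$model, x$config$N, x$seed,
              x$mean_vaf, x$F_eff$mean, x$F_eff$sd))
  invisible(x)
}

#' Current-stimulation experiment
#'
#' Calibrates the tonic current `I0` for the carrier rate `F0` and the
#' modulation amplitude `A_I` for relative modulation `a`, then simulates `N`
#' cells driven by `I0 + A_I x(t)` (push-pull halves receive `-x`), with
#' optional per-cell OU noise currents of amplitude `A_IN` (calibrated from
#' `a_n` by the same convention), and analyzes the population output.
#'
#' @param config an [experiment_config()] with `kind = "current"`.
#' @param seed integer seed.
#' @return an `experiment_result` with the transfer function, VAF spectrum,
#'   mean VAF and realized firing rates.
#' @export
run_current_experiment <- function(config, seed = 1) {
  cfg <- config
  params <- neuron_params(cfg$model)
  dur <- cfg$duration_s * 1000
  x <- gen_bandlimited_gaussian(cfg$cutoff, dur, cfg$dt, seed)
  I0 <- calibrate_tonic_current(params, cfg$F0, dt = cfg$dt)
  A_I <- calibrate_modulation_amplitude(params, I0, cfg$a, cfg$F0, dt = cfg$dt)
  A_IN <- if (cfg$noise == "none") 0 else
    calibrate_modulation_amplitude(params, I0, cfg$a_n, cfg$F0, dt = cfg$dt)
  asg <- population_assignment(cfg$N, cfg$push_pull, cfg$F0, seed)
  n <- length(x$samples)
  trains <- vector("list", cfg$N)
  for (i in seq_len(cfg$N)) {
    nz <- if (cfg$noise == "none") 0 else
      gen_ou_noise(noise_tau(cfg$noise), dur, cfg$dt,
                   asg$cell_seeds[i])$samples
    trains[[i]] <- sim_if_raw(params, x$samples, nz, A_I * asg$signs[i],
                              A_IN, I0, n, cfg$dt)
  }
  y <- population_output(trains, asg$signs, cfg$analysis_bin_ms)
  an <- analyze_run(x, y, cfg)
  feff <- measure_rates(trains, cfg$warmup_s * 1000)
  experiment_result(cfg, seed, an, feff, f0 = cfg$F0,
                    extra = list(I0 = I0, A_I = A_I, A_IN = A_IN))
}

#' Ideal-encoder experiment
#'
#' Rate signal to ideal-IF spike trains to population output, with no
#' membrane model involved: isolates the effect of spike sampling (and of
#' rectification at large `a`) on transmission.  Per-cell carrier rates are
#' drawn with relative variance `carrier_v` (truncated normal); each encoder
#' starts at a random accumulator phase.
#'
#' @inheritParams run_current_experiment
#' @export
run_encoder_experiment <- function(config, seed = 1) {
  cfg <- config
  dur <- cfg$duration_s * 1000
  x <- gen_bandlimited_gaussian(cfg$cutoff, dur, cfg$dt, seed)
  carriers <- if (cfg$carrier_v > 0 && cfg$N > 1)
    sample_carrier_rates(cfg$N, cfg$F0in, cfg$carrier_v, derive_seed(seed, 0))
  else rep(cfg$F0in, cfg$N)
  asg <- population_assignment(cfg$N, cfg$push_pull, carriers, seed)
  n <- length(x$samples)
  trains <- vector("list", cfg$N)
  for (i in seq_len(cfg$N)) {
    phase <- with_local_seed(asg$cell_seeds[i], stats::runif(1))
    res <- sim_ideal_cpp(x$samples, cfg$a * carriers[i] * asg$signs[i],
                         carriers[i], as.double(n), cfg$dt, phase)
    trains[[i]] <- spike_train(res$times, cfg$dt, dur)
  }
  y <- population_output(trains, asg$signs, cfg$analysis_bin_ms)
  an <- analyze_run(x, y, cfg)
  feff <- measure_rates(trains, cfg$warmup_s * 1000)
  experiment_result(cfg, seed, an, feff,
                    extra = list(carriers = carriers))
}

#' Low-rate population experiment
#'
#' Per-cell tonic currents are calibrated (modulation and noise active) so
#' the effective rates match draws from a truncated normal
#' (`lowrate_mean`, `lowrate_sd`); the modulation amplitude is fixed at
#' `A_I` pA.  Supports push-pull coding and slow OU noise.
#'
#' @inheritParams run_current_experiment
#' @export
run_lowrate_experiment <- function(config, seed = 1) {
  cfg <- config
  params <- neuron_params(cfg$model)
  dur <- cfg$duration_s * 1000
  x <- gen_bandlimited_gaussian(cfg$cutoff, dur, cfg$dt, seed)
  asg <- population_assignment(cfg$N, cfg$push_pull, NA, seed)
  A_IN <- if (cfg$noise == "none") 0 else cfg$A_IN
  targets <- draw_feff_targets(cfg$N, cfg$lowrate_mean, cfg$lowrate_sd,
                               derive_seed(seed, 0))
  n <- length(x$samples)
  trains <- vector("list", cfg$N)
  I0 <- cal_realized <- numeric(cfg$N)
  # per-cell: generate the (frozen) noise trace once, calibrate the tonic
  # current on it, run the full-length simulation, then discard the trace
  for (i in seq_len(cfg$N)) {
    nz <- if (cfg$noise == "none") 0 else
      gen_ou_noise(noise_tau(cfg$noise), dur, cfg$dt, asg$cell_seeds[i])$samples
    cal <- calibrate_cell_feff(params, targets[i], cfg$A_I * asg$signs[i],
                               x$samples, nz, A_IN, cfg$dt)
    I0[i] <- cal$I0
    cal_realized[i] <- cal$realized
    trains[[i]] <- sim_if_raw(params, x$samples, nz, cfg$A_I * asg$signs[i],
                              A_IN, I0[i], n, cfg$dt)
  }
  y <- population_output(trains, asg$signs, cfg$analysis_bin_ms)
  an <- analyze_run(x, y, cfg)
  feff <- measure_rates(trains, cfg$warmup_s * 1000)
  experiment_result(cfg, seed, an, feff,
                    extra = list(calibration = list(
                      I0 = I0, targets = targets, realized = cal_realized,
                      A_I = cfg$A_I, A_IN = A_IN)))
}

#' Seed-averaged mean VAF for a config
#'
#' Runs the experiment once per seed and returns the per-seed mean-VAF values
#' together with their average and standard error.  Summary comparisons use
#' the seed-averaged value.
#'
#' @param config an [experiment_config()].
#' @param seeds integer vector of seeds.
#' @return list with `mean_vaf` (seed average), `per_seed`, `se`, `results`.
#' @export
run_experiment_seeds <- function(config, seeds = 1:3) {
  results <- lapply(seeds, function(s) run_experiment(config, s))
  per_seed <- vapply(results, `[[`, numeric(1), "mean_vaf")
  list(mean_vaf = mean(per_seed), per_seed = per_seed,
       se = if (length(per_seed) > 1)
         stats::sd(per_seed) / sqrt(length(per_seed)) else NA_real_,
       results = results)
}

#' Maximum transmittable cutoff versus firing rate
#'
#' For each target effective rate, bisects the input cutoff frequency until
#' the seed-mean VAF crosses the 90% quality threshold (to within `tol_hz`),
#' giving the frontier of faithful transmission.  For the ideal encoder at
#' `a = 1` the frontier follows the Nyquist relation cutoff = F_eff / 2.
#'
#' @param model model kind (currently `"ideal"`; membrane models accepted via
#'   `kind = "current"` configs are not part of the frontier sweep).
#' @param a relative modulation amplitude.
#' @param push_pull use push-pull coding.
#' @param F_eff_grid target effective rates (spikes/s).
#' @param N population size.
#' @param duration_s run length per evaluation (s).
#' @param seeds seeds averaged per evaluation.
#' @param vaf_threshold quality threshold (percent).
#' @param cutoff_range search range (Hz).
#' @param tol_hz bisection tolerance (Hz).
#' @return data frame with `F_eff_target`, `F_eff_realized`, `max_cutoff`
#'   (NA when censored: no cutoff in range reaches the threshold).
#' @export
sweep_max_cutoff <- function(model = "ideal", a = 1, push_pull = FALSE,
                             F_eff_grid = c(20, 40, 80), N = 100,
                             duration_s = 60, seeds = 1,
                             vaf_threshold = 90, cutoff_range = c(1, 120),
                             tol_hz = 1) {
  stopifnot(model == "ideal")
  eval_cfg <- function(F0in, cutoff) {
    cfg <- experiment_config("encoder", N = N, F0in = F0in, a = a,
                             cutoff = cutoff, push_pull = push_pull,
                             duration_s = duration_s)
    r <- run_experiment_seeds(cfg, seeds)
    feff <- mean(vapply(r$results, function(x) x$F_eff$mean, numeric(1)))
    list(vaf = r$mean_vaf, feff = feff)
  }
  rows <- lapply(F_eff_grid, function(Ft) {
    lo <- cutoff_range[1]
    hi <- cutoff_range[2]
    elo <- eval_cfg(Ft, lo)
    if (elo$vaf < vaf_threshold)
      return(data.frame(F_eff_target = Ft, F_eff_realized = elo$feff,
                        max_cutoff = NA_real_))
    ehi <- eval_cfg(Ft, hi)
    if (ehi$vaf >= vaf_threshold)
      return(data.frame(F_eff_target = Ft, F_eff_realized = ehi$feff,
                        max_cutoff = hi))
    feff <- elo$feff
    while (hi - lo > tol_hz) {
      mid <- (lo + hi) / 2
      em <- eval_cfg(Ft, mid)
      if (em$vaf >= vaf_threshold) {
        lo <- mid
        feff <- em$feff
      } else hi <- mid
    }
    data.frame(F_eff_target = Ft, F_eff_realized = feff, max_cutoff = lo)
  })
  do.call(rbind, rows)
}

#' Named figure-style conditions
#'
#' Ready-made configs for the benchmark conditions the package reproduces:
#' single-cell and population current stimulation, ideal-encoder populations
#' and low-rate populations, each with its published mean-VAF reference.
#'
#' @param name one of `"lif_baseline"`, `"lif_carrier20"`, `"lif_a1"`,
#'   `"rif_baseline"`, `"iif_n1"`, `"iif_n40"`, `"iif_pop_a1"`,
#'   `"iif_pop_a10_pp"`, `"lowrate_plain"`, `"lowrate_pp_noise"`.
#' @param duration_s run length per seed (s).
#' @return an [experiment_config()].
#' @export
benchmark_condition <- function(name, duration_s = 120) {
  switch(name,
    lif_baseline = experiment_config("current", "lif", N = 1, F0 = 40,
                                     a = 0.1, cutoff = 20,
                                     duration_s = duration_s),
    lif_carrier20 = experiment_config("current", "lif", N = 1, F0 = 20,
                                      a = 0.1, cutoff = 20,
                                      duration_s = duration_s),
    lif_a1 = experiment_config("current", "lif", N = 1, F0 = 40, a = 1,
                               cutoff = 20, duration_s = duration_s),
    rif_baseline = experiment_config("current", "rif", N = 1, F0 = 40,
                                     a = 0.1, cutoff = 20,
                                     duration_s = duration_s),
    iif_n1 = experiment_config("encoder", N = 1, F0in = 40, a = 1,
                               cutoff = 20, duration_s = duration_s),
    iif_n40 = experiment_config("encoder", N = 40, F0in = 40, carrier_v = 0.5,
                                a = 1, cutoff = 20, duration_s = duration_s),
    iif_pop_a1 = experiment_config("encoder", N = 100, F0in = 20,
                                   carrier_v = 0.5, a = 1, cutoff = 30,
                                   duration_s = duration_s),
    iif_pop_a10_pp = experiment_config("encoder", N = 100, F0in = 20,
                                       carrier_v = 0.5, a = 10, cutoff = 30,
                                       push_pull = TRUE,
                                       duration_s = duration_s),
    lowrate_plain = experiment_config("lowrate", "lif", N = 100, cutoff = 20,
                                      A_I = 2, lowrate_mean = 4,
                                      lowrate_sd = 2,
                                      duration_s = duration_s),
    lowrate_pp_noise = experiment_config("lowrate", "lif", N = 100,
                                         cutoff = 20, A_I = 2, A_IN = 2,
                                         noise = "slow", push_pull = TRUE,
                                         lowrate_mean = 4, lowrate_sd = 2,
                                         duration_s = duration_s),
    stop("unknown condition: ", name)
  )
}

#' @rdname benchmark_condition
#' @export
benchmark_conditions <- function() c(
  "lif_baseline", "lif_carrier20", "lif_a1", "rif_baseline",
  "iif_n1", "iif_n40", "iif_pop_a1", "iif_pop_a10_pp",
  "lowrate_plain", "lowrate_pp_noise")
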