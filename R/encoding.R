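#' Rate-coded input signal
#'
#' Affine map of a normalized modulation signal onto firing rate:
#' `R(t) = a * F0in * x(t) + F0in`, with `x` following the 2*sd = 1
#' convention so the amplitude `a * F0in` covers the input firing rate about
#' 95% of the time.  No clipping is applied here; negative instantaneous
#' rates are rectified by the ideal-IF encoder at encoding time.
#'
#' @param x modulation signal (`continuous_signal`, normalized).
#' @param F0in input carrier rate (spikes/s).
#' @param a relative modulation amplitude (dimensionless).
#' @return a `continuous_signal` in spikes/s with attributes `F0in` and `a`.
#' @export
make_rate_signal <- function(x, F0in, a) {
  stopifnot(inherits(x, "continuous_signal"), F0in >= 0, a >= 0)
  out <- continuous_signal(a * F0in * x$samples + F0in, x$dt, "spikes/s")
  out$F0in <- F0in
  out$a <- a
  out
}

#' Sample heterogeneous input carrier rates
#'
#' Normal draws with mean `mean` and standard deviation `v * mean / 2`
#' (the relative-variance convention `2*std(F0in) = v * m(F0in)`), truncated
#' at zero since negative rates are meaningless.
#'
#' @param N_in number of input channels.
#' @param mean mean carrier rate (spikes/s).
#' @param v relative variance (default 0.5: mean 40 gives sd 10).
#' @param seed integer seed.
#' @return numeric vector of carrier rates (spikes/s).
#' @export
sample_carrier_rates <- function(N_in, mean, v = 0.5, seed = 1) {
  stopifnot(N_in >= 1, mean > 0, v >= 0)
  if (v == 0) return(rep(mean, N_in))
  sdev <- v * mean / 2
  with_local_seed(seed, {
    r <- numeric(N_in)
    for (i in seq_len(N_in)) {
      repeat {
        val <- stats::rnorm(1, mean, sdev)
        if (val >= 0) break
      }
      r[i] <- val
    }
    r
  })
}

#' Inhomogeneous Poisson spike-train encoder
#'
#' Per-step Bernoulli generation with probability `R(t) dt`; negative rates
#' are clipped to zero.  Poisson trains have ISI CV near 1, the
#' higher-variability contrast to the deterministic ideal-IF encoder.
#'
#' @param R rate signal (`continuous_signal` in spikes/s).
#' @param seed integer seed.
#' @return a [spike_train()].
#' @export
encode_poisson <- function(R, seed = 1) {
  stopifnot(inherits(R, "continuous_signal"))
  p <- pmax(R$samples, 0) * R$dt / 1000
  if (any(p > 0.2))
    warning("rate*dt > 0.2: Bernoulli approximation to Poisson is coarse")
  hit <- with_local_seed(seed, stats::runif(length(p)) < p)
  spike_train(which(hit) * R$dt, R$dt, length(p) * R$dt)
}

#' Population input assignment (carriers, signs, seeds)
#'
#' Assigns each cell its carrier rate, its modulation sign and a noise seed.
#' Under push-pull coding exactly `floor(N/2)` cells (the second half) form
#' the sub-population that receives the inverted signal; the split is
#' deterministic.
#'
#' @param N population size.
#' @param push_pull split the population into +x and -x halves.
#' @param carrier_rates per-cell carrier rates (length `N` or 1, recycled).
#' @param seed base seed from which per-cell seeds are derived.
#' @return list with `N`, `carrier_rates`, `signs`, `cell_seeds`.
#' @export
population_assignment <- function(N, push_pull = FALSE, carrier_rates = NA,
                                  seed = 1) {
  stopifnot(N >= 1)
  if (push_pull && N < 2) stop("push-pull coding needs at least 2 cells")
  signs <- rep(1, N)
  if (push_pull) signs[(N - floor(N / 2) + 1):N] <- -1
  list(N = N, carrier_rates = rep_len(carrier_rates, N), signs = signs,
       cell_seeds = vapply(seq_len(N), function(i) derive_seed(seed, i),
                           integer(1)))
}

#' @rdname population_assignment
#' @export
assign_push_pull <- function(N, seed = 1)
  population_assignment(N, push_pull = TRUE, seed = seed)
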