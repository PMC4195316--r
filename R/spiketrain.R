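#' Spike train for one cell over one trial
#'
#' Ordered spike times (ms) together with the simulation step that produced
#' them and the trial duration.
#'
#' @param times numeric vector of strictly increasing spike times in
#'   `[0, duration]` (ms).
#' @param dt simulation step the train was produced at (ms).
#' @param duration trial duration (ms).
#' @export
spike_train <- function(times, dt, duration) {
  times <- as.numeric(times)
  if (anyNA(times) || any(times < 0) || any(times > duration))
    stop("spike times must lie within [0, duration]")
  if (is.unsorted(times, strictly = TRUE))
    stop("spike times must be strictly increasing")
  structure(list(times = times, dt = dt, duration = duration),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes over %.3f s (dt = %g ms), rate = %.2f spikes/s\n",
              length(x$times), x$duration / 1000, x$dt,
              1000 * length(x$times) / x$duration))
  invisible(x)
}

#' Mean firing rates of one or more spike trains
#'
#' Spike count divided by measurement time after a warm-up discard, per cell;
#' the population mean and standard deviation are reported alongside.  Used
#' both for the carrier rate F0 (no modulation) and the effective rate F_eff
#' (modulation active).
#'
#' @param trains a `spike_train` or list of them.
#' @param warmup initial interval discarded before counting (ms).
#' @return list with `per_cell` (spikes/s), `mean` and `sd`.
#' @export
measure_rates <- function(trains, warmup = 1000) {
  if (inherits(trains, "spike_train")) trains <- list(trains)
  per_cell <- vapply(trains, function(tr) {
    win <- tr$duration - warmup
    if (win <= 0) stop("warm-up exceeds the trial duration")
    1000 * sum(tr$times > warmup) / win
  }, numeric(1))
  list(per_cell = per_cell, mean = mean(per_cell),
       sd = if (length(per_cell) > 1) stats::sd(per_cell) else 0)
}

#' Write / read spike trains as CSV (cell_id, time_ms)
#'
#' @param trains list of `spike_train` objects.
#' @param path file path.
#' @export
write_spikes_csv <- function(trains, path) {
  if (inherits(trains, "spike_train")) trains <- list(trains)
  d <- data.frame(
    cell_id = rep(seq_along(trains), vapply(trains, function(t) length(t$times),
                                            integer(1))),
    time_ms = unlist(lapply(trains, `[[`, "times"), use.names = FALSE)
  )
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spikes_csv
#' @param dt,duration grid step and duration to attach on read (ms).
#' @param n_cells number of cells (so silent trailing cells are kept).
#' @export
read_spikes_csv <- function(path, dt, duration, n_cells = NULL) {
  d <- utils::read.csv(path)
  if (is.null(n_cells))
    n_cells <- if (nrow(d)) max(d$cell_id) else 0L
  lapply(seq_len(n_cells), function(i)
    spike_train(sort(d$time_ms[d$cell_id == i]), dt, duration))
}
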