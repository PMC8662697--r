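## Derived readouts: calcium spike detection, inter-spike intervals,
## intercellular wave metrics, zonal glucose outputs, percent changes.

#' Detect calcium spikes in a trace
#'
#' Local maxima of a uniformly sampled trace that exceed an absolute
#' height and a prominence threshold (height above the deeper of the two
#' flanking minima), separated by at least a refractory interval. The
#' default height equals the glycogenolysis activation threshold
#' (0.44 uM), so detected spikes are exactly the metabolically relevant
#' ones.
#'
#' @param trace data.frame with columns `time` and `CaI` (or any second
#'   column holding the signal), or a numeric vector with `times` given.
#' @param min_height minimum absolute peak height (uM).
#' @param min_prominence minimum prominence over flanking minima (uM).
#' @param refractory minimum spacing between accepted spikes (s).
#' @param times sampling times when `trace` is a bare numeric vector.
#' @return object of class `spike_train`: list with `times` (s) and
#'   `amplitudes` (uM), both ordered.
#' @export
detect_spikes <- function(trace, min_height = 0.44, min_prominence = 0.1,
                          refractory = 20, times = NULL) {
  if (is.data.frame(trace)) {
    times <- trace[[1]]
    x <- trace[[2]]
  } else {
    x <- as.numeric(trace)
    if (is.null(times)) times <- seq_along(x)
  }
  if (length(x) == 0) stop("empty trace", call. = FALSE)
  n <- length(x)
  train <- structure(list(times = numeric(0), amplitudes = numeric(0)),
                     class = "spike_train")
  if (n < 3) return(train)
  cand <- which(x[2:(n - 1)] >= x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
  cand <- cand[x[cand] >= min_height]
  if (!length(cand)) return(train)
  ## prominence: height above the higher of the two flanking valley floors,
  ## valleys delimited by the nearest equal-or-higher samples
  keep <- logical(length(cand))
  for (j in seq_along(cand)) {
    i <- cand[j]
    lb <- rev(which(x[1:(i - 1)] > x[i]))
    left_min <- min(x[(if (length(lb)) lb[1] else 1):i])
    rb <- which(x[(i + 1):n] > x[i])
    right_min <- min(x[i:(if (length(rb)) i + rb[1] else n)])
    keep[j] <- (x[i] - max(left_min, right_min)) >= min_prominence
  }
  cand <- cand[keep]
  if (!length(cand)) return(train)
  ## refractory pruning, highest-first
  ord <- cand[order(-x[cand])]
  acc <- numeric(0)
  for (i in ord)
    if (!length(acc) || all(abs(times[i] - times[acc]) >= refractory))
      acc <- c(acc, i)
  acc <- sort(acc)
  structure(list(times = times[acc], amplitudes = x[acc]),
            class = "spike_train")
}

#' Mean inter-spike interval of a spike train
#'
#' @param train a `spike_train` from [detect_spikes()], or a numeric
#'   vector of spike times.
#' @return mean of successive spike-time differences (s).
#' @export
interspike_interval <- function(train) {
  tt <- if (inherits(train, "spike_train")) train$times else as.numeric(train)
  if (length(tt) < 2)
    stop("undefined inter-spike interval: fewer than 2 spikes",
         call. = FALSE)
  mean(diff(tt))
}

#' Intercellular calcium wave metrics
#'
#' Characterizes wave propagation along the hepatocyte chain from the
#' per-cell spike trains. After discarding each cell's first (transient)
#' spike, the pericentral cell's spikes define reference waves with mean
#' period `P`; for every reference spike, each cell contributes its
#' nearest spike within half a period, so that phase is unwrapped and a
#' wave is a front crossing the whole chain. The lag of a wave is
#' `t(PP spike) - t(PC spike)` between the extreme cells: a positive lag
#' means the wave travels PC to PP. Metrics are averaged over complete
#' waves. Spiking is classified as direction `"none"` when too few
#' whole-chain waves exist, when the lag is smaller than `lag_tol`
#' (synchronous firing), or when the lag fluctuates by more than a
#' quarter period between waves (unsynchronized cells drifting at their
#' intrinsic frequencies, as with uncoupled gap junctions).
#'
#' @param trains list of `spike_train`s, one per cell, ordered PP (cell 1)
#'   to PC (cell N).
#' @param cell_length optional hepatocyte diameter (um) to convert the
#'   velocity from cells/s to um/s.
#' @param lag_tol lags with absolute value below this (s) count as
#'   synchronous, direction `"none"`.
#' @param min_waves minimum number of complete waves required.
#' @param min_complete_frac minimum fraction of reference spikes that must
#'   form complete whole-chain waves; sporadic coincidences between
#'   unsynchronized trains fall below this.
#' @return object of class `wave_metrics`: list with `lag_time` (s,
#'   signed mean over waves), `velocity` (cells/s, or um/s when
#'   `cell_length` is given), `direction` (`"PC->PP"`, `"PP->PC"`, or
#'   `"none"`), `period` (s), `start_site` (modal earliest-spiking cell),
#'   and `n_waves`.
#' @export
wave_metrics <- function(trains, cell_length = NULL, lag_tol = 1,
                         min_waves = 6L, min_complete_frac = 0.35) {
  N <- length(trains)
  stopifnot(N >= 2)
  none <- structure(list(lag_time = NA_real_, velocity = NA_real_,
                         direction = "none", period = NA_real_,
                         start_site = NA_integer_, n_waves = 0L),
                    class = "wave_metrics")
  tt <- lapply(trains, function(tr) tr$times[-1])  # drop transient spike
  ref <- tt[[N]]
  if (length(ref) < min_waves + 1L || any(vapply(tt, length, 1L) < 2L))
    return(none)
  ## median inter-spike interval: robust to silent gaps between bursts
  period <- stats::median(diff(ref))
  ## trace each wave front cell by cell from the pericentral reference:
  ## cell i contributes its spike nearest to cell i+1's matched spike,
  ## within half a period per step, so cumulative front spreads larger
  ## than half a period remain correctly oriented
  tmat <- matrix(NA_real_, length(ref), N)
  tmat[, N] <- ref
  for (i in rev(seq_len(N - 1L))) {
    prev <- tmat[, i + 1L]
    ok <- which(!is.na(prev))
    if (!length(ok)) break
    d <- outer(prev[ok], tt[[i]], function(a, b) b - a)
    j <- apply(abs(d), 1, which.min)
    off <- d[cbind(seq_along(ok), j)]
    off[abs(off) > period / 2] <- NA
    tmat[ok, i] <- prev[ok] + off
  }
  complete <- stats::complete.cases(tmat)
  ## unsynchronized chains yield only sporadic whole-chain coincidences
  if (sum(complete) < min_waves ||
      mean(complete) < min_complete_frac) return(none)
  tmat <- tmat[complete, , drop = FALSE]
  lags <- tmat[, 1] - tmat[, N]
  lag <- mean(lags)
  if (stats::sd(lags) > period / 4) return(none)
  start <- as.integer(names(sort(table(apply(tmat, 1, which.min)),
                                 decreasing = TRUE))[1])
  out <- list(lag_time = lag, velocity = NA_real_, direction = "none",
              period = period, start_site = start, n_waves = nrow(tmat))
  if (abs(lag) > lag_tol) {
    out$velocity <- (N - 1) / abs(lag)
    if (!is.null(cell_length)) out$velocity <- out$velocity * cell_length
    out$direction <- if (lag > 0) "PC->PP" else "PP->PC"
  }
  structure(out, class = "wave_metrics")
}

#' @export
print.wave_metrics <- function(x, ...) {
  cat(sprintf(
    "calcium wave: direction %s, lag %.2f s, velocity %.3f, period %.1f s, start cell %s, %d waves\n",
    x$direction, x$lag_time, x$velocity, x$period,
    as.character(x$start_site), x$n_waves))
  invisible(x)
}

#' Per-cell spike trains of a simulation
#'
#' @param sim a `lobule_sim`.
#' @param window optional time window `c(t0, t1)` restricting the traces.
#' @param ... passed to [detect_spikes()].
#' @return list of `spike_train`s, PP to PC.
#' @export
spike_trains <- function(sim, window = NULL, ...) {
  N <- sim$config$transport$N
  ca <- get_species(sim, "CaI")
  tt <- sim$time
  if (!is.null(window)) {
    sel <- tt >= window[1] & tt <= window[2]
    tt <- tt[sel]
    ca <- ca[sel, , drop = FALSE]
  }
  lapply(seq_len(N), function(i)
    detect_spikes(ca[, i], times = tt, ...))
}

#' Total and per-layer hepatic glucose output
#'
#' Time integral (trapezoidal) of each layer's glucose export flux over a
#' window; the total is the sum over layers. Units are uM of glucose in
#' sinusoidal-compartment volume, i.e. umol per compartment unit volume.
#'
#' @param sim a `lobule_sim`.
#' @param window time interval `c(t0, t1)` within the simulated horizon.
#' @return list with `total` and `per_layer` (length-`N` vector).
#' @export
glucose_outputs <- function(sim, window = c(0, max(sim$time))) {
  stopifnot(window[1] >= min(sim$time), window[2] <= max(sim$time),
            window[2] > window[1])
  fl <- export_fluxes(sim)
  sel <- sim$time >= window[1] & sim$time <= window[2]
  tt <- sim$time[sel]
  fl <- fl[sel, , drop = FALSE]
  dt <- diff(tt)
  per <- vapply(seq_len(ncol(fl)), function(i)
    sum(dt * (fl[-1, i] + fl[-nrow(fl), i]) / 2), numeric(1))
  list(total = sum(per), per_layer = per)
}

#' Cumulative glycogenolysis over a window
#'
#' Trapezoidal time integral of the summed per-layer glycogen breakdown
#' flux (uM glucosyl units).
#'
#' @param sim a `lobule_sim`.
#' @param window time interval `c(t0, t1)`.
#' @return scalar cumulative breakdown.
#' @export
cumulative_glycogenolysis <- function(sim, window = c(0, max(sim$time))) {
  fl <- glycogenolysis_fluxes(sim)
  sel <- sim$time >= window[1] & sim$time <= window[2]
  tt <- sim$time[sel]
  fl <- rowSums(fl[sel, , drop = FALSE])
  sum(diff(tt) * (fl[-1] + fl[-length(fl)]) / 2)
}

#' Percent change of `a` relative to `b`
#'
#' @param a,b amounts; `b` must be positive.
#' @return `100 * (a - b) / b`.
#' @export
percent_change <- function(a, b) {
  if (any(b == 0)) stop("reference amount is zero", call. = FALSE)
  100 * (a - b) / b
}
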