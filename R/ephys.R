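# Passive membrane properties, miniature EPSC detection and feature
# extraction, and the event-frequency vs stimulation-rate regression.
# Conventions: inward synaptic currents are negative (pA); thresholds are
# signed; times are seconds, kinetic features milliseconds.

#' Passive membrane properties from a voltage step
#'
#' Standard whole-cell estimates from a hyperpolarising command step:
#' total membrane capacitance `Cm = Q / dV` (charge transferred during the
#' step over the step size), total membrane conductance `Gm = Iss / dV`
#' (steady-state current over step size) and series resistance
#' `Rs = dV / Ip` (step size over the capacitive transient peak).
#'
#' @param Q charge transfer in pC.
#' @param dV command step in mV (non-zero).
#' @param Iss steady-state current in pA.
#' @param Ip capacitive-transient peak current in pA (non-zero).
#' @return An object of class `passive_membrane` with `Cm_pF`, `Gm_nS`,
#'   `Rs_MOhm` (pC/mV is nF, reported in pF; pA/mV is nS; mV/pA is GOhm,
#'   reported in MOhm).
#' @export
passive_membrane <- function(Q, dV, Iss, Ip) {
  if (!is.numeric(dV) || dV == 0) stop_user("'dV' must be non-zero")
  if (!is.numeric(Ip) || Ip == 0) stop_user("'Ip' must be non-zero")
  structure(list(Cm_pF = 1000 * Q / dV,
                 Gm_nS = Iss / dV,
                 Rs_MOhm = 1000 * dV / Ip),
            class = "passive_membrane")
}

#' @export
print.passive_membrane <- function(x, ...) {
  cat(sprintf("Cm = %.4g pF, Gm = %.4g nS, Rs = %.4g MOhm\n",
              x$Cm_pF, x$Gm_nS, x$Rs_MOhm))
  invisible(x)
}

#' Series-resistance exclusion rule
#'
#' A recording is excluded when the series resistance rises by more than
#' 30% over its initial value at any point in the recording.
#'
#' @param rs_series series-resistance values in MOhm over the recording,
#'   at least two, all positive.
#' @return `TRUE` if the recording should be excluded.
#' @export
rs_exclusion <- function(rs_series) {
  rs_series <- as.numeric(rs_series)
  if (length(rs_series) < 2L) stop_user("need at least two Rs values")
  if (any(!is.finite(rs_series)) || any(rs_series <= 0))
    stop_user("Rs values must be positive and finite")
  max(rs_series) / rs_series[1] > 1.30
}

#' Continuous current recording
#'
#' @param samples current samples in pA.
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param stimulus_times optional stimulus marker times in s.
#' @return An object of class `current_trace`.
#' @export
current_trace <- function(samples, sampling_rate, stimulus_times = NULL) {
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) stop_user("trace samples must be finite")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop_user("'sampling_rate' must be > 0")
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 stimulus_times = stimulus_times),
            class = "current_trace")
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("<current_trace: %.3f s at %g Hz>\n",
              length(x$samples) / x$sampling_rate, x$sampling_rate))
  invisible(x)
}

odd_window <- function(ms, fs, n) {
  k <- max(3L, as.integer(round(ms / 1000 * fs)))
  if (k %% 2L == 0L) k <- k + 1L
  min(k, if (n %% 2L == 1L) n else n - 1L)
}

#' Detect miniature EPSCs in a current trace
#'
#' Subtracts a running-median baseline and thresholds a lightly smoothed
#' copy of the residual (a short running mean), so that noise wiggles on an
#' event's decay do not split one event into several; each contiguous
#' threshold-crossing excursion contributes one event at the extremum of
#' the *raw* residual, and a refractory separation is enforced (the more
#' extreme of two conflicting events wins). Detection is deterministic and
#' invariant to DC offsets.
#'
#' @param trace a [current_trace()].
#' @param threshold signed detection threshold in pA; negative for inward
#'   events.
#' @param refractory_ms minimum event separation in ms; the default of 2 ms
#'   is the resolvability scale (longer than an event's peak width, shorter
#'   than its decay).
#' @param baseline_ms running-median window in ms; must exceed the event
#'   duration so events are not absorbed into the baseline.
#' @param smooth_ms running-mean window applied before thresholding, in ms
#'   (0 disables smoothing); the default matches the ~0.3 ms rise time of
#'   these events, the matched-filter scale.
#' @return Integer vector of event sample indices (1-based, at event peaks).
#' @export
detect_events <- function(trace, threshold, refractory_ms = 2,
                          baseline_ms = 50, smooth_ms = 0.3) {
  stopifnot(inherits(trace, "current_trace"))
  if (threshold == 0) stop_user("'threshold' must be non-zero and signed")
  s <- trace$samples
  n <- length(s)
  fs <- trace$sampling_rate
  k <- odd_window(baseline_ms, fs, n)
  r <- s - runmed(s, k, endrule = "median")
  if (threshold < 0) { r <- -r; threshold <- -threshold }
  rs <- r
  if (smooth_ms > 0) {
    ks <- odd_window(smooth_ms, fs, n)
    if (ks >= 3L) {
      kern <- rep(1 / ks, ks)
      rs <- as.numeric(stats::filter(r, kern, sides = 2))
      half <- (ks - 1L) %/% 2L
      rs[seq_len(half)] <- r[seq_len(half)]
      rs[(n - half + 1L):n] <- r[(n - half + 1L):n]
    }
  }
  refr <- max(1L, as.integer(round(refractory_ms / 1000 * fs)))
  # hysteresis: an excursion opens below the full threshold but only closes
  # at half threshold, so noise on a decay cannot re-trigger; genuinely
  # merged events are split back apart at peaks whose connecting valley
  # drops below 60% of the smaller peak
  hi <- threshold / 2
  over <- rs >= hi
  if (!any(over)) return(integer(0))
  runs <- rle(over)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- integer(0)
  for (i in which(runs$values)) {
    seg <- starts[i]:ends[i]
    v <- rs[seg]
    if (max(v) < threshold) next
    m <- length(v)
    is_peak <- v >= threshold &
      v >= c(-Inf, v[-m]) & v > c(v[-1], -Inf)
    peaks <- seg[is_peak]
    if (!length(peaks)) peaks <- seg[which.max(v)]
    acc <- integer(0)
    for (p in peaks[order(-rs[peaks])]) {
      ok <- TRUE
      for (a in acc) {
        between <- min(p, a):max(p, a)
        valley_ok <- min(rs[between]) < 0.6 * min(rs[p], rs[a])
        if (abs(p - a) < refr || !valley_ok) { ok <- FALSE; break }
      }
      if (ok) acc <- c(acc, p)
    }
    cand <- c(cand, sort(acc))
  }
  if (!length(cand)) return(integer(0))
  # re-centre each event on the raw residual's local extremum
  half <- max(1L, as.integer(round(max(smooth_ms, 0.05) / 1000 * fs)))
  cand <- vapply(cand, function(p) {
    win <- max(1L, p - half):min(n, p + half)
    win[which.max(r[win])]
  }, integer(1))
  cand <- sort(unique(cand))
  keep <- integer(0)
  for (idx in cand) {
    if (length(keep) && idx - keep[length(keep)] < refr) {
      if (r[idx] > r[keep[length(keep)]]) keep[length(keep)] <- idx
    } else keep <- c(keep, idx)
  }
  keep
}

# linear-interpolated crossing time (fractional sample index) of level `lev`
# on the rising limb ending at sample `i_peak` of the normalised event `u`
cross_back <- function(u, i_peak, lev, max_back) {
  j <- i_peak
  lo <- max(1L, i_peak - max_back)
  while (j > lo && u[j - 1L] >= lev) j <- j - 1L
  if (j == lo && u[j] >= lev) return(NA_real_)   # never dropped below level
  if (u[j] <= lev) return(j)                     # exact hit at a sample
  # crossing lies between j - 1 and j
  (j - 1L) + (lev - u[j - 1L]) / (u[j] - u[j - 1L])
}

#' Features of one detected mEPSC
#'
#' Computes, relative to a 1 ms pre-event median baseline: the signed peak
#' amplitude, the 10%-90% rise time on the rising phase (linear
#' interpolation between samples), and the weighted decay time constant
#' `(A1*tau1 + A2*tau2) / (A1 + A2)` from a bi-exponential least-squares fit
#' of the decay, falling back to a single exponential when the second
#' component is degenerate.
#'
#' @param trace a [current_trace()].
#' @param index event peak sample index (from [detect_events()]).
#' @param baseline_ms pre-event baseline window length in ms.
#' @param baseline_gap_ms gap between the end of the baseline window and the
#'   event peak in ms (should exceed the rise time).
#' @param decay_ms decay-fit window length in ms.
#' @param peak_smooth_ms when > 0, the peak amplitude is the mean of the
#'   samples within this window around the extremum instead of the single
#'   extremum sample; a fraction of the rise time suppresses
#'   single-sample noise without biasing the waveform.
#' @return A one-row `data.frame`: `time_s`, `peak_amplitude_pA`,
#'   `rise_10_90_ms`, `weighted_decay_ms`, `decay_biexponential` (logical;
#'   `NA` features flag a failed fit).
#' @export
event_features <- function(trace, index, baseline_ms = 1,
                           baseline_gap_ms = 1.5, decay_ms = 40,
                           peak_smooth_ms = 0) {
  stopifnot(inherits(trace, "current_trace"))
  s <- trace$samples
  fs <- trace$sampling_rate
  n <- length(s)
  i <- as.integer(index)
  if (i < 2L || i > n - 1L) stop_user("event index too close to trace ends")
  gap <- as.integer(round(baseline_gap_ms / 1000 * fs))
  blen <- max(1L, as.integer(round(baseline_ms / 1000 * fs)))
  b_end <- max(1L, i - gap)
  b_start <- max(1L, b_end - blen + 1L)
  baseline <- median(s[b_start:b_end])
  peak <- s[i] - baseline
  if (peak_smooth_ms > 0) {
    half <- max(1L, as.integer(round(peak_smooth_ms / 2000 * fs)))
    win <- max(1L, i - half):min(n, i + half)
    peak <- mean(s[win]) - baseline
  }
  u <- (s - baseline) / peak           # normalised: u[i] == 1, event positive
  max_back <- max(2L, as.integer(round(5 / 1000 * fs)))  # look back <= 5 ms
  t90 <- cross_back(u, i, 0.9, max_back)
  t10 <- cross_back(u, i, 0.1, max_back)
  rise <- if (is.na(t90) || is.na(t10)) NA_real_ else (t90 - t10) / fs * 1000
  # decay fit on the normalised falling limb
  dlen <- min(n - i, as.integer(round(decay_ms / 1000 * fs)))
  wdecay <- NA_real_
  biexp <- NA
  if (dlen >= 5L) {
    t_ms <- (0:dlen) / fs * 1000
    y <- u[i + 0:dlen]
    below <- which(y < exp(-1))
    tau0 <- if (length(below)) max(t_ms[below[1]], 0.2) else max(t_ms) / 2
    fit2 <- tryCatch(minpack.lm::nls.lm(
      par = c(a1 = 0.7, t1 = tau0 / 2, a2 = 0.3, t2 = tau0 * 2),
      lower = c(0, 0.01, 0, 0.01), upper = c(2, 500, 2, 500),
      fn = function(p) p[1] * exp(-t_ms / p[2]) + p[3] * exp(-t_ms / p[4]) - y,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    ok2 <- !is.null(fit2) && fit2$info %in% 1:4
    if (ok2) {
      p <- fit2$par
      minor <- min(p[1], p[3]) / max(1e-12, p[1] + p[3])
      if (minor >= 0.01 && max(p[2], p[4]) / min(p[2], p[4]) > 1.05) {
        wdecay <- (p[1] * p[2] + p[3] * p[4]) / (p[1] + p[3])
        biexp <- TRUE
      }
    }
    if (is.na(wdecay)) {               # single-exponential fallback
      fit1 <- tryCatch(minpack.lm::nls.lm(
        par = c(a = 1, tau = tau0), lower = c(0, 0.01), upper = c(2, 500),
        fn = function(p) p[1] * exp(-t_ms / p[2]) - y,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(fit1) && fit1$info %in% 1:4) {
        wdecay <- fit1$par[2]
        biexp <- FALSE
      }
    }
  }
  data.frame(time_s = (i - 1L) / fs, peak_amplitude_pA = peak,
             rise_10_90_ms = rise, weighted_decay_ms = wdecay,
             decay_biexponential = biexp)
}

#' Detect events and extract their features
#'
#' Convenience pipeline: [detect_events()] followed by [event_features()]
#' per event, plus the instantaneous frequency (reciprocal inter-event
#' interval, assigned to the later event of each pair).
#'
#' @inheritParams detect_events
#' @param ... passed to [event_features()].
#' @return A `data.frame` with one row per event and an
#'   `instantaneous_frequency_Hz` column (`NA` for the first event).
#' @export
extract_events <- function(trace, threshold, refractory_ms = 2,
                           baseline_ms = 50, ...) {
  idx <- detect_events(trace, threshold, refractory_ms, baseline_ms)
  n <- length(trace$samples)
  idx <- idx[idx >= 2L & idx <= n - 1L]
  if (!length(idx)) {
    out <- event_features(current_trace(c(0, 1, 0), 1), 2)[0, ]
    out$instantaneous_frequency_Hz <- numeric(0)
    out$index <- integer(0)
    return(out)
  }
  rows <- lapply(idx, function(i) event_features(trace, i, ...))
  out <- do.call(rbind, rows)
  out$index <- idx
  out$instantaneous_frequency_Hz <- c(NA_real_, 1 / diff(out$time_s))
  rownames(out) <- NULL
  out
}

#' Regression of mEPSC frequency on optical stimulation rate
#'
#' Ordinary least squares of event frequency (Hz) against stimulation rate
#' (Hz), with the slope's standard error and the 5%/95% confidence limits
#' of the fitted line.
#'
#' @param rates stimulation rates in Hz (at least 3 points, at least 2
#'   distinct rates).
#' @param freqs mEPSC frequencies in Hz, same length.
#' @return An object of class `rate_regression`: `slope`, `slope_se`,
#'   `intercept`, `intercept_se`, `r_squared`, `conf_limits` (data frame of
#'   rate, fit, lower and upper 5%/95% limits) and the underlying `lm` fit.
#' @export
frequency_rate_regression <- function(rates, freqs) {
  rates <- as.numeric(rates); freqs <- as.numeric(freqs)
  ok <- is.finite(rates) & is.finite(freqs)
  rates <- rates[ok]; freqs <- freqs[ok]
  if (length(rates) < 3L) stop_user("need at least 3 points")
  if (length(unique(rates)) < 2L)
    stop_user("all stimulation rates identical: slope undefined")
  fit <- lm(freqs ~ rates)
  sm <- summary(fit)
  xs <- sort(unique(rates))
  band <- predict(fit, newdata = data.frame(rates = xs),
                  interval = "confidence", level = 0.90)
  structure(list(slope = unname(coef(fit)[2]),
                 slope_se = sm$coefficients[2, 2],
                 intercept = unname(coef(fit)[1]),
                 intercept_se = sm$coefficients[1, 2],
                 r_squared = sm$r.squared,
                 conf_limits = data.frame(rate = xs, fit = band[, "fit"],
                                          lower_5 = band[, "lwr"],
                                          upper_95 = band[, "upr"]),
                 fit = fit),
            class = "rate_regression")
}

#' @export
print.rate_regression <- function(x, ...) {
  cat(sprintf("slope = %.3g +/- %.2g Hz/Hz (r^2 = %.3f), intercept = %.3g Hz\n",
              x$slope, x$slope_se, x$r_squared, x$intercept))
  invisible(x)
}
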