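# Doppler spectrogram envelope extraction and velocity summary indices.

#' Extract the velocity envelope from a PW-Doppler spectrogram
#'
#' Per time bin, the envelope is the largest velocity (on the dominant side
#' of the baseline) at which the cumulative power, integrated outward from
#' zero velocity, reaches `percentile` of the bin's total power, with linear
#' sub-bin interpolation; the result is median-filtered over 5 bins. Bins
#' with negligible total power are interpolated from their neighbours; if
#' more than 30% of bins are empty an error is raised.
#'
#' @param spec a [spectrogram()].
#' @param percentile cumulative-power fraction defining the envelope.
#' @param median_window odd median-filter window, bins.
#' @param empty_rel relative power threshold below which a bin counts as
#'   empty.
#' @param floor_frac per-column noise-floor suppression: bins below this
#'   fraction of the column maximum are zeroed before the percentile scan
#'   (the usual -dB display threshold of clinical envelope detectors).
#' @return a [velocity_trace()] (summaries unset; see [velocity_indices()]).
#' @export
extract_envelope <- function(spec, percentile = 0.95, median_window = 5L,
                             empty_rel = 1e-3, floor_frac = 0.15) {
  stopifnot(inherits(spec, "spectrogram"))
  p <- spec$power; v <- spec$velocity_axis
  nt <- ncol(p)
  if (floor_frac > 0) {
    cmax <- apply(p, 2L, max)
    p[p < rep(floor_frac * cmax, each = nrow(p))] <- 0
  }
  totals <- colSums(p)
  empty <- totals <= empty_rel * max(totals)
  if (all(empty))
    stop_musecho("spectrogram is empty: no bin carries power",
                 "musecho_empty_spectrogram")
  if (mean(empty) > 0.3)
    stop_musecho(sprintf("%.0f%% of time bins carry no power",
                         100 * mean(empty)), "musecho_empty_spectrogram")
  # dominant flow side from the power-weighted mean velocity
  side <- sign(sum(p %*% rep(1, nt) * v))
  if (side == 0) side <- 1
  env <- rep(NA_real_, nt)
  ord <- order(side * v)          # from most-negative (folded) to signal side
  vo <- v[ord]
  for (j in which(!empty)) {
    cum <- cumsum(p[ord, j])
    tot <- cum[length(cum)]
    k <- which(cum >= percentile * tot)[1L]
    if (k == 1L) { env[j] <- vo[1L]; next }
    # linear interpolation inside bin k
    c0 <- cum[k - 1L]; c1 <- cum[k]
    f <- (percentile * tot - c0) / max(c1 - c0, .Machine$double.eps)
    env[j] <- vo[k - 1L] + f * (vo[k] - vo[k - 1L])
  }
  if (any(empty)) {
    good <- which(!empty)
    env[empty] <- stats::approx(good, env[good], xout = which(empty),
                                rule = 2)$y
  }
  if (median_window > 1L && nt >= median_window)
    env <- stats::runmed(env, median_window, endrule = "median")
  velocity_trace(spec$time_axis, as.numeric(env))
}

# First full cycle of a periodic envelope: foot-to-foot via upstroke
# detection. Returns c(start, end) indices, or the whole trace when no
# periodicity is apparent.
detect_cycle <- function(trace, period_hint = NULL) {
  v <- trace$velocity; t <- trace$time; n <- length(v)
  dt <- t[2L] - t[1L]
  dd <- v - mean(v)
  if (stats::sd(v) < 1e-9) return(c(1L, n))
  ac <- stats::acf(dd, lag.max = n - 2L, plot = FALSE)$acf[, 1, 1]
  lag_min <- max(3L, round(0.04 / dt))
  lags <- lag_min:(length(ac) - 1L)
  locmax <- lags[ac[lags + 1L] > 0.25 &
                 ac[lags + 1L] >= ac[lags] & ac[lags + 1L] >= ac[lags + 2L]]
  if (!length(locmax)) return(c(1L, n))
  # a multi-peaked cycle (e.g. E and A inflow bumps) has an autocorrelation
  # alias at the intra-cycle peak spacing: take the smallest lag whose peak
  # is close to the strongest one, not simply the first local maximum
  best <- max(ac[locmax + 1L])
  period <- locmax[ac[locmax + 1L] >= 0.9 * best][1L]
  start <- which.min(v[seq_len(min(period, n))])
  end <- start + period
  if (end > n) { end <- n; start <- max(1L, end - period) }
  c(start, end)
}

#' Velocity summary indices over one cardiac cycle
#'
#' PSV is the cycle maximum, EDV the minimum of the pre-upstroke window (the
#' 20% of the cycle preceding the systolic upstroke foot, tolerant of
#' dicrotic notches), MV the cycle mean of the envelope.
#'
#' @param trace a [velocity_trace()].
#' @param cycle optional integer length-2 (start, end sample of one cycle);
#'   defaults to automatic detection of the first full cycle.
#' @return the trace with `PSV`, `EDV`, `MV` and `cycle_bounds` filled.
#' @export
velocity_indices <- function(trace, cycle = NULL) {
  stopifnot(inherits(trace, "velocity_trace"))
  cycle <- cycle %||% trace$cycle_bounds %||% detect_cycle(trace)
  i0 <- cycle[1L]; i1 <- cycle[2L]
  if (i1 - i0 + 1L < 10L)
    stop_musecho("cycle shorter than 10 bins", "musecho_cycle_error")
  v <- trace$velocity[i0:i1]
  m <- length(v)
  psv_i <- which.max(abs(v))
  # upstroke foot: last sample below 10% of peak-to-peak before the peak
  rng <- diff(range(v))
  if (rng < 1e-9) {
    edv <- v[1L]
  } else {
    low <- which(v[seq_len(psv_i)] <= min(v) + 0.1 * rng)
    foot <- if (length(low)) max(low) else 1L
    w0 <- max(1L, foot - ceiling(0.2 * m))
    edv <- min(v[w0:foot])
  }
  velocity_trace(trace$time, trace$velocity, cycle_bounds = c(i0, i1),
                 PSV = v[psv_i], EDV = edv, MV = mean(v))
}

#' Renal resistivity and pulsatility indices
#'
#' `RI = (PSV - EDV)/PSV` and `PI = (PSV - EDV)/MV`.
#'
#' @param PSV peak systolic velocity (or a [velocity_trace()] with summaries
#'   filled, in which case the other arguments are ignored).
#' @param EDV end-diastolic velocity.
#' @param MV cycle-mean velocity.
#' @return list with `RI` and `PI` (dimensionless).
#' @export
renal_indices <- function(PSV, EDV = NULL, MV = NULL) {
  if (inherits(PSV, "velocity_trace")) {
    tr <- PSV
    if (is.null(tr$PSV)) tr <- velocity_indices(tr)
    PSV <- tr$PSV; EDV <- tr$EDV; MV <- tr$MV
  }
  if (PSV <= 0) stop_musecho("PSV must be positive", "musecho_index_error")
  if (MV <= 0) stop_musecho("MV must be positive", "musecho_index_error")
  list(RI = (PSV - EDV) / PSV, PI = (PSV - EDV) / MV)
}

#' Transmitral E and A peak velocities and their ratio
#'
#' Identifies the two prominent peaks of one diastolic inflow cycle in
#' temporal order (E first, A second). A single prominent peak is reported as
#' E-A fusion with the ratio undefined (`NA`); zero or more than two
#' prominent peaks raise a peak-count error.
#'
#' @param trace a [velocity_trace()] of mitral inflow.
#' @param cycle optional cycle bounds (see [velocity_indices()]).
#' @param prominence_frac minimum peak height as a fraction of the cycle
#'   maximum.
#' @return list with `E`, `A` (mm/s), `EA` (ratio, `NA` on fusion) and
#'   `fused` (logical).
#' @export
mitral_ea <- function(trace, cycle = NULL, prominence_frac = 0.2) {
  stopifnot(inherits(trace, "velocity_trace"))
  if (is.null(cycle)) {
    # anchor the cycle inside the systolic no-inflow gap (the longest
    # low-velocity run), so E precedes A within the window regardless of
    # where the recording happens to start
    va <- abs(trace$velocity)
    n_all <- length(va)
    period <- diff(detect_cycle(trace)) + 1L
    low <- va < 0.1 * max(va)
    r <- rle(low)
    ends <- cumsum(r$lengths)
    runs <- which(r$values)
    if (length(runs) && period < n_all) {
      k <- runs[which.max(r$lengths[runs])]
      start <- ends[k] - r$lengths[k] %/% 2L
      if (start + period - 1L > n_all) start <- max(1L, n_all - period + 1L)
      cycle <- c(start, start + period - 1L)
    } else {
      cycle <- trace$cycle_bounds %||% detect_cycle(trace)
    }
  }
  v <- abs(trace$velocity[cycle[1L]:cycle[2L]])
  n <- length(v)
  if (n < 10L) stop_musecho("cycle shorter than 10 bins", "musecho_cycle_error")
  thr <- prominence_frac * max(v)
  is_peak <- v > thr &
    v >= c(-Inf, v[-n]) & v > c(v[-1L], -Inf)
  peaks <- which(is_peak)
  # merge plateau/adjacent detections closer than 5% of the cycle
  if (length(peaks) > 1L) {
    keep <- c(TRUE, diff(peaks) > max(2L, round(0.05 * n)))
    grp <- cumsum(keep)
    peaks <- vapply(split(peaks, grp),
                    function(ix) ix[which.max(v[ix])], integer(1))
  }
  if (length(peaks) == 1L) {
    return(list(E = v[peaks], A = NA_real_, EA = NA_real_, fused = TRUE))
  }
  if (length(peaks) < 1L || length(peaks) > 2L)
    stop_musecho(sprintf("expected 1-2 prominent peaks, found %d",
                         length(peaks)), "musecho_peak_count_error")
  E <- v[peaks[1L]]; A <- v[peaks[2L]]
  list(E = E, A = A, EA = E / A, fused = FALSE)
}
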