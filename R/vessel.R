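# Vessel diameter from longitudinal B-mode loops: per-scanline axial
# gradient-pair edge detection, temporally constrained contour tracking, and
# beat segmentation of the resulting waveform.

# Candidate wall bands in one axial profile: a band is a rising gradient
# peak followed within `band_w` px by a falling gradient trough. Positions
# are parabolic-refined; the band centre is their midpoint (coincides with
# the intensity-band centre for symmetric wall profiles).
find_band_candidates <- function(profile, band_w = 12L, min_strength = 8) {
  n <- length(profile)
  g <- c(0, (profile[3:n] - profile[1:(n - 2L)]) / 2, 0)
  rising <- which(g > min_strength &
                  g >= c(-Inf, g[-n]) & g >= c(g[-1L], -Inf))
  out <- NULL
  for (yr in rising) {
    win <- yr + seq_len(min(band_w, n - yr))
    if (!length(win)) next
    yf <- win[which.min(g[win])]
    if (g[yf] > -min_strength) next
    yr_s <- yr + parabolic_offset(g, yr)
    yf_s <- yf + parabolic_offset(-g, yf)
    out <- rbind(out, c(center = (yr_s + yf_s) / 2,
                        strength = g[yr] - g[yf]))
  }
  out
}

#' Detect near and far vessel wall positions in one frame
#'
#' Finds the two dominant wall bands along the axial (row) direction inside a
#' lateral ROI by gradient-pair detection on each scanline, then averages
#' across scanlines. Positions are sub-pixel (parabolic interpolation of the
#' gradient extrema), 1-based image rows. When `prior` is given, candidates
#' are restricted to a window around the previous wall positions (contour
#' tracking).
#'
#' @param frame numeric matrix (one B-mode frame, rows axial).
#' @param roi integer vector of column indices; default central lateral third
#'   (at least 11 scanlines when the frame allows).
#' @param prior optional numeric length-2 (near, far) wall rows from the
#'   previous frame.
#' @param search_px half-width of the prior search window, px.
#' @param smooth_sigma axial Gaussian presmoothing, px.
#' @return list with `near`, `far` (rows, `NA` when not found), `confidence`
#'   in `[0, 1]` and `ok` (logical). Never silently returns zeros: failures
#'   are flagged through `ok = FALSE` / low confidence.
#' @export
detect_wall_edges <- function(frame, roi = NULL, prior = NULL,
                              search_px = 10, smooth_sigma = 1.0) {
  h <- nrow(frame); w <- ncol(frame)
  roi <- roi %||% default_vessel_roi(w)
  if (any(roi < 1L) || any(roi > w))
    stop_musecho("ROI columns outside frame", "musecho_roi_error")
  sub <- frame[, roi, drop = FALSE]
  if (smooth_sigma > 0) sub <- apply(sub, 2L, smooth1d, sigma = smooth_sigma)
  nears <- fars <- strengths <- rep(NA_real_, length(roi))
  for (j in seq_along(roi)) {
    cand <- find_band_candidates(sub[, j])
    if (is.null(cand)) next
    if (!is.null(prior)) {
      near_ok <- abs(cand[, "center"] - prior[1L]) <= search_px
      far_ok <- abs(cand[, "center"] - prior[2L]) <= search_px
      cn <- cand[near_ok, , drop = FALSE]
      cf <- cand[far_ok, , drop = FALSE]
      if (!nrow(cn) || !nrow(cf)) next
      ni <- which.max(cn[, "strength"]); fi <- which.max(cf[, "strength"])
      if (cf[fi, "center"] <= cn[ni, "center"]) next
      nears[j] <- cn[ni, "center"]; fars[j] <- cf[fi, "center"]
      strengths[j] <- min(cn[ni, "strength"], cf[fi, "strength"])
    } else {
      if (nrow(cand) < 2L) next
      ord <- order(cand[, "strength"], decreasing = TRUE)
      top <- cand[ord, , drop = FALSE]
      # strongest pair with plausible separation
      pick <- NULL
      for (a in seq_len(min(4L, nrow(top)) - 1L)) {
        for (b in (a + 1L):min(4L, nrow(top))) {
          if (abs(top[a, "center"] - top[b, "center"]) >= 6) {
            pick <- c(a, b); break
          }
        }
        if (!is.null(pick)) break
      }
      if (is.null(pick)) next
      cc <- sort(top[pick, "center"])
      nears[j] <- cc[1L]; fars[j] <- cc[2L]
      strengths[j] <- min(top[pick, "strength"])
    }
  }
  valid <- is.finite(nears) & is.finite(fars)
  if (!any(valid))
    return(list(near = NA_real_, far = NA_real_, confidence = 0, ok = FALSE))
  near <- stats::median(nears[valid]); far <- stats::median(fars[valid])
  # confidence: fraction of scanlines detected, damped by gradient prominence
  prom <- stats::median(strengths[valid]) / 20
  conf <- mean(valid) * min(1, prom)
  list(near = near, far = far, confidence = min(conf, 1), ok = conf >= 0.05)
}

default_vessel_roi <- function(w, min_scanlines = 11L) {
  half <- max(min_scanlines %/% 2L, floor(w / 6))
  ctr <- (w + 1L) %/% 2L
  lo <- max(1L, ctr - half); hi <- min(w, ctr + half)
  lo:hi
}

#' Track the instantaneous vessel diameter through a cine loop
#'
#' Applies [detect_wall_edges()] frame by frame with the previous wall
#' positions as prior, enforces temporal continuity through a per-frame jump
#' cap, interpolates low-confidence frames, and converts to millimetres with
#' the loop's axial pixel spacing. Beats are segmented afterwards when
#' possible (see [segment_beats()]); a static vessel simply yields no beats.
#'
#' @param loop a [cine_loop()] in a vessel long-axis view.
#' @param roi columns to analyse; default the central lateral third, at least
#'   11 scanlines.
#' @param jump_cap_px maximum credible per-frame diameter change, px.
#' @param conf_min confidence below which a frame is interpolated.
#' @param max_bad_frac tolerated fraction of low-confidence frames before a
#'   tracking-failure error.
#' @param segment segment beats after tracking (errors are tolerated: the
#'   trace is then returned without beats)?
#' @return a [diameter_trace()].
#' @export
track_diameter <- function(loop, roi = NULL, jump_cap_px = 5,
                           conf_min = 0.3, max_bad_frac = 0.3,
                           segment = TRUE) {
  stopifnot(inherits(loop, "cine_loop"))
  d <- dim(loop$frames)
  roi <- roi %||% default_vessel_roi(d[2L])
  n <- d[3L]
  diam_px <- conf <- numeric(n)
  bad <- logical(n)
  prior <- NULL
  for (i in seq_len(n)) {
    e <- detect_wall_edges(loop$frames[, , i], roi, prior)
    if (!e$ok || e$confidence < conf_min) {
      bad[i] <- TRUE
      diam_px[i] <- if (i > 1L) diam_px[i - 1L] else NA_real_
      conf[i] <- e$confidence
      next
    }
    dpx <- e$far - e$near
    if (i > 1L && !bad[i - 1L] && abs(dpx - diam_px[i - 1L]) > jump_cap_px) {
      bad[i] <- TRUE
      diam_px[i] <- diam_px[i - 1L]
      conf[i] <- e$confidence
      next
    }
    diam_px[i] <- dpx
    conf[i] <- e$confidence
    prior <- c(e$near, e$far)
  }
  if (mean(bad) > max_bad_frac)
    stop_musecho(sprintf("tracking failed: %.0f%% low-confidence frames",
                         100 * mean(bad)), "musecho_tracking_failure")
  good <- which(!bad & is.finite(diam_px))
  if (!length(good))
    stop_musecho("tracking failed: no confident frames", "musecho_tracking_failure")
  if (any(bad)) {
    diam_px[-good] <- stats::approx(good, diam_px[good], xout = which(bad),
                                    rule = 2)$y
  }
  trace <- diameter_trace(frame_times(loop), diam_px * loop$pixel_spacing[1L],
                          quality = conf)
  if (segment) {
    seg <- tryCatch(segment_beats(trace, ecg = loop$ecg), error = function(e) trace)
    trace <- seg
  }
  trace
}

# R-peak sample indices of an impulse-like ECG.
find_r_peaks <- function(signal, fs, refractory_s = 0.06) {
  thr <- 0.5 * max(signal)
  cand <- which(signal >= thr)
  if (!length(cand)) return(integer(0))
  keep <- cand[c(TRUE, diff(cand) > refractory_s * fs)]
  keep
}

#' Segment a diameter waveform into beats
#'
#' With an ECG, beats are delimited by consecutive R peaks; `Dd` is the
#' minimum just after the R peak (first 30% of the beat), `Ds` the intra-beat
#' maximum. Without an ECG, the cycle length is estimated from the
#' autocorrelation of the detrended waveform and beats are delimited by
#' diameter minima. The ensemble beat is the pointwise median of all beats
#' after time normalisation to a common phase axis.
#'
#' @param trace a [diameter_trace()].
#' @param ecg optional list (`signal`, `fs`).
#' @param n_phase samples of the normalised ensemble beat.
#' @return the trace with `beats` (data.frame `start`, `end`, `Dd`, `Ds`) and
#'   `ensemble` filled.
#' @export
segment_beats <- function(trace, ecg = NULL, n_phase = 101L) {
  stopifnot(inherits(trace, "diameter_trace"))
  d <- trace$diameter_mm; t <- trace$time; n <- length(d)
  bounds <- NULL
  if (!is.null(ecg)) {
    rp <- find_r_peaks(ecg$signal, ecg$fs)
    rt <- (rp - 1L) / ecg$fs
    idx <- vapply(rt, function(x) which.min(abs(t - x)), integer(1))
    idx <- unique(idx[t[idx] <= t[n]])
    if (length(idx) < 2L)
      stop_musecho("fewer than two R peaks inside the trace",
                   "musecho_beat_segmentation_error")
    bounds <- idx
  } else {
    dd <- d - movavg(d, max(3L, 2L * (n %/% 8L) + 1L))
    if (stats::sd(d) < 1e-6 * mean(d))
      stop_musecho("no periodicity detected in the diameter waveform",
                   "musecho_beat_segmentation_error")
    ac <- stats::acf(dd, lag.max = n - 2L, plot = FALSE)$acf[, 1, 1]
    dt <- t[2L] - t[1L]
    lag_min <- max(3L, round(0.04 / dt))
    lags <- lag_min:(length(ac) - 1L)
    locmax <- lags[ac[lags + 1L] > 0.3 &
                   ac[lags + 1L] >= ac[lags] & ac[lags + 1L] >= ac[lags + 2L]]
    if (!length(locmax))
      stop_musecho("no periodicity detected in the diameter waveform",
                   "musecho_beat_segmentation_error")
    best <- max(ac[locmax + 1L])
    period <- locmax[ac[locmax + 1L] >= 0.9 * best][1L]
    k <- 0L; mins <- integer(0); pos <- which.min(d[seq_len(min(n, period))])
    while (pos <= n) {
      mins <- c(mins, pos)
      nxt_lo <- pos + round(0.65 * period); nxt_hi <- min(n, pos + round(1.35 * period))
      if (nxt_lo >= n) break
      win <- nxt_lo:nxt_hi
      pos <- win[which.min(d[win])]
      k <- k + 1L
      if (k > 1000L) break
    }
    if (length(mins) < 2L)
      stop_musecho("no periodicity detected in the diameter waveform",
                   "musecho_beat_segmentation_error")
    bounds <- mins
  }
  nb <- length(bounds) - 1L
  beats <- data.frame(start = integer(nb), end = integer(nb),
                      Dd = numeric(nb), Ds = numeric(nb))
  phases <- matrix(NA_real_, n_phase, nb)
  phase <- seq(0, 1, length.out = n_phase)
  for (b in seq_len(nb)) {
    i0 <- bounds[b]; i1 <- bounds[b + 1L]
    seg <- d[i0:i1]
    dd_win <- seg[seq_len(max(2L, ceiling(0.3 * length(seg))))]
    beats$start[b] <- i0; beats$end[b] <- i1
    beats$Dd[b] <- min(dd_win)
    beats$Ds[b] <- max(seg)
    u <- (t[i0:i1] - t[i0]) / (t[i1] - t[i0])
    phases[, b] <- stats::approx(u, seg, xout = phase, rule = 2)$y
  }
  ensemble <- list(phase = phase,
                   diameter = apply(phases, 1L, stats::median))
  diameter_trace(trace$time, trace$diameter_mm, trace$quality,
                 beats = beats, ensemble = ensemble)
}

# Per-beat (or whole-trace fallback) systolic/diastolic diameters of a trace.
trace_ds_dd <- function(trace) {
  if (!is.null(trace$beats) && nrow(trace$beats) > 0) {
    c(Ds = mean(trace$beats$Ds), Dd = mean(trace$beats$Dd))
  } else {
    c(Ds = max(trace$diameter_mm), Dd = min(trace$diameter_mm))
  }
}
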