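#' Calibrated grayscale cine loop
#'
#' Container for a B-mode image sequence with its spatial and temporal
#' calibration. Frames are stored as an `H x W x T` array of gray intensities
#' in `[0, 255]`; rows are the axial (beam) direction, columns lateral.
#'
#' @param frames numeric array `H x W x T`, `T >= 2`, values in `[0, 255]`.
#' @param pixel_spacing numeric length-2, (axial, lateral) mm per pixel.
#' @param frame_rate frames per second.
#' @param ecg optional list with `signal` (numeric) and `fs` (sampling rate,
#'   Hz); must span the whole loop duration.
#' @param view one of `"aorta-long-axis"`, `"carotid-long-axis"`, `"PLAX"`,
#'   `"SAX"`, `"liver-kidney"`.
#' @return an object of class `cine_loop`.
#' @export
cine_loop <- function(frames, pixel_spacing, frame_rate, ecg = NULL,
                      view = c("aorta-long-axis", "carotid-long-axis",
                               "PLAX", "SAX", "liver-kidney")) {
  view <- match.arg(view)
  if (length(dim(frames)) != 3L || dim(frames)[3L] < 2L)
    stop_musecho("frames must be an H x W x T array with T >= 2", "musecho_invalid_loop")
  if (length(pixel_spacing) != 2L || any(pixel_spacing <= 0))
    stop_musecho("pixel_spacing must be two positive values (axial, lateral mm/px)",
                 "musecho_invalid_loop")
  if (frame_rate <= 0)
    stop_musecho("frame_rate must be positive", "musecho_invalid_loop")
  if (min(frames) < 0 || max(frames) > 255)
    stop_musecho("frame intensities must lie in [0, 255]", "musecho_invalid_loop")
  duration <- (dim(frames)[3L] - 1L) / frame_rate
  if (!is.null(ecg)) {
    stopifnot(is.list(ecg), !is.null(ecg$signal), !is.null(ecg$fs))
    if ((length(ecg$signal) - 1L) / ecg$fs < duration - 1e-9)
      stop_musecho("ECG must span the loop duration", "musecho_invalid_loop")
  }
  structure(list(frames = frames,
                 pixel_spacing = as.numeric(pixel_spacing),
                 frame_rate = frame_rate, ecg = ecg, view = view),
            class = "cine_loop")
}

#' @export
print.cine_loop <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<cine_loop> %s: %d x %d px, %d frames @ %g fps, %g x %g mm/px%s\n",
              x$view, d[1L], d[2L], d[3L], x$frame_rate,
              x$pixel_spacing[1L], x$pixel_spacing[2L],
              if (is.null(x$ecg)) "" else ", with ECG"))
  invisible(x)
}

# Frame timestamps (s) of a cine loop.
frame_times <- function(loop) (seq_len(dim(loop$frames)[3L]) - 1L) / loop$frame_rate

#' Pulsed-wave Doppler spectrogram
#'
#' Power as a `V x T` matrix (rows: velocity bins, columns: time bins), with
#' strictly monotone axes and the baseline (zero velocity) inside the
#' velocity axis. Velocities are angle-corrected mm/s; the correction angle is
#' stored for provenance but never re-applied.
#'
#' @param power nonnegative numeric matrix, velocity bins x time bins.
#' @param time_axis seconds, strictly increasing, length `ncol(power)`.
#' @param velocity_axis mm/s, strictly increasing, length `nrow(power)`.
#' @param prf pulse repetition frequency, Hz.
#' @param angle_correction beam-to-flow angle, degrees (stored only).
#' @return an object of class `spectrogram`.
#' @export
spectrogram <- function(power, time_axis, velocity_axis, prf,
                        angle_correction = 60) {
  if (any(power < 0)) stop_musecho("spectrogram power must be nonnegative",
                                   "musecho_invalid_spectrogram")
  if (nrow(power) != length(velocity_axis) || ncol(power) != length(time_axis))
    stop_musecho("axis lengths must match power dimensions", "musecho_invalid_spectrogram")
  if (any(diff(time_axis) <= 0) || any(diff(velocity_axis) <= 0))
    stop_musecho("axes must be strictly increasing", "musecho_invalid_spectrogram")
  if (prf <= 0) stop_musecho("prf must be positive", "musecho_invalid_spectrogram")
  structure(list(power = power, time_axis = time_axis,
                 velocity_axis = velocity_axis, prf = prf,
                 angle_correction = angle_correction),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> %d velocity x %d time bins, v in [%g, %g] mm/s, PRF %g Hz\n",
              nrow(x$power), ncol(x$power), min(x$velocity_axis),
              max(x$velocity_axis), x$prf))
  invisible(x)
}

#' Instantaneous vessel diameter waveform
#'
#' @param time seconds, strictly increasing.
#' @param diameter_mm positive diameters, mm.
#' @param quality per-frame tracking confidence in `[0, 1]`.
#' @param beats optional data.frame with columns `start`, `end` (frame
#'   indices), `Dd`, `Ds` (mm) as filled by [segment_beats()].
#' @param ensemble optional ensemble-averaged beat (list `phase`, `diameter`).
#' @return object of class `diameter_trace`; `Dm` is the time-averaged mean
#'   diameter.
#' @export
diameter_trace <- function(time, diameter_mm, quality = rep(1, length(time)),
                           beats = NULL, ensemble = NULL) {
  stopifnot(length(time) == length(diameter_mm))
  if (any(diff(time) <= 0))
    stop_musecho("time must be strictly increasing", "musecho_invalid_trace")
  if (any(diameter_mm <= 0))
    stop_musecho("diameters must be positive", "musecho_invalid_trace")
  if (!is.null(beats) && nrow(beats) > 0 && any(beats$Ds < beats$Dd))
    stop_musecho("within each beat Ds must be >= Dd", "musecho_invalid_trace")
  structure(list(time = time, diameter_mm = diameter_mm,
                 quality = pmin(pmax(quality, 0), 1),
                 beats = beats, ensemble = ensemble,
                 Dm = mean(diameter_mm)),
            class = "diameter_trace")
}

#' @export
print.diameter_trace <- function(x, ...) {
  cat(sprintf("<diameter_trace> %d samples over %.3f s, Dm = %.3f mm, %d beat(s)\n",
              length(x$time), diff(range(x$time)), x$Dm,
              if (is.null(x$beats)) 0L else nrow(x$beats)))
  invisible(x)
}

#' Doppler velocity envelope with summary indices
#'
#' @param time seconds, strictly increasing.
#' @param velocity signed envelope, mm/s.
#' @param cycle_bounds integer length-2, first and last sample index of the
#'   analysed cardiac cycle.
#' @param PSV,EDV,MV optional precomputed summaries; when missing they are
#'   derived from the cycle via [velocity_indices()] conventions.
#' @return object of class `velocity_trace`.
#' @export
velocity_trace <- function(time, velocity, cycle_bounds = NULL,
                           PSV = NULL, EDV = NULL, MV = NULL) {
  stopifnot(length(time) == length(velocity))
  if (any(diff(time) <= 0))
    stop_musecho("time must be strictly increasing", "musecho_invalid_trace")
  structure(list(time = time, velocity = velocity,
                 cycle_bounds = cycle_bounds,
                 PSV = PSV, EDV = EDV, MV = MV),
            class = "velocity_trace")
}

#' @export
print.velocity_trace <- function(x, ...) {
  cat(sprintf("<velocity_trace> %d samples over %.3f s", length(x$time),
              diff(range(x$time))))
  if (!is.null(x$PSV))
    cat(sprintf("; PSV %.1f, EDV %.1f, MV %.1f mm/s", x$PSV, x$EDV, x$MV))
  cat("\n")
  invisible(x)
}

#' Left-ventricular contour trace
#'
#' Per-frame endocardial (and optionally epicardial) contours in mm, plus the
#' long-axis length per frame for PLAX traces.
#'
#' @param time frame timestamps, s.
#' @param endo list of `N x 2` matrices (x, y in mm), one per frame; constant
#'   point count, simple polygons.
#' @param epi optional list like `endo`; per frame its area must be at least
#'   the endocardial area.
#' @param laxis optional numeric vector of long-axis lengths (mm) per frame.
#' @param view `"PLAX"` or `"SAX"`.
#' @return object of class `lv_trace`.
#' @export
lv_trace <- function(time, endo, epi = NULL, laxis = NULL,
                     view = c("PLAX", "SAX")) {
  view <- match.arg(view)
  stopifnot(length(endo) == length(time))
  npts <- vapply(endo, nrow, integer(1))
  if (length(unique(npts)) != 1L)
    stop_musecho("contour point count must be constant across frames",
                 "musecho_invalid_trace")
  if (!is.null(epi)) {
    stopifnot(length(epi) == length(time))
    a_en <- vapply(endo, function(p) abs(shoelace_area(p)), numeric(1))
    a_ep <- vapply(epi, function(p) abs(shoelace_area(p)), numeric(1))
    if (any(a_ep < a_en - 1e-9))
      stop_musecho("epicardial area must be >= endocardial area in every frame",
                   "musecho_invalid_trace")
  }
  structure(list(time = time, endo = endo, epi = epi, laxis = laxis,
                 view = view),
            class = "lv_trace")
}
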