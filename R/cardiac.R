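# Left-ventricular function: volumes and mass from traced contours
# (area-length), speckle-tracking point trajectories, segmental and global
# strain/strain-rate, and heart rate.

MYOCARDIAL_DENSITY <- 1.05  # g/ml

# Chord length of a simple polygon along the minor axis at the mid-level of
# its principal (long) axis.
midcavity_chord <- function(poly) {
  ctr <- colMeans(poly)
  p <- sweep(poly, 2L, ctr)
  ev <- eigen(stats::cov(p), symmetric = TRUE)$vectors
  rot <- p %*% ev                       # column 1: long axis
  x <- rot[, 1L]; y <- rot[, 2L]
  n <- length(x)
  j <- c(2:n, 1L)
  crossing <- (x <= 0 & x[j] > 0) | (x > 0 & x[j] <= 0)
  ys <- y[crossing] + (0 - x[crossing]) / (x[j][crossing] - x[crossing]) *
    (y[j][crossing] - y[crossing])
  if (length(ys) < 2L) return(NA_real_)
  diff(range(ys))
}

# Area-length (monoplane) volume: V = 8 A^2 / (3 pi L), mm^3 == microlitres.
area_length_volume <- function(area, laxis) 8 * area^2 / (3 * pi * laxis)

#' LV systolic metrics from a traced contour sequence
#'
#' Volumes by the monoplane area-length rule `V = 8 A^2 / (3 pi L)` at the
#' end-diastolic (largest) and end-systolic (smallest) frames; `SV = EDV -
#' ESV`, `EF = 100 SV / EDV`, `CO = SV x HR` converted to ml/min, `FS` from
#' the mid-cavity minor-axis chord, and `LVmass = 1.05 (V_epi - V_endo)` at
#' end-diastole (myocardial density 1.05 g/ml; mass in mg for volumes in
#' microlitres).
#'
#' @param trace an [lv_trace()] (PLAX, with `laxis`; epicardial contours
#'   required for the mass).
#' @param hr heart rate, bpm.
#' @return list with `LVmass_mg`, `EDV_ul`, `ESV_ul`, `SV_ul`, `EF_pct`,
#'   `FS_pct`, `CO_ml_min`, and the frame indices `ed_frame`, `es_frame`.
#' @export
lv_metrics <- function(trace, hr) {
  stopifnot(inherits(trace, "lv_trace"))
  if (hr <= 0) stop_musecho("hr must be positive", "musecho_index_error")
  if (is.null(trace$laxis))
    stop_musecho("area-length volumes need the long-axis length per frame",
                 "musecho_index_error")
  areas <- vapply(trace$endo, function(p) abs(shoelace_area(p)), numeric(1))
  vols <- area_length_volume(areas, trace$laxis)
  ed <- which.max(vols); es <- which.min(vols)
  edv <- vols[ed]; esv <- vols[es]
  if (edv <= 0) stop_musecho("nonpositive end-diastolic volume",
                             "musecho_index_error")
  sv <- edv - esv
  lvidd <- midcavity_chord(trace$endo[[ed]])
  lvids <- midcavity_chord(trace$endo[[es]])
  fs <- 100 * (lvidd - lvids) / lvidd
  mass <- NA_real_
  if (!is.null(trace$epi)) {
    a_epi <- abs(shoelace_area(trace$epi[[ed]]))
    l_epi <- trace$laxis[ed] + 2 * (sqrt(a_epi / pi) - sqrt(areas[ed] / pi))
    v_epi <- area_length_volume(a_epi, l_epi)
    mass <- MYOCARDIAL_DENSITY * (v_epi - edv)   # mg for microlitre volumes
  } else {
    stop_musecho("epicardial contours required for LV mass",
                 "musecho_index_error")
  }
  list(LVmass_mg = mass, EDV_ul = edv, ESV_ul = esv, SV_ul = sv,
       EF_pct = 100 * sv / edv, FS_pct = fs,
       CO_ml_min = sv * hr / 1000, ed_frame = ed, es_frame = es)
}

#' Track contour points through a cine loop by block matching
#'
#' Each seeded point is tracked frame to frame by normalised
#' cross-correlation block matching with parabolic sub-pixel refinement. The
#' matching score blends the previous-frame template with the frame-0
#' template (50/50 by default), which controls drift over the loop.
#'
#' @param loop a [cine_loop()].
#' @param contours named list of `N x 2` point matrices (x, y in mm relative
#'   to the image centre), seeded on frame 1 -- e.g. `list(endo = ...,
#'   epi = ...)`.
#' @param block odd block (template) size, px.
#' @param search search half-width, px.
#' @param blend weight of the previous-frame template in the score.
#' @param min_corr correlation below which a point match counts as failed.
#' @param max_fail_frac tolerated fraction of failed points per frame before
#'   a tracking-failure error.
#' @return list of class `trajectories`: `time`, `sets` (per input set an
#'   array `T x N x 2` of (x, y) mm), `score` (T x total points), `view`.
#' @export
speckle_track <- function(loop, contours, block = 17L, search = 7L,
                          blend = 0.5, min_corr = 0.3, max_fail_frac = 0.2) {
  stopifnot(inherits(loop, "cine_loop"), is.list(contours))
  d <- dim(loop$frames)
  h <- d[1L]; w <- d[2L]; n_frames <- d[3L]
  if (block >= min(h, w) || 2L * search + block >= min(h, w))
    stop_musecho("block/search windows exceed the frame", "musecho_roi_error")
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  spx <- loop$pixel_spacing
  mm2px <- function(p) cbind(p[, 2L] / spx[1L] + cy, p[, 1L] / spx[2L] + cx)
  px2mm <- function(p) cbind((p[, 2L] - cx) * spx[2L], (p[, 1L] - cy) * spx[1L])
  sizes <- vapply(contours, nrow, integer(1))
  pts0 <- do.call(rbind, lapply(contours, mm2px))   # (y, x) px, 1-based
  ntot <- nrow(pts0)
  pos <- array(NA_real_, dim = c(n_frames, ntot, 2L))
  score <- matrix(1, n_frames, ntot)
  pos[1L, , ] <- pts0
  cur_pts <- pts0
  f0 <- loop$frames[, , 1L]
  for (i in 2:n_frames) {
    res <- .ncc_step(loop$frames[, , i - 1L], loop$frames[, , i], f0,
                     cur_pts, pts0, as.integer(block), as.integer(search),
                     blend)
    fail <- res[, 3L] < min_corr
    if (mean(fail) > max_fail_frac)
      stop_musecho(sprintf("speckle tracking failed at frame %d: %.0f%% of points below corr %.2f",
                           i, 100 * mean(fail), min_corr),
                   "musecho_tracking_failure")
    cur_pts <- res[, 1:2, drop = FALSE]
    pos[i, , ] <- cur_pts
    score[i, ] <- res[, 3L]
  }
  sets <- list()
  off <- 0L
  for (nm in names(contours)) {
    idx <- off + seq_len(sizes[[nm]])
    arr <- array(NA_real_, dim = c(n_frames, length(idx), 2L))
    for (i in seq_len(n_frames)) arr[i, , ] <- px2mm(pos[i, idx, , drop = TRUE])
    sets[[nm]] <- arr
    off <- off + sizes[[nm]]
  }
  structure(list(time = frame_times(loop), sets = sets, score = score,
                 view = loop$view),
            class = "trajectories")
}

# Arc length of an ordered set of points (open chain).
chain_length <- function(p) sum(sqrt(rowSums(diff(p)^2)))

# Split 1..n into k contiguous spans (the six standard segments).
segment_spans <- function(n, k = 6L) {
  br <- round(seq(1L, n + 1L, length.out = k + 1L))
  lapply(seq_len(k), function(i) br[i]:(br[i + 1L] - 1L))
}

#' Segmental and global Lagrangian strain and strain rate
#'
#' Per segment, strain is `100 (L(t) - L0)/L0` where `L` is the segment's
#' inter-point arc length along the measured direction (circumferential /
#' longitudinal) or the mean endo-to-epi wall thickness (radial). Strain rate
#' is the central-difference time derivative of fractional strain, smoothed
#' with a 5-point moving average. The myocardium is divided into six
#' segments: equal angular/arc-length spans of the contour. The global value
#' is the arithmetic mean of the six segmental peaks (signed extremum: most
#' positive for radial, most negative otherwise).
#'
#' @param traj a `trajectories` object from [speckle_track()] (or built
#'   analytically; see the phantom module). Radial strain needs two point
#'   sets named `endo` and `epi` with paired points; circumferential uses the
#'   midwall (mean of endo/epi when both present), longitudinal the first
#'   set.
#' @param direction `"longitudinal"`, `"radial"` or `"circumferential"`.
#' @param n_segments number of segments (6 standard).
#' @param sr_window strain-rate smoothing window, frames.
#' @return list of class `strain_result`: `time`, `segment_strain`
#'   (T x segments, percent), `segment_rate` (1/s), `segment_peaks`,
#'   `global_peak` (percent), `global_rate_peak` (1/s), `direction`.
#' @export
strain_curves <- function(traj, direction = c("longitudinal", "radial",
                                              "circumferential"),
                          n_segments = 6L, sr_window = 5L) {
  direction <- match.arg(direction)
  t <- traj$time
  nt <- length(t)
  if (direction == "radial") {
    if (is.null(traj$sets$endo) || is.null(traj$sets$epi))
      stop_musecho("radial strain needs paired endo and epi point sets",
                   "musecho_strain_error")
    en <- traj$sets$endo; ep <- traj$sets$epi
    np <- dim(en)[2L]
    spans <- segment_spans(np, n_segments)
    if (any(lengths(spans) < 2L))
      stop_musecho("segment with fewer than 2 points", "musecho_strain_error")
    thick <- sqrt((ep[, , 1L] - en[, , 1L])^2 + (ep[, , 2L] - en[, , 2L])^2)
    seg <- sapply(spans, function(ix) rowMeans(thick[, ix, drop = FALSE]))
  } else {
    ring <- if (!is.null(traj$sets$endo) && !is.null(traj$sets$epi))
      (traj$sets$endo + traj$sets$epi) / 2 else traj$sets[[1L]]
    np <- dim(ring)[2L]
    spans <- segment_spans(np, n_segments)
    if (any(lengths(spans) < 2L))
      stop_musecho("segment with fewer than 2 points", "musecho_strain_error")
    seg <- matrix(NA_real_, nt, n_segments)
    for (i in seq_len(nt)) {
      p <- ring[i, , , drop = TRUE]
      for (k in seq_len(n_segments))
        seg[i, k] <- chain_length(p[spans[[k]], , drop = FALSE])
    }
  }
  l0 <- seg[1L, ]
  strain <- 100 * sweep(seg, 2L, l0, "/") - 100
  rate <- apply(strain / 100, 2L, function(e) movavg(central_diff(e, t), sr_window))
  pick_peak <- function(x) if (direction == "radial") max(x) else min(x)
  seg_peaks <- apply(strain, 2L, pick_peak)
  rate_peaks <- apply(rate, 2L, pick_peak)
  structure(list(time = t, segment_strain = strain, segment_rate = rate,
                 segment_peaks = seg_peaks, global_peak = mean(seg_peaks),
                 segment_rate_peaks = rate_peaks,
                 global_rate_peak = mean(rate_peaks),
                 direction = direction),
            class = "strain_result")
}

#' @export
print.strain_result <- function(x, ...) {
  cat(sprintf("<strain_result> %s: global peak %.2f%%, rate peak %.2f 1/s\n",
              x$direction, x$global_peak, x$global_rate_peak))
  invisible(x)
}

#' Heart rate from an ECG or from cine-loop periodicity
#'
#' With an ECG, `HR = 60 / median(R-R)`. With a cine loop, the cycle length
#' is taken from the first strong autocorrelation peak of the mean frame
#' intensity.
#'
#' @param x list (`signal`, `fs`) or a [cine_loop()] (its attached ECG is
#'   preferred when present).
#' @return heart rate, bpm.
#' @export
heart_rate <- function(x) {
  if (inherits(x, "cine_loop")) {
    if (!is.null(x$ecg)) return(heart_rate(x$ecg))
    mi <- apply(x$frames, 3L, mean)
    n <- length(mi)
    if (n < 8L) stop_musecho("loop too short for periodicity analysis",
                             "musecho_hr_error")
    if (stats::sd(mi) < 1e-9 * max(mean(mi), 1))
      stop_musecho("no periodicity found in frame intensities", "musecho_hr_error")
    ac <- stats::acf(mi - mean(mi), lag.max = n - 2L, plot = FALSE)$acf[, 1, 1]
    lags <- 3:(length(ac) - 1L)
    locmax <- lags[ac[lags + 1L] > 0.25 &
                   ac[lags + 1L] >= ac[lags] & ac[lags + 1L] >= ac[lags + 2L]]
    if (!length(locmax))
      stop_musecho("no periodicity found in frame intensities", "musecho_hr_error")
    return(60 * x$frame_rate / locmax[1L])
  }
  stopifnot(is.list(x), !is.null(x$signal), !is.null(x$fs))
  peaks <- find_r_peaks(x$signal, x$fs)
  if (length(peaks) < 2L)
    stop_musecho("fewer than two R peaks", "musecho_hr_error")
  rr <- diff((peaks - 1L) / x$fs)
  60 / stats::median(rr)
}
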