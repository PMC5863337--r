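# Synthetic ultrasound phantoms with analytic ground truth. Every generator
# is deterministic given (spec, seed) and returns the reference trace /
# contour / truth alongside the rendered data, so downstream estimators can
# be validated by recovery instead of against acquired images.

#' Ground-truth specification for synthetic phantoms
#'
#' Collects every tunable of the phantom world: the vessel diameter waveform,
#' the generating pulse wave velocity, the prescribed LV strain, the Doppler
#' velocity waveform, parenchyma gray means and the noise model. Identical
#' spec and seed yield bit-identical artifacts.
#'
#' @param seed integer RNG seed.
#' @param diameter list with `Dd` (diastolic diameter, mm), `Ds` (systolic,
#'   mm, `>= Dd`), `period` (s) and `upstroke_frac` (fraction of the period
#'   occupied by the systolic upstroke).
#' @param pwv generating pulse wave velocity, m/s (coupled phantoms).
#' @param strain list with fractional `radial` thickening (positive),
#'   `circumferential` and `longitudinal` shortening (positive numbers; the
#'   rendered strains are negative by convention).
#' @param velocity Doppler waveform spec: list with `type` `"renal"` (`PSV`,
#'   `EDV`, optional `MV` target, mm/s) or `"mitral"` (`E`, `A` peak
#'   velocities, mm/s), plus `period` (s).
#' @param gray_means length-2 numeric, (liver, kidney) mean gray levels in
#'   `[0, 255]`.
#' @param noise list with `speckle_sd` (multiplicative speckle contrast,
#'   standard deviation of the unit-mean field) and `additive_sd` (gray
#'   levels).
#' @return an object of class `phantom_truth`.
#' @export
phantom_truth <- function(seed = 1L,
                          diameter = list(Dd = 1.0, Ds = 1.2, period = 0.16,
                                          upstroke_frac = 0.25),
                          pwv = 2.0,
                          strain = list(radial = 0.30, circumferential = 0.20,
                                        longitudinal = 0.15),
                          velocity = list(type = "renal", PSV = 120, EDV = 40,
                                          MV = NULL, period = 0.16),
                          gray_means = c(liver = 120, kidney = 100),
                          noise = list(speckle_sd = 0.25, additive_sd = 2)) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (diameter$Dd <= 0 || diameter$Ds < diameter$Dd)
    stop_musecho("diameter spec requires Ds >= Dd > 0", "musecho_invalid_truth")
  if (diameter$period <= 0 || diameter$upstroke_frac <= 0 ||
      diameter$upstroke_frac >= 1)
    stop_musecho("period must be positive and upstroke_frac in (0,1)",
                 "musecho_invalid_truth")
  if (!is.null(pwv) && pwv <= 0)
    stop_musecho("pwv must be positive", "musecho_invalid_truth")
  if (any(gray_means < 0) || any(gray_means > 255))
    stop_musecho("gray means must lie in [0, 255]", "musecho_invalid_truth")
  if (noise$speckle_sd < 0 || noise$additive_sd < 0)
    stop_musecho("noise levels must be nonnegative", "musecho_invalid_truth")
  structure(list(seed = as.integer(seed), diameter = diameter, pwv = pwv,
                 strain = strain, velocity = velocity,
                 gray_means = gray_means, noise = noise),
            class = "phantom_truth")
}

#' Evaluate the parametric diameter waveform
#'
#' Raised-cosine upstroke from `Dd` to `Ds` over `upstroke_frac` of the
#' period, raised-cosine relaxation back to `Dd` over the remainder; periodic.
#'
#' @param truth a [phantom_truth()] (or its `diameter` list).
#' @param t times, s.
#' @return diameters in mm.
#' @export
diameter_waveform <- function(truth, t) {
  d <- if (inherits(truth, "phantom_truth")) truth$diameter else truth
  ph <- (t %% d$period) / d$period
  s <- ifelse(ph < d$upstroke_frac,
              0.5 * (1 - cos(pi * ph / d$upstroke_frac)),
              0.5 * (1 + cos(pi * (ph - d$upstroke_frac) / (1 - d$upstroke_frac))))
  d$Dd + (d$Ds - d$Dd) * s
}

# Velocity implied by the diameter-velocity loop model over the whole cycle:
# V(t) = 2 * PWV * ln(D(t)/Dd) + v_offset, mm/s with PWV in m/s.
# Single-valued (reflection-free), smooth decay after systole because D(t)
# itself relaxes smoothly. The constant diastolic forward-flow offset shifts
# the loop intercept only, never its slope, so PWV recovery is unaffected.
coupled_velocity <- function(truth, t, v_offset = 0) {
  2 * truth$pwv * 1000 * log(diameter_waveform(truth, t) / truth$diameter$Dd) +
    v_offset
}

# Render one vessel frame: two bright horizontal wall bands (Gaussian axial
# profile, sd sigma_w px) centred at y0 -/+ D/2, dark lumen, multiplicative
# speckle and additive noise already folded in by the caller.
render_vessel_frame <- function(h, w, y_near, y_far, sigma_w = 2.0,
                                lumen = 12, wall = 200) {
  y <- seq_len(h)
  prof <- lumen + wall * (exp(-(y - y_near)^2 / (2 * sigma_w^2)) +
                          exp(-(y - y_far)^2 / (2 * sigma_w^2)))
  matrix(prof, h, w)
}

#' Synthetic pulsating-vessel cine loop
#'
#' Longitudinal view of a straight vessel: two bright wall bands on a dark
#' lumen whose separation follows the prescribed diameter waveform exactly at
#' sub-pixel accuracy, plus correlated multiplicative speckle and additive
#' noise per the truth spec.
#'
#' @param truth a [phantom_truth()].
#' @param n_beats number of cardiac cycles to render.
#' @param frame_rate frames per second (EKV-class default 700).
#' @param pixel_spacing (axial, lateral) mm/px.
#' @param size_px image (height, width) in pixels.
#' @param view loop view tag.
#' @param with_ecg attach an impulse-train ECG (R peak at each cycle start)?
#' @param ecg_fs ECG sampling rate, Hz.
#' @return list with `loop` (a [cine_loop()]), `reference` (the analytic
#'   [diameter_trace()] at frame times) and `truth`.
#' @export
make_vessel_cine <- function(truth, n_beats = 4, frame_rate = 700,
                             pixel_spacing = c(0.02, 0.02),
                             size_px = c(96, 48),
                             view = "aorta-long-axis",
                             with_ecg = FALSE, ecg_fs = 1000) {
  stopifnot(inherits(truth, "phantom_truth"))
  h <- size_px[1L]; w <- size_px[2L]
  n_frames <- max(2L, ceiling(n_beats * truth$diameter$period * frame_rate))
  t <- (seq_len(n_frames) - 1L) / frame_rate
  D <- diameter_waveform(truth, t)
  y0 <- (h + 1) / 2
  half_px <- max(D) / 2 / pixel_spacing[1L]
  if (y0 - half_px < 8 || y0 + half_px > h - 7)
    stop_musecho("vessel does not fit in the frame: enlarge size_px or shrink the diameter",
                 "musecho_sizing_error")
  frames <- with_seed(truth$seed, {
    arr <- array(0, dim = c(h, w, n_frames))
    for (i in seq_len(n_frames)) {
      half <- D[i] / 2 / pixel_spacing[1L]
      img <- render_vessel_frame(h, w, y0 - half, y0 + half)
      img <- img * speckle_field(h, w, truth$noise$speckle_sd)
      if (truth$noise$additive_sd > 0)
        img <- img + matrix(stats::rnorm(h * w, 0, truth$noise$additive_sd), h, w)
      arr[, , i] <- clamp255(img)
    }
    arr
  })
  ecg <- if (with_ecg) make_ecg(n_frames / frame_rate, truth$diameter$period, ecg_fs)
         else NULL
  loop <- cine_loop(frames, pixel_spacing, frame_rate, ecg, view)
  list(loop = loop, reference = diameter_trace(t, D), truth = truth)
}

#' Impulse-train ECG at a prescribed cycle length
#'
#' Only R-peak timing is consumed downstream, so the trace is a unit impulse
#' at each cycle start on a zero baseline.
#'
#' @param duration s.
#' @param period cycle length, s.
#' @param fs sampling rate, Hz.
#' @return list with `signal` and `fs`.
#' @export
make_ecg <- function(duration, period, fs = 1000) {
  n <- ceiling(duration * fs) + 1L
  sig <- numeric(n)
  peaks <- seq(0, duration, by = period)
  sig[pmin(n, round(peaks * fs) + 1L)] <- 1
  list(signal = sig, fs = fs)
}

# Spectrogram renderer: one column per time bin. Power is a mixture of a
# uniform fill between baseline and V(t) (weight 0.3) and a half-Gaussian
# envelope band just below V(t) (weight 0.7, sd sigma_v mm/s), so the
# cumulative-power envelope detector lands within a bin of V(t).
render_spectrogram <- function(v_ref, time_axis, prf, noise,
                               seed, v_axis = NULL, sigma_v = NULL,
                               angle_correction = 60,
                               velocity_per_hz = 0.0642) {
  # one-sided span with the baseline shifted to the far edge, the usual
  # setting for unidirectional arterial flow: the full PRF maps to velocity
  v_nyq <- velocity_per_hz * prf
  if (max(abs(v_ref)) > v_nyq)
    stop_musecho(sprintf(
      "waveform peak %.0f mm/s exceeds the PRF-implied Nyquist velocity %.0f mm/s (aliasing)",
      max(abs(v_ref)), v_nyq), "musecho_aliasing_error")
  if (is.null(v_axis)) {
    vmax <- max(1.35 * max(abs(v_ref)), 50)
    vlo <- if (min(v_ref) < 0) -vmax else -0.15 * vmax
    v_axis <- seq(vlo, vmax, length.out = 160L)
  }
  dv <- v_axis[2L] - v_axis[1L]
  if (is.null(sigma_v)) sigma_v <- 2 * dv
  nt <- length(time_axis); nv <- length(v_axis)
  power <- matrix(0, nv, nt)
  for (j in seq_len(nt)) {
    V <- v_ref[j]
    s <- sign(V); if (s == 0) s <- 1
    a <- abs(V)
    va <- s * v_axis     # fold so the signal side is positive
    col <- numeric(nv)
    if (a >= 2 * dv) {
      inband <- va >= 0 & va <= a
      col[inband] <- 0.3 / a * dv
    }
    band <- va <= a
    col[band] <- col[band] +
      0.7 * 2 / (sigma_v * sqrt(2 * pi)) * dv *
      exp(-(va[band] - a)^2 / (2 * sigma_v^2))
    power[, j] <- col
  }
  power <- power / max(power) * 220
  with_seed(seed, {
    if (noise$speckle_sd > 0)
      power <- power * speckle_field(nv, nt, noise$speckle_sd)
    if (noise$additive_sd > 0)
      power <- power + abs(matrix(stats::rnorm(nv * nt, 0, noise$additive_sd), nv, nt))
    power
  }) -> power
  spectrogram(pmax(power, 0), time_axis, v_axis, prf, angle_correction)
}

#' Coupled vessel phantom: cine loop plus Doppler spectrogram
#'
#' The velocity waveform is constructed from the diameter waveform through the
#' diameter-velocity loop model, `V(t) = 2 PWV ln(D(t)/Dd)` (mm/s, PWV in
#' m/s), so the loop-based PWV estimator is well-posed and its truth known.
#'
#' @inheritParams make_vessel_cine
#' @param prf Doppler pulse repetition frequency, Hz.
#' @param dt_doppler spectrogram time-bin width, s.
#' @param v_offset constant diastolic forward-flow velocity added to the
#'   loop-model waveform, mm/s (shifts the loop intercept, not its slope).
#' @return list with `loop`, `spec` (the [spectrogram()]), `reference_d` and
#'   `reference_v` (analytic traces) and `truth`.
#' @export
make_coupled_vessel <- function(truth, n_beats = 4, frame_rate = 700,
                                pixel_spacing = c(0.02, 0.02),
                                size_px = c(96, 48),
                                view = "aorta-long-axis",
                                with_ecg = FALSE, prf = 17500,
                                dt_doppler = 0.002, v_offset = 0) {
  if (is.null(truth$pwv))
    stop_musecho("coupled phantom requires truth$pwv", "musecho_invalid_truth")
  vessel <- make_vessel_cine(truth, n_beats, frame_rate, pixel_spacing,
                             size_px, view, with_ecg)
  t_dop <- seq(0, n_beats * truth$diameter$period, by = dt_doppler)
  v_ref <- coupled_velocity(truth, t_dop, v_offset)
  spec <- render_spectrogram(v_ref, t_dop, prf, truth$noise,
                             seed = truth$seed + 101L)
  list(loop = vessel$loop, spec = spec,
       reference_d = vessel$reference,
       reference_v = velocity_trace(t_dop, v_ref),
       truth = truth)
}

# Renal-type velocity waveform shape on phase u in [0,1): raised-cosine
# upstroke over u_up, then power-law relaxation (1-x)^alpha. Returns the
# shape in [0,1]; V = EDV + (PSV-EDV)*shape.
renal_shape <- function(u, u_up = 0.15, alpha = 2) {
  ifelse(u < u_up,
         0.5 * (1 - cos(pi * u / u_up)),
         (1 - (u - u_up) / (1 - u_up))^alpha)
}

# Solve the relaxation exponent so the cycle-mean velocity hits the MV
# target, if attainable.
solve_renal_alpha <- function(PSV, EDV, MV, u_up = 0.15) {
  target <- (MV - EDV) / (PSV - EDV)
  f <- function(a) mean(renal_shape(seq(0, 1, length.out = 4001L), u_up, a)) - target
  lo <- f(0.2); hi <- f(12)
  if (sign(lo) == sign(hi))
    stop_musecho("MV target unattainable for this PSV/EDV pair", "musecho_invalid_truth")
  stats::uniroot(f, c(0.2, 12), tol = 1e-10)$root
}

#' Evaluate the parametric Doppler velocity waveform
#'
#' @param vspec a velocity spec list (see [phantom_truth()]).
#' @param t times, s.
#' @return velocities, mm/s.
#' @export
velocity_waveform <- function(vspec, t) {
  u <- (t %% vspec$period) / vspec$period
  if (identical(vspec$type, "renal")) {
    alpha <- if (!is.null(vspec$MV))
      solve_renal_alpha(vspec$PSV, vspec$EDV, vspec$MV) else 2
    vspec$EDV + (vspec$PSV - vspec$EDV) * renal_shape(u, alpha = alpha)
  } else if (identical(vspec$type, "mitral")) {
    bump <- function(u, c, w) {
      x <- (u - c) / w
      ifelse(abs(x) < 1, 0.5 * (1 + cos(pi * x)), 0)
    }
    vspec$E * bump(u, 0.35, 0.12) + vspec$A * bump(u, 0.72, 0.12)
  } else if (identical(vspec$type, "flat")) {
    rep(vspec$value, length(t))
  } else stop_musecho("unknown velocity waveform type", "musecho_invalid_truth")
}

#' Synthetic PW-Doppler spectrogram with reference envelope
#'
#' @param vspec velocity waveform spec (see [phantom_truth()]); `type`
#'   `"renal"`, `"mitral"` or `"flat"` (constant `value`).
#' @param seed RNG seed.
#' @param n_cycles number of cardiac cycles.
#' @param prf pulse repetition frequency, Hz; waveform peaks above the
#'   PRF-implied Nyquist velocity raise an aliasing error.
#' @param dt time-bin width, s.
#' @param noise list (`speckle_sd`, `additive_sd`); defaults to noiseless.
#' @return list with `spec` (the [spectrogram()]) and `reference` (analytic
#'   [velocity_trace()] with PSV/EDV/MV filled over the first cycle).
#' @export
make_doppler_trace <- function(vspec, seed = 1L, n_cycles = 2, prf = 9500,
                               dt = 0.001,
                               noise = list(speckle_sd = 0, additive_sd = 0)) {
  t <- seq(0, n_cycles * vspec$period - dt / 2, by = dt)
  v <- velocity_waveform(vspec, t)
  spec <- render_spectrogram(v, t, prf, noise, seed)
  cyc <- which(t < vspec$period)
  ref <- velocity_trace(t, v, cycle_bounds = range(cyc),
                        PSV = max(v[cyc]), EDV = min(v[cyc]), MV = mean(v[cyc]))
  list(spec = spec, reference = ref)
}

# Cyclic deformation phase: 0 at end-diastole, 1 at peak systole.
lv_phase <- function(t, period) 0.5 * (1 - cos(2 * pi * (t %% period) / period))

#' Synthetic left-ventricle cine loop with prescribed strain
#'
#' SAX view: a speckle-textured annulus whose wall thickens by the prescribed
#' radial fraction while its midwall radius shortens by the circumferential
#' fraction; the displacement field is analytic, so true strain is known in
#' closed form. PLAX view: an elliptical annulus under uniform scaling by the
#' longitudinal shortening fraction (every arc shortens by exactly that
#' fraction). The speckle texture is material (advected with the tissue), so
#' block matching can recover the field.
#'
#' @param truth a [phantom_truth()] (uses `strain`, `diameter$period`,
#'   `noise`, `seed`).
#' @param view `"SAX"` or `"PLAX"`.
#' @param n_beats cycles to render.
#' @param frame_rate fps.
#' @param pixel_spacing (axial, lateral) mm/px.
#' @param size_px image size (height, width) px.
#' @param geometry SAX: list `r_endo`, `r_epi` (end-diastolic radii, mm);
#'   PLAX: list `a`, `b` (endocardial semi-axes, mm), `wall` (thickness, mm).
#' @param n_contour points per reference contour ring.
#' @return list with `loop`, `contours` (per-frame endo/epi reference rings,
#'   mm), `true_strain` (percent peaks per direction), `phase` (deformation
#'   phase per frame) and `truth`.
#' @export
make_lv_cine <- function(truth, view = c("SAX", "PLAX"), n_beats = 1,
                         frame_rate = 250, pixel_spacing = c(0.035, 0.035),
                         size_px = c(128, 128), geometry = NULL,
                         n_contour = 48L) {
  view <- match.arg(view)
  stopifnot(inherits(truth, "phantom_truth"))
  h <- size_px[1L]; w <- size_px[2L]
  period <- truth$diameter$period
  n_frames <- max(2L, ceiling(n_beats * period * frame_rate))
  t <- (seq_len(n_frames) - 1L) / frame_rate
  s <- lv_phase(t, period)
  px <- pixel_spacing[1L]
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  theta <- seq(0, 2 * pi, length.out = n_contour + 1L)[-(n_contour + 1L)]

  # reference material texture: wall intensity plus correlated speckle,
  # sampled on the end-diastolic (s = 0) configuration
  tex <- with_seed(truth$seed, 1 + 0.35 * (speckle_field(h, w, 1) - 1))
  noise_fields <- with_seed(truth$seed + 7L, {
    if (truth$noise$additive_sd > 0)
      lapply(seq_len(n_frames), function(i)
        matrix(stats::rnorm(h * w, 0, truth$noise$additive_sd), h, w))
    else NULL
  })

  xg <- matrix(rep(seq_len(w), each = h), h, w)
  yg <- matrix(rep(seq_len(h), w), h, w)

  bilinear <- function(img, xq, yq) {
    x0 <- floor(xq); y0 <- floor(yq)
    x0 <- pmin(pmax(x0, 1L), w - 1L); y0 <- pmin(pmax(y0, 1L), h - 1L)
    fx <- pmin(pmax(xq - x0, 0), 1); fy <- pmin(pmax(yq - y0, 0), 1)
    i00 <- (x0 - 1L) * h + y0
    img[i00] * (1 - fx) * (1 - fy) + img[i00 + h] * fx * (1 - fy) +
      img[i00 + 1L] * (1 - fx) * fy + img[i00 + h + 1L] * fx * fy
  }

  frames <- array(0, dim = c(h, w, n_frames))
  contours <- vector("list", n_frames)

  if (view == "SAX") {
    geom <- geometry %||% list(r_endo = 0.9, r_epi = 1.4)
    rm0 <- (geom$r_endo + geom$r_epi) / 2
    w0 <- geom$r_epi - geom$r_endo
    alpha <- truth$strain$radial %||% 0
    beta <- truth$strain$circumferential %||% 0
    rmax <- max((rm0 * (1 - beta * s) + w0 * (1 + alpha * s) / 2)) / px
    if (rmax + 6 > min(cx, cy))
      stop_musecho("deformed wall leaves the frame: enlarge size_px",
                   "musecho_sizing_error")
    r_px <- sqrt((xg - cx)^2 + (yg - cy)^2) * px  # radius in mm
    th <- atan2(yg - cy, xg - cx)
    for (i in seq_len(n_frames)) {
      rmi <- rm0 * (1 - beta * s[i]); wi <- w0 * (1 + alpha * s[i])
      r0 <- rm0 + (r_px - rmi) * w0 / wi          # material radius, mm
      x0q <- cx + r0 / px * cos(th); y0q <- cy + r0 / px * sin(th)
      body <- bilinear(tex, x0q, y0q)
      re <- rmi - wi / 2; rp <- rmi + wi / 2
      edge <- 1.5 * px
      mask <- pmin(pmax((r_px - (re - edge)) / edge, 0), 1) *
              pmin(pmax(((rp + edge) - r_px) / edge, 0), 1)
      img <- 10 + 170 * body * mask
      if (!is.null(noise_fields)) img <- img + noise_fields[[i]]
      frames[, , i] <- clamp255(img)
      # contours in mm relative to the image centre
      contours[[i]] <- list(endo = cbind(re * cos(theta), re * sin(theta)),
                            epi = cbind(rp * cos(theta), rp * sin(theta)))
    }
    true_strain <- list(radial = 100 * alpha,
                        circumferential = -100 * beta)
  } else {
    geom <- geometry %||% list(a = 1.6, b = 0.9, wall = 0.4)
    gam <- truth$strain$longitudinal %||% 0
    amax <- (geom$a + geom$wall) / px
    if (amax + 6 > cx || (geom$b + geom$wall) / px + 6 > cy)
      stop_musecho("LV geometry does not fit in the frame", "musecho_sizing_error")
    xm <- (xg - cx) * px; ym <- (yg - cy) * px  # mm from centre
    for (i in seq_len(n_frames)) {
      k <- 1 - gam * s[i]                        # uniform scale factor
      x0 <- xm / k; y0 <- ym / k                 # material coords, mm
      rho <- sqrt((x0 / geom$a)^2 + (y0 / geom$b)^2)
      rho_o <- sqrt((x0 / (geom$a + geom$wall))^2 + (y0 / (geom$b + geom$wall))^2)
      edge <- 0.08
      mask <- pmin(pmax((rho - (1 - edge)) / edge, 0), 1) *
              pmin(pmax((1 + edge - rho_o) / edge, 0), 1)
      body <- bilinear(tex, cx + x0 / px, cy + y0 / px)
      img <- 10 + 170 * body * mask
      if (!is.null(noise_fields)) img <- img + noise_fields[[i]]
      frames[, , i] <- clamp255(img)
      contours[[i]] <- list(
        endo = cbind(k * geom$a * cos(theta), k * geom$b * sin(theta)),
        epi = cbind(k * (geom$a + geom$wall) * cos(theta),
                    k * (geom$b + geom$wall) * sin(theta)))
    }
    true_strain <- list(longitudinal = -100 * gam)
  }
  loop <- cine_loop(frames, pixel_spacing, frame_rate, NULL, view)
  list(loop = loop, contours = contours, true_strain = true_strain,
       phase = s, truth = truth)
}

#' Analytic PLAX contour trace with prescribed volumes
#'
#' Generates per-frame endocardial and epicardial ellipse contours whose
#' area-length volumes interpolate between a prescribed end-diastolic and
#' end-systolic volume, for testing and driving the LV metrics stage without
#' image tracking. Cavity semi-axes scale between the two states with a
#' raised-cosine time course; the wall thickens to conserve myocardial
#' volume approximately.
#'
#' @param edv,esv end-diastolic / end-systolic cavity volume, microlitres.
#' @param hr heart rate, bpm (sets the cycle period).
#' @param wall wall thickness at end-diastole, mm.
#' @param n_frames frames per cycle.
#' @param aspect long-axis to short-axis ratio of the cavity ellipse.
#' @param n_contour contour points.
#' @return an [lv_trace()] with attribute `"truth"` carrying the prescribed
#'   volumes.
#' @export
make_lv_contour_trace <- function(edv = 50, esv = 25, hr = 400, wall = 0.8,
                                  n_frames = 40L, aspect = 2.0,
                                  n_contour = 64L) {
  stopifnot(edv > 0, esv > 0, esv <= edv, hr > 0)
  period <- 60 / hr
  t <- seq(0, period, length.out = n_frames)
  # prolate ellipsoid: V = (4/3) pi (L/2) b^2 with L = 2 a, a = aspect * b
  b_of_v <- function(v) (v * 3 / (4 * pi * aspect))^(1 / 3)
  s <- lv_phase(t, period + 1e-12)
  vols <- edv + (esv - edv) * s
  theta <- seq(0, 2 * pi, length.out = n_contour + 1L)[-(n_contour + 1L)]
  endo <- list(); epi <- list(); laxis <- numeric(n_frames)
  for (i in seq_len(n_frames)) {
    b <- b_of_v(vols[i]); a <- aspect * b
    endo[[i]] <- cbind(a * cos(theta), b * sin(theta))
    epi[[i]] <- cbind((a + wall) * cos(theta), (b + wall) * sin(theta))
    laxis[i] <- 2 * a
  }
  tr <- lv_trace(t, endo, epi, laxis, view = "PLAX")
  attr(tr, "truth") <- list(edv = edv, esv = esv, hr = hr)
  tr
}

#' Synthetic liver/kidney B-mode image with prescribed mean gray levels
#'
#' Two textured parenchyma regions side by side (liver left, kidney right)
#' whose ROI-interior expected means equal the prescribed levels; the speckle
#' texture is mean-preserving.
#'
#' @param gray_means length-2 numeric, (liver, kidney) means in `[0, 255]`.
#' @param seed RNG seed.
#' @param size_px image (height, width).
#' @param noise list (`speckle_sd`, `additive_sd`).
#' @return list with `image` (matrix), `liver_roi` and `kidney_roi`
#'   (rectangles `c(row0, col0, row1, col1)`, 0-based half-open) and
#'   `gray_means`.
#' @export
make_liver_kidney_image <- function(gray_means = c(liver = 120, kidney = 100),
                                    seed = 1L, size_px = c(128, 160),
                                    noise = list(speckle_sd = 0.25,
                                                 additive_sd = 0)) {
  if (any(gray_means < 0) || any(gray_means > 255))
    stop_musecho("gray means must lie in [0, 255]", "musecho_invalid_truth")
  h <- size_px[1L]; w <- size_px[2L]
  half <- w %/% 2L
  img <- with_seed(seed, {
    m <- matrix(0, h, w)
    m[, seq_len(half)] <- gray_means[1L] *
      speckle_field(h, half, noise$speckle_sd)
    m[, (half + 1L):w] <- gray_means[2L] *
      speckle_field(h, w - half, noise$speckle_sd)
    if (noise$additive_sd > 0)
      m <- m + matrix(stats::rnorm(h * w, 0, noise$additive_sd), h, w)
    m
  })
  list(image = clamp255(img),
       liver_roi = c(h %/% 4L, half %/% 4L, 3L * (h %/% 4L), 3L * (half %/% 4L)),
       kidney_roi = c(h %/% 4L, half + half %/% 4L, 3L * (h %/% 4L),
                      half + 3L * (half %/% 4L)),
       gray_means = gray_means)
}
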