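# LV metrics, speckle tracking, strain curves, heart rate.

test_that("lv_metrics arithmetic is internally exact and ellipsoid-accurate", {
  tr <- make_lv_contour_trace(edv = 50, esv = 25, hr = 400)
  m <- lv_metrics(tr, hr = 400)
  # area-length on a discretised ellipse matches the closed-form ellipsoid
  expect_equal(m$EDV_ul, 50, tolerance = 0.02 * 50)
  expect_equal(m$ESV_ul, 25, tolerance = 0.02 * 25)
  # formula layer: exact identities
  expect_equal(m$SV_ul, m$EDV_ul - m$ESV_ul, tolerance = 1e-9)
  expect_equal(m$EF_pct, 100 * m$SV_ul / m$EDV_ul, tolerance = 1e-9)
  expect_equal(m$CO_ml_min, m$SV_ul * 400 / 1000, tolerance = 1e-9)
  expect_equal(m$EF_pct, 50, tolerance = 1)
  # CO unit conversion: SV 40 ul at 400 bpm = 16 ml/min
  tr2 <- make_lv_contour_trace(edv = 80, esv = 40, hr = 400)
  m2 <- lv_metrics(tr2, hr = 400)
  expect_equal(m2$CO_ml_min, m2$SV_ul * 400 / 1000, tolerance = 1e-9)
  expect_equal(m2$CO_ml_min, 16, tolerance = 0.6)
  expect_error(lv_metrics(tr, hr = 0), class = "musecho_index_error")
})

test_that("LV mass is nonnegative, zero iff epi == endo, and EF scale-free", {
  tr <- make_lv_contour_trace(edv = 60, esv = 30, hr = 350, wall = 0.8)
  m <- lv_metrics(tr, 350)
  expect_gt(m$LVmass_mg, 0)
  degen <- lv_trace(tr$time, tr$endo, tr$endo, tr$laxis, view = "PLAX")
  expect_equal(lv_metrics(degen, 350)$LVmass_mg, 0, tolerance = 1e-9)
  # EF invariant to uniform spatial scaling
  sc <- lv_trace(tr$time, lapply(tr$endo, function(p) 1.7 * p),
                 lapply(tr$epi, function(p) 1.7 * p), 1.7 * tr$laxis,
                 view = "PLAX")
  expect_equal(lv_metrics(sc, 350)$EF_pct, m$EF_pct, tolerance = 1e-9)
  expect_error(lv_metrics(lv_trace(tr$time, tr$endo, NULL, tr$laxis,
                                   view = "PLAX"), 350),
               class = "musecho_index_error")
})

test_that("block matching recovers rigid translation at 2 px/frame", {
  base <- musecho:::with_seed(9, musecho:::speckle_field(90, 90, 1))
  nfr <- 5L
  arr <- array(10, dim = c(90, 90, nfr))
  for (i in seq_len(nfr)) {
    sh <- 2L * (i - 1L)
    arr[(1L + sh):90, , i] <- musecho:::clamp255(20 + 150 * base[1:(90 - sh), ])
  }
  loop <- cine_loop(arr, c(0.05, 0.05), 100, view = "SAX")
  pts <- cbind(seq(-0.8, 0.8, length.out = 10), rep(-0.5, 10))  # mm
  traj <- speckle_track(loop, list(p = pts), block = 13, search = 5,
                        blend = 1)   # pure frame-to-frame for a known shift
  slopes <- apply(traj$sets$p[, , 2L], 2L, function(y) mean(diff(y))) / 0.05
  expect_true(all(abs(slopes - 2) < 0.1))
  # static sequence: zero displacement everywhere
  stat <- cine_loop(array(rep(arr[, , 1L], 4), dim = c(90, 90, 4)),
                    c(0.05, 0.05), 100, view = "SAX")
  ts <- speckle_track(stat, list(p = pts), block = 13, search = 5)
  disp <- sqrt((ts$sets$p[4, , 1] - ts$sets$p[1, , 1])^2 +
               (ts$sets$p[4, , 2] - ts$sets$p[1, , 2])^2) / 0.05
  expect_true(all(disp < 0.1))
})

test_that("tracking follows the prescribed radial thickening field", {
  tr <- phantom_truth(seed = 2, noise = noiseless,
                      strain = list(radial = 0.2, circumferential = 0.15,
                                    longitudinal = 0))
  lv <- make_lv_cine(tr, view = "SAX", n_beats = 1)
  c0 <- lv$contours[[1L]]
  traj <- speckle_track(lv$loop, list(endo = c0$endo, epi = c0$epi))
  # compare tracked endo positions with the reference contour at peak phase
  pk <- which.max(lv$phase)
  err_px <- sqrt((traj$sets$endo[pk, , 1L] - lv$contours[[pk]]$endo[, 1L])^2 +
                 (traj$sets$endo[pk, , 2L] - lv$contours[[pk]]$endo[, 2L])^2) /
    lv$loop$pixel_spacing[1L]
  expect_lt(stats::median(err_px), 0.5)
  expect_lt(max(err_px), 1.5)
})

test_that("tracking failure raises on structureless input", {
  arr <- array(128, dim = c(64, 64, 3))
  loop <- cine_loop(arr, c(0.05, 0.05), 100, view = "SAX")
  pts <- cbind(seq(-0.5, 0.5, length.out = 8), rep(0, 8))
  expect_error(speckle_track(loop, list(p = pts), block = 13, search = 5),
               class = "musecho_tracking_failure")
  expect_error(speckle_track(loop, list(p = pts), block = 65, search = 5),
               class = "musecho_roi_error")
})

test_that("strain curves are Lagrangian with exact global averaging", {
  # analytic ring scaled to 0.9: every segment -10%, global -10
  k <- c(1, 0.975, 0.95, 0.925, 0.9)
  traj <- analytic_ring_traj(k)
  sc <- strain_curves(traj, "circumferential")
  expect_equal(unname(sc$segment_strain[5L, ]), rep(-10, 6), tolerance = 1e-9)
  expect_equal(sc$global_peak, mean(sc$segment_peaks), tolerance = 1e-12)
  expect_equal(sc$global_peak, -10, tolerance = 1e-9)
  expect_equal(unname(sc$segment_strain[1L, ]), rep(0, 6))
  # strain-rate is the time derivative of fractional strain
  expect_equal(dim(sc$segment_rate), dim(sc$segment_strain))
  # two successive 10% stretches compose to 21% Lagrangian strain
  k2 <- c(1, 1.1, 1.1 * 1.1)
  s2c <- strain_curves(analytic_ring_traj(k2), "circumferential")
  expect_equal(unname(s2c$segment_strain[3L, ]), rep(21, 6), tolerance = 1e-9)
  expect_error(strain_curves(analytic_ring_traj(k, n_pts = 6L), "radial"),
               class = "musecho_strain_error")
})

test_that("radial strain needs paired contours and measures thickness", {
  nfr <- 4L
  th <- c(0.5, 0.55, 0.6, 0.65)   # mm thickness ramp: +30% at end
  n_pts <- 12L
  theta <- seq(0, 2 * pi, length.out = n_pts + 1L)[-(n_pts + 1L)]
  en <- ep <- array(NA_real_, dim = c(nfr, n_pts, 2L))
  for (i in seq_len(nfr)) {
    en[i, , 1L] <- cos(theta); en[i, , 2L] <- sin(theta)
    ep[i, , 1L] <- (1 + th[i]) * cos(theta)
    ep[i, , 2L] <- (1 + th[i]) * sin(theta)
  }
  traj <- structure(list(time = seq(0, 0.3, length.out = nfr),
                         sets = list(endo = en, epi = ep), view = "SAX"),
                    class = "trajectories")
  sr <- strain_curves(traj, "radial")
  expect_equal(sr$global_peak, 100 * (0.65 - 0.5) / 0.5, tolerance = 1e-9)
})

test_that("speckle-tracked strain recovers prescribed deformations", {
  tr <- phantom_truth(seed = 2, noise = noiseless,
                      strain = list(radial = 0.3, circumferential = 0.2,
                                    longitudinal = 0.15))
  lv <- make_lv_cine(tr, view = "SAX", n_beats = 1)
  c0 <- lv$contours[[1L]]
  traj <- speckle_track(lv$loop, list(endo = c0$endo, epi = c0$epi))
  gRS <- strain_curves(traj, "radial")$global_peak
  gCS <- strain_curves(traj, "circumferential")$global_peak
  expect_lt(abs(gRS - 30), 2)
  expect_lt(abs(gCS - (-20)), 2)
  expect_gt(gRS, 0)        # thickening positive
  expect_lt(gCS, 0)        # shortening negative
  pl <- make_lv_cine(tr, view = "PLAX", n_beats = 1)
  cp0 <- pl$contours[[1L]]
  tj <- speckle_track(pl$loop, list(endo = cp0$endo, epi = cp0$epi))
  gLS <- strain_curves(tj, "longitudinal")$global_peak
  expect_lt(abs(gLS - (-15)), 2)
  expect_lt(gLS, 0)
})

test_that("heart rate from ECG and from cine periodicity", {
  expect_equal(heart_rate(make_ecg(1.0, 0.2, 1000)), 300, tolerance = 1e-9)
  expect_equal(heart_rate(make_ecg(1.2, 0.1587, 1000)), 378, tolerance = 1)
  # jittered intervals: median rule
  sig <- numeric(800); sig[c(1, 191, 391, 601)] <- 1
  expect_equal(heart_rate(list(signal = sig, fs = 1000)), 60 / 0.2,
               tolerance = 1e-9)
  expect_error(heart_rate(list(signal = c(0, 1, 0), fs = 1000)),
               class = "musecho_hr_error")
  # from the loop itself (mean-intensity periodicity): the SAX annulus
  # changes its wall area over the cycle, the vessel phantom does not
  trlv <- phantom_truth(seed = 2, noise = noiseless)
  lv <- make_lv_cine(trlv, n_beats = 3, frame_rate = 125)
  expect_equal(heart_rate(lv$loop), 60 / 0.16, tolerance = 8)
  flat <- cine_loop(array(100, dim = c(16, 16, 20)), c(0.05, 0.05), 100,
                    view = "SAX")
  expect_error(heart_rate(flat), class = "musecho_hr_error")
})
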