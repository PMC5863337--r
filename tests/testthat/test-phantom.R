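# Phantom generators: geometry, determinism, noise contract, coupling.

test_that("vessel phantom geometry follows the prescribed waveform", {
  tr <- truth_basic()
  v <- make_vessel_cine(tr, n_beats = 2)
  # systolic frame: wall-band centre separation = Ds / axial spacing px
  sys <- which.max(v$reference$diameter_mm)
  e <- detect_wall_edges(v$loop$frames[, , sys])
  expect_equal(e$far - e$near, 1.2 / 0.02, tolerance = 0.01)
  # reference trace is the analytic waveform at frame times (machine precision)
  expect_equal(v$reference$diameter_mm,
               diameter_waveform(tr, v$reference$time))
  # ECG spans the loop and peaks at cycle starts
  ve <- make_vessel_cine(tr, n_beats = 2, with_ecg = TRUE)
  expect_gte((length(ve$loop$ecg$signal) - 1) / ve$loop$ecg$fs,
             (dim(ve$loop$frames)[3] - 1) / ve$loop$frame_rate)
})

test_that("static vessel phantom gives a constant reference with zero distension", {
  tr <- truth_basic(Ds = 1.0)
  v <- make_vessel_cine(tr, n_beats = 2)
  expect_equal(diff(range(v$reference$diameter_mm)), 0)
})

test_that("identical spec + seed gives bit-identical artifacts", {
  tr <- truth_basic(seed = 7, noise = list(speckle_sd = 0.25, additive_sd = 2))
  a <- make_vessel_cine(tr, n_beats = 1)
  b <- make_vessel_cine(tr, n_beats = 1)
  expect_identical(a$loop$frames, b$loop$frames)
  img1 <- make_liver_kidney_image(seed = 9)
  img2 <- make_liver_kidney_image(seed = 9)
  expect_identical(img1$image, img2$image)
  s1 <- make_doppler_trace(list(type = "renal", PSV = 120, EDV = 40,
                                period = 0.16), seed = 5,
                           noise = list(speckle_sd = 0.2, additive_sd = 1))
  s2 <- make_doppler_trace(list(type = "renal", PSV = 120, EDV = 40,
                                period = 0.16), seed = 5,
                           noise = list(speckle_sd = 0.2, additive_sd = 1))
  expect_identical(s1$spec$power, s2$spec$power)
})

test_that("phantom truth invariants are enforced", {
  expect_error(phantom_truth(diameter = list(Dd = 1.2, Ds = 1.0, period = 0.16,
                                             upstroke_frac = 0.25)),
               class = "musecho_invalid_truth")
  expect_error(phantom_truth(gray_means = c(300, 100)),
               class = "musecho_invalid_truth")
  expect_error(phantom_truth(pwv = -1), class = "musecho_invalid_truth")
  # oversized vessel is rejected, not silently cropped
  big <- truth_basic(Dd = 3, Ds = 3.2)
  expect_error(make_vessel_cine(big), class = "musecho_sizing_error")
})

test_that("coupled phantom satisfies the loop relation", {
  tr <- truth_basic(Ds = 1.1)
  cp <- make_coupled_vessel(tr, n_beats = 2)
  # peak velocity = 2 * PWV * ln(Ds/Dd), evaluated directly
  expect_equal(max(cp$reference_v$velocity), 2 * 2000 * log(1.1),
               tolerance = 1e-6)
  expect_equal(2 * 2000 * log(1.1), 381.2, tolerance = 1e-3)
  # degenerate: static diameter gives identically zero velocity
  st <- make_coupled_vessel(truth_basic(Ds = 1.0), n_beats = 1)
  expect_equal(max(abs(st$reference_v$velocity)), 0)
  # aliasing is refused, never rendered
  fast <- truth_basic(pwv = 8, Ds = 1.2)
  expect_error(make_coupled_vessel(fast, prf = 9500),
               class = "musecho_aliasing_error")
})

test_that("doppler phantom reference indices are by construction", {
  ren <- make_doppler_trace(list(type = "renal", PSV = 120, EDV = 40,
                                 period = 0.16), seed = 1)
  expect_equal(ren$reference$PSV, 120, tolerance = 1e-6)
  expect_equal(ren$reference$EDV, 40, tolerance = 1e-6)
  ri <- renal_indices(ren$reference$PSV, ren$reference$EDV, ren$reference$MV)
  expect_equal(ri$RI, (120 - 40) / 120, tolerance = 1e-6)
  # MV target honoured by the relaxation-exponent solve
  ren2 <- make_doppler_trace(list(type = "renal", PSV = 200, EDV = 50,
                                  MV = 110, period = 0.16), seed = 1,
                             prf = 20000)
  expect_equal(ren2$reference$MV, 110, tolerance = 0.01)
  # flat waveform: PSV = EDV = MV
  fl <- make_doppler_trace(list(type = "flat", value = 75, period = 0.16),
                           seed = 1, prf = 20000)
  expect_equal(fl$reference$PSV, 75)
  expect_equal(fl$reference$EDV, 75)
  expect_equal(fl$reference$MV, 75)
})

test_that("liver/kidney phantom honours the noise contract", {
  # noiseless: ROI means equal the prescribed means exactly
  lk0 <- make_liver_kidney_image(c(120, 100), seed = 1, noise = noiseless)
  expect_equal(roi_mean(lk0$image, lk0$liver_roi), 120)
  expect_equal(roi_mean(lk0$image, lk0$kidney_roi), 100)
  # speckled: sample mean within 3 sd/sqrt(N) of the prescribed mean
  lk <- make_liver_kidney_image(c(120, 100), seed = 2,
                                noise = list(speckle_sd = 0.25, additive_sd = 0))
  m <- roi_mean(lk$image, lk$liver_roi)
  n_px <- (lk$liver_roi[3] - lk$liver_roi[1]) * (lk$liver_roi[4] - lk$liver_roi[2])
  # correlated speckle: effective N shrinks by ~ the correlation area
  tol <- 3 * 0.25 * 120 / sqrt(n_px / (pi * 1.5^2))
  expect_lt(abs(m - 120), tol)
})

test_that("LV phantoms expose closed-form truth", {
  tr <- phantom_truth(seed = 2, noise = noiseless,
                      strain = list(radial = 0.3, circumferential = 0.2,
                                    longitudinal = 0.15))
  lv <- make_lv_cine(tr, view = "SAX", n_beats = 1, frame_rate = 50)
  expect_equal(lv$true_strain$radial, 30)
  expect_equal(lv$true_strain$circumferential, -20)
  # reference contours follow the prescribed deformation: wall thickness at
  # peak phase = w0 * (1 + radial strain)
  pk <- which.max(lv$phase)
  th0 <- sqrt(sum((lv$contours[[1]]$epi[1, ] - lv$contours[[1]]$endo[1, ])^2))
  thp <- sqrt(sum((lv$contours[[pk]]$epi[1, ] - lv$contours[[pk]]$endo[1, ])^2))
  expect_equal(thp / th0 - 1, 0.3 * lv$phase[pk], tolerance = 1e-9)
  pl <- make_lv_cine(tr, view = "PLAX", n_beats = 1, frame_rate = 50)
  expect_equal(pl$true_strain$longitudinal, -15)
  # zero deformation: all reference contours identical
  tz <- phantom_truth(seed = 2, noise = noiseless,
                      strain = list(radial = 0, circumferential = 0,
                                    longitudinal = 0))
  lz <- make_lv_cine(tz, view = "SAX", n_beats = 1, frame_rate = 50)
  expect_equal(lz$contours[[1]]$endo, lz$contours[[length(lz$contours)]]$endo)
})
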