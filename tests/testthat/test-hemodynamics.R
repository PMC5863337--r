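# Relative distension, loop PWV, pulse pressure, wall shear rate.

test_that("relative distension is exact arithmetic with guarded inputs", {
  expect_equal(relative_distension(1.2, 1.0), 20, tolerance = 1e-12)
  expect_equal(relative_distension(1.0, 1.0), 0)
  expect_equal(relative_distension(1.1739, 1.0), 17.39, tolerance = 1e-9)
  expect_error(relative_distension(0.9, 1.0), class = "musecho_index_error")
  expect_error(relative_distension(1.0, 0), class = "musecho_index_error")
})

test_that("loop PWV recovers the generating velocity", {
  cp <- make_coupled_vessel(truth_basic(Ds = 1.18), n_beats = 2,
                            prf = prf_for(2, 1, 1.18))
  fit <- pwv_loop(track_diameter(cp$loop), extract_envelope(cp$spec))
  expect_lt(abs(fit$pwv - 2.0) / 2.0, 0.01)
  expect_gt(fit$r2, 0.95)
})

test_that("PWV recovery sweep over the physiological range", {
  for (p in c(1.0, 1.8, 4.0, 6.0)) {
    tr <- truth_basic(seed = 5, Ds = 1.10, pwv = p)
    cp <- make_coupled_vessel(tr, n_beats = 2, prf = prf_for(p, 1, 1.10))
    fit <- pwv_loop(track_diameter(cp$loop), extract_envelope(cp$spec))
    expect_lt(abs(fit$pwv - p) / p, 0.05)
  }
  # distension sweep at fixed PWV
  for (relD in c(5, 15, 25)) {
    Ds <- 1 * (1 + relD / 100)
    tr <- truth_basic(seed = 6, Ds = Ds, pwv = 3)
    cp <- make_coupled_vessel(tr, n_beats = 2, prf = prf_for(3, 1, Ds))
    fit <- pwv_loop(track_diameter(cp$loop), extract_envelope(cp$spec))
    expect_lt(abs(fit$pwv - 3) / 3, 0.05)
  }
})

test_that("loop PWV under default speckle noise stays within 15%", {
  tr <- phantom_truth(seed = 3, pwv = 2.0)    # default noise
  cp <- make_coupled_vessel(tr, n_beats = 3)
  fit <- pwv_loop(track_diameter(cp$loop), extract_envelope(cp$spec))
  expect_lt(abs(fit$pwv - 2.0) / 2.0, 0.15)
})

test_that("degenerate loop inputs raise, never return a number", {
  st <- make_coupled_vessel(truth_basic(seed = 6, Ds = 1.0), n_beats = 2)
  d <- track_diameter(st$loop)
  v <- velocity_trace(st$reference_v$time,
                      200 + 0 * st$reference_v$velocity)
  expect_error(pwv_loop(d, v), class = "musecho_loop_fit_error")
  # non-overlapping traces
  d2 <- diameter_trace(seq(10, 11, by = 0.01), rep(1, 101) + sin(1:101) / 50)
  expect_error(pwv_loop(d2, st$reference_v), class = "musecho_loop_fit_error")
})

test_that("pulse pressure implements all three conventions", {
  lit <- pulse_pressure(1.80, 20.77, "literal")
  expect_equal(lit$pp_pa, 1.80^2 * 1059 * 0.2077, tolerance = 1e-12)
  expect_equal(lit$pp_pa, 712.7, tolerance = 1e-3)
  expect_equal(lit$pp_mmhg, 712.6897 / 133.322, tolerance = 1e-4)
  lin <- pulse_pressure(1.80, 20.77, "linearized_area")
  expect_equal(lin$pp_pa, 2 * lit$pp_pa, tolerance = 1e-12)
  expect_equal(lin$pp_mmhg, 10.69, tolerance = 1e-3)
  ex <- pulse_pressure(1.80, 20.77, "exact_area")
  expect_equal(ex$pp_pa, 1.80^2 * 1059 * ((1.2077)^2 - 1), tolerance = 1e-12)
  expect_equal(pulse_pressure(3.3, 0, "exact_area")$pp_pa, 0)
  expect_error(pulse_pressure(1.8, 20, "bogus"))
  expect_error(pulse_pressure(-1, 20), class = "musecho_index_error")
})

test_that("pulse pressure monotonicity and convention ordering", {
  pwvs <- c(1, 2, 4); relds <- c(5, 12, 25)
  for (conv in c("literal", "linearized_area", "exact_area")) {
    pp_pwv <- vapply(pwvs, function(p) pulse_pressure(p, 15, conv)$pp_pa,
                     numeric(1))
    pp_rd <- vapply(relds, function(r) pulse_pressure(2, r, conv)$pp_pa,
                    numeric(1))
    expect_true(all(diff(pp_pwv) > 0))
    expect_true(all(diff(pp_rd) > 0))
  }
  for (r in relds) {
    v <- vapply(c("literal", "linearized_area", "exact_area"),
                function(cv) pulse_pressure(2, r, cv)$pp_pa, numeric(1))
    expect_true(all(diff(v) > 0))
  }
  # round trip: relD recovered from literal PP to machine precision
  pp <- pulse_pressure(2.3, 17.39, "literal")$pp_pa
  expect_equal(pp / (2.3^2 * 1059), 0.1739, tolerance = 1e-12)
})

test_that("wall shear rate is 4 Vmean / Dd with exact homogeneity", {
  expect_equal(wall_shear_rate(250, 1.0), 1000, tolerance = 1e-12)
  expect_equal(wall_shear_rate(0, 0.5), 0)
  expect_equal(wall_shear_rate(260, 1.0009), 4 * 260 / 1.0009,
               tolerance = 1e-12)
  expect_equal(wall_shear_rate(260, 1.0009), 1039, tolerance = 1e-3)
  for (k in c(0.2, 2, 9)) {
    expect_equal(wall_shear_rate(k * 260, 1.0009),
                 k * wall_shear_rate(260, 1.0009), tolerance = 1e-12)
  }
  expect_error(wall_shear_rate(100, 0), class = "musecho_index_error")
})

test_that("vascular summary recovers every field end to end", {
  tr <- truth_basic(seed = 12, Ds = 1.2, pwv = 2)
  cp <- make_coupled_vessel(tr, n_beats = 3, prf = prf_for(2, 1, 1.2))
  vs <- vascular_summary(track_diameter(cp$loop),
                         velocity_indices(extract_envelope(cp$spec)))
  expect_equal(vs$Dm, cp$reference_d$Dm, tolerance = 0.05 * cp$reference_d$Dm)
  expect_lt(abs(vs$relD - 20) / 20, 0.05)
  expect_lt(abs(vs$pwv - 2) / 2, 0.05)
  mv_ref <- mean(cp$reference_v$velocity[cp$reference_v$time < 0.16])
  wsr_true <- wall_shear_rate(mv_ref, 1.0)
  expect_lt(abs(unname(vs$wsr) - wsr_true) / wsr_true, 0.05)
  pp_true <- pulse_pressure(2, 20, "literal")$pp_mmhg
  expect_lt(abs(vs$pp_mmhg - pp_true) / pp_true, 0.12)
})

test_that("static phantom summary degrades gracefully", {
  st <- make_coupled_vessel(truth_basic(seed = 6, Ds = 1.0), n_beats = 2)
  vs <- vascular_summary(track_diameter(st$loop),
                         velocity_indices(extract_envelope(st$spec)))
  expect_lt(vs$relD, 0.5)
  expect_true(is.na(vs$pwv))
  expect_false(is.null(vs$pwv_error))
  expect_equal(vs$pp_pa, 0)
  expect_equal(vs$Dm, 1.0, tolerance = 0.005)
})

test_that("the pipeline succeeds at carotid scale", {
  tc <- truth_basic(seed = 4, Dd = 0.42, Ds = 0.52, pwv = 1.43)
  cp <- make_coupled_vessel(tc, n_beats = 2, view = "carotid-long-axis",
                            prf = prf_for(1.43, 0.42, 0.52))
  vs <- vascular_summary(track_diameter(cp$loop),
                         velocity_indices(extract_envelope(cp$spec)))
  expect_equal(vs$Dm, cp$reference_d$Dm, tolerance = 0.02)
  expect_lt(abs(vs$pwv - 1.43) / 1.43, 0.05)
})

test_that("vascular CSV has the documented columns", {
  tr <- truth_basic(seed = 12, Ds = 1.2)
  cp <- make_coupled_vessel(tr, n_beats = 2)
  vs <- vascular_summary(track_diameter(cp$loop),
                         velocity_indices(extract_envelope(cp$spec)))
  p <- withr::local_tempfile(fileext = ".csv")
  df <- write_vascular_csv(list(m01 = vs), p)
  expect_identical(names(df), c("animal", "Dm_mm", "relD_pct", "PWV_m_s",
                                "PP_mmHg", "WSR_per_s", "convention"))
  expect_identical(names(utils::read.csv(p)), names(df))
})
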