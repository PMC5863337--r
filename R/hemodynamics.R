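# Vascular biomarkers: relative distension, loop-based local pulse wave
# velocity, pulse pressure by the inverted Bramwell-Hill relation, and wall
# shear rate.

#' Blood density used throughout the package (kg/m^3)
#' @export
RHO_BLOOD <- 1059

MMHG_PER_PA <- 1 / 133.322

#' Relative distension of a vessel
#'
#' `relD = 100 (Ds - Dd)/Dd` in percent.
#'
#' @param Ds systolic diameter, mm.
#' @param Dd diastolic diameter, mm (`0 < Dd <= Ds`).
#' @return percent distension.
#' @export
relative_distension <- function(Ds, Dd) {
  if (any(Dd <= 0)) stop_musecho("Dd must be positive", "musecho_index_error")
  if (any(Ds < Dd))
    stop_musecho("Ds < Dd: beat segmentation fault upstream", "musecho_index_error")
  100 * (Ds - Dd) / Dd
}

# Upstroke foot by intersecting tangents: the crossing of the tangent at the
# maximum-slope point of v(t) with the pre-upstroke baseline level.
upstroke_foot <- function(t, v) {
  peak <- which.max(v)
  if (peak < 3L) return(1L)
  dv <- central_diff(v, t)
  ms <- which.max(dv[seq_len(peak)])
  base_win <- seq_len(max(1L, ms - 1L))
  base <- min(v[base_win])
  t_foot <- t[ms] - (v[ms] - base) / max(dv[ms], .Machine$double.eps)
  max(1L, which.min(abs(t - t_foot)))
}

#' Local pulse wave velocity from the diameter-velocity loop
#'
#' Resamples the diameter and velocity waveforms onto the denser common time
#' base, selects the early-systolic (reflection-free) limb -- from the
#' upstroke foot of V(t), found by intersecting tangents, to the sample where
#' V first reaches `peak_frac` of its peak -- and regresses V on ln(D). The
#' water-hammer relation with the diameter-to-area conversion gives
#' `PWV = slope / 2`, reported in m/s for V in mm/s.
#'
#' @param dtrace a [diameter_trace()].
#' @param vtrace a [velocity_trace()].
#' @param peak_frac fraction of the velocity peak ending the fit window.
#' @param min_points minimum samples in the window.
#' @param min_r2 minimum regression R^2 before the fit is declared
#'   unreliable.
#' @return list of class `loop_fit` with `pwv` (m/s), `slope` (mm/s per unit
#'   ln D), `window` (index range on the common base), `r2`, and the common
#'   base traces `time`, `lnD`, `v`.
#' @export
pwv_loop <- function(dtrace, vtrace, peak_frac = 0.8, min_points = 5L,
                     min_r2 = 0.8) {
  stopifnot(inherits(dtrace, "diameter_trace"), inherits(vtrace, "velocity_trace"))
  t0 <- max(min(dtrace$time), min(vtrace$time))
  t1 <- min(max(dtrace$time), max(vtrace$time))
  if (t1 <= t0)
    stop_musecho("diameter and velocity traces do not overlap in time",
                 "musecho_loop_fit_error")
  dt_d <- stats::median(diff(dtrace$time)); dt_v <- stats::median(diff(vtrace$time))
  tt <- seq(t0, t1, by = min(dt_d, dt_v))
  D <- stats::approx(dtrace$time, dtrace$diameter_mm, tt)$y
  V <- stats::approx(vtrace$time, vtrace$velocity, tt)$y
  if (stats::sd(D) / mean(D) < 1e-5)
    stop_musecho("diameter is constant: ln(D) carries no information",
                 "musecho_loop_fit_error")
  # restrict to the first cycle's upstroke
  cyc <- detect_cycle(velocity_trace(tt, V))
  tw <- cyc[1L]:cyc[2L]
  foot <- tw[upstroke_foot(tt[tw], V[tw])]
  vp <- max(V[tw])
  after <- foot:max(tw)
  endi <- after[which(V[after] >= peak_frac * vp)[1L]]
  if (is.na(endi) || endi - foot + 1L < min_points)
    stop_musecho(sprintf("early-systolic window too short (%d samples)",
                         max(0L, endi - foot + 1L)), "musecho_loop_fit_error")
  win <- foot:endi
  lnD <- log(D[win])
  fit <- stats::lm(V[win] ~ lnD)
  r2 <- summary(fit)$r.squared
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(r2) || r2 < min_r2 || slope <= 0)
    stop_musecho(sprintf("unreliable loop fit: R^2 = %.3f, slope = %.1f",
                         r2, slope), "musecho_loop_fit_error")
  structure(list(pwv = slope / 2 / 1000, slope = slope,
                 window = range(win), r2 = r2,
                 time = tt, lnD = log(D), v = V),
            class = "loop_fit")
}

#' @export
print.loop_fit <- function(x, ...) {
  cat(sprintf("<loop_fit> PWV = %.3f m/s (slope %.1f mm/s, R^2 %.3f, window %d..%d)\n",
              x$pwv, x$slope, x$r2, x$window[1L], x$window[2L]))
  invisible(x)
}

#' Pulse pressure from PWV and relative distension (inverted Bramwell-Hill)
#'
#' Three conventions for the distension term are available, because the
#' relation is written in terms of the fractional *area* change while
#' `relD` is a *diameter* ratio:
#' \describe{
#'   \item{`literal`}{`PP = PWV^2 rho (relD/100)` -- the equation as usually
#'     printed with the diameter distension inserted directly (default).}
#'   \item{`linearized_area`}{`PP = PWV^2 rho 2 (relD/100)` -- first-order
#'     area change, `dA/A ~ 2 dD/D`.}
#'   \item{`exact_area`}{`PP = PWV^2 rho ((1 + relD/100)^2 - 1)` -- exact
#'     area ratio.}
#' }
#' Blood density is fixed at 1059 kg/m^3.
#'
#' @param pwv pulse wave velocity, m/s.
#' @param relD relative distension, percent.
#' @param convention one of `"literal"`, `"linearized_area"`, `"exact_area"`.
#' @return list with `pp_pa` and `pp_mmhg`.
#' @export
pulse_pressure <- function(pwv, relD,
                           convention = c("literal", "linearized_area",
                                          "exact_area")) {
  convention <- match.arg(convention)
  if (pwv <= 0) stop_musecho("pwv must be positive", "musecho_index_error")
  if (relD < 0) stop_musecho("relD must be nonnegative", "musecho_index_error")
  frac <- relD / 100
  term <- switch(convention,
                 literal = frac,
                 linearized_area = 2 * frac,
                 exact_area = (1 + frac)^2 - 1)
  pp_pa <- pwv^2 * RHO_BLOOD * term
  list(pp_pa = pp_pa, pp_mmhg = pp_pa * MMHG_PER_PA, convention = convention)
}

#' Wall shear rate
#'
#' Poiseuille estimate `WSR = 4 Vmean / Dd`; with `v_mean` in mm/s and `Dd`
#' in mm the units reduce to 1/s.
#'
#' @param v_mean cycle-mean velocity, mm/s.
#' @param Dd diastolic diameter, mm.
#' @return shear rate, 1/s.
#' @export
wall_shear_rate <- function(v_mean, Dd) {
  if (any(Dd <= 0)) stop_musecho("Dd must be positive", "musecho_index_error")
  4 * v_mean / Dd
}

#' Per-vessel summary of all vascular biomarkers
#'
#' Assembles mean diameter, relative distension (from the ensemble beat when
#' beats were segmented), loop PWV, pulse pressure and wall shear rate. A
#' failed loop fit (e.g. a static vessel) is reported as `NA` PWV with the
#' diagnostic message in `pwv_error`; pulse pressure is zero whenever the
#' distension is zero and `NA` when it needs an unavailable PWV.
#'
#' @param dtrace a [diameter_trace()].
#' @param vtrace a [velocity_trace()] (indices are computed if missing).
#' @param convention pulse-pressure convention, see [pulse_pressure()].
#' @return list of class `vascular_summary` with `Dm`, `relD`, `pwv`,
#'   `pp_pa`, `pp_mmhg`, `wsr`, `rho`, `convention`, `pwv_error`.
#' @export
vascular_summary <- function(dtrace, vtrace,
                             convention = c("literal", "linearized_area",
                                            "exact_area")) {
  convention <- match.arg(convention)
  stopifnot(inherits(dtrace, "diameter_trace"))
  if (is.null(vtrace$PSV)) vtrace <- velocity_indices(vtrace)
  sd_ <- trace_ds_dd(dtrace)
  relD <- relative_distension(sd_["Ds"], sd_["Dd"])
  fit <- tryCatch(pwv_loop(dtrace, vtrace), error = function(e) e)
  pwv_err <- NULL
  if (inherits(fit, "error")) {
    pwv <- NA_real_; pwv_err <- conditionMessage(fit)
  } else pwv <- fit$pwv
  if (relD == 0) {
    pp <- list(pp_pa = 0, pp_mmhg = 0)
  } else if (is.na(pwv)) {
    pp <- list(pp_pa = NA_real_, pp_mmhg = NA_real_)
  } else {
    pp <- pulse_pressure(pwv, relD, convention)
  }
  structure(list(Dm = dtrace$Dm, relD = unname(relD), pwv = pwv,
                 pp_pa = pp$pp_pa, pp_mmhg = pp$pp_mmhg,
                 wsr = wall_shear_rate(vtrace$MV, sd_["Dd"]),
                 rho = RHO_BLOOD, convention = convention,
                 pwv_error = pwv_err),
            class = "vascular_summary")
}

#' @export
print.vascular_summary <- function(x, ...) {
  cat(sprintf(paste0("<vascular_summary> Dm %.3f mm | relD %.2f%% | PWV %s m/s | ",
                     "PP %.2f mmHg (%s) | WSR %.0f 1/s\n"),
              x$Dm, x$relD,
              if (is.na(x$pwv)) "NA" else sprintf("%.2f", x$pwv),
              x$pp_mmhg, x$convention, x$wsr))
  if (!is.null(x$pwv_error)) cat("  PWV fit error:", x$pwv_error, "\n")
  invisible(x)
}

#' Write vascular summaries as one CSV row per animal
#'
#' Columns: `Dm_mm`, `relD_pct`, `PWV_m_s`, `PP_mmHg`, `WSR_per_s`,
#' `convention`.
#'
#' @param summaries named list of `vascular_summary` objects (names become
#'   row identifiers).
#' @param path output CSV path.
#' @return the data.frame written, invisibly.
#' @export
write_vascular_csv <- function(summaries, path) {
  df <- do.call(rbind, lapply(names(summaries), function(id) {
    s <- summaries[[id]]
    data.frame(animal = id, Dm_mm = s$Dm, relD_pct = s$relD,
               PWV_m_s = s$pwv, PP_mmHg = s$pp_mmhg, WSR_per_s = unname(s$wsr),
               convention = s$convention)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
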