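---
title: "Quantifying murine high-frequency ultrasound: models, assumptions, and phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying murine high-frequency ultrasound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`musecho` quantifies multiorgan high-frequency ultrasound examinations of the
mouse: vessel geometry and stiffness from B-mode cine loops, Doppler
velocimetry, left-ventricular (LV) function and speckle-tracking strain, a
hepatorenal gray-level steatosis index, and two-group nonparametric
statistics. Because raw preclinical image data are rarely shareable, every
estimator is paired with a synthetic phantom generator whose ground truth is
known in closed form. This vignette describes the models, the tunable
parameters, the numerical choices, and what the phantom-based tests do and
do not establish.

## Vessel diameter from B-mode

Longitudinal views of the abdominal aorta or common carotid show the two
vessel walls as bright, roughly horizontal bands on a dark lumen. The wall
detector works on the axial intensity profile of each scanline: a wall band
is a maximum rising intensity gradient followed by a falling one, and the
reported wall position is the midpoint of the two parabolic-refined gradient
extrema. For a symmetric wall profile this midpoint coincides with the band
centre, which makes the diameter estimate independent of the band width —
the reason this operator was preferred over a plain leading-edge rule, whose
positions shift with the wall's point-spread width. Distances stay in pixel
units internally and are converted to millimetres only when the trace is
assembled, so the axial pixel spacing enters the result exactly once (an
exact equivariance the tests assert).

`track_diameter()` applies the detector frame by frame, using the previous
wall positions as a search prior (contour tracking), averaging across at
least 11 scanlines, capping per-frame diameter jumps at 5 px (at 700 fps the
true inter-frame motion is far below this), and interpolating low-confidence
frames. More than 30% low-confidence frames is a tracking failure, not a
result. Beats are delimited by ECG R peaks when available (diastolic
diameter `Dd` just after the R peak, systolic `Ds` as the intra-beat
maximum); without an ECG the cycle length comes from the autocorrelation of
the waveform and beats are delimited by diameter minima. Among
autocorrelation peaks we take the smallest lag close to the strongest peak,
which rejects intra-cycle aliases (such as the E–A spacing of a mitral
trace, or harmonics).

## Doppler envelope and velocity indices

The envelope of a pulsed-wave spectrogram is extracted per time bin as the
largest velocity at which the cumulative power, integrated outward from the
baseline on the dominant flow side, reaches 95% of the bin's total, with
sub-bin linear interpolation and a 5-bin median filter. Before the scan,
bins below 15% of their column's maximum are zeroed — the display threshold
any clinical envelope detector applies — so an additive noise floor spread
over the whole velocity axis cannot inflate the cumulative sum. Empty
columns are interpolated from their neighbours; more than 30% empty is an
error.

Summary indices follow their standard definitions on a single cardiac
cycle: PSV is the cycle maximum, EDV the minimum of the 20% of the cycle
preceding the systolic upstroke foot (robust to dicrotic notches; the global
minimum is deliberately not used), MV the cycle mean. The renal resistivity
and pulsatility indices are `RI = (PSV − EDV)/PSV` and
`PI = (PSV − EDV)/MV`. Transmitral E and A are the two prominent peaks (at
least 20% of the cycle maximum) in temporal order; to guarantee E precedes A
regardless of where the recording starts, the analysis cycle is anchored
inside the longest low-velocity run, which is the systolic no-inflow pause.
A single prominent peak is reported as E–A fusion with the ratio undefined.
The stored beam-to-flow angle (60° in the intended acquisitions) is
metadata only: velocities are assumed already angle-corrected.

## Loop-based pulse wave velocity and pulse pressure

Local pulse wave velocity (PWV) is estimated from the diameter–velocity
loop. During early systole, before reflected waves arrive, the water-hammer
relation with the diameter-to-area conversion gives `V = 2·PWV·ln(D/Dd)` up
to an additive constant, so a regression of V on ln D over the
early-systolic limb has slope `2·PWV`. The limb is selected automatically:
its start is the upstroke foot of V(t) found by intersecting tangents, its
end the first sample at 80% of the velocity peak. Both traces are resampled
onto the denser common time base by linear interpolation first (B-mode runs
at ~700 fps, Doppler bins at ~1 ms). A window shorter than 5 samples, a
regression R² below 0.8, or a non-positive slope raises an unreliable-fit
error carrying diagnostics — a static vessel can never silently return a
PWV. Because a constant diastolic flow offset moves only the intercept,
estimation is insensitive to baseline forward flow.

Pulse pressure comes from inverting the Bramwell–Hill relation, with blood
density fixed at ρ = 1059 kg/m³. The relation is defined through the
fractional *area* distension, while the reported distension
`relD = (Ds − Dd)/Dd` is a *diameter* ratio, so three conventions are
implemented and must be chosen explicitly:

* `literal`: `PP = PWV²·ρ·(relD/100)` — the equation as it is usually
  printed, with the diameter distension inserted directly (default);
* `linearized_area`: `PP = PWV²·ρ·2·(relD/100)` — first-order area change,
  dA/A ≈ 2 dD/D;
* `exact_area`: `PP = PWV²·ρ·((1 + relD/100)² − 1)`.

The distinction matters in practice: at a typical healthy-control operating
point (PWV 1.80 m/s, relD 20.77%) the literal form gives ≈5.35 mmHg while
the linearized-area form gives ≈10.69 mmHg — a factor of two. Published
murine pulse-pressure values derived from this inversion are consistent
with the area-based reading (≈10.5 mmHg) even when the equation is printed
in its literal diameter form, and the source the package models does not
state which was computed; the package therefore keeps `literal` as the
faithful default and exposes the others, and the acceptance suite documents
the discrepancy rather than hiding it. Wall shear rate is the Poiseuille
estimate `WSR = 4·Vmean/Dd` (mm/s over mm, hence s⁻¹).

## LV metrics and speckle-tracking strain

Volumes use the monoplane area–length rule `V = 8A²/(3πL)` on traced
endocardial contours (PLAX), with end-diastole and end-systole as the
largest- and smallest-volume frames; `SV = EDV − ESV`, `EF = 100·SV/EDV`,
`CO = SV·HR` (µl·bpm → ml/min). Fractional shortening uses the mid-cavity
minor-axis chord, i.e. the chord perpendicular to the principal axis at its
midpoint — the trace format does not record the conventional M-mode cursor,
and mid-cavity is the assumption stated here once. LV mass is
`1.05·(V_epi − V_endo)` at end-diastole (myocardial density 1.05 g/ml;
volumes in µl give mass in mg); the epicardial long axis is extrapolated
from the endocardial one through the equivalent-radius difference of the
two contour areas.

Speckle tracking is normalized cross-correlation block matching (default
block 17 px, search ±7 px) with parabolic sub-pixel refinement. Each
candidate is scored by a 50/50 blend of the previous-frame template and the
frame-0 template; the fixed reference anchors the track and controls drift
over the loop. Two numerical details proved essential and are locked in by
tests: the measured shift is applied to the *unrounded* point position
(templates are anchored at rounded pixels, displacements are not), and
sub-pixel refinement is skipped when the correlation peak is numerically
perfect, where the parabola vertex would otherwise be pulled off-centre by
asymmetric neighbour correlations. Both are required for a zero-motion loop
to return exactly zero strain.

Strain is Lagrangian per segment, `ε(t) = 100·(L(t) − L0)/L0`, with L the
inter-point arc length of the segment (circumferential, longitudinal) or
the mean endo-to-epi thickness (radial); the myocardium is divided into six
equal spans. Strain rate is the central-difference derivative of fractional
strain, smoothed with a 5-point moving average. The global value is the
arithmetic mean of the six segmental peaks, taking the signed extremum per
segment — most positive for radial (thickening), most negative for
circumferential/longitudinal (shortening), which fixes the sign convention:
radial strain positive, circumferential and longitudinal negative.

## Steatosis index

The steatosis score is the ratio of the mean gray level in a liver ROI to
that in a kidney-parenchyma ROI on one B-mode image containing both organs.
ROIs may be rectangles (0-based, half-open) or polygons, must not overlap,
and must contain at least 100 px — a statistical-stability guard, since the
acquisition protocol this mirrors does not fix ROI size or placement. No depth or
time-gain compensation is applied: the index is deliberately a raw
gray-level ratio, and a compensation hook would change its meaning.

## Cohort statistics

Biomarkers are summarised per group as median [IQR], with type-7
(linear-interpolation) quantiles and the IQR reported as the single width
Q3 − Q1. Two groups are compared with the Mann–Whitney test: exact two-sided
p by full enumeration of the permutation distribution when n ≤ 14 without
ties, otherwise the normal approximation with midrank tie correction and
continuity correction. No multiple-testing correction is applied — the
analysis mirrors a raw p < 0.05 screen, and that caveat transfers to any
interpretation. The pipeline writes per-animal, summary and comparison CSVs
plus a JSON manifest; per-animal failures are logged and excluded, never
imputed.

## The phantom world

Every phantom states its world explicitly and returns its truth:

* **Vessel loops**: two Gaussian-profile wall bands whose centre separation
  follows a raised-cosine diameter waveform (diastolic `Dd`, systolic `Ds`,
  period 0.16 s ≈ 375 bpm, upstroke 25% of the cycle) at sub-pixel
  positions; 0.02 mm/px, 700 fps, as in retrospectively gated murine
  vascular imaging. Speckle is a unit-mean Rayleigh field low-pass filtered
  to a 1.5 px correlation length (multiplicative, default contrast 0.25)
  plus additive Gaussian noise (default 2 gray levels).
* **Coupled loops**: the Doppler waveform is `V = 2·PWV·ln(D/Dd)` over the
  *whole* cycle plus an optional diastolic offset — D(t) relaxes smoothly
  back to `Dd`, so V decays smoothly after systole and the loop stays
  single-valued (a reflection-free vessel). Spectrogram columns mix a
  uniform fill (30% of power) with a half-Gaussian envelope band just below
  V(t) (70%), so the 95th-percentile envelope lands within a bin of V(t).
  The velocity-per-Doppler-Hz calibration follows v = c·f_d/(2·f₀·cosθ)
  with c = 1540 m/s, f₀ = 24 MHz, θ = 60°; waveform peaks beyond the
  one-sided full-PRF span (baseline shifted to the far edge, the usual
  setting for unidirectional arterial flow) raise an aliasing error rather
  than wrapping, since aliasing handling is out of scope.
* **LV loops**: a material speckle texture advected by an analytic
  displacement field. Short axis: an annulus whose wall thickens by the
  prescribed radial fraction while the midwall radius shortens by the
  circumferential fraction; long axis: an elliptical annulus under uniform
  scaling, so every arc shortens by exactly the longitudinal fraction. The
  default calibration is 0.035 mm/px on a 128² grid: at 0.05 mm/px the
  0.5 mm wall would span only 10 px — less than the 17 px matching block —
  so blocks would straddle both wall edges and mix the different endo- and
  epicardial motions, biasing circumferential strain several points low.
  35 µm sampling is plausible for the 40–55 MHz probe class.
* **Doppler-only spectrograms**: renal-type waveforms (raised-cosine
  upstroke, power-law relaxation whose exponent is solved by root finding
  when a mean-velocity target is given) and mitral-type waveforms (two
  raised-cosine bumps, E at 35% and A at 72% of the cycle). Time bins are
  1 ms — coarser bins visibly clip the narrow renal systolic peak through
  the median filter.
* **Liver/kidney images**: two speckle textures with prescribed means; the
  noise is mean-preserving, so ROI means converge to the prescribed values
  at the 3σ/√N rate (with N deflated by the speckle correlation area).

Identical spec and seed give bit-identical artifacts; all randomness flows
through one seeded RNG whose state is restored afterwards.

**What a green phantom test establishes — and what it does not.** The
phantoms exercise geometry, sub-pixel estimation, windowing, noise
robustness and every formula on data whose truth is known exactly. They do
not contain shadowing, clutter, reverberation, out-of-plane motion,
respiratory drift, anisotropic point-spread functions, or operator
variability in ROI and contour placement. Recovery within tolerance on
phantoms is therefore a necessary, not sufficient, condition for accuracy
on acquired images.

## Synthetic cohorts

`make_cohort_config()` builds a two-group validation cohort (default 8
animals per group) around published group medians for a healthy control and
a leptin-receptor-deficient diabetic model: lower heart rate, LV mass,
stroke volume, ejection fraction, fractional shortening, cardiac output,
vessel diameter, relative distension and wall shear rate, and higher E/A,
renal resistivity and pulsatility in the diabetic-like group; pulse wave
velocity and the steatosis index are planted null. The wall-shear-rate
difference is planted through the diastolic flow offset (100 vs 40 mm/s),
which moves the cycle-mean velocity without touching the loop slope. The
between-animal coefficient of variation is fixed at 4% — the repeatability
scale of phantom measurements, chosen once so that every planted effect is
well powered at n = 8 with a rank test; real cohorts of this size are far
more variable, and the end-to-end test validates sign recovery and error
control, not the power of any real experiment.

## Known limitations

* The TIFF codec covers exactly the package's own artifact format
  (little-endian, 8-bit grayscale, uncompressed, multi-page).
* Two-point (transit-time) PWV, wave separation, aliased Doppler,
  respiratory artifacts and 3D/torsional strain are out of scope.
* The E/A cycle anchor assumes a visible systolic no-inflow pause; heavily
  fused inflow at very high heart rates is reported as fusion, not split.
* FS depends on the mid-cavity chord assumption stated above; traces whose
  principal axis is ill-defined (nearly circular contours) make FS
  unstable.
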