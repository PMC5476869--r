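---
title: "Analysing head motion and psychometric outcomes of VR telemindfulness sessions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing head motion and psychometric outcomes of VR telemindfulness sessions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mindmotion)
```

## The measurement problem

A seated participant in a head-mounted display moves their head to look
around: slow gaze drift, deliberate rotations toward points of interest,
quick saccade-like reorientations, and a low-amplitude oscillatory component
in roughly the 0.3–1 Hz band. In a mindfulness intervention the *change* in
this behaviour across matched sessions is itself an outcome: a participant
who has settled into the practice scans the scenery less and produces less
high-frequency "turbulent" movement. `mindmotion` quantifies that change
from the headset's orientation stream, and pairs it with the standard
questionnaire outcomes (SWLS, MAAS, MMSE) collected before, at midterm and
after an 8-session program.

## Orientation model

The headset serializes orientation as timestamped unit quaternions, stored
scalar-last `(q_x, q_y, q_z, q_w)` — the convention of the Unity-based
source devices. Quaternions avoid gimbal-lock singularities in the sensor
stream itself; the singular representation enters only when we convert to
interpretable angles.

Head pose is factored in the intrinsic **Y–Z–X** sequence: yaw about the
vertical Y axis first, then pitch about Z, then roll about X. With
$R(q)$ the rotation matrix of the quaternion, the factorization
$R = R_Y(\Phi) R_Z(\theta) R_X(\varphi)$ gives

$$\theta = \arcsin(R_{21}), \qquad
  \Phi = \operatorname{atan2}(-R_{31}, R_{11}), \qquad
  \varphi = \operatorname{atan2}(-R_{23}, R_{22}),$$

using the two-argument arctangent so yaw and roll cover $(-180°, 180°]$
rather than $\pm 90°$. The decomposition is intrinsic because the angles
describe rotations of the head-fixed frame; whether the physical device's
roll sign matches a given headset cannot be decided without the hardware,
so channel signs are trivially flippable downstream.

**Gimbal lock.** At $|\theta| = 90°$ yaw and roll act about the same world
axis and only their combination is observable. Within 0.1° of the pole
(`gimbal_tol_deg`) we adopt the deterministic convention $\varphi := 0$ with
the residual rotation absorbed into $\Phi$. Any convention is equally valid
here; a fixed one makes the conversion testable and round-trippable at the
rotation level (the round-trip test compares rotations, not angle triples).

**Resampling.** Sensor timestamps jitter by a few milliseconds, so after
per-sample conversion and shortest-arc unwrapping (no consecutive jump may
exceed 180°) each channel is linearly interpolated onto a uniform grid at
the nominal rate (default 50 Hz). Linear interpolation is adequate because
the signal content of interest lies below ~1 Hz, two orders of magnitude
under the sample rate.

## Conditioning

Two artifact classes survive conversion: genuine tracking resets (the
sensor re-references and the angle jumps by a large, persistent step) and
residual wrap effects. Detection uses level-1 Haar wavelet detail
coefficients in *stationary* (undecimated) form,
$d_i = (x_{i+1} - x_i)/\sqrt{2}$: the decimated transform has zero response
to a step falling on a coefficient-pair boundary, which would blind the
detector to half the possible step positions. A sample is flagged where
$|d_i - \operatorname{med}(d)|$ is a local maximum exceeding
`threshold_mult` × MAD$(d)$. The default multiplier 8 was chosen from the
geometry of smooth traces — for sinusoidal motion the maximum detail sits
near 1 MAD, and for Gaussian drift increments the expected maximum over a
session is under 4 MAD — leaving a wide margin on both sides; the test
suite confirms zero false positives over 1000 seeded smooth traces and full
recovery of injected ±360°/350° steps.

Elimination subtracts each flagged jump (in excess of the channel's median
one-sample difference, so real slope survives) from all subsequent samples,
then re-interpolates a 3-sample window around the flag; overlapping windows
are merged.

**Order of operations.** The chain runs *detect → eliminate → filter*,
although a naive reading of the preprocessing description would filter
first. A 2 Hz zero-phase filter spreads a 350° step over dozens of samples;
after that, no local estimate of the jump magnitude exists and
step-subtraction cannot recover the signal. Eliminating on the raw trace is
the only order under which the elimination contract (residual deviation
< 0.5° on a wrapped ramp) is achievable.

**The filter.** The published description names a Butterworth with
"f = 0.5 F_S" at F_S = 50 Hz — literally the Nyquist frequency, i.e. a
no-op, and presumably either normalized-frequency notation or a typo. We
therefore treat the cutoff as a configuration parameter. The default is
2 Hz, order 4, zero-phase: comfortably above the 0.34/0.44 Hz analysis
bands, comfortably below broadband sensor noise. Zero-phase application
(forward–backward) matters because time-domain metrics and spectra are
compared across sessions; it is implemented with odd-reflection padding and
steady-state initial conditions so a constant trace passes through at
rounding precision, and the first `max(order, 10)` samples at each end are
excluded from downstream metrics regardless.

## Spectra and band-power contrast

Spectral analysis of the yaw channel uses a plain, untapered periodogram of
the mean-removed signal, one-sided, normalized so that the summed power
equals $\operatorname{mean}((x-\bar x)^2)$ (Parseval with the divisor-$n$
variance; this makes the normalization an exact identity rather than an
$n/(n-1)$ approximation). No taper is applied by default because the
downstream use is a coarse band-power contrast, and the windowless
periodogram keeps the Parseval identity and the sinusoid-recovery tests
exact. A note on leakage: a 0.4 Hz tone in a 4096-sample/50 Hz record is
off-bin and leaks ≈1.3% of its power above 0.44 Hz; at an 80 s record
(n = 4000) the tone is an exact bin and the band split is exact. Validation
fixtures therefore use exact-bin durations, with one frozen off-bin case
documenting the leakage.

Band power over $(f_\mathrm{lo}, f_\mathrm{hi}]$ is a half-open sum so
adjacent bands partition the axis. Matched segments are compared by the
ratio of band power above `f_cut` — 0.34 Hz (employees) and 0.44 Hz
(patients), analyst-supplied constants with no derivation to reproduce —
after truncating both channels to the shorter length. The verdict is
*reduced* / *increased* outside a ±20% `negligible_frac` band, *negligible*
inside; a zero baseline with positive follow-up reports a ratio of `Inf`.

## Motion-curve area

"The area of the yaw–roll plane curve" is not a standard quantity, so the
package defines it as the **convex-hull area** of the (yaw, roll) point
cloud of the conditioned, edge-trimmed trace: deterministic,
parameter-free, translation-invariant, exactly quadratic under scaling, and
monotone under added excursions. A 95% covariance-ellipse area is available
(`method = "ellipse"`) as a robustness check — it tracks the hull within a
small factor on elliptic clouds but is less sensitive to single extreme
excursions. Whether the original analysis used raw or filtered angles is
unstated; we compute on conditioned traces, consistent with every other
metric. Percent change between matched segments is signed, negative for a
reduction.

## Psychometric scoring

SWLS: sum of 5 items (1–7), banded 31–35 *extremely satisfied*, 26–30
*satisfied*, 21–25 *slightly satisfied*, 20 *neutral*, 15–19 *slightly
dissatisfied*, 10–14 *dissatisfied*, 5–9 *extremely dissatisfied* (an
exhaustive test confirms the bands partition 5–35). MAAS: mean of 15 items
(1–6) reported at one decimal; the anchors already run 1 = almost always …
6 = almost never, so no reverse scoring. MMSE is accepted as a 0–30 total
with bands 25–30 normal, 21–24 mild, 10–20 moderate, <10 severe.

Group summaries use the **sample** SD (divisor $n-1$) and
**half-away-from-zero** rounding. These two conventions are forced by the
published group statistics: with population SD or banker's rounding the
printed values (e.g. a mean of 27.25 reported as 27.3, SDs 3.9/1.8/0.8/1.0/0.7
from four participants) are not reproducible. Where a statistic is printed
as an integer, `precision = 0` applies the same rounding rule. The published
summary numbers are internally inconsistent in two places (a patient MAAS
baseline appearing as 3.3, 3.2 and 3.25 in different spots; an employee
midterm SWLS as 26 vs 25); the package treats the per-participant table as
authoritative and reproduces only statistics consistent with it.

## The synthetic-data generator

No recording of the original study is available, so validation rests on
generated data; what the generator does and does not emulate bounds what
the passing tests can claim.

A `motion_spec()` describes one segment recording: sinusoidal components
(frequency, amplitude, phase, channel), saccade-like steps realized as
smooth sigmoids with ~0.3 s rise time (fast, but continuous — they must not
trip the discontinuity detector, as real saccades do not), Gaussian
random-walk drift (default 0.02° per sample at 50 Hz, keeping hour-scale
traces within the ±10–40° ranges typical of seated viewing), timestamp
jitter (default 2 ms, exercising the resampler) and tracking resets.
Because orientation is serialized as quaternions, a pure modulo-360
re-encoding of yaw is *unobservable* — it is the same rotation — so resets
are injected as +350° persistent steps, observable after conversion as
their wrapped −10° residual; the conditioning module's full-magnitude
contract is validated on channel-level fixtures where ±360°/350° steps are
injected directly. The generator does not attempt biomechanical realism
(no head–neck dynamics, no vestibular coupling, no realistic sensor noise
spectrum), so the pipeline's validated properties are signal-processing
properties, not claims about human behaviour.

`make_study_fixture()` assembles the full study: 4 patients and 4
employees, 60 s recordings for the matched segments of the 8-session
program (body scan at the Dooney Rock 360° video in sessions 1/8,
mindfulness in the mountain-view VE in 2/3, sitting in the fireplace room
in 5/6/7, poem reading at the River Bonnet video in 5/7), and item-level
questionnaire responses that score exactly to the reference outcomes. The
designed contrasts mirror the reported pattern: employees lose high-band
(>0.34 Hz) yaw power across sessions in the 360°-video segments and show no
spectral change in the rendered environments; patients lose high-band
(>0.44 Hz) power in the VE sitting segments and show no change at the
video. Matched fireplace/River Bonnet segments additionally encode
motion-area contrasts of −23%, +17% and −72% by scaling the low-band
component amplitudes (drift is drawn independently per session, so the
recovered percent changes scatter around the designed values rather than
equalling them). The patients' fireplace case carries both designs at once
— a *rising* area and a *falling* high band — which is only encodable when
the high-band amplitude is small against the low band; the generator keeps
the designed high-band power ratios at sub-2° amplitudes for that reason.
These recovered contrasts are properties of the fixture design, not
reproductions of the unreleased recordings, which is also why the area
percentages are reported but never asserted against the published figures.

## Numerical choices and problem sizes

* Quaternion normalization tolerance 1e-3 for acceptance into conversion
  (with re-normalization applied); unit-norm invariant 1e-6 after
  normalization; round-trip agreement required at 1e-6 over ≥1000 random
  rotations (achieved: ~1e-14).
* The brute-force factorization oracle in the tests minimizes the Frobenius
  distance to $R_Y R_Z R_X$ over a 10° grid with Nelder–Mead refinement,
  for 100 random rotations with $|\theta| < 80°$.
* Validation problem sizes: 60 s segments (3001 samples) for the study
  fixture, 80 s for exact-bin spectral fixtures, 600-sample channels for
  the 100-fixture detector sweep, 1000-trace false-positive sweep at 400
  samples. The whole suite runs in well under a minute on one core.
* Degenerate inputs: all-zero quaternions are hard errors naming the
  sample; zero-variance channels produce all-zero spectra (not errors);
  collinear yaw–roll clouds have area 0; a zero area baseline makes percent
  change an error rather than a division by zero.

## Known limitations

* The Y–Z–X axis assignment and roll sign match the documented device frame
  but cannot be verified against hardware; signs are flippable in config.
* Hull area is sensitive to single extreme excursions (one glance inflates
  it); the ellipse alternative exists precisely for that sensitivity check.
* The band-power verdict is a ratio test with a fixed ±20% dead zone, not a
  statistical test; with n = 4 per group no inferential claim is intended.
* MMSE is accepted only as a total; item-level administration, reliability
  and validity analysis of the scales are out of scope.
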