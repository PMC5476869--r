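# mindmotion

Head-motion kinematics and psychometric outcome analysis for VR
telemindfulness sessions.

Remotely delivered mindfulness programs run in head-mounted displays produce
two kinds of measurable outcomes: the head-orientation stream the headset
records throughout each session, and the questionnaire scores collected
around the program. `mindmotion` is an analysis pipeline for both, aimed at
researchers evaluating seated VR meditation interventions (e.g. small
feasibility studies with patient and employee groups).

## What it computes

**Kinematics.** The headset reports orientation as timestamped unit
quaternions `q = (q_x, q_y, q_z, q_w)` at a nominal 50 Hz. These are
converted to Euler angles in the intrinsic **Y–Z–X** sequence — yaw `Φ`
about the vertical Y axis, pitch `θ` about Z, roll `φ` about X — using
`atan2` throughout, with a deterministic gimbal-lock convention
(`|θ| → 90°`: roll set to 0, residual rotation absorbed into yaw). Channels
are unwrapped and resampled onto a uniform grid.

**Conditioning.** Tracking resets and residual wrap artifacts are detected
with stationary level-1 Haar wavelet details thresholded at a multiple of
their MAD, eliminated by step subtraction with local re-interpolation, and
the trace is then low-pass filtered (zero-phase Butterworth, default 2 Hz,
order 4) with filter edges trimmed.

**Spectral contrast.** Yaw channels get a one-sided, Parseval-normalized
periodogram (`Σ power = var(x − x̄)`). High-frequency "turbulent" head
movement is the band power above a cutoff `f_cut` (0.34 Hz for employees,
0.44 Hz for patients by convention) and matched session segments are
classified **reduced / increased / negligible** by the band-power ratio.

**Motion area.** Per-segment per-axis ranges and the *motion curve area* —
the convex-hull area (deg²) of the trajectory in the yaw–roll plane — with
signed percent change between matched segments (negative = calmer).

**Psychometrics.** SWLS (5 items 1–7, score = sum, banded from *extremely
dissatisfied* to *extremely satisfied*), MAAS (15 items 1–6, score = item
mean at one decimal), MMSE (0–30, banded normal/mild/moderate/severe), plus
longitudinal group summaries (sample SD, half-away-from-zero rounding).

**Synthetic data.** The original headset recordings were never deposited, so
the package ships a seeded generator (`motion_spec()`,
`generate_recording()`, `make_study_fixture()`) producing recordings with
known ground truth — gaze drift, 0.3–1 Hz oscillation, saccade-like steps,
tracking resets, timestamp jitter — and questionnaire responses reproducing
the published per-participant outcomes exactly.

## Worked example

```r
library(mindmotion)

# score the bundled reference outcomes through generated item responses
ref <- reference_scores()
rows <- lapply(seq_len(nrow(ref)), function(i) {
  items <- generate_scale_items(ref$scale[i], ref$score[i], seed = i)
  tibble::tibble(participant = ref$participant[i], group = ref$group[i],
                 timepoint = ref$timepoint[i], scale = ref$scale[i],
                 item_index = seq_along(items), value = items)
})
longitudinal_report(dplyr::bind_rows(rows))
#> # A tibble: 15 x 8
#>    group    scale timepoint     n  mean    sd mean_rounded sd_rounded
#>    <chr>    <chr> <chr>     <int> <dbl> <dbl>        <dbl>      <dbl>
#>  1 employee MAAS  before        4 4.3   0.787          4.3        0.8
#>  2 employee MAAS  midterm       4 3.8   1.01           3.8        1
#>  3 employee MAAS  after         4 4.32  0.675          4.3        0.7
#>  4 employee SWLS  before        4 27.2  2.87          27.3        2.9
#>  ...
#> 13 patient  SWLS  before        4 18.2  3.86          18.3        3.9
#> 15 patient  SWLS  after         4 23    1.83          23          1.8
```

Patients' life satisfaction rises from 18.3 (SD 3.9, *slightly dissatisfied*
territory) to 23.0 (SD 1.8, *slightly satisfied*); employees stay high on
mindful attention (4.3 before and after, with a midterm dip to 3.8).

A full synthetic study, end to end:

```r
dir <- tempfile()
make_study_fixture(seed = 1, dir = dir)              # 8 participants x 9 segments
report <- run_study(file.path(dir, "config.yaml"),
                    out_dir = file.path(dir, "out"))
subset(report$comparisons, level == "group" & segment == "body-scan-dooney",
       c(id, session_a, session_b, power_ratio, verdict))
#> # A tibble: 2 x 5
#>   id       session_a session_b power_ratio verdict
#>   <chr>        <int>     <int>       <dbl> <chr>
#> 1 employee         1         8       0.106 reduced
#> 2 patient          1         8       0.996 negligible
```

Employees lose ~90% of their >0.34 Hz yaw band power between the first and
last body scan at the Dooney Rock 360° video (they settle down); patients
show no change there — exactly the contrast the fixture is designed to carry.

The same can be driven from a shell via the thin CLI:

```sh
exec/mindmotion simulate --seed 1 --out study/
exec/mindmotion analyze  --config study/config.yaml --out study/out
exec/mindmotion score    --responses study/responses.csv --out study/scores.csv
```

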