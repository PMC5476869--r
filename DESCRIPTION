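Package: mindmotion
Title: Head-Motion Kinematics and Psychometric Outcomes for VR Telemindfulness Sessions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for head-mounted-display orientation recordings and
    questionnaire outcomes from remotely delivered (telemindfulness) virtual-reality
    mindfulness programs. Converts timestamped unit quaternions from the headset
    sensor to yaw/pitch/roll Euler angles in the intrinsic Y-Z-X sequence with a
    deterministic gimbal-lock convention, conditions the angle traces (zero-phase
    Butterworth low-pass, Haar-wavelet discontinuity detection and elimination),
    computes Parseval-normalized power spectra and high-frequency band-power
    contrasts between sessions with matched content, and summarizes motion by
    per-axis ranges and the convex-hull area of the yaw-roll trajectory. Also
    scores the Satisfaction With Life Scale (SWLS), the Mindful Attention
    Awareness Scale (MAAS) and the Mini-Mental State Examination (MMSE), with
    longitudinal group summaries. A seeded synthetic-data generator emulates
    headset recordings with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    rlang,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
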