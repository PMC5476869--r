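#' Synthetic eight-participant study fixture
#'
#' Builds a full synthetic study: 4 patients and 4 employees, the matched
#' session segments of the 8-session program (body scan at the Dooney Rock
#' 360-degree video in sessions 1 and 8, mindfulness practice in the mountain
#' view virtual environment in sessions 2 and 3, sitting practice in the
#' fireplace room in sessions 5-7, poem reading at the River Bonnet
#' 360-degree video in sessions 5 and 7), plus questionnaire responses that
#' reproduce the reference per-participant outcomes exactly.
#'
#' Designed motion contrasts (the conditions the analysis is validated
#' against): employees lose high-band (> 0.34 Hz) power across sessions in
#' the 360-degree-video segments, patients lose high-band (> 0.44 Hz) power
#' in the virtual-environment sitting segments, and the matched fireplace /
#' River Bonnet segments encode motion-curve-area contrasts of -23%, +17%
#' and -72% via low-band amplitude scaling.
#'
#' @name fixture
NULL

fixture_participants <- function() {
  tibble(
    participant = c(paste0("patient", 1:4), paste0("employee", 1:4)),
    group = rep(c("patient", "employee"), each = 4L)
  )
}

# segment plan: one row per (session, segment); environments: dooney & bonnet
# are 360-degree videos, mountain & fireplace are rendered VEs
fixture_segments <- function() {
  tibble(
    session = c(1L, 8L, 2L, 3L, 5L, 6L, 7L, 5L, 7L),
    segment = c("body-scan-dooney", "body-scan-dooney",
                "mindfulness-mountain", "mindfulness-mountain",
                "sitting-fireplace", "sitting-fireplace", "sitting-fireplace",
                "poem-bonnet", "poem-bonnet"),
    environment = c("dooney", "dooney", "mountain", "mountain",
                    "fireplace", "fireplace", "fireplace", "bonnet", "bonnet"),
    activity = c("body-scan", "body-scan", "mindfulness", "mindfulness",
                 "sitting", "sitting", "sitting", "poem", "poem")
  )
}

fixture_comparisons <- function() {
  tibble(
    segment = c("body-scan-dooney", "mindfulness-mountain",
                "sitting-fireplace", "sitting-fireplace", "sitting-fireplace",
                "poem-bonnet"),
    session_a = c(1L, 2L, 5L, 6L, 5L, 5L),
    session_b = c(8L, 3L, 6L, 7L, 7L, 7L)
  )
}

# amplitude schedule per (group, segment, session): low-band gaze components
# (yaw/roll < 0.2 Hz, dominate ranges and curve area) and the high-band
# 0.6 Hz oscillation the spectral contrasts are designed on
fixture_amplitudes <- function(group, segment, session) {
  emp <- group == "employee"
  key <- paste(segment, session)
  if (segment == "body-scan-dooney") {
    low <- if (emp) c(`1` = 35, `8` = 5)[as.character(session)] else 15
    high <- if (emp) c(`1` = 6, `8` = 2)[as.character(session)] else 3
    pitch <- if (emp) 4 else 8  # patients also scan up and down
  } else if (segment == "mindfulness-mountain") {
    low <- if (emp) c(`2` = 8, `3` = 6)[as.character(session)] else 7
    high <- if (emp) 2 else c(`2` = 4, `3` = 1.5)[as.character(session)]
    pitch <- 3
  } else if (segment == "sitting-fireplace") {
    # matched-session area contrasts: employees -23% (S5 -> S6),
    # patients +17%; scale factor sqrt(1 + pct/100) on the low band
    base <- if (emp) 14 else 7
    k <- if (emp) c(`5` = 1, `6` = sqrt(0.77), `7` = sqrt(0.77))[as.character(session)]
         else c(`5` = 1, `6` = sqrt(1.17), `7` = sqrt(1.17))[as.character(session)]
    low <- base * k
    # patients' gradual high-band loss keeps the designed power ratios but a
    # small absolute amplitude, so it does not confound the low-band area design
    high <- if (emp) 1.5 else c(`5` = 1.6, `6` = 1.0, `7` = 0.4)[as.character(session)]
    pitch <- 4
  } else if (segment == "poem-bonnet") {
    # employees: area smaller by 72% in session 7; patients: calm in 5, moving in 7
    low <- if (emp) c(`5` = 15, `7` = 15 * sqrt(0.28))[as.character(session)]
           else c(`5` = 8, `7` = 20)[as.character(session)]
    high <- if (emp) c(`5` = 5, `7` = 1.5)[as.character(session)] else 2
    pitch <- 3
  } else {
    stop("unknown fixture segment '", segment, "' (", key, ")")
  }
  list(low = unname(low), high = unname(high), pitch = unname(pitch))
}

fixture_motion_spec <- function(group, segment, session, seed) {
  a <- fixture_amplitudes(group, segment, session)
  motion_spec(
    duration = 60, rate = 50, drift_sd = 0.02, jitter_sd = 0.002,
    components = list(
      list(channel = "yaw", freq = 0.12, amplitude = a$low, phase = 0),
      list(channel = "roll", freq = 0.07, amplitude = a$low / 2, phase = pi / 3),
      list(channel = "pitch", freq = 0.1, amplitude = a$pitch, phase = pi / 5),
      list(channel = "yaw", freq = 0.6, amplitude = a$high, phase = pi / 7)
    ),
    seed = seed
  )
}

#' Generate the full synthetic study bundle
#'
#' @param seed integer master seed; every recording and item draw derives its
#'   own sub-seed from it, so the whole bundle is a pure function of `seed`.
#' @param dir if non-NULL, the bundle is written there:
#'   `participant/session-N/segment.csv` (+ JSON sidecars), `responses.csv`
#'   and a ready-to-run `config.yaml`.
#' @return List with `recordings` (nested list
#'   `[[participant]][[session-segment]]` of `orientation_recording`s),
#'   `truths` (matching ground-truth lists), `responses` (long tibble) and
#'   `config` (the analysis configuration as a list).
#' @export
make_study_fixture <- function(seed = 1L, dir = NULL) {
  seed <- as.integer(seed)
  parts <- fixture_participants()
  segs <- fixture_segments()

  recordings <- list()
  truths <- list()
  for (i in seq_len(nrow(parts))) {
    pid <- parts$participant[i]
    recordings[[pid]] <- list()
    truths[[pid]] <- list()
    for (j in seq_len(nrow(segs))) {
      sub_seed <- (seed * 10007L + i * 613L + j * 101L) %% 2147483647L
      spec <- fixture_motion_spec(parts$group[i], segs$segment[j],
                                  segs$session[j], seed = sub_seed)
      gen <- generate_recording(spec, participant = pid,
                                session = segs$session[j],
                                segment = segs$segment[j])
      key <- sprintf("session-%d/%s", segs$session[j], segs$segment[j])
      recordings[[pid]][[key]] <- gen$recording
      truths[[pid]][[key]] <- gen$truth
    }
  }

  ref <- reference_scores()
  resp <- list()
  for (i in seq_len(nrow(ref))) {
    items <- generate_scale_items(ref$scale[i], ref$score[i],
                                  seed = (seed * 7919L + i * 257L) %% 2147483647L)
    resp[[i]] <- tibble(
      participant = ref$participant[i], group = ref$group[i],
      timepoint = ref$timepoint[i], scale = ref$scale[i],
      item_index = seq_along(items), value = items
    )
  }
  responses <- bind_rows(resp)

  config <- list(
    data_dir = ".",
    responses = "responses.csv",
    rate_hz = 50,
    filter = list(cutoff_hz = 2, order = 4L, zero_phase = TRUE),
    discontinuity = list(threshold_mult = 8),
    spectral = list(f_cut = list(employee = 0.34, patient = 0.44),
                    negligible_frac = 0.2),
    groups = as.list(setNames(parts$group, parts$participant)),
    plan = list(
      segments = lapply(seq_len(nrow(segs)), function(j) as.list(segs[j, ])),
      comparisons = lapply(seq_len(nrow(fixture_comparisons())), function(j) {
        as.list(fixture_comparisons()[j, ])
      })
    ),
    seed = seed
  )

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (pid in names(recordings)) {
      for (key in names(recordings[[pid]])) {
        path <- file.path(dir, pid, dirname(key))
        dir.create(path, recursive = TRUE, showWarnings = FALSE)
        write_recording(recordings[[pid]][[key]],
                        file.path(dir, pid, paste0(key, ".csv")))
      }
    }
    write_responses(responses, file.path(dir, "responses.csv"))
    yaml::write_yaml(config, file.path(dir, "config.yaml"))
  }

  list(recordings = recordings, truths = truths, responses = responses,
       config = config)
}
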