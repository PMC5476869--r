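#' Full-study analysis pipeline
#'
#' [run_study()] orchestrates the whole analysis: load recordings per the
#' segment plan, convert to Euler traces, condition (discontinuity
#' elimination, zero-phase low-pass, edge trimming), compute per-segment
#' motion summaries and yaw spectra, compare matched segments across sessions
#' (motion-curve-area change and high-band spectral contrast at the group's
#' cutoff), score questionnaire responses, and write a deterministic report.
#'
#' @name pipeline
NULL

config_allowed_keys <- c("data_dir", "responses", "rate_hz", "filter",
                         "discontinuity", "spectral", "groups", "plan",
                         "out_dir", "seed")

#' Read and validate an analysis configuration
#'
#' @param path YAML configuration file; relative `data_dir`/`responses` paths
#'   resolve against its directory.
#' @return Validated config list (class `mindmotion_config`).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), config_allowed_keys)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "; valid keys are: ", paste(config_allowed_keys, collapse = ", "))
  }
  base <- dirname(normalizePath(path))
  cfg$rate_hz <- if (is.null(cfg$rate_hz)) 50 else as.numeric(cfg$rate_hz)
  f <- cfg$filter
  cfg$filter <- filter_spec(
    cutoff_hz = if (is.null(f$cutoff_hz)) 2 else as.numeric(f$cutoff_hz),
    order = if (is.null(f$order)) 4L else as.integer(f$order),
    zero_phase = if (is.null(f$zero_phase)) TRUE else isTRUE(f$zero_phase)
  )
  if (cfg$filter$cutoff_hz >= cfg$rate_hz / 2) {
    stop("config filter.cutoff_hz = ", cfg$filter$cutoff_hz,
         " Hz is at or above the Nyquist frequency ", cfg$rate_hz / 2,
         " Hz for rate_hz = ", cfg$rate_hz)
  }
  if (is.null(cfg$discontinuity$threshold_mult)) cfg$discontinuity$threshold_mult <- 8
  if (is.null(cfg$spectral$negligible_frac)) cfg$spectral$negligible_frac <- 0.2
  if (is.null(cfg$spectral$f_cut)) cfg$spectral$f_cut <- list(default = 0.34)
  if (is.null(cfg$plan$segments) || is.null(cfg$plan$comparisons)) {
    stop("config must define plan.segments and plan.comparisons")
  }
  segs <- bind_rows(lapply(cfg$plan$segments, as_tibble))
  cmps <- bind_rows(lapply(cfg$plan$comparisons, as_tibble))
  for (k in seq_len(nrow(cmps))) {
    for (s in c("session_a", "session_b")) {
      hit <- segs$segment == cmps$segment[k] & segs$session == cmps[[s]][k]
      if (!any(hit)) {
        stop("plan comparison ", k, " references undefined segment '",
             cmps$segment[k], "' in session ", cmps[[s]][k])
      }
    }
  }
  cfg$plan$segments <- segs
  cfg$plan$comparisons <- cmps
  cfg$data_dir <- if (is.null(cfg$data_dir)) base else {
    p <- cfg$data_dir
    if (!grepl("^(/|[A-Za-z]:)", p)) file.path(base, p) else p
  }
  if (!is.null(cfg$responses) && !grepl("^(/|[A-Za-z]:)", cfg$responses)) {
    cfg$responses <- file.path(base, cfg$responses)
  }
  class(cfg) <- "mindmotion_config"
  cfg
}

participant_group <- function(cfg, pid) {
  if (!is.null(cfg$groups[[pid]])) return(cfg$groups[[pid]])
  sub("[0-9]+$", "", pid)
}

group_f_cut <- function(cfg, group) {
  fc <- cfg$spectral$f_cut
  if (!is.null(fc[[group]])) as.numeric(fc[[group]])
  else if (!is.null(fc$default)) as.numeric(fc$default)
  else 0.34
}

# config hash for provenance: md5 of the canonical JSON of the config minus
# machine-local paths, so identical analyses hash identically anywhere
config_hash <- function(cfg) {
  c2 <- unclass(cfg)
  c2$data_dir <- NULL; c2$out_dir <- NULL; c2$responses <- NULL
  c2$filter <- unclass(c2$filter)
  c2$plan <- lapply(c2$plan, function(d) if (is.data.frame(d)) as.list(d) else d)
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(c2, tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

log_msg <- function(level, ...) {
  message(format(Sys.time(), "%Y-%m-%dT%H:%M:%S "), "[", level, "] ", ...)
}

#' Run the full study analysis
#'
#' @param config path to a YAML config file, or a list/`mindmotion_config`.
#' @param out_dir output directory (overrides the config's `out_dir`); created
#'   if missing. If NULL and the config has none, nothing is written and only
#'   the report object is returned.
#' @param quiet suppress progress logging (default FALSE).
#' @return Invisibly, a `session_report` list: `segments` (tibble of motion
#'   summaries), `comparisons` (tibble of per-participant and group-level
#'   area changes and spectral contrasts), `scores` (longitudinal group
#'   summaries or NULL), `excluded` (character vector of missing segment
#'   files), `provenance`. Writes `report.json`, `metrics.csv` and (with
#'   responses) `scores.csv` under `out_dir`.
#' @export
run_study <- function(config, out_dir = NULL, quiet = FALSE) {
  cfg <- if (inherits(config, "mindmotion_config")) config
         else if (is.character(config)) read_config(config)
         else stop("config must be a path or a mindmotion_config")
  note <- function(...) if (!quiet) log_msg("info", ...)
  segs <- cfg$plan$segments
  pids <- sort(list.dirs(cfg$data_dir, recursive = FALSE, full.names = FALSE))
  pids <- pids[vapply(pids, function(p) {
    length(list.files(file.path(cfg$data_dir, p), pattern = "\\.csv$",
                      recursive = TRUE)) > 0
  }, logical(1L))]
  if (length(pids) == 0L) stop("no participant recording directories under ", cfg$data_dir)

  summaries <- list(); spectra <- list(); traces <- list(); excluded <- character(0)
  for (pid in pids) {
    for (j in seq_len(nrow(segs))) {
      key <- sprintf("session-%d/%s", segs$session[j], segs$segment[j])
      path <- file.path(cfg$data_dir, pid, paste0(key, ".csv"))
      if (!file.exists(path)) {
        warning("missing segment file, excluded: ", pid, "/", key, call. = FALSE)
        excluded <- c(excluded, paste0(pid, "/", key))
        next
      }
      rec <- read_recording(path)
      cond <- condition_trace(to_euler_trace(rec), spec = cfg$filter,
                              threshold_mult = cfg$discontinuity$threshold_mult)
      tr <- cond$trace
      traces[[paste0(pid, "/", key)]] <- tr
      summaries[[paste0(pid, "/", key)]] <-
        motion_summary(tr, segment = segs$segment[j], session = segs$session[j],
                       participant = pid)
      spectra[[paste0(pid, "/", key)]] <- power_spectrum(tr$yaw, tr$rate)
    }
    note("conditioned segments for ", pid)
  }
  seg_tbl <- bind_rows(summaries)

  cmps <- cfg$plan$comparisons
  rows <- list()
  for (k in seq_len(nrow(cmps))) {
    sgm <- cmps$segment[k]; sa <- cmps$session_a[k]; sb <- cmps$session_b[k]
    for (pid in pids) {
      ka <- sprintf("%s/session-%d/%s", pid, sa, sgm)
      kb <- sprintf("%s/session-%d/%s", pid, sb, sgm)
      if (is.null(traces[[ka]]) || is.null(traces[[kb]])) next
      grp <- participant_group(cfg, pid)
      fc <- group_f_cut(cfg, grp)
      ta <- traces[[ka]]; tb <- traces[[kb]]
      nmin <- min(length(ta$yaw), length(tb$yaw))
      spa <- power_spectrum(ta$yaw[seq_len(nmin)], ta$rate)
      spb <- power_spectrum(tb$yaw[seq_len(nmin)], tb$rate)
      sc <- compare_sessions_spectra(spa, spb, f_cut = fc,
                                     negligible_frac = cfg$spectral$negligible_frac)
      aa <- seg_tbl$curve_area[seg_tbl$participant == pid &
                               seg_tbl$session == sa & seg_tbl$segment == sgm]
      ab <- seg_tbl$curve_area[seg_tbl$participant == pid &
                               seg_tbl$session == sb & seg_tbl$segment == sgm]
      rows[[length(rows) + 1L]] <- tibble(
        level = "participant", id = pid, group = grp, segment = sgm,
        session_a = sa, session_b = sb,
        area_before = aa, area_after = ab,
        percent_change = percent_area_change(aa, ab),
        f_cut = fc, power_a = sc$power_a, power_b = sc$power_b,
        power_ratio = sc$ratio, verdict = sc$verdict
      )
    }
    # group-level contrast: band powers pooled over the group's participants
    done <- bind_rows(rows)
    for (grp in sort(unique(vapply(pids, function(p) participant_group(cfg, p), character(1L))))) {
      sel <- done$level == "participant" & done$group == grp & done$segment == sgm &
             done$session_a == sa & done$session_b == sb
      if (!any(sel)) next
      pa <- sum(done$power_a[sel]); pb <- sum(done$power_b[sel])
      nf <- cfg$spectral$negligible_frac
      ratio <- if (pa > 0) pb / pa else if (pb > 0) Inf else 1
      verdict <- if (pb < (1 - nf) * pa) "reduced"
                 else if (pb > (1 + nf) * pa) "increased" else "negligible"
      ab_m <- mean(done$percent_change[sel])
      rows[[length(rows) + 1L]] <- tibble(
        level = "group", id = grp, group = grp, segment = sgm,
        session_a = sa, session_b = sb,
        area_before = sum(done$area_before[sel]), area_after = sum(done$area_after[sel]),
        percent_change = ab_m,
        f_cut = group_f_cut(cfg, grp), power_a = pa, power_b = pb,
        power_ratio = ratio, verdict = verdict
      )
    }
  }
  cmp_tbl <- bind_rows(rows)
  for (k in seq_len(nrow(cmps))) {
    hit <- cmp_tbl$segment == cmps$segment[k] &
           cmp_tbl$session_a == cmps$session_a[k] &
           cmp_tbl$session_b == cmps$session_b[k]
    if (!any(hit)) warning("plan comparison has no usable data: ",
                           cmps$segment[k], " S", cmps$session_a[k], " vs S",
                           cmps$session_b[k], call. = FALSE)
  }

  scores <- NULL
  if (!is.null(cfg$responses) && file.exists(cfg$responses)) {
    scores <- longitudinal_report(read_responses(cfg$responses))
    note("scored questionnaire responses")
  }

  report <- list(
    segments = seg_tbl,
    comparisons = cmp_tbl,
    scores = scores,
    excluded = excluded,
    provenance = list(
      package = "mindmotion",
      version = as.character(packageVersion("mindmotion")),
      config_hash = config_hash(cfg),
      seed = if (is.null(cfg$seed)) NA else cfg$seed
    )
  )
  class(report) <- "session_report"
  validate_report(report)

  out <- if (!is.null(out_dir)) out_dir else cfg$out_dir
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(segments = seg_tbl, comparisons = cmp_tbl, scores = scores,
           excluded = excluded, provenance = report$provenance),
      file.path(out, "report.json"),
      auto_unbox = TRUE, digits = 10, na = "null", pretty = TRUE
    )
    write_metrics_csv(seg_tbl, file.path(out, "metrics.csv"))
    if (!is.null(scores)) write_scores_csv(scores, file.path(out, "scores.csv"))
    note("report written to ", out)
  }
  invisible(report)
}

# tidy long metrics: participant,session,segment,metric,value (fixed formatting
# so repeated runs serialize byte-identically)
write_metrics_csv <- function(seg_tbl, path) {
  metrics <- c("range_yaw", "range_pitch", "range_roll", "curve_area", "duration")
  lines <- "participant,session,segment,metric,value"
  for (i in seq_len(nrow(seg_tbl))) {
    lines <- c(lines, sprintf("%s,%d,%s,%s,%.6f",
                              seg_tbl$participant[i], seg_tbl$session[i],
                              seg_tbl$segment[i], metrics,
                              as.numeric(seg_tbl[i, metrics])))
  }
  writeLines(lines, path)
  invisible(path)
}

write_scores_csv <- function(scores, path) {
  lines <- c(
    "group,scale,timepoint,n,mean,sd,mean_rounded,sd_rounded",
    sprintf("%s,%s,%s,%d,%.6f,%s,%.1f,%s",
            scores$group, scores$scale, scores$timepoint, scores$n, scores$mean,
            ifelse(is.na(scores$sd), "", sprintf("%.6f", scores$sd)),
            scores$mean_rounded,
            ifelse(is.na(scores$sd_rounded), "", sprintf("%.1f", scores$sd_rounded)))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Structural validation of a session report
#'
#' Checks the report against the shipped schema's structural requirements
#' (`inst/schema/session-report.schema.json`): required components, column
#' sets, value domains, and that every planned comparison appears at most once
#' per analysis level and id.
#'
#' @param report a `session_report`.
#' @return TRUE invisibly; stops with a message otherwise.
#' @export
validate_report <- function(report) {
  stopifnot(is.list(report))
  need <- c("segments", "comparisons", "scores", "excluded", "provenance")
  miss <- setdiff(need, names(report))
  if (length(miss) > 0L) stop("report is missing components: ", paste(miss, collapse = ", "))
  seg_cols <- c("participant", "session", "segment", "range_yaw", "range_pitch",
                "range_roll", "curve_area", "duration")
  if (!all(seg_cols %in% names(report$segments))) stop("report$segments has wrong columns")
  cmp_cols <- c("level", "id", "group", "segment", "session_a", "session_b",
                "area_before", "area_after", "percent_change", "f_cut",
                "power_a", "power_b", "power_ratio", "verdict")
  if (nrow(report$comparisons) > 0L) {
    if (!all(cmp_cols %in% names(report$comparisons))) stop("report$comparisons has wrong columns")
    if (!all(report$comparisons$verdict %in% c("reduced", "increased", "negligible"))) {
      stop("invalid verdict in report$comparisons")
    }
    key <- with(report$comparisons, paste(level, id, segment, session_a, session_b))
    if (anyDuplicated(key)) stop("duplicate comparison rows in report")
  }
  if (!all(c("package", "version", "config_hash") %in% names(report$provenance))) {
    stop("report$provenance incomplete")
  }
  invisible(TRUE)
}
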