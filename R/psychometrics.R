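#' Psychometric scale scoring and group aggregation
#'
#' Scoring for the three instruments used around an 8-week telemindfulness
#' program: the Satisfaction With Life Scale (SWLS; 5 items scored 1-7, score
#' is the sum, 5-35, with named satisfaction bands), the Mindful Attention
#' Awareness Scale (MAAS; 15 items scored 1-6, score is the item mean reported
#' to one decimal, higher = more dispositional mindfulness; the response
#' anchors run 1 = almost always to 6 = almost never, so no reverse scoring is
#' applied), and the Mini-Mental State Examination (MMSE; 0-30 total with
#' impairment bands). Group summaries use the sample standard deviation
#' (divisor n-1) and half-away-from-zero rounding, the conventions under which
#' published per-participant tables and their printed group statistics agree.
#'
#' @name psychometrics
NULL

swls_bands <- data.frame(
  lo = c(31, 26, 21, 20, 15, 10, 5),
  hi = c(35, 30, 25, 20, 19, 14, 9),
  category = c("extremely satisfied", "satisfied", "slightly satisfied",
               "neutral", "slightly dissatisfied", "dissatisfied",
               "extremely dissatisfied")
)

check_items <- function(items, n_items, lo, hi, scale) {
  if (length(items) != n_items) {
    stop(scale, " requires exactly ", n_items, " items, got ", length(items))
  }
  bad <- which(!is.finite(items) | items != round(items) | items < lo | items > hi)
  if (length(bad) > 0L) {
    stop(scale, " item ", bad[1L], " (value ", items[bad[1L]],
         ") is not an integer in ", lo, "-", hi)
  }
  invisible(as.integer(items))
}

#' Score the Satisfaction With Life Scale
#'
#' @param items integer vector of 5 responses, each in 1-7.
#' @return List of class `scale_score`: `scale`, `value` (sum, 5-35),
#'   `category` (satisfaction band).
#' @examples
#' score_swls(c(3, 3, 3, 3, 4))$category  # sum 16: "slightly dissatisfied"
#' @export
score_swls <- function(items) {
  items <- check_items(items, 5L, 1L, 7L, "SWLS")
  value <- sum(items)
  band <- swls_bands$category[value >= swls_bands$lo & value <= swls_bands$hi]
  structure(list(scale = "SWLS", value = value, category = band),
            class = "scale_score")
}

#' Score the Mindful Attention Awareness Scale
#'
#' @param items integer vector of 15 responses, each in 1-6.
#' @return List of class `scale_score`: `scale`, `value` (item mean rounded
#'   half-away-from-zero to one decimal), `category` (`NA`; the MAAS has no
#'   banding convention).
#' @export
score_maas <- function(items) {
  items <- check_items(items, 15L, 1L, 6L, "MAAS")
  structure(list(scale = "MAAS", value = round_half_away(mean(items), 1L),
                 category = NA_character_),
            class = "scale_score")
}

#' Classify a Mini-Mental State Examination total
#'
#' Bands: 25-30 normal, 21-24 mild, 10-20 moderate, below 10 severe.
#'
#' @param total integer 0-30.
#' @return Category label.
#' @examples
#' classify_mmse(19)  # "moderate"
#' @export
classify_mmse <- function(total) {
  if (!is.finite(total) || total != round(total) || total < 0 || total > 30) {
    stop("MMSE total must be an integer in 0-30, got ", total)
  }
  if (total >= 25) "normal"
  else if (total >= 21) "mild"
  else if (total >= 10) "moderate"
  else "severe"
}

#' @export
print.scale_score <- function(x, ...) {
  cat(sprintf("<%s score> %s%s\n", x$scale, format(x$value),
              if (is.na(x$category)) "" else paste0(" (", x$category, ")")))
  invisible(x)
}

score_items <- function(scale, items) {
  switch(scale,
    SWLS = score_swls(items),
    MAAS = score_maas(items),
    MMSE = {
      if (length(items) != 1L) stop("MMSE is accepted as a single total only")
      structure(list(scale = "MMSE", value = as.integer(items),
                     category = classify_mmse(items)),
                class = "scale_score")
    },
    stop("unknown scale '", scale, "' (expected SWLS, MAAS or MMSE)")
  )
}

#' Mean and sample SD of a group of scores
#'
#' @param scores numeric vector, length >= 1.
#' @param precision reporting decimals for the rounded statistics (default 1;
#'   use 0 where integers are reported).
#' @return One-row tibble: `n`, `mean`, `sd` (`NA` for n = 1; divisor n-1),
#'   `mean_rounded`, `sd_rounded` (half-away-from-zero).
#' @examples
#' summarize_group(c(16, 16, 17, 24))  # mean 18.3, sd 3.9
#' @export
summarize_group <- function(scores, precision = 1L) {
  if (length(scores) < 1L) stop("summarize_group needs at least one score")
  m <- mean(scores)
  s <- if (length(scores) >= 2L) sd(scores) else NA_real_
  tibble(
    n = length(scores), mean = m, sd = s,
    mean_rounded = round_half_away(m, precision),
    sd_rounded = if (is.na(s)) NA_real_ else round_half_away(s, precision)
  )
}

timepoint_levels <- c("before", "midterm", "after")

#' Longitudinal group report over scale responses
#'
#' Scores every (participant, scale, timepoint) response and aggregates to one
#' group summary per (group, scale, timepoint) cell, ordered group, then
#' scale, then timepoint (before < midterm < after).
#'
#' @param responses long-format data frame with columns `participant`,
#'   `group`, `timepoint`, `scale`, `item_index`, `value` — one row per item
#'   response (MMSE: a single row holding the total).
#' @param precision reporting decimals (default 1).
#' @return Tibble with `group`, `scale`, `timepoint`, `n`, `mean`, `sd`,
#'   `mean_rounded`, `sd_rounded`.
#' @export
longitudinal_report <- function(responses, precision = 1L) {
  need <- c("participant", "group", "timepoint", "scale", "item_index", "value")
  miss <- setdiff(need, names(responses))
  if (length(miss) > 0L) stop("responses are missing columns: ", paste(miss, collapse = ", "))
  bad_tp <- setdiff(unique(responses$timepoint), timepoint_levels)
  if (length(bad_tp) > 0L) {
    stop("unknown timepoint(s): ", paste(bad_tp, collapse = ", "),
         " (expected ", paste(timepoint_levels, collapse = "/"), ")")
  }
  if (nrow(responses) == 0L) {
    return(tibble(group = character(), scale = character(), timepoint = character(),
                  n = integer(), mean = numeric(), sd = numeric(),
                  mean_rounded = numeric(), sd_rounded = numeric()))
  }
  scored <- responses %>%
    group_by(.data$participant, .data$group, .data$scale, .data$timepoint) %>%
    summarise(
      score = score_items(unique(.data$scale),
                          .data$value[order(.data$item_index)])$value,
      .groups = "drop"
    )
  out <- scored %>%
    group_by(.data$group, .data$scale, .data$timepoint) %>%
    summarise(summarize_group(.data$score, precision = precision), .groups = "drop") %>%
    mutate(timepoint = factor(.data$timepoint, levels = timepoint_levels)) %>%
    arrange(.data$group, .data$scale, .data$timepoint) %>%
    mutate(timepoint = as.character(.data$timepoint))
  out
}

#' Read / write item responses CSV
#'
#' Long format: `participant,group,timepoint,scale,item_index,value`.
#'
#' @param path CSV path.
#' @export
read_responses <- function(path) {
  if (!file.exists(path)) stop("responses file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "group", "timepoint", "scale", "item_index", "value")
  if (!identical(names(df), need)) {
    stop("malformed responses CSV ", path, ": header must be exactly '",
         paste(need, collapse = ","), "'")
  }
  as_tibble(df)
}

#' @rdname read_responses
#' @param responses long-format responses data frame.
#' @export
write_responses <- function(responses, path) {
  lines <- c(
    "participant,group,timepoint,scale,item_index,value",
    sprintf("%s,%s,%s,%s,%d,%d",
            responses$participant, responses$group, responses$timepoint,
            responses$scale, as.integer(responses$item_index),
            as.integer(responses$value))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Reference per-participant outcomes of the eight-week feasibility program
#'
#' Per-participant scale scores from the eight-participant telemindfulness
#' feasibility study (four outpatients recovering from brain injury, four
#' hospital employees), assessed before, at midterm (week 4) and after the
#' program. Bundled as a worked example and as the ground truth the synthetic
#' questionnaire generator reproduces. MMSE is included only for the one
#' patient whose trajectory was reported (19 at entry, 26 midterm, 29 after).
#'
#' @return Tibble with `participant`, `group`, `timepoint`, `scale`, `score`.
#' @export
reference_scores <- function() {
  maas_p <- c(3.3, 2.3, 2.3, 4.2, 4.1, 4.8, 3.1, 3.4, 3.6, 2.4, 2.5, 3.0)
  swls_p <- c(16, 18, 21, 16, 11, 24, 17, 21, 22, 24, 25, 25)
  maas_e <- c(3.3, 2.5, 3.9, 4.2, 3.5, 3.7, 4.5, 4.5, 4.5, 5.2, 4.7, 5.2)
  swls_e <- c(28, 22, 25, 25, 22, 21, 25, 25, 25, 31, 32, 32)
  ids_p <- paste0("patient", rep(1:4, each = 3))
  ids_e <- paste0("employee", rep(1:4, each = 3))
  tp <- rep(timepoint_levels, times = 4)
  bind_rows(
    tibble(participant = ids_p, group = "patient", timepoint = tp,
           scale = "MAAS", score = maas_p),
    tibble(participant = ids_p, group = "patient", timepoint = tp,
           scale = "SWLS", score = swls_p),
    tibble(participant = ids_e, group = "employee", timepoint = tp,
           scale = "MAAS", score = maas_e),
    tibble(participant = ids_e, group = "employee", timepoint = tp,
           scale = "SWLS", score = swls_e),
    tibble(participant = "patient2", group = "patient", timepoint = timepoint_levels,
           scale = "MMSE", score = c(19, 26, 29))
  )
}
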