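test_that("SWLS scoring sums items and assigns satisfaction bands", {
  s <- score_swls(c(3, 3, 3, 3, 4))
  expect_equal(s$value, 16)
  expect_equal(s$category, "slightly dissatisfied")
  s2 <- score_swls(c(4, 4, 4, 4, 5))
  expect_equal(s2$value, 21)
  expect_equal(s2$category, "slightly satisfied")
  expect_equal(score_swls(rep(7, 5))$value, 35)
  expect_equal(score_swls(rep(7, 5))$category, "extremely satisfied")
  expect_error(score_swls(c(1, 2, 3, 4)), "exactly 5")
  expect_error(score_swls(c(1, 2, 3, 4, 8)), "item 5")
})

test_that("SWLS bands partition 5-35 without gaps or overlaps", {
  cats <- vapply(5:35, function(total) {
    items <- generate_scale_items("SWLS", total, seed = total)
    score_swls(items)$category
  }, character(1))
  expect_false(any(is.na(cats)))
  expect_equal(unname(table(cats)["neutral"]), 1L)
  # monotone: satisfaction never decreases as the sum rises
  order_ref <- c("extremely dissatisfied", "dissatisfied", "slightly dissatisfied",
                 "neutral", "slightly satisfied", "satisfied", "extremely satisfied")
  expect_true(all(diff(match(cats, order_ref)) >= 0))
})

test_that("MAAS scoring is the item mean at one-decimal reporting", {
  expect_equal(score_maas(rep(6, 15))$value, 6)
  expect_equal(score_maas(rep(1, 15))$value, 1)
  expect_equal(score_maas(c(rep(2, 8), rep(3, 7)))$value, 2.5)  # 37/15 -> 2.5
  expect_error(score_maas(rep(3, 14)), "exactly 15")
  expect_error(score_maas(c(rep(3, 14), 7)), "item 15")
})

test_that("scoring is permutation-invariant in the items", {
  set.seed(51)
  items <- generate_scale_items("MAAS", 3.7, seed = 2)
  for (i in 1:10) {
    expect_equal(score_maas(sample(items))$value, score_maas(items)$value)
  }
  sw <- generate_scale_items("SWLS", 23, seed = 3)
  expect_equal(score_swls(rev(sw))$value, score_swls(sw)$value)
})

test_that("MMSE bands match the screening convention", {
  expect_equal(classify_mmse(19), "moderate")
  expect_equal(classify_mmse(30), "normal")
  expect_equal(classify_mmse(25), "normal")
  expect_equal(classify_mmse(24), "mild")
  expect_equal(classify_mmse(21), "mild")
  expect_equal(classify_mmse(20), "moderate")
  expect_equal(classify_mmse(10), "moderate")
  expect_equal(classify_mmse(9), "severe")
  expect_error(classify_mmse(31), "0-30")
  expect_error(classify_mmse(-1), "0-30")
})

test_that("group summaries use sample SD and half-away-from-zero rounding", {
  g1 <- summarize_group(c(16, 16, 17, 24))
  expect_equal(g1$mean_rounded, 18.3)
  expect_equal(g1$sd_rounded, 3.9)
  g2 <- summarize_group(c(21, 24, 22, 25))
  expect_equal(g2$mean_rounded, 23.0)
  expect_equal(g2$sd_rounded, 1.8)
  # 27.25 must round up, not to even
  g3 <- summarize_group(c(28, 25, 25, 31))
  expect_equal(g3$mean_rounded, 27.3)
  # integer reporting precision
  g4 <- summarize_group(c(22, 22, 25, 32), precision = 0)
  expect_equal(g4$mean_rounded, 25)
  s1 <- summarize_group(5)
  expect_equal(s1$mean, 5)
  expect_true(is.na(s1$sd))
  expect_error(summarize_group(numeric(0)), "at least one")
})

test_that("longitudinal report aggregates by group, scale and timepoint", {
  ref <- reference_scores()
  rows <- lapply(seq_len(nrow(ref)), function(i) {
    items <- generate_scale_items(ref$scale[i], ref$score[i], seed = 100 + i)
    tibble::tibble(participant = ref$participant[i], group = ref$group[i],
                   timepoint = ref$timepoint[i], scale = ref$scale[i],
                   item_index = seq_along(items), value = items)
  })
  rep <- longitudinal_report(dplyr::bind_rows(rows))
  cell <- function(g, sc, tp) rep[rep$group == g & rep$scale == sc & rep$timepoint == tp, ]
  expect_equal(cell("employee", "MAAS", "before")$mean_rounded, 4.3)
  expect_equal(cell("employee", "MAAS", "before")$sd_rounded, 0.8)
  expect_equal(cell("employee", "MAAS", "midterm")$mean_rounded, 3.8)
  expect_equal(cell("employee", "MAAS", "midterm")$sd_rounded, 1.0)
  expect_equal(cell("employee", "MAAS", "after")$mean_rounded, 4.3)
  expect_equal(cell("employee", "MAAS", "after")$sd_rounded, 0.7)
  expect_equal(cell("patient", "SWLS", "before")$mean_rounded, 18.3)
  expect_equal(cell("patient", "SWLS", "before")$sd_rounded, 3.9)
  expect_equal(cell("patient", "SWLS", "after")$mean_rounded, 23.0)
  expect_equal(cell("patient", "SWLS", "after")$sd_rounded, 1.8)
  # ordering: group, then scale, then before < midterm < after
  expect_equal(rep$timepoint[rep$group == "employee" & rep$scale == "MAAS"],
               c("before", "midterm", "after"))
  expect_true(all(rep$n[rep$scale != "MMSE"] == 4))
})

test_that("longitudinal report handles edge inputs", {
  empty <- longitudinal_report(tibble::tibble(
    participant = character(), group = character(), timepoint = character(),
    scale = character(), item_index = integer(), value = integer()))
  expect_equal(nrow(empty), 0)
  one <- tibble::tibble(participant = "p", group = "patient",
                        timepoint = rep(c("before", "midterm", "after"), each = 5),
                        scale = "SWLS", item_index = rep(1:5, 3),
                        value = rep(4L, 15))
  rep1 <- longitudinal_report(one)
  expect_equal(nrow(rep1), 3)
  expect_true(all(is.na(rep1$sd)))
  bad <- one
  bad$timepoint <- "week9"
  expect_error(longitudinal_report(bad), "timepoint")
})

test_that("responses survive the CSV round trip", {
  fx <- tibble::tibble(participant = "e1", group = "employee",
                       timepoint = "before", scale = "SWLS",
                       item_index = 1:5, value = c(5L, 6L, 5L, 6L, 6L))
  path <- file.path(tempdir(), "resp.csv")
  write_responses(fx, path)
  back <- read_responses(path)
  expect_equal(as.data.frame(back), as.data.frame(fx))
})
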