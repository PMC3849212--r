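test_that("point, range and relational age expressions normalize to days", {
  cases <- list(
    # phrase, start_days, end_days, inferred
    list("6-week-old mice were examined", 42, 42, FALSE),
    list("mice aged 42 days were examined", 42, 42, FALSE),
    list("examined at 3 months of age", 90, 90, FALSE),
    list("mice at the age of 2 years", 730, 730, FALSE),
    list("around the age of 12–15 months", 360, 450, FALSE),
    list("aged 6-8 weeks at baseline", 42, 56, FALSE),
    list("under age 30 in this cohort", 0, 30, TRUE),
    list("over the age of 22 months", 660, Inf, TRUE),
    list("mice older than 8 weeks were used", 56, Inf, TRUE),
    list("animals younger than 10 days", 0, 10, TRUE))
  for (case in cases) {
    m <- detect_age_mentions(case[[1]])
    expect_equal(nrow(m), 1L, info = case[[1]])
    expect_equal(m$start_days, case[[2]], info = case[[1]])
    expect_equal(m$end_days, case[[3]], info = case[[1]])
    expect_equal(m$inferred, case[[4]], info = case[[1]])
  }
})

test_that("text without age expressions yields no mentions", {
  expect_equal(nrow(detect_age_mentions("mice were housed in groups of 6")),
               0L)
  expect_equal(nrow(detect_age_mentions("the 6 mice weighed 30 grams")), 0L)
})

test_that("a range is one mention, not two overlapping point ages", {
  m <- detect_age_mentions("mice aged 6–8 weeks developed tumors")
  expect_equal(nrow(m), 1L)
  expect_false(m$inferred)
  expect_equal(c(m$start_days, m$end_days), c(42, 56))
})

test_that("detection is insensitive to surrounding filler text", {
  set.seed(42)
  words <- c("the", "mice", "were", "housed", "and", "monitored", "daily",
             "for", "signs", "of", "distress", "throughout")
  for (i in 1:25) {
    pre <- paste(sample(words, 8, replace = TRUE), collapse = " ")
    post <- paste(sample(words, 8, replace = TRUE), collapse = " ")
    body <- paste(pre, "animals aged 6 weeks were analyzed", post)
    m <- detect_age_mentions(body)
    expect_equal(m$start_days, 42)
    expect_equal(m$end_days, 42)
  }
})

test_that("week conversion is 7x the day value for any count", {
  for (n in c(0, 1, 2, 13, 40)) {
    wk <- detect_age_mentions(paste0("mice aged ", n, " weeks"))
    dy <- detect_age_mentions(paste0("mice aged ", 7 * n, " days"))
    expect_equal(wk$start_days, 7 * n)
    expect_equal(wk$start_days, dy$start_days)
  }
})

test_that("relational expressions default to the requested unit", {
  m_day <- detect_age_mentions("patients under age 30", default_unit = "day")
  m_year <- detect_age_mentions("patients under age 30",
                                default_unit = "year")
  expect_equal(m_day$end_days, 30)
  expect_equal(m_year$end_days, 30 * 365)
  expect_true(m_day$inferred && m_year$inferred)
})

test_that("sentence segmentation respects abbreviations", {
  sp <- sentence_spans("First one. Second with e.g. no split here. Third!")
  expect_equal(nrow(sp), 3L)
  txt <- "Mice were old. Samples were taken."
  sp2 <- sentence_spans(txt)
  expect_equal(substr(txt, sp2$start[2], sp2$end[2]),
               "Samples were taken.")
})

test_that("snippets are the mention sentence plus immediate neighbours", {
  s <- c("One starts here.", "Two follows.", "Three mentions 6-week-old mice.",
         "Four continues.", "Five ends.")
  body <- paste(s, collapse = " ")
  m <- detect_age_mentions(body)
  snip <- extract_snippet(body, m$char_start, m$char_end)
  expect_equal(snip, paste(s[2:4], collapse = " "))
  # boundary: mention in the first of four sentences
  body2 <- paste("At 6 weeks of age mice were dosed.", s[1], s[2], s[4])
  m2 <- detect_age_mentions(body2)
  expect_equal(extract_snippet(body2, m2$char_start),
               paste("At 6 weeks of age mice were dosed.", s[1]))
  # single-sentence abstract returns that sentence
  one <- "Mice aged 10 days were examined."
  m3 <- detect_age_mentions(one)
  expect_equal(extract_snippet(one, m3$char_start), one)
})

test_that("snippet extraction rejects spans outside the body", {
  expect_error(extract_snippet("short body", 50), "outside")
  expect_error(extract_snippet("short body", 0), "outside")
})
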