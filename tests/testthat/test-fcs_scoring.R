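cfg <- fcs_config()

test_that("triglyceride criteria: sustained runs, peaks, prior lows", {
  cases <- list(
    # tg series              sustained peak prior_low
    list(c(12.0, 15.5, 11.2),        5,   0,   0),
    list(c(25.0, 1.8, 12.0, 13.0, 11.0), 5, 1, -5),
    list(numeric(0),                 0,   0,   0),
    list(c(12.0, 9.0, 12.0, 12.0),   0,   0,   0),  # longest run = 2
    list(c(10.0, 10.0, 10.0),        0,   0,   0),  # strict inequality
    list(c(20.0),                    0,   0,   0),
    list(c(20.01),                   0,   1,   0))
  for (cs in cases) {
    got <- tg_criteria_points(tg_history(cs[[1]]), cfg)
    expect_equal(unname(got), c(cs[[2]], cs[[3]], cs[[4]]),
                 label = paste("tg:", paste(cs[[1]], collapse = ",")))
  }
})

test_that("fasting eligibility governs the positive TG criteria", {
  # non-fasting values are excluded from the eligible sequence (they do not
  # break a run); consecutive refers to consecutive fasting analyses
  h <- tg_history(c(12, 9, 11, 13, 12), fasting = c(TRUE, FALSE, TRUE,
                                                    TRUE, TRUE))
  expect_equal(tg_criteria_points(h, cfg)[["sustained"]], 5)
  # but a fasting value at/below threshold does break it
  h0 <- tg_history(c(12, 9, 11, 13), fasting = TRUE)
  expect_equal(tg_criteria_points(h0, cfg)[["sustained"]], 0)
  # unknown fasting counts as fasting by default ...
  h2 <- tg_history(c(12, 12, 13), fasting = c(TRUE, NA, TRUE))
  expect_equal(tg_criteria_points(h2, cfg)[["sustained"]], 5)
  # ... but not when the toggle is off
  cfg2 <- fcs_config(unknown_fasting_counts_as_fasting = FALSE)
  expect_equal(tg_criteria_points(h2, cfg2)[["sustained"]], 0)
  # prior-low counts non-fasting measurements as well
  h3 <- tg_history(c(12, 1.5), fasting = c(TRUE, FALSE))
  expect_equal(tg_criteria_points(h3, cfg)[["prior_low"]], -5)
})

test_that("secondary-factor criterion honours gate and exemptions", {
  expect_equal(secondary_factor_points(
    tg_history(12, codes = "Z33"), cfg), 2)        # pregnancy exempt
  expect_equal(secondary_factor_points(
    tg_history(12, codes = "E1165"), cfg), 0)      # diabetes
  expect_equal(secondary_factor_points(
    tg_history(5, codes = character()), cfg), 0)   # gate fails
  expect_equal(secondary_factor_points(
    tg_history(12, codes = "Z794"), cfg), 2)       # ethinylestradiol exempt
  expect_equal(secondary_factor_points(
    tg_history(12, codes = c("Z33", "F1020")), cfg), 0)
})

test_that("event criteria: pancreatitis, recurrent pain, FCHL", {
  expect_equal(unname(event_criteria_points(
    tg_history(12, codes = "K850"), cfg)), c(1, 0, 1))
  h <- tg_history(12, codes = c("R100", "R100"),
                  code_dates = as.Date(c("2010-05-01", "2011-05-01")))
  expect_equal(event_criteria_points(h, cfg)[["abdominal_pain"]], 1)
  # same-day duplicates are one event
  h2 <- tg_history(12, codes = c("R100", "R104"),
                   code_dates = as.Date(c("2010-05-01", "2010-05-01")))
  expect_equal(event_criteria_points(h2, cfg)[["abdominal_pain"]], 0)
  expect_equal(event_criteria_points(
    tg_history(12, codes = "E782"), cfg)[["no_fchl"]], 0)
  expect_equal(event_criteria_points(
    tg_history(1.2), cfg)[["no_fchl"]], 0)         # gate fails
})

test_that("treatment non-response compares pre/post medians", {
  h <- tg_history(c(20, 20, 17, 17))
  mid <- as.Date("2010-03-01")  # splits the series 2 / 2
  expect_equal(treatment_nonresponse_points(h, cfg, mid), 1)  # 15% < 20%
  h2 <- tg_history(c(20, 20, 10, 10))
  expect_equal(treatment_nonresponse_points(h2, cfg, mid), 0) # 50%
  expect_equal(treatment_nonresponse_points(h, cfg, NULL), 0)
  # window without measurements on one side -> not assessable
  expect_equal(treatment_nonresponse_points(h, cfg, as.Date("2005-01-01")),
               0)
})

test_that("onset age awards only the narrowest band", {
  mk <- function(age) tg_history(12, birth_year = 2010L - age)
  expect_equal(onset_age_points(mk(8), cfg), 3)
  expect_equal(onset_age_points(mk(15), cfg), 2)
  expect_equal(onset_age_points(mk(35), cfg), 1)
  expect_equal(onset_age_points(mk(55), cfg), 0)
  expect_equal(onset_age_points(tg_history(5), cfg), 0)  # no qualifying event
  # first pancreatitis can set onset even without high TG
  h <- patient_history("P", birth_year = 2001L,
                       diagnoses = data.frame(date = as.Date("2010-06-01"),
                                              icd10 = "K850"))
  expect_equal(onset_age_points(h, cfg), 3)
})

test_that("compute_fcs_score sums the rubric and classifies", {
  h <- tg_history(c(12, 15, 11, 22), birth_year = 1976L, codes = "K850")
  s <- compute_fcs_score(h, cfg)
  expect_equal(s$total, 11)  # 5 + 1 + 2 + 1 + 1 + 1 (onset 34)
  expect_equal(s$category, "likely")
  expect_true(s$evaluable)

  s0 <- compute_fcs_score(patient_history("E"), cfg)
  expect_equal(s0$total, 0)
  expect_false(s0$evaluable)
  expect_equal(s0$category, "highly_unlikely")

  s_low <- compute_fcs_score(tg_history(1.2), cfg)
  expect_equal(s_low$total, -5)
})

test_that("classification thresholds follow the body convention", {
  expect_equal(classify_score(10), "likely")
  expect_equal(classify_score(9), "unlikely")
  expect_equal(classify_score(8), "unlikely")
  expect_equal(classify_score(7), "highly_unlikely")
  expect_equal(classify_score(0), "highly_unlikely")
  expect_equal(classify_score(-5), "highly_unlikely")
  # footnote variant
  expect_equal(classify_score(10, "footnote"), "unlikely")
  expect_equal(classify_score(11, "footnote"), "likely")
})

test_that("total equals breakdown sum and matches criterion functions", {
  for (seed in 1:40) {
    h <- random_history(seed)
    s <- compute_fcs_score(h, cfg)
    pts <- unlist(s[startsWith(names(s), "points_")])
    expect_equal(s$total, sum(pts))
    expect_gte(s$total, -5)
    expect_lte(s$total, 15)
    # single-pass path agrees with the exported criterion functions
    tg <- tg_criteria_points(h, cfg)
    ev <- event_criteria_points(h, cfg)
    expect_equal(unname(pts[c("points_sustained_tg", "points_peak_tg",
                              "points_prior_low_tg")]), unname(tg))
    expect_equal(pts[["points_no_secondary"]],
                 secondary_factor_points(h, cfg))
    expect_equal(unname(pts[c("points_pancreatitis",
                              "points_abdominal_pain", "points_no_fchl")]),
                 unname(ev))
    expect_equal(pts[["points_onset_age"]], onset_age_points(h, cfg))
  }
})

test_that("maximum total 15 is attained by an all-criteria history", {
  h <- tg_history(c(12, 22, 12, 22), birth_year = 2002L,
                  codes = c("K850", "R100", "R100"),
                  code_dates = as.Date(c("2010-02-01", "2010-03-01",
                                         "2011-03-01")))
  # treatment non-response: symmetric series around the mid date
  s <- compute_fcs_score(h, cfg, treatment_start = as.Date("2010-03-01"))
  expect_equal(s$total, 15)  # 5+1+2+1+1+1+1+3
  expect_equal(s$category, "likely")
})

test_that("monotonicity: pancreatitis never hurts, low TG never helps", {
  for (seed in 1:15) {
    h <- random_history(seed)
    base <- compute_fcs_score(h, cfg)$total
    h_panc <- h
    h_panc$diagnoses <- rbind(
      h$diagnoses, data.frame(date = as.Date("2013-01-01"),
                              icd10 = "K850"))
    expect_gte(compute_fcs_score(h_panc, cfg)$total, base)
    h_low <- h
    h_low$labs <- rbind(
      h$labs, data.frame(date = as.Date("2013-01-01"), analyte = "TG",
                         value = 1.0, fasting = TRUE))
    expect_lte(compute_fcs_score(h_low, cfg)$total, base)
  }
})

test_that("score_cohort returns one row per patient with consistent totals", {
  roster <- data.frame(patient_id = c("A", "B"), sex = c("male", "female"),
                       birth_year = c(1970L, 1990L))
  labs <- data.frame(patient_id = "A",
                     date = as.Date("2010-01-01") + c(0, 30, 60),
                     analyte = "TG", value = c(12, 13, 14), fasting = TRUE)
  h <- assemble_histories(roster, labs)
  sc <- score_cohort(h, cfg)
  expect_equal(nrow(sc), 2L)
  expect_equal(sc$total[sc$patient_id == "A"],
               compute_fcs_score(h$A, cfg)$total)
  expect_equal(sc$category, classify_score(sc$total))
})
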