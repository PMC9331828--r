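# shared fixtures: history builders and independent oracles

# history with a fasting TG series at monthly dates; extra labs/codes optional
tg_history <- function(tg, id = "P1", birth_year = 1970L,
                       fasting = TRUE, codes = character(),
                       code_dates = NULL, start = as.Date("2010-01-15")) {
  labs <- if (length(tg))
    data.frame(date = start + 30 * (seq_along(tg) - 1), analyte = "TG",
               value = tg, fasting = fasting)
  else NULL
  dx <- if (length(codes)) {
    if (is.null(code_dates)) code_dates <- start + seq_along(codes)
    data.frame(date = as.Date(code_dates), icd10 = codes)
  } else NULL
  patient_history(id, birth_year = birth_year, labs = labs, diagnoses = dx)
}

# ---------------------------------------------------------------------------
# Independent rubric oracle, written directly from the published scoring
# table; shares no code with compute_fcs_score. Only handles the fixture
# shapes used in the oracle tests: all-fasting TG series + ICD code list.
oracle_fcs_score <- function(tg, codes = character(), code_dates = NULL,
                             birth_year = 1970L,
                             start = as.Date("2010-01-15")) {
  dates <- start + 30 * (seq_along(tg) - 1)
  if (is.null(code_dates)) code_dates <- start + seq_along(codes)
  code_dates <- as.Date(code_dates)

  # row 1: fasting TG > 10 for three consecutive analyses (+5),
  #        fasting TG > 20 at least once (+1)
  sustained <- 0
  if (length(tg) >= 3)
    for (i in 1:(length(tg) - 2))
      if (tg[i] > 10 && tg[i + 1] > 10 && tg[i + 2] > 10) sustained <- 5
  peak <- if (any(tg > 20)) 1 else 0
  # row 2: previous TG < 2 (-5)
  prior_low <- if (any(tg < 2)) -5 else 0

  gate <- any(tg > 10)
  pfx <- function(code, set) any(startsWith(code, set))
  secondary_sets <- c("E10", "E11", "E12", "E13", "E14", "E8881", "E03",
                      "F10", "Z721", "Z795")
  exempt_sets <- c("O", "Z32", "Z33", "Z34", "Z35", "Z36", "Z37", "Z794")
  relevant <- codes[!vapply(codes, pfx, TRUE, set = exempt_sets)]
  # row 3: no secondary factor except pregnancy/ethinylestradiol (+2)
  no_secondary <- if (gate &&
                      !any(vapply(relevant, pfx, TRUE,
                                  set = secondary_sets))) 2 else 0
  # row 4: history of pancreatitis (+1)
  panc_sets <- c("K85", "K860", "K861")
  is_panc <- vapply(codes, pfx, TRUE, set = panc_sets)
  panc <- if (any(is_panc)) 1 else 0
  # row 5: unexplained recurrent abdominal pain (+1): >= 2 distinct dates
  pain_dates <- code_dates[vapply(codes, pfx, TRUE, set = "R10")]
  pain <- if (length(unique(pain_dates)) >= 2) 1 else 0
  # row 6: no history of familial combined hyperlipidemia (+1)
  no_fchl <- if (gate && !any(vapply(codes, pfx, TRUE,
                                     set = c("E782", "Z834")))) 1 else 0
  # row 8: onset age bands, narrowest only
  onset_dates <- c(dates[tg > 10], code_dates[is_panc])
  onset <- 0
  if (length(onset_dates)) {
    age <- as.integer(format(min(onset_dates), "%Y")) - birth_year
    onset <- if (age < 10) 3 else if (age < 20) 2 else if (age < 40) 1
             else 0
  }
  sustained + peak + prior_low + no_secondary + panc + pain + no_fchl +
    onset
}

# exhaustive O(n1*n0) pair-counting AUC, ties counted one half
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# small deterministic random history for property tests
random_history <- function(seed) {
  set.seed(seed)
  n_tg <- sample(0:6, 1)
  tg <- round(runif(n_tg, 0.5, 30), 1)
  pool <- c("E1165", "E039", "F1020", "Z795", "Z33", "K850", "R100",
            "R104", "E782", "I1000", "J4500")
  codes <- sample(pool, sample(0:3, 1))
  tg_history(tg, codes = codes,
             birth_year = sample(1930:2005, 1),
             fasting = if (n_tg) sample(c(TRUE, FALSE, NA), n_tg,
                                        replace = TRUE,
                                        prob = c(0.7, 0.15, 0.15))
                       else TRUE)
}
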