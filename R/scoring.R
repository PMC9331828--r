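#' FCS score engine
#'
#' The diagnostic rubric sums nine criteria evaluated on a patient's
#' longitudinal record: sustained fasting hypertriglyceridemia (+5), a
#' single fasting TG peak above 20 mmol/L (+1), any previous TG below
#' 2 mmol/L (-5), absence of secondary factors (+2), history of pancreatitis
#' (+1), unexplained recurrent abdominal pain (+1), no familial combined
#' hyperlipidemia (+1), non-response to hypolipidemic treatment (+1) and
#' young symptom onset (+1/+2/+3 for <40/<20/<10 years, narrowest band
#' only). Totals range from -5 to 15.
#'
#' @name fcs_scoring
NULL

# fasting-eligible TG values + dates, in date order (labs are pre-sorted)
.eligible_tg <- function(history, cfg) {
  labs <- history$labs
  is_tg <- labs$analyte == "TG"
  if (cfg$require_fasting) {
    f <- labs$fasting
    ok <- !is.na(f) & f
    if (cfg$unknown_fasting_counts_as_fasting) ok <- ok | is.na(f)
    is_tg <- is_tg & ok
  }
  list(value = labs$value[is_tg], date = labs$date[is_tg])
}

.all_tg_values <- function(history) {
  labs <- history$labs
  labs$value[labs$analyte == "TG"]
}

# evaluability gate for the absence-based criteria: at least
# min_tg_records_for_absence_criteria fasting-eligible TG above threshold
.absence_gate <- function(history, cfg) {
  v <- .eligible_tg(history, cfg)$value
  sum(v > cfg$tg_sustained_threshold) >=
    cfg$min_tg_records_for_absence_criteria
}

.has_run_above <- function(v, threshold, run_length) {
  if (length(v) < run_length) return(FALSE)
  r <- rle(v > threshold)
  any(r$values & r$lengths >= run_length)
}

#' Triglyceride criteria (sustained, peak, prior low)
#'
#' Sustained: `cfg$tg_sustained_run_length` consecutive entries of the
#' date-ordered fasting-eligible TG sequence each strictly above
#' `cfg$tg_sustained_threshold` (+5). Peak: any fasting-eligible TG strictly
#' above `cfg$tg_peak_threshold` (+1). Prior low: any TG measurement,
#' fasting or not, strictly below `cfg$tg_low_threshold` (-5).
#'
#' @param history A `patient_history`.
#' @param cfg An [fcs_config()].
#' @return Named numeric vector `c(sustained=, peak=, prior_low=)` with
#'   values in \{0,5\}, \{0,1\}, \{0,-5\}.
#' @export
tg_criteria_points <- function(history, cfg = fcs_config()) {
  el <- .eligible_tg(history, cfg)
  sustained <- if (.has_run_above(el$value, cfg$tg_sustained_threshold,
                                  cfg$tg_sustained_run_length)) 5 else 0
  peak <- as.numeric(any(el$value > cfg$tg_peak_threshold))
  prior_low <- if (any(.all_tg_values(history) < cfg$tg_low_threshold)) -5
               else 0
  c(sustained = sustained, peak = peak, prior_low = prior_low)
}

#' Absence-of-secondary-factor criterion
#'
#' +2 when the evaluability gate holds (at least one fasting-eligible TG
#' above the sustained threshold by default) and no diagnosis matches a
#' secondary-factor prefix; diagnoses matching an exemption prefix
#' (pregnancy, ethinylestradiol) are ignored. The gate prevents
#' record-poor patients from scoring absence criteria vacuously.
#'
#' @inheritParams tg_criteria_points
#' @return 0 or 2.
#' @export
secondary_factor_points <- function(history, cfg = fcs_config()) {
  if (!.absence_gate(history, cfg)) return(0)
  codes <- history$diagnoses$icd10
  codes <- codes[!match_any_prefix(codes, unlist(cfg$exemption_codes))]
  if (any(match_any_prefix(codes, unlist(cfg$secondary_factor_codes))))
    return(0)
  2
}

#' Event-history criteria (pancreatitis, abdominal pain, no FCHL)
#'
#' Pancreatitis: any diagnosis matching `cfg$pancreatitis_codes` (+1).
#' Recurrent abdominal pain: at least `cfg$min_abdominal_pain_events`
#' matching diagnoses on distinct dates (+1). No FCHL: the evaluability
#' gate holds and no diagnosis matches `cfg$fchl_codes` (+1).
#'
#' @inheritParams tg_criteria_points
#' @return Named numeric vector `c(pancreatitis=, abdominal_pain=, no_fchl=)`.
#' @export
event_criteria_points <- function(history, cfg = fcs_config()) {
  dx <- history$diagnoses
  panc <- as.numeric(any(match_any_prefix(dx$icd10, cfg$pancreatitis_codes)))
  pain_dates <- dx$date[match_any_prefix(dx$icd10, cfg$abdominal_pain_codes)]
  pain <- as.numeric(length(unique(pain_dates)) >=
                       cfg$min_abdominal_pain_events)
  no_fchl <- as.numeric(.absence_gate(history, cfg) &&
                          !any(match_any_prefix(dx$icd10, cfg$fchl_codes)))
  c(pancreatitis = panc, abdominal_pain = pain, no_fchl = no_fchl)
}

#' Treatment non-response criterion
#'
#' +1 when a treatment start date is supplied, both the pre- and the
#' post-treatment window contain at least one fasting-eligible TG
#' measurement, and the relative decrease of the median TG
#' `(median_before - median_after) / median_before` is strictly below
#' `cfg$treatment_response_threshold`. Without a treatment date the
#' criterion is not assessable and conservatively scores 0.
#'
#' @inheritParams tg_criteria_points
#' @param treatment_start Optional `Date` at which hypolipidemic treatment
#'   started; measurements on the start date count as post-treatment.
#' @return 0 or 1.
#' @export
treatment_nonresponse_points <- function(history, cfg = fcs_config(),
                                         treatment_start = NULL) {
  if (is.null(treatment_start) || is.na(treatment_start)) return(0)
  treatment_start <- as.Date(treatment_start)
  el <- .eligible_tg(history, cfg)
  before <- el$value[el$date < treatment_start]
  after <- el$value[el$date >= treatment_start]
  if (!length(before) || !length(after)) return(0)
  mb <- stats::median(before)
  if (mb <= 0) return(0)
  decrease <- (mb - stats::median(after)) / mb
  as.numeric(decrease < cfg$treatment_response_threshold)
}

#' Symptom-onset age criterion
#'
#' Onset is proxied by the earliest of (first fasting-eligible TG above the
#' sustained threshold, first pancreatitis diagnosis); age in whole years is
#' computed from `birth_year`. Only the narrowest satisfied band scores
#' (defaults: <10 -> 3, <20 -> 2, <40 -> 1); no qualifying event or onset at
#' 40+ scores 0.
#'
#' @inheritParams tg_criteria_points
#' @return Points from `cfg$onset_age_bands` (default 0, 1, 2 or 3).
#' @export
onset_age_points <- function(history, cfg = fcs_config()) {
  if (is.null(history$birth_year) || is.na(history$birth_year)) return(0)
  el <- .eligible_tg(history, cfg)
  cand <- el$date[el$value > cfg$tg_sustained_threshold]
  dx <- history$diagnoses
  cand <- c(cand, dx$date[match_any_prefix(dx$icd10, cfg$pancreatitis_codes)])
  if (!length(cand)) return(0)
  onset_age <- as.integer(format(min(cand), "%Y")) - history$birth_year
  bands <- cfg$onset_age_bands
  hit <- which(onset_age < bands$max_age)
  if (!length(hit)) return(0)
  bands$points[hit[1]]
}

#' Compute the full FCS score of one patient
#'
#' Evaluates all nine rubric criteria, sums them and classifies the total.
#'
#' @inheritParams treatment_nonresponse_points
#' @return An `fcs_score` object: list with the nine per-criterion point
#'   fields (`points_sustained_tg`, `points_peak_tg`, `points_prior_low_tg`,
#'   `points_no_secondary`, `points_pancreatitis`, `points_abdominal_pain`,
#'   `points_no_fchl`, `points_nonresponse`, `points_onset_age`), `total`,
#'   `evaluable` (the absence-criteria gate) and `category`.
#' @export
#' @examples
#' h <- patient_history("P1", birth_year = 1976,
#'   labs = data.frame(date = as.Date("2010-01-01") + c(0, 30, 60, 90),
#'                     analyte = "TG", value = c(12, 15, 11, 22)),
#'   diagnoses = data.frame(date = as.Date("2010-02-01"), icd10 = "K850"))
#' compute_fcs_score(h)
compute_fcs_score <- function(history, cfg = fcs_config(),
                              treatment_start = NULL) {
  # single pass over the record: same logic as the exported per-criterion
  # functions (pinned by an equivalence property test), sharing the
  # eligible-TG extraction and the evaluability gate
  labs <- history$labs
  is_tg <- labs$analyte == "TG"
  all_tg <- labs$value[is_tg]
  if (cfg$require_fasting) {
    f <- labs$fasting[is_tg]
    ok <- !is.na(f) & f
    if (cfg$unknown_fasting_counts_as_fasting) ok <- ok | is.na(f)
    el_v <- all_tg[ok]
    el_d <- labs$date[is_tg][ok]
  } else {
    el_v <- all_tg
    el_d <- labs$date[is_tg]
  }
  gate <- sum(el_v > cfg$tg_sustained_threshold) >=
    cfg$min_tg_records_for_absence_criteria

  tg <- c(
    sustained = if (.has_run_above(el_v, cfg$tg_sustained_threshold,
                                   cfg$tg_sustained_run_length)) 5 else 0,
    peak = as.numeric(any(el_v > cfg$tg_peak_threshold)),
    prior_low = if (any(all_tg < cfg$tg_low_threshold)) -5 else 0)

  codes <- history$diagnoses$icd10
  dx_dates <- history$diagnoses$date
  sec <- 0
  if (gate) {
    kept <- codes[!match_any_prefix(codes, unlist(cfg$exemption_codes))]
    if (!any(match_any_prefix(kept, unlist(cfg$secondary_factor_codes))))
      sec <- 2
  }
  panc_hit <- match_any_prefix(codes, cfg$pancreatitis_codes)
  pain_dates <- dx_dates[match_any_prefix(codes, cfg$abdominal_pain_codes)]
  ev <- c(
    pancreatitis = as.numeric(any(panc_hit)),
    abdominal_pain = as.numeric(length(unique(pain_dates)) >=
                                  cfg$min_abdominal_pain_events),
    no_fchl = as.numeric(gate &&
                           !any(match_any_prefix(codes, cfg$fchl_codes))))

  nr <- treatment_nonresponse_points(history, cfg, treatment_start)

  on <- 0
  if (!is.null(history$birth_year) && !is.na(history$birth_year)) {
    cand <- c(el_d[el_v > cfg$tg_sustained_threshold], dx_dates[panc_hit])
    if (length(cand)) {
      onset_age <- as.integer(format(min(cand), "%Y")) - history$birth_year
      hit <- which(onset_age < cfg$onset_age_bands$max_age)
      if (length(hit)) on <- cfg$onset_age_bands$points[hit[1]]
    }
  }
  res <- list(
    patient_id = history$patient_id,
    points_sustained_tg = unname(tg["sustained"]),
    points_peak_tg = unname(tg["peak"]),
    points_prior_low_tg = unname(tg["prior_low"]),
    points_no_secondary = sec,
    points_pancreatitis = unname(ev["pancreatitis"]),
    points_abdominal_pain = unname(ev["abdominal_pain"]),
    points_no_fchl = unname(ev["no_fchl"]),
    points_nonresponse = nr,
    points_onset_age = on)
  res$total <- sum(unlist(res[startsWith(names(res), "points_")]))
  res$evaluable <- gate
  res$category <- classify_score(res$total, cfg$classification_rule)
  class(res) <- "fcs_score"
  res
}

#' @export
print.fcs_score <- function(x, ...) {
  cat("<fcs_score>", x$patient_id, "total", x$total,
      paste0("(", x$category, ")\n"))
  pts <- unlist(x[startsWith(names(x), "points_")])
  pts <- pts[pts != 0]
  if (length(pts))
    cat("  ", paste(sub("points_", "", names(pts)), pts, sep = "=",
                    collapse = ", "), "\n")
  invisible(x)
}

#' Classify an FCS score total
#'
#' Body convention (default): total >= 10 "likely", 8--9 "unlikely",
#' <= 7 "highly_unlikely". The published footnote variant uses the stricter
#' bounds >= 11 / 9--10 / <= 8 and is available as `rule = "footnote"`.
#'
#' @param total Integer score total(s); vectorized.
#' @param rule `"body"` or `"footnote"`.
#' @return Character vector in
#'   `c("likely", "unlikely", "highly_unlikely")`.
#' @export
classify_score <- function(total, rule = c("body", "footnote")) {
  rule <- match.arg(rule)
  lo <- if (rule == "body") 8 else 9
  hi <- if (rule == "body") 10 else 11
  ifelse(total >= hi, "likely",
         ifelse(total >= lo, "unlikely", "highly_unlikely"))
}

#' Score every patient in a cohort
#'
#' @param histories Named list of `patient_history` objects
#'   ([assemble_histories()]).
#' @param cfg An [fcs_config()].
#' @param treatment_starts Optional named vector/list of treatment start
#'   dates keyed by patient_id.
#' @return A `data.table` with one row per patient: the nine point columns,
#'   `total`, `evaluable`, `category`.
#' @export
score_cohort <- function(histories, cfg = fcs_config(),
                         treatment_starts = NULL) {
  rows <- lapply(histories, function(h) {
    ts <- if (!is.null(treatment_starts)) treatment_starts[[h$patient_id]]
          else NULL
    s <- compute_fcs_score(h, cfg, ts)
    data.table::as.data.table(unclass(s))
  })
  data.table::rbindlist(rows)
}
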