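#' Specification of a synthetic screening cohort
#'
#' Describes the stated world the generator emulates: a large hospital
#' background population with mostly normal fasting triglycerides, an
#' MFCS-like stratum (high TG driven by secondary factors, elevated liver
#' enzymes and glucose, occasional TG dips below 2 mmol/L) and a rare
#' planted FCS stratum (sustained fasting TG far above 10 mmol/L, never
#' below 2 mmol/L, no secondary factors, young onset, frequent
#' pancreatitis, male-predominant).
#'
#' @param n_patients Cohort size.
#' @param fcs_fraction Per-patient probability of the planted FCS stratum.
#'   Default 2e-3 (testing scale; a realistic hospital prevalence is ~2e-5).
#' @param mfcs_fraction Probability of the MFCS-like stratum. Default 0.01.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @param visits_mean Mean visits per patient (Poisson, minimum 1; FCS
#'   patients get at least 3 so the sustained-TG construction is possible).
#' @param panel_prob Per-visit presence probability of each non-lipid
#'   analyte (TG and cholesterol are measured at every visit); the induced
#'   missingness exercises the feature builder.
#' @param fcs_tg_floor Hard floor (mmol/L) on planted FCS triglycerides;
#'   2.5 implements "never below 2" with margin.
#' @param fcs_pancreatitis_prob,mfcs_pancreatitis_prob,bg_pancreatitis_prob
#'   Probability of an acute-pancreatitis code per stratum.
#' @param mfcs_low_tg_prob Probability that an MFCS patient has at least one
#'   TG measurement below 2 mmol/L (the -5 discriminator the rubric
#'   exploits).
#' @param fcs_onset_max_age Upper bound (exclusive) on the planted FCS
#'   first-visit age. Default 40.
#' @param fcs_onset_under20_prob Fraction of FCS patients with onset below
#'   20 years. Default 0.5.
#' @param fcs_male_fraction,other_male_fraction Male fraction per stratum
#'   (0.8 for FCS, 0.45 otherwise).
#' @param window Two calendar years bounding the visit dates (an 8-year
#'   hospital extract window by default).
#' @param lab_params Data frame of per-analyte log-normal location (median)
#'   and log-scale per stratum; see [default_lab_params()].
#' @return A validated `cohort_spec` object.
#' @export
cohort_spec <- function(n_patients,
                        fcs_fraction = 2e-3,
                        mfcs_fraction = 0.01,
                        seed = 1L,
                        visits_mean = 8,
                        panel_prob = 0.7,
                        fcs_tg_floor = 2.5,
                        fcs_pancreatitis_prob = 0.5,
                        mfcs_pancreatitis_prob = 0.1,
                        bg_pancreatitis_prob = 0.005,
                        mfcs_low_tg_prob = 0.3,
                        fcs_onset_max_age = 40,
                        fcs_onset_under20_prob = 0.5,
                        fcs_male_fraction = 0.8,
                        other_male_fraction = 0.45,
                        window = c(2007L, 2014L),
                        lab_params = default_lab_params()) {
  spec <- as.list(environment())
  if (n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  fr <- c(fcs_fraction, mfcs_fraction)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1)
    stop("stratum fractions must lie in [0,1] and sum to at most 1",
         call. = FALSE)
  probs <- c(panel_prob, fcs_pancreatitis_prob, mfcs_pancreatitis_prob,
             bg_pancreatitis_prob, mfcs_low_tg_prob, fcs_onset_under20_prob,
             fcs_male_fraction, other_male_fraction)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0,1]", call. = FALSE)
  stopifnot(visits_mean >= 1, fcs_tg_floor > 2, fcs_onset_max_age > 0,
            length(window) == 2L, window[2] >= window[1])
  class(spec) <- "cohort_spec"
  spec
}

#' Default per-stratum laboratory distributions
#'
#' Log-normal medians and log-scales per analyte and stratum. These are
#' synthetic assumptions, not fitted values: the published evidence fixes
#' only the direction of each stratum contrast (planted FCS sits above the
#' decisive triglyceride cuts and below the liver-enzyme / glucose /
#' inflammation cuts; the MFCS-like stratum is the mirror image), and the
#' magnitudes were chosen once at clinically plausible levels.
#'
#' @return Data frame with columns `analyte`, and `<stratum>_median`,
#'   `<stratum>_sdlog` for `bg`, `mfcs`, `fcs`.
#' @export
default_lab_params <- function() {
  p <- utils::read.csv(text = "
analyte,bg_median,bg_sdlog,mfcs_median,mfcs_sdlog,fcs_median,fcs_sdlog
TG,1.3,0.45,8,0.45,16,0.35
CHOL,5.2,0.20,6.0,0.25,6.0,0.20
GLU,5.2,0.15,7.0,0.20,4.9,0.12
GPT,18,0.40,40,0.50,14,0.30
GGT,25,0.50,60,0.60,18,0.30
HGB,140,0.08,145,0.08,150,0.07
MCHC,330,0.03,330,0.03,336,0.03
AMYL,60,0.30,70,0.40,80,0.45
BASO_PCT,0.4,0.45,0.4,0.45,0.55,0.45
LYMPH_PCT,25,0.25,22,0.25,30,0.20
NEUT_PCT,60,0.15,62,0.15,55,0.15
WBC,6.5,0.25,7.5,0.25,6.0,0.20
NA,140,0.015,141,0.015,139,0.012
CREA,75,0.25,85,0.25,68,0.20
CRP,3,0.80,5,0.80,2.5,0.70
ALP,70,0.30,80,0.30,72,0.30
UREA,5.5,0.30,6.0,0.30,4.5,0.25
", stringsAsFactors = FALSE, strip.white = TRUE, na.strings = "",
    colClasses = c(analyte = "character"))  # sodium is literally "NA"
  p
}

.trunc_norm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm((lo - mean) / sd)
  phi <- stats::pnorm((hi - mean) / sd)
  mean + sd * stats::qnorm(plo + runif(n) * (phi - plo))
}

#' Generate a synthetic screening cohort
#'
#' Deterministic given `spec$seed`. Construction guarantees for the planted
#' FCS stratum: at least 3 visits; the first three chronological visits are
#' fasting with TG forced above the sustained threshold (so the sustained
#' run and the evaluability gate hold by construction); all TG values
#' floored at `fcs_tg_floor`; no secondary-factor codes; first-visit age
#' below `fcs_onset_max_age`; cholesterol clamped to 4--11 mmol/L;
#' pancreatitis code with probability `fcs_pancreatitis_prob`.
#'
#' @param spec A [cohort_spec()].
#' @return An `fcs_cohort` list: `roster`, `labs`, `diagnoses` (the
#'   records-IO table layouts), `truth` (`patient_id`, `stratum` in
#'   \{"FCS", "MFCS", "background"\}) and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients
  ids <- sprintf("P%06d", seq_len(n))

  u <- runif(n)
  stratum <- ifelse(u < spec$fcs_fraction, "FCS",
                    ifelse(u < spec$fcs_fraction + spec$mfcs_fraction,
                           "MFCS", "background"))
  is_fcs <- stratum == "FCS"
  is_mfcs <- stratum == "MFCS"

  male_frac <- ifelse(is_fcs, spec$fcs_male_fraction,
                      spec$other_male_fraction)
  sex <- ifelse(runif(n) < male_frac, "male", "female")

  k <- pmax(rpois(n, spec$visits_mean), 1L)
  k[is_fcs] <- pmax(k[is_fcs], 3L)

  # first-visit age per stratum
  age <- numeric(n)
  n_f <- sum(is_fcs)
  if (n_f) {
    under20 <- runif(n_f) < spec$fcs_onset_under20_prob
    hi <- spec$fcs_onset_max_age
    age[is_fcs] <- ifelse(under20, runif(n_f, 8, min(20, hi)),
                          runif(n_f, min(20, hi), hi))
  }
  age[is_mfcs] <- runif(sum(is_mfcs), 25, 70)
  n_b <- sum(!is_fcs & !is_mfcs)
  age[!is_fcs & !is_mfcs] <- .trunc_norm(n_b, 38, 23, 1, 90)
  age <- pmax(floor(age), 1)

  # visit dates, uniform over the window, sorted within patient
  day0 <- as.Date(sprintf("%d-01-01", spec$window[1]))
  day1 <- as.Date(sprintf("%d-12-31", spec$window[2]))
  span <- as.integer(day1 - day0) + 1L
  V <- sum(k)
  visits <- data.table::data.table(
    pidx = rep(seq_len(n), k),
    date = day0 + floor(runif(V) * span))
  data.table::setorder(visits, pidx, date)
  visits[, visit_idx := seq_len(.N), by = "pidx"]
  visits[, stratum := stratum[pidx]]
  visits[, patient_id := ids[pidx]]

  first_date <- visits[visits$visit_idx == 1L, ]
  birth_year <- as.integer(format(first_date$date, "%Y")) - age

  # fasting flag per visit (shared by all analytes drawn at that visit)
  rf <- runif(V)
  fasting <- rep(NA, V)
  fasting[rf < 0.85] <- TRUE
  fasting[rf >= 0.95] <- FALSE
  fasting <- as.logical(fasting)
  forced <- is_fcs[visits$pidx] & visits$visit_idx <= 3L
  fasting[forced] <- TRUE
  visits[, fasting := fasting]

  lp <- spec$lab_params
  stratum_col <- function(analyte, what) {
    row <- lp[lp$analyte == analyte, ]
    map <- c(background = row[[paste0("bg_", what)]],
             MFCS = row[[paste0("mfcs_", what)]],
             FCS = row[[paste0("fcs_", what)]])
    unname(map[visits$stratum])
  }
  draw_lab <- function(analyte) {
    med <- stratum_col(analyte, "median")
    sdl <- stratum_col(analyte, "sdlog")
    exp(rnorm(V, log(med), sdl))
  }

  # TG: every visit; planted-FCS floor and guaranteed sustained run
  tg <- draw_lab("TG")
  f_rows <- is_fcs[visits$pidx]
  tg[f_rows] <- pmax(tg[f_rows], spec$fcs_tg_floor)
  tg[forced] <- pmax(tg[forced], 10.5)
  # MFCS dip below 2 mmol/L on the first visit with given probability
  dip <- is_mfcs & runif(n) < spec$mfcs_low_tg_prob
  dip_rows <- dip[visits$pidx] & visits$visit_idx == 1L
  tg[dip_rows] <- runif(sum(dip_rows), 0.8, 1.9)

  chol <- draw_lab("CHOL")
  chol[f_rows] <- pmin(pmax(chol[f_rows], 4), 11)

  lab_list <- list(
    data.table::data.table(patient_id = visits$patient_id,
                           date = visits$date, analyte = "TG",
                           value = round(tg, 2), fasting = visits$fasting),
    data.table::data.table(patient_id = visits$patient_id,
                           date = visits$date, analyte = "CHOL",
                           value = round(chol, 2),
                           fasting = visits$fasting))
  for (analyte in setdiff(lp$analyte, c("TG", "CHOL"))) {
    val <- draw_lab(analyte)
    present <- runif(V) < spec$panel_prob
    lab_list[[length(lab_list) + 1L]] <- data.table::data.table(
      patient_id = visits$patient_id[present],
      date = visits$date[present], analyte = analyte,
      value = round(val[present], 2), fasting = visits$fasting[present])
  }
  labs <- data.table::rbindlist(lab_list)
  data.table::setorder(labs, patient_id, date, analyte)

  # diagnoses -----------------------------------------------------------
  cum_k <- cumsum(k)
  start_k <- cum_k - k
  visit_date_of <- function(pidx_sel, which_idx) {
    visits$date[start_k[pidx_sel] + which_idx]
  }
  dx_list <- list()
  add_dx <- function(pidx_sel, code) {
    if (!length(pidx_sel)) return(invisible(NULL))
    idx <- 1L + floor(runif(length(pidx_sel)) * k[pidx_sel])
    dx_list[[length(dx_list) + 1L]] <<- data.table::data.table(
      patient_id = ids[pidx_sel], date = visit_date_of(pidx_sel, idx),
      icd10 = code)
    invisible(NULL)
  }
  bg_idx <- which(!is_fcs & !is_mfcs)
  mfcs_idx <- which(is_mfcs)
  fcs_idx <- which(is_fcs)
  sec_codes <- c(diabetes = "E1190", metabolic_syndrome = "E8881",
                 hypothyroidism = "E039", alcohol_abuse = "F1020",
                 corticosteroid_therapy = "Z795")

  # MFCS: at least one secondary factor, sometimes two
  if (length(mfcs_idx)) {
    cat1 <- sample(names(sec_codes), length(mfcs_idx), replace = TRUE,
                   prob = c(0.5, 0.1, 0.15, 0.15, 0.1))
    for (cc in names(sec_codes))
      add_dx(mfcs_idx[cat1 == cc], sec_codes[[cc]])
    second <- mfcs_idx[runif(length(mfcs_idx)) < 0.3]
    if (length(second)) {
      cat2 <- sample(names(sec_codes), length(second), replace = TRUE)
      for (cc in names(sec_codes))
        add_dx(second[cat2 == cc], sec_codes[[cc]])
    }
  }
  # background: independent low-probability secondary factors
  bg_sec_probs <- c(diabetes = 0.08, metabolic_syndrome = 0.01,
                    hypothyroidism = 0.02, alcohol_abuse = 0.03,
                    corticosteroid_therapy = 0.02)
  for (cc in names(sec_codes))
    add_dx(bg_idx[runif(length(bg_idx)) < bg_sec_probs[[cc]]],
           sec_codes[[cc]])

  # pregnancy / hormone-use exemption codes (females, non-FCS)
  fem_bgm <- c(bg_idx, mfcs_idx)
  fem_bgm <- fem_bgm[sex[fem_bgm] == "female"]
  add_dx(fem_bgm[runif(length(fem_bgm)) < 0.06], "Z33")
  add_dx(fem_bgm[runif(length(fem_bgm)) < 0.02], "Z794")

  # pancreatitis
  add_dx(fcs_idx[runif(length(fcs_idx)) < spec$fcs_pancreatitis_prob],
         "K850")
  add_dx(mfcs_idx[runif(length(mfcs_idx)) < spec$mfcs_pancreatitis_prob],
         "K850")
  add_dx(bg_idx[runif(length(bg_idx)) < spec$bg_pancreatitis_prob], "K850")

  # recurrent abdominal pain: two events on (usually) distinct dates
  pain2 <- fcs_idx[runif(length(fcs_idx)) < 0.3]
  add_dx(pain2, "R104"); add_dx(pain2, "R104")
  add_dx(mfcs_idx[runif(length(mfcs_idx)) < 0.1], "R104")
  pain_bg <- bg_idx[runif(length(bg_idx)) < 0.05]
  add_dx(pain_bg, "R104")
  add_dx(pain_bg[runif(length(pain_bg)) < 0.2], "R104")

  # familial combined hyperlipidemia in the background only
  add_dx(bg_idx[runif(length(bg_idx)) < 0.002], "E782")

  diagnoses <- if (length(dx_list)) data.table::rbindlist(dx_list)
               else data.table::data.table(patient_id = character(),
                                           date = as.Date(character()),
                                           icd10 = character())
  data.table::setorder(diagnoses, patient_id, date, icd10)

  out <- list(
    roster = data.table::data.table(patient_id = ids, sex = sex,
                                    birth_year = birth_year),
    labs = labs,
    diagnoses = diagnoses,
    truth = data.table::data.table(patient_id = ids, stratum = stratum),
    spec = spec)
  class(out) <- "fcs_cohort"
  out
}

#' @export
print.fcs_cohort <- function(x, ...) {
  cat("<fcs_cohort>", nrow(x$roster), "patients (",
      sum(x$truth$stratum == "FCS"), "FCS,",
      sum(x$truth$stratum == "MFCS"), "MFCS ),",
      nrow(x$labs), "lab rows,", nrow(x$diagnoses), "diagnoses\n")
  invisible(x)
}

#' Write a synthetic cohort to a directory
#'
#' Emits `labs.csv`, `diagnoses.csv`, `roster.csv` in the records-IO
#' formats plus `truth.csv` (`patient_id`, `stratum`).
#'
#' @param cohort An `fcs_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_lab_records(cohort$labs, file.path(dir, "labs.csv"))
  write_diagnosis_records(cohort$diagnoses, file.path(dir, "diagnoses.csv"))
  write_roster(cohort$roster, file.path(dir, "roster.csv"))
  data.table::fwrite(cohort$truth, file.path(dir, "truth.csv"))
  invisible(dir)
}

#' Assemble the per-patient histories of a generated cohort
#'
#' @param cohort An `fcs_cohort`.
#' @return Named list of `patient_history` objects
#'   (see [assemble_histories()]).
#' @export
cohort_histories <- function(cohort) {
  assemble_histories(cohort$roster, cohort$labs, cohort$diagnoses)
}

#' Guaranteed rubric floor of the planted FCS stratum
#'
#' Sums the points that the generator's FCS construction makes
#' deterministic: +5 sustained TG (the first three visits are forced above
#' the threshold), +2 no secondary factor (none are planted and the gate
#' holds), and the onset-band points guaranteed by `fcs_onset_max_age`
#' (+1 for the default bound of 40, +2 if forced below 20, +3 below 10);
#' +1 pancreatitis is added only when `fcs_pancreatitis_prob` is 1.
#' Peak TG above 20, pancreatitis (at the default 0.5), narrower onset
#' bands, and abdominal pain remain stochastic and are not counted. The
#' floor is conservative: planted FCS patients also carry no FCHL codes, so
#' in practice they score one point above it.
#'
#' @param spec A [cohort_spec()].
#' @return Integer score floor (8 for the default spec).
#' @export
planted_score_floor <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  bands <- fcs_config()$onset_age_bands
  guaranteed <- bands$points[match(TRUE,
                                   spec$fcs_onset_max_age <= bands$max_age)]
  if (is.na(guaranteed)) guaranteed <- 0
  5 + 2 + guaranteed + as.integer(spec$fcs_pancreatitis_prob >= 1)
}
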