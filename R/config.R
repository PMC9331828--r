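#' Criteria configuration for FCS scoring
#'
#' Builds the configuration object consumed by the scoring engine, the rapid
#' cascade and the feature builder. Every rubric threshold, ICD-10 code set
#' and evaluability convention is surfaced here; nothing is hard-coded in the
#' scoring functions.
#'
#' Default ICD-10 prefix sets (all overridable):
#' * secondary factors: diabetes `E10`--`E14`, metabolic syndrome `E8881`,
#'   hypothyroidism `E03`, alcohol abuse `F10`/`Z721`, corticosteroid therapy
#'   `Z795`;
#' * exemptions (ignored when testing for secondary factors): pregnancy
#'   (chapter `O` plus `Z32`--`Z37`), ethinylestradiol / long-term hormone use
#'   `Z794`;
#' * pancreatitis `K85` (acute), `K860`/`K861` (chronic); abdominal pain
#'   `R10`; familial combined hyperlipidemia `E782` plus family history
#'   `Z834`.
#'
#' @param tg_sustained_threshold Fasting triglyceride threshold (mmol/L) for
#'   the sustained-elevation criterion. Default 10.
#' @param tg_sustained_run_length Number of consecutive fasting TG analyses
#'   that must exceed the threshold. Default 3.
#' @param tg_peak_threshold Single-measurement fasting TG threshold (mmol/L).
#'   Default 20.
#' @param tg_low_threshold TG level (mmol/L) below which any measurement,
#'   fasting or not, triggers the -5 criterion. Default 2.
#' @param onset_age_bands Data frame with columns `max_age`, `points`:
#'   exclusive age bands for symptom onset; the narrowest satisfied band
#'   scores. Default `<10 -> 3`, `<20 -> 2`, `<40 -> 1`.
#' @param secondary_factor_codes Named list of ICD-10 prefix vectors defining
#'   secondary hypertriglyceridemia factors.
#' @param exemption_codes Named list of prefixes exempted from the
#'   secondary-factor test (pregnancy, ethinylestradiol).
#' @param pancreatitis_codes,abdominal_pain_codes,fchl_codes ICD-10 prefix
#'   vectors for the event criteria.
#' @param treatment_response_threshold Fractional TG decrease under
#'   hypolipidemic treatment below which the non-response point is awarded.
#'   Default 0.20.
#' @param min_abdominal_pain_events Distinct dated abdominal-pain diagnoses
#'   required for "recurrent". Default 2.
#' @param require_fasting If `TRUE` (default) only fasting-eligible TG
#'   measurements feed the positive TG criteria.
#' @param unknown_fasting_counts_as_fasting If `TRUE` (default) a missing
#'   fasting flag counts as fasting; retrospective hospital lipid panels are
#'   predominantly fasting.
#' @param min_tg_records_for_absence_criteria Evaluability gate: number of
#'   TG measurements above `tg_sustained_threshold` required before the
#'   absence-based criteria (no secondary factor, no FCHL) can score.
#'   Default 1.
#' @param classification_rule `"body"` (default): total >= 10 likely, 8--9
#'   unlikely, <= 7 highly unlikely. `"footnote"`: the stricter published
#'   footnote variant (>= 11 / 9--10 / <= 8).
#' @return An object of class `fcs_config` (a validated named list).
#' @export
#' @examples
#' cfg <- fcs_config()
#' cfg$tg_sustained_threshold
fcs_config <- function(tg_sustained_threshold = 10,
                       tg_sustained_run_length = 3,
                       tg_peak_threshold = 20,
                       tg_low_threshold = 2,
                       onset_age_bands = data.frame(
                         max_age = c(10, 20, 40),
                         points  = c(3, 2, 1)),
                       secondary_factor_codes = list(
                         diabetes = c("E10", "E11", "E12", "E13", "E14"),
                         metabolic_syndrome = "E8881",
                         hypothyroidism = "E03",
                         alcohol_abuse = c("F10", "Z721"),
                         corticosteroid_therapy = "Z795"),
                       exemption_codes = list(
                         pregnancy = c("O", "Z32", "Z33", "Z34", "Z35",
                                       "Z36", "Z37"),
                         ethinylestradiol = "Z794"),
                       pancreatitis_codes = c("K85", "K860", "K861"),
                       abdominal_pain_codes = "R10",
                       fchl_codes = c("E782", "Z834"),
                       treatment_response_threshold = 0.20,
                       min_abdominal_pain_events = 2,
                       require_fasting = TRUE,
                       unknown_fasting_counts_as_fasting = TRUE,
                       min_tg_records_for_absence_criteria = 1,
                       classification_rule = c("body", "footnote")) {
  cfg <- list(
    tg_sustained_threshold = tg_sustained_threshold,
    tg_sustained_run_length = tg_sustained_run_length,
    tg_peak_threshold = tg_peak_threshold,
    tg_low_threshold = tg_low_threshold,
    onset_age_bands = as.data.frame(onset_age_bands),
    secondary_factor_codes = secondary_factor_codes,
    exemption_codes = exemption_codes,
    pancreatitis_codes = pancreatitis_codes,
    abdominal_pain_codes = abdominal_pain_codes,
    fchl_codes = fchl_codes,
    treatment_response_threshold = treatment_response_threshold,
    min_abdominal_pain_events = min_abdominal_pain_events,
    require_fasting = isTRUE(require_fasting),
    unknown_fasting_counts_as_fasting =
      isTRUE(unknown_fasting_counts_as_fasting),
    min_tg_records_for_absence_criteria =
      min_tg_records_for_absence_criteria,
    classification_rule = match.arg(classification_rule)
  )
  class(cfg) <- "fcs_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "fcs_config"))
  num_pos <- c("tg_sustained_threshold", "tg_peak_threshold",
               "tg_low_threshold", "treatment_response_threshold")
  for (k in num_pos) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("config field '", k, "' must be a single positive number",
           call. = FALSE)
  }
  for (k in c("tg_sustained_run_length", "min_abdominal_pain_events",
              "min_tg_records_for_absence_criteria")) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != round(v))
      stop("config field '", k, "' must be a positive integer",
           call. = FALSE)
  }
  b <- cfg$onset_age_bands
  if (!is.data.frame(b) || !all(c("max_age", "points") %in% names(b)) ||
      nrow(b) < 1L)
    stop("onset_age_bands must be a data frame with columns max_age, points",
         call. = FALSE)
  if (is.unsorted(b$max_age, strictly = TRUE))
    stop("onset_age_bands max_age must be strictly increasing",
         call. = FALSE)
  if (is.unsorted(rev(b$points), strictly = TRUE))
    stop("onset_age_bands points must be strictly decreasing",
         call. = FALSE)
  for (k in c("secondary_factor_codes", "exemption_codes")) {
    v <- cfg[[k]]
    if (!is.list(v) || is.null(names(v)) || any(names(v) == ""))
      stop("config field '", k, "' must be a named list of prefix vectors",
           call. = FALSE)
  }
  invisible(cfg)
}

#' Load a criteria configuration from a YAML or JSON file
#'
#' Unspecified fields take the [fcs_config()] defaults; unknown keys are a
#' fatal error (guards against typos silently reverting a threshold to its
#' default). The effective configuration is echoed via `message()`.
#'
#' @param path Path to a YAML (or JSON; YAML is a superset) file whose keys
#'   are [fcs_config()] argument names. An empty file yields all defaults.
#' @param quiet Suppress the effective-config echo.
#' @return An `fcs_config` object.
#' @export
load_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config file must contain a mapping", call. = FALSE)
  known <- names(formals(fcs_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(raw$onset_age_bands)) {
    b <- raw$onset_age_bands
    if (is.list(b) && !is.data.frame(b))
      b <- data.frame(max_age = vapply(b, function(x) as.numeric(x[[1]]), 0),
                      points  = vapply(b, function(x) as.numeric(x[[2]]), 0))
    raw$onset_age_bands <- b
  }
  cfg <- do.call(fcs_config, raw)
  if (!quiet)
    message("effective config: ",
            paste(sprintf("%s=%s", names(cfg)[1:4], unlist(cfg[1:4])),
                  collapse = ", "),
            ", classification_rule=", cfg$classification_rule)
  cfg
}

# prefix matching for ICD-10 code sets: TRUE for each code matching any prefix
match_any_prefix <- function(codes, prefixes) {
  if (!length(codes)) return(logical(0))
  hit <- rep(FALSE, length(codes))
  for (p in prefixes) hit <- hit | startsWith(codes, p)
  hit
}
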