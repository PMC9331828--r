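#' Per-patient feature engineering for the classification benchmark
#'
#' For every analyte observed in the cohort, five aggregates over the whole
#' record history: highest, lowest, average, fluctuation (sample standard
#' deviation; undefined below two measurements) and measurement count.
#' For every configured ICD-10 prefix group, a binary presence flag.
#' Analytes a patient was never measured for yield missing aggregates
#' (count 0); downstream learners handle missingness natively (trees) or by
#' median imputation plus indicator columns (kernel machine, network).
#'
#' @name ml_features
NULL

.icd_groups <- function(cfg) {
  c(cfg$secondary_factor_codes,
    list(pancreatitis = cfg$pancreatitis_codes,
         abdominal_pain = cfg$abdominal_pain_codes,
         fchl = cfg$fchl_codes),
    cfg$exemption_codes)
}

#' Build the feature matrix of a cohort
#'
#' @param labs Lab table ([read_lab_records()] layout).
#' @param diagnoses Diagnosis table ([read_diagnosis_records()] layout).
#' @param roster Roster table; one output row per roster patient, in roster
#'   order.
#' @param cfg An [fcs_config()] providing the ICD-10 prefix groups.
#' @param analytes Analyte codes to aggregate; defaults to those present in
#'   `labs`, sorted.
#' @return A `data.table` with `patient_id` and numeric columns
#'   `<ANALYTE>_highest/_lowest/_average/_fluctuation/_count` plus
#'   `icd_<group>` flags.
#' @export
build_feature_matrix <- function(labs, diagnoses, roster,
                                 cfg = fcs_config(), analytes = NULL) {
  if (is.null(analytes)) analytes <- sort(unique(labs$analyte))
  ids <- roster$patient_id
  out <- data.table::data.table(patient_id = ids)
  if (nrow(labs)) {
    l <- data.table::as.data.table(labs)[analyte %in% analytes]
    agg <- l[, list(highest = max(value), lowest = min(value),
                    average = mean(value),
                    fluctuation = if (.N >= 2L) stats::sd(value)
                                  else NA_real_,
                    count = as.numeric(.N)),
             by = c("patient_id", "analyte")]
    for (a in analytes) {
      sub <- agg[agg$analyte == a]
      m <- match(ids, sub$patient_id)
      for (stat in c("highest", "lowest", "average", "fluctuation",
                     "count")) {
        col <- sub[[stat]][m]
        if (stat == "count") col[is.na(col)] <- 0
        data.table::set(out, j = paste0(a, "_", stat), value = col)
      }
    }
  }
  groups <- .icd_groups(cfg)
  for (g in names(groups)) {
    if (nrow(diagnoses)) {
      hit <- diagnoses$patient_id[match_any_prefix(diagnoses$icd10,
                                                   groups[[g]])]
      flag <- as.numeric(ids %in% hit)
    } else flag <- numeric(length(ids))
    data.table::set(out, j = paste0("icd_", g), value = flag)
  }
  out
}

#' Build the feature vector of a single patient history
#'
#' Single-patient wrapper around [build_feature_matrix()] (same code path).
#'
#' @param history A `patient_history`.
#' @param cfg An [fcs_config()].
#' @param analytes Optional fixed analyte panel (defaults to the analytes in
#'   this history).
#' @return A one-row `data.table` of features.
#' @export
build_feature_vector <- function(history, cfg = fcs_config(),
                                 analytes = NULL) {
  labs <- data.table::data.table(patient_id = history$patient_id,
                                 history$labs)
  dx <- data.table::data.table(patient_id = history$patient_id,
                               history$diagnoses)
  roster <- data.table::data.table(patient_id = history$patient_id,
                                   sex = history$sex,
                                   birth_year = history$birth_year)
  build_feature_matrix(labs, dx, roster, cfg, analytes)
}
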