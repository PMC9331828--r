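#' @import data.table
#' @importFrom stats median rnorm rpois runif rbinom quantile sd setNames
#' @importFrom utils head tail
NULL

# Canonical unit per analyte code. Sodium is coded "NA" (the chemical symbol),
# so readers must never treat the string "NA" as missing.
.canonical_units <- c(
  TG = "mmol/L", CHOL = "mmol/L", GLU = "mmol/L", `NA` = "mmol/L",
  UREA = "mmol/L", GPT = "U/L", GGT = "U/L", AMYL = "U/L", ALP = "U/L",
  HGB = "g/L", MCHC = "g/L", CREA = "umol/L", CRP = "mg/L", WBC = "G/L",
  BASO_PCT = "%", LYMPH_PCT = "%", NEUT_PCT = "%")

#' Canonical units of the laboratory analyte panel
#'
#' @return Named character vector mapping analyte code to its canonical unit
#'   (lipids/glucose/sodium/urea in mmol/L, enzymes in U/L, hemoglobin and
#'   MCHC in g/L, creatinine in umol/L, CRP in mg/L, white cells in G/L,
#'   differential counts in percent).
#' @export
analyte_units <- function() .canonical_units

.parse_fasting <- function(x) {
  x <- tolower(trimws(x))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes", "y")] <- TRUE
  out[x %in% c("false", "f", "0", "no", "n")] <- FALSE
  as.logical(out)
}

.read_table <- function(path, required, dialect = ",") {
  if (!is.character(path) || length(path) != 1L)
    stop("invalid file path", call. = FALSE)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = dialect, colClasses = "character",
                          na.strings = NULL, header = TRUE)
  miss <- setdiff(required, names(dt))
  if (length(miss))
    stop("missing required column(s) in ", basename(path), ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  dt
}

.finish_read <- function(dt, keep, reasons, what) {
  rejected <- sum(!keep)
  out <- dt[keep]
  if (nrow(out) == 0L)
    warning("no valid ", what, " rows read", call. = FALSE)
  data.table::setattr(out, "rejected", rejected)
  data.table::setattr(out, "rejection_reasons",
                      table(reasons[!keep], dnn = NULL))
  out
}

#' Read laboratory measurements
#'
#' Expects a CSV with header `patient_id,date,analyte,value,unit,fasting`
#' (the `unit` and `fasting` columns are optional), ISO-8601 dates, UTF-8.
#' Rows with an unparseable date or value, a negative value, or a unit that
#' contradicts the analyte's canonical unit are dropped and counted in the
#' `rejected` attribute; a per-reason breakdown is in `rejection_reasons`.
#'
#' @param path CSV file path.
#' @param dialect Field delimiter, default `","`.
#' @return A `data.table` with columns `patient_id`, `date` (`Date`),
#'   `analyte`, `value` (numeric), `fasting` (logical, `NA` = unknown), plus
#'   attributes `rejected` (count) and `rejection_reasons`.
#' @export
read_lab_records <- function(path, dialect = ",") {
  dt <- .read_table(path, c("patient_id", "date", "analyte", "value"),
                    dialect)
  n <- nrow(dt)
  date <- as.Date(dt$date, format = "%Y-%m-%d")
  value <- suppressWarnings(as.numeric(dt$value))
  analyte <- toupper(trimws(dt$analyte))
  fasting <- if ("fasting" %in% names(dt)) .parse_fasting(dt$fasting)
             else rep(NA, n)
  reasons <- rep("ok", n)
  reasons[analyte == ""] <- "empty analyte"
  if ("unit" %in% names(dt)) {
    unit <- trimws(dt$unit)
    canon <- .canonical_units[analyte]
    bad_unit <- !is.na(canon) & unit != "" & unit != canon
    reasons[bad_unit] <- "unit mismatch"
  }
  reasons[is.na(value) | value < 0] <- "bad value"
  reasons[is.na(date)] <- "bad date"
  keep <- reasons == "ok"
  out <- data.table::data.table(
    patient_id = dt$patient_id, date = date, analyte = analyte,
    value = value, fasting = as.logical(fasting))
  .finish_read(out, keep, reasons, "lab")
}

#' Write laboratory measurements
#'
#' Inverse of [read_lab_records()]: writes the canonical CSV layout
#' (`patient_id,date,analyte,value,unit,fasting`), with the fasting flag as
#' `true`/`false` and unknown as the empty string, so that a round trip is
#' field-for-field lossless.
#'
#' @param labs A lab `data.table` as returned by [read_lab_records()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lab_records <- function(labs, path) {
  unit <- .canonical_units[labs$analyte]
  unit[is.na(unit)] <- ""
  out <- data.table::data.table(
    patient_id = labs$patient_id,
    date = format(labs$date, "%Y-%m-%d"),
    analyte = labs$analyte,
    value = labs$value,
    unit = unit,
    fasting = ifelse(is.na(labs$fasting), "",
                     ifelse(labs$fasting, "true", "false")))
  data.table::fwrite(out, path)
  invisible(path)
}

#' Read diagnosis events
#'
#' Expects a CSV with header `patient_id,date,icd10`. Codes are normalized
#' (uppercased, dot removed, truncated to 5 characters); codes not matching
#' the ICD-10 pattern (letter, two digits, up to two alphanumerics) are
#' rejected and counted.
#'
#' @param path CSV file path.
#' @param dialect Field delimiter, default `","`.
#' @return A `data.table` with columns `patient_id`, `date`, `icd10`, plus
#'   `rejected` / `rejection_reasons` attributes.
#' @export
read_diagnosis_records <- function(path, dialect = ",") {
  dt <- .read_table(path, c("patient_id", "date", "icd10"), dialect)
  date <- as.Date(dt$date, format = "%Y-%m-%d")
  code <- substr(gsub(".", "", toupper(trimws(dt$icd10)), fixed = TRUE), 1, 5)
  reasons <- rep("ok", nrow(dt))
  reasons[!grepl("^[A-Z][0-9]{2}[A-Z0-9]{0,2}$", code)] <- "bad code"
  reasons[is.na(date)] <- "bad date"
  out <- data.table::data.table(patient_id = dt$patient_id, date = date,
                                icd10 = code)
  .finish_read(out, reasons == "ok", reasons, "diagnosis")
}

#' Write diagnosis events
#' @param diagnoses Diagnosis `data.table` ([read_diagnosis_records()] layout).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_diagnosis_records <- function(diagnoses, path) {
  out <- data.table::data.table(
    patient_id = diagnoses$patient_id,
    date = format(diagnoses$date, "%Y-%m-%d"),
    icd10 = diagnoses$icd10)
  data.table::fwrite(out, path)
  invisible(path)
}

#' Read the patient roster
#'
#' CSV with header `patient_id,sex,birth_year`; sex coded `male`/`female`
#' (`m`/`f` accepted), birth year within [1900, current year]. Invalid rows
#' are rejected and counted.
#'
#' @param path CSV file path.
#' @param dialect Field delimiter, default `","`.
#' @return A `data.table` with `patient_id`, `sex`, `birth_year` plus
#'   rejection attributes.
#' @export
read_roster <- function(path, dialect = ",") {
  dt <- .read_table(path, c("patient_id", "sex", "birth_year"), dialect)
  sex <- tolower(trimws(dt$sex))
  sex[sex == "m"] <- "male"
  sex[sex == "f"] <- "female"
  by <- suppressWarnings(as.integer(dt$birth_year))
  yr_now <- as.integer(format(Sys.Date(), "%Y"))
  reasons <- rep("ok", nrow(dt))
  reasons[!sex %in% c("male", "female")] <- "bad sex"
  reasons[is.na(by) | by < 1900 | by > yr_now] <- "bad birth_year"
  out <- data.table::data.table(patient_id = dt$patient_id, sex = sex,
                                birth_year = by)
  .finish_read(out, reasons == "ok", reasons, "roster")
}

#' Write the patient roster
#' @param roster Roster `data.table` ([read_roster()] layout).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_roster <- function(roster, path) {
  data.table::fwrite(roster[, c("patient_id", "sex", "birth_year")], path)
  invisible(path)
}

#' Assemble per-patient longitudinal histories
#'
#' Joins the roster, lab and diagnosis tables into one `patient_history`
#' object per roster patient. Records are sorted by calendar date with
#' same-day ties kept in input order; lab or diagnosis rows for patients
#' absent from the roster are excluded and counted in the `orphans`
#' attribute.
#'
#' @param roster Roster table (`patient_id`, `sex`, `birth_year`).
#' @param labs Lab table ([read_lab_records()] layout); may be `NULL`.
#' @param diagnoses Diagnosis table ([read_diagnosis_records()] layout); may
#'   be `NULL`.
#' @return A named list (patient_id -> `patient_history`), each history a
#'   list with `patient_id`, `sex`, `birth_year`, `labs` (data.frame `date`,
#'   `analyte`, `value`, `fasting`) and `diagnoses` (data.frame `date`,
#'   `icd10`). Attribute `orphans` counts excluded foreign records.
#' @export
assemble_histories <- function(roster, labs = NULL, diagnoses = NULL) {
  ids <- roster$patient_id
  if (anyDuplicated(ids))
    stop("duplicate patient_id in roster: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  empty_labs <- data.frame(date = as.Date(character()),
                           analyte = character(), value = numeric(),
                           fasting = logical())
  empty_dx <- data.frame(date = as.Date(character()), icd10 = character())
  orphans <- 0L
  split_sorted <- function(tab) {
    if (is.null(tab) || nrow(tab) == 0L)
      return(list(parts = list(), orphans = 0L))
    known <- tab$patient_id %in% ids
    orph <- sum(!known)
    tab <- tab[known, ]
    tab <- tab[order(tab$patient_id, tab$date, method = "radix"), ]
    list(parts = split(as.data.frame(tab)[, -1, drop = FALSE],
                       factor(tab$patient_id, levels = ids), drop = FALSE),
         orphans = orph)
  }
  sl <- split_sorted(labs)
  sd_ <- split_sorted(diagnoses)
  orphans <- sl$orphans + sd_$orphans
  if (orphans > 0L)
    message(orphans, " lab/diagnosis record(s) for patients not in roster ",
            "were excluded")
  histories <- vector("list", length(ids))
  names(histories) <- ids
  for (i in seq_along(ids)) {
    lab_i <- if (length(sl$parts)) sl$parts[[i]] else empty_labs
    dx_i <- if (length(sd_$parts)) sd_$parts[[i]] else empty_dx
    if (is.null(lab_i)) lab_i <- empty_labs
    if (is.null(dx_i)) dx_i <- empty_dx
    h <- list(patient_id = ids[i], sex = roster$sex[i],
              birth_year = roster$birth_year[i],
              labs = lab_i, diagnoses = dx_i)
    class(h) <- "patient_history"
    histories[[i]] <- h
  }
  attr(histories, "orphans") <- orphans
  histories
}

#' @export
print.patient_history <- function(x, ...) {
  cat("<patient_history>", x$patient_id, "|", x$sex, "| born", x$birth_year,
      "|", nrow(x$labs), "lab records,", nrow(x$diagnoses), "diagnoses\n")
  invisible(x)
}

# lightweight constructor used by tests and examples
#' Construct a single patient history in code
#'
#' Convenience constructor for examples and tests: builds the same
#' `patient_history` object that [assemble_histories()] produces from files.
#' Records are sorted by date (ties keep input order).
#'
#' @param patient_id Patient identifier.
#' @param sex `"male"` or `"female"`.
#' @param birth_year Integer birth year.
#' @param labs Data frame with `date`, `analyte`, `value` and optional
#'   `fasting` (default `TRUE`).
#' @param diagnoses Data frame with `date`, `icd10`.
#' @return A `patient_history` object.
#' @export
patient_history <- function(patient_id, sex = "male", birth_year = 1970L,
                            labs = NULL, diagnoses = NULL) {
  if (is.null(labs))
    labs <- data.frame(date = as.Date(character()), analyte = character(),
                       value = numeric(), fasting = logical())
  labs <- as.data.frame(labs)
  if (is.null(labs$fasting)) labs$fasting <- TRUE
  labs$date <- as.Date(labs$date)
  labs <- labs[order(labs$date, method = "radix"), , drop = FALSE]
  if (is.null(diagnoses))
    diagnoses <- data.frame(date = as.Date(character()), icd10 = character())
  diagnoses <- as.data.frame(diagnoses)
  if (nrow(diagnoses)) {
    diagnoses$date <- as.Date(diagnoses$date)
    diagnoses <- diagnoses[order(diagnoses$date, method = "radix"), ,
                           drop = FALSE]
  }
  h <- list(patient_id = patient_id, sex = sex,
            birth_year = as.integer(birth_year),
            labs = labs, diagnoses = diagnoses)
  class(h) <- "patient_history"
  h
}
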