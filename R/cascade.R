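#' Rapid cascading estimation of FCS score categories
#'
#' Instead of computing the full rubric for every patient, the rapid
#' estimate filters the population through the strong, objectively
#' measurable criteria in a fixed order, attributing a running score label
#' to each stage:
#'
#' 1. all clinical-site patients (`0+`);
#' 2. sustained fasting TG above 10 mmol/L for three consecutive analyses
#'    and TG never below 2 mmol/L (`5+`);
#' 3. additionally no secondary medical factor (`7+`);
#' 4. additionally TG above 20 mmol/L at least once (`8+`);
#' 5. additionally symptom onset below age 40 (`9+`);
#' 6. additionally a history of acute pancreatitis (`10+`).
#'
#' The stage predicates are the exact scoring-engine functions (single
#' source of truth), so every patient surviving a stage has a full-rubric
#' total at least equal to the stage's numeric label; the cascade simply
#' omits the subjective criteria (abdominal pain, FCHL history, treatment
#' response).
#'
#' @param histories Named list of `patient_history` objects.
#' @param cfg An [fcs_config()].
#' @return A `cascade_result`: data.frame with columns `stage`, `feature`,
#'   `score_label`, `count`, `rate` (auto-scaled formatted rate over the
#'   full population), with attributes `population` and `survivors` (list of
#'   patient-id vectors per stage).
#' @export
run_cascade <- function(histories, cfg = fcs_config()) {
  n <- length(histories)
  ids <- names(histories)
  flags <- vapply(histories, function(h) {
    tg <- tg_criteria_points(h, cfg)
    c(sustained = tg[["sustained"]] == 5,
      never_low = tg[["prior_low"]] == 0,
      no_secondary = secondary_factor_points(h, cfg) == 2,
      peak = tg[["peak"]] == 1,
      onset_lt40 = onset_age_points(h, cfg) >= 1,
      pancreatitis =
        event_criteria_points(h, cfg)[["pancreatitis"]] == 1)
  }, logical(6))
  flags <- t(flags)

  stage_defs <- list(
    list("Clinical site patients", "0+", rep(TRUE, n)),
    list("TG > 10 mmol/L sustained and TG never < 2 mmol/L", "5+",
         flags[, "sustained"] & flags[, "never_low"]),
    list("No secondary medical factors", "7+", flags[, "no_secondary"]),
    list("TG > 20 mmol/L at least once", "8+", flags[, "peak"]),
    list("Symptoms below age 40", "9+", flags[, "onset_lt40"]),
    list("Treated with acute pancreatitis", "10+", flags[, "pancreatitis"]))

  alive <- rep(TRUE, n)
  rows <- vector("list", length(stage_defs))
  survivors <- vector("list", length(stage_defs))
  for (i in seq_along(stage_defs)) {
    alive <- alive & stage_defs[[i]][[3]]
    cnt <- sum(alive)
    rows[[i]] <- data.frame(
      stage = i,
      feature = stage_defs[[i]][[1]],
      score_label = stage_defs[[i]][[2]],
      count = cnt,
      rate = format_rate(prevalence_rate(cnt, n, "auto")),
      stringsAsFactors = FALSE)
    survivors[[i]] <- ids[alive]
  }
  res <- do.call(rbind, rows)
  attr(res, "population") <- n
  attr(res, "survivors") <- survivors
  class(res) <- c("cascade_result", "data.frame")
  res
}

#' @export
print.cascade_result <- function(x, ...) {
  cat("Rapid FCS score estimation cascade (population ",
      attr(x, "population"), ")\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
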