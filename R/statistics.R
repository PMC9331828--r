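#' Prevalence rates and score-distribution tables
#'
#' Rates are reported in the units the field mixes freely: percent, per
#' mille, per ten thousand, pcm (per 100,000) and ppm (per 1,000,000).
#' Values are rounded half-up.
#'
#' @name cohort_statistics
NULL

.rate_scales <- c(percent = 1e2, permille = 1e3, per_ten_thousand = 1e4,
                  pcm = 1e5, ppm = 1e6)
.rate_symbols <- c(percent = "%", permille = "\u2030",
                   per_ten_thousand = "\u2031", pcm = " pcm", ppm = " ppm")

# round half away from zero at `digits` decimals; the small epsilon guards
# against binary representations of exact halves (e.g. 2.675 * 100)
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Prevalence rate of a count within a population
#'
#' @param count Number of cases, `0 <= count <= population`.
#' @param population Population size, > 0.
#' @param scale One of `"percent"`, `"permille"`, `"per_ten_thousand"`,
#'   `"pcm"` (per 100,000), `"ppm"` (per 1,000,000), or `"auto"`: the
#'   smallest scale at which the value reaches 1 (ppm if none does) —
#'   the convention behind the mixed units of published cohort tables.
#' @param digits Decimals for half-up rounding; 2 by default, matching the
#'   two-decimal table convention (use 1 for abstract-style one-decimal
#'   rates).
#' @return A `rate_value`: list with `value` (rounded), `scale`, `count`,
#'   `population`.
#' @export
#' @examples
#' format_rate(prevalence_rate(5, 590500, "ppm"))    # "8.47 ppm"
#' format_rate(prevalence_rate(9946, 1341722, "auto")) # "7.41‰"
prevalence_rate <- function(count, population,
                            scale = c("auto", "percent", "permille",
                                      "per_ten_thousand", "pcm", "ppm"),
                            digits = 2) {
  scale <- match.arg(scale)
  if (length(population) != 1L || !is.finite(population) || population <= 0)
    stop("population must be a single positive number", call. = FALSE)
  if (count < 0 || count > population)
    stop("count must lie in [0, population]", call. = FALSE)
  if (scale == "auto") {
    frac <- count / population
    ge1 <- names(.rate_scales)[frac * .rate_scales >= 1]
    scale <- if (length(ge1)) ge1[1] else "ppm"
  }
  out <- list(value = round_half_up(count / population *
                                      .rate_scales[[scale]], digits),
              scale = scale, count = count, population = population)
  class(out) <- "rate_value"
  out
}

#' Format a rate value the way cohort tables print it
#'
#' Two-decimal value plus the scale symbol (`%`, per-mille, per-ten-thousand
#' signs, `" pcm"`, `" ppm"`); whole-number percentages drop the decimals
#' (`"100%"`).
#'
#' @param rate A `rate_value` from [prevalence_rate()].
#' @return A character scalar.
#' @export
format_rate <- function(rate) {
  stopifnot(inherits(rate, "rate_value"))
  v <- formatC(rate$value, format = "f", digits = 2)
  if (rate$scale == "percent" && rate$value == round(rate$value))
    v <- formatC(rate$value, format = "f", digits = 0)
  paste0(v, .rate_symbols[[rate$scale]])
}

#' @export
print.rate_value <- function(x, ...) {
  cat(format_rate(x), sprintf("(%g / %g)\n", x$count, x$population))
  invisible(x)
}

#' Sex-stratified score-distribution table
#'
#' Builds the cumulative ("k+", totals >= k) or disjoint ("= k") score
#' distribution of a scored cohort. Negative totals are floored at 0 so the
#' `0+` row always covers the whole roster.
#'
#' @param results A data.frame of score results with `patient_id` and
#'   `total` ([score_cohort()] output), one row per roster patient.
#' @param roster Roster table with `patient_id` and `sex`.
#' @param convention `"cumulative"` (default; row k counts totals >= k) or
#'   `"disjoint"` (row k counts totals == k).
#' @return A data.frame with `threshold`, `label`, `male_count`,
#'   `female_count`, `total_count`, `male_pct`, `female_pct` (whole-number
#'   percentages of the row total) and `rate` (auto-scaled formatted rate
#'   over the roster size).
#' @export
score_distribution <- function(results, roster,
                               convention = c("cumulative", "disjoint")) {
  convention <- match.arg(convention)
  unknown <- setdiff(results$patient_id, roster$patient_id)
  if (length(unknown))
    stop("score results for patients not in roster: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  if (nrow(results) != nrow(roster) ||
      anyDuplicated(results$patient_id))
    stop("need exactly one score result per roster patient", call. = FALSE)
  sex <- roster$sex[match(results$patient_id, roster$patient_id)]
  tot <- pmax(results$total, 0)
  n <- nrow(roster)
  ks <- 0:max(tot)
  rows <- lapply(ks, function(k) {
    sel <- if (convention == "cumulative") tot >= k else tot == k
    male <- sum(sel & sex == "male")
    female <- sum(sel & sex == "female")
    all_ <- sum(sel)
    data.frame(
      threshold = k,
      label = if (convention == "cumulative") paste0(k, "+") else
        as.character(k),
      male_count = male, female_count = female, total_count = all_,
      male_pct = if (all_ > 0) round_half_up(100 * male / all_, 0) else 0,
      female_pct = if (all_ > 0) round_half_up(100 * female / all_, 0)
                   else 0,
      rate = format_rate(prevalence_rate(all_, n, "auto")),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
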