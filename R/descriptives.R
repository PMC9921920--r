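#' Sex-stratified descriptive comparison table
#'
#' Builds the cohort characteristics table: per variable and sex, the
#' mean with a t-based 95% confidence interval, the median with a
#' distribution-free confidence interval from binomial order statistics
#' and the interquartile range, plus a two-group comparison p-value with
#' automatic test dispatch (Student t when both sexes pass Shapiro-Wilk,
#' Mann-Whitney U otherwise).
#'
#' @param cohort Scored cohort data.frame with both sexes.
#' @param variables Character vector of numeric column names; defaults to
#'   the body-composition indices, activity domain scores, total
#'   MET-min/week, sitting time and the two diet-quality indices.
#' @param level Confidence level (default 0.95).
#' @return Data.frame with one row per variable.
#' @export
descriptive_table <- function(cohort, variables = NULL, level = 0.95) {
  if (is.null(variables)) {
    variables <- c("bmi", "bfp_percent", "fat_mass_kg", "fmi",
                   paste0("met_domain_",
                          c("work", "transport", "domestic", "leisure")),
                   "total_met", "pa_sitting",
                   "hdi8_healthy", "hdi8_unhealthy")
  }
  stopifnot(all(variables %in% names(cohort)),
            all(c("male", "female") %in% cohort$sex))
  z <- stats::qnorm(1 - (1 - level) / 2)
  one <- function(v) {
    xm <- cohort[[v]][cohort$sex == "male"]
    xf <- cohort[[v]][cohort$sex == "female"]
    cell <- function(x) {
      se <- stats::sd(x) / sqrt(length(x))
      mci <- median_ci(x, level)
      c(mean = mean(x), ci_lower = mean(x) - z * se,
        ci_upper = mean(x) + z * se, median = stats::median(x),
        median_ci_lower = mci$lower, median_ci_upper = mci$upper,
        iqr = stats::IQR(x))
    }
    p <- descriptive_compare(xm, xf)$p
    data.frame(variable = v, t(c(male = cell(xm), female = cell(xf))),
               p = p, row.names = NULL)
  }
  do.call(rbind, lapply(variables, one))
}

#' Write a distance matrix as a labeled square CSV
#'
#' @param d A \code{dist} object or square symmetric matrix.
#' @param path Output CSV path.
#' @export
write_distance_csv <- function(d, path) {
  m <- as.matrix(d)
  utils::write.csv(m, path, row.names = TRUE)
}

#' Scoring reference tables
#'
#' The constants behind questionnaire scoring, bundled for audit: MET
#' coefficients per activity item, times/day coefficients per frequency
#' category, item-to-index assignment, and the category bands.
#'
#' @return Nested list, suitable for JSON serialization.
#' @export
scoring_reference <- function() {
  list(
    met_coefficients = stats::setNames(as.list(ipaq_items()$met),
                                       ipaq_items()$item),
    activity_bands = list(low = "< 600 MET-min/week",
                          moderate = "600-2999 MET-min/week",
                          high = ">= 3000 MET-min/week"),
    frequency_coefficients = as.list(qeb_frequency_table()),
    healthy_items = qeb_items("healthy"),
    unhealthy_items = qeb_items("unhealthy"),
    diet_index_bands = list(low = "0-33 points", moderate = "34-66 points",
                            high = "67-100 points"),
    diet_index_scale = "100 x (sum of 8 item frequencies) / 16"
  )
}
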