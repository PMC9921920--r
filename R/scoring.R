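#' IPAQ long-form item metadata and MET coefficients
#'
#' One row per activity item of the long-form physical activity questionnaire
#' (11 activity items across four domains, plus sitting). The MET coefficients
#' follow the official long-form scoring protocol: walking 3.3 (work and
#' leisure), cycling for transport 6.0, moderate activities 4.0, vigorous
#' activities 8.0, vigorous yard work 5.5, moderate inside chores 3.0.
#' Sitting carries no MET coefficient and is tracked in minutes per week.
#'
#' @return A data.frame with columns \code{item}, \code{domain} and
#'   \code{met} (the MET coefficient, \code{NA} for sitting).
#' @export
ipaq_items <- function() {
  data.frame(
    item = c("work_vigorous", "work_moderate", "work_walking",
             "transport_walking", "transport_cycling",
             "domestic_vigorous_outside", "domestic_moderate_outside",
             "domestic_moderate_inside",
             "leisure_walking", "leisure_vigorous", "leisure_moderate",
             "sitting"),
    domain = c(rep("work", 3), rep("transport", 2), rep("domestic", 3),
               rep("leisure", 3), "sitting"),
    met = c(8.0, 4.0, 3.3,
            3.3, 6.0,
            5.5, 4.0, 3.0,
            3.3, 8.0, 4.0,
            NA),
    stringsAsFactors = FALSE
  )
}

#' Food-frequency response vocabulary and times/day coefficients
#'
#' The six ordinal consumption categories of the food-frequency questionnaire
#' and their published times/day conversion coefficients.
#'
#' @return Named numeric vector mapping category label to times/day.
#' @export
qeb_frequency_table <- function() {
  c("never" = 0,
    "1-3 times per month" = 0.06,
    "once per week" = 0.14,
    "several times per week" = 0.5,
    "daily" = 1,
    "several times per day" = 2)
}

#' Names of the 16 food-frequency items
#'
#' Eight pro-healthy food groups (wholegrain bread, milk, fermented milk
#' drinks, curd cheese, fish, legume dishes, fruits, vegetables) and eight
#' non-healthy groups (fast food, fried foods, yellow cheese, sweets, canned
#' meat/fish/vegetable-meat, sweetened carbonated beverages, energy drinks,
#' alcoholic drinks).
#'
#' @param which \code{"all"}, \code{"healthy"} or \code{"unhealthy"}.
#' @return Character vector of item names.
#' @export
qeb_items <- function(which = c("all", "healthy", "unhealthy")) {
  which <- match.arg(which)
  healthy <- c("wholegrain_bread", "milk", "fermented_milk_drinks",
               "curd_cheese", "fish", "legumes", "fruits", "vegetables")
  unhealthy <- c("fast_food", "fried_foods", "yellow_cheese", "sweets",
                 "canned_food", "sweetened_beverages", "energy_drinks",
                 "alcoholic_drinks")
  switch(which, all = c(healthy, unhealthy),
         healthy = healthy, unhealthy = unhealthy)
}

#' Score the 12 physical-activity items into MET-min/week
#'
#' Multiplies weekly minutes of each activity item by its MET coefficient,
#' sums items into the four domain scores (work/school, transport,
#' domestic/garden, leisure) and a total, and assigns the categorical
#' activity level: low (< 600 MET-min/week), moderate (600-2999) or
#' high (>= 3000). Sitting minutes are carried through unscored.
#'
#' The official truncation rules (capping daily minutes) are off by default;
#' set \code{truncate_minutes} to a weekly cap per item to apply one.
#'
#' @param pa_minutes Numeric vector of 12 weekly minutes, ordered (and
#'   optionally named) as \code{ipaq_items()$item}.
#' @param truncate_minutes Optional per-item weekly cap in minutes
#'   (single number), applied before scoring. \code{NULL} (default) leaves
#'   minutes untouched.
#' @return Object of class \code{met_profile}: list with \code{item_scores}
#'   (11 MET-min/week values), \code{domain_scores} (4 values),
#'   \code{total_met}, \code{sitting_min_week} and \code{category}.
#' @export
score_ipaq <- function(pa_minutes, truncate_minutes = NULL) {
  items <- ipaq_items()
  if (length(pa_minutes) != nrow(items)) {
    stop("expected ", nrow(items), " physical-activity values, got ",
         length(pa_minutes))
  }
  if (anyNA(pa_minutes) || any(pa_minutes < 0)) {
    stop("physical-activity minutes must be nonnegative and complete")
  }
  x <- as.numeric(pa_minutes)
  if (!is.null(names(pa_minutes))) {
    if (!setequal(names(pa_minutes), items$item)) {
      stop("unrecognized physical-activity item names: ",
           paste(setdiff(names(pa_minutes), items$item), collapse = ", "))
    }
    x <- as.numeric(pa_minutes[items$item])
  }
  if (!is.null(truncate_minutes)) x <- pmin(x, truncate_minutes)
  act <- items$domain != "sitting"
  item_scores <- items$met[act] * x[act]
  names(item_scores) <- items$item[act]
  domain_scores <- tapply(item_scores, items$domain[act], sum)
  domain_scores <- domain_scores[c("work", "transport", "domestic", "leisure")]
  total <- sum(domain_scores)
  structure(list(
    item_scores = item_scores,
    domain_scores = domain_scores,
    sitting_min_week = x[items$domain == "sitting"],
    total_met = total,
    category = met_category(total)
  ), class = "met_profile")
}

#' Categorical physical-activity level from total MET-min/week
#'
#' @param total_met Total MET-min/week (nonnegative).
#' @return \code{"low"} (< 600), \code{"moderate"} (600-2999) or
#'   \code{"high"} (>= 3000).
#' @export
met_category <- function(total_met) {
  stopifnot(is.numeric(total_met), total_met >= 0)
  ifelse(total_met < 600, "low", ifelse(total_met < 3000, "moderate", "high"))
}

#' Convert food-frequency category labels to times/day
#'
#' @param category_label Character vector of category labels from the
#'   six-level vocabulary (see \code{qeb_frequency_table()}). \code{NA}
#'   passes through as \code{NA}.
#' @return Numeric vector of times/day coefficients.
#' @export
convert_qeb_frequency <- function(category_label) {
  tab <- qeb_frequency_table()
  out <- tab[match(category_label, names(tab))]
  bad <- !is.na(category_label) & is.na(out)
  if (any(bad)) {
    stop("unknown food-frequency category: ",
         paste(unique(category_label[bad]), collapse = ", "))
  }
  unname(out)
}

#' Diet-quality index over eight food groups
#'
#' Sums the eight times/day frequencies and rescales to 0-100 points
#' (100 x sum / 16, the maximum sum with every item at "several times per
#' day"). Banded low (0-33), moderate (34-66), high (67-100).
#'
#' @param frequencies Numeric vector of 8 times/day values, each from
#'   \code{\{0, 0.06, 0.14, 0.5, 1, 2\}}.
#' @return List with \code{points} (0-100) and \code{category}.
#' @export
compute_hdi8 <- function(frequencies) {
  if (length(frequencies) != 8) {
    stop("the diet index is computed over exactly 8 items, got ",
         length(frequencies))
  }
  codomain <- unname(qeb_frequency_table())
  if (anyNA(frequencies) ||
      !all(vapply(frequencies, function(f)
        any(abs(f - codomain) < 1e-9), logical(1)))) {
    stop("frequencies must come from the times/day codomain ",
         paste(codomain, collapse = ", "))
  }
  points <- min(max(100 * sum(frequencies) / 16, 0), 100)
  list(points = points, category = hdi8_category(points))
}

#' Diet-index band from points
#'
#' @param points Index points in [0, 100].
#' @return \code{"low"} (0-33), \code{"moderate"} (34-66) or
#'   \code{"high"} (67-100).
#' @export
hdi8_category <- function(points) {
  stopifnot(all(points >= 0 & points <= 100, na.rm = TRUE))
  ifelse(points <= 33, "low", ifelse(points <= 66, "moderate", "high"))
}

#' Body-composition indices from height, weight and body-fat percentage
#'
#' Computes body mass index (weight / height^2), fat mass
#' (bfp/100 x weight) and fat mass index (fat mass / height^2).
#'
#' @param height_cm Body height in centimeters (> 0).
#' @param weight_kg Body weight in kilograms (> 0).
#' @param bfp_percent Body-fat percentage in [0, 100).
#' @return List with \code{bmi} (kg/m^2), \code{bfp} (percent),
#'   \code{fat_mass_kg} and \code{fmi} (kg/m^2). Vectorized.
#' @export
compute_body_composition <- function(height_cm, weight_kg, bfp_percent) {
  if (any(height_cm <= 0) || any(weight_kg <= 0)) {
    stop("height and weight must be strictly positive")
  }
  if (any(bfp_percent < 0) || any(bfp_percent >= 100)) {
    stop("body-fat percentage must lie in [0, 100)")
  }
  h_m <- height_cm / 100
  fat <- bfp_percent / 100 * weight_kg
  list(bmi = weight_kg / h_m^2,
       bfp = bfp_percent,
       fat_mass_kg = fat,
       fmi = fat / h_m^2)
}

#' Score a whole cohort table
#'
#' Applies \code{score_ipaq}, \code{convert_qeb_frequency},
#' \code{compute_hdi8} and \code{compute_body_composition} row-wise and
#' returns the cohort with appended feature columns: per-item MET scores
#' (\code{met_} prefix), domain scores, \code{total_met}, \code{pa_category},
#' times/day diet coefficients (\code{freq_} prefix), \code{hdi8_healthy},
#' \code{hdi8_unhealthy} (with category columns), \code{bmi},
#' \code{fat_mass_kg} and \code{fmi}. Missing diet cells stay missing and
#' the diet indices for those rows are computed only when all eight items
#' of an index are present.
#'
#' @param cohort A cohort data.frame as produced by \code{generate_cohort()}
#'   or read by \code{read_cohort_csv()}.
#' @return The cohort with scored feature columns appended.
#' @export
score_cohort <- function(cohort) {
  items <- ipaq_items()
  pa_cols <- paste0("pa_", items$item)
  stopifnot(all(pa_cols %in% names(cohort)))
  qcols <- paste0("qeb_", qeb_items())
  stopifnot(all(qcols %in% names(cohort)))

  pa <- as.matrix(cohort[, pa_cols])
  act <- items$domain != "sitting"
  met_mat <- sweep(pa[, act, drop = FALSE], 2, items$met[act], `*`)
  colnames(met_mat) <- paste0("met_", items$item[act])
  for (d in c("work", "transport", "domestic", "leisure")) {
    cohort[[paste0("met_domain_", d)]] <-
      rowSums(met_mat[, items$domain[act] == d, drop = FALSE])
  }
  cohort <- cbind(cohort, as.data.frame(met_mat))
  cohort$total_met <- rowSums(met_mat)
  cohort$pa_category <- met_category(cohort$total_met)

  freq <- vapply(qcols, function(cn) convert_qeb_frequency(cohort[[cn]]),
                 numeric(nrow(cohort)))
  freq <- matrix(freq, nrow = nrow(cohort),
                 dimnames = list(NULL, paste0("freq_", qeb_items())))
  cohort <- cbind(cohort, as.data.frame(freq))

  hcols <- paste0("freq_", qeb_items("healthy"))
  ucols <- paste0("freq_", qeb_items("unhealthy"))
  hdi <- function(m) {
    pts <- 100 * rowSums(m) / 16
    pmin(pmax(pts, 0), 100)
  }
  cohort$hdi8_healthy <- hdi(as.matrix(cohort[, hcols]))
  cohort$hdi8_unhealthy <- hdi(as.matrix(cohort[, ucols]))
  cohort$hdi8_healthy_category <-
    ifelse(is.na(cohort$hdi8_healthy), NA, hdi8_category(cohort$hdi8_healthy))
  cohort$hdi8_unhealthy_category <-
    ifelse(is.na(cohort$hdi8_unhealthy), NA,
           hdi8_category(cohort$hdi8_unhealthy))

  bc <- compute_body_composition(cohort$height_cm, cohort$weight_kg,
                                 cohort$bfp_percent)
  cohort$bmi <- bc$bmi
  cohort$fat_mass_kg <- bc$fat_mass_kg
  cohort$fmi <- bc$fmi
  cohort
}

#' @export
print.met_profile <- function(x, ...) {
  cat("Physical-activity profile\n")
  cat("  total:", format(x$total_met), "MET-min/week (", x$category, ")\n")
  cat("  domains:",
      paste(names(x$domain_scores), round(x$domain_scores, 1),
            collapse = ", "), "\n")
  cat("  sitting:", x$sitting_min_week, "min/week\n")
  invisible(x)
}
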