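#' Specification of a synthetic cohort
#'
#' Bundles and validates the parameters of the synthetic-cohort
#' generator. Defaults mirror the study conditions: 52 males, 55 females,
#' three latent lifestyle classes per sex, strong between-sex item
#' congruence, a moderate standardized diet effect on body fat, and a
#' missing-completely-at-random rate matching 13 missing cells out of
#' 107 x 16 diet responses.
#'
#' @param n_male,n_female Participants per sex; each must be at least
#'   15 x \code{k_clusters} (the 15-30-per-subgroup sample-size rule).
#' @param k_clusters Latent classes per sex (default 3).
#' @param item_congruence_rho Target Mantel correlation in [0, 1] between
#'   the male and female item-distance matrices (default 0.8).
#' @param diet_effect Standardized effect of the unhealthy-diet latent
#'   score on body-fat percentage (default 0.4).
#' @param missing_rate MCAR probability in [0, 1) for diet items
#'   (default 13/1712).
#' @param selfreport_sd Self-report error SD: kg for weight, percentage
#'   points for body fat (default 1).
#' @param seed Integer seed; the same spec and seed give an identical
#'   cohort.
#' @return Object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_male = 52, n_female = 55, k_clusters = 3,
                        item_congruence_rho = 0.8, diet_effect = 0.4,
                        missing_rate = 13 / 1712, selfreport_sd = 1,
                        seed = 1) {
  stopifnot(n_male >= 1, n_female >= 1, k_clusters >= 1)
  if (n_male < 15 * k_clusters || n_female < 15 * k_clusters) {
    stop("each sex needs at least 15 participants per anticipated subgroup ",
         "(15 x k_clusters = ", 15 * k_clusters, ")")
  }
  if (item_congruence_rho < 0 || item_congruence_rho > 1) {
    stop("item_congruence_rho must lie in [0, 1]")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)")
  }
  if (selfreport_sd < 0) stop("selfreport_sd must be nonnegative")
  structure(list(n_male = as.integer(n_male),
                 n_female = as.integer(n_female),
                 k_clusters = as.integer(k_clusters),
                 item_congruence_rho = item_congruence_rho,
                 diet_effect = diet_effect,
                 missing_rate = missing_rate,
                 selfreport_sd = selfreport_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Internal generator constants (see the methods vignette for rationale).
.gen <- list(
  q = 3,             # latent congruence dimensions
  sigma_g = NULL,    # item loading SD, set to 1/sqrt(q) below
  sigma_e = 0.4,     # item-level noise SD on the latent scale
  separation = 2,    # pairwise latent class separation, within-class SDs
  lambda_diet = 0.1,     # loading of the unhealthy-diet score on diet items
  diet_gradient = 1.6,   # class offsets (+a, 0, -a, ...) of the diet score
  log_scale_pa = 0.5,    # latent -> log-minutes scale
  # median weekly minutes per activity item (work vig/mod/walk, transport
  # walk/cycle, domestic vig-out/mod-out/mod-in, leisure walk/vig/mod,
  # sitting)
  pa_median = c(60, 120, 180, 180, 60, 60, 90, 120, 120, 120, 90, 1800),
  # probability of a reported zero per activity item (sitting never zero)
  pa_zero = c(rep(0.05, 11), 0),
  # marginal category probabilities (never ... several times/day),
  # shared by all 16 food groups
  diet_marginal = c(0.10, 0.22, 0.24, 0.25, 0.13, 0.06),
  # anthropometrics: mean/SD by sex
  height = list(male = c(180.39, 6.69), female = c(167.99, 8.28)),
  weight = list(male = c(79.68, 10.83), female = c(64.15, 9.92)),
  bfp = list(male = c(18.45, 5.0), female = c(22.55, 6.0)),
  bfp_weight_slope = 0.25  # pp of body fat per kg, within sex
)
.gen$sigma_g <- 1 / sqrt(.gen$q)

# Calibration of the latent loading mixture weight against the realized
# Mantel correlation between male and female item-distance matrices
# (fitted once by Monte-Carlo under the default spec; see vignette).
.rho_cal <- list(
  w = c(0, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1.0),
  r = c(0, 0.0761, 0.1462, 0.2136, 0.2908, 0.3676, 0.4571, 0.5530,
        0.6532, 0.7641, 0.8973)
)

rho_to_weight <- function(rho) {
  if (rho <= 0) return(0)
  r <- .rho_cal$r
  w <- .rho_cal$w
  if (rho >= max(r)) return(1)
  stats::approx(r, w, xout = rho, ties = "ordered")$y
}

#' Generate a synthetic lifestyle cohort
#'
#' Draws a cohort with the statistical structure the downstream analysis
#' assumes: per sex, participants belong to \code{k_clusters} latent
#' classes whose per-item mean profiles differ by two within-class SDs in
#' expectation; activity minutes are exponentiated Gaussians (right-skewed, with
#' occasional reported zeros); diet responses are six-level ordinal
#' categories obtained by thresholding latent Gaussians; the female item
#' loadings are a noised copy of the male loadings mixed so that the
#' expected Mantel correlation between the sexes' item-distance matrices
#' matches \code{item_congruence_rho}; and body-fat percentage carries a
#' standardized effect of the unhealthy-diet latent score. Classes also
#' differ along a diet-quality gradient (class 1 most unhealthy-leaning).
#'
#' @param spec A \code{cohort_spec}.
#' @return Data.frame with one row per participant: \code{participant_id},
#'   \code{sex}, \code{latent_class} (planted ground truth), 12
#'   \code{pa_} minute columns, 16 \code{qeb_} categorical columns,
#'   anthropometrics, and empty measurement columns (see
#'   \code{generate_selfreport_pairs}). The planted unhealthy-diet scores
#'   are attached as attribute \code{"diet_score"}.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  g <- .gen
  pa_items <- ipaq_items()$item
  d_items <- qeb_items()
  p_pa <- length(pa_items)
  p_d <- length(d_items)
  p <- p_pa + p_d
  k <- spec$k_clusters
  w <- rho_to_weight(spec$item_congruence_rho)

  # shared-vs-independent item loadings carry the planted congruence
  G_m <- matrix(stats::rnorm(p * g$q, sd = g$sigma_g), p, g$q)
  G_f <- sqrt(w) * G_m +
    sqrt(1 - w) * matrix(stats::rnorm(p * g$q, sd = g$sigma_g), p, g$q)

  # latent class means on scaled coordinate axes. `separation` is the
  # expected per-item class-mean difference in within-class SD units:
  # an item's class contrast is g_i (m_a - m_b) with E|g_i u| =
  # sigma_g sqrt(2/pi) |u|, and its within-class SD on the latent scale
  # is sqrt(q sigma_g^2 + sigma_e^2).
  per_item <- sqrt(g$q * g$sigma_g^2 + g$sigma_e^2) /
    (g$sigma_g * sqrt(2 / pi))
  s <- g$separation * per_item / sqrt(2)
  class_means <- matrix(0, k, g$q)
  for (c in seq_len(k)) class_means[c, min(c, g$q)] <- s

  diet_offsets <- if (k > 1) {
    g$diet_gradient * seq(1, -1, length.out = k)
  } else 0

  one_sex <- function(n, sex, G) {
    classes <- rep(seq_len(k), length.out = n)
    t_p <- class_means[classes, , drop = FALSE] +
      matrix(stats::rnorm(n * g$q), n, g$q)
    z <- diet_offsets[classes] + stats::rnorm(n)     # unhealthy-diet score
    latent <- t_p %*% t(G) +
      matrix(stats::rnorm(n * p, sd = g$sigma_e), n, p)

    # activity minutes: exponentiated Gaussian with item medians and
    # latent-censored zeros
    pa <- matrix(0, n, p_pa, dimnames = list(NULL, paste0("pa_", pa_items)))
    for (j in seq_len(p_pa)) {
      lj <- latent[, j]
      lj <- (lj - mean(lj)) / stats::sd(lj)
      minutes <- round(exp(log(g$pa_median[j]) + g$log_scale_pa * lj))
      minutes[lj < stats::qnorm(g$pa_zero[j])] <- 0
      pa[, j] <- minutes
    }

    # diet categories: thresholded latent Gaussian with a health-axis
    # loading (+ for unhealthy items, - for healthy items)
    labs <- names(qeb_frequency_table())
    qeb <- matrix(NA_character_, n, p_d,
                  dimnames = list(NULL, paste0("qeb_", d_items)))
    healthy_set <- qeb_items("healthy")
    for (j in seq_len(p_d)) {
      sign_j <- if (d_items[j] %in% healthy_set) -1 else 1
      lj <- latent[, p_pa + j] + sign_j * g$lambda_diet * z
      lj <- (lj - mean(lj)) / stats::sd(lj)
      marg <- g$diet_marginal
      cuts <- stats::qnorm(cumsum(marg)[-length(marg)])
      qeb[, j] <- labs[findInterval(lj, cuts) + 1L]
    }

    hw <- g$height[[sex]]; ww <- g$weight[[sex]]; bb <- g$bfp[[sex]]
    height <- pmax(stats::rnorm(n, hw[1], hw[2]), 120)
    weight <- pmax(stats::rnorm(n, ww[1], ww[2]), 35)
    z_std <- (z - mean(z)) / stats::sd(z)
    d_eff <- spec$diet_effect
    resid_sd <- bb[2] * sqrt(max(1 - d_eff^2, 0.05))
    bfp <- bb[1] + g$bfp_weight_slope * (weight - ww[1]) +
      d_eff * bb[2] * z_std + stats::rnorm(n, 0, resid_sd)
    bfp <- pmin(pmax(bfp, 3), 60)

    out <- data.frame(
      participant_id = paste0(substr(sex, 1, 1), sprintf("%03d", seq_len(n))),
      sex = sex, latent_class = classes, stringsAsFactors = FALSE
    )
    out <- cbind(out, as.data.frame(pa), as.data.frame(qeb))
    out$height_cm <- round(height, 1)
    out$weight_kg <- round(weight, 1)
    out$bfp_percent <- round(bfp, 1)
    out$measured_flag <- FALSE
    out$measured_weight_kg <- NA_real_
    out$measured_bfp_percent <- NA_real_
    attr(out, "diet_score") <- z_std
    out
  }

  males <- one_sex(spec$n_male, "male", G_m)
  females <- one_sex(spec$n_female, "female", G_f)
  cohort <- rbind(males, females)
  rownames(cohort) <- NULL
  attr(cohort, "diet_score") <- c(attr(males, "diet_score"),
                                  attr(females, "diet_score"))
  attr(cohort, "spec") <- spec
  if (spec$missing_rate > 0) {
    cohort <- apply_mcar(cohort, spec$missing_rate,
                         seed = spec$seed + 1000003L)
  }
  cohort
}

#' Set diet responses missing completely at random
#'
#' Each diet cell is independently set missing with probability
#' \code{rate}; activity and anthropometric cells are untouched, so the
#' missingness indicator is independent of all values (MCAR).
#'
#' @param cohort Cohort data.frame with \code{qeb_} columns.
#' @param rate Missingness probability in [0, 1).
#' @param seed Integer seed.
#' @return The cohort with missing diet cells.
#' @export
apply_mcar <- function(cohort, rate, seed = 1) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(cohort)
  qcols <- paste0("qeb_", qeb_items())
  stopifnot(all(qcols %in% names(cohort)))
  set.seed(seed)
  for (cn in qcols) {
    hit <- stats::runif(nrow(cohort)) < rate
    cohort[[cn]][hit] <- NA_character_
  }
  cohort
}

#' Mark a measured validation subset and attach measured records
#'
#' Selects \code{ceiling(fraction * n)} participants at random, sets
#' their \code{measured_flag}, and fills their measured body fat as
#' self-reported + \code{shift} + Gaussian(0, \code{sd}) (and measured
#' weight as self-reported + Gaussian(0, \code{sd})). \code{shift = 0}
#' emulates the validated-agreement regime; a nonzero shift plants a
#' vertical offset the agreement regression should detect.
#'
#' @param cohort Cohort data.frame.
#' @param shift Systematic self-report bias in body-fat percentage points.
#' @param sd Measurement-vs-report noise SD.
#' @param fraction Fraction of participants measured (0 < fraction <= 1).
#' @param seed Integer seed.
#' @return The cohort with measured columns filled for the subset.
#' @export
generate_selfreport_pairs <- function(cohort, shift = 0, sd = 1,
                                      fraction = 19 / 107, seed = 1) {
  stopifnot(fraction > 0, fraction <= 1, sd >= 0)
  n <- nrow(cohort)
  set.seed(seed)
  idx <- sample.int(n, ceiling(fraction * n))
  cohort$measured_flag <- FALSE
  cohort$measured_flag[idx] <- TRUE
  cohort$measured_weight_kg <- NA_real_
  cohort$measured_bfp_percent <- NA_real_
  cohort$measured_weight_kg[idx] <-
    cohort$weight_kg[idx] + stats::rnorm(length(idx), 0, sd)
  cohort$measured_bfp_percent[idx] <-
    cohort$bfp_percent[idx] + shift + stats::rnorm(length(idx), 0, sd)
  cohort
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort spec:", x$n_male, "males +", x$n_female, "females |",
      x$k_clusters, "classes/sex | congruence rho =", x$item_congruence_rho,
      "| diet effect =", x$diet_effect, "SD | missing rate =",
      signif(x$missing_rate, 3), "| seed =", x$seed, "\n")
  invisible(x)
}

#' Read a cohort specification from a key-value config file
#'
#' Accepts one `key: value` or `key = value` pair per line (blank lines
#' and `#` comments ignored); keys are the arguments of
#' \code{cohort_spec()}. Unknown keys are an error.
#'
#' @param path Path to the config file.
#' @return A validated \code{cohort_spec}.
#' @export
read_cohort_spec <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*[:=]\\s*(.+)$", lines))
  bad <- vapply(kv, length, integer(1)) != 3
  if (any(bad)) stop("unparseable config line(s): ",
                     paste(lines[bad], collapse = "; "))
  keys <- vapply(kv, `[`, character(1), 2)
  vals <- as.numeric(vapply(kv, `[`, character(1), 3))
  known <- names(formals(cohort_spec))
  if (any(!keys %in% known)) {
    stop("unknown cohort spec key(s): ",
         paste(setdiff(keys, known), collapse = ", "))
  }
  do.call(cohort_spec, as.list(stats::setNames(vals, keys)))
}
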