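#' Yeo-Johnson power transformation
#'
#' The four-branch power transform defined on all reals: for x >= 0,
#' ((x+1)^lambda - 1)/lambda (log(x+1) at lambda = 0); for x < 0,
#' -((-x+1)^(2-lambda) - 1)/(2-lambda) (-log(-x+1) at lambda = 2).
#' Strictly increasing for every lambda, so order statistics are preserved.
#'
#' @param x Finite numeric vector.
#' @param lambda Transform exponent, or \code{"fit"} to choose lambda by
#'   maximizing the Gaussian profile log-likelihood of the transformed
#'   sample (golden-section search on [-5, 5], tolerance 1e-6).
#' @return List with \code{y} (transformed vector) and \code{spec}, a
#'   \code{transform_spec} recording the lambda used and whether it was
#'   fitted.
#' @export
yeo_johnson <- function(x, lambda = "fit") {
  stopifnot(is.numeric(x), all(is.finite(x)))
  fitted <- identical(lambda, "fit")
  if (fitted) lambda <- fit_yj_lambda(x)
  stopifnot(is.numeric(lambda), is.finite(lambda))
  structure(list(
    y = yj_apply(x, lambda),
    spec = structure(list(lambda = lambda, fitted = fitted),
                     class = "transform_spec")
  ), class = "yeo_johnson")
}

yj_apply <- function(x, lambda) {
  y <- numeric(length(x))
  pos <- x >= 0
  if (abs(lambda) > 1e-12) {
    y[pos] <- ((x[pos] + 1)^lambda - 1) / lambda
  } else {
    y[pos] <- log1p(x[pos])
  }
  if (abs(lambda - 2) > 1e-12) {
    y[!pos] <- -((-x[!pos] + 1)^(2 - lambda) - 1) / (2 - lambda)
  } else {
    y[!pos] <- -log1p(-x[!pos])
  }
  y
}

# Profile Gaussian log-likelihood of the transformed sample; the Jacobian
# term is (lambda - 1) * sum(sign(x) * log(|x| + 1)).
yj_loglik <- function(x, lambda) {
  y <- yj_apply(x, lambda)
  n <- length(x)
  s2 <- stats::var(y) * (n - 1) / n
  if (!is.finite(s2) || s2 <= 0) return(-Inf)
  -n / 2 * log(s2) + (lambda - 1) * sum(sign(x) * log(abs(x) + 1))
}

fit_yj_lambda <- function(x, lower = -5, upper = 5, tol = 1e-6) {
  if (stats::var(x) < .Machine$double.eps) return(1)
  stats::optimize(function(l) yj_loglik(x, l), c(lower, upper),
                  maximum = TRUE, tol = tol)$maximum
}

#' Min-max normalization to [0, 1]
#'
#' @param x Numeric vector with \code{max(x) > min(x)}.
#' @param name Variable name used in the degenerate-input error message.
#' @return \code{(x - min) / (max - min)}.
#' @export
minmax_scale <- function(x, name = deparse(substitute(x))) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  r <- range(x)
  if (r[1] == r[2]) {
    stop("cannot min-max scale constant variable '", name, "'")
  }
  (x - r[1]) / (r[2] - r[1])
}

#' Transform and scale a feature matrix for clustering
#'
#' Applies the Yeo-Johnson transformation column-wise (lambda fitted per
#' column on all rows pooled) followed by min-max scaling to [0, 1] --
#' the normalization pipeline preceding every distance computation.
#'
#' @param m Numeric matrix (observations x variables), no missing values.
#' @param yj Logical; apply the Yeo-Johnson step (default TRUE).
#' @return Matrix of the same shape with values in [0, 1]; fitted lambdas
#'   attached as attribute \code{"lambda"}.
#' @export
normalize_features <- function(m, yj = TRUE) {
  m <- as.matrix(m)
  stopifnot(!anyNA(m))
  lambdas <- rep(NA_real_, ncol(m))
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    if (yj) {
      tr <- yeo_johnson(x)
      x <- tr$y
      lambdas[j] <- tr$spec$lambda
    }
    m[, j] <- minmax_scale(x, name = colnames(m)[j] %||% as.character(j))
  }
  attr(m, "lambda") <- lambdas
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pairwise Euclidean distances along rows or columns
#'
#' @param m Numeric matrix with no missing values.
#' @param axis \code{"rows"} (observations; default) or \code{"columns"}
#'   (items/variables).
#' @return A \code{dist} object with labels from the corresponding dimnames.
#' @export
euclidean_distances <- function(m, axis = c("rows", "columns")) {
  axis <- match.arg(axis)
  m <- as.matrix(m)
  if (anyNA(m)) stop("distance computation requires complete data; impute first")
  if (axis == "columns") m <- t(m)
  stats::dist(m, method = "euclidean")
}

#' Impute missing diet responses by chained equations with predictive
#' mean matching
#'
#' Fills missing cells in the times/day diet-coefficient columns using
#' chained-equations regression imputation with predictive mean matching
#' (PMM): per incomplete column, a linear model on the remaining diet
#' columns predicts the missing entries, and each is replaced by the
#' observed value of one of the \code{donors} nearest observed predictions.
#' Because donors are observed responses, every imputed value lies in the
#' legal times/day codomain. \code{n_imputations} independent chains are
#' run and pooled by the modal imputed value per cell (ties resolved
#' toward the smaller coefficient). Observed cells are never altered.
#'
#' @param cohort Cohort data.frame with \code{freq_} diet columns (run
#'   \code{score_cohort()} first); missingness is expected only there.
#' @param n_imputations Number of chains pooled (default 5).
#' @param seed Integer seed controlling the chains.
#' @param n_cycles Chained-equation sweeps per chain (default 5).
#' @param donors Donor-pool size for PMM (default 5).
#' @return The cohort with all \code{freq_} cells filled (and the diet
#'   indices recomputed).
#' @export
impute_missing <- function(cohort, n_imputations = 5, seed = 1,
                           n_cycles = 5, donors = 5) {
  fcols <- paste0("freq_", qeb_items())
  stopifnot(all(fcols %in% names(cohort)))
  m <- as.matrix(cohort[, fcols])
  miss <- is.na(m)
  if (!any(miss)) return(cohort)
  if (any(colSums(!miss) < 2)) {
    stop("column(s) with fewer than 2 observed values cannot be imputed: ",
         paste(fcols[colSums(!miss) < 2], collapse = ", "))
  }
  chains <- array(NA_real_, c(sum(miss), n_imputations))
  for (ch in seq_len(n_imputations)) {
    set.seed(seed + 104729L * ch)
    chains[, ch] <- pmm_chain(m, miss, n_cycles, donors)
  }
  pooled <- apply(chains, 1, function(v) {
    tb <- table(v)
    as.numeric(names(tb)[which.max(tb)])  # which.max: first = smallest value
  })
  m[miss] <- pooled
  cohort[, fcols] <- m
  hcols <- paste0("freq_", qeb_items("healthy"))
  ucols <- paste0("freq_", qeb_items("unhealthy"))
  cohort$hdi8_healthy <- pmin(100 * rowSums(cohort[, hcols]) / 16, 100)
  cohort$hdi8_unhealthy <- pmin(100 * rowSums(cohort[, ucols]) / 16, 100)
  cohort$hdi8_healthy_category <- hdi8_category(cohort$hdi8_healthy)
  cohort$hdi8_unhealthy_category <- hdi8_category(cohort$hdi8_unhealthy)
  cohort
}

# One chained-equations PMM pass; returns imputed values for the TRUE
# entries of `miss` in column-major order.
pmm_chain <- function(m, miss, n_cycles, donors) {
  filled <- m
  for (j in which(colSums(miss) > 0)) {
    obs <- m[!miss[, j], j]
    filled[miss[, j], j] <- sample(obs, sum(miss[, j]), replace = TRUE)
  }
  for (cycle in seq_len(n_cycles)) {
    for (j in which(colSums(miss) > 0)) {
      yobs <- m[!miss[, j], j]
      X <- filled[, -j, drop = FALSE]
      fit <- stats::lm.fit(cbind(1, X[!miss[, j], , drop = FALSE]), yobs)
      beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
      pred_obs <- drop(cbind(1, X[!miss[, j], , drop = FALSE]) %*% beta)
      pred_mis <- drop(cbind(1, X[miss[, j], , drop = FALSE]) %*% beta)
      imp <- vapply(pred_mis, function(p) {
        nn <- order(abs(pred_obs - p))[seq_len(min(donors, length(pred_obs)))]
        yobs[nn[sample.int(length(nn), 1L)]]
      }, numeric(1))
      filled[miss[, j], j] <- imp
    }
  }
  filled[miss]
}

#' @export
print.transform_spec <- function(x, ...) {
  cat("Yeo-Johnson transform: lambda =", format(x$lambda),
      if (x$fitted) "(fitted by maximum likelihood)" else "(fixed)", "\n")
  invisible(x)
}
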