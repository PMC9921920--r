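#' Scored feature blocks of a cohort
#'
#' Extracts the numeric feature matrices the clustering stages operate
#' on: the 12 weekly-minute activity columns and the 16 times/day diet
#' coefficient columns (cohort must be scored and imputed).
#'
#' @param cohort Scored cohort data.frame.
#' @return List with matrices \code{pa}, \code{diet} and \code{all}
#'   (participants x items, item names as column names).
#' @export
cohort_features <- function(cohort) {
  pa_cols <- paste0("pa_", ipaq_items()$item)
  f_cols <- paste0("freq_", qeb_items())
  stopifnot(all(c(pa_cols, f_cols) %in% names(cohort)))
  pa <- as.matrix(cohort[, pa_cols])
  colnames(pa) <- ipaq_items()$item
  diet <- as.matrix(cohort[, f_cols])
  colnames(diet) <- qeb_items()
  rownames(pa) <- rownames(diet) <- cohort$participant_id
  list(pa = pa, diet = diet, all = cbind(pa, diet))
}

# Yeo-Johnson (fitted on both sexes pooled) then per-sex min-max scaling;
# returns the per-sex normalized matrices for one feature block.
normalized_by_sex <- function(cohort, block = c("all", "pa", "diet")) {
  block <- match.arg(block)
  feats <- cohort_features(cohort)[[block]]
  for (j in seq_len(ncol(feats))) {
    feats[, j] <- yeo_johnson(feats[, j])$y
  }
  lapply(split(seq_len(nrow(feats)), cohort$sex), function(idx) {
    m <- feats[idx, , drop = FALSE]
    for (j in seq_len(ncol(m))) {
      m[, j] <- minmax_scale(m[, j], name = colnames(m)[j])
    }
    m
  })
}

#' Per-sex item-distance matrices
#'
#' The pipeline's canonical item-tree input: features are Yeo-Johnson
#' transformed (lambda fitted on the pooled sexes), min-max scaled within
#' sex, and Euclidean distances computed between items (columns).
#'
#' @param cohort Scored, imputed cohort.
#' @param block \code{"all"} (default), \code{"pa"} or \code{"diet"}.
#' @return List of \code{dist} objects, one per sex.
#' @export
item_distance_matrices <- function(cohort, block = "all") {
  lapply(normalized_by_sex(cohort, block),
         function(m) euclidean_distances(m, "columns"))
}

#' Realized between-sex item congruence of a cohort
#'
#' Mantel correlation (statistic only) between the male and female
#' item-distance matrices, averaged over the requested feature blocks --
#' the quantity the synthetic generator's \code{item_congruence_rho} is
#' calibrated against. Blocks are assessed separately (matching the
#' per-behavior item trees of the analysis) because the activity and
#' diet blocks have different marginal scales.
#'
#' @param cohort Scored, imputed cohort with both sexes.
#' @param blocks Feature blocks (default activity and diet).
#' @return Mean Pearson correlation of the lower triangles across blocks.
#' @export
item_congruence <- function(cohort, blocks = c("pa", "diet")) {
  rs <- vapply(blocks, function(b) {
    d <- item_distance_matrices(cohort, b)
    stopifnot(all(c("male", "female") %in% names(d)))
    stats::cor(as.vector(d$male), as.vector(d$female))
  }, numeric(1))
  mean(rs)
}

#' Run the full congruence analysis
#'
#' Executes the end-to-end procedure on a cohort (or generates one from
#' \code{spec}): scoring, imputation, normalization, per-sex item and
#' participant Ward trees, tanglegrams with congruence statistics
#' (male-vs-female for the activity and diet item trees; activity-vs-diet
#' participant trees within each sex), two-way clusterings, k-means
#' subgrouping on the two diet-quality indices with silhouette/elbow
#' model selection, ANOVA (+ Tukey HSD) of BMI, body-fat percentage and
#' fat mass index across subgroups, and the self-report agreement
#' regression on the measured subset.
#'
#' @param spec A \code{cohort_spec} used when \code{cohort} is NULL.
#' @param cohort Optional cohort data.frame (raw; scored internally).
#' @param k_range Candidate subgroup counts (default 2:6).
#' @param L Entanglement norm exponent (default 1.5).
#' @param n_perm_mantel,n_perm_fmi Permutation counts (defaults 9999 and
#'   1999).
#' @param untangle_method,restarts Passed to \code{untangle()}.
#' @param fmi_k Fowlkes-Mallows cut level; \code{NULL} (default) uses the
#'   smaller of the two sexes' recommended participant k for the block.
#' @param seed Root seed; every randomized stage consumes an independent
#'   child seed derived from it.
#' @param output_dir Optional directory; when given, reports (JSON),
#'   trees (Newick), tanglegram layouts (CSV/SVG), the cohort (CSV) and a
#'   manifest are written there.
#' @return Object of class \code{copatterns_run}.
#' @export
run_pipeline <- function(spec = cohort_spec(), cohort = NULL,
                         k_range = 2:6, L = 1.5,
                         n_perm_mantel = 9999, n_perm_fmi = 1999,
                         untangle_method = "step2side", restarts = 20,
                         fmi_k = NULL, seed = spec$seed,
                         output_dir = NULL) {
  child <- function(i) (seed * 48271L + i * 2147483L) %% 2101234567L
  if (is.null(cohort)) {
    cohort <- generate_cohort(spec)
    cohort <- generate_selfreport_pairs(
      cohort, shift = 0, sd = spec$selfreport_sd, seed = child(1))
  }
  cohort <- score_cohort(cohort)
  cohort <- impute_missing(cohort, seed = child(2))

  sexes <- c("male", "female")
  stopifnot(all(sexes %in% cohort$sex))

  # item trees per sex and block
  item_d <- list(pa = item_distance_matrices(cohort, "pa"),
                 diet = item_distance_matrices(cohort, "diet"))
  item_tree <- lapply(item_d, function(ds) lapply(ds, ward_linkage))

  # participant trees per sex and block
  norm_pa <- normalized_by_sex(cohort, "pa")
  norm_diet <- normalized_by_sex(cohort, "diet")
  part_d <- list(pa = lapply(norm_pa, euclidean_distances, axis = "rows"),
                 diet = lapply(norm_diet, euclidean_distances, axis = "rows"))
  part_tree <- lapply(part_d, function(ds) lapply(ds, ward_linkage))

  # FMI level: recommended participant k per block (smaller of the sexes)
  pick_k <- function(mats, s0) {
    ks <- vapply(seq_along(mats), function(i) {
      choose_k(mats[[i]], k_range = k_range, seed = child(s0 + i))$k
    }, integer(1))
    min(ks)
  }
  k_pa <- if (is.null(fmi_k)) pick_k(norm_pa, 10) else fmi_k
  k_diet <- if (is.null(fmi_k)) pick_k(norm_diet, 20) else fmi_k

  congr <- list(
    pa_sexes = congruence_report(
      item_tree$pa$male, item_tree$pa$female,
      item_d$pa$male, item_d$pa$female,
      k = min(k_pa, nrow(item_tree$pa$male$merge)), L = L,
      n_perm_mantel = n_perm_mantel, n_perm_fmi = n_perm_fmi,
      untangle_method = untangle_method, restarts = restarts,
      seed = child(31)),
    diet_sexes = congruence_report(
      item_tree$diet$male, item_tree$diet$female,
      item_d$diet$male, item_d$diet$female,
      k = min(k_diet, nrow(item_tree$diet$male$merge)), L = L,
      n_perm_mantel = n_perm_mantel, n_perm_fmi = n_perm_fmi,
      untangle_method = untangle_method, restarts = restarts,
      seed = child(32))
  )
  for (s in sexes) {
    congr[[paste0("pa_diet_", s)]] <- congruence_report(
      part_tree$pa[[s]], part_tree$diet[[s]],
      part_d$pa[[s]], part_d$diet[[s]],
      k = if (s == "male") min(k_pa, k_diet) else min(k_pa, k_diet),
      L = L, n_perm_mantel = n_perm_mantel, n_perm_fmi = n_perm_fmi,
      untangle_method = untangle_method, restarts = restarts,
      seed = child(if (s == "male") 33 else 34))
  }

  two_way <- list(
    pa = lapply(norm_pa, two_way_cluster, scale = FALSE),
    diet = lapply(norm_diet, two_way_cluster, scale = FALSE)
  )

  # subgroups on the two diet-quality indices, then body-composition ANOVA
  subgroups <- list()
  for (s in sexes) {
    rows <- cohort$sex == s
    idx <- scale(cbind(healthy = cohort$hdi8_healthy[rows],
                       unhealthy = cohort$hdi8_unhealthy[rows]))
    ck <- choose_k(idx, k_range = k_range,
                   seed = child(if (s == "male") 41 else 42))
    sol <- kmeans_cluster(idx, ck$k,
                          seed = child(if (s == "male") 43 else 44))
    outcomes <- list(bmi = cohort$bmi[rows], bfp = cohort$bfp_percent[rows],
                     fmi = cohort$fmi[rows])
    anv <- lapply(outcomes, one_way_anova, group_labels = sol$labels)
    tk <- if (sol$k >= 3) lapply(anv, tukey_hsd) else NULL
    subgroups[[s]] <- list(choice = ck, solution = sol, anova = anv,
                           tukey = tk)
  }

  # self-report agreement on the measured subset, per sex
  agreement <- list()
  for (s in sexes) {
    sub <- cohort[cohort$sex == s & cohort$measured_flag, ]
    agreement[[s]] <- if (nrow(sub) >= 3) {
      agreement_regression(
        bfp = c(sub$bfp_percent, sub$measured_bfp_percent),
        weight = c(sub$weight_kg, sub$measured_weight_kg),
        source_labels = rep(c("self_report", "measured"), each = nrow(sub)))
    } else NULL
  }

  feats <- cohort_features(cohort)$all
  yj_lambda <- vapply(seq_len(ncol(feats)), function(j)
    yeo_johnson(feats[, j])$spec$lambda, numeric(1))
  names(yj_lambda) <- colnames(feats)

  run <- structure(list(
    cohort = cohort,
    descriptives = descriptive_table(cohort),
    yj_lambda = yj_lambda,
    item_trees = item_tree, item_distances = item_d,
    participant_trees = part_tree, participant_distances = part_d,
    congruence = congr, two_way = two_way,
    subgroups = subgroups, agreement = agreement,
    settings = list(k_range = k_range, L = L,
                    n_perm_mantel = n_perm_mantel, n_perm_fmi = n_perm_fmi,
                    untangle_method = untangle_method, restarts = restarts,
                    seed = seed, k_pa = k_pa, k_diet = k_diet)
  ), class = "copatterns_run")
  if (!is.null(output_dir)) write_run(run, output_dir)
  run
}

# serialize the run directory: JSON reports, Newick trees, tanglegram
# layouts, cohort CSV and a manifest with seeds and a config hash
write_run <- function(run, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  jw <- function(x, file) jsonlite::write_json(
    x, file.path(output_dir, file), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, force = TRUE)

  for (nm in names(run$congruence)) {
    rp <- run$congruence[[nm]]
    jw(list(mantel_r = rp$mantel_r, mantel_p = rp$mantel_p,
            cophenetic_c = as.list(rp$cophenetic_c),
            bakers_gamma = rp$bakers_gamma,
            fmi_k = rp$fmi_k, fmi_bk = rp$fmi_bk, fmi_p = rp$fmi_p,
            entanglement_before = rp$entanglement_before,
            entanglement_after = rp$entanglement_after),
       paste0("congruence_", nm, ".json"))
    write_tanglegram_csv(rp$tanglegram,
                         file.path(output_dir,
                                   paste0("tanglegram_", nm, ".csv")))
    write_tanglegram_svg(rp$tanglegram,
                         file.path(output_dir,
                                   paste0("tanglegram_", nm, ".svg")))
  }
  for (blk in names(run$item_trees)) {
    for (s in names(run$item_trees[[blk]])) {
      write_newick(run$item_trees[[blk]][[s]],
                   file.path(output_dir,
                             paste0("items_", blk, "_", s, ".nwk")))
      write_newick(run$participant_trees[[blk]][[s]],
                   file.path(output_dir,
                             paste0("participants_", blk, "_", s, ".nwk")))
      utils::write.csv(run$two_way[[blk]][[s]]$scaled_matrix,
                       file.path(output_dir,
                                 paste0("heatmap_", blk, "_", s, ".csv")))
    }
  }
  for (s in names(run$subgroups)) {
    sg <- run$subgroups[[s]]
    jw(list(k = sg$solution$k,
            silhouette_curve = as.list(sg$choice$silhouette_curve),
            wss_curve = as.list(sg$choice$wss_curve),
            labels = sg$solution$labels,
            anova = lapply(sg$anova, function(a)
              list(F = a$F, p = a$p, group_means = as.list(a$group_means),
                   group_sds = as.list(a$group_sds))),
            tukey = lapply(sg$tukey, function(tk)
              if (is.null(tk)) NULL else
                stats::setNames(as.list(tk$p_adj), tk$pair))),
       paste0("subgroups_", s, ".json"))
  }
  jw(lapply(run$agreement, function(a) if (is.null(a)) NULL else
    list(intercept_diff_p = a$intercept_diff_p,
         slope_diff_p = a$slope_diff_p)), "agreement.json")
  write_cohort_csv(run$cohort, file.path(output_dir, "cohort.csv"))
  utils::write.csv(run$descriptives,
                   file.path(output_dir, "descriptives.csv"),
                   row.names = FALSE)
  jw(scoring_reference(), "scoring_reference.json")
  for (blk in names(run$item_distances)) {
    for (s in names(run$item_distances[[blk]])) {
      write_distance_csv(run$item_distances[[blk]][[s]],
                         file.path(output_dir,
                                   paste0("item_distances_", blk, "_", s,
                                          ".csv")))
    }
  }

  cfg <- file.path(output_dir, "config.json")
  jw(c(run$settings, list(yj_lambda = as.list(run$yj_lambda))),
     "config.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("copatterns")),
    seed = run$settings$seed,
    config_hash = unname(tools::md5sum(cfg)),
    n_participants = nrow(run$cohort)
  )
  jw(manifest, "manifest.json")
  invisible(output_dir)
}

#' @export
print.copatterns_run <- function(x, ...) {
  cat("Lifestyle-pattern congruence run:", nrow(x$cohort),
      "participants\n\n")
  for (nm in names(x$congruence)) {
    cat("--", nm, "--\n")
    print(x$congruence[[nm]])
  }
  for (s in names(x$subgroups)) {
    sg <- x$subgroups[[s]]
    cat(sprintf("\n%s subgroups (k = %d):\n", s, sg$solution$k))
    for (o in names(sg$anova)) {
      cat(sprintf("  %s: F = %.2f, p = %.3f\n", o, sg$anova[[o]]$F,
                  sg$anova[[o]]$p))
    }
  }
  invisible(x)
}
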