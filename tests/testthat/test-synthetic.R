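test_that("generated cohorts honor the dimension contract", {
  co <- generate_cohort(cohort_spec(n_male = 52, n_female = 55,
                                    k_clusters = 3, seed = 7))
  expect_equal(nrow(co), 107)
  expect_equal(sum(co$sex == "male"), 52)
  expect_equal(sum(startsWith(names(co), "pa_")), 12)
  expect_equal(sum(startsWith(names(co), "qeb_")), 16)
  pa <- as.matrix(co[, startsWith(names(co), "pa_")])
  expect_true(all(pa >= 0))
  vocab <- names(qeb_frequency_table())
  qeb <- as.matrix(co[, startsWith(names(co), "qeb_")])
  expect_true(all(is.na(qeb) | qeb %in% vocab))
  expect_true(all(co$height_cm > 0 & co$weight_kg > 0))
})

test_that("identical spec and seed give an identical cohort", {
  sp <- cohort_spec(seed = 42)
  expect_identical(generate_cohort(sp), generate_cohort(sp))
  sp2 <- cohort_spec(seed = 43)
  expect_false(identical(generate_cohort(sp), generate_cohort(sp2)))
})

test_that("spec invariants are enforced", {
  expect_error(cohort_spec(n_male = 30, k_clusters = 3), "15")
  expect_error(cohort_spec(item_congruence_rho = 1.2), "0, 1")
  expect_error(cohort_spec(missing_rate = 1), "missing_rate")
})

test_that("MCAR removal hits only diet cells at the binomial rate", {
  co <- generate_cohort(cohort_spec(seed = 3, missing_rate = 0))
  expect_identical(apply_mcar(co, 0, seed = 1), co)

  out <- apply_mcar(co, 0.1, seed = 9)
  qcols <- paste0("qeb_", qeb_items())
  n_cells <- nrow(co) * length(qcols)
  n_miss <- sum(is.na(out[, qcols]))
  expect_lt(abs(n_miss - 0.1 * n_cells), 3 * sqrt(n_cells * 0.1 * 0.9))
  # non-diet columns untouched
  other <- setdiff(names(co), qcols)
  expect_identical(out[, other], co[, other])
})

test_that("missingness is independent of the underlying responses", {
  # point-biserial correlation between the missingness indicator and the
  # (pre-deletion) coefficient values, averaged over replicate deletions
  co <- score_cohort(generate_cohort(cohort_spec(seed = 4, missing_rate = 0)))
  truth <- as.matrix(co[, paste0("freq_", qeb_items())])
  rs <- vapply(1:40, function(s) {
    del <- apply_mcar(co, 0.15, seed = 100 + s)
    miss <- is.na(as.matrix(del[, paste0("qeb_", qeb_items())]))
    cor(as.vector(miss), as.vector(truth))
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("the measured validation subset matches the study design", {
  co <- generate_cohort(cohort_spec(seed = 5, missing_rate = 0))
  out <- generate_selfreport_pairs(co, fraction = 19 / 107, seed = 2)
  expect_equal(sum(out$measured_flag), 19)
  exact <- generate_selfreport_pairs(co, shift = 0, sd = 0, seed = 2)
  m <- exact$measured_flag
  expect_equal(exact$measured_bfp_percent[m], exact$bfp_percent[m])
  expect_equal(exact$measured_weight_kg[m], exact$weight_kg[m])
  expect_true(all(is.na(exact$measured_bfp_percent[!m])))
})

test_that("the planted diet effect shows in body fat", {
  # a positive diet effect implies higher body fat in the
  # unhealthy-leaning class 1 than in class k
  sp <- cohort_spec(diet_effect = 0.8, seed = 11, missing_rate = 0)
  co <- generate_cohort(sp)
  f <- co$sex == "female"
  expect_gt(mean(co$bfp_percent[f & co$latent_class == 1]),
            mean(co$bfp_percent[f & co$latent_class == 3]))
})

test_that("a cohort spec round-trips through a key-value config file", {
  p <- tempfile(fileext = ".cfg")
  writeLines(c("# synthetic cohort", "n_male: 45", "n_female = 46",
               "k_clusters: 3", "item_congruence_rho: 0.4", "seed: 9"), p)
  sp <- read_cohort_spec(p)
  expect_equal(sp$n_male, 45L)
  expect_equal(sp$n_female, 46L)
  expect_equal(sp$item_congruence_rho, 0.4)
  expect_equal(sp$seed, 9L)
  writeLines("n_males: 45", p)
  expect_error(read_cohort_spec(p), "n_males")
})
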