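test_that("entanglement is 0 for aligned orders, 1 for full reversal", {
  t1 <- make_tree(6, seed = 101)
  tg <- tanglegram(t1, t1)
  expect_equal(tg$entanglement, 0)

  # full reversal of one side via the normalization definition
  eo <- copatterns:::entanglement_of_orders
  labs <- paste0("L", 1:6)
  expect_equal(eo(labs, rev(labs), 1.5), 1)
  expect_equal(eo(labs, labs, 1.5), 0)
  # 4-leaf hand example at L = 1: displacements 0,1,1,0 -> 2/8
  expect_equal(eo(c("a", "b", "c", "d"), c("a", "c", "b", "d"), 1), 0.25)
})

test_that("tanglegram construction demands matching label sets", {
  t1 <- make_tree(5, seed = 102)
  t2 <- make_tree(5, seed = 103)
  t2$labels <- paste0("X", 1:5)
  expect_error(tanglegram(t1, t2), "X1")
  expect_error(tanglegram(t1, t2), "L1")
})

test_that("untangling never increases entanglement, for every method", {
  for (s in 1:5) {
    t1 <- make_tree(8, seed = 200 + s)
    t2 <- make_tree(8, seed = 300 + s)
    tg <- tanglegram(t1, t2)
    for (meth in c("step1side", "step2side", "random")) {
      out <- untangle(tg, method = meth, seed = s)
      expect_lte(out$entanglement, tg$entanglement)
      expect_equal(out$entanglement, entanglement(out))  # state consistent
    }
  }
  # an already perfectly aligned tanglegram stays at zero
  t1 <- make_tree(6, seed = 104)
  tg0 <- untangle(tanglegram(t1, t1), seed = 1)
  expect_equal(tg0$entanglement, 0)
})

test_that("two-sided search reaches the exhaustive optimum on scrambled copies", {
  for (s in 1:3) {
    t1 <- make_tree(6, seed = 400 + s)
    tg <- tanglegram(t1, t1)
    set.seed(s)
    tg$left_flips <- sample(c(TRUE, FALSE), 5, replace = TRUE)
    tg$right_flips <- sample(c(TRUE, FALSE), 5, replace = TRUE)
    tg$entanglement <- entanglement(tg)
    out <- untangle(tg, method = "step2side", restarts = 20, seed = s)
    expect_equal(out$entanglement, 0)  # identical trees can always align
  }
})

test_that("the Mantel statistic is a correlation of lower triangles", {
  d1 <- euclidean_distances(make_points(8, seed = 105))
  expect_equal(mantel_test(d1, d1, n_perm = 99)$r, 1)
  expect_equal(mantel_test(d1, 2 * d1, n_perm = 99)$r, 1)  # scale invariant

  d2 <- euclidean_distances(make_points(8, seed = 106))
  mt <- mantel_test(d1, d2, n_perm = 199, seed = 5)
  lt <- lower.tri(as.matrix(d1))
  expect_equal(mt$r, cor(as.matrix(d1)[lt], as.matrix(d2)[lt]))
  expect_true(mt$p > 0 && mt$p <= 1)
  # bit-for-bit reproducible given the seed
  expect_identical(mt, mantel_test(d1, d2, n_perm = 199, seed = 5))

  const <- as.dist(matrix(1, 4, 4) - diag(4))
  expect_error(mantel_test(const, const, 9), "constant")
})

test_that("the Mantel statistic agrees with an independent implementation", {
  skip_if_not_installed("vegan")
  d1 <- euclidean_distances(make_points(10, seed = 107))
  d2 <- euclidean_distances(make_points(10, seed = 108))
  expect_equal(mantel_test(d1, d2, n_perm = 9)$r,
               unname(vegan::mantel(d1, d2, permutations = 9)$statistic),
               tolerance = 1e-12)
})

test_that("cophenetic correlation is exact on ultrametric input", {
  base <- make_tree(7, seed = 109)
  d_ultra <- cophenetic_matrix(base)
  t_avg <- hclust(d_ultra, method = "average")  # reproduces an ultrametric
  expect_equal(cophenetic_correlation(d_ultra, t_avg), 1)

  pts <- make_points(10, seed = 110)
  d <- euclidean_distances(pts)
  tree <- ward_linkage(d)
  cm <- brute_cophenetic(tree)
  lt <- lower.tri(cm)
  expect_equal(cophenetic_correlation(d, tree),
               cor(as.matrix(d)[lt], cm[lt]), tolerance = 1e-12)
  expect_true(abs(cophenetic_correlation(d, tree)) <= 1)
})

test_that("Baker's Gamma matches the pairwise-level oracle", {
  t1 <- make_tree(8, seed = 111)
  expect_equal(bakers_gamma(t1, t1), 1)

  t2 <- make_tree(8, seed = 112)
  expect_equal(bakers_gamma(t1, t2), brute_bakers_gamma(t1, t2),
               tolerance = 1e-12)

  # invariant under a relabeling-preserving rebuild (branch rotations)
  pts <- make_points(8, seed = 113)
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  t_a <- ward_linkage(euclidean_distances(pts))
  t_b <- ward_linkage(euclidean_distances(pts[perm, ]))
  expect_equal(bakers_gamma(t_a, t_b), 1, tolerance = 1e-12)

  t3 <- make_tree(9, seed = 114)
  expect_error(bakers_gamma(t1, t3), "differ")
})

test_that("the Fowlkes-Mallows index matches explicit pair counting", {
  t1 <- make_tree(10, seed = 115)
  fm_same <- fowlkes_mallows(t1, t1, k = 3, n_perm = 99, seed = 1)
  expect_equal(fm_same$bk, 1)

  t2 <- make_tree(10, seed = 116)
  fm <- fowlkes_mallows(t1, t2, k = 3, n_perm = 199, seed = 2)
  c1 <- cut_tree(t1, 3)
  c2 <- cut_tree(t2, 3)[names(c1)]
  expect_equal(fm$bk, brute_bk(c1, c2), tolerance = 1e-12)
  expect_true(fm$e_bk_null >= 0 && fm$e_bk_null <= 1)
  expect_identical(fm, fowlkes_mallows(t1, t2, k = 3, n_perm = 199, seed = 2))
  expect_error(fowlkes_mallows(t1, t2, k = 1), "k must")
})

test_that("tanglegram layout is complete, aligned when sorted, and pure", {
  t1 <- make_tree(7, seed = 117)
  t2 <- make_tree(7, seed = 118)
  tg <- tanglegram(t1, t2)
  lay <- tanglegram_layout(tg)
  expect_equal(nrow(lay$connectors), 7)
  expect_identical(lay, tanglegram_layout(tg))  # pure

  tg_same <- tanglegram(t1, t1)
  lay_same <- tanglegram_layout(tg_same)
  expect_equal(lay_same$connectors$y_left, lay_same$connectors$y_right)
})

test_that("congruence reports bundle consistent statistics", {
  pts1 <- make_points(12, seed = 119)
  pts2 <- 0.8 * pts1 + 0.2 * make_points(12, seed = 120)
  d1 <- euclidean_distances(pts1)
  d2 <- euclidean_distances(pts2)
  rp <- congruence_report(ward_linkage(d1), ward_linkage(d2), d1, d2,
                          k = 3, n_perm_mantel = 199, n_perm_fmi = 199,
                          seed = 3)
  expect_lte(rp$entanglement_after, rp$entanglement_before)
  expect_true(abs(rp$mantel_r) <= 1 && abs(rp$bakers_gamma) <= 1)
  expect_true(rp$fmi_bk >= 0 && rp$fmi_bk <= 1)
  expect_gt(rp$mantel_r, 0.5)  # strongly related clouds
})
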