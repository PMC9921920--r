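test_that("Ward linkage handles the base cases of the distance dialect", {
  d <- dist(c(a = 0, b = 3))
  t2 <- ward_linkage(d)
  expect_equal(t2$height, 3)  # two leaves merge at their distance

  same <- ward_linkage(dist(rep(1, 5)))
  expect_equal(same$height, rep(0, 4))
  expect_error(ward_linkage(dist(1)), "2")
})

test_that("Ward merges match exhaustive objective-recomputing agglomeration", {
  for (s in 1:12) {
    n <- sample(4:8, 1)
    pts <- make_points(n, p = 2, seed = 400 + s)
    tree <- ward_linkage(euclidean_distances(pts))
    oracle <- brute_ward(pts)
    got <- hclust_steps(tree)
    for (step in seq_len(n - 1)) {
      expect_equal(got[[step]]$leaves, oracle[[step]]$leaves,
                   info = paste("seed", 400 + s, "step", step))
      expect_equal(got[[step]]$height, oracle[[step]]$height,
                   tolerance = 1e-10)
    }
  }
})

test_that("Ward heights are monotone nondecreasing", {
  for (s in 1:8) {
    tree <- make_tree(12, seed = 500 + s)
    expect_true(all(diff(tree$height) >= -1e-12))
  }
})

test_that("cophenetic distances read off the merge heights and are ultrametric", {
  d <- dist(c(A = 0, B = 2))
  cm <- as.matrix(cophenetic_matrix(ward_linkage(d)))
  expect_equal(unname(cm), rbind(c(0, 2), c(2, 0)))

  for (s in 1:6) {
    tree <- make_tree(6, seed = 600 + s)
    cm <- as.matrix(cophenetic_matrix(tree))
    expect_equal(unname(cm), unname(brute_cophenetic(tree)),
                 tolerance = 1e-12)
    for (i in 1:6) for (j in 1:6) for (k in 1:6) {
      expect_lte(cm[i, j], max(cm[i, k], cm[j, k]) + 1e-12)
    }
  }
})

test_that("tree cutting removes the highest merges and nests across k", {
  tree <- make_tree(9, seed = 42)
  expect_equal(unname(cut_tree(tree, 1)), rep(1L, 9))
  expect_equal(sort(unname(cut_tree(tree, 9))), 1:9)

  # k = 3 equals brute-force removal of the two highest merges
  steps <- hclust_steps(tree)
  kept <- steps[1:6]  # drop the 2 highest of 8 merges
  memb <- as.list(1:9)
  for (st in kept) {
    grp <- unique(unlist(memb[st$leaves]))
    for (l in st$leaves) memb[[l]] <- grp
  }
  brute <- vapply(memb, min, numeric(1))
  got <- unname(cut_tree(tree, 3))
  expect_equal(length(unique(got)), 3)
  # same partition up to label names
  expect_equal(unname(split(1:9, got)[order(vapply(split(1:9, got), min, 1))]),
               unname(split(1:9, brute)[order(vapply(split(1:9, brute), min, 1))]))

  # hierarchy nesting: k-partition refines the (k-1)-partition
  for (k in 3:8) {
    ck <- cut_tree(tree, k)
    ck1 <- cut_tree(tree, k - 1)
    expect_true(all(tapply(ck1, ck, function(v) length(unique(v))) == 1))
  }
  expect_error(cut_tree(tree, 10), "\\[1, 9\\]")
})

test_that("k-means recovers planted well-separated clusters", {
  expect_equal(kmeans_cluster(matrix(1, 5, 2), 1, seed = 1)$inertia, 0)

  set.seed(7)
  centers <- rbind(c(0, 0), c(16, 0), c(0, 16))  # 8 within-SD separation
  m <- centers[rep(1:3, each = 30), ] + matrix(rnorm(180, sd = 2), 90, 2)
  truth <- rep(1:3, each = 30)
  sol <- kmeans_cluster(m, 3, seed = 2)
  tab <- table(sol$labels, truth)
  expect_equal(sum(apply(tab, 1, max)), 90)  # perfect agreement up to relabel

  i3 <- kmeans_cluster(m, 3, seed = 3)$inertia
  i4 <- kmeans_cluster(m, 4, seed = 3)$inertia
  expect_lte(i4, i3)
  expect_error(kmeans_cluster(m[1:2, ], 3), "k = 3")
})

test_that("silhouette model selection matches the per-point formula", {
  set.seed(8)
  m <- rbind(matrix(rnorm(10, 0, 0.3), 5, 2),
             matrix(rnorm(10, 6, 0.3), 5, 2))
  sol <- kmeans_cluster(m, 2, seed = 4)
  expect_equal(sol$silhouette, brute_silhouette(m, sol$labels),
               tolerance = 1e-12)

  ck <- choose_k(m, 2:5, seed = 5)
  expect_equal(ck$k, 2L)
  expect_true(all(diff(ck$wss_curve) <= 1e-8))
  expect_error(choose_k(m, integer(0)), "empty")
})

test_that("two-way clustering orders blocks contiguously and is permutation-stable", {
  expect_equal(two_way_cluster(matrix(1:4, 1))$row_order, 1)
  expect_equal(two_way_cluster(matrix(1:4, 4))$col_order, 1)

  set.seed(9)
  blockm <- rbind(matrix(rnorm(40, 0, 0.2), 4, 10),
                  matrix(rnorm(40, 5, 0.2), 4, 10))
  tw <- two_way_cluster(blockm)
  ro <- tw$row_order
  expect_true(all(diff(ro %in% 1:4) == 0) ||
                identical(sort(ro[1:4]), 1:4) || identical(sort(ro[5:8]), 1:4))

  perm <- c(3, 1, 4, 2, 7, 5, 8, 6)
  tw_p <- two_way_cluster(blockm[perm, ])
  part <- cutree(tw$row_tree, 2)
  part_p <- cutree(tw_p$row_tree, 2)[order(perm)]
  expect_true(all(tapply(part_p, part, function(v) length(unique(v))) == 1))
})
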