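# Independent brute-force oracles and small fixtures used across the suite.

make_points <- function(n, p = 3, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n * p), n, p)
  rownames(m) <- paste0("L", seq_len(n))
  m
}

make_tree <- function(n, seed = 1, p = 3) {
  ward_linkage(dist(make_points(n, p, seed)))
}

# Exhaustive Ward agglomeration recomputing the objective from raw points
# at each step: merge cost is the increase in within-cluster error sum of
# squares; heights on the distance scale (h^2 = 2 * delta ESS). Ties go to
# the lowest-index pair. Returns per-step leaf sets and heights.
brute_ward <- function(points) {
  n <- nrow(points)
  clusters <- as.list(seq_len(n))
  ess <- function(idx) {
    if (length(idx) == 1) return(0)
    sub <- points[idx, , drop = FALSE]
    sum(sweep(sub, 2, colMeans(sub))^2)
  }
  steps <- list()
  for (s in seq_len(n - 1)) {
    best <- NULL
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        d_ess <- ess(c(clusters[[i]], clusters[[j]])) -
          ess(clusters[[i]]) - ess(clusters[[j]])
        if (is.null(best) || d_ess < best$d - 1e-12) {
          best <- list(i = i, j = j, d = d_ess)
        }
      }
    }
    merged <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    steps[[s]] <- list(leaves = merged, height = sqrt(2 * best$d))
    clusters[[best$i]] <- merged
    clusters <- clusters[-best$j]
  }
  steps
}

# per-step leaf sets of an hclust merge matrix
hclust_steps <- function(tree) {
  members <- vector("list", nrow(tree$merge))
  lapply(seq_len(nrow(tree$merge)), function(s) {
    a <- tree$merge[s, 1]; b <- tree$merge[s, 2]
    ia <- if (a < 0) -a else members[[a]]
    ib <- if (b < 0) -b else members[[b]]
    members[[s]] <<- sort(c(ia, ib))
    list(leaves = members[[s]], height = tree$height[s])
  })
}

# cophenetic matrix by independent pairwise scan over merge steps
brute_cophenetic <- function(tree) {
  n <- nrow(tree$merge) + 1
  steps <- hclust_steps(tree)
  cm <- matrix(0, n, n)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      for (s in seq_along(steps)) {
        if (i %in% steps[[s]]$leaves && j %in% steps[[s]]$leaves) {
          cm[i, j] <- cm[j, i] <- steps[[s]]$height
          break
        }
      }
    }
  }
  dimnames(cm) <- list(tree$labels, tree$labels)
  cm
}

# pairwise first-co-clustering levels via a cutree scan (independent of
# the package's merge-traversal implementation)
brute_pair_levels <- function(tree) {
  n <- nrow(tree$merge) + 1
  lv <- matrix(0, n, n)
  for (k in n:1) {
    cl <- cutree(tree, k)
    hit <- outer(cl, cl, "==") & lv == 0
    lv[hit] <- k
  }
  diag(lv) <- 0
  lv
}

brute_bakers_gamma <- function(t1, t2) {
  l1 <- brute_pair_levels(t1)
  l2 <- brute_pair_levels(t2)
  lt <- lower.tri(l1)
  cor(l1[lt], l2[lt], method = "spearman")
}

# Fowlkes-Mallows Bk by explicit enumeration of all leaf pairs
brute_bk <- function(c1, c2) {
  n <- length(c1)
  t_both <- p1 <- p2 <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      s1 <- c1[i] == c1[j]
      s2 <- c2[i] == c2[j]
      if (s1 && s2) t_both <- t_both + 1
      if (s1) p1 <- p1 + 1
      if (s2) p2 <- p2 + 1
    }
  }
  t_both / sqrt(p1 * p2)
}

# mean silhouette width from the textbook per-point formula
brute_silhouette <- function(m, labels) {
  d <- as.matrix(dist(m))
  n <- nrow(m)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(g)
      mean(d[i, labels == g]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# exhaustive entanglement minimum over every rotation assignment of both
# trees (2^(n-1) x 2^(n-1) states)
brute_min_entanglement <- function(tg) {
  nl <- nrow(tg$left$merge)
  nr <- nrow(tg$right$merge)
  states <- function(k) {
    g <- expand.grid(rep(list(c(FALSE, TRUE)), k))
    lapply(seq_len(nrow(g)), function(i) as.logical(g[i, ]))
  }
  best <- Inf
  for (lf in states(nl)) {
    for (rf in states(nr)) {
      e <- copatterns:::flip_entanglement(tg, lf, rf)
      if (e < best) best <- e
    }
  }
  best
}

# small scored synthetic cohort for pipeline-level tests
small_cohort <- function(seed = 1, rho = 0.8, missing_rate = 0) {
  sp <- cohort_spec(item_congruence_rho = rho, missing_rate = missing_rate,
                    seed = seed)
  score_cohort(generate_cohort(sp))
}
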