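#' Tanglegram of two dendrograms over the same label set
#'
#' A tanglegram faces two trees built over the same labels and connects
#' matching leaves; its entanglement measures how crossed the connectors
#' are. Branch rotations (flipping the two children of an internal node)
#' change the leaf order without changing the tree, and are the search
#' space of \code{untangle()}.
#'
#' Leaf order is canonical before any rotation: at each merge the subtree
#' containing the smaller original leaf index goes left. Rotation states
#' are kept per internal node.
#'
#' @param left,right \code{hclust} trees with identical label sets.
#' @param L Entanglement norm exponent (default 1.5).
#' @return Object of class \code{tanglegram}.
#' @export
tanglegram <- function(left, right, L = 1.5) {
  stopifnot(inherits(left, "hclust"), inherits(right, "hclust"))
  ll <- tree_labels(left)
  rl <- tree_labels(right)
  if (!setequal(ll, rl)) {
    stop("label sets differ; only in left: ",
         paste(setdiff(ll, rl), collapse = ", "),
         "; only in right: ", paste(setdiff(rl, ll), collapse = ", "))
  }
  if (anyDuplicated(ll) || anyDuplicated(rl)) stop("duplicated leaf labels")
  tg <- structure(list(
    left = left, right = right,
    left_flips = rep(FALSE, nrow(left$merge)),
    right_flips = rep(FALSE, nrow(right$merge)),
    L = L
  ), class = "tanglegram")
  tg$entanglement <- entanglement(tg)
  tg
}

tree_labels <- function(tree) {
  tree$labels %||% as.character(seq_len(nrow(tree$merge) + 1))
}

# Leaf indices in display order for a given per-node flip state.
# Canonical (all flips FALSE): subtree with smaller minimum original
# index goes left.
leaf_order_indices <- function(tree, flips) {
  merge <- tree$merge
  n_merge <- nrow(merge)
  ords <- vector("list", n_merge)
  mins <- integer(n_merge)
  for (s in seq_len(n_merge)) {
    a <- merge[s, 1]; b <- merge[s, 2]
    ord_a <- if (a < 0) -a else ords[[a]]
    min_a <- if (a < 0) -a else mins[a]
    ord_b <- if (b < 0) -b else ords[[b]]
    min_b <- if (b < 0) -b else mins[b]
    if (min_b < min_a) {  # canonical order first
      tmp <- ord_a; ord_a <- ord_b; ord_b <- tmp
      tmpm <- min_a; min_a <- min_b; min_b <- tmpm
    }
    if (flips[s]) {
      ords[[s]] <- c(ord_b, ord_a)
    } else {
      ords[[s]] <- c(ord_a, ord_b)
    }
    mins[s] <- min(min_a, min_b)
  }
  ords[[n_merge]]
}

#' Current leaf orders of a tanglegram
#'
#' @param tg A \code{tanglegram}.
#' @return List with \code{left} and \code{right} label vectors in
#'   display order.
#' @export
leaf_orders <- function(tg) {
  stopifnot(inherits(tg, "tanglegram"))
  list(left = tree_labels(tg$left)[leaf_order_indices(tg$left, tg$left_flips)],
       right = tree_labels(tg$right)[leaf_order_indices(tg$right,
                                                        tg$right_flips)])
}

#' Tanglegram entanglement
#'
#' Normalized crossing measure in [0, 1]: the sum over labels of
#' |position in left order - position in right order|^L, divided by the
#' value of the same sum when one order is the full reversal of the other
#' (the worst case). 0 means perfectly aligned connectors.
#'
#' @param tg A \code{tanglegram}.
#' @param L Norm exponent; defaults to the tanglegram's own.
#' @return Entanglement value in [0, 1].
#' @export
entanglement <- function(tg, L = tg$L) {
  ords <- leaf_orders(tg)
  entanglement_of_orders(ords$left, ords$right, L)
}

entanglement_of_orders <- function(left_order, right_order, L) {
  n <- length(left_order)
  if (n < 2) return(0)
  pos_right <- match(left_order, right_order)
  num <- sum(abs(seq_len(n) - pos_right)^L)
  den <- sum(abs(seq_len(n) - rev(seq_len(n)))^L)
  if (den == 0) return(0)
  num / den
}

#' Minimize tanglegram entanglement by branch rotation
#'
#' Searches over internal-node rotations (topology-preserving) to reduce
#' entanglement. \code{step1side} greedily flips nodes of one tree against
#' the fixed other until no single flip improves; \code{step2side}
#' alternates sides until neither improves, restarted from
#' \code{restarts} random rotation states (plus the incoming state);
#' \code{random} samples seeded rotation states and keeps the best. The
#' returned entanglement never exceeds the input entanglement.
#'
#' @param tg A \code{tanglegram}.
#' @param method \code{"step2side"} (default), \code{"step1side"} or
#'   \code{"random"}.
#' @param restarts Random restarts for \code{step2side} / samples for
#'   \code{random} (default 20).
#' @param side Side rotated by \code{step1side} (\code{"right"} default).
#' @param seed Integer seed for the random components.
#' @return The tanglegram with updated rotation states and
#'   \code{entanglement}.
#' @export
untangle <- function(tg, method = c("step2side", "step1side", "random"),
                     restarts = 20, side = c("right", "left"), seed = 1) {
  stopifnot(inherits(tg, "tanglegram"))
  method <- match.arg(method)
  side <- match.arg(side)
  nl <- length(tg$left_flips)
  nr <- length(tg$right_flips)
  set.seed(seed)

  best <- list(lf = tg$left_flips, rf = tg$right_flips,
               e = entanglement(tg))
  consider <- function(state) {
    if (state$e < best$e) best <<- state
    invisible(NULL)
  }

  if (method == "step1side") {
    st <- greedy_flip_pass(tg, best$lf, best$rf, side)
    consider(st)
  } else if (method == "random") {
    for (r in seq_len(restarts)) {
      lf <- sample(c(TRUE, FALSE), nl, replace = TRUE)
      rf <- sample(c(TRUE, FALSE), nr, replace = TRUE)
      e <- flip_entanglement(tg, lf, rf)
      consider(list(lf = lf, rf = rf, e = e))
    }
  } else {  # step2side
    starts <- list(list(lf = best$lf, rf = best$rf))
    for (r in seq_len(restarts)) {
      starts[[r + 1]] <- list(lf = sample(c(TRUE, FALSE), nl, replace = TRUE),
                              rf = sample(c(TRUE, FALSE), nr, replace = TRUE))
    }
    for (st0 in starts) {
      st <- step2side_refine(tg, st0$lf, st0$rf)
      consider(st)
    }
  }

  tg$left_flips <- best$lf
  tg$right_flips <- best$rf
  tg$entanglement <- best$e
  tg
}

flip_entanglement <- function(tg, lf, rf, L = tg$L) {
  lo <- tree_labels(tg$left)[leaf_order_indices(tg$left, lf)]
  ro <- tree_labels(tg$right)[leaf_order_indices(tg$right, rf)]
  entanglement_of_orders(lo, ro, L)
}

# One greedy sweep cycle over the nodes of `side`, repeated until no
# single flip improves.
greedy_flip_pass <- function(tg, lf, rf, side) {
  e <- flip_entanglement(tg, lf, rf)
  repeat {
    improved <- FALSE
    flips <- if (side == "left") lf else rf
    for (s in seq_along(flips)) {
      cand <- flips; cand[s] <- !cand[s]
      e_cand <- if (side == "left") flip_entanglement(tg, cand, rf)
                else flip_entanglement(tg, lf, cand)
      if (e_cand < e - 1e-14) {
        flips <- cand; e <- e_cand; improved <- TRUE
      }
    }
    if (side == "left") lf <- flips else rf <- flips
    if (!improved) break
  }
  list(lf = lf, rf = rf, e = e)
}

step2side_refine <- function(tg, lf, rf) {
  e <- flip_entanglement(tg, lf, rf)
  repeat {
    st <- greedy_flip_pass(tg, lf, rf, "right")
    st <- greedy_flip_pass(tg, st$lf, st$rf, "left")
    if (st$e < e - 1e-14) {
      lf <- st$lf; rf <- st$rf; e <- st$e
    } else break
  }
  list(lf = lf, rf = rf, e = e)
}

#' Mantel permutation test between two distance matrices
#'
#' Pearson correlation between the lower triangles, with a one-sided
#' permutation p-value (congruence corresponds to positive association):
#' labels of the second matrix are permuted jointly over rows and columns,
#' and p = (1 + #\{permuted r >= observed r\}) / (n_perm + 1).
#'
#' @param d1,d2 \code{dist} objects (or square symmetric matrices) over
#'   the same labels in the same order.
#' @param n_perm Number of permutations (default 9999).
#' @param seed Integer seed.
#' @return Object of class \code{mantel_test}: list with \code{r},
#'   \code{p}, \code{n_perm}, \code{n}.
#' @export
mantel_test <- function(d1, d2, n_perm = 9999, seed = 1) {
  m1 <- as.matrix(d1)
  m2 <- as.matrix(d2)
  if (!all(dim(m1) == dim(m2))) stop("distance matrices differ in size")
  if (!is.null(rownames(m1)) && !is.null(rownames(m2)) &&
      !identical(rownames(m1), rownames(m2))) {
    stop("distance matrices must share the same labels in the same order")
  }
  n <- nrow(m1)
  if (n < 3) stop("the Mantel test needs at least 3 objects")
  lt <- lower.tri(m1)
  v1 <- m1[lt]
  v2 <- m2[lt]
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    stop("constant lower triangle: correlation undefined")
  }
  r_obs <- stats::cor(v1, v2)
  set.seed(seed)
  count <- 0L
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    if (stats::cor(v1, m2[p, p][lt]) >= r_obs) count <- count + 1L
  }
  structure(list(r = r_obs, p = (1 + count) / (n_perm + 1),
                 n_perm = n_perm, n = n),
            class = "mantel_test")
}

#' Cophenetic correlation between a tree and its input distances
#'
#' Pearson correlation between the lower triangle of the input distance
#' matrix and the tree's cophenetic distances -- how faithfully the
#' dendrogram maps the raw pairwise dissimilarities.
#'
#' @param d \code{dist} object the tree was built from.
#' @param tree \code{hclust} over the same labels.
#' @return Correlation coefficient in [-1, 1].
#' @export
cophenetic_correlation <- function(d, tree) {
  m <- as.matrix(d)
  cm <- as.matrix(cophenetic_matrix(tree))
  labs <- rownames(m)
  if (!is.null(labs) && !is.null(rownames(cm))) {
    if (!setequal(labs, rownames(cm))) stop("tree and distance labels differ")
    cm <- cm[labs, labs]
  }
  lt <- lower.tri(m)
  v1 <- m[lt]; v2 <- cm[lt]
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    stop("constant lower triangle: correlation undefined")
  }
  stats::cor(v1, v2)
}

# n x n matrix of "cluster-count level at first co-clustering": a pair
# joined at merge step s first co-clusters when n - s clusters remain.
pair_coclustering_levels <- function(tree) {
  merge <- tree$merge
  n <- nrow(merge) + 1
  lv <- matrix(NA_real_, n, n)
  diag(lv) <- 0
  members <- vector("list", nrow(merge))
  for (s in seq_len(nrow(merge))) {
    a <- merge[s, 1]; b <- merge[s, 2]
    ia <- if (a < 0) -a else members[[a]]
    ib <- if (b < 0) -b else members[[b]]
    lv[ia, ib] <- n - s
    lv[ib, ia] <- n - s
    members[[s]] <- c(ia, ib)
  }
  labs <- tree_labels(tree)
  dimnames(lv) <- list(labs, labs)
  lv
}

#' Baker's Gamma correlation between two dendrograms
#'
#' For every leaf pair, each tree yields the lowest cluster-count level k
#' at which the pair first shares a cluster; Baker's Gamma is the
#' tie-aware Spearman rank correlation between the two pairwise level
#' vectors. Invariant under branch rotations.
#'
#' @param t1,t2 \code{hclust} trees over the same label set.
#' @return Correlation in [-1, 1].
#' @export
bakers_gamma <- function(t1, t2) {
  l1 <- pair_coclustering_levels(t1)
  l2 <- pair_coclustering_levels(t2)
  labs <- rownames(l1)
  if (!setequal(labs, rownames(l2))) {
    stop("label sets differ; only in first: ",
         paste(setdiff(labs, rownames(l2)), collapse = ", "),
         "; only in second: ",
         paste(setdiff(rownames(l2), labs), collapse = ", "))
  }
  l2 <- l2[labs, labs]
  lt <- lower.tri(l1)
  stats::cor(l1[lt], l2[lt], method = "spearman")
}

bk_statistic <- function(c1, c2) {
  n <- length(c1)
  c1 <- as.integer(factor(c1))
  c2 <- as.integer(factor(c2))
  k1 <- max(c1); k2 <- max(c2)
  ct <- matrix(tabulate((c1 - 1L) * k2 + c2, nbins = k1 * k2),
               k1, k2, byrow = TRUE)
  tk <- sum(ct^2) - n
  pk <- sum(rowSums(ct)^2) - n
  qk <- sum(colSums(ct)^2) - n
  if (pk == 0 || qk == 0) stop("degenerate partition: all singletons")
  list(bk = tk / sqrt(pk * qk), pk = pk, qk = qk, tk = tk)
}

#' Fowlkes-Mallows index between two dendrograms cut at level k
#'
#' Both trees are cut into k clusters; Bk = Tk / sqrt(Pk Qk) from the
#' pair-count contingency table. A one-sided permutation p-value (is the
#' agreement larger than chance?) is computed by permuting one labeling,
#' and the closed-form null expectation under fixed margins,
#' E(Bk) = sqrt(Pk Qk) / (n (n - 1)), is reported alongside.
#'
#' @param t1,t2 \code{hclust} trees over the same label set.
#' @param k Cut level, 2 <= k < n.
#' @param n_perm Number of permutations (default 1999).
#' @param seed Integer seed.
#' @return Object of class \code{fowlkes_mallows}: list with \code{bk},
#'   \code{p}, \code{e_bk_null}, \code{k}, \code{n_perm}.
#' @export
fowlkes_mallows <- function(t1, t2, k, n_perm = 1999, seed = 1) {
  n <- nrow(t1$merge) + 1
  if (k < 2 || k >= n) stop("k must satisfy 2 <= k < ", n)
  labs <- tree_labels(t1)
  if (!setequal(labs, tree_labels(t2))) stop("label sets differ")
  c1 <- cut_tree(t1, k)
  names(c1) <- labs
  c2 <- cut_tree(t2, k)
  names(c2) <- tree_labels(t2)
  c2 <- c2[labs]
  st <- bk_statistic(c1, c2)
  e_null <- sqrt(st$pk * st$qk) / (n * (n - 1))
  set.seed(seed)
  count <- 0L
  for (b in seq_len(n_perm)) {
    if (bk_statistic(c1, c2[sample.int(n)])$bk >= st$bk - 1e-14) {
      count <- count + 1L
    }
  }
  structure(list(bk = st$bk, p = (1 + count) / (n_perm + 1),
                 e_bk_null = e_null, k = k, n_perm = n_perm),
            class = "fowlkes_mallows")
}

#' Plot coordinates for a tanglegram
#'
#' Deterministic layout: leaf y-positions on each side (top position = 1
#' maps to the highest y), one connector segment per label, and a color
#' group per label from cutting the left tree into (at most) three
#' subtrees.
#'
#' @param tg A \code{tanglegram}.
#' @param groups_k Number of subtree color groups (default 3, capped at
#'   the leaf count).
#' @return List with \code{left_leaves}, \code{right_leaves} and
#'   \code{connectors} data.frames.
#' @export
tanglegram_layout <- function(tg, groups_k = 3) {
  ords <- leaf_orders(tg)
  n <- length(ords$left)
  grp <- cut_tree(tg$left, min(groups_k, n))
  left <- data.frame(label = ords$left, y = n:1,
                     group = unname(grp[ords$left]))
  right <- data.frame(label = ords$right, y = n:1,
                      group = unname(grp[ords$right]))
  connectors <- data.frame(
    label = left$label,
    y_left = left$y,
    y_right = right$y[match(left$label, right$label)],
    group = left$group
  )
  list(left_leaves = left, right_leaves = right, connectors = connectors)
}

#' Full congruence report for two trees
#'
#' Bundles the congruence statistics comparing two dendrograms built over
#' the same objects: entanglement before and after untangling, the Mantel
#' test between the two input distance matrices, each tree's cophenetic
#' correlation with its own distances, Baker's Gamma, and the
#' Fowlkes-Mallows index at level k with its permutation p-value.
#'
#' @param t1,t2 \code{hclust} trees over the same labels.
#' @param d1,d2 The \code{dist} inputs the trees were built from.
#' @param k Fowlkes-Mallows cut level (default 3).
#' @param L Entanglement norm exponent (default 1.5).
#' @param n_perm_mantel,n_perm_fmi Permutation counts (defaults 9999, 1999).
#' @param untangle_method,restarts Passed to \code{untangle()}.
#' @param seed Integer seed.
#' @return Object of class \code{congruence_report}.
#' @export
congruence_report <- function(t1, t2, d1, d2, k = 3, L = 1.5,
                              n_perm_mantel = 9999, n_perm_fmi = 1999,
                              untangle_method = "step2side", restarts = 20,
                              seed = 1) {
  tg <- tanglegram(t1, t2, L = L)
  e_before <- tg$entanglement
  tg <- untangle(tg, method = untangle_method, restarts = restarts,
                 seed = seed)
  mt <- mantel_test(d1, d2, n_perm = n_perm_mantel, seed = seed + 1L)
  fm <- fowlkes_mallows(t1, t2, k = k, n_perm = n_perm_fmi, seed = seed + 2L)
  structure(list(
    mantel_r = mt$r, mantel_p = mt$p,
    cophenetic_c = c(left = cophenetic_correlation(d1, t1),
                     right = cophenetic_correlation(d2, t2)),
    bakers_gamma = bakers_gamma(t1, t2),
    fmi_bk = fm$bk, fmi_p = fm$p, fmi_e_null = fm$e_bk_null, fmi_k = fm$k,
    entanglement_before = e_before,
    entanglement_after = tg$entanglement,
    tanglegram = tg
  ), class = "congruence_report")
}

#' @export
print.tanglegram <- function(x, ...) {
  cat("Tanglegram over", nrow(x$left$merge) + 1, "labels | entanglement",
      sprintf("(L = %g): %.4f", x$L, x$entanglement), "\n")
  invisible(x)
}

#' @export
print.mantel_test <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.3f, p = %.4g (%d permutations, n = %d)\n",
              x$r, x$p, x$n_perm, x$n))
  invisible(x)
}

#' @export
print.fowlkes_mallows <- function(x, ...) {
  cat(sprintf(
    "Fowlkes-Mallows: B%d = %.3f, p = %.4g (null expectation %.3f)\n",
    x$k, x$bk, x$p, x$e_bk_null))
  invisible(x)
}

#' @export
print.congruence_report <- function(x, ...) {
  cat("Dendrogram congruence report\n")
  cat(sprintf("  Mantel:          r = %.3f, p = %.4g\n", x$mantel_r,
              x$mantel_p))
  cat(sprintf("  cophenetic c:    left %.3f, right %.3f\n",
              x$cophenetic_c[["left"]], x$cophenetic_c[["right"]]))
  cat(sprintf("  Baker's Gamma:   %.3f\n", x$bakers_gamma))
  cat(sprintf("  Fowlkes-Mallows: B%d = %.3f, p = %.4g\n", x$fmi_k,
              x$fmi_bk, x$fmi_p))
  cat(sprintf("  entanglement:    %.3f -> %.3f\n", x$entanglement_before,
              x$entanglement_after))
  invisible(x)
}
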