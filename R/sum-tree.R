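#' Balanced k-ary cumulative-sum trees
#'
#' A `sum_tree` stores an ordered sequence of non-negative leaf weights in a
#' balanced k-ary tree whose internal nodes hold the sum of their children, so
#' the root holds the total weight. Leaf updates and weighted lookups both cost
#' O(log_k n). Leaves are padded with zero-weight dummies up to the capacity
#' k^h of the last level; the leaf set is fixed after construction (reaction
#' sets are static once preprocessing has run).
#'
#' Nodes are kept in a single flat numeric vector, level by level from the
#' root; `lvl[l + 1]` is the 0-based offset of level `l`, whose nodes are
#' `nodes[lvl[l + 1] + 1:(k^l)]`.
#'
#' @param weights numeric vector of non-negative leaf weights (may be empty).
#' @param k integer branching factor, at least 2. Default 4.
#' @return an object of class `sum_tree`.
#' @examples
#' tr <- build_tree(c(1, 2, 3, 4), k = 2)
#' tree_root(tr)           # 10
#' locate(tr, 3.5)         # leaf 3, residual 0.5
#' @export
build_tree <- function(weights, k = 4L) {
  weights <- as.numeric(weights)
  if (anyNA(weights)) stop("leaf weights must not be NA")
  if (any(weights < 0)) stop("negative leaf weight")
  k <- as.integer(k)
  if (is.na(k) || k < 2L) stop("branching factor k must be an integer >= 2")
  n <- length(weights)
  h <- 0L
  while (k^h < n) h <- h + 1L
  lvl <- as.integer((k^(0:(h + 1L)) - 1L) / (k - 1L))
  nodes <- numeric(lvl[h + 2L])
  if (n > 0L) nodes[lvl[h + 1L] + seq_len(n)] <- weights
  tree <- structure(
    list(k = k, h = h, n_leaves = n, cap = as.integer(k^h), lvl = lvl,
         nodes = nodes),
    class = "sum_tree"
  )
  recompute_tree(tree)
}

#' Rebuild every internal node of a sum tree exactly from its leaves
#'
#' Used to control floating-point drift after long sequences of incremental
#' updates, and as the from-scratch oracle in consistency checks. Idempotent.
#'
#' @param tree a `sum_tree`.
#' @return the tree with all internal sums recomputed.
#' @export
recompute_tree <- function(tree) {
  k <- tree$k
  h <- tree$h
  lvl <- tree$lvl
  nodes <- tree$nodes
  if (h > 0L) {
    for (l in seq(h - 1L, 0L)) {
      nn <- k^l
      ch <- nodes[(lvl[l + 2L] + 1L):(lvl[l + 2L] + nn * k)]
      nodes[(lvl[l + 1L] + 1L):(lvl[l + 1L] + nn)] <-
        colSums(matrix(ch, nrow = k))
    }
  }
  tree$nodes <- nodes
  tree
}

#' Total weight held at the root of a sum tree
#' @param tree a `sum_tree`.
#' @return the root value (sum of all leaves).
#' @export
tree_root <- function(tree) tree$nodes[1L]

#' Current leaf weights of a sum tree (dummy padding excluded)
#' @param tree a `sum_tree`.
#' @return numeric vector of the `n_leaves` stored weights.
#' @export
tree_leaves <- function(tree) {
  if (tree$n_leaves == 0L) return(numeric(0))
  tree$nodes[tree$lvl[tree$h + 1L] + seq_len(tree$n_leaves)]
}

#' Replace one leaf weight, refreshing the sums along the leaf-to-root path
#'
#' Only the leaf-to-root path is touched, so the cost is O(k log_k n). The
#' leaf is set exactly to `value`, and each ancestor on the path is
#' recomputed as the in-order sum of its k children (rather than nudged by
#' the delta), so incremental updates do not accumulate a floating-point
#' random walk: after any update sequence every path node equals a freshly
#' rounded sum of its children.
#'
#' @param tree a `sum_tree`.
#' @param index 1-based leaf index in `1:n_leaves`.
#' @param value new non-negative weight.
#' @return the updated tree.
#' @export
update_leaf <- function(tree, index, value) {
  index <- as.integer(index)
  if (is.na(index) || index < 1L || index > tree$n_leaves)
    stop("leaf index out of range")
  if (is.na(value) || value < 0) stop("leaf value must be non-negative")
  leaf_pos <- tree$lvl[tree$h + 1L] + index
  if (value == tree$nodes[leaf_pos]) return(tree)
  tree$nodes[leaf_pos] <- value
  k <- tree$k
  j <- index
  if (tree$h > 0L) {
    for (l in seq(tree$h - 1L, 0L)) {
      j <- (j - 1L) %/% k + 1L
      cb <- tree$lvl[l + 2L] + (j - 1L) * k
      acc <- 0
      for (cc in seq_len(k)) acc <- acc + tree$nodes[cb + cc]
      tree$nodes[tree$lvl[l + 1L] + j] <- acc
    }
  }
  tree
}

#' Map a weight coordinate to the covering leaf
#'
#' Descends from the root; at each level the child intervals are scanned left
#' to right, subtracting the weight of each passed sibling from `r`. Intervals
#' are half-open, so a leaf with cumulative span `[c, c + w)` is selected iff
#' `c <= r < c + w`; zero-weight leaves (including padding) are never selected
#' and `r` equal to a cumulative boundary selects the next leaf.
#'
#' @param tree a `sum_tree` with positive root.
#' @param r numeric in `[0, tree_root(tree))`.
#' @return list with `index` (1-based leaf) and `residual` in `[0, w_index)`.
#' @export
locate <- function(tree, r) {
  root <- tree_root(tree)
  if (is.na(r) || r < 0 || r >= root)
    stop("r must lie in [0, root)")
  k <- tree$k
  lvl <- tree$lvl
  nodes <- tree$nodes
  pos <- 1L
  if (tree$h > 0L) {
    for (l in seq_len(tree$h)) {
      base <- (pos - 1L) * k
      off <- lvl[l + 1L]
      taken <- FALSE
      last_pos <- 0L
      last_w <- 0
      for (ci in seq_len(k)) {
        w <- nodes[off + base + ci]
        if (w > 0) {
          last_pos <- base + ci
          last_w <- w
        }
        if (r < w) {
          pos <- base + ci
          taken <- TRUE
          break
        }
        r <- r - w
      }
      if (!taken) {
        # floating-point fallthrough at the extreme right edge: clamp into the
        # rightmost positive child
        if (last_pos == 0L) stop("sum tree drift: no positive child on path")
        pos <- last_pos
        r <- last_w * (1 - 1e-15)
      }
    }
  }
  list(index = pos, residual = r)
}

#' Vectorized leaf lookup over many weight coordinates
#'
#' Batch form of [locate()]: the same level-by-level descent executed for all
#' coordinates at once. Used by the frozen-selection histogram harness.
#'
#' @param tree a `sum_tree` with positive root.
#' @param r numeric vector of coordinates in `[0, root)`.
#' @return list with integer vector `index` and numeric vector `residual`.
#' @export
locate_many <- function(tree, r) {
  root <- tree_root(tree)
  if (any(r < 0 | r >= root)) stop("all r must lie in [0, root)")
  k <- tree$k
  lvl <- tree$lvl
  nodes <- tree$nodes
  n <- length(r)
  pos <- rep.int(1L, n)
  if (tree$h > 0L && n > 0L) {
    for (l in seq_len(tree$h)) {
      base <- (pos - 1L) * k
      off <- lvl[l + 1L]
      branch <- rep.int(0L, n)
      active <- rep.int(TRUE, n)
      for (ci in seq_len(k)) {
        w <- nodes[off + base + ci]
        hit <- active & (r < w)
        branch[hit] <- ci
        active <- active & !hit
        r[active] <- r[active] - w[active]
      }
      if (any(active)) {
        # clamp float fallthrough to the rightmost positive child
        for (i in which(active)) {
          ws <- nodes[off + base[i] + seq_len(k)]
          ci <- max(which(ws > 0))
          branch[i] <- ci
          r[i] <- ws[ci] * (1 - 1e-15)
        }
      }
      pos <- base + branch
    }
  }
  list(index = pos, residual = r)
}
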