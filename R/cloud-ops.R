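#' Factored propensity total of one cloud
#'
#' A cloud over factor-species T with primary-tree root R and secondary
#' aggregate C = sum_j x_sj * S_j has member-propensity sum a_T = x_T*(R + C).
#'
#' @param st a `sim_structures`.
#' @param cloud cloud index.
#' @return the cached cloud total `a_T`.
#' @export
cloud_total <- function(st, cloud) {
  st$x[st$cl_factor[cloud]] * (st$cl_R[cloud] + st$cl_C[cloud])
}

# Set main-tree leaf `cloud` to aT and refresh the cached totals.
set_cloud_total <- function(st, cloud, aT) {
  st$cl_aT[cloud] <- aT
  st$main <- update_leaf(st$main, cloud, aT)
  st$a0 <- st$P_sc + tree_root(st$main)
  st
}

#' Rescale a cloud after a change of its factor-species count
#'
#' The O(1) update at the heart of propensity factoring: when the
#' factor-species count moves by `delta`, every member propensity scales
#' together, so only `a_T = x_T * (R + C)` is recomputed -- R, C and all trees
#' are untouched. The species count, the main-tree leaf and `a0` are updated.
#' Note this is a cloud-local primitive: self-reaction leaves of the factor
#' species and structures in other clouds are the update program's
#' responsibility.
#'
#' @param st a `sim_structures`.
#' @param cloud cloud index.
#' @param delta signed integer change of the factor-species count.
#' @return the updated structures.
#' @export
on_factor_species_change <- function(st, cloud, delta) {
  f <- st$cl_factor[cloud]
  if (f == 1L && delta != 0) stop("the omnipresent species is immutable")
  if (st$x[f] + delta < 0) stop("invalid update: count would become negative")
  st$x[f] <- st$x[f] + delta
  set_cloud_total(st, cloud, st$x[f] * (st$cl_R[cloud] + st$cl_C[cloud]))
}

#' Refresh a primary-tree leaf after its non-factor reactant count changed
#'
#' Sets the leaf of `reaction` to `c_i * new_other_count`, adjusts R by the
#' leaf delta along the O(log_k |T0|) tree path, recomputes `a_T`, and updates
#' the main tree and `a0`. Also moves the stored count of the non-factor
#' reactant to `new_other_count` so the structures stay self-consistent.
#'
#' @param st a `sim_structures`.
#' @param cloud cloud index.
#' @param reaction reaction index; must live in this cloud's primary tree.
#' @param new_other_count new count of the reaction's non-factor reactant.
#' @return the updated structures.
#' @export
on_primary_reactant_change <- function(st, cloud, reaction, new_other_count) {
  if (st$loc_kind[reaction] != 1L || st$loc_cloud[reaction] != cloud)
    stop("wiring error: reaction is not in this cloud's primary tree")
  if (new_other_count < 0) stop("invalid update: negative count")
  leaf <- st$loc_pos[reaction]
  if (st$pl_self[[cloud]][leaf])
    stop("wiring error: self-reaction leaves are refreshed via the factor species")
  other <- st$pl_other[[cloud]][leaf]
  st$x[other] <- new_other_count
  v <- st$system$reactions$rate[reaction] * new_other_count
  st$prim[[cloud]] <- update_leaf(st$prim[[cloud]], leaf, v)
  st$cl_R[cloud] <- tree_root(st$prim[[cloud]])
  f <- st$cl_factor[cloud]
  set_cloud_total(st, cloud, st$x[f] * (st$cl_R[cloud] + st$cl_C[cloud]))
}

#' Adjust a cloud after a change of a sub-tree's secondary species count
#'
#' Sub-tree leaves are the constant rates and the sub-tree root S_j is a
#' constant, so a change of the secondary count x_sj only moves the aggregate
#' `C` by `delta * S_j` -- an O(1) update regardless of sub-tree size.
#'
#' @param st a `sim_structures`.
#' @param cloud cloud index.
#' @param j sub-tree index within the cloud.
#' @param delta signed integer change of the secondary species count.
#' @return the updated structures.
#' @export
on_secondary_species_change <- function(st, cloud, j, delta) {
  sub <- st$sub[[cloud]][[j]]
  if (is.null(sub)) stop("wiring error: no such sub-tree")
  if (st$x[sub$s] + delta < 0) stop("invalid update: count would become negative")
  st$x[sub$s] <- st$x[sub$s] + delta
  # compensated add keeps C within a few ulp of sum_j x_sj * S_j while
  # remaining O(1) per update
  y <- delta * sub$S - st$cl_Ccomp[cloud]
  tt <- st$cl_C[cloud] + y
  st$cl_Ccomp[cloud] <- (tt - st$cl_C[cloud]) - y
  st$cl_C[cloud] <- tt
  f <- st$cl_factor[cloud]
  set_cloud_total(st, cloud, st$x[f] * (st$cl_R[cloud] + st$cl_C[cloud]))
}

#' Select a reaction within a cloud from a residual random coordinate
#'
#' Rescales `r` into the factored domain by dividing by the factor-species
#' count; coordinates below R descend the primary tree, and the remainder
#' steps through the sub-trees subtracting `x_sj * S_j` until the containing
#' sub-tree is found, whose descent uses the residual divided by `x_sj`. The
#' measure of `r` in `[0, a_T)` mapping to each member equals that member's
#' propensity.
#'
#' @param st a `sim_structures`.
#' @param cloud cloud index.
#' @param r numeric in `[0, cloud a_T)`.
#' @return the selected reaction index.
#' @export
select_in_cloud <- function(st, cloud, r) {
  f <- st$cl_factor[cloud]
  xT <- st$x[f]
  if (is.na(r) || r < 0 || xT <= 0 || r >= st$cl_aT[cloud])
    stop("r outside [0, a_T) or empty cloud")
  rp <- r / xT
  R <- st$cl_R[cloud]
  if (rp < R) {
    rt <- tree_root(st$prim[[cloud]])
    loc <- locate(st$prim[[cloud]], if (rp >= rt) rt * (1 - 1e-16) else rp)
    leaf <- min(loc$index, length(st$pl_rxn[[cloud]]))
    return(st$pl_rxn[[cloud]][leaf])
  }
  rp <- rp - R
  subs <- st$sub[[cloud]]
  for (j in seq_along(subs)) {
    xs <- st$x[subs[[j]]$s]
    w <- xs * subs[[j]]$S
    if (rp < w) {
      rt <- rp / xs
      if (rt >= subs[[j]]$S) rt <- subs[[j]]$S * (1 - 1e-16)
      loc <- locate(subs[[j]]$tree, rt)
      leaf <- min(loc$index, length(subs[[j]]$rxn))
      return(subs[[j]]$rxn[leaf])
    }
    rp <- rp - w
  }
  # floating-point fallthrough at the right edge: clamp to the last structure
  # holding positive weight
  for (j in rev(seq_along(subs))) {
    xs <- st$x[subs[[j]]$s]
    if (xs * subs[[j]]$S > 0) {
      loc <- locate(subs[[j]]$tree, subs[[j]]$S * (1 - 1e-15))
      return(subs[[j]]$rxn[min(loc$index, length(subs[[j]]$rxn))])
    }
  }
  if (tree_root(st$prim[[cloud]]) > 0) {
    loc <- locate(st$prim[[cloud]], tree_root(st$prim[[cloud]]) * (1 - 1e-15))
    return(st$pl_rxn[[cloud]][min(loc$index, length(st$pl_rxn[[cloud]]))])
  }
  stop("internal consistency error: cloud selected with no positive weight")
}

#' Linear scan of the super-cache
#'
#' Steps through the cached propensities subtracting each from `r`; a hit
#' returns the covering reaction, a miss returns the residual `r - P_sc` for
#' main-tree descent.
#'
#' @param st a `sim_structures`.
#' @param r non-negative selection coordinate.
#' @return `list(hit = TRUE, reaction = index)` or
#'   `list(hit = FALSE, residual = r - P_sc)`.
#' @export
super_cache_select <- function(st, r) {
  if (r < st$P_sc) {
    for (e in seq_along(st$sc_idx)) {
      w <- st$sc_a[e]
      if (r < w) return(list(hit = TRUE, reaction = st$sc_idx[e]))
      r <- r - w
    }
    # float fallthrough: clamp to the last positive entry
    pos <- which(st$sc_a > 0)
    if (length(pos))
      return(list(hit = TRUE, reaction = st$sc_idx[pos[length(pos)]]))
  }
  list(hit = FALSE, residual = r - st$P_sc)
}

#' Recompute one super-cache entry from the current state
#'
#' Entries are refreshed by full per-entry recomputation (not factoring);
#' `P_sc` absorbs the delta.
#'
#' @param st a `sim_structures`.
#' @param reaction a reaction index currently held in the super-cache.
#' @return the updated structures.
#' @export
refresh_super_cache_entry <- function(st, reaction) {
  e <- match(reaction, st$sc_idx)
  if (is.na(e)) stop("wiring error: reaction is not in the super-cache")
  a_new <- propensity(st$system, reaction, st$x)
  st$P_sc <- st$P_sc + (a_new - st$sc_a[e])
  st$sc_a[e] <- a_new
  st$a0 <- st$P_sc + tree_root(st$main)
  st
}

#' Execute a reaction's compiled update program
#'
#' Applies the net stoichiometric count changes, then runs the precomputed
#' instruction list (see [compile_update_programs()]), leaving every cached
#' sum consistent with its from-scratch value.
#'
#' @param st a `sim_structures`.
#' @param reaction index of the fired reaction.
#' @return the updated structures.
#' @export
execute_program <- function(st, reaction) {
  pr <- st$prog[[reaction]]
  if (length(pr$sp)) {
    st$x[pr$sp] <- st$x[pr$sp] + pr$d
    if (any(st$x[pr$sp] < 0))
      stop(sprintf("impossible event: firing %s drives a count negative",
                   st$system$reactions$id[reaction]))
  }
  ops <- pr$ops
  for (i in seq_len(nrow(ops))) {
    kind <- ops[i, 1L]
    if (kind == 1L) {
      ci <- ops[i, 2L]
      f <- st$cl_factor[ci]
      st <- set_cloud_total(st, ci, st$x[f] * (st$cl_R[ci] + st$cl_C[ci]))
    } else if (kind == 2L || kind == 5L) {
      ci <- ops[i, 2L]; leaf <- ops[i, 3L]
      f <- st$cl_factor[ci]
      v <- if (kind == 2L)
        st$pl_rate[[ci]][leaf] * st$x[st$pl_other[[ci]][leaf]]
      else
        max(st$pl_rate[[ci]][leaf] * (st$x[f] - 1) * st$half, 0)
      st$prim[[ci]] <- update_leaf(st$prim[[ci]], leaf, v)
      st$cl_R[ci] <- tree_root(st$prim[[ci]])
      st <- set_cloud_total(st, ci, st$x[f] * (st$cl_R[ci] + st$cl_C[ci]))
    } else if (kind == 3L) {
      ci <- ops[i, 2L]
      y <- pr$val[i] - st$cl_Ccomp[ci]
      tt <- st$cl_C[ci] + y
      st$cl_Ccomp[ci] <- (tt - st$cl_C[ci]) - y
      st$cl_C[ci] <- tt
      f <- st$cl_factor[ci]
      st <- set_cloud_total(st, ci, st$x[f] * (st$cl_R[ci] + st$cl_C[ci]))
    } else {
      e <- ops[i, 2L]
      q <- st$sc_idx[e]
      a_new <- propensity(st$system, q, st$x)
      st$P_sc <- st$P_sc + (a_new - st$sc_a[e])
      st$sc_a[e] <- a_new
    }
  }
  # resum the (small) super-cache exactly; in-order scalar adds
  acc <- 0
  for (e in seq_along(st$sc_a)) acc <- acc + st$sc_a[e]
  st$P_sc <- acc
  st$a0 <- st$P_sc + tree_root(st$main)
  st
}

#' Rebuild every cached quantity from the bare state
#'
#' The from-scratch reconstruction used both for periodic floating-point
#' drift control and as the oracle side of [check_consistency()]: primary
#' leaves are recomputed from counts and rates, all trees are rebuilt exactly,
#' and R, C, a_T, the super-cache propensities, P_sc and a0 are re-derived.
#'
#' @param st a `sim_structures`.
#' @return structures with all caches exact.
#' @export
recompute_structures <- function(st) {
  rx <- st$system$reactions
  x <- st$x
  for (ci in seq_len(st$n_clouds)) {
    p <- st$pl_rxn[[ci]]
    f <- st$cl_factor[ci]
    leaf_w <- ifelse(st$pl_self[[ci]],
                     rx$rate[p] * (x[f] - 1) * st$half,
                     rx$rate[p] * x[st$pl_other[[ci]]])
    st$prim[[ci]] <- build_tree(pmax(leaf_w, 0), k = st$k)
    st$cl_R[ci] <- tree_root(st$prim[[ci]])
    subs <- st$sub[[ci]]
    for (j in seq_along(subs)) {
      subs[[j]]$tree <- recompute_tree(subs[[j]]$tree)
      subs[[j]]$S <- tree_root(subs[[j]]$tree)
    }
    st$sub[[ci]] <- subs
    st$cl_C[ci] <- if (length(subs))
      sum(vapply(subs, function(g) x[g$s] * g$S, numeric(1)))
    else 0
    st$cl_Ccomp[ci] <- 0
    st$cl_aT[ci] <- x[f] * (st$cl_R[ci] + st$cl_C[ci])
  }
  st$main <- build_tree(st$cl_aT, k = st$k)
  if (length(st$sc_idx)) {
    a <- propensities(st$system, x)
    st$sc_a <- a[st$sc_idx]
  }
  st$P_sc <- sum(st$sc_a)
  st$a0 <- st$P_sc + tree_root(st$main)
  st
}

#' Compare every cached sum against its from-scratch recomputation
#'
#' @param st a `sim_structures`.
#' @return list of maximum relative deviations (relative to the exact value,
#'   floored at magnitude 1): tree nodes, R, C, S_j, a_T, super-cache entries,
#'   P_sc, a0 (vs the rebuilt total) and a0 vs the brute-force
#'   [total_propensity()]; plus `max` over all components.
#' @export
check_consistency <- function(st) {
  fresh <- recompute_structures(st)
  rel <- function(a, b) {
    if (length(a) == 0L) return(0)
    max(abs(a - b) / pmax(abs(b), 1))
  }
  tree_dev <- 0
  for (ci in seq_len(st$n_clouds))
    tree_dev <- max(tree_dev, rel(st$prim[[ci]]$nodes, fresh$prim[[ci]]$nodes))
  out <- list(
    tree_nodes = max(tree_dev, rel(st$main$nodes, fresh$main$nodes)),
    R = rel(st$cl_R, fresh$cl_R),
    C = rel(st$cl_C, fresh$cl_C),
    S = rel(unlist(lapply(st$sub, function(ss) vapply(ss, `[[`, numeric(1), "S"))),
            unlist(lapply(fresh$sub, function(ss) vapply(ss, `[[`, numeric(1), "S")))),
    a_T = rel(st$cl_aT, fresh$cl_aT),
    super_cache = rel(st$sc_a, fresh$sc_a),
    P_sc = rel(st$P_sc, fresh$P_sc),
    a0 = rel(st$a0, fresh$a0),
    a0_vs_brute_force = rel(st$a0, total_propensity(st$system, st$x))
  )
  out$max <- max(unlist(out))
  out
}

#' Serialize the full structure set to canonical JSON text
#'
#' A deterministic debug dump (counts, caches, every tree node, cloud wiring)
#' used for golden-file and determinism tests: two runs with the same seed
#' must produce byte-identical dumps.
#'
#' @param st a `sim_structures`.
#' @return a JSON string.
#' @export
dump_structures <- function(st) {
  payload <- list(
    time = st$time, a0 = st$a0, x = st$x,
    super_cache = list(reactions = st$sc_idx, propensities = st$sc_a,
                       P_sc = st$P_sc),
    main_tree = st$main$nodes,
    clouds = lapply(seq_len(st$n_clouds), function(ci) list(
      factor = st$cl_factor[ci], R = st$cl_R[ci], C = st$cl_C[ci],
      a_T = st$cl_aT[ci],
      primary = list(reactions = st$pl_rxn[[ci]], nodes = st$prim[[ci]]$nodes),
      sub_trees = lapply(st$sub[[ci]], function(g)
        list(s = g$s, S = g$S, reactions = g$rxn, nodes = g$tree$nodes))
    ))
  )
  as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA))
}

#' Enumerate the Phase-1 selection intervals of a frozen structure set
#'
#' Walks the full selection procedure analytically: super-cache entries in
#' scan order, then clouds in main-tree leaf order, each cloud's primary
#' leaves (spanning `x_T * leaf`) followed by its sub-trees (leaves spanning
#' `x_T * x_sj * c_i`). The returned interval lengths are the exact selection
#' measure of each reaction; exactness of the method means they equal the
#' current propensities.
#'
#' @param st a `sim_structures`.
#' @return data.frame with columns `reaction`, `lo`, `hi`, `measure`, the
#'   intervals partitioning `[0, a0)` in procedure order.
#' @export
selection_breakpoints <- function(st) {
  rxn <- integer(0)
  span <- numeric(0)
  if (length(st$sc_idx)) {
    rxn <- st$sc_idx
    span <- st$sc_a
  }
  for (ci in seq_len(st$n_clouds)) {
    xT <- st$x[st$cl_factor[ci]]
    pl <- tree_leaves(st$prim[[ci]])
    rxn <- c(rxn, st$pl_rxn[[ci]])
    span <- c(span, xT * pl)
    for (g in st$sub[[ci]]) {
      rxn <- c(rxn, g$rxn)
      span <- c(span, xT * st$x[g$s] * tree_leaves(g$tree))
    }
  }
  lo <- cumsum(c(0, span))[seq_along(span)]
  data.frame(reaction = rxn, lo = lo, hi = lo + span, measure = span)
}
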