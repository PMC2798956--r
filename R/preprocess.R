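#' Average propensities over a trial simulation run
#'
#' Runs the textbook direct-method SSA for `n_steps` events and returns the
#' time-averaged propensity of each reaction (each propensity weighted by the
#' exponential holding time during which it was current). These averages drive
#' super-cache selection, greedy cloud assignment and the ODM baseline's array
#' order. Deterministic given `seed`; with `seed = NULL` the current RNG
#' stream is consumed.
#'
#' @param system a `reaction_system`.
#' @param counts starting counts; defaults to [initial_counts()].
#' @param n_steps number of trial events (the run ends early if the system
#'   goes extinct). `n_steps = 0` returns the initial propensities.
#' @param seed optional integer seed.
#' @return numeric vector of length `M`, non-negative.
#' @export
sample_average_propensities <- function(system, counts = NULL, n_steps = 1e5,
                                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(counts)) counts <- initial_counts(system)
  a <- propensities(system, counts)
  if (n_steps == 0) return(a)
  if (sum(a) <= 0)
    stop("degenerate system: all initial propensities are zero")
  res <- direct_engine(system, counts, max_steps = n_steps, max_time = Inf,
                       accumulate_avg = TRUE)
  if (res$avg_time > 0) res$avg_acc / res$avg_time else a
}

#' Select the super-cache: the reactions with the largest average propensity
#'
#' @param profile numeric vector of average propensities (length `M`).
#' @param size number of reactions to cache, `0 <= size <= M`.
#' @return integer vector of reaction indices in descending average-propensity
#'   order, ties broken by ascending reaction index.
#' @export
build_super_cache <- function(profile, size) {
  size <- as.integer(size)
  if (size < 0L || size > length(profile)) stop("super-cache size out of range")
  if (size == 0L) return(integer(0))
  order(-profile, seq_along(profile))[seq_len(size)]
}

#' Greedy assignment of reactions to clouds
#'
#' Implements the greedy loop: a candidate cloud is created for every
#' (non-placeholder) species, containing every eligible reaction with that
#' species as a reactant; each candidate is scored by the summed average
#' propensity of its members; the best-scoring cloud is fixed (ties broken by
#' lowest species index), its members are removed from all other candidates,
#' scores are refreshed and empty candidates dropped, until every eligible
#' reaction is assigned. Reactions whose reactants are both the placeholder
#' cannot share a real reactant and go to a dedicated placeholder cloud whose
#' factor count is the frozen 1.
#'
#' @param system a `reaction_system`.
#' @param profile average-propensity vector of length `M`.
#' @param super_cache integer vector of reactions excluded from clouding.
#' @return list of clouds, each `list(factor = species index,
#'   members = integer reaction indices)`, in fixing order (placeholder cloud,
#'   if any, last). Together with the super-cache this partitions `1:M`.
#' @export
assign_clouds <- function(system, profile, super_cache = integer(0)) {
  rx <- system$reactions
  M <- system$M
  eligible <- setdiff(seq_len(M), super_cache)
  null_rx <- eligible[rx$r1[eligible] == 1L & rx$r2[eligible] == 1L]
  remaining <- setdiff(eligible, null_rx)

  members <- lapply(seq_len(system$N), function(s) {
    if (s == 1L) integer(0)
    else remaining[rx$r1[remaining] == s | rx$r2[remaining] == s]
  })
  alive <- rep(TRUE, M)
  clouds <- list()
  cand <- which(lengths(members) > 0L)
  while (length(remaining) > 0L) {
    scores <- vapply(cand, function(s) sum(profile[members[[s]][alive[members[[s]]]]]),
                     numeric(1))
    best <- cand[which.max(scores)]  # which.max takes the first (lowest index) on ties
    mem <- members[[best]][alive[members[[best]]]]
    clouds[[length(clouds) + 1L]] <- list(factor = best, members = mem)
    alive[mem] <- FALSE
    remaining <- setdiff(remaining, mem)
    cand <- setdiff(cand, best)
    keep <- vapply(cand, function(s) any(alive[members[[s]]]), logical(1))
    cand <- cand[keep]
  }
  if (length(null_rx))
    clouds[[length(clouds) + 1L]] <- list(factor = 1L, members = null_rx)
  clouds
}

#' Partition a cloud's members into the primary set and constant sub-trees
#'
#' Members are grouped by their non-factor reactant; any group of at least
#' `threshold` reactions becomes a sub-tree (its leaves are the constant rates
#' and its root is constant for the lifetime of the cloud). Everything else --
#' small groups, placeholder-partnered reactions, and self-reactions of the
#' factor-species -- stays in the primary set.
#'
#' @param system a `reaction_system`.
#' @param factor species index of the cloud's factor-species.
#' @param members integer reaction indices, all having `factor` as a reactant.
#' @param threshold minimum group size for a sub-tree (default 3).
#' @return `list(primary = integer vector, sub = list of list(s = species,
#'   members = integer vector))`, sub-trees ordered by species index.
#' @export
build_subtree_partition <- function(system, factor, members, threshold = 3L) {
  rx <- system$reactions
  partner <- ifelse(rx$r1[members] == factor, rx$r2[members], rx$r1[members])
  is_self <- rx$r1[members] == factor & rx$r2[members] == factor
  partner[is_self] <- NA  # self-reactions always stay primary
  partner[partner == 1L] <- NA  # placeholder-partnered too
  groupable <- !is.na(partner)
  tab <- table(partner[groupable])
  big <- sort(as.integer(names(tab)[tab >= threshold]))
  sub <- lapply(big, function(s)
    list(s = s, members = members[groupable & partner == s & !is.na(partner)]))
  in_sub <- if (length(big)) groupable & partner %in% big else rep(FALSE, length(members))
  list(primary = members[!in_sub], sub = sub)
}

#' Build the bipartite species/reaction update dependency graph
#'
#' Each species points to the reactions in which it is a reactant; each
#' reaction points to the species whose counts it changes with nonzero net
#' stoichiometric delta (so a catalytic appearance contributes no edge). The
#' omnipresent placeholder has a frozen count and carries no edges. With at
#' most 2 reactant-side memberships and 4 affected species per reaction the
#' edge count is bounded by 6M.
#'
#' @param system a `reaction_system`.
#' @return list with `sp2rx` (list over species of reactant-side reaction
#'   indices), `aff`/`dlt` (per reaction: affected species and net deltas) and
#'   `n_edges`.
#' @export
build_bipartite_udg <- function(system) {
  rx <- system$reactions
  sp2rx <- vector("list", system$N)
  sp2rx[] <- list(integer(0))
  for (s in seq_len(system$N)[-1L]) {
    sp2rx[[s]] <- which(rx$r1 == s | rx$r2 == s)
  }
  sd <- stoich_deltas(system)
  list(sp2rx = sp2rx, aff = sd$species, dlt = sd$delta,
       n_edges = sum(lengths(sp2rx)) + sum(lengths(sd$species)))
}

#' Build the reaction-to-reaction (clique-forming) update dependency graph
#'
#' Reaction `u` points to reaction `v` iff executing `u` changes the count of
#' a reactant of `v` (including `u` itself when it changes its own reactants).
#' This is the representation used by ODM/NRM; when one species is a reactant
#' of many reactions those reactions form a clique, so the edge count can
#' approach M^2. Used here only for the ODM baseline and for edge-count
#' comparison.
#'
#' @param system a `reaction_system`.
#' @param udg optional precomputed [build_bipartite_udg()] result.
#' @return list of integer vectors: `adj[[u]]` are the reactions to update
#'   after firing `u`; attribute `n_edges` holds the total edge count.
#' @export
build_clique_udg <- function(system, udg = NULL) {
  if (is.null(udg)) udg <- build_bipartite_udg(system)
  adj <- vector("list", system$M)
  for (u in seq_len(system$M)) {
    aff <- udg$aff[[u]]
    adj[[u]] <- if (length(aff))
      sort(unique(unlist(udg$sp2rx[aff], use.names = FALSE)))
    else integer(0)
  }
  attr(adj, "n_edges") <- as.numeric(sum(lengths(adj)))
  adj
}

# Edge count of the clique UDG without materializing the adjacency lists.
clique_edge_count <- function(system, udg = NULL) {
  if (is.null(udg)) udg <- build_bipartite_udg(system)
  total <- 0
  for (u in seq_len(system$M)) {
    aff <- udg$aff[[u]]
    if (length(aff))
      total <- total + length(unique(unlist(udg$sp2rx[aff], use.names = FALSE)))
  }
  total
}

#' Compile per-reaction update programs
#'
#' For every reaction, precompute the ordered instruction list that must run
#' when it fires: first the net stoichiometric count adjustments, then for
#' each affected species the cheapest correct structure update -- an O(1)
#' factor-rescale for a cloud whose factor-species changed, an O(1) C-adjust
#' for a sub-tree secondary species, a leaf refresh for a primary-tree
#' partner, a self-reaction leaf refresh where the factor-species partners
#' itself, and a full per-entry recomputation for super-cache members.
#' Instructions are deduplicated and sorted (cloud index, kind, position;
#' super-cache refreshes last) so compilation is reproducible bit for bit.
#'
#' Instruction encoding (matrix columns `kind`, `a1`, `a2`, parallel numeric
#' `val`): 1 = factor-scale(cloud); 2 = primary-leaf-refresh(cloud, leaf);
#' 3 = C-adjust(cloud, subtree) with `val = S_j * delta`; 4 =
#' super-cache-refresh(entry); 5 = self-reaction-leaf-refresh(cloud, leaf).
#'
#' @param st a partially built structure set (see [build_sim_structures()]);
#'   called internally.
#' @return list over reactions of `list(sp, d, ops, val)`.
#' @keywords internal
compile_update_programs <- function(st) {
  M <- st$system$M
  udg <- st$udg
  progs <- vector("list", M)
  for (m in seq_len(M)) {
    sp <- udg$aff[[m]]
    d <- udg$dlt[[m]]
    keys <- character(0)
    ops <- matrix(integer(0), ncol = 3)
    val <- numeric(0)
    add <- function(kind, a1, a2, v = NA_real_) {
      key <- paste(kind, a1, a2)
      if (key %in% keys) return()
      keys <<- c(keys, key)
      ops <<- rbind(ops, c(kind, a1, a2))
      val <<- c(val, v)
    }
    for (i in seq_along(sp)) {
      s <- sp[i]
      for (q in udg$sp2rx[[s]]) {
        kind <- st$loc_kind[q]
        cl <- st$loc_cloud[q]
        if (kind == 0L) {
          add(4L, st$loc_pos[q], 0L)
        } else if (kind == 1L) {
          if (s == st$cl_factor[cl]) {
            add(1L, cl, 0L)
            if (st$pl_self[[cl]][st$loc_pos[q]]) add(5L, cl, st$loc_pos[q])
          } else {
            add(2L, cl, st$loc_pos[q])
          }
        } else {
          if (s == st$cl_factor[cl]) {
            add(1L, cl, 0L)
          } else {
            add(3L, cl, st$loc_sub[q],
                v = st$sub[[cl]][[st$loc_sub[q]]]$S * d[i])
          }
        }
      }
    }
    if (nrow(ops)) {
      # order: cloud instructions by (cloud, kind, pos), then sc refreshes by entry
      sc <- ops[, 1] == 4L
      ord <- order(sc, ops[, 2], ops[, 1], ops[, 3])
      ops <- ops[ord, , drop = FALSE]
      val <- val[ord]
    }
    storage.mode(ops) <- "integer"
    progs[[m]] <- list(sp = sp, d = d, ops = ops, val = val)
  }
  progs
}

#' Build the full simulation structure set for a reaction system
#'
#' Runs the preprocessing pipeline: trial-run propensity profile (unless
#' given), super-cache selection, greedy cloud assignment, sub-tree
#' partitioning, k-ary tree construction, bipartite update-graph construction
#' and update-program compilation, all evaluated at the given starting counts.
#'
#' @param system a `reaction_system`.
#' @param profile optional average-propensity vector; if `NULL` it is sampled
#'   with [sample_average_propensities()] over `trial_steps` events
#'   (`trial_steps = 0` uses the initial propensities).
#' @param counts starting counts; defaults to [initial_counts()].
#' @param k tree branching factor (default 4).
#' @param supercache_size maximum super-cache size (default 16; capped at M).
#' @param subtree_threshold minimum shared-partner group size for a sub-tree
#'   (default 3).
#' @param trial_steps trial-run length when `profile` is `NULL`.
#' @param trial_seed optional seed for the trial run.
#' @return an object of class `sim_structures`; see [check_consistency()],
#'   [run_lolcat()], [dump_structures()].
#' @export
build_sim_structures <- function(system, profile = NULL, counts = NULL,
                                 k = 4L, supercache_size = 16L,
                                 subtree_threshold = 3L, trial_steps = 1e5,
                                 trial_seed = NULL) {
  if (is.null(counts)) counts <- initial_counts(system)
  if (is.null(profile)) {
    profile <- tryCatch(
      sample_average_propensities(system, counts, n_steps = trial_steps,
                                  seed = trial_seed),
      error = function(e) {
        if (grepl("degenerate system", conditionMessage(e)))
          rep(1, system$M)  # uniform fallback for stalled trial runs
        else stop(e)
      })
  }
  stopifnot(length(profile) == system$M)
  M <- system$M
  rx <- system$reactions
  half <- if (system$self_half) 0.5 else 1

  sc_idx <- build_super_cache(profile, min(as.integer(supercache_size), M))
  clouds <- assign_clouds(system, profile, sc_idx)
  n_clouds <- length(clouds)

  st <- list(system = system,
             x = stats::setNames(as.numeric(counts), system$species$id),
             time = 0,
             k = as.integer(k), half = half, profile = profile,
             supercache_size = as.integer(supercache_size),
             subtree_threshold = as.integer(subtree_threshold))
  st$sc_idx <- sc_idx
  st$n_clouds <- n_clouds
  st$cl_factor <- vapply(clouds, `[[`, integer(1), "factor")

  loc_kind <- integer(M); loc_cloud <- integer(M)
  loc_sub <- integer(M); loc_pos <- integer(M)
  if (length(sc_idx)) {
    loc_kind[sc_idx] <- 0L
    loc_pos[sc_idx] <- seq_along(sc_idx)
  }

  prim <- vector("list", n_clouds)
  pl_rxn <- vector("list", n_clouds)
  pl_other <- vector("list", n_clouds)
  pl_self <- vector("list", n_clouds)
  pl_rate <- vector("list", n_clouds)
  sub <- vector("list", n_clouds)
  cl_R <- numeric(n_clouds); cl_C <- numeric(n_clouds)
  cl_aT <- numeric(n_clouds)

  for (ci in seq_len(n_clouds)) {
    f <- clouds[[ci]]$factor
    part <- build_subtree_partition(system, f, clouds[[ci]]$members,
                                    threshold = subtree_threshold)
    p <- part$primary
    other <- ifelse(rx$r1[p] == f, rx$r2[p], rx$r1[p])
    selfr <- rx$r1[p] == f & rx$r2[p] == f
    leaf_w <- ifelse(selfr,
                     rx$rate[p] * (counts[f] - 1) * half,
                     rx$rate[p] * counts[other])
    leaf_w <- pmax(leaf_w, 0)
    prim[[ci]] <- build_tree(leaf_w, k = k)
    pl_rxn[[ci]] <- p
    pl_other[[ci]] <- other
    pl_self[[ci]] <- selfr
    pl_rate[[ci]] <- rx$rate[p]
    loc_kind[p] <- 1L; loc_cloud[p] <- ci; loc_pos[p] <- seq_along(p)

    subs <- lapply(part$sub, function(g) {
      tr <- build_tree(rx$rate[g$members], k = k)
      list(s = g$s, S = tree_root(tr), rxn = g$members, tree = tr)
    })
    sub[[ci]] <- subs
    for (j in seq_along(subs)) {
      g <- subs[[j]]
      loc_kind[g$rxn] <- 2L; loc_cloud[g$rxn] <- ci
      loc_sub[g$rxn] <- j; loc_pos[g$rxn] <- seq_along(g$rxn)
    }
    cl_R[ci] <- tree_root(prim[[ci]])
    cl_C[ci] <- if (length(subs))
      sum(vapply(subs, function(g) counts[g$s] * g$S, numeric(1)))
    else 0
    cl_aT[ci] <- counts[f] * (cl_R[ci] + cl_C[ci])
  }

  st$prim <- prim; st$pl_rxn <- pl_rxn; st$pl_other <- pl_other
  st$pl_self <- pl_self; st$pl_rate <- pl_rate; st$sub <- sub
  st$cl_R <- cl_R; st$cl_C <- cl_C; st$cl_aT <- cl_aT
  st$cl_Ccomp <- numeric(n_clouds)
  st$main <- build_tree(cl_aT, k = k)
  st$loc_kind <- loc_kind; st$loc_cloud <- loc_cloud
  st$loc_sub <- loc_sub; st$loc_pos <- loc_pos

  a <- propensities(system, counts)
  st$sc_a <- a[sc_idx]
  st$P_sc <- sum(st$sc_a)
  st$udg <- build_bipartite_udg(system)
  st$prog <- compile_update_programs(st)
  st$a0 <- st$P_sc + tree_root(st$main)
  class(st) <- "sim_structures"
  st
}

#' @export
print.sim_structures <- function(x, ...) {
  cat(sprintf(paste0(
    "sim_structures: %d reactions | super-cache %d | %d clouds ",
    "(%d sub-trees) | k = %d\n  a0 = %.6g at t = %.6g\n"),
    x$system$M, length(x$sc_idx), x$n_clouds,
    sum(lengths(x$sub)), x$k, x$a0, x$time))
  invisible(x)
}

#' Structure summary report
#'
#' @param st a `sim_structures`.
#' @return list with cloud count and sizes, sub-tree counts, super-cache
#'   contents, and bipartite vs clique UDG edge counts.
#' @export
structure_summary <- function(st) {
  list(
    M = st$system$M,
    super_cache = st$system$reactions$id[st$sc_idx],
    n_clouds = st$n_clouds,
    cloud_factor = st$system$species$id[st$cl_factor],
    cloud_size = vapply(seq_len(st$n_clouds), function(ci)
      length(st$pl_rxn[[ci]]) + sum(lengths(lapply(st$sub[[ci]], `[[`, "rxn"))),
      numeric(1)),
    n_subtrees = vapply(st$sub, length, integer(1)),
    bipartite_edges = st$udg$n_edges,
    clique_edges = clique_edge_count(st$system, st$udg)
  )
}
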