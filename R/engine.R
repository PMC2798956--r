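#' Exponential waiting time between reaction events
#'
#' @param a0 positive total propensity.
#' @param u uniform variate(s) in `(0, 1]`.
#' @return `tau = log(1/u) / a0`, the holding time(s).
#' @export
advance_time <- function(a0, u) {
  if (is.na(a0) || a0 <= 0)
    stop("extinction: total propensity must be positive to advance time")
  if (any(is.na(u) | u <= 0 | u > 1)) stop("u must lie in (0, 1]")
  log(1 / u) / a0
}

#' Map a selection coordinate to a reaction (Phase 1, scalar)
#'
#' Executes the full two-stage lookup on a frozen structure set: linear scan
#' of the super-cache first; on a miss, descend the main tree to a cloud and
#' select within it. Deterministic in `r`; the measure of `r` values in
#' `[0, a0)` selecting each reaction equals that reaction's propensity.
#'
#' @param st a `sim_structures`.
#' @param r numeric in `[0, a0)`.
#' @return the selected reaction index.
#' @export
select_reaction <- function(st, r) {
  if (is.na(r) || r < 0 || r >= st$a0) stop("r must lie in [0, a0)")
  sc <- super_cache_select(st, r)
  if (sc$hit) return(sc$reaction)
  root <- tree_root(st$main)
  if (root <= 0)
    stop("internal consistency error: selection miss with empty main tree")
  rr <- sc$residual
  if (rr >= root) rr <- root * (1 - 1e-16)
  loc <- locate(st$main, rr)
  ci <- min(loc$index, st$n_clouds)
  select_in_cloud(st, ci, loc$residual)
}

# Vectorized in-cloud selection (same procedure as select_in_cloud, batch).
select_in_cloud_many <- function(st, cloud, r) {
  f <- st$cl_factor[cloud]
  xT <- st$x[f]
  out <- integer(length(r))
  rp <- r / xT
  R <- st$cl_R[cloud]
  inP <- rp < R
  if (any(inP)) {
    tr <- st$prim[[cloud]]
    lp <- locate_many(tr, pmin(rp[inP], tree_root(tr) * (1 - 1e-16)))
    leaf <- pmin(lp$index, length(st$pl_rxn[[cloud]]))
    out[inP] <- st$pl_rxn[[cloud]][leaf]
  }
  idx_act <- which(!inP)
  rp2 <- rp[!inP] - R
  for (g in st$sub[[cloud]]) {
    if (!length(idx_act)) break
    xs <- st$x[g$s]
    w <- xs * g$S
    hit <- rp2 < w
    if (any(hit)) {
      lp <- locate_many(g$tree, pmin(rp2[hit] / xs, g$S * (1 - 1e-16)))
      out[idx_act[hit]] <- g$rxn[pmin(lp$index, length(g$rxn))]
    }
    idx_act <- idx_act[!hit]
    rp2 <- rp2[!hit] - w
  }
  if (length(idx_act))  # float fallthrough at the right edge
    out[idx_act] <- select_in_cloud(st, cloud, st$cl_aT[cloud] * (1 - 1e-15))
  out
}

#' Vectorized Phase-1 selection over many coordinates
#'
#' Batch execution of the same super-cache scan / main-tree descent / in-cloud
#' selection as [select_reaction()], used by the frozen-selection histogram.
#'
#' @param st a `sim_structures`.
#' @param r numeric vector of coordinates in `[0, a0)`.
#' @return integer vector of selected reaction indices.
#' @export
select_reaction_many <- function(st, r) {
  n <- length(r)
  out <- integer(n)
  nsc <- length(st$sc_idx)
  insc <- if (nsc && st$P_sc > 0) r < st$P_sc else rep(FALSE, n)
  if (any(insc)) {
    b <- cumsum(st$sc_a)
    e <- findInterval(r[insc], b) + 1L
    e[e > nsc] <- nsc
    out[insc] <- st$sc_idx[e]
  }
  if (any(!insc)) {
    root <- tree_root(st$main)
    if (root <= 0) {
      # all weight sits in the super-cache; clamp the (rounding-edge) misses
      pos <- which(st$sc_a > 0)
      out[!insc] <- st$sc_idx[pos[length(pos)]]
    } else {
      rr <- pmax(pmin(r[!insc] - st$P_sc, root * (1 - 1e-16)), 0)
      lm <- locate_many(st$main, rr)
      ci <- pmin(lm$index, st$n_clouds)
      res <- integer(length(rr))
      for (cu in unique(ci)) {
        sel <- ci == cu
        res[sel] <- select_in_cloud_many(st, cu, lm$residual[sel])
      }
      out[!insc] <- res
    }
  }
  out
}

#' Selection frequencies over repeated draws on a frozen structure set
#'
#' Performs `n_draws` independent Phase-1 selections without executing any
#' reaction, for goodness-of-fit comparison against the exact selection
#' probabilities `a_j / a0`.
#'
#' @param st a `sim_structures`.
#' @param n_draws number of independent draws.
#' @param seed optional integer seed.
#' @return numeric vector of length `M` of observed frequencies, with the raw
#'   counts in attribute `"counts"`.
#' @export
frozen_selection_histogram <- function(st, n_draws, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (st$a0 <= 0) stop("total propensity is zero; nothing to select")
  counts <- tabulate(
    select_reaction_many(st, stats::runif(n_draws) * st$a0),
    nbins = st$system$M)
  structure(counts / n_draws, counts = counts)
}

#' One iteration of the factored two-phase algorithm
#'
#' Phase 1 draws `u1` and maps `r = u1 * a0` to a reaction through the
#' super-cache and trees; Phase 2 draws `u2`, advances time by
#' `log(1/u2)/a0`, and runs the reaction's compiled update program. Exactly
#' two uniform variates are consumed per step, in that order, so trajectories
#' are reproducible from the seed.
#'
#' @param st a `sim_structures` with positive `a0`.
#' @return `list(structures, reaction, tau)`.
#' @export
lolcat_step <- function(st) {
  if (st$a0 <= 0) stop("extinction: total propensity is zero")
  u1 <- stats::runif(1)
  m <- select_reaction(st, u1 * st$a0)
  u2 <- stats::runif(1)
  tau <- log(1 / u2) / st$a0
  st$time <- st$time + tau
  st <- execute_program(st, m)
  list(structures = st, reaction = m, tau = tau)
}

# ---------------------------------------------------------------------------
# time-grid recorder (sample-and-hold at interval boundaries)

new_recorder <- function(interval, idx, max_time) {
  if (is.null(interval)) return(NULL)
  stopifnot(interval > 0)
  finite <- is.finite(max_time)
  K <- if (finite) floor(max_time / interval + 1e-9) else 1024L
  env <- new.env(parent = emptyenv())
  env$times <- interval * seq_len(K)
  env$S <- matrix(NA_real_, nrow = K, ncol = length(idx))
  env$n <- 0L
  env$idx <- idx
  env$interval <- interval
  env$finite <- finite
  env
}

# record the held state x at every grid boundary strictly before t_new
rec_advance <- function(env, t_new, x) {
  repeat {
    nxt <- env$n + 1L
    if (nxt > length(env$times)) {
      if (env$finite) break
      env$times <- c(env$times,
                     env$interval * (length(env$times) + seq_len(length(env$times))))
      env$S <- rbind(env$S, matrix(NA_real_, nrow = nrow(env$S), ncol = ncol(env$S)))
    }
    if (env$times[nxt] >= t_new) break
    env$S[nxt, ] <- x[env$idx]
    env$n <- nxt
  }
  invisible(env)
}

resolve_record_species <- function(system, record_species) {
  if (is.null(record_species)) return(seq_len(system$N)[-1L])
  if (is.character(record_species)) {
    idx <- match(record_species, system$species$id)
    if (anyNA(idx)) stop("unknown species in record_species: ",
                         paste(record_species[is.na(idx)], collapse = ", "))
    idx
  } else as.integer(record_species)
}

new_trajectory <- function(method, system, rec_idx, rec, x0, x, t_final,
                           steps, events, extinct, ops = NULL) {
  ids <- system$species$id[rec_idx]
  if (!is.null(rec)) {
    times <- c(0, rec$times[seq_len(rec$n)])
    states <- rbind(x0[rec_idx], rec$S[seq_len(rec$n), , drop = FALSE])
  } else {
    times <- 0
    states <- matrix(x0[rec_idx], nrow = 1)
  }
  colnames(states) <- ids
  structure(list(
    method = method, times = times, states = states, species = ids,
    events = stats::setNames(events, system$reactions$id),
    final_counts = stats::setNames(x, system$species$id),
    final_time = t_final, n_steps = steps, extinct = extinct, ops = ops),
    class = "ssa_trajectory")
}

#' @export
print.ssa_trajectory <- function(x, ...) {
  cat(sprintf("ssa_trajectory (%s): %g events to t = %.6g%s\n", x$method,
              x$n_steps, x$final_time,
              if (x$extinct) " [extinct]" else ""))
  cat(sprintf("  %d samples of %d species; final counts: %s\n",
              length(x$times), length(x$species),
              paste(sprintf("%s=%g", x$species,
                            x$final_counts[x$species]), collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.ssa_trajectory <- function(x, ...) {
  data.frame(time = x$times, x$states, check.names = FALSE)
}

#' @export
plot.ssa_trajectory <- function(x, ...) {
  graphics::matplot(x$times, x$states, type = "s", lty = 1,
                    xlab = "time (s)", ylab = "molecule count", ...)
  graphics::legend("topright", legend = x$species, col = seq_along(x$species),
                   lty = 1, bty = "n")
  invisible(x)
}

#' Write a trajectory to TSV
#'
#' @param traj an `ssa_trajectory`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_trajectory_tsv <- function(traj, path) {
  utils::write.table(as.data.frame(traj), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# direct method (textbook SSA): full propensity rescan every step

direct_engine <- function(system, counts, max_steps = Inf, max_time = Inf,
                          record_interval = NULL, record_species = NULL,
                          accumulate_avg = FALSE) {
  rx <- system$reactions
  r1 <- rx$r1; r2 <- rx$r2; rate <- rx$rate
  selfm <- which(r1 == r2 & r1 != 1L)
  half <- if (system$self_half) 0.5 else 1
  sd <- stoich_deltas(system)
  aff <- sd$species; dlt <- sd$delta
  M <- system$M
  x <- unname(as.numeric(counts))
  x0 <- x
  rec_idx <- resolve_record_species(system, record_species)
  rec <- new_recorder(record_interval, rec_idx, max_time)
  t <- 0; steps <- 0; events <- numeric(M)
  avg_acc <- numeric(M); avg_time <- 0
  extinct <- FALSE
  repeat {
    if (steps >= max_steps) break
    a <- rate * x[r1] * x[r2]
    if (length(selfm)) {
      xs <- x[r1[selfm]]
      a[selfm] <- pmax(rate[selfm] * xs * (xs - 1) * half, 0)
    }
    a0 <- sum(a)
    if (a0 <= 0) { extinct <- TRUE; break }
    u1 <- stats::runif(1)
    cs <- cumsum(a)
    j <- findInterval(u1 * a0, cs) + 1L
    if (j > M) j <- max(which(a > 0))
    u2 <- stats::runif(1)
    tau <- log(1 / u2) / a0
    if (t + tau > max_time) {
      if (!is.null(rec)) rec_advance(rec, Inf, x)
      t <- max_time
      break
    }
    if (accumulate_avg) {
      avg_acc <- avg_acc + a * tau
      avg_time <- avg_time + tau
    }
    if (!is.null(rec)) rec_advance(rec, t + tau, x)
    t <- t + tau
    steps <- steps + 1
    events[j] <- events[j] + 1
    af <- aff[[j]]
    if (length(af)) {
      x[af] <- x[af] + dlt[[j]]
      if (min(x[af]) < 0)
        stop(sprintf("impossible event: firing %s drives a count negative",
                     rx$id[j]))
    }
  }
  if (extinct && is.finite(max_time)) {
    if (!is.null(rec)) rec_advance(rec, Inf, x)
    t <- max_time
  }
  list(x = x, x0 = x0, time = t, steps = steps, events = events,
       rec = if (!is.null(rec)) list(times = rec$times, S = rec$S, n = rec$n),
       rec_idx = rec_idx, extinct = extinct,
       avg_acc = avg_acc, avg_time = avg_time)
}

#' Simulate with the textbook direct-method SSA
#'
#' The reference engine: every step recomputes all M propensities, selects a
#' reaction from the weighted distribution, advances time exponentially and
#' applies the stoichiometry. Statistically this is the ground truth the
#' factored engine is checked against (the two engines are compared
#' distributionally, not path-wise: their data layouts map the same uniform
#' variate to different reactions).
#'
#' @param system a `reaction_system`.
#' @param max_time stop after this much simulated time (seconds).
#' @param max_steps stop after this many reaction events.
#' @param seed optional integer seed.
#' @param record_interval sampling interval (simulated seconds); the state is
#'   recorded sample-and-hold at each grid boundary. `NULL` records only the
#'   initial state.
#' @param record_species species ids (or indices) to record; default all.
#' @return an `ssa_trajectory`.
#' @export
run_direct <- function(system, max_time = Inf, max_steps = Inf, seed = NULL,
                       record_interval = NULL, record_species = NULL) {
  if (!is.finite(max_time) && !is.finite(max_steps))
    stop("set at least one stop criterion (max_time or max_steps)")
  if (!is.null(seed)) set.seed(seed)
  a0 <- total_propensity(system, initial_counts(system))
  if (a0 <= 0) {
    warning("degenerate system: initial total propensity is zero")
    return(new_trajectory("direct", system,
                          resolve_record_species(system, record_species),
                          NULL, initial_counts(system),
                          initial_counts(system), 0, 0,
                          numeric(system$M), TRUE))
  }
  res <- direct_engine(system, initial_counts(system), max_steps, max_time,
                       record_interval, record_species)
  new_trajectory("direct", system, res$rec_idx,
                 if (!is.null(res$rec)) res$rec, res$x0, res$x, res$time,
                 res$steps, res$events, res$extinct)
}

# ---------------------------------------------------------------------------
# the factored two-phase engine (hot loop over flat arrays)

lolcat_engine <- function(st, max_steps = Inf, max_time = Inf,
                          record_interval = NULL, record_species = NULL,
                          recompute_every = 1e6) {
  system <- st$system
  rx <- system$reactions
  k <- st$k
  half <- st$half
  n_clouds <- st$n_clouds

  # flatten all mutable trees (main tree first, then each primary tree)
  tree_objs <- c(list(st$main), st$prim)
  nd <- lapply(tree_objs, `[[`, "nodes")
  base <- c(0L, cumsum(lengths(nd)))[seq_along(nd)]
  TN <- unlist(nd, use.names = FALSE)
  hs <- vapply(tree_objs, `[[`, integer(1), "h")
  lvls <- lapply(tree_objs, `[[`, "lvl")
  mh <- hs[1L]
  mlvl <- lvls[[1L]]
  mleaf_off <- mlvl[mh + 1L]

  x <- st$x
  t <- st$time
  a0 <- st$a0
  P_sc <- st$P_sc
  sc_idx <- st$sc_idx
  sc_a <- st$sc_a
  nsc <- length(sc_idx)
  cl_factor <- st$cl_factor
  cl_R <- st$cl_R; cl_C <- st$cl_C; cl_aT <- st$cl_aT
  cl_Ccomp <- st$cl_Ccomp
  pl_rxn <- st$pl_rxn; pl_other <- st$pl_other
  pl_self <- st$pl_self; pl_rate <- st$pl_rate
  sub_s <- lapply(st$sub, function(ss) vapply(ss, `[[`, integer(1), "s"))
  sub_S <- lapply(st$sub, function(ss) vapply(ss, `[[`, numeric(1), "S"))
  sub_rxn <- lapply(st$sub, function(ss) lapply(ss, `[[`, "rxn"))
  sub_tree <- lapply(st$sub, function(ss) lapply(ss, `[[`, "tree"))
  prog <- st$prog
  rr1 <- rx$r1; rr2 <- rx$r2; rrate <- rx$rate
  selff <- rr1 == rr2 & rr1 != 1L
  sc_r1 <- rr1[sc_idx]; sc_r2 <- rr2[sc_idx]; sc_rate <- rrate[sc_idx]
  sc_self <- selff[sc_idx]

  rec_idx <- resolve_record_species(system, record_species)
  rec <- new_recorder(record_interval, rec_idx, max_time)
  x0 <- x
  events <- numeric(system$M)
  steps <- 0
  extinct <- FALSE
  n_cloud_updates <- 0; n_sc_refresh <- 0
  n_tree_writes <- 0; n_comparisons <- 0

  flat_recompute <- function() {
    # rebuild every cached quantity from x (drift control); mirrors
    # recompute_structures over the flat layout
    for (ci in seq_len(n_clouds)) {
      d <- ci + 1L
      f <- cl_factor[ci]
      nlv <- length(pl_rxn[[ci]])
      leaf_w <- if (nlv) pmax(ifelse(pl_self[[ci]],
                                     pl_rate[[ci]] * (x[f] - 1) * half,
                                     pl_rate[[ci]] * x[pl_other[[ci]]]), 0)
                else numeric(0)
      cap <- k^hs[d]
      leaves <- numeric(cap)
      leaves[seq_len(nlv)] <- leaf_w
      TN[base[d] + lvls[[d]][hs[d] + 1L] + seq_len(cap)] <<- leaves
      if (hs[d] > 0L) for (l in seq(hs[d] - 1L, 0L)) {
        nn <- k^l
        o2 <- base[d] + lvls[[d]][l + 2L]
        o1 <- base[d] + lvls[[d]][l + 1L]
        TN[(o1 + 1L):(o1 + nn)] <<- colSums(matrix(TN[(o2 + 1L):(o2 + nn * k)],
                                                   nrow = k))
      }
      cl_R[ci] <<- TN[base[d] + 1L]
      cl_C[ci] <<- if (length(sub_S[[ci]])) sum(x[sub_s[[ci]]] * sub_S[[ci]]) else 0
      cl_Ccomp[ci] <<- 0
      cl_aT[ci] <<- x[f] * (cl_R[ci] + cl_C[ci])
    }
    if (n_clouds > 0L) {
      cap <- k^mh
      leaves <- numeric(cap)
      leaves[seq_len(n_clouds)] <- cl_aT
      TN[mleaf_off + seq_len(cap)] <<- leaves
      if (mh > 0L) for (l in seq(mh - 1L, 0L)) {
        nn <- k^l
        o2 <- mlvl[l + 2L]
        o1 <- mlvl[l + 1L]
        TN[(o1 + 1L):(o1 + nn)] <<- colSums(matrix(TN[(o2 + 1L):(o2 + nn * k)],
                                                   nrow = k))
      }
    }
    if (nsc) {
      xa <- x[sc_r1]
      asc <- sc_rate * xa * x[sc_r2]
      if (any(sc_self)) asc[sc_self] <- pmax(
        sc_rate[sc_self] * xa[sc_self] * (xa[sc_self] - 1) * half, 0)
      sc_a <<- asc
    }
    P_sc <<- sum(sc_a)
    a0 <<- P_sc + TN[1L]
  }

  repeat {
    if (steps >= max_steps) break
    if (a0 <= 0) { extinct <- TRUE; break }
    if (recompute_every > 0 && steps > 0 && steps %% recompute_every == 0)
      flat_recompute()

    # ---- Phase 1: choose a reaction -------------------------------------
    u1 <- stats::runif(1)
    r <- u1 * a0
    m <- 0L
    if (nsc && r < P_sc) {
      for (e in seq_len(nsc)) {
        w <- sc_a[e]
        n_comparisons <- n_comparisons + 1
        if (r < w) { m <- sc_idx[e]; break }
        r <- r - w
      }
      if (m == 0L) {  # float fallthrough inside the cache
        pos <- which(sc_a > 0)
        m <- sc_idx[pos[length(pos)]]
      }
    } else {
      rr <- r - P_sc
      root <- TN[1L]
      if (root <= 0) {
        pos <- which(sc_a > 0)
        if (!length(pos)) stop("internal consistency error: no selectable reaction")
        m <- sc_idx[pos[length(pos)]]
      } else {
        if (rr >= root) rr <- root * (1 - 1e-16)
        pos <- 1L
        if (mh > 0L) for (l in seq_len(mh)) {
          bb <- (pos - 1L) * k
          off <- mlvl[l + 1L]
          taken <- FALSE; last_pos <- 0L; last_w <- 0
          for (cc in seq_len(k)) {
            w <- TN[off + bb + cc]
            n_comparisons <- n_comparisons + 1
            if (w > 0) { last_pos <- bb + cc; last_w <- w }
            if (rr < w) { pos <- bb + cc; taken <- TRUE; break }
            rr <- rr - w
          }
          if (!taken) { pos <- last_pos; rr <- last_w * (1 - 1e-15) }
        }
        ci <- min(pos, n_clouds)
        # ---- within the cloud ----
        f <- cl_factor[ci]
        xT <- x[f]
        rp <- rr / xT
        R <- cl_R[ci]
        if (rp < R) {
          d <- ci + 1L
          pos <- 1L
          if (hs[d] > 0L) for (l in seq_len(hs[d])) {
            bb <- (pos - 1L) * k
            off <- base[d] + lvls[[d]][l + 1L]
            taken <- FALSE; last_pos <- 0L; last_w <- 0
            for (cc in seq_len(k)) {
              w <- TN[off + bb + cc]
              n_comparisons <- n_comparisons + 1
              if (w > 0) { last_pos <- bb + cc; last_w <- w }
              if (rp < w) { pos <- bb + cc; taken <- TRUE; break }
              rp <- rp - w
            }
            if (!taken) { pos <- last_pos; rp <- last_w * (1 - 1e-15) }
          }
          m <- pl_rxn[[ci]][min(pos, length(pl_rxn[[ci]]))]
        } else {
          rp <- rp - R
          ss <- sub_s[[ci]]
          SS <- sub_S[[ci]]
          for (j in seq_along(ss)) {
            w <- x[ss[j]] * SS[j]
            n_comparisons <- n_comparisons + 1
            if (rp < w) {
              rt <- rp / x[ss[j]]
              if (rt >= SS[j]) rt <- SS[j] * (1 - 1e-16)
              loc <- locate(sub_tree[[ci]][[j]], rt)
              m <- sub_rxn[[ci]][[j]][min(loc$index, length(sub_rxn[[ci]][[j]]))]
              break
            }
            rp <- rp - w
          }
          if (m == 0L) {  # float fallthrough at the cloud's right edge
            for (j in rev(seq_along(ss))) {
              if (x[ss[j]] * SS[j] > 0) {
                loc <- locate(sub_tree[[ci]][[j]], SS[j] * (1 - 1e-15))
                m <- sub_rxn[[ci]][[j]][min(loc$index, length(sub_rxn[[ci]][[j]]))]
                break
              }
            }
            if (m == 0L && R > 0) {
              d <- ci + 1L
              loc_r <- R * (1 - 1e-15)
              pos <- 1L
              if (hs[d] > 0L) for (l in seq_len(hs[d])) {
                bb <- (pos - 1L) * k
                off <- base[d] + lvls[[d]][l + 1L]
                taken <- FALSE; last_pos <- 0L; last_w <- 0
                for (cc in seq_len(k)) {
                  w <- TN[off + bb + cc]
                  if (w > 0) { last_pos <- bb + cc; last_w <- w }
                  if (loc_r < w) { pos <- bb + cc; taken <- TRUE; break }
                  loc_r <- loc_r - w
                }
                if (!taken) { pos <- last_pos; loc_r <- last_w * (1 - 1e-15) }
              }
              m <- pl_rxn[[ci]][min(pos, length(pl_rxn[[ci]]))]
            }
            if (m == 0L) stop("internal consistency error: empty cloud selected")
          }
        }
      }
    }

    # ---- Phase 2: execute ------------------------------------------------
    u2 <- stats::runif(1)
    tau <- log(1 / u2) / a0
    if (t + tau > max_time) {
      if (!is.null(rec)) rec_advance(rec, Inf, x)
      t <- max_time
      break
    }
    if (!is.null(rec)) {
      before <- rec$n
      rec_advance(rec, t + tau, x)
      if (rec$n > before) flat_recompute()  # drift control at checkpoints
    }
    t <- t + tau
    steps <- steps + 1
    events[m] <- events[m] + 1

    pr <- prog[[m]]
    sp <- pr$sp
    if (length(sp)) {
      x[sp] <- x[sp] + pr$d
      if (min(x[sp]) < 0)
        stop(sprintf("impossible event: firing %s drives a count negative",
                     rx$id[m]))
    }
    ops <- pr$ops
    vals <- pr$val
    nop <- nrow(ops)
    if (nop) for (i in seq_len(nop)) {
      kind <- ops[i, 1L]
      if (kind == 4L) {
        e <- ops[i, 2L]
        q <- sc_idx[e]
        xa <- x[rr1[q]]
        a_new <- if (selff[q]) {
          v <- rrate[q] * xa * (xa - 1) * half
          if (v > 0) v else 0
        } else rrate[q] * xa * x[rr2[q]]
        P_sc <- P_sc + (a_new - sc_a[e])
        sc_a[e] <- a_new
        n_sc_refresh <- n_sc_refresh + 1
      } else {
        ci <- ops[i, 2L]
        f <- cl_factor[ci]
        if (kind == 2L || kind == 5L) {
          leaf <- ops[i, 3L]
          v <- if (kind == 2L) {
            pl_rate[[ci]][leaf] * x[pl_other[[ci]][leaf]]
          } else {
            vv <- pl_rate[[ci]][leaf] * (x[f] - 1) * half
            if (vv > 0) vv else 0
          }
          d <- ci + 1L
          lp <- base[d] + lvls[[d]][hs[d] + 1L] + leaf
          if (v != TN[lp]) {
            TN[lp] <- v
            jj <- leaf
            if (hs[d] > 0L) for (l in seq(hs[d] - 1L, 0L)) {
              jj <- (jj - 1L) %/% k + 1L
              cb <- base[d] + lvls[[d]][l + 2L] + (jj - 1L) * k
              acc <- 0
              for (cc in seq_len(k)) acc <- acc + TN[cb + cc]
              TN[base[d] + lvls[[d]][l + 1L] + jj] <- acc
            }
            n_tree_writes <- n_tree_writes + hs[d] + 1
          }
          cl_R[ci] <- TN[base[d] + 1L]
        } else if (kind == 3L) {
          y <- vals[i] - cl_Ccomp[ci]
          tt <- cl_C[ci] + y
          cl_Ccomp[ci] <- (tt - cl_C[ci]) - y
          cl_C[ci] <- tt
        }
        aT <- x[f] * (cl_R[ci] + cl_C[ci])
        lp <- mleaf_off + ci
        if (aT != TN[lp]) {
          TN[lp] <- aT
          jj <- ci
          if (mh > 0L) for (l in seq(mh - 1L, 0L)) {
            jj <- (jj - 1L) %/% k + 1L
            cb <- mlvl[l + 2L] + (jj - 1L) * k
            acc <- 0
            for (cc in seq_len(k)) acc <- acc + TN[cb + cc]
            TN[mlvl[l + 1L] + jj] <- acc
          }
          n_tree_writes <- n_tree_writes + mh + 1
        }
        cl_aT[ci] <- aT
        n_cloud_updates <- n_cloud_updates + 1
      }
    }
    acc <- 0
    for (e in seq_len(nsc)) acc <- acc + sc_a[e]
    P_sc <- acc
    a0 <- P_sc + TN[1L]
  }

  if (extinct && is.finite(max_time)) {
    if (!is.null(rec)) rec_advance(rec, Inf, x)
    t <- max_time
  }

  # write the flat layout back into the structure objects
  st$x <- x
  st$time <- t
  st$a0 <- a0
  st$P_sc <- P_sc
  st$sc_a <- sc_a
  st$cl_R <- cl_R; st$cl_C <- cl_C; st$cl_aT <- cl_aT
  st$cl_Ccomp <- cl_Ccomp
  for (d in seq_along(tree_objs)) {
    tree_objs[[d]]$nodes <- TN[(base[d] + 1L):(base[d] + length(nd[[d]]))]
  }
  st$main <- tree_objs[[1L]]
  if (n_clouds > 0L) st$prim <- tree_objs[-1L]

  list(st = st, x = x, x0 = x0, time = t, steps = steps, events = events,
       rec = if (!is.null(rec)) list(times = rec$times, S = rec$S, n = rec$n),
       rec_idx = rec_idx, extinct = extinct,
       ops = list(cloud_updates = n_cloud_updates,
                  sc_refreshes = n_sc_refresh,
                  tree_writes = n_tree_writes,
                  comparisons = n_comparisons,
                  per_step = if (steps > 0)
                    c(cloud_updates = n_cloud_updates / steps,
                      sc_refreshes = n_sc_refresh / steps,
                      tree_writes = n_tree_writes / steps,
                      comparisons = n_comparisons / steps)
                  else c(cloud_updates = 0, sc_refreshes = 0,
                         tree_writes = 0, comparisons = 0)))
}

#' Simulate with the factored two-phase engine
#'
#' Preprocesses the system (trial run, super-cache, greedy clouds, bipartite
#' update graph, compiled update programs) and then iterates the two-phase
#' algorithm: Phase 1 maps a uniform variate to a reaction via super-cache
#' scan and tree descents; Phase 2 advances time and replays the fired
#' reaction's compiled update program. Selection probabilities are exactly
#' `a_j / a0` at every step, so the produced trajectories are statistically
#' identical to the direct method's.
#'
#' @inheritParams run_direct
#' @param k tree branching factor.
#' @param supercache_size super-cache capacity.
#' @param subtree_threshold minimum shared-partner group for a sub-tree.
#' @param trial_steps trial-run length used to estimate average propensities
#'   (0 = use initial propensities).
#' @param profile optional precomputed average-propensity vector (skips the
#'   trial run).
#' @param recompute_every rebuild all cached sums from scratch every this many
#'   steps (floating-point drift control); they are also rebuilt at every
#'   recording checkpoint.
#' @param structures optional prebuilt `sim_structures` (counts and caches are
#'   used as-is; `system` may be omitted then).
#' @param return_structures if `TRUE` the final `sim_structures` is attached
#'   to the result as `$structures`.
#' @return an `ssa_trajectory`; `$ops` holds per-step operation counters
#'   (cloud structure updates, super-cache refreshes, tree node writes,
#'   comparisons).
#' @export
run_lolcat <- function(system, max_time = Inf, max_steps = Inf, seed = NULL,
                       record_interval = NULL, record_species = NULL,
                       k = 4L, supercache_size = 16L, subtree_threshold = 3L,
                       trial_steps = 1e5, profile = NULL,
                       recompute_every = 1e6, structures = NULL,
                       return_structures = FALSE) {
  if (!is.finite(max_time) && !is.finite(max_steps))
    stop("set at least one stop criterion (max_time or max_steps)")
  if (!is.null(seed)) set.seed(seed)
  st <- if (!is.null(structures)) structures
  else build_sim_structures(system, profile = profile, k = k,
                            supercache_size = supercache_size,
                            subtree_threshold = subtree_threshold,
                            trial_steps = trial_steps)
  system <- st$system
  if (st$a0 <= 0) {
    warning("degenerate system: initial total propensity is zero")
    traj <- new_trajectory("lolcat", system,
                           resolve_record_species(system, record_species),
                           NULL, st$x, st$x, 0, 0, numeric(system$M), TRUE)
    if (return_structures) traj$structures <- st
    return(traj)
  }
  res <- lolcat_engine(st, max_steps, max_time, record_interval,
                       record_species, recompute_every)
  traj <- new_trajectory("lolcat", system, res$rec_idx,
                         if (!is.null(res$rec)) res$rec, res$x0, res$x,
                         res$time, res$steps, res$events, res$extinct,
                         ops = res$ops)
  if (return_structures) traj$structures <- res$st
  traj
}

# ---------------------------------------------------------------------------
# ODM baseline: propensity-sorted array + (clique | bipartite) update graph

#' Simulate with the optimized-direct-method baseline
#'
#' ODM keeps reactions in an array sorted by descending trial-run average
#' propensity and selects by linear scan; after a firing it recomputes exactly
#' the propensities its update dependency graph prescribes. With
#' `udg = "clique"` that is the reaction-to-reaction graph (per-step update
#' count = the fired reaction's valence); with `udg = "bipartite"` (the MODM
#' variant) the affected species' reactant lists are walked instead. Used for
#' operation-count comparisons against the factored engine, not for speed.
#'
#' @inheritParams run_direct
#' @param udg `"clique"` or `"bipartite"`.
#' @param trial_steps trial-run length for the sort order (0 = initial
#'   propensities).
#' @param profile optional precomputed average-propensity vector.
#' @param recompute_every full propensity refresh period (drift control).
#' @return an `ssa_trajectory` with `$ops` counters: per-step propensity
#'   updates and scan comparisons, plus `$order` (the sorted reaction array).
#' @export
run_odm <- function(system, max_time = Inf, max_steps = Inf, seed = NULL,
                    udg = c("clique", "bipartite"),
                    record_interval = NULL, record_species = NULL,
                    trial_steps = 1e5, profile = NULL,
                    recompute_every = 1e4) {
  udg <- match.arg(udg)
  if (!is.finite(max_time) && !is.finite(max_steps))
    stop("set at least one stop criterion (max_time or max_steps)")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(profile))
    profile <- sample_average_propensities(system, n_steps = trial_steps)
  rx <- system$reactions
  M <- system$M
  arr <- order(-profile, seq_len(M))
  budg <- build_bipartite_udg(system)
  if (udg == "clique") {
    nb <- build_clique_udg(system, budg)
    fanout <- lengths(nb)
  } else {
    nb <- vector("list", M)
    fanout <- numeric(M)
    for (u in seq_len(M)) {
      af <- budg$aff[[u]]
      nb[[u]] <- if (length(af))
        sort(unique(unlist(budg$sp2rx[af], use.names = FALSE)))
      else integer(0)
      fanout[u] <- sum(lengths(budg$sp2rx[af]))
    }
  }
  r1 <- rx$r1; r2 <- rx$r2; rate <- rx$rate
  selfm <- r1 == r2 & r1 != 1L
  half <- if (system$self_half) 0.5 else 1
  prop_of <- function(idx) {
    xa <- x[r1[idx]]
    a <- rate[idx] * xa * x[r2[idx]]
    s <- selfm[idx]
    if (any(s)) a[s] <- pmax(rate[idx][s] * xa[s] * (xa[s] - 1) * half, 0)
    a
  }
  x <- unname(as.numeric(initial_counts(system)))
  x0 <- x
  a <- prop_of(seq_len(M))
  a0 <- sum(a)
  rec_idx <- resolve_record_species(system, record_species)
  rec <- new_recorder(record_interval, rec_idx, max_time)
  t <- 0; steps <- 0; events <- numeric(M)
  n_updates <- 0; n_comparisons <- 0
  extinct <- FALSE
  if (a0 <= 0) {
    warning("degenerate system: initial total propensity is zero")
    extinct <- TRUE
  } else repeat {
    if (steps >= max_steps) break
    if (a0 <= 0) { extinct <- TRUE; break }
    if (recompute_every > 0 && steps > 0 && steps %% recompute_every == 0) {
      a <- prop_of(seq_len(M))
      a0 <- sum(a)
      if (a0 <= 0) { extinct <- TRUE; break }
    }
    u1 <- stats::runif(1)
    cs <- cumsum(a[arr])
    p <- findInterval(u1 * a0, cs) + 1L
    if (p > M) p <- max(which(a[arr] > 0))
    n_comparisons <- n_comparisons + p
    j <- arr[p]
    u2 <- stats::runif(1)
    tau <- log(1 / u2) / a0
    if (t + tau > max_time) {
      if (!is.null(rec)) rec_advance(rec, Inf, x)
      t <- max_time
      break
    }
    if (!is.null(rec)) rec_advance(rec, t + tau, x)
    t <- t + tau
    steps <- steps + 1
    events[j] <- events[j] + 1
    af <- budg$aff[[j]]
    if (length(af)) {
      x[af] <- x[af] + budg$dlt[[j]]
      if (min(x[af]) < 0)
        stop(sprintf("impossible event: firing %s drives a count negative",
                     rx$id[j]))
    }
    upd <- nb[[j]]
    if (length(upd)) {
      anew <- prop_of(upd)
      a0 <- a0 + sum(anew - a[upd])
      a[upd] <- anew
    }
    n_updates <- n_updates + fanout[j]
  }
  if (extinct && is.finite(max_time)) {
    if (!is.null(rec)) rec_advance(rec, Inf, x)
    t <- max_time
  }
  traj <- new_trajectory(paste0("odm-", udg), system, rec_idx,
                         if (!is.null(rec)) list(times = rec$times, S = rec$S,
                                                 n = rec$n),
                         x0, x, t, steps, events, extinct,
                         ops = list(prop_updates = n_updates,
                                    comparisons = n_comparisons,
                                    per_step = if (steps > 0)
                                      c(prop_updates = n_updates / steps,
                                        comparisons = n_comparisons / steps)
                                    else c(prop_updates = 0, comparisons = 0)))
  traj$order <- arr
  traj
}
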