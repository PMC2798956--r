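#' Generate a random hub ("super-species") reaction network
#'
#' Emulates the structural signature of large biochemical models: a few hub
#' species (think ATP) participate as reactants in a large, controllable
#' fraction of reactions, and log-uniform rates over four decades combined
#' with large hub counts produce a heavy-tailed propensity distribution.
#' Exactly `round(hub_participation * n_reactions)` reactions get a hub as
#' first reactant with a uniformly drawn non-hub partner; the remaining
#' reactions draw both reactants uniformly among non-hubs (occasionally
#' yielding natural self-reactions).
#'
#' The network is built as a closed, mass-conserving recycling system so that
#' long stress runs do not stall in an absorbing state: every hub-consuming
#' reaction returns a (uniformly chosen) hub as its first product --
#' mirroring how real super-species pools such as ATP/ADP are continuously
#' regenerated -- and all other product slots are drawn uniformly among the
#' non-hubs, so both the hub pool and the non-hub molecule count are
#' conserved. A `catalytic_fraction` of reactions reappear their first
#' reactant literally as product (zero net delta, exercising the net-delta
#' rule of the update graph), every non-hub is patched to occur at least once
#' as a reactant (no token sinks), and any species still unused is patched
#' into a product slot. Deterministic given `seed`.
#'
#' @param n_species total species count (hubs included).
#' @param n_reactions number of reactions.
#' @param hub_count number of hub species (`>= 1` when participation > 0).
#' @param hub_participation fraction of reactions with a hub reactant.
#' @param rate_range log-uniform bounds for the rate constants.
#' @param count_range integer bounds (inclusive) for non-hub initial counts.
#' @param hub_initial initial count of each hub species.
#' @param catalytic_fraction fraction of reactions made catalytic.
#' @param seed integer seed (default 1).
#' @return a validated `reaction_system`; the generating parameters are kept
#'   in attribute `"hub_spec"`.
#' @export
generate_hub_network <- function(n_species = 50, n_reactions = 500,
                                 hub_count = 2, hub_participation = 0.9,
                                 rate_range = c(1e-2, 1e2),
                                 count_range = c(0, 100),
                                 hub_initial = 1000,
                                 catalytic_fraction = 0.1, seed = 1L) {
  if (hub_count >= n_species) stop("hub_count must be smaller than n_species")
  if (hub_participation < 0 || hub_participation > 1)
    stop("hub_participation must lie in [0, 1]")
  n_hub_rxn <- round(hub_participation * n_reactions)
  if (n_hub_rxn > 0 && hub_count < 1)
    stop("hub participation requested but hub_count is 0")
  if (n_species - hub_count < 1)
    stop("at least one non-hub species is required")
  set.seed(seed)
  ids <- c(if (hub_count > 0) sprintf("h%d", seq_len(hub_count)),
           sprintf("s%d", seq_len(n_species - hub_count)))
  hubs <- seq_len(hub_count)
  nonhubs <- setdiff(seq_len(n_species), hubs)
  counts <- integer(n_species)
  counts[hubs] <- hub_initial
  counts[nonhubs] <- sample(seq(count_range[1], count_range[2]),
                            length(nonhubs), replace = TRUE)

  M <- n_reactions
  nh <- length(nonhubs)
  r1 <- integer(M); r2 <- integer(M)
  if (n_hub_rxn > 0) {
    r1[1:n_hub_rxn] <- hubs[sample.int(hub_count, n_hub_rxn, replace = TRUE)]
    r2[1:n_hub_rxn] <- nonhubs[sample.int(nh, n_hub_rxn, replace = TRUE)]
  }
  if (n_hub_rxn < M) {
    rest <- (n_hub_rxn + 1):M
    r1[rest] <- nonhubs[sample.int(nh, length(rest), replace = TRUE)]
    r2[rest] <- nonhubs[sample.int(nh, length(rest), replace = TRUE)]
  }
  # hub-consuming reactions convert the consumed hub into a *different* hub
  # (an ATP -> ADP style cycle: the super-species pool is conserved but hub
  # counts change on almost every firing); everything else moves tokens among
  # the non-hubs
  p1 <- integer(M)
  is_hub_rxn <- seq_len(M) <= n_hub_rxn
  if (n_hub_rxn > 0) {
    if (hub_count >= 2L) {
      i1 <- match(r1[is_hub_rxn], hubs)
      off <- sample.int(hub_count - 1L, n_hub_rxn, replace = TRUE)
      p1[is_hub_rxn] <- hubs[((i1 - 1L + off) %% hub_count) + 1L]
    } else {
      p1[is_hub_rxn] <- r1[is_hub_rxn]  # single hub: degenerate catalytic pool
    }
  }
  if (n_hub_rxn < M)
    p1[!is_hub_rxn] <- nonhubs[sample.int(nh, M - n_hub_rxn, replace = TRUE)]
  p2 <- nonhubs[sample.int(nh, M, replace = TRUE)]
  n_cat <- round(catalytic_fraction * M)
  if (n_cat > 0) {
    cat_idx <- sample.int(M, n_cat)
    p1[cat_idx] <- r1[cat_idx]
  }
  # avoid token sinks where capacity allows: place species that never occur
  # as a reactant into slots whose occupant is a reactant elsewhere too
  react_count <- tabulate(c(r1, r2), nbins = n_species)
  missing_r <- nonhubs[react_count[nonhubs] == 0L]
  if (length(missing_r)) {
    slot_rxn <- c(seq_len(M), if (n_hub_rxn < M) (n_hub_rxn + 1L):M)
    slot_side <- c(rep(2L, M), rep(1L, max(M - n_hub_rxn, 0L)))
    si <- 1L
    for (s in missing_r) {
      while (si <= length(slot_rxn)) {
        j <- slot_rxn[si]; side <- slot_side[si]
        occ <- if (side == 2L) r2[j] else r1[j]
        si <- si + 1L
        if (react_count[occ] >= 2L) {
          react_count[occ] <- react_count[occ] - 1L
          if (side == 2L) r2[j] <- s else r1[j] <- s
          react_count[s] <- 1L
          break
        }
      }
      if (si > length(slot_rxn)) break  # capacity exhausted; best effort
    }
  }
  # guarantee every species appears in some reaction
  used <- unique(c(r1, r2, p1, p2))
  missing <- setdiff(seq_len(n_species), used)
  if (length(missing) > M)
    stop("infeasible spec: more unused species than reactions to patch")
  if (length(missing)) p2[seq_along(missing)] <- missing
  rate <- exp(stats::runif(M, log(rate_range[1]), log(rate_range[2])))

  sys <- reaction_system(
    data.frame(id = ids, count = counts, stringsAsFactors = FALSE),
    data.frame(id = sprintf("R%d", seq_len(M)),
               r1 = ids[r1], r2 = ids[r2], p1 = ids[p1], p2 = ids[p2],
               rate = rate, stringsAsFactors = FALSE))
  attr(sys, "hub_spec") <- list(n_species = n_species, n_reactions = M,
                                hub_count = hub_count,
                                hub_participation = hub_participation,
                                rate_range = rate_range,
                                count_range = count_range,
                                hub_initial = hub_initial,
                                catalytic_fraction = catalytic_fraction,
                                seed = seed, hubs = ids[hubs])
  sys
}

#' Canonical analytically solvable test models
#'
#' Small systems with closed-form facts used as statistical oracles:
#' \describe{
#'   \item{immigration_death}{`0 -> A` at rate 10/s, `A -> 0` at 1/s per
#'     molecule, from `x_A = 0`; the stationary law is Poisson with mean and
#'     variance `lambda/gamma = 10` (an M/M/infinity queue).}
#'   \item{decay}{`A -> 0` at 1/s from `x_A = 1000`; `E x(t) = 1000 e^{-t}`.}
#'   \item{isomerization}{symmetric `A <-> B` at 1/s with 100 molecules;
#'     stationary mean of `x_A` is 50.}
#'   \item{dimerization}{`A + A -> B` from even `x_A = 100`; consumes A in
#'     pairs, so the parity of `x_A` is invariant.}
#'   \item{enzyme_toy}{five substrates bind a shared enzyme hub
#'     (`E + S_i -> C_i`, `C_i -> E + P_i`), exercising clouds whose
#'     factor-species is the enzyme.}
#' }
#'
#' @param name one of the model names above.
#' @return `list(system = reaction_system, facts = list(...))` where `facts`
#'   holds the model's analytic quantities.
#' @export
canonical_model <- function(name = c("immigration_death", "decay",
                                     "isomerization", "dimerization",
                                     "enzyme_toy")) {
  name <- match.arg(name)
  switch(name,
    immigration_death = list(
      system = reaction_system(
        data.frame(id = "A", count = 0),
        data.frame(id = c("birth", "death"),
                   r1 = c(NA, "A"), r2 = c(NA, NA),
                   p1 = c("A", NA), p2 = c(NA, NA),
                   rate = c(10, 1))),
      facts = list(lambda = 10, gamma = 1, stationary_mean = 10,
                   stationary_var = 10, fano = 1)),
    decay = list(
      system = reaction_system(
        data.frame(id = "A", count = 1000),
        data.frame(id = "decay", r1 = "A", r2 = NA, p1 = NA, p2 = NA,
                   rate = 1)),
      facts = list(x0 = 1000, c = 1,
                   mean_at = function(t) 1000 * exp(-t))),
    isomerization = list(
      system = reaction_system(
        data.frame(id = c("A", "B"), count = c(100, 0)),
        data.frame(id = c("ab", "ba"), r1 = c("A", "B"), r2 = c(NA, NA),
                   p1 = c("B", "A"), p2 = c(NA, NA), rate = c(1, 1))),
      facts = list(total = 100, stationary_mean_A = 50)),
    dimerization = list(
      system = reaction_system(
        data.frame(id = c("A", "B"), count = c(100, 0)),
        data.frame(id = "dim", r1 = "A", r2 = "A", p1 = "B", p2 = NA,
                   rate = 0.01)),
      facts = list(x0 = 100, parity = 0)),
    enzyme_toy = {
      ns <- 5
      sub_ids <- sprintf("S%d", seq_len(ns))
      cpx_ids <- sprintf("C%d", seq_len(ns))
      prd_ids <- sprintf("P%d", seq_len(ns))
      list(
        system = reaction_system(
          data.frame(id = c("E", sub_ids, cpx_ids, prd_ids),
                     count = c(10, rep(50, ns), rep(0, ns), rep(0, ns))),
          data.frame(id = c(sprintf("bind%d", seq_len(ns)),
                            sprintf("cat%d", seq_len(ns))),
                     r1 = c(rep("E", ns), cpx_ids),
                     r2 = c(sub_ids, rep(NA, ns)),
                     p1 = c(cpx_ids, rep("E", ns)),
                     p2 = c(rep(NA, ns), prd_ids),
                     rate = c(rep(0.01, ns), rep(1, ns)))),
        facts = list(enzyme_total = 10,
                     conserved = "E + sum(C_i) is invariant"))
    })
}
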