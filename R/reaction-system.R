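#' Mass-action reaction systems
#'
#' A `reaction_system` is an immutable description of a well-mixed chemical
#' system: species with non-negative integer initial counts, and mass-action
#' reactions with at most two reactants, at most two products, and a constant
#' stochastic rate. Zero- and first-order reactions are encoded uniformly via
#' the omnipresent placeholder species `"0"`, which sits at index 1 with a
#' frozen count of 1 and is never mutated; empty reactant/product slots are
#' padded with it. Reactions with more than two reactants or products are
#' rejected (decomposition into binary reactions is the modeler's job).
#'
#' @param species data.frame with columns `id` (character, unique, `"0"` is
#'   reserved) and `count` (non-negative integers).
#' @param reactions data.frame with columns `id` (character), `r1`, `r2`,
#'   `p1`, `p2` (species ids; `"0"` or `NA` marks an empty slot) and `rate`
#'   (positive numeric, the stochastic rate constant).
#' @param self_half logical; if `TRUE` (default) a self-reaction `A + A -> ...`
#'   has propensity `c * x * (x - 1) / 2` (the standard combinatorial
#'   convention); if `FALSE` the divisor 2 is dropped.
#' @return an object of class `reaction_system` with elements `species`
#'   (including the placeholder at row 1), `reactions` (slots as integer
#'   species indices, real reactant/product first within each pair), `N`, `M`,
#'   and `self_half`.
#' @examples
#' sys <- reaction_system(
#'   data.frame(id = c("A", "B", "C"), count = c(3, 4, 0)),
#'   data.frame(id = "R1", r1 = "A", r2 = "B", p1 = "C", p2 = NA, rate = 2)
#' )
#' propensities(sys, initial_counts(sys))  # 24
#' @export
reaction_system <- function(species, reactions, self_half = TRUE) {
  species <- as.data.frame(species, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "count") %in% names(species)),
            all(c("id", "r1", "r2", "p1", "p2", "rate") %in% names(reactions)))
  sid <- as.character(species$id)
  if (any(sid == "0")) stop("species id \"0\" is reserved for the omnipresent placeholder")
  if (anyDuplicated(sid)) stop("duplicate species ids: ",
                               paste(unique(sid[duplicated(sid)]), collapse = ", "))
  cnt <- as.numeric(species$count)
  if (anyNA(cnt) || any(cnt < 0) || any(cnt != floor(cnt)))
    stop("species counts must be non-negative integers")

  sp <- data.frame(id = c("0", sid), count = c(1, cnt), stringsAsFactors = FALSE)
  N <- nrow(sp)

  resolve <- function(x) {
    x <- as.character(x)
    x[is.na(x) | x == ""] <- "0"
    idx <- match(x, sp$id)
    if (anyNA(idx))
      stop("undeclared species referenced: ",
           paste(unique(x[is.na(idx)]), collapse = ", "))
    idx
  }
  r1 <- resolve(reactions$r1); r2 <- resolve(reactions$r2)
  p1 <- resolve(reactions$p1); p2 <- resolve(reactions$p2)
  # canonical slot order: real species before the placeholder
  swap <- r1 == 1L & r2 != 1L
  tmp <- r1[swap]; r1[swap] <- r2[swap]; r2[swap] <- tmp
  swap <- p1 == 1L & p2 != 1L
  tmp <- p1[swap]; p1[swap] <- p2[swap]; p2[swap] <- tmp

  rate <- as.numeric(reactions$rate)
  if (anyNA(rate) || any(rate <= 0)) stop("reaction rates must be positive")
  rid <- as.character(reactions$id)
  if (anyDuplicated(rid)) stop("duplicate reaction ids")

  rx <- data.frame(id = rid, r1 = r1, r2 = r2, p1 = p1, p2 = p2, rate = rate,
                   stringsAsFactors = FALSE)
  structure(list(species = sp, reactions = rx, N = N, M = nrow(rx),
                 self_half = isTRUE(self_half)),
            class = "reaction_system")
}

#' Initial molecule counts of a system
#'
#' @param system a `reaction_system`.
#' @return numeric vector of length `N` (placeholder count 1 at position 1),
#'   named by species id.
#' @export
initial_counts <- function(system) {
  x <- system$species$count
  names(x) <- system$species$id
  x
}

#' @export
print.reaction_system <- function(x, ...) {
  cat(sprintf("reaction_system: %d species (+ placeholder), %d reactions\n",
              x$N - 1L, x$M))
  cat(sprintf("self-reaction convention: c*x*(x-1)%s\n",
              if (x$self_half) "/2" else ""))
  invisible(x)
}

#' Mass-action propensities of all reactions at a given state
#'
#' For distinct reactants the propensity is `c * x_i * x_j`; for a self
#' reaction `A + A -> ...` it is `c * x * (x - 1) / 2` under the default
#' convention (see [reaction_system()]); the placeholder contributes a factor
#' of 1, so a first-order reaction has propensity `c * x` and a zero-order
#' reaction propensity `c`.
#'
#' @param system a `reaction_system`.
#' @param counts numeric vector of length `N` of current molecule counts
#'   (placeholder first, count 1).
#' @return numeric vector of length `M` of non-negative propensities.
#' @export
propensities <- function(system, counts) {
  if (anyNA(counts) || any(counts < 0)) stop("invalid state: negative or missing count")
  rx <- system$reactions
  xa <- counts[rx$r1]
  xb <- counts[rx$r2]
  a <- rx$rate * xa * xb
  self <- rx$r1 == rx$r2 & rx$r1 != 1L
  if (any(self)) {
    half <- if (system$self_half) 0.5 else 1
    a[self] <- rx$rate[self] * xa[self] * (xa[self] - 1) * half
  }
  unname(pmax(a, 0))
}

#' Propensity of a single reaction
#'
#' @inheritParams propensities
#' @param j reaction index in `1:M`.
#' @return the non-negative propensity of reaction `j`.
#' @export
propensity <- function(system, j, counts) {
  if (anyNA(counts) || any(counts < 0)) stop("invalid state: negative or missing count")
  rx <- system$reactions
  r1 <- rx$r1[j]; r2 <- rx$r2[j]; rate <- rx$rate[j]
  if (r1 == r2 && r1 != 1L) {
    half <- if (system$self_half) 0.5 else 1
    unname(max(rate * counts[r1] * (counts[r1] - 1) * half, 0))
  } else {
    unname(rate * counts[r1] * counts[r2])
  }
}

#' Total propensity by direct summation
#'
#' The brute-force sum over all reactions; every incrementally maintained
#' total in the package is checked against this oracle.
#'
#' @inheritParams propensities
#' @return `sum(propensities(system, counts))`.
#' @export
total_propensity <- function(system, counts) {
  sum(propensities(system, counts))
}

#' Net stoichiometric change of each reaction
#'
#' @param system a `reaction_system`.
#' @return list with integer-vector elements `species[[j]]` (indices whose
#'   count changes when reaction `j` fires, placeholder excluded) and parallel
#'   numeric `delta[[j]]` (signed net change). Catalytic appearances (same
#'   species consumed and produced) cancel and are omitted.
#' @export
stoich_deltas <- function(system) {
  rx <- system$reactions
  species <- vector("list", system$M)
  delta <- vector("list", system$M)
  for (j in seq_len(system$M)) {
    idx <- c(rx$r1[j], rx$r2[j], rx$p1[j], rx$p2[j])
    d <- c(-1, -1, 1, 1)
    keep <- idx != 1L
    idx <- idx[keep]; d <- d[keep]
    if (length(idx)) {
      agg <- tapply(d, idx, sum)
      nz <- agg != 0
      species[[j]] <- as.integer(names(agg))[nz]
      delta[[j]] <- as.numeric(agg)[nz]
    } else {
      species[[j]] <- integer(0)
      delta[[j]] <- numeric(0)
    }
  }
  list(species = species, delta = delta)
}

#' Execute one reaction on a state vector
#'
#' Each non-placeholder reactant slot is decremented and each non-placeholder
#' product slot incremented. A firing that would drive any count negative is
#' an impossible event (a positive propensity implies feasibility), reported
#' as an error because it signals a propensity bookkeeping bug.
#'
#' @inheritParams propensity
#' @return the updated counts vector.
#' @export
apply_reaction <- function(system, j, counts) {
  rx <- system$reactions
  for (s in c(rx$r1[j], rx$r2[j])) if (s != 1L) counts[s] <- counts[s] - 1
  for (s in c(rx$p1[j], rx$p2[j])) if (s != 1L) counts[s] <- counts[s] + 1
  if (any(counts < 0))
    stop(sprintf("impossible event: firing reaction %s drives a count negative",
                 rx$id[j]))
  counts
}

#' Validate the raw ingredients of a reaction network
#'
#' Report-only checker used by the parser and exposed for direct use. Unlike
#' [reaction_system()], which refuses to build an invalid object, this accepts
#' arbitrary reactant/product term lists (as `+`-separated strings) and lists
#' every violation it finds.
#'
#' @param species data.frame with columns `id`, `count`.
#' @param reactions data.frame with columns `id`, `reactants`, `products`
#'   (strings like `"A + B"`, `"0"` for the placeholder) and `rate`.
#' @return data.frame with columns `where` and `problem`; zero rows if clean.
#' @export
validate_network <- function(species, reactions) {
  probs <- list()
  add <- function(where, problem)
    probs[[length(probs) + 1L]] <<- data.frame(where = where, problem = problem,
                                               stringsAsFactors = FALSE)
  sid <- as.character(species$id)
  dup <- unique(sid[duplicated(sid)])
  for (d in dup) add(d, "duplicate species id")
  bad <- sid[is.na(species$count) | species$count < 0 |
               species$count != floor(species$count)]
  for (b in bad) add(b, "initial count must be a non-negative integer")
  known <- c("0", sid)
  split_terms <- function(s) {
    s <- trimws(strsplit(as.character(s), "+", fixed = TRUE)[[1]])
    s[s != ""]
  }
  for (i in seq_len(nrow(reactions))) {
    rid <- as.character(reactions$id[i])
    rterms <- split_terms(reactions$reactants[i])
    pterms <- split_terms(reactions$products[i])
    if (length(rterms) > 2L)
      add(rid, sprintf("%d reactants; at most 2 allowed", length(rterms)))
    if (length(pterms) > 2L)
      add(rid, sprintf("%d products; at most 2 allowed", length(pterms)))
    undec <- setdiff(c(rterms, pterms), known)
    for (u in undec) add(rid, sprintf("undeclared species \"%s\"", u))
    rate <- suppressWarnings(as.numeric(reactions$rate[i]))
    if (is.na(rate) || rate <= 0)
      add(rid, "rate must be a positive number")
  }
  if (length(probs)) do.call(rbind, probs)
  else data.frame(where = character(0), problem = character(0),
                  stringsAsFactors = FALSE)
}

#' Validate a built reaction system
#'
#' @param system a `reaction_system`.
#' @return a violations data.frame as in [validate_network()] (empty when the
#'   object satisfies all structural invariants).
#' @export
validate_system <- function(system) {
  sp <- system$species
  rx <- system$reactions
  raw_species <- data.frame(id = sp$id[-1L], count = sp$count[-1L],
                            stringsAsFactors = FALSE)
  term <- function(i) sp$id[i]
  raw_rx <- data.frame(
    id = rx$id,
    reactants = paste(term(rx$r1), "+", term(rx$r2)),
    products = paste(term(rx$p1), "+", term(rx$p2)),
    rate = rx$rate, stringsAsFactors = FALSE)
  out <- validate_network(raw_species, raw_rx)
  if (sp$id[1L] != "0" || sp$count[1L] != 1)
    out <- rbind(out, data.frame(where = "0",
                                 problem = "placeholder species corrupted"))
  if (system$M != nrow(rx) || system$N != nrow(sp))
    out <- rbind(out, data.frame(where = "<system>",
                                 problem = "M/N inconsistent with table lengths"))
  out
}
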