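#' Reaction valences: how many propensities a firing invalidates
#'
#' The valence of a reaction is the number of reactions whose propensities
#' change when it executes -- its out-degree in the reaction-to-reaction
#' (clique-forming) update graph. A reaction that changes the count of its
#' own reactants depends on itself; `include_self = FALSE` drops that
#' self-dependency from the count.
#'
#' @param system a `reaction_system`.
#' @param clique_udg optional precomputed [build_clique_udg()] result.
#' @param include_self count the reaction itself when it invalidates its own
#'   propensity (default `TRUE`).
#' @return integer vector of length `M`.
#' @export
reaction_valence <- function(system, clique_udg = NULL, include_self = TRUE) {
  if (is.null(clique_udg)) clique_udg <- build_clique_udg(system)
  v <- lengths(clique_udg)
  if (!include_self) {
    has_self <- vapply(seq_along(clique_udg),
                       function(u) u %in% clique_udg[[u]], logical(1))
    v <- v - as.integer(has_self)
  }
  v
}

#' Propensity-weighted valence distribution
#'
#' Computes the PDF of reaction valence with each reaction weighted by its
#' average propensity over a trial profile, then the CDF as its running sum.
#' A steep climb of the CDF near a particular valence signals that a large
#' share of the executed reactions have that valence -- typically the
#' signature of a super-species involved in many reactions, which is exactly
#' the structure propensity factoring exploits.
#'
#' @param system a `reaction_system`.
#' @param profile average-propensity weights of length `M`; if `NULL`, a
#'   trial run of `trial_steps` events estimates them (all-zero weights fall
#'   back to uniform with a warning).
#' @param trial_steps trial-run length when `profile` is `NULL`.
#' @param include_self passed to [reaction_valence()].
#' @return object of class `valence_profile`: list with `valence` (per
#'   reaction), `weight` (normalized), and `cdf` (data.frame `valence`,
#'   `pdf`, `cdf` over distinct valences, ending at 1).
#' @export
valence_cdf <- function(system, profile = NULL, trial_steps = 1e4,
                        include_self = TRUE) {
  if (is.null(profile))
    profile <- sample_average_propensities(system, n_steps = trial_steps)
  stopifnot(length(profile) == system$M)
  if (all(profile == 0)) {
    warning("all-zero weights; falling back to uniform weighting")
    profile <- rep(1, system$M)
  }
  v <- reaction_valence(system, include_self = include_self)
  w <- profile / sum(profile)
  pdf <- tapply(w, v, sum)
  vals <- as.integer(names(pdf))
  ord <- order(vals)
  cdf <- data.frame(valence = vals[ord], pdf = as.numeric(pdf)[ord],
                    cdf = cumsum(as.numeric(pdf)[ord]))
  structure(list(valence = v, weight = w, cdf = cdf),
            class = "valence_profile")
}

#' @export
print.valence_profile <- function(x, ...) {
  cat(sprintf("valence_profile: %d reactions, valence range [%d, %d]\n",
              length(x$valence), min(x$valence), max(x$valence)))
  print(utils::head(x$cdf, 10))
  invisible(x)
}

#' @export
plot.valence_profile <- function(x, ...) {
  plot(x$cdf$valence, x$cdf$cdf, type = "s", xlab = "reaction valence",
       ylab = "cumulative propensity-weighted mass", ylim = c(0, 1), ...)
  invisible(x)
}

#' Memory accounting for the two update-graph representations
#'
#' Counts edges in the bipartite species/reaction graph (bounded by 6M) and
#' in the reaction-to-reaction clique-forming graph (up to M^2 when a shared
#' reactant forms a clique), and converts both to nominal byte footprints at
#' a fixed per-edge cost of one index pair (8 bytes), keeping the report
#' hardware-independent.
#'
#' @param system a `reaction_system`.
#' @param bytes_per_edge nominal storage per edge (default 8).
#' @return list with `bipartite_edges`, `clique_edges`, `bipartite_bytes`,
#'   `clique_bytes`, and `ratio` (clique / bipartite edges).
#' @export
udg_memory_report <- function(system, bytes_per_edge = 8) {
  budg <- build_bipartite_udg(system)
  be <- budg$n_edges
  ce <- clique_edge_count(system, budg)
  list(bipartite_edges = be, clique_edges = ce,
       bipartite_bytes = be * bytes_per_edge,
       clique_bytes = ce * bytes_per_edge,
       ratio = if (be > 0) ce / be else NA_real_)
}
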