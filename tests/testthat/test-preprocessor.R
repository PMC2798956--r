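test_that("trial-run averages are deterministic and balance at stationarity", {
  # frozen system: every reaction is catalytic, so propensities never change
  frozen <- reaction_system(
    data.frame(id = c("A", "B"), count = c(2, 3)),
    data.frame(id = c("r1", "r2"), r1 = c("A", "B"), r2 = NA,
               p1 = c("A", "B"), p2 = NA, rate = c(1, 2)))
  prof <- sample_average_propensities(frozen, n_steps = 500, seed = 1)
  expect_equal(prof, propensities(frozen, initial_counts(frozen)))

  p1 <- sample_average_propensities(frozen, n_steps = 200, seed = 9)
  p2 <- sample_average_propensities(frozen, n_steps = 200, seed = 9)
  expect_identical(p1, p2)

  # immigration-death: mean death propensity == immigration rate (detailed
  # balance at stationarity), here within 5%
  im <- canonical_model("immigration_death")
  prof <- sample_average_propensities(im$system, n_steps = 1e5, seed = 4)
  expect_lt(abs(prof[2] - 10) / 10, 0.05)

  dead <- reaction_system(
    data.frame(id = "A", count = 0),
    data.frame(id = "r", r1 = "A", r2 = NA, p1 = NA, p2 = NA, rate = 1))
  expect_error(sample_average_propensities(dead, n_steps = 10),
               "degenerate")
})

test_that("the super-cache holds the top average propensities in order", {
  expect_identical(build_super_cache(c(9, 5, 1), 2), c(1L, 2L))
  expect_identical(build_super_cache(c(9, 5, 1), 0), integer(0))
  expect_identical(build_super_cache(c(5, 9, 9), 2), c(2L, 3L))  # tie by index
  set.seed(6)
  for (i in 1:10) {
    prof <- sample(stats::runif(40, 0, 100))
    size <- sample(0:40, 1)
    got <- build_super_cache(prof, size)
    want <- order(-prof, seq_along(prof))[seq_len(size)]
    expect_identical(got, want)
    expect_true(all(prof[got] >= max(c(prof[-got], -Inf))))
  }
})

test_that("greedy cloud assignment follows the scored fixing order", {
  # reactions {X+Y, X+Z, X+Y} with averages {5,3,2}: X's score 10 beats
  # Y's 7 and Z's 3, so a single cloud on X takes all three
  sys <- reaction_system(
    data.frame(id = c("X", "Y", "Z"), count = c(1, 1, 1)),
    data.frame(id = c("r1", "r2", "r3"),
               r1 = c("X", "X", "X"), r2 = c("Y", "Z", "Y"),
               p1 = NA, p2 = NA, rate = 1))
  cl <- assign_clouds(sys, profile = c(5, 3, 2))
  expect_equal(length(cl), 1L)
  expect_equal(sys$species$id[cl[[1]]$factor], "X")
  expect_setequal(cl[[1]]$members, 1:3)

  # one reaction: one cloud on its first reactant
  one <- reaction_system(
    data.frame(id = c("A", "B"), count = c(1, 1)),
    data.frame(id = "r", r1 = "A", r2 = "B", p1 = NA, p2 = NA, rate = 1))
  cl <- assign_clouds(one, profile = 1)
  expect_equal(length(cl), 1L)
  expect_equal(one$species$id[cl[[1]]$factor], "A")

  # equal scores: the lowest species index wins
  tie <- reaction_system(
    data.frame(id = c("U", "V"), count = c(1, 1)),
    data.frame(id = c("r1", "r2"), r1 = c("U", "V"), r2 = NA,
               p1 = NA, p2 = NA, rate = 1))
  cl <- assign_clouds(tie, profile = c(1, 1))
  expect_equal(tie$species$id[cl[[1]]$factor], "U")

  # placeholder-only reactions go to the dedicated placeholder cloud
  zo <- reaction_system(
    data.frame(id = "A", count = 1),
    data.frame(id = c("r1", "r2"), r1 = c("A", NA), r2 = NA,
               p1 = c(NA, "A"), p2 = NA, rate = c(1, 2)))
  cl <- assign_clouds(zo, profile = c(1, 2))
  expect_equal(length(cl), 2L)
  expect_equal(cl[[2]]$factor, 1L)
  expect_equal(cl[[2]]$members, 2L)

  # the result partitions the non-super-cache reactions
  st <- random_frozen_structures(55)
  expect_setequal(c(st$sc_idx, unlist(st$pl_rxn),
                    unlist(lapply(st$sub, function(ss)
                      unlist(lapply(ss, `[[`, "rxn"))))),
                  seq_len(st$system$M))
})

test_that("sub-tree partitioning groups shared partners at the threshold", {
  mk <- function(partners) {
    ids <- unique(c("T", partners))
    reaction_system(
      data.frame(id = ids, count = 1),
      data.frame(id = sprintf("r%d", seq_along(partners)),
                 r1 = "T", r2 = partners, p1 = NA, p2 = NA, rate = 1))
  }
  sys <- mk(c("Y", "Y", "Y", "Z"))
  part <- build_subtree_partition(sys, match("T", sys$species$id), 1:4)
  expect_equal(length(part$sub), 1L)
  expect_equal(sys$species$id[part$sub[[1]]$s], "Y")
  expect_equal(part$sub[[1]]$members, 1:3)
  expect_equal(part$primary, 4L)

  part <- build_subtree_partition(mk(c("Y", "Z", "W")),  # all distinct
                                  match("T", mk(c("Y", "Z", "W"))$species$id), 1:3)
  expect_equal(length(part$sub), 0L)
  expect_equal(part$primary, 1:3)

  sys <- mk(c(rep("Y", 5), rep("Z", 3), rep("W", 2)))
  part <- build_subtree_partition(sys, match("T", sys$species$id), 1:10)
  expect_equal(length(part$sub), 2L)
  expect_setequal(sys$species$id[vapply(part$sub, `[[`, integer(1), "s")],
                  c("Y", "Z"))
  expect_equal(part$primary, 9:10)

  # self-reactions stay primary even in bulk
  self_sys <- reaction_system(
    data.frame(id = "T", count = 5),
    data.frame(id = sprintf("r%d", 1:4), r1 = "T", r2 = "T",
               p1 = NA, p2 = NA, rate = 1))
  part <- build_subtree_partition(self_sys, 2L, 1:4)
  expect_equal(length(part$sub), 0L)
})

test_that("the bipartite update graph applies the net-delta rule", {
  sys <- reaction_system(
    data.frame(id = c("A", "B", "C", "D"), count = c(1, 1, 1, 1)),
    data.frame(id = "r", r1 = "A", r2 = "B", p1 = "C", p2 = "D", rate = 1))
  udg <- build_bipartite_udg(sys)
  iA <- match("A", sys$species$id)
  expect_equal(udg$sp2rx[[iA]], 1L)
  expect_setequal(sys$species$id[udg$aff[[1]]], c("A", "B", "C", "D"))
  expect_equal(udg$n_edges, 6L)

  catal <- reaction_system(
    data.frame(id = c("A", "B", "C"), count = c(1, 1, 1)),
    data.frame(id = "r", r1 = "A", r2 = "B", p1 = "A", p2 = "C", rate = 1))
  u2 <- build_bipartite_udg(catal)
  expect_setequal(catal$species$id[u2$aff[[1]]], c("B", "C"))  # A nets to 0
  expect_equal(u2$n_edges, 4L)

  # bound: <= 6M on generated networks
  sys <- generate_hub_network(n_species = 40, n_reactions = 300, hub_count = 2,
                              hub_participation = 0.9, seed = 12)
  expect_lte(build_bipartite_udg(sys)$n_edges, 6L * sys$M)
})

test_that("the clique update graph matches a brute-force dependency check", {
  # zero-order reactions change no reactant of anything
  indep <- reaction_system(
    data.frame(id = c("A", "B"), count = c(0, 0)),
    data.frame(id = c("r1", "r2"), r1 = NA, r2 = NA, p1 = c("A", "B"),
               p2 = NA, rate = 1))
  adj <- build_clique_udg(indep)
  expect_equal(attr(adj, "n_edges"), 0L)

  # n reactions all consuming H form a clique with self-edges: n^2 edges
  n <- 7
  hub <- reaction_system(
    data.frame(id = c("H", sprintf("P%d", 1:n)), count = 1),
    data.frame(id = sprintf("r%d", 1:n), r1 = "H", r2 = NA,
               p1 = sprintf("P%d", 1:n), p2 = NA, rate = 1))
  adj <- build_clique_udg(hub)
  expect_equal(attr(adj, "n_edges"), n^2)
  expect_true(all(vapply(adj, function(v) identical(v, 1:n), logical(1))))

  # random network vs pairwise oracle
  sys <- generate_hub_network(n_species = 12, n_reactions = 25, hub_count = 2,
                              hub_participation = 0.6, seed = 17)
  adj <- build_clique_udg(sys)
  sd <- stoich_deltas(sys)
  rx <- sys$reactions
  for (u in seq_len(sys$M)) {
    want <- which(vapply(seq_len(sys$M), function(v)
      any(c(rx$r1[v], rx$r2[v]) %in% sd$species[[u]]), logical(1)))
    expect_identical(adj[[u]], want)
  }
  expect_identical(attr(adj, "n_edges"), udg_memory_report(sys)$clique_edges)
})

test_that("compiled update programs leave every cached sum exact", {
  for (i in 1:12) {
    st <- random_frozen_structures(700 + i, k = c(2, 4, 8, 16)[(i %% 4) + 1])
    a <- propensities(st$system, st$x)
    fired <- 0
    for (m in which(a > 0)) {
      st2 <- execute_program(st, m)
      expect_lt(check_consistency(st2)$max, 1e-9)
      fired <- fired + 1
      if (fired >= 5) break
    }
  }
  # a reaction touching only a cloud's factor-species compiles to a single
  # factor-scale (plus count adjustments)
  sys <- reaction_system(
    data.frame(id = c("T", "P", "Q"), count = c(5, 3, 2)),
    data.frame(id = c("grow", "use1", "use2"),
               r1 = c(NA, "T", "T"), r2 = c(NA, "P", "Q"),
               p1 = c("T", "P", "Q"), p2 = NA, rate = c(1, 1, 1)))
  st <- build_sim_structures(sys, supercache_size = 0, trial_steps = 0)
  grow <- which(sys$reactions$id == "grow")
  pr <- st$prog[[grow]]
  expect_equal(nrow(pr$ops), 1L)
  expect_equal(pr$ops[1, 1], 1L)  # factor-scale only

  # a null (catalytic, zero net delta) reaction compiles to nothing
  nullsys <- reaction_system(
    data.frame(id = c("A", "B"), count = c(2, 2)),
    data.frame(id = c("null", "other"), r1 = c("A", "B"), r2 = NA,
               p1 = c("A", "B"), p2 = NA, rate = 1))
  stn <- build_sim_structures(nullsys, supercache_size = 0, trial_steps = 0)
  nl <- which(nullsys$reactions$id == "null")
  expect_equal(length(stn$prog[[nl]]$sp), 0L)
  expect_equal(nrow(stn$prog[[nl]]$ops), 0L)
})

test_that("preprocessing is deterministic given identical inputs", {
  sys <- generate_hub_network(n_species = 25, n_reactions = 120, hub_count = 2,
                              hub_participation = 0.8, seed = 20)
  st1 <- build_sim_structures(sys, trial_steps = 2000, trial_seed = 3)
  st2 <- build_sim_structures(sys, trial_steps = 2000, trial_seed = 3)
  expect_identical(dump_structures(st1), dump_structures(st2))
  expect_identical(st1$prog, st2$prog)
})
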