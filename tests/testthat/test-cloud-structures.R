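test_that("cloud_total is the factored product x_T * (R + C)", {
  fake <- list(x = c(1, 10), cl_factor = 2L, cl_R = 2.5, cl_C = 1.5)
  expect_equal(cloud_total(fake, 1), 40)
  fake$x[2] <- 0
  expect_equal(cloud_total(fake, 1), 0)

  # brute-force member-sum oracle on a random cloud
  sys <- shared_reactant_system(n_partners = 30, t_count = 7, seed = 5)
  st <- build_sim_structures(sys, supercache_size = 0, trial_steps = 0)
  expect_equal(st$n_clouds, 1L)
  members <- which(st$loc_cloud == 1L)
  a <- propensities(sys, st$x)
  expect_lt(rel_dev(cloud_total(st, 1), sum(a[members])), 1e-9)
  expect_lt(rel_dev(st$cl_aT[1], sum(a[members])), 1e-9)
})

test_that("factor-species changes rescale the cloud in O(1)", {
  sys <- shared_reactant_system(n_partners = 50, t_count = 10, seed = 8)
  st <- build_sim_structures(sys, supercache_size = 0, trial_steps = 0)
  RC <- st$cl_R[1] + st$cl_C[1]
  st2 <- on_factor_species_change(st, 1, +1L)
  expect_equal(st2$cl_aT[1], 11 * RC)
  expect_identical(st2$cl_R, st$cl_R)  # trees untouched
  expect_identical(st2$prim[[1]]$nodes, st$prim[[1]]$nodes)
  expect_identical(on_factor_species_change(st, 1, 0L)$cl_aT, st$cl_aT)
  st3 <- on_factor_species_change(st, 1, -1L)
  expect_lt(rel_dev(st3$cl_aT[1], sum(propensities(sys, st3$x))), 1e-9)
  expect_lt(rel_dev(st3$a0, total_propensity(sys, st3$x)), 1e-9)
  expect_error(on_factor_species_change(st, 1, -11L), "negative")
})

test_that("primary-leaf and secondary-species updates keep the factored sums exact", {
  # partners P1..P3 are distinct (primary tree); P4 repeated 4x (sub-tree)
  sys <- reaction_system(
    data.frame(id = c("T", "P1", "P2", "P3", "P4"), count = c(6, 3, 0, 5, 2)),
    data.frame(id = sprintf("R%d", 1:7),
               r1 = "T",
               r2 = c("P1", "P2", "P3", "P4", "P4", "P4", "P4"),
               p1 = c("P1", "P2", "P3", "P4", "P4", "P4", "P4"),
               p2 = NA,
               rate = c(0.5, 1.25, 2, 0.2, 0.4, 0.8, 1.6)))
  st <- build_sim_structures(sys, supercache_size = 0, trial_steps = 0)
  expect_equal(st$n_clouds, 1L)
  expect_equal(length(st$sub[[1]]), 1L)       # the P4 group
  expect_equal(st$sub[[1]][[1]]$S, 3)         # constant sum of rates
  oracle <- function(s) {
    expect_lt(rel_dev(s$cl_aT[1], total_propensity(sys, s$x)), 1e-9)
    expect_lt(rel_dev(s$cl_C[1], s$x[st$sub[[1]][[1]]$s] * s$sub[[1]][[1]]$S), 1e-9)
  }
  # leaf refresh: P2 count 0 -> 4 moves R by rate * 4
  r3 <- which(sys$reactions$id == "R2")
  st2 <- on_primary_reactant_change(st, 1, r3, 4)
  expect_equal(st2$cl_R[1] - st$cl_R[1], 1.25 * 4)
  oracle(st2)
  expect_identical(on_primary_reactant_change(st2, 1, r3, 4)$cl_aT, st2$cl_aT)
  # secondary change: C moves by delta * S_j, sub-tree untouched
  st3 <- on_secondary_species_change(st2, 1, 1, +3L)
  expect_equal(st3$cl_C[1] - st2$cl_C[1], 3 * 3)
  expect_identical(st3$sub[[1]][[1]]$tree$nodes, st2$sub[[1]][[1]]$tree$nodes)
  oracle(st3)
  expect_identical(on_secondary_species_change(st3, 1, 1, 0L)$cl_C, st3$cl_C)
  expect_error(on_secondary_species_change(st3, 1, 1, -99L), "negative")
  expect_error(on_primary_reactant_change(st3, 1, which(sys$reactions$id == "R5"), 1),
               "wiring error")
  # a long mixed update sequence stays on the member-sum oracle
  set.seed(13)
  s <- st
  for (i in 1:300) {
    op <- sample(3, 1)
    if (op == 1) {
      d <- sample(c(-1L, 1L), 1)
      if (s$x["T"] + d >= 0) s <- on_factor_species_change(s, 1, d)
    } else if (op == 2) {
      r <- sample(3, 1)
      s <- on_primary_reactant_change(s, 1, r, sample(0:9, 1))
    } else {
      d <- sample(c(-1L, 1L), 1)
      if (s$x["P4"] + d >= 0) s <- on_secondary_species_change(s, 1, 1, d)
    }
  }
  expect_lt(rel_dev(s$cl_aT[1], total_propensity(sys, s$x)), 1e-9)
  expect_lt(check_consistency(s)$max, 1e-9)
})

test_that("in-cloud selection respects the rescaled factored measure", {
  # primary leaves [1, 2, 3] with x_T = 2: a_T = 12
  sys <- reaction_system(
    data.frame(id = c("T", "P1", "P2", "P3"), count = c(2, 1, 2, 3)),
    data.frame(id = c("R1", "R2", "R3"), r1 = "T", r2 = c("P1", "P2", "P3"),
               p1 = c("P1", "P2", "P3"), p2 = NA, rate = 1))
  st <- build_sim_structures(sys, supercache_size = 0, trial_steps = 0)
  expect_equal(tree_leaves(st$prim[[1]]), c(1, 2, 3))
  expect_equal(st$cl_aT[1], 12)
  expect_equal(select_in_cloud(st, 1, 5.99), 2L)  # 5.99 / 2 = 2.995 in [1, 3)
  expect_equal(select_in_cloud(st, 1, 0), 1L)
  expect_equal(select_in_cloud(st, 1, 11.99), 3L)
  expect_error(select_in_cloud(st, 1, 12), "a_T")
})

test_that("selection measure equals propensity for random clouds with sub-trees", {
  for (i in 1:25) {
    st <- random_frozen_structures(400 + i, k = c(2, 4, 8, 16)[(i %% 4) + 1],
                                   supercache_size = 0)
    a <- propensities(st$system, st$x)
    bp <- selection_breakpoints(st)
    m <- numeric(st$system$M)
    m[bp$reaction] <- bp$measure
    pos <- a > 0
    expect_lt(max(abs(m[pos] - a[pos]) / a[pos]), 1e-9)
    expect_true(all(m[!pos] == 0))
  }
})

test_that("the super-cache scans linearly and misses carry the residual", {
  sys <- reaction_system(
    data.frame(id = c("A", "B", "C"), count = c(1, 1, 1)),
    data.frame(id = c("R1", "R2", "R3"),
               r1 = c("A", "B", "C"), r2 = NA, p1 = c("A", "B", "C"), p2 = NA,
               rate = c(5, 3, 2)))
  st <- build_sim_structures(sys, profile = c(5, 3, 2), supercache_size = 2)
  expect_identical(st$sc_idx, c(1L, 2L))
  hit <- super_cache_select(st, 6.0)
  expect_true(hit$hit)
  expect_equal(hit$reaction, 2L)
  miss <- super_cache_select(st, 8.5)
  expect_false(miss$hit)
  expect_equal(miss$residual, 0.5)

  st2 <- refresh_super_cache_entry(st, 2L)  # unchanged propensity: identity
  expect_identical(st2$sc_a, st$sc_a)
  expect_error(refresh_super_cache_entry(st, 3L), "wiring error")
  # refresh picks up a changed state
  st$x["B"] <- 4
  st3 <- refresh_super_cache_entry(st, 2L)
  expect_equal(st3$sc_a[2], 12)
  expect_equal(st3$P_sc - st$P_sc, 9)
  # random refresh sequences keep P_sc equal to the entry sum
  set.seed(33)
  s <- st
  for (i in 1:100) {
    s$x[sample(2:4, 1)] <- sample(0:9, 1)
    s <- refresh_super_cache_entry(s, sample(st$sc_idx, 1))
  }
  s <- refresh_super_cache_entry(refresh_super_cache_entry(s, 1L), 2L)
  expect_lt(rel_dev(s$P_sc, sum(s$sc_a)), 1e-9)
})

test_that("structure dumps are canonical and deterministic", {
  st1 <- random_frozen_structures(77)
  st2 <- random_frozen_structures(77)
  expect_identical(dump_structures(st1), dump_structures(st2))
  st3 <- execute_program(st1, which(propensities(st1$system, st1$x) > 0)[1])
  expect_false(identical(dump_structures(st1), dump_structures(st3)))
})
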