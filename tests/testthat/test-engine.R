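test_that("holding times are exponential with rate a0", {
  expect_equal(advance_time(2, exp(-2)), 1)
  expect_equal(advance_time(5, 1), 0)
  expect_error(advance_time(0, 0.5), "extinction")
  expect_error(advance_time(2, 0), "\\(0, 1\\]")
  set.seed(15)
  tau <- advance_time(5, stats::runif(1e5))
  se <- stats::sd(tau) / sqrt(length(tau))
  expect_lt(abs(mean(tau) - 0.2), 3 * se)
})

test_that("select_reaction walks super-cache then main tree", {
  sys <- reaction_system(
    data.frame(id = c("A", "B", "C"), count = c(1, 1, 1)),
    data.frame(id = c("R1", "R2", "R3"),
               r1 = c("A", "B", "C"), r2 = NA, p1 = c("A", "B", "C"), p2 = NA,
               rate = c(5, 3, 2)))
  st <- build_sim_structures(sys, profile = c(5, 3, 2), supercache_size = 2)
  expect_equal(st$a0, 10)
  expect_equal(select_reaction(st, 7.9), 2L)   # linear scan hit
  expect_equal(select_reaction(st, 9.5), 3L)   # miss -> cloud (residual 1.5)
  expect_equal(select_reaction(st, 0), 1L)
  expect_error(select_reaction(st, 10), "\\[0, a0\\)")

  # scalar and vectorized selection agree draw for draw
  for (i in 1:6) {
    stf <- random_frozen_structures(900 + i, k = c(2, 4, 8, 16)[(i %% 4) + 1])
    set.seed(i)
    r <- stats::runif(2000) * stf$a0
    scalar <- vapply(r, function(ri) select_reaction(stf, ri), integer(1))
    expect_identical(select_reaction_many(stf, r), scalar)
  }
})

test_that("frozen selection frequencies match a_j / a0", {
  two <- reaction_system(
    data.frame(id = c("A", "B"), count = c(1, 1)),
    data.frame(id = c("R1", "R2"), r1 = c("A", "B"), r2 = NA,
               p1 = c("A", "B"), p2 = NA, rate = c(3, 1)))
  st <- build_sim_structures(two, trial_steps = 0, supercache_size = 1)
  f <- frozen_selection_histogram(st, 1e5, seed = 8)
  se <- sqrt(0.75 * 0.25 / 1e5)
  expect_lt(abs(f[1] - 0.75), 3 * se)
  one <- build_sim_structures(
    reaction_system(data.frame(id = "A", count = 1),
                    data.frame(id = "r", r1 = "A", r2 = NA, p1 = "A",
                               p2 = NA, rate = 2)),
    trial_steps = 0)
  expect_equal(frozen_selection_histogram(one, 1000, seed = 1)[1], 1)

  st <- random_frozen_structures(321, k = 4)
  a <- propensities(st$system, st$x)
  f <- frozen_selection_histogram(st, 2e5, seed = 5)
  expect_gt(chisq_gof_p(attr(f, "counts"), a / sum(a)), 0.001)
  expect_true(all(attr(f, "counts")[a == 0] == 0))
})

test_that("single steps fire, advance time, and signal extinction", {
  grow <- reaction_system(
    data.frame(id = "A", count = 0),
    data.frame(id = "r", r1 = NA, r2 = NA, p1 = "A", p2 = NA, rate = 1))
  st <- build_sim_structures(grow, trial_steps = 0)
  set.seed(2)
  for (i in 1:5) {
    out <- lolcat_step(st)
    st <- out$structures
    expect_equal(out$reaction, 1L)
    expect_gt(out$tau, 0)
  }
  expect_equal(unname(st$x["A"]), 5)
  expect_gt(st$time, 0)

  die <- reaction_system(
    data.frame(id = "A", count = 1),
    data.frame(id = "r", r1 = "A", r2 = NA, p1 = NA, p2 = NA, rate = 1))
  std <- build_sim_structures(die, trial_steps = 0)
  out <- lolcat_step(std)
  expect_equal(out$structures$a0, 0)
  expect_error(lolcat_step(out$structures), "extinction")
  tr <- run_lolcat(die, max_steps = 100, seed = 3, trial_steps = 0)
  expect_true(tr$extinct)
  expect_equal(tr$n_steps, 1)
})

test_that("the engine loop reproduces repeated functional steps exactly", {
  sys <- generate_hub_network(n_species = 18, n_reactions = 50, hub_count = 2,
                              hub_participation = 0.8, seed = 44)
  tr <- run_lolcat(sys, max_steps = 400, seed = 99, trial_steps = 500,
                   recompute_every = 1e9, return_structures = TRUE)
  set.seed(99)
  st <- build_sim_structures(sys, trial_steps = 500)
  for (i in seq_len(400)) st <- lolcat_step(st)$structures
  expect_identical(tr$structures$x, st$x)
  expect_identical(tr$structures$a0, st$a0)
  expect_identical(tr$structures$main$nodes, st$main$nodes)
  expect_identical(tr$structures$cl_R, st$cl_R)
  expect_identical(tr$structures$cl_C, st$cl_C)
  expect_identical(tr$structures$P_sc, st$P_sc)
  for (ci in seq_len(st$n_clouds))
    expect_identical(tr$structures$prim[[ci]]$nodes, st$prim[[ci]]$nodes)
})

test_that("trajectories are bit-identical under a fixed seed", {
  sys <- generate_hub_network(n_species = 15, n_reactions = 40, hub_count = 2,
                              hub_participation = 0.7, seed = 5)
  t1 <- run_lolcat(sys, max_steps = 2000, seed = 7, record_interval = 1e-4,
                   trial_steps = 1000, return_structures = TRUE)
  t2 <- run_lolcat(sys, max_steps = 2000, seed = 7, record_interval = 1e-4,
                   trial_steps = 1000, return_structures = TRUE)
  expect_identical(t1$states, t2$states)
  expect_identical(t1$times, t2$times)
  expect_identical(t1$events, t2$events)
  expect_identical(dump_structures(t1$structures), dump_structures(t2$structures))
  d1 <- run_direct(sys, max_steps = 2000, seed = 7, record_interval = 1e-4)
  d2 <- run_direct(sys, max_steps = 2000, seed = 7, record_interval = 1e-4)
  expect_identical(d1$states, d2$states)
  expect_identical(d1$events, d2$events)
})

test_that("direct-method selection frequencies follow the propensity weights", {
  frozen <- reaction_system(
    data.frame(id = c("A", "B"), count = c(1, 1)),
    data.frame(id = c("r1", "r2"), r1 = c("A", "B"), r2 = NA,
               p1 = c("A", "B"), p2 = NA, rate = c(3, 1)))
  tr <- run_direct(frozen, max_steps = 1e5, seed = 21)
  f <- tr$events[1] / sum(tr$events)
  expect_lt(abs(f - 0.75), 3 * sqrt(0.75 * 0.25 / 1e5))

  # single-reaction systems: both engines execute exactly the budget
  grow <- reaction_system(
    data.frame(id = "A", count = 0),
    data.frame(id = "r", r1 = NA, r2 = NA, p1 = "A", p2 = NA, rate = 1))
  expect_equal(unname(run_direct(grow, max_steps = 500, seed = 1)$events[1]), 500)
  expect_equal(unname(run_lolcat(grow, max_steps = 500, seed = 1,
                                 trial_steps = 0)$events[1]), 500)
})

test_that("both engines agree with the analytic oracles on small runs", {
  im <- canonical_model("immigration_death")
  for (runner in list(run_lolcat, run_direct)) {
    tr <- runner(im$system, max_time = 300, seed = 31, record_interval = 0.1)
    w <- tr$times >= 10
    bs <- batch_stats(tr$states[w, "A"], nb = 20)
    expect_lt(abs(bs$mean - 10), 3 * max(bs$se, 0.05))
  }
  dec <- canonical_model("decay")
  set.seed(77)
  xs <- replicate(60, run_lolcat(dec$system, max_time = 1,
                                 trial_steps = 0)$final_counts[["A"]])
  se <- stats::sd(xs) / sqrt(length(xs))
  expect_lt(abs(mean(xs) - dec$facts$mean_at(1)), 3 * se)
})

test_that("zero iteration budget yields only the initial sample", {
  im <- canonical_model("immigration_death")
  tr <- run_lolcat(im$system, max_steps = 0, seed = 1, trial_steps = 0)
  expect_equal(tr$n_steps, 0)
  expect_equal(nrow(tr$states), 1L)
  expect_equal(tr$times, 0)
})

test_that("time-grid recording samples and holds at boundaries", {
  # deterministic-ish: pure growth, check monotone non-decreasing samples
  grow <- reaction_system(
    data.frame(id = "A", count = 0),
    data.frame(id = "r", r1 = NA, r2 = NA, p1 = "A", p2 = NA, rate = 100))
  tr <- run_lolcat(grow, max_time = 2, seed = 13, record_interval = 0.05,
                   trial_steps = 0)
  expect_equal(tr$times, c(0, seq(0.05, 2, by = 0.05)))
  expect_true(all(diff(tr$states[, "A"]) >= 0))
  expect_equal(tr$final_time, 2)
  # extinction freezes the state through the rest of the grid
  die <- reaction_system(
    data.frame(id = "A", count = 3),
    data.frame(id = "r", r1 = "A", r2 = NA, p1 = NA, p2 = NA, rate = 5))
  trd <- run_direct(die, max_time = 50, seed = 2, record_interval = 1)
  expect_equal(trd$times, 0:50)
  expect_equal(unname(trd$states[nrow(trd$states), "A"]), 0)
})

test_that("the ODM baseline sorts by trial profile and matches the oracles", {
  sys <- generate_hub_network(n_species = 15, n_reactions = 40, hub_count = 2,
                              hub_participation = 0.7, seed = 5)
  prof <- sample_average_propensities(sys, n_steps = 2000, seed = 3)
  tr <- run_odm(sys, max_steps = 100, seed = 9, profile = prof, udg = "clique")
  expect_identical(tr$order, order(-prof, seq_len(sys$M)))

  im <- canonical_model("immigration_death")
  for (kind in c("clique", "bipartite")) {
    tro <- run_odm(im$system, max_time = 300, seed = 41, udg = kind,
                   record_interval = 0.1, trial_steps = 1000)
    w <- tro$times >= 10
    bs <- batch_stats(tro$states[w, "A"], nb = 20)
    expect_lt(abs(bs$mean - 10), 3 * max(bs$se, 0.05))
  }
})

test_that("operation counters expose the factoring advantage on hub networks", {
  sys <- generate_hub_network(n_species = 60, n_reactions = 220, hub_count = 2,
                              hub_participation = 0.9, seed = 61)
  trl <- run_lolcat(sys, max_steps = 2000, seed = 3, trial_steps = 2000)
  tro <- run_odm(sys, max_steps = 2000, seed = 3, trial_steps = 2000,
                 udg = "clique")
  expect_gt(tro$ops$per_step["prop_updates"],
            10 * trl$ops$per_step["cloud_updates"])
})
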