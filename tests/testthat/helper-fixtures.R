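# shared fixtures and oracles, built in code at test time

# max deviation relative to the exact value, floored at magnitude 1
rel_dev <- function(a, b) {
  if (length(a) == 0L) return(0)
  max(abs(a - b) / pmax(abs(b), 1))
}

# a small random network with full structures, frozen at its initial state
random_frozen_structures <- function(seed, k = 4L, max_M = 50L,
                                     supercache_size = NULL) {
  set.seed(seed)
  M <- sample(10:max_M, 1)
  hubs <- sample(2:3, 1)
  N <- max(sample(8:25, 1), hubs + 3)
  part <- stats::runif(1, 0.3, 0.9)
  if (is.null(supercache_size)) supercache_size <- sample(0:8, 1)
  sys <- generate_hub_network(n_species = N, n_reactions = M,
                              hub_count = hubs, hub_participation = part,
                              count_range = c(0, 30), hub_initial = 50,
                              seed = seed + 1000L)
  build_sim_structures(sys, k = k, supercache_size = supercache_size,
                       trial_steps = 0)
}

# a small network with one dominant shared reactant, for cloud-level tests
shared_reactant_system <- function(n_partners = 6, t_count = 10,
                                   partner_counts = NULL, rates = NULL,
                                   seed = 1) {
  set.seed(seed)
  if (is.null(partner_counts)) partner_counts <- sample(0:20, n_partners, TRUE)
  if (is.null(rates)) rates <- round(stats::runif(n_partners, 0.1, 3), 3)
  ids <- sprintf("P%d", seq_len(n_partners))
  reaction_system(
    data.frame(id = c("T", ids), count = c(t_count, partner_counts)),
    data.frame(id = sprintf("R%d", seq_len(n_partners)),
               r1 = "T", r2 = ids, p1 = ids, p2 = NA, rate = rates))
}

# batch-means estimate of the mean of an autocorrelated series and its SE
batch_stats <- function(v, nb = 30) {
  bs <- floor(length(v) / nb)
  m <- vapply(seq_len(nb), function(b) mean(v[((b - 1) * bs + 1):(b * bs)]),
              numeric(1))
  list(mean = mean(m), se = stats::sd(m) / sqrt(nb))
}

# batch-means estimate of the Fano factor (variance / mean)
batch_fano <- function(v, nb = 30) {
  bs <- floor(length(v) / nb)
  f <- vapply(seq_len(nb), function(b) {
    seg <- v[((b - 1) * bs + 1):(b * bs)]
    stats::var(seg) / mean(seg)
  }, numeric(1))
  list(mean = mean(f), se = stats::sd(f) / sqrt(nb))
}

# chi-square goodness of fit with small expected cells pooled
chisq_gof_p <- function(counts, probs, min_expected = 10) {
  n <- sum(counts)
  keep <- probs > 0
  counts <- counts[keep]; probs <- probs[keep]
  expected <- n * probs
  small <- expected < min_expected
  if (sum(small) > 1) {
    counts <- c(counts[!small], sum(counts[small]))
    probs <- c(probs[!small], sum(probs[small]))
  }
  if (length(counts) < 2) return(1)
  suppressWarnings(stats::chisq.test(counts, p = probs / sum(probs))$p.value)
}
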