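test_that("initial state respects the phosphorylation probability", {
  g <- canonical_graph
  set.seed(1)
  expect_identical(initialize_state(g, 0), integer(60))
  expect_identical(initialize_state(g, 1), rep(1L, 60))
  set.seed(7)
  draws <- replicate(200, mean(initialize_state(g, 0.5)))
  # binomial: mean of 12000 fair bits, 4 sigma band
  expect_lt(abs(mean(draws) - 0.5), 4 * 0.5 / sqrt(200 * 60))
})

test_that("boundary rates behave as absorbing or flushing dynamics", {
  lat <- make_fixture("triangle")
  zero <- rate_params(kphr = 0, kdpr = 0, kphs = 0, kdps = 0)
  st <- c(1L, 0L, 1L, 0L)
  set.seed(1)
  expect_identical(sim_step(st, lat, allosteric_table("product_activation"),
                            zero), st)
  flush <- rate_params(kphr = 0, kdpr = 1, kphs = 0, kdps = 1)
  set.seed(1)
  expect_identical(sim_step(c(1L, 1L, 1L, 1L), lat,
                            allosteric_table("product_activation"), flush),
                   c(0L, 0L, 0L, 0L))
})

test_that("trajectories are deterministic given the seed", {
  cfg <- sim_config(n_steps = 50, burn_in = 10, seed = 123, n_replicates = 3)
  t1 <- run_sim(cfg, canonical_graph)
  t2 <- run_sim(cfg, canonical_graph)
  expect_identical(t1, t2)
  r1 <- run_replicates(cfg, canonical_graph)
  r2 <- run_replicates(cfg, canonical_graph)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  # zero steps: initial fractions only
  t0 <- run_sim(sim_config(n_steps = 0, burn_in = 0, seed = 1),
                canonical_graph)
  expect_equal(nrow(t0), 1)
  # single replicate has zero ensemble variance
  one <- run_replicates(sim_config(n_steps = 20, burn_in = 0, seed = 1,
                                   n_replicates = 1), canonical_graph)
  expect_true(all(one$var_R_P == 0) && all(one$var_S_P == 0))
})

test_that("neighbour-independent rules reach kph/(kph + kdp) per species", {
  cfg <- sim_config(table = uniform_allosteric_table(1),
                    n_steps = 800, burn_in = 200, seed = 11,
                    n_replicates = 20)
  s <- run_replicates(cfg, canonical_graph, keep_replicates = TRUE)
  reps <- attr(s, "replicates")
  rep_means_R <- colMeans(reps$R)
  rep_means_S <- colMeans(reps$S)
  want_R <- 0.1 / (0.1 + 0.06)
  want_S <- 0.4 / (0.4 + 1)
  se_R <- stats::sd(rep_means_R) / sqrt(length(rep_means_R))
  se_S <- stats::sd(rep_means_S) / sqrt(length(rep_means_S))
  expect_lt(abs(mean(rep_means_R) - want_R), 4 * se_R + 1e-3)
  expect_lt(abs(mean(rep_means_S) - want_S), 4 * se_S + 1e-3)
})

test_that("one-step distribution matches the exact permutation-averaged chain", {
  lat <- make_fixture("triangle")
  tab <- allosteric_table("product_activation")
  rates <- rate_params(kphr = 0.3, kdpr = 0.2, kphs = 0.4, kdps = 0.5)
  Tm <- exact_transition_matrix(lat, tab, rates)
  # rows are stochastic
  expect_equal(rowSums(Tm), rep(1, 16))
  start <- c(0L, 1L, 1L, 0L)
  s0 <- sum(start * 2^(0:3))
  n_draw <- 20000
  set.seed(99)
  idx <- integer(n_draw)
  for (k in seq_len(n_draw)) {
    st <- sim_step(start, lat, tab, rates)
    idx[k] <- sum(st * 2^(0:3))
  }
  emp <- tabulate(idx + 1L, 16) / n_draw
  exact <- Tm[s0 + 1, ]
  se <- sqrt(pmax(exact * (1 - exact), 1e-12) / n_draw)
  expect_true(all(abs(emp - exact) <= 4 * se + 1e-4))
})

test_that("stationary distribution on the triangle matches the exact chain", {
  lat <- make_fixture("triangle")
  tab <- allosteric_table("product_activation")
  rates <- rate_params(kphr = 0.3, kdpr = 0.2, kphs = 0.4, kdps = 0.5)
  pi_exact <- stationary_distribution(exact_transition_matrix(lat, tab, rates))
  expect_equal(sum(pi_exact), 1, tolerance = 1e-10)
  n_rep <- 30
  n_steps <- 1500
  seeds <- 1000 + seq_len(n_rep)
  freq <- matrix(0, n_rep, 16)
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(table = tab, rates = rates,
                      schedule = stress_schedule(rates$kphr),
                      n_steps = n_steps, burn_in = 300, seed = seeds[r],
                      n_replicates = 1)
    tr <- run_sim(cfg, lat, record_bits = TRUE)
    idx <- state_index(attr(tr, "bits"))
    freq[r, ] <- tabulate(idx + 1L, 16) / length(idx)
  }
  emp <- colMeans(freq)
  se <- apply(freq, 2, stats::sd) / sqrt(n_rep)
  expect_true(all(abs(emp - pi_exact) <= 3 * se + 2e-3))
})

test_that("equilibrium is independent of the initial state", {
  base <- function(p0, seed) {
    steady_state(sim_config(model = "product_activation", n_steps = 500,
                            burn_in = 300, seed = seed, n_replicates = 15,
                            p0 = p0), canonical_graph)
  }
  lo <- base(0, 21)
  hi <- base(1, 22)
  expect_lt(abs(lo["R"] - hi["R"]), 0.02)
  expect_lt(abs(lo["S"] - hi["S"]), 0.02)
})

test_that("steady_state guards its preconditions", {
  cfg <- sim_config(schedule = stress_schedule(c(0.1, 1), c(0, 5)),
                    n_steps = 20, burn_in = 0, seed = 1, n_replicates = 2)
  expect_error(steady_state(cfg, canonical_graph), "constant")
  cfg2 <- sim_config(n_steps = 0, burn_in = 10, seed = 1, n_replicates = 2)
  expect_error(steady_state(cfg2, canonical_graph), "n_steps")
  # kph = 0 everywhere drains the lattice
  cfg3 <- sim_config(rates = rate_params(kphr = 0, kphs = 0),
                     schedule = stress_schedule(0), n_steps = 100,
                     burn_in = 100, seed = 1, n_replicates = 3)
  expect_equal(unname(steady_state(cfg3, canonical_graph)), c(0, 0))
})

test_that("synchronous mode is exposed and deterministic", {
  cfg <- sim_config(n_steps = 30, burn_in = 5, seed = 5, synchronous = TRUE,
                    n_replicates = 2)
  a <- run_replicates(cfg, canonical_graph)
  b <- run_replicates(cfg, canonical_graph)
  expect_identical(as.data.frame(a), as.data.frame(b))
})
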