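test_that("paralysable dead time: defining rule on hand-built streams", {
  # isolated event survives
  s1 <- singles_table(1000, 1)
  expect_equal(nrow(apply_dead_time(s1, 300)), 1L)
  # two events 400 ns apart on one module: both survive
  s2 <- singles_table(c(0, 400), c(1, 1))
  expect_equal(nrow(apply_dead_time(s2, 300)), 2L)
  # 200 ns apart on one module: the second is lost ...
  s3 <- singles_table(c(0, 200), c(1, 1))
  expect_equal(apply_dead_time(s3, 300)$t_ns, 0)
  # ... but different modules do not veto each other
  s4 <- singles_table(c(0, 200), c(1, 2))
  expect_equal(nrow(apply_dead_time(s4, 300)), 2L)
  # paralysis extends: 0, 250, 500 on one module -> only the first survives
  s5 <- singles_table(c(0, 250, 500), c(1, 1, 1))
  expect_equal(apply_dead_time(s5, 300)$t_ns, 0)
  # unordered input rejected
  expect_error(apply_dead_time(singles_table(c(5, 1), c(1, 2)), 300),
               "time-ordered")
})

test_that("paralysable throughput follows r * exp(-r tau) over three decades", {
  set.seed(51)
  tau <- 300
  for (r in c(1e4, 1e5, 1e6, 1e7)) {
    dur_ns <- 2e5 / r * 1e9  # 2e5 expected arrivals
    n <- rpois(1, 2e5)
    s <- singles_table(sort(runif(n, 0, dur_ns)), 1L)
    out <- nrow(apply_dead_time(s, tau))
    expected <- n * exp(-r * tau * 1e-9)
    expect_equal(out, expected, tolerance = 4 / sqrt(expected) + 0.003)
  }
})

test_that("energy window is a closed interval", {
  s <- singles_table(1:5 * 1e6, 1:5, energy = c(511, 430, 651, 440, 650))
  kept <- energy_window_filter(s)
  expect_equal(kept$energy, c(511, 440, 650))
})

test_that("window pairing and the multiples policies", {
  # two singles 1 ns apart on different modules: one prompt
  p <- pair_coincidences(singles_table(c(0, 1), c(1, 2)))
  expect_equal(nrow(p), 1L)
  expect_equal(p$dt_ns, -1)
  # 5 ns apart: outside the 3 ns window
  expect_equal(nrow(pair_coincidences(singles_table(c(0, 5), c(1, 2)))), 0L)
  # same module: discarded
  expect_equal(nrow(pair_coincidences(singles_table(c(0, 1), c(1, 1)))), 0L)
  # triple within the window: killAll discards, takeAllGoods keeps the
  # three distinct-module pairs
  s3 <- singles_table(c(0, 1, 2), c(1, 2, 3))
  expect_equal(nrow(pair_coincidences(s3, policy = "killAll")), 0L)
  expect_equal(nrow(pair_coincidences(s3, policy = "takeAllGoods")), 3L)
  # the window opens at the first single of a group: {0, 2.5} pair up and
  # 4.0 starts a new (lone) group even though it is within 3 ns of 2.5
  s <- singles_table(c(0, 2.5, 4), c(1, 2, 3))
  p3 <- pair_coincidences(s, policy = "killAll")
  expect_equal(nrow(p3), 1L)
  expect_equal(p3$dt_ns, -2.5)
})

test_that("truth classification partitions prompts exactly", {
  co <- classify_truth(pair_coincidences(singles_table(
    t_ns = c(0, 1, 100, 101, 200, 201),
    module = c(1, 20, 2, 30, 3, 40),
    decay_id = c(1, 1, 2, 2, 3, 4),
    n_scatters = c(0, 0, 1, 0, 0, 0))))
  expect_equal(co$truth, c("true", "scatter", "random"))
  bad <- data.table::data.table(decay_id1 = 1, decay_id2 = NA_real_,
                                nscat1 = 0L, nscat2 = 0L)
  expect_error(classify_truth(bad), "lineage")

  scn <- scenario_scatter("design_a", 2)
  sim <- run_simulation(scn, n_decays = 2e5, seed = 52)
  pc <- process_coincidences(sim)
  expect_equal(pc$counts[["prompts"]],
               pc$counts[["trues"]] + pc$counts[["scatters"]] +
                 pc$counts[["randoms"]])
})

test_that("randoms grow quadratically, trues linearly with activity", {
  run <- function(act, seed) {
    s <- make_sensitivity_source(activity_bq = act)
    scn <- scenario(design_a(), s$phantom, s$source)
    sim <- run_simulation(scn, duration = 6e6 / act, seed = seed,
                          max_decays = 1e7)
    process_coincidences(sim)$counts
  }
  c1 <- run(5e6, 53)
  c2 <- run(1e7, 54)
  # equal decay counts, doubled activity: trues stay, randoms double in
  # *count*, i.e. quadruple in rate
  r1 <- c1[["randoms"]] / c1[["trues"]]
  r2 <- c2[["randoms"]] / c2[["trues"]]
  expect_equal(r2 / r1, 2, tolerance = 0.25)
  expect_gt(c1[["randoms"]], 200)
  # with no phantom the scatter class is empty
  expect_equal(c1[["scatters"]], 0)
})
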