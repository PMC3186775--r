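test_that("a zero-rate phase only extends the clock", {
  tr <- simulate_bd_phase(bd_origin(), 0, 0, 7.5)
  expect_equal(nrow(tr$nodes), 1L)
  expect_equal(n_extant(tr), 1L)
  expect_equal(tr$present_time, 7.5)
})

test_that("phase simulation rejects invalid parameters", {
  expect_error(simulate_bd_phase(bd_origin(), -1, 0, 1), "rates")
  expect_error(simulate_bd_phase(bd_origin(), 1, -0.1, 1), "rates")
  expect_error(simulate_bd_phase(bd_origin(), 1, 0, -1), "duration")
})

test_that("pure-birth growth matches the Yule expectation E[N] = exp(lambda t)", {
  set.seed(101)
  n <- replicate(2000, n_extant(simulate_bd_phase(bd_origin(), 1, 0, 2)))
  se <- sd(n) / sqrt(length(n))
  expect_lt(abs(mean(n) - exp(2)), 3 * se)
})

test_that("pure-death survival matches exp(-mu t)", {
  set.seed(102)
  alive <- replicate(2000, n_extant(simulate_bd_phase(bd_origin(), 0, 0.2, 10)) > 0)
  p <- exp(-2)
  se <- sqrt(p * (1 - p) / length(alive))
  expect_lt(abs(mean(alive) - p), 3 * se)
})

test_that("scenario_config enforces its invariants", {
  expect_error(scenario_config(lambda_wax = 0.1, mu_wax = 0.2), "waxing")
  expect_error(scenario_config(lambda_wane = 0.5, mu_wane = 0.1), "waning")
  expect_error(scenario_config(lambda_wax = -1), "rates")
  expect_error(scenario_config(decline_duration = 0), "decline_duration")
  expect_error(scenario_config(n_final = 0), "n_final")
  expect_s3_class(scenario_config(), "scenario_config")
})

test_that("conditioned trees hit the final diversity and decline duration exactly", {
  set.seed(103)
  cfg <- scenario_config()
  trees <- lapply(1:20, function(i) simulate_two_phase_conditioned(cfg))
  for (tr in trees) {
    expect_identical(n_extant(tr), cfg$n_final)
    expect_equal(tr$present_time - tr$shift_time, cfg$decline_duration)
    # topological accounting: branching events = tips - 1
    n_splits <- sum(tr$nodes$id %in% tr$nodes$parent)
    n_tips <- sum(!(tr$nodes$id %in% tr$nodes$parent))
    expect_identical(n_splits, n_tips - 1L)
    # peak diversity is the standing diversity at the shift
    expect_identical(tr$peak_n, lineage_count_at(tr, cfg$decline_duration))
  }
})

test_that("identical seed and config give identical node tables", {
  cfg <- fast_config()
  set.seed(42); a <- simulate_two_phase_conditioned(cfg)
  set.seed(42); b <- simulate_two_phase_conditioned(cfg)
  expect_identical(a$nodes, b$nodes)
  expect_identical(a$shift_time, b$shift_time)
})

test_that("fixed-n growth stops at the target diversity", {
  set.seed(104)
  tr <- simulate_fixed_n(1, 0, 2)
  expect_equal(n_extant(tr), 2L)
  expect_equal(sum(tr$nodes$id %in% tr$nodes$parent), 1L)  # one branching
  # stopping at the instant of the split: root age = the first waiting time
  expect_equal(tr$present_time, tr$nodes$t_death[1])

  tr76 <- simulate_fixed_n(2.0, 0.1, 76)
  expect_equal(n_extant(tr76), 76L)
  expect_error(simulate_fixed_n(0.1, 0.2, 10), "lambda > mu")
})

test_that("fixed-n stop times track the deterministic-growth approximation", {
  set.seed(105)
  stops <- replicate(200, simulate_fixed_n(2.0, 0.1, 76)$present_time)
  expect_lt(abs(mean(stops) - log(76) / 1.9) / (log(76) / 1.9), 0.25)
})

test_that("stasis extension adds time but no events", {
  set.seed(106)
  tr <- reconstructed(simulate_fixed_n(1, 0, 10))
  expect_identical(extend_stasis(tr, 0)$nodes, tr$nodes)
  aged <- extend_stasis(tr, 10)
  expect_identical(aged$nodes, tr$nodes)
  expect_equal(aged$present_time, tr$present_time + 10)
  expect_identical(n_extant(aged), n_extant(tr))
  expect_lt(gamma_stat(aged)$gamma, gamma_stat(tr)$gamma)
  expect_error(extend_stasis(tr, -1), "duration")
})

test_that("per-replicate substream seeds are reproducible and bounded", {
  s1 <- replicate_seeds(7, 10)
  s2 <- replicate_seeds(7, 10)
  expect_identical(s1, s2)
  expect_true(all(s1 >= 1 & s1 < 2^31))
})
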