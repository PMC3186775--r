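test_that("time travel records diversity and gamma along the grid", {
  set.seed(401)
  cfg <- fast_config()
  tr <- simulate_two_phase_conditioned(cfg)
  tt <- time_travel(tr, grid = cfg$decline_duration:0)
  expect_identical(nrow(tt), length(cfg$decline_duration:0))
  expect_identical(tt$n_extant[tt$t_before_present == 0], cfg$n_final)
  expect_identical(tt$n_extant[tt$t_before_present == cfg$decline_duration],
                   tr$peak_n)
  expect_error(time_travel(tr, grid = c(0, 1e6)), "depth")
})

test_that("gamma is undefined exactly where fewer than 3 lineages existed", {
  h <- tree_4tip()
  tt <- time_travel(h, grid = c(0, 3, 5))
  expect_false(anyNA(tt$gamma[tt$n_extant >= 3]))
  expect_true(all(is.na(tt$gamma[tt$n_extant < 3])))
  expect_identical(tt$n_extant, c(3L, 4L, 2L))
})

test_that("aggregation follows the declared conventions", {
  s1 <- data.frame(t = c(2, 1, 0), n_extant = c(5, 4, 3),
                   gamma = c(-2, -1, NA))
  s2 <- data.frame(t = c(2, 1, 0), n_extant = c(6, 5, 4),
                   gamma = c(-3, 1, 0.5))
  # single series: means are the values, sd = 0 by convention
  one <- summarize_series(list(s1))
  expect_equal(one$mean_gamma[1:2], c(-2, -1))
  expect_true(all(one$sd_gamma == 0))
  expect_identical(one$n_defined, c(1L, 1L, 0L))
  # undefined gammas are excluded, not imputed
  two <- summarize_series(list(s1, s2))
  expect_equal(two$mean_gamma, c(-2.5, 0, 0.5))
  expect_identical(two$n_defined, c(2L, 2L, 1L))
  expect_equal(two$mean_n, c(5.5, 4.5, 3.5))
  # all significant -> fraction 1
  s3 <- data.frame(t = 0, n_extant = 10, gamma = -5)
  expect_equal(summarize_series(list(s3, s3))$frac_significant, 1)
  expect_error(summarize_series(list()), "no series")
  expect_error(summarize_series(list(s1, s1[1:2, ])), "common grid")
})

test_that("null-calibrated gammas are significant about 5% of the time", {
  set.seed(402)
  g <- replicate(150, gamma_stat(reconstructed(
    simulate_fixed_n(1, 0, 30, complete_last_interval = TRUE)))$gamma)
  frac <- mean(g < gamma_critical(0.05))
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / length(g)))
})

test_that("the decline experiment aggregates replicate trajectories", {
  cfg <- fast_config(seed = 403)
  ex <- run_decline_experiment(cfg)
  grid <- seq(cfg$decline_duration, 0, by = -1)
  expect_identical(nrow(ex$summary), length(grid))
  expect_equal(ex$summary$t_before_present, grid)
  expect_length(ex$trees, cfg$n_replicates)
  expect_equal(ex$summary$mean_n[grid == 0], cfg$n_final)
  # determinism: same master seed, byte-identical summaries
  ex2 <- run_decline_experiment(cfg)
  expect_identical(ex$summary, ex2$summary)
  expect_identical(ex$series, ex2$series)
  expect_error(run_decline_experiment(cfg, grid = c(0, 99)),
               "decline_duration")
})

test_that("under-sampling keeps the full-tree gamma at k = n_pool", {
  us <- run_undersampling_experiment(n_pool = 30, k_grid = c(30, 15, 8, 4),
                                     n_replicates = 4, seed = 404)
  expect_identical(nrow(us$summary), 4L)
  # the k = n_pool row is the unpruned tree: recompute directly
  set.seed(us$seeds[1])
  tr <- simulate_fixed_n(2, 0.1, 30, complete_last_interval = TRUE)
  full_gamma <- gamma_stat(reconstructed(tr))$gamma
  first <- us$series[us$series$replicate == 1 & us$series$k_retained == 30, ]
  expect_equal(first$gamma, full_gamma, tolerance = 1e-9)
  expect_error(run_undersampling_experiment(n_pool = 30, k_grid = c(10, 30),
                                            n_replicates = 2), "descend")
})

test_that("stasis trajectories decrease strictly toward the star bound", {
  st <- run_stasis_experiment(n_peak = 15, stasis_grid = 0:6,
                              n_replicates = 6, seed = 405)
  for (r in unique(st$series$replicate)) {
    tr <- st$series$gamma[st$series$replicate == r]
    expect_true(all(diff(tr) < 0))
    expect_true(all(tr > gamma_star_min(15)))
  }
  expect_equal(attr(st$summary, "gamma_star"), gamma_star_min(15))
})

test_that("the zero-speciation decline adds no nodes after the shift", {
  cfg <- scenario_config(lambda_wane = 0, mu_wane = 0.2, n_replicates = 5,
                         n_final = 5, decline_duration = 5, seed = 406)
  ex <- run_no_speciation_decline(cfg, aging_peaks = c(5, 20))
  for (tr in ex$decline$trees) {
    expect_true(all(tr$nodes$t_birth <= tr$shift_time))
    expect_lte(n_extant(tr), tr$peak_n)        # pure death erodes diversity
  }
  expect_named(ex$aging, c("n5", "n20"))
  expect_error(run_no_speciation_decline(fast_config()), "lambda_wane")
})
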