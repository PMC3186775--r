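test_that("lineage counts match hand enumeration on the 4-tip tree", {
  h <- tree_4tip()
  expect_identical(lineage_count_at(h, 0), 3L)   # extant tips
  expect_identical(lineage_count_at(h, 3), 4L)   # before the death at 4 My
  expect_identical(lineage_count_at(h, 5), 2L)   # exactly at the crown split
  expect_error(lineage_count_at(h, 7), "depth")
  expect_error(lineage_count_at(h, -1), "depth")
})

test_that("slicing truncates the event table correctly", {
  h <- tree_4tip()
  expect_identical(slice_at(h, 0), h)                      # identity
  s <- slice_at(h, 3)
  expect_identical(n_extant(s), 4L)                        # hand enumeration
  expect_equal(s$present_time, 3)
  # the lineage that died at 4 My is alive in the sliced tree
  expect_true(all(is.na(s$nodes$t_death[!(s$nodes$id %in% s$nodes$parent)])))
  expect_error(slice_at(h, 6), "depth")
  expect_error(slice_at(h, -0.5), "depth")
})

test_that("slicing a conditioned tree at the shift recovers the peak diversity", {
  set.seed(201)
  tr <- simulate_two_phase_conditioned(fast_config())
  s <- slice_at(tr, tr$present_time - tr$shift_time)
  expect_identical(n_extant(s), tr$peak_n)
})

test_that("reconstruction prunes extinct lineages and stays ultrametric", {
  h <- tree_4tip()
  r <- reconstructed(h)
  expect_identical(n_extant(r), 3L)
  expect_setequal(r$nodes$label[is.na(r$nodes$t_death)], c("t3", "t6", "t7"))
  # hand-derived structure: crown at 1 My, second split at 3 My
  splits <- sort(r$nodes$t_death[r$nodes$id %in% r$nodes$parent])
  expect_equal(splits, c(1, 3))
  # a tree with no extinct lineages is unchanged
  set.seed(202)
  y <- simulate_fixed_n(1, 0, 12)
  expect_true(all.equal(as.phylo(reconstructed(y)), as.phylo(y),
                        use.edge.length = TRUE))
  # a slice that leaves a single extant lineage still reconstructs
  expect_no_error(reconstructed(slice_at(tree_4tip(), 5.5)))
})

test_that("reconstruction agrees with the drop-extinct-tips oracle", {
  set.seed(203)
  cfg <- fast_config()
  for (i in 1:25) {
    tr <- simulate_two_phase_conditioned(cfg)
    mine <- as.phylo(reconstructed(tr))
    oracle <- ape::drop.fossil(as.phylo(tr))
    expect_true(isTRUE(all.equal(mine, oracle, use.edge.length = TRUE)))
    # commutation with slicing, against the same oracle
    t_slice <- runif(1, 0, cfg$decline_duration)
    sl <- slice_at(tr, t_slice)
    if (n_extant(sl) >= 2) {
      mine_s <- as.phylo(reconstructed(sl))
      oracle_s <- ape::drop.fossil(as.phylo(sl))
      expect_true(isTRUE(all.equal(mine_s, oracle_s, use.edge.length = TRUE)))
    }
  }
})

test_that("reconstructed tip depths agree to 1e-9", {
  set.seed(204)
  tr <- simulate_two_phase_conditioned(fast_config())
  phy <- as.phylo(reconstructed(tr))
  depths <- ape::node.depth.edgelength(phy)[seq_along(phy$tip.label)]
  expect_lt(diff(range(depths)), 1e-9)
})

test_that("internode intervals telescope to the crown age", {
  h <- reconstructed(tree_4tip())
  iv <- internode_intervals(h)
  expect_equal(unname(iv$g), c(2, 3))
  expect_equal(iv$crown_age, 5)
  expect_equal(iv$total_T, 13)
  # star construction, directly from intervals
  star <- internode_intervals(c(0, 0, 0, 4))
  expect_equal(star$crown_age, 4)
  expect_equal(star$n, 5L)
  # random reconstructed trees: sum g = crown age
  set.seed(205)
  for (i in 1:10) {
    r <- reconstructed(simulate_fixed_n(2, 0.3, 20))
    iv <- internode_intervals(r)
    crown <- r$present_time - min(r$nodes$t_death[r$nodes$id %in% r$nodes$parent])
    expect_equal(sum(iv$g), crown)
  }
  expect_error(internode_intervals(c(1)), "3 tips")
  expect_error(internode_intervals(tree_4tip()), "ultrametric")
})

test_that("interval extraction from phylo and bd_tree agree", {
  set.seed(206)
  r <- reconstructed(simulate_fixed_n(1.5, 0.2, 15))
  a <- internode_intervals(r)
  b <- internode_intervals(as.phylo(r))
  expect_equal(a$g, b$g, tolerance = 1e-9)
  expect_error(internode_intervals(as.phylo(tree_4tip())), "ultrametric")
})

test_that("subsampling is nested-friendly, identity at k = n", {
  set.seed(207)
  r <- reconstructed(simulate_fixed_n(1, 0, 20))
  expect_identical(subsample_tips(r, 20)$nodes, r$nodes)
  s3 <- subsample_tips(r, 3)
  expect_identical(n_extant(s3), 3L)
  phy3 <- as.phylo(s3)
  expect_true(ape::is.ultrametric(phy3, tol = 1e-9))
  expect_error(subsample_tips(r, 2), "3 <= k")
  expect_error(subsample_tips(r, 21), "3 <= k")
  # prefix-keeping gives nested tip sets
  ord <- sample(extant_tips(r))
  k5 <- keep_tips(r, ord[1:5])
  k4 <- keep_tips(r, ord[1:4])
  expect_true(all(k4$nodes$label[is.na(k4$nodes$t_death)] %in%
                    k5$nodes$label[is.na(k5$nodes$t_death)]))
})

test_that("heavy subsampling drags gamma down on pure-birth trees", {
  set.seed(208)
  d <- replicate(30, {
    r <- reconstructed(simulate_fixed_n(2, 0, 76, complete_last_interval = TRUE))
    gamma_stat(subsample_tips(r, 10))$gamma - gamma_stat(r)$gamma
  })
  expect_lt(mean(d), 0)
})
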