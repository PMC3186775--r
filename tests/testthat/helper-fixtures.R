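# Hand-built 4-tip tree used throughout: origin splits at 1 My, further
# splits at 2 and 3 My, one lineage dies at 4 My, present at 6 My.
# Extant tips: t3, t6, t7; reconstructed tree has splits at 1 and 3 My,
# so internode intervals are g2 = 2, g3 = 3.
tree_4tip <- function() {
  nd <- data.frame(
    id = 1:7,
    parent = c(NA, 1L, 1L, 2L, 2L, 4L, 4L),
    t_birth = c(0, 1, 1, 2, 2, 3, 3),
    t_death = c(1, 2, NA, 3, 4, NA, NA))
  bd_tree(nd, present_time = 6)
}

# gamma for the hand-built tree's reconstructed intervals (g2=2, g3=3),
# evaluated by hand: T = 2*2 + 3*3 = 13; numerator = 4 - 13/2
gamma_4tip_expected <- -2.5 / (13 * sqrt(1 / 12))

# independent brute-force gamma: explicit double loop over sorted node
# depths of an ultrametric phylo, no shared code with the package pipeline
gamma_depth_oracle <- function(phy) {
  ages <- sort(as.numeric(ape::branching.times(phy)), decreasing = TRUE)
  n <- length(ages) + 1L
  splits <- ages[1] - ages            # forward from crown
  bounds <- c(splits, ages[1])        # ... to the present
  g <- numeric(n)                     # g[k] = interval with k lineages
  for (k in 2:n) g[k] <- bounds[k] - bounds[k - 1]
  total <- 0
  for (j in 2:n) total <- total + j * g[j]
  acc <- 0
  for (i in 2:(n - 1)) {
    ti <- 0
    for (k in 2:i) ti <- ti + k * g[k]
    acc <- acc + ti
  }
  (acc / (n - 2) - total / 2) / (total * sqrt(1 / (12 * (n - 2))))
}

# random interval vectors (g2..gn) for property tests
random_intervals <- function(n) {
  g <- stats::rexp(n - 1)
  # occasionally zero-out some interior intervals to probe near-star shapes
  if (stats::runif(1) < 0.3) g[sample(n - 1, floor((n - 1) / 2))] <- 0
  if (sum(g) == 0) g[n - 1] <- 1
  g
}

# small, fast scenario for experiment-structure tests
fast_config <- function(...) {
  scenario_config(lambda_wax = 1.0, mu_wax = 0.1,
                  lambda_wane = 0.1, mu_wane = 0.4,
                  decline_duration = 5, n_final = 5, n_replicates = 5,
                  t1_max = 20, ...)
}
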