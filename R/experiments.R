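#' "Time travel" through a tree's history
#'
#' Evaluates standing diversity and the gamma statistic of the reconstructed
#' (extant-only) phylogeny at each of a grid of past time points: at every
#' grid time the full tree is sliced ([slice_at()]), pruned to the lineages
#' that would have made up the molecular phylogeny then ([reconstructed()]),
#' and summarized.  Gamma is `NA` wherever fewer than 3 lineages were alive.
#'
#' @param tree a `bd_tree`.
#' @param grid time points, My before the present (default every 1 My
#'   through a 10-My decline).
#' @param alpha significance level for the slowdown test.
#' @return data.frame with columns `t_before_present`, `n_extant`, `gamma`.
#' @export
time_travel <- function(tree, grid = 0:10, alpha = 0.05) {
  stopifnot(inherits(tree, "bd_tree"))
  origin_birth <- tree$nodes$t_birth[is.na(tree$nodes$parent)]
  if (any(grid < 0 | grid >= tree$present_time - origin_birth))
    stop("grid values must lie within the tree's depth", call. = FALSE)
  rows <- lapply(grid, function(t) {
    sl <- slice_at(tree, t)
    n <- n_extant(sl)
    g <- if (n >= 3L) {
      gamma_stat(reconstructed(sl), alpha = alpha)$gamma
    } else NA_real_
    data.frame(t_before_present = t, n_extant = n, gamma = g)
  })
  do.call(rbind, rows)
}

#' Aggregate replicate time-travel series
#'
#' Per grid point: mean and sd of the defined gamma values, the fraction of
#' defined gammas below the one-tailed critical value, the mean lineage
#' count, and how many replicates had undefined gamma (fewer than 3
#' lineages) — those are excluded from the gamma averages, not imputed.
#'
#' @param series list of data.frames as returned by [time_travel()] (or any
#'   frames sharing a first grid column, `n_extant` and `gamma`), all on a
#'   common grid.
#' @param alpha significance level defining `frac_significant`.
#' @return data.frame of class `experiment_summary`, one row per grid point:
#'   grid column, `mean_gamma`, `sd_gamma`, `frac_significant`, `mean_n`,
#'   `n_defined`, `n_replicates`.
#' @export
summarize_series <- function(series, alpha = 0.05) {
  if (length(series) == 0L) stop("no series supplied", call. = FALSE)
  key <- names(series[[1]])[1]
  grid <- series[[1]][[key]]
  if (!all(vapply(series, function(s) identical(s[[key]], grid), logical(1))))
    stop("all series must share a common grid", call. = FALSE)
  crit <- gamma_critical(alpha)
  gmat <- matrix(unlist(lapply(series, function(s) as.numeric(s$gamma))),
                 nrow = length(grid))
  nmat <- matrix(unlist(lapply(series, function(s) as.numeric(s$n_extant))),
                 nrow = length(grid))
  out <- data.frame(
    grid = grid,
    mean_gamma = apply(gmat, 1, function(v) mean(v[!is.na(v)])),
    sd_gamma = apply(gmat, 1, function(v) {
      d <- v[!is.na(v)]
      if (length(d) <= 1L) 0 else sd(d)
    }),
    frac_significant = apply(gmat, 1, function(v) {
      d <- v[!is.na(v)]
      if (length(d) == 0L) NA_real_ else mean(d < crit)
    }),
    mean_n = rowMeans(nmat),
    n_defined = as.integer(rowSums(!is.na(gmat))),
    n_replicates = length(series))
  names(out)[1] <- key
  class(out) <- c("experiment_summary", "data.frame")
  out
}

# shared replicate loop: simulate a conditioned tree per replicate seed and
# time travel it on the grid
decline_replicates <- function(config, grid, alpha, seeds) {
  lapply(seq_along(seeds), function(r) {
    set.seed(seeds[r])
    tree <- tryCatch(simulate_two_phase_conditioned(config),
                     error = function(e) stop("replicate ", r, ": ",
                                              conditionMessage(e),
                                              call. = FALSE))
    list(tree = tree, series = time_travel(tree, grid, alpha = alpha))
  })
}

#' Decline experiment: gamma through the waning phase
#'
#' Simulates `config$n_replicates` conditioned rise-and-fall trees and time
#' travels each through the decline phase (default: every 1 My from the
#' rate shift to the present), aggregating mean gamma, the fraction of
#' replicates with a significant slowdown, and mean diversity per time
#' point.
#'
#' @param config a [scenario_config()].
#' @param grid time grid, My before present, within
#'   `[0, config$decline_duration]`.
#' @param alpha significance level.
#' @param seed master seed; defaults to `config$seed`.
#' @return list of class `experiment_result`: `summary`
#'   (an [summarize_series()] table with first column `t_before_present`),
#'   `series` (per-replicate long data.frame with `replicate` column),
#'   `trees` (list of accepted `bd_tree`s), `seeds`, `config`.
#' @export
run_decline_experiment <- function(config,
                                   grid = seq(config$decline_duration, 0, by = -1),
                                   alpha = 0.05, seed = config$seed) {
  config <- validate_scenario_config(config)
  if (any(grid < 0 | grid > config$decline_duration))
    stop("grid must lie within [0, decline_duration]", call. = FALSE)
  seeds <- replicate_seeds(seed, config$n_replicates)
  reps <- decline_replicates(config, grid, alpha, seeds)
  series <- lapply(reps, `[[`, "series")
  long <- do.call(rbind, Map(function(s, r) cbind(replicate = r, s),
                             series, seq_along(series)))
  structure(list(summary = summarize_series(series, alpha),
                 series = long,
                 trees = lapply(reps, `[[`, "tree"),
                 seeds = seeds, config = config),
            class = "experiment_result")
}

#' Under-sampling experiment: gamma under progressive tip loss
#'
#' Grows each replicate to a fixed standing diversity `n_pool`
#' ([simulate_fixed_n()]), then removes extant tips at random down a nested
#' grid of retained tip counts (the `k-1` tip set is always a subset of the
#' `k` set, via a single random permutation per replicate), recording gamma
#' at every step.  Emulates incomplete taxon sampling — and extinction viewed
#' as "evolutionary under-sampling".
#'
#' @param lambda,mu growth-phase rates (defaults: the fast rise, 2.0/0.1).
#' @param n_pool standing diversity at which growth stops.
#' @param k_grid descending tip counts to retain; default 12 approximately
#'   log-spaced values from `n_pool` down to 10.
#' @param n_replicates replicates.
#' @param alpha significance level.
#' @param seed master seed.
#' @param complete_last_interval passed to [simulate_fixed_n()]; the default
#'   `TRUE` draws the final internode interval in full.
#' @return list of class `experiment_result` with `summary` (first column
#'   `k_retained`), `series`, `seeds`.
#' @export
run_undersampling_experiment <- function(lambda = 2.0, mu = 0.1, n_pool = 76,
                                         k_grid = NULL, n_replicates = 100,
                                         alpha = 0.05, seed = NULL,
                                         complete_last_interval = TRUE) {
  if (is.null(k_grid))
    k_grid <- sort(unique(round(exp(seq(log(n_pool), log(10),
                                        length.out = 12)))),
                   decreasing = TRUE)
  if (any(diff(k_grid) >= 0) || k_grid[1] > n_pool || min(k_grid) < 3)
    stop("k_grid must descend from <= n_pool with minimum >= 3",
         call. = FALSE)
  seeds <- replicate_seeds(seed, n_replicates)
  series <- lapply(seq_len(n_replicates), function(r) {
    set.seed(seeds[r])
    tree <- simulate_fixed_n(lambda, mu, n_pool,
                             complete_last_interval = complete_last_interval)
    recon <- reconstructed(tree)
    tip_order <- sample(extant_tips(recon))
    rows <- lapply(k_grid, function(k) {
      sub <- keep_tips(recon, tip_order[seq_len(k)])
      data.frame(k_retained = k, n_extant = k,
                 gamma = gamma_stat(sub, alpha = alpha)$gamma)
    })
    do.call(rbind, rows)
  })
  long <- do.call(rbind, Map(function(s, r) cbind(replicate = r, s),
                             series, seq_along(series)))
  structure(list(summary = summarize_series(series, alpha), series = long,
                 seeds = seeds),
            class = "experiment_result")
}

#' Stasis (pure aging) experiment
#'
#' Grows each replicate to `n_peak` lineages and then simply extends the
#' terminal branches along a grid of stasis durations ([extend_stasis()]),
#' with no further speciation or extinction, tracking gamma as the clade
#' ages.  Gamma decreases strictly with stasis time toward the
#' star-phylogeny bound, reported as attribute `"gamma_star"` (the value at
#' infinite aging).
#'
#' @param lambda,mu growth-phase rates.
#' @param n_peak standing diversity held in stasis (the study uses 10
#'   and 76).
#' @param stasis_grid elapsed stasis times, My.
#' @param n_replicates replicates.
#' @param alpha significance level.
#' @param seed master seed.
#' @param complete_last_interval passed to [simulate_fixed_n()].
#' @return list of class `experiment_result` with `summary` (first column
#'   `t_stasis`), `series`, `seeds`; attribute `"gamma_star"` on the summary
#'   holds [gamma_star_min()]`(n_peak)`.
#' @export
run_stasis_experiment <- function(lambda = 2.0, mu = 0.1, n_peak = 76,
                                  stasis_grid = 0:10, n_replicates = 100,
                                  alpha = 0.05, seed = NULL,
                                  complete_last_interval = TRUE) {
  if (any(stasis_grid < 0)) stop("stasis times must be >= 0", call. = FALSE)
  seeds <- replicate_seeds(seed, n_replicates)
  series <- lapply(seq_len(n_replicates), function(r) {
    set.seed(seeds[r])
    tree <- simulate_fixed_n(lambda, mu, n_peak,
                             complete_last_interval = complete_last_interval)
    recon <- reconstructed(tree)
    rows <- lapply(stasis_grid, function(t) {
      aged <- extend_stasis(recon, t)
      data.frame(t_stasis = t, n_extant = n_extant(aged),
                 gamma = gamma_stat(aged, alpha = alpha)$gamma)
    })
    do.call(rbind, rows)
  })
  long <- do.call(rbind, Map(function(s, r) cbind(replicate = r, s),
                             series, seq_along(series)))
  summary <- summarize_series(series, alpha)
  attr(summary, "gamma_star") <- gamma_star_min(n_peak)
  structure(list(summary = summary, series = long, seeds = seeds),
            class = "experiment_result")
}

#' Decline with zero speciation, against pure-aging references
#'
#' The decline experiment rerun with no speciation at all in the waning
#' phase (`lambda_wane = 0`): diversity erodes by pure extinction, so no new
#' nodes can make gamma more positive.  The result bundles the two
#' pure-aging reference curves (peak diversities `n_final` and the mean
#' peak, by default 10 and 76), between which the zero-speciation decline
#' trajectory is expected to fall.
#'
#' @param config a [scenario_config()] with `lambda_wane = 0` (default:
#'   rise 2.0/0.1, decline 0.0/0.2, the standard conditioning).
#' @param aging_peaks peak diversities for the reference aging curves.
#' @param grid time grid, My before present.
#' @param alpha significance level.
#' @param seed master seed.
#' @return list of class `experiment_result`: `decline` (an
#'   [run_decline_experiment()] result), `aging` (named list of
#'   [run_stasis_experiment()] results).
#' @export
run_no_speciation_decline <- function(config = scenario_config(
                                        lambda_wane = 0, mu_wane = 0.2),
                                      aging_peaks = c(10, 76),
                                      grid = seq(config$decline_duration, 0,
                                                 by = -1),
                                      alpha = 0.05, seed = config$seed) {
  config <- validate_scenario_config(config)
  if (config$lambda_wane != 0)
    stop("this experiment requires lambda_wane = 0", call. = FALSE)
  seeds <- replicate_seeds(seed, length(aging_peaks) + 1L)
  decline <- run_decline_experiment(config, grid = grid, alpha = alpha,
                                    seed = seeds[1])
  aging <- lapply(seq_along(aging_peaks), function(i) {
    run_stasis_experiment(config$lambda_wax, config$mu_wax,
                          n_peak = aging_peaks[i],
                          stasis_grid = sort(config$decline_duration - grid),
                          n_replicates = config$n_replicates, alpha = alpha,
                          seed = seeds[i + 1L])
  })
  names(aging) <- paste0("n", aging_peaks)
  structure(list(decline = decline, aging = aging, config = config),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result>\n")
  if (!is.null(x$summary)) print(utils::head(as.data.frame(x$summary), 12))
  invisible(x)
}
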