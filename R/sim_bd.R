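#' Scenario configuration for the two-phase (wax/wane) simulations
#'
#' Bundles the rates and conditioning parameters of one rise-and-fall
#' scenario.  Diversity first grows exponentially at
#' (`lambda_wax`, `mu_wax`) and then declines at (`lambda_wane`, `mu_wane`);
#' accepted trees are conditioned on having exactly `n_final` extant tips at
#' the present and a decline phase lasting exactly `decline_duration` My.
#' All rates are events/lineage/My.
#'
#' Defaults follow the study design: decline at `lambda_wane = 0.1`,
#' `mu_wane = 0.3` (net -0.2/My), a 10-My decline conditioned on 10 extant
#' lineages, and a fast rise (`lambda_wax = 2`, `mu_wax = 0.1`, net +1.9/My)
#' giving a wax/wane speciation ratio of 20.  Use `lambda_wax = 0.25` for the
#' ratio-2.5 (fast relative decline) scenario.
#'
#' @param lambda_wax,mu_wax speciation/extinction rate of the growth phase.
#' @param lambda_wane,mu_wane speciation/extinction rate of the decline phase.
#' @param decline_duration length of the decline phase, My.
#' @param n_final number of extant tips conditioned on at the present.
#' @param n_replicates replicates per experiment.
#' @param t1_max cap on proposed growth-phase durations, My (the rejection
#'   sampler draws the growth duration uniformly on `[0, t1_max]`).
#' @param seed optional master seed for experiment drivers.
#' @param max_attempts rejection-sampling proposal budget per accepted tree.
#' @param n_cap live-lineage cap: growth-phase proposals whose standing
#'   diversity exceeds this are rejected early (their probability of
#'   declining to `n_final` tips is numerically zero).
#' @return A validated list of class `scenario_config`.
#' @export
scenario_config <- function(lambda_wax = 2.0, mu_wax = 0.1,
                            lambda_wane = 0.1, mu_wane = 0.3,
                            decline_duration = 10, n_final = 10,
                            n_replicates = 100, t1_max = 60,
                            seed = NULL, max_attempts = 1e6, n_cap = 5000) {
  cfg <- structure(
    list(lambda_wax = lambda_wax, mu_wax = mu_wax,
         lambda_wane = lambda_wane, mu_wane = mu_wane,
         decline_duration = decline_duration, n_final = as.integer(n_final),
         n_replicates = as.integer(n_replicates), t1_max = t1_max,
         seed = seed, max_attempts = max_attempts, n_cap = as.integer(n_cap)),
    class = "scenario_config")
  validate_scenario_config(cfg)
}

#' @rdname scenario_config
#' @param cfg a `scenario_config`.
#' @export
validate_scenario_config <- function(cfg) {
  rates <- unlist(cfg[c("lambda_wax", "mu_wax", "lambda_wane", "mu_wane")])
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rates must be finite and >= 0", call. = FALSE)
  if (cfg$lambda_wax - cfg$mu_wax <= 0)
    stop("waxing phase must grow: lambda_wax - mu_wax > 0 required",
         call. = FALSE)
  if (cfg$lambda_wane - cfg$mu_wane >= 0)
    stop("waning phase must decline: lambda_wane - mu_wane < 0 required",
         call. = FALSE)
  if (cfg$decline_duration <= 0) stop("decline_duration must be > 0",
                                      call. = FALSE)
  if (cfg$n_final < 1L) stop("n_final must be >= 1", call. = FALSE)
  if (cfg$n_replicates < 1L) stop("n_replicates must be >= 1", call. = FALSE)
  if (cfg$t1_max <= 0) stop("t1_max must be > 0", call. = FALSE)
  cfg
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(paste0("<scenario_config> wax: lambda=%.3g mu=%.3g | ",
                     "wane: lambda=%.3g mu=%.3g | decline %.3g My -> ",
                     "%d tips | %d replicates\n"),
              x$lambda_wax, x$mu_wax, x$lambda_wane, x$mu_wane,
              x$decline_duration, x$n_final, x$n_replicates))
  invisible(x)
}

#' Read / write a scenario configuration (YAML or JSON)
#'
#' The on-disk keys mirror the `scenario_config` field names exactly; the
#' format is chosen by file extension (`.yml`/`.yaml` or `.json`).
#'
#' @param path file path.
#' @param cfg a `scenario_config`.
#' @return `read_scenario_config()`: a validated `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("config file must be .yaml/.yml or .json", call. = FALSE)
  known <- names(formals(scenario_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(scenario_config, vals)
}

#' @rdname read_scenario_config
#' @export
write_scenario_config <- function(cfg, path) {
  vals <- unclass(cfg)
  vals <- vals[!vapply(vals, is.null, logical(1))]
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(vals, path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else stop("config file must be .yaml/.yml or .json", call. = FALSE)
  invisible(path)
}

# rebuild a bd_tree from the C++ lineage-table output (0-based parents)
tree_from_cpp <- function(res, present_time, shift_time = NA_real_,
                          peak_n = NA_integer_) {
  nd <- data.frame(id = seq_along(res$parent),
                   parent = ifelse(is.na(res$parent), NA_integer_,
                                   res$parent + 1L),
                   t_birth = res$t_birth, t_death = res$t_death)
  bd_tree(nd, present_time = present_time, shift_time = shift_time,
          peak_n = peak_n)
}

#' Advance a tree by one constant-rate birth--death phase
#'
#' Continuous-time Markov simulation: each live lineage independently
#' speciates at rate `lambda` and goes extinct at rate `mu`, with
#' exponential waiting times, for exactly `duration` My.  A tree with no
#' live lineages is returned unchanged except for the advanced present.
#'
#' @param tree a `bd_tree` (e.g. [bd_origin()]).
#' @param lambda,mu per-lineage rates, events/lineage/My (>= 0).
#' @param duration phase length, My (>= 0).
#' @param n_cap optional live-lineage cap; when exceeded the simulation
#'   stops and the result carries `attr(, "capped") = TRUE`.
#' @return the advanced `bd_tree`.
#' @export
simulate_bd_phase <- function(tree, lambda, mu, duration, n_cap = Inf) {
  stopifnot(inherits(tree, "bd_tree"))
  if (lambda < 0 || mu < 0) stop("rates must be >= 0", call. = FALSE)
  if (duration < 0) stop("duration must be >= 0", call. = FALSE)
  cap <- if (is.finite(n_cap)) as.integer(n_cap) else .Machine$integer.max
  res <- bd_phase_cpp(ifelse(is.na(tree$nodes$parent), NA_integer_,
                             tree$nodes$parent - 1L),
                      tree$nodes$t_birth, tree$nodes$t_death,
                      tree$present_time, lambda, mu, duration, cap)
  out <- tree_from_cpp(res, present_time = tree$present_time + duration,
                       shift_time = tree$shift_time, peak_n = tree$peak_n)
  if (res$capped) attr(out, "capped") <- TRUE
  out
}

#' Simulate a rise-and-fall tree conditioned on final diversity and
#' decline duration
#'
#' Rejection sampler for the two-phase process: a growth-phase duration is
#' proposed uniformly on `[0, t1_max]`; phase 1 is simulated from a single
#' origin lineage at (`lambda_wax`, `mu_wax`); proposals extinct at the shift
#' (or exceeding the live-lineage cap) are rejected; phase 2 then runs for
#' `decline_duration` at (`lambda_wane`, `mu_wane`) and the tree is accepted
#' iff exactly `n_final` lineages survive to the present.  The accepted tree
#' records the shift time and the peak diversity (live-lineage count at the
#' shift).
#'
#' @param config a [scenario_config()].
#' @return a `bd_tree` with `shift_time`, `peak_n` and attribute
#'   `"attempts"` (proposals used).
#' @export
simulate_two_phase_conditioned <- function(config) {
  config <- validate_scenario_config(config)
  for (attempt in seq_len(config$max_attempts)) {
    t1 <- runif(1, 0, config$t1_max)
    p1 <- bd_phase_cpp(NA_integer_, 0, NA_real_, 0,
                       config$lambda_wax, config$mu_wax, t1, config$n_cap)
    if (p1$capped || p1$n_alive == 0L) next
    p2 <- bd_phase_cpp(p1$parent, p1$t_birth, p1$t_death, t1,
                       config$lambda_wane, config$mu_wane,
                       config$decline_duration, config$n_cap)
    if (p2$capped) next
    if (p2$n_alive == config$n_final) {
      out <- tree_from_cpp(p2, present_time = t1 + config$decline_duration,
                           shift_time = t1, peak_n = p1$n_alive)
      attr(out, "attempts") <- attempt
      return(out)
    }
  }
  stop(sprintf(paste0("conditioned simulation failed: no acceptance in ",
                      "%d attempts"), config$max_attempts), call. = FALSE)
}

#' Grow a clade to a fixed standing diversity
#'
#' Simulates a constant-rate birth--death tree from one origin lineage and
#' stops the instant the live-lineage count first reaches `n_stop`; runs that
#' go extinct first are rejected and retried.  With
#' `complete_last_interval = TRUE` the present is instead placed at the time
#' the *next* event would have occurred (the event is not executed), so the
#' final internode interval is the full exponential waiting time — the
#' standard sample for trees conditioned on `n` tips, and the variant to use
#' for null calibration of the gamma statistic.
#'
#' @param lambda,mu per-lineage rates; `lambda > mu >= 0` required.
#' @param n_stop target live-lineage count (>= 2).
#' @param complete_last_interval see above.
#' @param max_attempts retry budget for runs that go extinct.
#' @return a `bd_tree` with exactly `n_stop` extant tips; attribute
#'   `"attempts"` counts the runs used.
#' @export
simulate_fixed_n <- function(lambda, mu, n_stop,
                             complete_last_interval = FALSE,
                             max_attempts = 1e6) {
  if (!(lambda > mu && mu >= 0))
    stop("need lambda > mu >= 0 (stopping is not guaranteed otherwise)",
         call. = FALSE)
  if (n_stop < 2) stop("n_stop must be >= 2", call. = FALSE)
  for (attempt in seq_len(max_attempts)) {
    res <- bd_grow_to_n_cpp(lambda, mu, as.integer(n_stop),
                            complete_last_interval)
    if (!res$extinct) {
      out <- tree_from_cpp(res, present_time = res$present_time)
      attr(out, "attempts") <- attempt
      return(out)
    }
  }
  stop("clade went extinct in every attempt", call. = FALSE)
}

#' Age a clade in stasis
#'
#' Extends every extant terminal branch by `duration` My without adding or
#' removing any lineage: the present simply advances.  This is the
#' "pure aging" manipulation — with three or more extant tips it strictly
#' decreases the gamma statistic, approaching the star-phylogeny bound
#' [gamma_star_min()] as `duration` grows.
#'
#' @param tree a `bd_tree` with at least one extant tip.
#' @param duration My to add (>= 0).
#' @return the aged `bd_tree`.
#' @export
extend_stasis <- function(tree, duration) {
  stopifnot(inherits(tree, "bd_tree"))
  if (duration < 0) stop("duration must be >= 0", call. = FALSE)
  if (n_extant(tree) < 1L) stop("tree has no extant tips", call. = FALSE)
  bd_tree(tree$nodes, present_time = tree$present_time + duration,
          shift_time = tree$shift_time, peak_n = tree$peak_n)
}

#' Derive per-replicate substream seeds from a master seed
#'
#' Each replicate of an experiment is simulated under its own seed so that
#' individual replicates are reproducible in isolation.
#'
#' @param seed master seed (integer) or `NULL` to leave the RNG state alone
#'   and draw seeds from it.
#' @param n number of substream seeds.
#' @return integer vector of length `n`.
#' @export
replicate_seeds <- function(seed, n) {
  if (!is.null(seed)) set.seed(seed)
  sample.int(2147483646L, n)
}
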