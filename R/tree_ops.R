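#' Truncate a tree at a past time point
#'
#' Returns the tree as it stood `t_before_present` My ago: lineages alive at
#' the slice time become the new extant set, lineages born after it are
#' dropped, and the slice time becomes the new present.  A lineage is counted
#' alive on the half-open interval `[t_birth, t_death)`, so a lineage born
#' exactly at the slice is kept (with a zero-length branch) and one dying
#' exactly at the slice is not — events with probability zero in simulation,
#' but fixed for hand-built inputs.
#'
#' @param tree a `bd_tree`.
#' @param t_before_present slice time, My before the present; must satisfy
#'   `0 <= t_before_present < present_time - t_birth(origin)`.
#' @return the truncated `bd_tree`.
#' @export
slice_at <- function(tree, t_before_present) {
  stopifnot(inherits(tree, "bd_tree"))
  new_present <- tree$present_time - t_before_present
  origin_birth <- tree$nodes$t_birth[is.na(tree$nodes$parent)]
  if (t_before_present < 0 || new_present <= origin_birth)
    stop("slice time must lie within the tree's depth", call. = FALSE)
  if (t_before_present == 0) return(tree)
  nd <- tree$nodes
  keep <- nd$t_birth <= new_present
  nd <- nd[keep, , drop = FALSE]
  # renumber 1..M (creation order is preserved, so parents stay first)
  new_id <- cumsum(keep)
  nd$id <- seq_len(nrow(nd))
  nd$parent <- ifelse(is.na(nd$parent), NA_integer_, new_id[nd$parent])
  # lineages whose death/split was dropped are alive at the slice; one dying
  # exactly at the slice stays dead ([t_birth, t_death) convention)
  nd$t_death[!is.na(nd$t_death) & nd$t_death > new_present] <- NA_real_
  shift <- if (!is.na(tree$shift_time) && tree$shift_time <= new_present)
    tree$shift_time else NA_real_
  bd_tree(nd, present_time = new_present, shift_time = shift,
          peak_n = if (is.na(shift)) NA_integer_ else tree$peak_n)
}

#' Number of lineages alive at a past time point
#'
#' Counts every lineage alive `t_before_present` My ago, including those that
#' later went extinct (the true standing diversity, not the reconstructed
#' lineage count).  Aliveness uses the `[t_birth, t_death)` convention of
#' [slice_at()].
#'
#' @inheritParams slice_at
#' @return integer count.
#' @export
lineage_count_at <- function(tree, t_before_present) {
  stopifnot(inherits(tree, "bd_tree"))
  tt <- tree$present_time - t_before_present
  origin_birth <- tree$nodes$t_birth[is.na(tree$nodes$parent)]
  if (t_before_present < 0 || tt < origin_birth)
    stop("slice time must lie within the tree's depth", call. = FALSE)
  nd <- tree$nodes
  sum(nd$t_birth <= tt & (is.na(nd$t_death) | nd$t_death > tt))
}

# induced tree of a set of extant tips: drop all lineages with no selected
# descendant, suppress unifurcations by concatenating branch lengths.
# The path from the origin to the crown split collapses into the new stem.
induced_tree <- function(tree, tip_ids) {
  nd <- tree$nodes
  n <- nrow(nd)
  selected <- nd$id %in% tip_ids
  if (any(selected & !is.na(nd$t_death)))
    stop("selected tips must be extant", call. = FALSE)
  # children ids precede nothing: parents < children, so one reverse sweep
  n_desc <- as.integer(selected)
  for (i in n:2) {
    p <- nd$parent[i]
    if (!is.na(p)) n_desc[p] <- n_desc[p] + n_desc[i]
  }
  keep_kids <- integer(n)   # number of children subtrees containing tips
  for (i in n:2) {
    p <- nd$parent[i]
    if (!is.na(p) && n_desc[i] > 0L) keep_kids[p] <- keep_kids[p] + 1L
  }
  is_split <- keep_kids >= 2L            # real nodes of the induced tree
  is_new <- selected | is_split
  if (sum(selected) == 0L) stop("no tips selected", call. = FALSE)
  # map each retained node to its nearest strict ancestor that is a split
  anc_split <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    p <- nd$parent[i]
    if (!is.na(p)) anc_split[i] <- if (is_split[p]) p else anc_split[p]
  }
  old_ids <- nd$id[is_new]
  new_of <- integer(n)
  new_of[old_ids] <- seq_along(old_ids)   # old ids ascend => parents first
  origin_birth <- nd$t_birth[is.na(nd$parent)]
  out <- data.frame(
    id = seq_along(old_ids),
    parent = ifelse(is.na(anc_split[old_ids]), NA_integer_,
                    new_of[pmax(anc_split[old_ids], 1L)]),
    t_birth = ifelse(is.na(anc_split[old_ids]), origin_birth,
                     nd$t_death[pmax(anc_split[old_ids], 1L)]),
    t_death = ifelse(is_split[old_ids], nd$t_death[old_ids], NA_real_),
    label = nd$label[old_ids])
  bd_tree(out, present_time = tree$present_time,
          shift_time = tree$shift_time, peak_n = tree$peak_n)
}

#' Prune a tree to its extant lineages (the "molecular" tree)
#'
#' Drops every lineage with no extant descendant and suppresses the resulting
#' unifurcations by concatenating branch lengths.  The output is ultrametric:
#' what a molecular phylogeny of the living species records.
#'
#' @param tree a `bd_tree` with at least one extant tip.
#' @return an ultrametric `bd_tree` whose tips are exactly the extant tips of
#'   the input.
#' @export
reconstructed <- function(tree) {
  stopifnot(inherits(tree, "bd_tree"))
  tips <- extant_tips(tree)
  if (length(tips) == 0L) stop("tree has no extant tips", call. = FALSE)
  induced_tree(tree, tips)
}

#' Keep a chosen set of extant tips
#'
#' Induced tree of `tip_ids` (node ids of extant tips), pruning everything
#' else and suppressing unifurcations.
#'
#' @param tree a `bd_tree`.
#' @param tip_ids extant tip ids to retain.
#' @return the induced `bd_tree`.
#' @export
keep_tips <- function(tree, tip_ids) {
  stopifnot(inherits(tree, "bd_tree"))
  if (!all(tip_ids %in% extant_tips(tree)))
    stop("tip_ids must be extant tips of the tree", call. = FALSE)
  induced_tree(tree, tip_ids)
}

#' Randomly subsample the extant tips of a tree
#'
#' Retains `k` extant tips chosen uniformly without replacement and prunes
#' the rest (emulating incomplete taxon sampling).  For nested downsampling
#' chains — where the `k-1` tip set must be a subset of the `k` set — draw a
#' single permutation of the tips and call [keep_tips()] on its prefixes, as
#' [run_undersampling_experiment()] does.
#'
#' @param tree a `bd_tree`.
#' @param k number of tips to retain, `3 <= k <=` number of extant tips.
#' @return the subsampled `bd_tree`.
#' @export
subsample_tips <- function(tree, k) {
  stopifnot(inherits(tree, "bd_tree"))
  tips <- extant_tips(tree)
  if (k < 3 || k > length(tips))
    stop("k must satisfy 3 <= k <= number of extant tips", call. = FALSE)
  if (k == length(tips)) return(keep_tips(tree, tips))
  keep_tips(tree, sample(tips, k))
}

#' Internode intervals of an ultrametric tree
#'
#' The interval `g_k` (k = 2..n) is the time span during which the
#' reconstructed tree contains exactly `k` lineages; `g_n` abuts the
#' present and the `g_k` sum to the crown age.  These intervals, and the
#' weighted total `T = sum_j j * g_j`, are the sufficient statistics for the
#' gamma statistic.
#'
#' @param x an ultrametric `bd_tree` (e.g. from [reconstructed()]), a `phylo`
#'   object, or a numeric vector of intervals `g_2..g_n` (all `>= 0`).
#' @param tol absolute ultrametricity tolerance, My.
#' @param ... passed to methods.
#' @return an object of class `internode_intervals`: list with `n`, `g`
#'   (named `g2..gn`), `total_T` and `crown_age`.
#' @export
internode_intervals <- function(x, ...) UseMethod("internode_intervals")

#' @rdname internode_intervals
#' @export
internode_intervals.numeric <- function(x, ...) {
  if (length(x) < 2) stop("need at least 3 tips (2 intervals)", call. = FALSE)
  if (any(x < 0)) stop("intervals must be >= 0", call. = FALSE)
  if (sum(x) <= 0) stop("degenerate tree: all intervals zero", call. = FALSE)
  n <- length(x) + 1L
  g <- setNames(as.numeric(x), paste0("g", 2:n))
  structure(list(n = n, g = g, total_T = sum((2:n) * g),
                 crown_age = sum(g)),
            class = "internode_intervals")
}

#' @rdname internode_intervals
#' @export
internode_intervals.bd_tree <- function(x, tol = 1e-9, ...) {
  nd <- x$nodes
  if (any(!is.na(nd$t_death) & !(nd$id %in% nd$parent)))
    stop("tree is not ultrametric: it contains extinct tips; ",
         "apply reconstructed() first", call. = FALSE)
  n <- n_extant(x)
  if (n < 3L) stop("need at least 3 tips", call. = FALSE)
  split_times <- sort(nd$t_death[nd$id %in% nd$parent])
  stopifnot(length(split_times) == n - 1L)
  bounds <- c(split_times, x$present_time)
  g <- diff(bounds)
  if (any(g < -tol)) stop("branching times exceed the present", call. = FALSE)
  internode_intervals.numeric(pmax(g, 0))
}

#' @rdname internode_intervals
#' @export
internode_intervals.phylo <- function(x, tol = 1e-9, ...) {
  if (length(x$tip.label) < 3L) stop("need at least 3 tips", call. = FALSE)
  if (!ape::is.ultrametric(x, tol = tol, option = 2))
    stop("tree is not ultrametric", call. = FALSE)
  bt <- sort(ape::branching.times(x), decreasing = TRUE)  # ages before present
  g <- diff(-c(bt, 0))
  internode_intervals.numeric(pmax(g, 0))
}

#' @export
print.internode_intervals <- function(x, ...) {
  cat(sprintf("<internode_intervals> n = %d tips, crown age = %.6g My, T = %.6g\n",
              x$n, x$crown_age, x$total_T))
  invisible(x)
}
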