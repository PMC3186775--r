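#' Event-level birth--death trees
#'
#' A `bd_tree` stores the complete outcome of a birth--death simulation as a
#' lineage table: one row per lineage with its parent, birth time and death
#' time (`NA` while extant), plus the time of the present.  Times are in
#' million years (My), running forward from the origin at 0.  A speciation
#' event closes the parent lineage and opens two daughters, so every lineage
#' has zero or two children and the number of branching events always equals
#' the number of tips minus one.  Extinct lineages are retained; use
#' [reconstructed()] for the extant-only (molecular) tree.
#'
#' @param nodes data.frame with columns `id` (1..N, parents precede
#'   children), `parent` (`NA` for the origin), `t_birth`, `t_death`
#'   (`NA` = extant).
#' @param present_time time of the present, My since the origin.
#' @param shift_time time of the waxing-to-waning rate shift, or `NA`.
#' @param peak_n number of lineages alive at the shift, or `NA`.
#' @return An object of class `bd_tree`.
#' @seealso [bd_origin()], [simulate_bd_phase()], [as.phylo.bd_tree()]
#' @export
bd_tree <- function(nodes, present_time, shift_time = NA_real_,
                    peak_n = NA_integer_) {
  stopifnot(is.data.frame(nodes),
            all(c("id", "parent", "t_birth", "t_death") %in% names(nodes)))
  if (is.null(nodes$label)) nodes$label <- paste0("t", nodes$id)
  rownames(nodes) <- NULL
  x <- structure(
    list(nodes = nodes, present_time = as.numeric(present_time),
         shift_time = as.numeric(shift_time), peak_n = as.integer(peak_n)),
    class = "bd_tree")
  validate_bd_tree(x)
}

#' Validate the structural invariants of a `bd_tree`
#'
#' Checks: exactly one origin; parents precede children; every lineage has 0
#' or 2 children; `t_birth < t_death` (weak inequality allowed only at the
#' origin, whose stem may have length zero in imported trees); extinct tips
#' die no later than the present.
#'
#' @param x a `bd_tree`.
#' @return `x`, invisibly usable; errors on violation.
#' @export
validate_bd_tree <- function(x) {
  nd <- x$nodes
  if (!identical(nd$id, seq_len(nrow(nd))))
    stop("node ids must be 1..N in order", call. = FALSE)
  root <- which(is.na(nd$parent))
  if (length(root) != 1L) stop("tree must have exactly one origin lineage",
                               call. = FALSE)
  if (any(nd$parent >= nd$id, na.rm = TRUE))
    stop("parents must precede children", call. = FALSE)
  nkids <- tabulate(nd$parent[!is.na(nd$parent)], nbins = nrow(nd))
  if (!all(nkids %in% c(0L, 2L)))
    stop("every lineage must have 0 or 2 children", call. = FALSE)
  # events (death/split) must strictly follow birth (weak at the origin,
  # whose imported stem may be zero); extant lineages may be newborn, i.e.
  # t_birth == present, when a simulation stops exactly at a speciation
  end <- ifelse(is.na(nd$t_death), x$present_time, nd$t_death)
  bad <- nd$t_birth > end |
    (!is.na(nd$t_death) & nd$t_birth == end & nd$id != root)
  if (any(bad)) stop("t_birth must precede t_death on every lineage",
                     call. = FALSE)
  if (any(end > x$present_time + 1e-9))
    stop("death times cannot exceed the present", call. = FALSE)
  x
}

#' @export
print.bd_tree <- function(x, ...) {
  n_ext <- n_extant(x)
  n_tip <- sum(!(x$nodes$id %in% x$nodes$parent))
  cat(sprintf("<bd_tree> %d lineages, %d tips (%d extant), present = %.4g My",
              nrow(x$nodes), n_tip, n_ext, x$present_time))
  if (!is.na(x$shift_time))
    cat(sprintf("; rate shift at %.4g My (peak diversity %d)",
                x$shift_time, x$peak_n))
  cat("\n")
  invisible(x)
}

#' Single-lineage starting state for a simulation
#'
#' @return A `bd_tree` with one extant lineage born at time 0 and
#'   `present_time = 0`.
#' @export
bd_origin <- function() {
  bd_tree(data.frame(id = 1L, parent = NA_integer_, t_birth = 0,
                     t_death = NA_real_),
          present_time = 0)
}

#' Number / ids of extant tips
#'
#' A lineage is extant when its death time is `NA`, i.e. it is alive at the
#' present.
#'
#' @param x a `bd_tree`.
#' @return `n_extant()`: an integer count. `extant_tips()`: integer node ids.
#' @export
n_extant <- function(x) length(extant_tips(x))

#' @rdname n_extant
#' @export
extant_tips <- function(x) x$nodes$id[is.na(x$nodes$t_death)]

#' Canonical node ordering
#'
#' Renumbers the lineage table into a deterministic order — by birth time,
#' then tree depth, then label — so that trees describing the same history
#' (e.g. before and after a newick round trip, where row order follows the
#' file rather than the simulation) have identical node tables.
#'
#' @param tree a `bd_tree`.
#' @return the reordered `bd_tree`.
#' @export
normalize_node_order <- function(tree) {
  nd <- tree$nodes
  depth <- integer(nrow(nd))
  for (i in seq_len(nrow(nd)))   # parents precede children, one pass
    if (!is.na(nd$parent[i])) depth[i] <- depth[nd$parent[i]] + 1L
  ord <- order(nd$t_birth, depth, nd$label)
  new_id <- integer(nrow(nd))
  new_id[ord] <- seq_len(nrow(nd))
  nd <- nd[ord, , drop = FALSE]
  nd$id <- seq_len(nrow(nd))
  nd$parent <- ifelse(is.na(nd$parent), NA_integer_, new_id[nd$parent])
  bd_tree(nd, present_time = tree$present_time,
          shift_time = tree$shift_time, peak_n = tree$peak_n)
}

# children list indexed by node id (integer vector per node)
node_children <- function(nd) {
  has_par <- !is.na(nd$parent)
  split(nd$id[has_par], factor(nd$parent[has_par], levels = nd$id))
}

#' Convert a `bd_tree` to an ape `phylo` object
#'
#' Internal vertices sit at the split times, tips at their death time (extinct)
#' or at the present (extant).  The stem branch from the origin's birth to the
#' first split is stored as `root.edge`.  Extinct tips are labelled with a
#' configurable prefix so that full (fossilized) trees survive a newick
#' round trip.
#'
#' @param x a `bd_tree` with at least 2 tips.
#' @param extinct_prefix label prefix marking extinct tips.
#' @param ... unused.
#' @return an object of class `phylo`.
#' @exportS3Method ape::as.phylo
as.phylo.bd_tree <- function(x, extinct_prefix = "X_", ...) {
  nd <- x$nodes
  is_internal <- nd$id %in% nd$parent
  tip_ids <- nd$id[!is_internal]
  int_ids <- nd$id[is_internal]
  n_tip <- length(tip_ids)
  if (n_tip < 2L) stop("need at least 2 tips to build a phylo", call. = FALSE)
  # phylo numbering: tips 1..n_tip, internals n_tip+1.. in id (preorder) order
  phylo_num <- integer(nrow(nd))
  phylo_num[tip_ids] <- seq_len(n_tip)
  phylo_num[int_ids] <- n_tip + seq_along(int_ids)
  end_time <- ifelse(is.na(nd$t_death), x$present_time, nd$t_death)
  has_par <- !is.na(nd$parent)
  edge <- cbind(phylo_num[nd$parent[has_par]], phylo_num[nd$id[has_par]])
  edge_length <- end_time[has_par] - end_time[nd$parent[has_par]]
  extinct <- !is_internal & !is.na(nd$t_death)
  labels <- paste0(ifelse(extinct[tip_ids], extinct_prefix, ""),
                   nd$label[tip_ids])
  root_id <- nd$id[is.na(nd$parent)]
  phy <- structure(
    list(edge = edge, edge.length = as.numeric(edge_length),
         Nnode = length(int_ids), tip.label = labels,
         node.label = nd$label[int_ids],
         root.edge = end_time[root_id] - nd$t_birth[root_id]),
    class = "phylo")
  stats::reorder(phy, "cladewise")
}

#' Convert an ape `phylo` object to a `bd_tree`
#'
#' Tip depths are measured from the root; the deepest tip (among tips not
#' carrying the extinct-label prefix) defines the present.  Tips labelled
#' with `extinct_prefix` become extinct lineages dying at their depth.  A
#' `root.edge`, if present, becomes the origin's stem.
#'
#' @param phy a `phylo` with branch lengths.
#' @param extinct_prefix label prefix marking extinct tips.
#' @return a `bd_tree`.
#' @export
as_bd_tree <- function(phy, extinct_prefix = "X_") {
  if (is.null(phy$edge.length))
    stop("branch lengths are required", call. = FALSE)
  if (!ape::is.binary(phy)) stop("tree must be strictly binary", call. = FALSE)
  phy <- stats::reorder(phy, "cladewise")
  n_tip <- length(phy$tip.label)
  nv <- n_tip + phy$Nnode
  root_vertex <- n_tip + 1L
  depth <- ape::node.depth.edgelength(phy)  # from root vertex
  stem <- if (!is.null(phy$root.edge)) phy$root.edge else 0
  extinct <- startsWith(phy$tip.label, extinct_prefix)
  if (all(extinct)) stop("no extant tips found", call. = FALSE)
  present <- stem + max(depth[seq_len(n_tip)][!extinct])
  # cladewise edge order lists every parent before its children, so
  # assigning ids root-first along the edge rows keeps parents < children
  new_id <- integer(nv)
  new_id[root_vertex] <- 1L
  new_id[phy$edge[, 2]] <- 1L + seq_len(nrow(phy$edge))
  parent_of <- integer(nv)
  parent_of[phy$edge[, 2]] <- phy$edge[, 1]
  parent_of[root_vertex] <- root_vertex
  is_tip <- seq_len(nv) <= n_tip
  ext_full <- c(extinct, rep(FALSE, phy$Nnode))
  tb <- ifelse(seq_len(nv) == root_vertex, 0, stem + depth[parent_of])
  td <- ifelse(is_tip & !ext_full, NA_real_, stem + depth)
  tip_lab <- ifelse(startsWith(phy$tip.label, extinct_prefix),
                    substring(phy$tip.label, nchar(extinct_prefix) + 1L),
                    phy$tip.label)
  int_lab <- if (!is.null(phy$node.label) &&
                 length(phy$node.label) == phy$Nnode &&
                 !anyNA(phy$node.label) && all(nzchar(phy$node.label))) {
    phy$node.label
  } else paste0("n", seq_len(phy$Nnode))
  nd <- data.frame(id = seq_len(nv), parent = NA_integer_,
                   t_birth = NA_real_, t_death = NA_real_,
                   label = NA_character_)
  idx <- new_id  # idx[v] = row for vertex v
  nd$parent[idx] <- ifelse(seq_len(nv) == root_vertex, NA_integer_,
                           new_id[parent_of])
  nd$t_birth[idx] <- tb
  nd$t_death[idx] <- td
  nd$label[idx] <- c(tip_lab, int_lab)
  bd_tree(nd, present_time = present)
}

#' Read / write trees in newick format
#'
#' Trees are written with branch lengths in My and extinct tips flagged by a
#' label prefix (default `"X_"`); reading inverts the convention.  Multiple
#' trees per file are supported (one per line, ape conventions).
#'
#' @param trees a `bd_tree` or list of them.
#' @param path file path.
#' @param extinct_prefix label prefix marking extinct tips.
#' @return `read_trees_newick()`: a list of `bd_tree`.
#' @export
write_trees_newick <- function(trees, path, extinct_prefix = "X_") {
  if (inherits(trees, "bd_tree")) trees <- list(trees)
  phys <- lapply(trees, as.phylo.bd_tree, extinct_prefix = extinct_prefix)
  class(phys) <- "multiPhylo"
  ape::write.tree(phys, file = path, digits = 12)
  invisible(path)
}

#' @rdname write_trees_newick
#' @export
read_trees_newick <- function(path, extinct_prefix = "X_") {
  phys <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("newick parse error in '", path,
                                            "': ", conditionMessage(e),
                                            call. = FALSE))
  if (is.null(phys)) stop("newick parse error in '", path, "'", call. = FALSE)
  if (inherits(phys, "phylo")) phys <- list(phys)
  lapply(phys, as_bd_tree, extinct_prefix = extinct_prefix)
}

#' Write the per-lineage event table as CSV
#'
#' Sidecar table for a newick file: node id, parent, birth and death times
#' (My since origin, empty for extant) plus the present and shift times.
#'
#' @param tree a `bd_tree`.
#' @param path file path for the CSV.
#' @export
write_node_table <- function(tree, path) {
  nd <- tree$nodes
  nd$present_time <- tree$present_time
  nd$shift_time <- tree$shift_time
  write.csv(nd, path, row.names = FALSE)
  invisible(path)
}
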