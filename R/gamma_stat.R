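#' The gamma statistic of Pybus & Harvey
#'
#' Standardized summary of the distribution of branching times in an
#' ultrametric phylogeny.  With internode intervals `g_2..g_n` and
#' `T = sum_{j=2..n} j * g_j`,
#'
#' \deqn{\gamma = \frac{\frac{1}{n-2}\sum_{i=2}^{n-1}\left(\sum_{k=2}^{i}
#'   k g_k\right) - T/2}{T\sqrt{1/(12(n-2))}}}
#'
#' Under a constant-rate pure-birth process gamma is asymptotically standard
#' normal; negative values mean the nodes are concentrated deep in the tree
#' (an apparent diversification slowdown), positive values near the tips.
#' The value is invariant to uniform rescaling of the intervals.
#' Significance is the one-tailed lower test against the normal null:
#' `gamma < qnorm(alpha)` (−1.645 at the conventional alpha = 0.05).
#'
#' @param x an [internode_intervals()] object, an ultrametric `bd_tree`, a
#'   `phylo` object, or a numeric vector of intervals `g_2..g_n`.
#' @param alpha one-tailed significance level for the slowdown test.
#' @param ... passed to [internode_intervals()].
#' @return An object of class `gamma_result`: list with `gamma`, `n` (tip
#'   count) and `is_significant`.
#' @examples
#' gamma_stat(c(1, 1))            # 3-tip tree, splits 2 and 1 My ago
#' gamma_stat(c(0, 0, 0, 5))      # 5-tip star phylogeny: -3
#' @export
gamma_stat <- function(x, alpha = 0.05, ...) UseMethod("gamma_stat")

#' @rdname gamma_stat
#' @export
gamma_stat.internode_intervals <- function(x, alpha = 0.05, ...) {
  n <- x$n
  g <- unname(x$g)
  k <- 2:n
  total <- sum(k * g)
  if (total <= 0) stop("degenerate tree: all intervals zero", call. = FALSE)
  cum <- cumsum(k * g)                       # T_i for i = 2..n
  num <- sum(cum[seq_len(n - 2)]) / (n - 2) - total / 2
  val <- num / (total * sqrt(1 / (12 * (n - 2))))
  structure(list(gamma = val, n = n,
                 is_significant = val < gamma_critical(alpha)),
            class = "gamma_result")
}

#' @rdname gamma_stat
#' @export
gamma_stat.numeric <- function(x, alpha = 0.05, ...)
  gamma_stat(internode_intervals(x), alpha = alpha)

#' @rdname gamma_stat
#' @export
gamma_stat.bd_tree <- function(x, alpha = 0.05, ...)
  gamma_stat(internode_intervals(x, ...), alpha = alpha)

#' @rdname gamma_stat
#' @export
gamma_stat.phylo <- function(x, alpha = 0.05, ...)
  gamma_stat(internode_intervals(x, ...), alpha = alpha)

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> gamma = %.6g, n = %d tips%s\n", x$gamma, x$n,
              if (x$is_significant) " (significant slowdown)" else ""))
  invisible(x)
}

#' Most negative gamma attainable with n tips (star phylogeny)
#'
#' The limit of an infinitely aged clade is a star phylogeny — all splits at
#' the crown — whose gamma is `-sqrt(3 * (n - 2))`, the lower bound for any
#' ultrametric tree with `n` tips.
#'
#' @param n tip count (>= 3); vectorized.
#' @return numeric, the bound.
#' @export
gamma_star_min <- function(n) {
  if (any(n < 3)) stop("n must be >= 3", call. = FALSE)
  -sqrt(3 * (n - 2))
}

#' One-tailed critical value of the gamma test
#'
#' Lower quantile of the standard normal null distribution of gamma; at
#' `alpha = 0.05` this is the familiar −1.645 cutoff for rejecting constant
#' diversification in favour of a slowdown.
#'
#' @param alpha significance level in (0, 1).
#' @return numeric, `qnorm(alpha)`.
#' @export
gamma_critical <- function(alpha = 0.05) {
  if (any(alpha <= 0 | alpha >= 1)) stop("alpha must be in (0, 1)",
                                         call. = FALSE)
  qnorm(alpha)
}

#' Gamma normalized by the star-phylogeny bound
#'
#' Divides gamma by the magnitude of the most negative value attainable with
#' the same number of tips, giving a scale-free index in which every star
#' phylogeny scores −1 regardless of size.  Useful when comparing trees of
#' different tip counts, where raw gamma is size-dependent.
#'
#' @param x a `gamma_result`, or a numeric gamma value (then `n` is needed).
#' @param n tip count, if `x` is a bare number.
#' @return numeric in `[-1, Inf)`.
#' @export
normalized_gamma <- function(x, n = NULL) {
  if (inherits(x, "gamma_result")) {
    g <- x$gamma
    n <- x$n
  } else {
    g <- as.numeric(x)
    if (is.null(n)) stop("supply n for a bare gamma value", call. = FALSE)
  }
  g / abs(gamma_star_min(n))
}
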