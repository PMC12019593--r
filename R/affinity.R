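#' Hoyer normalized sparsity of a nonnegative vector
#'
#' Computes the Hoyer sparsity measure
#' \deqn{\frac{1}{\sqrt{N}-1}\left(\sqrt{N} - \frac{\|v\|_1}{\|v\|_2}\right),}
#' which is 0 for a constant vector and 1 for a one-hot vector. It is
#' scale-invariant: multiplying `v` by a positive constant leaves it unchanged.
#'
#' @param v Nonnegative numeric vector with at least two entries, not all zero.
#' @return A single number in `[0, 1]`.
#' @examples
#' hoyer_sparsity(c(1, 0, 0, 0))   # 1: one-hot
#' hoyer_sparsity(rep(2, 8))       # 0: constant
#' @export
hoyer_sparsity <- function(v) {
  if (!is.numeric(v) || length(v) < 2) {
    stop("`v` must be a numeric vector with at least 2 entries.", call. = FALSE)
  }
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("`v` must be finite and nonnegative.", call. = FALSE)
  }
  l1 <- sum(v)
  l2 <- sqrt(sum(v^2))
  if (l2 == 0) stop("`v` must not be all zero.", call. = FALSE)
  n <- length(v)
  (sqrt(n) - l1 / l2) / (sqrt(n) - 1)
}

#' Build a hierarchical sensor-by-source affinity matrix
#'
#' Constructs an `n x n` affinity matrix (rows = sensors, columns = analyte
#' sources, `n = 2^hierarchy_depth`) inducing a balanced binary category
#' hierarchy among the analytes. Each analyte has one sensor maximally
#' sensitive to it (the diagonal); off-diagonal affinities decrease with the
#' tree distance between analytes, so siblings in the hierarchy are more
#' confusable than analytes from opposite subtrees.
#'
#' @param hierarchy_depth Number of levels in the balanced binary tree
#'   (default 3, giving the 8-analyte problem).
#' @param base_levels Affinity assigned at tree distance 1, 2, ...,
#'   `hierarchy_depth` (must be positive and non-increasing). The diagonal
#'   (distance 0) is fixed at 1 before tuning.
#' @return A matrix of class `hq_affinity` with attributes
#'   `hierarchy_depth` and (after [tune_sparsity()]) `alpha`.
#' @seealso [tune_sparsity()], [hoyer_sparsity()]
#' @export
build_hierarchical_affinity <- function(hierarchy_depth = 3,
                                        base_levels = c(0.45, 0.25, 0.10)) {
  if (length(base_levels) != hierarchy_depth) {
    stop("`base_levels` must have one entry per hierarchy level (",
         hierarchy_depth, ").", call. = FALSE)
  }
  if (any(base_levels <= 0) || is.unsorted(rev(base_levels))) {
    stop("`base_levels` must be positive and non-increasing.", call. = FALSE)
  }
  n <- 2L^hierarchy_depth
  # tree distance between leaves i, j of a balanced binary tree:
  # number of levels up to the lowest common ancestor
  tree_dist <- function(i, j) {
    if (i == j) return(0L)
    d <- 0L
    i <- i - 1L; j <- j - 1L
    while (i != j) {
      i <- i %/% 2L; j <- j %/% 2L; d <- d + 1L
    }
    d
  }
  G <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d <- tree_dist(i, j)
      G[i, j] <- if (d == 0L) 1 else base_levels[d]
    }
  }
  dimnames(G) <- list(paste0("sensor_", seq_len(n)),
                      paste0("analyte_", seq_len(n)))
  structure(G, class = c("hq_affinity", "matrix", "array"),
            hierarchy_depth = hierarchy_depth)
}

# mean row-wise Hoyer sparsity of a matrix
mean_row_hoyer <- function(G) {
  mean(apply(G, 1, hoyer_sparsity))
}

# element-wise power + row-wise l1 normalization
power_normalize <- function(G, alpha) {
  H <- G^alpha
  sweep(H, 1, rowSums(H), "/")
}

#' Tune the affinity matrix to a target mean Hoyer sparsity
#'
#' Applies element-wise exponentiation followed by row-wise l1 normalization,
#' `G_i <- G_i^alpha / ||G_i^alpha||_1`, choosing the exponent `alpha` by
#' bisection so that the mean row-wise Hoyer sparsity of the result hits
#' `target`. The transform preserves the within-row rank order of affinities
#' for any `alpha > 0`, so the hierarchical similarity structure survives
#' tuning; only the selectivity contrast changes.
#'
#' @param G Affinity matrix (strictly positive entries), e.g. from
#'   [build_hierarchical_affinity()].
#' @param target Target mean row-wise Hoyer sparsity in (0, 1); default 0.4,
#'   emulating moderately selective gas sensors.
#' @param tol Convergence tolerance on the achieved sparsity (default 1e-3).
#' @param max_iter Maximum bisection iterations (default 100).
#' @return The tuned matrix (rows l1-normalized, i.e. summing to 1), with the
#'   selected exponent in `attr(, "alpha")`.
#' @examples
#' G <- tune_sparsity(build_hierarchical_affinity())
#' mean(apply(G, 1, hoyer_sparsity))  # ~0.4
#' @export
tune_sparsity <- function(G, target = 0.4, tol = 1e-3, max_iter = 100L) {
  stopifnot(is.matrix(G), all(is.finite(G)), all(G >= 0))
  if (target <= 0 || target >= 1) stop("`target` must be in (0, 1).", call. = FALSE)
  if (any(rowSums(G > 0) == 0)) {
    stop("every row of `G` needs at least one positive entry.", call. = FALSE)
  }
  f <- function(alpha) mean_row_hoyer(power_normalize(G, alpha))
  # f is increasing in alpha (power sharpening); bracket the target
  lo <- 1; hi <- 1
  while (f(lo) > target && lo > 2^-20) lo <- lo / 2
  while (f(hi) < target && hi < 2^20) hi <- hi * 2
  if (f(lo) > target + tol || f(hi) < target - tol) {
    stop("target sparsity ", target, " not bracketable; achieved range [",
         signif(f(lo), 4), ", ", signif(f(hi), 4), "].", call. = FALSE)
  }
  alpha <- 1
  for (iter in seq_len(max_iter)) {
    alpha <- (lo + hi) / 2
    s <- f(alpha)
    if (abs(s - target) <= tol) break
    if (s < target) lo <- alpha else hi <- alpha
  }
  s <- f(alpha)
  if (abs(s - target) > tol) {
    stop("sparsity tuning did not converge in ", max_iter,
         " iterations; last achieved ", signif(s, 5), ".", call. = FALSE)
  }
  out <- power_normalize(G, alpha)
  structure(out, class = class(G),
            hierarchy_depth = attr(G, "hierarchy_depth"),
            alpha = alpha, hoyer = s)
}
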