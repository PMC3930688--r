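# Exact non-negative least squares for small design matrices, vectorized
# over many right-hand sides. For p columns, every one of the 2^p candidate
# supports is solved by unconstrained least squares; among candidates whose
# coefficients are all nonnegative the minimum-residual solution is the
# global NNLS optimum (the optimal active set's unconstrained solution is
# feasible and attains the optimum). With p = 3 template curves this is an
# exact Lawson-Hanson-equivalent minimizer with no iteration tolerance, and
# it vectorizes across ~1e5 voxels as dense matrix algebra.

#' Non-negative least squares with a small design matrix
#'
#' Solves `argmin_{w >= 0} || y - T w ||^2` exactly for every column of `Y`
#' by support enumeration.
#'
#' @param T numeric matrix, n x p, p <= 8 (p = 3 in the supervised
#'   clustering use). Must have full column rank.
#' @param Y numeric matrix of right-hand sides, n x m (or a length-n
#'   vector).
#' @return list with `coef` (p x m nonnegative matrix) and `rss` (length-m
#'   residual sums of squares).
#' @export
nnls_multi <- function(T, Y) {
  T <- as.matrix(T)
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1L)
  n <- nrow(T)
  p <- ncol(T)
  if (p > 8L) stop("nnls_multi: support enumeration limited to p <= 8")
  if (nrow(Y) != n) stop("nnls_multi: nrow(Y) must equal nrow(T)")
  if (qr(T)$rank < p)
    stop("nnls_multi: design matrix is rank deficient")
  m <- ncol(Y)
  TtY <- crossprod(T, Y)                       # p x m
  yty <- colSums(Y^2)
  best_rss <- yty                              # empty support: w = 0
  best_coef <- matrix(0, p, m)
  tol <- -1e-10
  for (code in seq_len(2^p - 1L)) {
    S <- which(bitwAnd(code, bitwShiftL(1L, 0:(p - 1L))) != 0L)
    G <- crossprod(T[, S, drop = FALSE])
    cf <- solve(G, TtY[S, , drop = FALSE])     # |S| x m
    feas <- colSums(cf < tol) == 0L
    if (!any(feas)) next
    # rss = yty - w' T' y for the LS solution on support S
    rss <- yty - colSums(cf * TtY[S, , drop = FALSE])
    take <- feas & (rss < best_rss - 1e-12 * pmax(yty, 1))
    if (any(take)) {
      best_rss[take] <- rss[take]
      best_coef[, take] <- 0
      best_coef[S, take] <- pmax(cf[, take, drop = FALSE], 0)
    }
  }
  list(coef = best_coef, rss = pmax(best_rss, 0))
}
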