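#' @useDynLib sptstates, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rgamma rbeta rbinom rchisq acf fft optimize
#'   quantile var cov sd complete.cases
#' @importFrom utils read.csv write.csv head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw from a Dirichlet distribution
#'
#' One draw per row of `alpha` (or a single draw for a vector), via
#' normalised independent gamma variates.
#'
#' @param alpha concentration vector, all entries > 0 (zeros are allowed and
#'   yield structural zeros in the draw)
#' @return numeric vector on the simplex
#' @keywords internal
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  s <- sum(g)
  if (s <= 0) {
    # all-zero pathological case: fall back to uniform over positive alphas
    out <- as.numeric(alpha > 0)
    return(out / sum(out))
  }
  g / s
}

#' Draw from an inverse-Wishart distribution
#'
#' Parameterised so that `E[X] = scale / (df - d - 1)` for `df > d + 1`.
#' Uses the Bartlett decomposition of the Wishart draw for `scale^{-1}`.
#'
#' @param df degrees of freedom, `> d - 1`
#' @param scale d x d symmetric positive-definite scale matrix
#' @return d x d symmetric positive-definite matrix
#' @keywords internal
rinvwishart1 <- function(df, scale) {
  d <- nrow(scale)
  stopifnot(df > d - 1)
  # X ~ IW(df, S)  <=>  X^{-1} ~ Wishart(df, S^{-1})
  S_inv <- chol2inv(chol(scale))
  L <- chol(S_inv)            # upper triangular, S_inv = t(L) %*% L
  A <- matrix(0, d, d)
  diag(A) <- sqrt(rchisq(d, df = df - seq_len(d) + 1))
  if (d > 1) A[upper.tri(A)] <- rnorm(d * (d - 1) / 2)
  # Wishart draw W = t(B) %*% B with B = A %*% chol(S^{-1})
  B <- A %*% L
  W <- crossprod(B)
  X <- chol2inv(chol(W))
  (X + t(X)) / 2
}

#' Solve a small linear assignment problem
#'
#' Minimises `sum(cost[i, perm[i]])` over permutations. Exhaustive search for
#' n <= 7, greedy with 2-opt refinement above that (occupied state counts in
#' this package are small, so the exact branch is the one normally taken).
#'
#' @param cost square cost matrix
#' @return integer permutation `perm` with `perm[i]` the column assigned to row i
#' @keywords internal
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  if (n == 1L) return(1L)
  if (n <= 7L) {
    perms <- permutations_of(n)
    costs <- vapply(perms, function(p) sum(cost[cbind(seq_len(n), p)]), numeric(1))
    return(perms[[which.min(costs)]])
  }
  # greedy seed
  perm <- integer(n)
  used <- logical(n)
  for (i in order(apply(cost, 1, min))) {
    j <- which.min(ifelse(used, Inf, cost[i, ]))
    perm[i] <- j
    used[j] <- TRUE
  }
  # 2-opt swaps until no improvement
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      cur <- cost[i, perm[i]] + cost[j, perm[j]]
      alt <- cost[i, perm[j]] + cost[j, perm[i]]
      if (alt < cur - 1e-15) {
        tmp <- perm[i]; perm[i] <- perm[j]; perm[j] <- tmp
        improved <- TRUE
      }
    }
  }
  perm
}

permutations_of <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- permutations_of(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (i in seq_len(n)) for (p in sub) {
    k <- k + 1L
    out[[k]] <- c(i, p + (p >= i))
  }
  out
}

#' Ensemble mean squared displacement of a set of paths
#'
#' Displacements are measured from each path's first frame (a true ensemble
#' average over realisations), not time-averaged along the path: for
#' weakly non-ergodic processes such as the continuous-time random walk the
#' two disagree, and the anomalous exponent lives in the ensemble average.
#'
#' @param paths list of position matrices (rows = frames, cols = x/y)
#' @param max_lag largest lag (frames) to evaluate
#' @return data.frame with `lag` (frames) and `msd` (squared length units)
#' @export
ensemble_msd <- function(paths, max_lag = 20L) {
  stopifnot(length(paths) >= 1L)
  lags <- seq_len(max_lag)
  msd <- vapply(lags, function(h) {
    acc <- 0; cnt <- 0L
    for (p in paths) {
      if (nrow(p) <= h) next
      d <- p[1L + h, ] - p[1L, ]
      acc <- acc + sum(d^2)
      cnt <- cnt + 1L
    }
    if (cnt == 0L) return(NA_real_)
    acc / cnt
  }, numeric(1))
  data.frame(lag = lags, msd = msd)
}

#' Log-log slope of an ensemble MSD curve
#'
#' Fits `log(msd) ~ log(lag)` by least squares; the slope estimates the
#' anomalous exponent alpha.
#'
#' @inheritParams ensemble_msd
#' @return fitted slope (dimensionless)
#' @export
msd_alpha <- function(paths, max_lag = 20L) {
  m <- ensemble_msd(paths, max_lag)
  m <- m[is.finite(m$msd) & m$msd > 0, ]
  stopifnot(nrow(m) >= 3L)
  stats::coef(stats::lm(log(m$msd) ~ log(m$lag)))[[2L]]
}
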