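#' Configuration for the sticky HDP-HMM sampler
#'
#' @param gamma top-level Dirichlet-process concentration (> 0)
#' @param alpha second-level (transition-row) concentration (> 0); the `a` of
#'   the transition prior `Dir(a beta_1, ..., a beta_j + kappa, ..., a beta_L)`
#' @param sticky_kappa self-transition bias (> 0). `NULL` (default) resolves
#'   at fit time to 10% of the total number of displacements, a weakly
#'   informative choice that scales with the dataset; motion-blur data
#'   benefits from a larger value.
#' @param L weak-limit truncation: maximum number of states carried by the
#'   sampler, must exceed the number of states you expect (>= 2)
#' @param niw_kappa Normal-inverse-Wishart pseudo-count (> 0); distinct from
#'   `sticky_kappa` even though the field traditionally writes both as kappa.
#'   The default 1e6 is a strong "no net transport" prior that keeps the
#'   emission mean essentially at zero (the convention of this field's
#'   fixed-mean analyses) while leaving `mu` in the model; weaker values let
#'   large states absorb dwell-scale drift of correlated walks as spurious
#'   extra states. Lower it only for data with genuine directed transport
#' @param niw_mean prior emission mean (um), length-2
#' @param niw_dof inverse-Wishart degrees of freedom (> 1 for d = 2)
#' @param niw_scale 2 x 2 symmetric positive-definite prior scale (um^2);
#'   `NULL` resolves at fit time to the empirical displacement covariance
#' @param n_iterations total Gibbs sweeps
#' @param burn_in sweeps discarded before recording (< n_iterations)
#' @param thin record every `thin`-th post-burn-in sweep (default 10, chosen
#'   from posterior autocorrelation; see [autocorrelation_diagnostic])
#' @param seed integer RNG seed for a fully reproducible chain
#' @param verbose print occupied-state count and log-likelihood every 100 sweeps
#' @return an `hdphmm_config` list
#' @export
hdphmm_config <- function(gamma = 1, alpha = 1, sticky_kappa = NULL, L = 10L,
                          niw_kappa = 1e6, niw_mean = c(0, 0), niw_dof = 4,
                          niw_scale = NULL, n_iterations = 2000L,
                          burn_in = 1000L, thin = 10L, seed = NULL,
                          verbose = FALSE) {
  stopifnot(gamma > 0, alpha > 0, is.null(sticky_kappa) || sticky_kappa > 0,
            L >= 2L, niw_kappa > 0, length(niw_mean) == 2L, niw_dof > 1,
            n_iterations >= 1L, burn_in >= 0L, burn_in < n_iterations,
            thin >= 1L)
  if (!is.null(niw_scale)) {
    niw_scale <- as.matrix(niw_scale)
    stopifnot(nrow(niw_scale) == 2L, ncol(niw_scale) == 2L,
              isSymmetric(niw_scale), all(eigen(niw_scale)$values > 0))
  }
  structure(list(gamma = gamma, alpha = alpha, sticky_kappa = sticky_kappa,
                 L = as.integer(L), niw_kappa = niw_kappa,
                 niw_mean = as.numeric(niw_mean), niw_dof = niw_dof,
                 niw_scale = niw_scale, n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = seed, verbose = verbose),
            class = "hdphmm_config")
}

#' Blocked draw of one hidden state sequence
#'
#' Samples the full label sequence of one displacement run from its exact
#' conditional posterior given the transition matrix and emissions, via
#' backward message passing and forward sampling (log-space).
#'
#' @param displacements T x 2 matrix of single-step displacements (um)
#' @param pi L x L row-stochastic transition matrix
#' @param emissions list of L lists, each with `mu` (length-2) and `Sigma`
#'   (2 x 2 SPD)
#' @param pi0 initial state distribution (default: uniform over L)
#' @return integer label vector of length T
#' @export
sample_state_sequence <- function(displacements, pi, emissions, pi0 = NULL) {
  x <- as.matrix(displacements)
  L <- nrow(pi)
  stopifnot(ncol(x) == 2L, ncol(pi) == L, length(emissions) == L,
            all(abs(rowSums(pi) - 1) < 1e-8))
  pi0 <- pi0 %||% rep(1 / L, L)
  mu <- do.call(rbind, lapply(emissions, `[[`, "mu"))
  sig <- do.call(rbind, lapply(emissions, function(e)
    c(e$Sigma[1, 1], e$Sigma[2, 2], e$Sigma[1, 2])))
  ll <- cpp_emission_loglik(x, mu, sig)
  cpp_sample_states(ll, pi, pi0,
                    run_start = 0L, run_length = nrow(x),
                    u = runif(nrow(x)))
}

#' Sample transition-matrix rows from their sticky Dirichlet posterior
#'
#' Row j is drawn from `Dir(a beta + kappa e_j + counts[j, ])`.
#'
#' @param beta global state weights (L-simplex)
#' @param alpha transition concentration a
#' @param sticky_kappa self-transition bias
#' @param counts L x L matrix of observed transition counts
#' @return L x L row-stochastic matrix
#' @export
sample_transition_rows <- function(beta, alpha, sticky_kappa, counts) {
  L <- length(beta)
  stopifnot(nrow(counts) == L, ncol(counts) == L, all(counts >= 0))
  P <- matrix(0, L, L)
  for (j in seq_len(L)) {
    conc <- alpha * beta + counts[j, ]
    conc[j] <- conc[j] + sticky_kappa
    P[j, ] <- rdirichlet1(conc)
  }
  P
}

#' Auxiliary table counts for the global-weight update
#'
#' For each (j, k) the number of "tables" is the number of new clusters a
#' Chinese-restaurant process with concentration `a beta_k + kappa 1(j = k)`
#' would open over `counts[j, k]` customers.  The sticky override correction
#' then removes the tables attributable to the self-transition bias:
#' `w_j ~ Binomial(m_jj, rho / (rho + beta_j (1 - rho)))` with
#' `rho = kappa / (a + kappa)`.
#'
#' @inheritParams sample_transition_rows
#' @return list with `m` (table counts, L x L) and `m_bar` (corrected)
#' @export
sample_table_counts <- function(beta, alpha, sticky_kappa, counts) {
  L <- length(beta)
  m <- matrix(0L, L, L)
  for (j in seq_len(L)) for (k in seq_len(L)) {
    n <- counts[j, k]
    if (n == 0) next
    w <- alpha * beta[k] + if (j == k) sticky_kappa else 0
    # P(new table at customer i) = w / (w + i - 1), i = 1..n
    m[j, k] <- sum(runif(n) < w / (w + seq_len(n) - 1))
  }
  m_bar <- m
  rho <- sticky_kappa / (alpha + sticky_kappa)
  if (rho > 0) {
    for (j in seq_len(L)) {
      if (m[j, j] == 0) next
      p_override <- rho / (rho + beta[j] * (1 - rho))
      m_bar[j, j] <- m[j, j] - rbinom(1L, m[j, j], p_override)
    }
  }
  list(m = m, m_bar = m_bar)
}

#' Sample the global state weights
#'
#' Weak-limit update: `beta ~ Dir(gamma / L + m_.1, ..., gamma / L + m_.L)`
#' where `m_.k` are column sums of the override-corrected table counts.
#'
#' @param gamma top-level concentration
#' @param L truncation level
#' @param table_counts L x L corrected table counts (`m_bar`), or a length-L
#'   vector of column sums; all zeros gives a draw from the prior
#' @return length-L simplex vector
#' @export
sample_beta <- function(gamma, L, table_counts = NULL) {
  m_k <- if (is.null(table_counts)) rep(0, L)
         else if (is.matrix(table_counts)) colSums(table_counts)
         else table_counts
  stopifnot(length(m_k) == L, all(m_k >= 0))
  rdirichlet1(gamma / L + m_k)
}

#' Normal-inverse-Wishart conjugate update
#'
#' Exact posterior parameters for a bivariate Gaussian with NIW prior:
#' `kappa' = kappa + N`, `kappa' theta' = kappa theta + sum(x)`,
#' `nu' = nu + N`,
#' `nu' Delta' = nu Delta + sum(x x^T) + kappa theta theta^T
#'  - kappa' theta' theta'^T`.
#'
#' @param x N x 2 matrix of displacements assigned to one state (may have
#'   zero rows, in which case the prior is returned unchanged)
#' @param prior list with `kappa`, `mean`, `dof`, `scale`
#' @return posterior list with the same fields
#' @export
niw_posterior_update <- function(x, prior) {
  x <- if (is.null(x)) matrix(0, 0, 2) else as.matrix(x)
  if (nrow(x) == 0L) return(prior)
  stopifnot(ncol(x) == 2L)
  N <- nrow(x)
  kap0 <- prior$kappa; th0 <- prior$mean; nu0 <- prior$dof; Del0 <- prior$scale
  kap <- kap0 + N
  sx <- colSums(x)
  th <- (kap0 * th0 + sx) / kap
  nu <- nu0 + N
  sxx <- crossprod(x)
  Del <- (nu0 * Del0 + sxx + kap0 * tcrossprod(th0) - kap * tcrossprod(th)) / nu
  Del <- (Del + t(Del)) / 2
  if (min(eigen(Del, only.values = TRUE)$values) <= 0) {
    warning("posterior NIW scale numerically non-PD; jittering diagonal")
    Del <- Del + diag(1e-10, 2)
  }
  list(kappa = kap, mean = th, dof = nu, scale = Del)
}

#' Draw emission parameters from a Normal-inverse-Wishart
#'
#' `Sigma ~ IW(nu, nu Delta)` (so `E[Sigma] = nu Delta / (nu - 3)` in 2D) and
#' `mu | Sigma ~ N(theta, Sigma / kappa)`.
#'
#' @param niw list with `kappa`, `mean`, `dof`, `scale`
#' @return list with `mu` (length-2) and `Sigma` (2 x 2 SPD)
#' @export
sample_emission <- function(niw) {
  Sigma <- tryCatch(
    rinvwishart1(niw$dof, niw$dof * niw$scale),
    error = function(e) rinvwishart1(niw$dof, niw$dof * (niw$scale + diag(1e-9, 2))))
  Lc <- chol(Sigma / niw$kappa)
  mu <- as.numeric(niw$mean + crossprod(Lc, rnorm(2)))
  list(mu = mu, Sigma = Sigma)
}

# concatenate displacement runs into one matrix plus run bookkeeping
flatten_runs <- function(disp_list) {
  lens <- vapply(disp_list, nrow, integer(1))
  X <- do.call(rbind, disp_list)
  list(X = X, run_start = c(0L, cumsum(lens))[seq_along(lens)],
       run_length = lens,
       track_id = vapply(disp_list,
                         function(d) as.character(attr(d, "track_id")),
                         character(1)))
}

#' Fit the sticky HDP-HMM to a trajectory dataset
#'
#' Blocked Gibbs sampling with weak-limit truncation. Each sweep (1) jointly
#' redraws every track's label sequence from its exact conditional posterior,
#' (2) accumulates transition counts and per-state sufficient statistics,
#' (3) redraws auxiliary table counts, the global weights `beta`, the
#' transition rows and each state's Gaussian parameters from its NIW
#' posterior (unoccupied states are redrawn from the prior).
#'
#' @param tracks a [track_set]
#' @param config an [hdphmm_config]
#' @return an `hdphmm_chain`: list with `samples` (retained posterior
#'   samples: `beta`, `pi`, `mu`, `Sigma`, `z`, `occupied`, `loglik`, `iter`),
#'   `config` (with resolved defaults), `runs` (displacement bookkeeping) and
#'   `tau`
#' @export
hdphmm_fit <- function(tracks, config = hdphmm_config()) {
  stopifnot(inherits(tracks, "track_set"), inherits(config, "hdphmm_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  disp <- displacements_from_tracks(tracks)
  if (length(disp) == 0L) stop("no displacements in tracks")
  fl <- flatten_runs(disp)
  X <- fl$X
  Tt <- nrow(X)
  L <- config$L
  # resolve data-dependent defaults
  kappa_s <- config$sticky_kappa %||% (0.1 * Tt)
  Del0 <- config$niw_scale %||% {
    v <- cov(X); (v + t(v)) / 2
  }
  prior <- list(kappa = config$niw_kappa, mean = config$niw_mean,
                dof = config$niw_dof, scale = Del0)
  config$sticky_kappa <- kappa_s
  config$niw_scale <- Del0

  # initialization: quantile-bin squared step length into L groups
  r2 <- rowSums(X^2)
  qs <- quantile(r2, probs = seq(0, 1, length.out = L + 1L))
  z <- as.integer(cut(r2, breaks = unique(qs), include.lowest = TRUE))
  z[is.na(z)] <- 1L
  if (max(z) < L) z <- pmin(z, L)

  beta <- rep(1 / L, L)
  stats_k <- state_sufficient_stats(X, z, L)
  counts <- transition_counts(z, fl$run_start, fl$run_length, L)
  tc <- sample_table_counts(beta, config$alpha, kappa_s, counts)
  beta <- sample_beta(config$gamma, L, tc$m_bar)
  P <- sample_transition_rows(beta, config$alpha, kappa_s, counts)
  emis <- draw_all_emissions(stats_k, prior)

  samples <- vector("list", 0L)
  for (it in seq_len(config$n_iterations)) {
    ll_mat <- cpp_emission_loglik(X, emis$mu, emis$sig3)
    z <- cpp_sample_states(ll_mat, P, beta,
                           fl$run_start, fl$run_length, runif(Tt))
    loglik <- sum(ll_mat[cbind(seq_len(Tt), z)])
    if (!is.finite(loglik))
      stop("sampler diverged (non-finite log-likelihood) at iteration ", it)
    counts <- transition_counts(z, fl$run_start, fl$run_length, L)
    stats_k <- state_sufficient_stats(X, z, L)
    tc <- sample_table_counts(beta, config$alpha, kappa_s, counts)
    # run starts are categorical draws from beta and enter its conditional
    init_counts <- tabulate(z[fl$run_start + 1L], nbins = L)
    beta <- sample_beta(config$gamma, L, colSums(tc$m_bar) + init_counts)
    P <- sample_transition_rows(beta, config$alpha, kappa_s, counts)
    emis <- draw_all_emissions(stats_k, prior)
    occupied <- sum(stats_k$N > 0L)
    if (config$verbose && it %% 100L == 0L)
      message(sprintf("iter %5d  occupied %d  loglik %.1f", it, occupied, loglik))
    if (it > config$burn_in && (it - config$burn_in) %% config$thin == 0L) {
      samples[[length(samples) + 1L]] <- list(
        iter = it, beta = beta, pi = P, mu = emis$mu, Sigma = emis$Sigma,
        z = z, occupied = occupied, n_steps = stats_k$N, loglik = loglik)
    }
  }
  structure(list(samples = samples, config = config,
                 runs = fl[c("run_start", "run_length", "track_id")],
                 tau = tracks$tau, n_steps_total = Tt),
            class = "hdphmm_chain")
}

#' @export
print.hdphmm_chain <- function(x, ...) {
  ks <- vapply(x$samples, `[[`, integer(1), "occupied")
  cat("<hdphmm_chain> ", length(x$samples), " retained samples, L = ",
      x$config$L, ", modal occupied states = ",
      as.integer(names(sort(table(ks), decreasing = TRUE))[1]), "\n", sep = "")
  invisible(x)
}

transition_counts <- function(z, run_start, run_length, L) {
  Tt <- length(z)
  last <- run_start + run_length            # 0-based index one past run end
  from_idx <- setdiff(seq_len(Tt), last)    # exclude final step of each run
  from <- z[from_idx]; to <- z[from_idx + 1L]
  matrix(tabulate((from - 1L) * L + to, nbins = L * L), L, L, byrow = TRUE)
}

state_sufficient_stats <- function(X, z, L) {
  N <- tabulate(z, nbins = L)
  part <- rowsum(cbind(X, X[, 1L]^2, X[, 2L]^2, X[, 1L] * X[, 2L]), z)
  sums <- matrix(0, L, 5L)
  sums[as.integer(rownames(part)), ] <- part
  list(N = N, sum_x = sums[, 1:2, drop = FALSE],
       sum_xx = sums[, 3:5, drop = FALSE])
}

draw_all_emissions <- function(stats_k, prior) {
  L <- length(stats_k$N)
  mu <- matrix(0, L, 2L)
  Sigma <- array(0, dim = c(2L, 2L, L))
  sig3 <- matrix(0, L, 3L)
  for (k in seq_len(L)) {
    if (stats_k$N[k] > 0L) {
      N <- stats_k$N[k]
      sx <- stats_k$sum_x[k, ]
      sxx <- matrix(c(stats_k$sum_xx[k, 1L], stats_k$sum_xx[k, 3L],
                      stats_k$sum_xx[k, 3L], stats_k$sum_xx[k, 2L]), 2L, 2L)
      post <- niw_update_from_stats(N, sx, sxx, prior)
    } else {
      post <- prior
    }
    e <- sample_emission(post)
    mu[k, ] <- e$mu
    Sigma[, , k] <- e$Sigma
    sig3[k, ] <- c(e$Sigma[1, 1], e$Sigma[2, 2], e$Sigma[1, 2])
  }
  list(mu = mu, Sigma = Sigma, sig3 = sig3)
}

niw_update_from_stats <- function(N, sum_x, sum_xx, prior) {
  kap <- prior$kappa + N
  th <- (prior$kappa * prior$mean + sum_x) / kap
  nu <- prior$dof + N
  Del <- (prior$dof * prior$scale + sum_xx +
          prior$kappa * tcrossprod(prior$mean) - kap * tcrossprod(th)) / nu
  Del <- (Del + t(Del)) / 2
  if (Del[1, 1] <= 0 || Del[2, 2] <= 0 ||
      Del[1, 1] * Del[2, 2] - Del[1, 2]^2 <= 0)
    Del <- Del + diag(1e-10, 2)
  list(kappa = kap, mean = th, dof = nu, scale = Del)
}
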