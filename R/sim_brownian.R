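#' Simulate a Markov-chain state label sequence
#'
#' @param transition_matrix K x K row-stochastic matrix; entry (i, j) is the
#'   probability of moving from state i to state j at the next step
#' @param initial_distribution length-K probability vector for the first label;
#'   defaults to the stationary distribution of the chain
#' @param length number of labels to draw, >= 1
#' @return integer vector of labels in 1..K
#' @export
simulate_state_sequence <- function(transition_matrix, initial_distribution = NULL,
                                    length) {
  P <- as.matrix(transition_matrix)
  K <- nrow(P)
  if (ncol(P) != K || any(P < 0) || any(abs(rowSums(P) - 1) > 1e-8))
    stop("transition_matrix must be square and row-stochastic")
  if (length < 1L) stop("length must be >= 1")
  p0 <- initial_distribution %||% stationary_distribution(P)
  if (length(p0) != K || any(p0 < 0) || abs(sum(p0) - 1) > 1e-8)
    stop("initial_distribution must be a length-K probability vector")
  z <- integer(length)
  z[1L] <- sample.int(K, 1L, prob = p0)
  if (length > 1L) {
    u <- runif(length - 1L)
    cumP <- t(apply(P, 1L, cumsum))
    for (t in 2:length) {
      z[t] <- findInterval(u[t - 1L], cumP[z[t - 1L], ], left.open = TRUE) + 1L
    }
  }
  z
}

stationary_distribution <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- abs(Re(e$vectors[, i]))
  v / sum(v)
}

#' Default self-transition-dominant transition matrix
#'
#' Off-diagonal mass `1 - p_stay` split evenly among the other states.
#'
#' @param K number of states
#' @param p_stay self-transition probability
#' @return K x K row-stochastic matrix
#' @export
sticky_transition_matrix <- function(K, p_stay = 0.95) {
  stopifnot(K >= 1L, p_stay >= 0, p_stay <= 1)
  if (K == 1L) return(matrix(1, 1, 1))
  P <- matrix((1 - p_stay) / (K - 1), K, K)
  diag(P) <- p_stay
  P
}

normalize_D <- function(D, K) {
  # accepts scalar-per-state vector or K x 2 matrix of per-axis coefficients
  if (is.matrix(D)) {
    stopifnot(nrow(D) == K, ncol(D) == 2)
    Dm <- D
  } else {
    stopifnot(length(D) == K)
    Dm <- cbind(D, D)
  }
  if (any(!is.finite(Dm)) || any(Dm <= 0)) stop("all diffusion coefficients must be > 0")
  colnames(Dm) <- c("x", "y")
  Dm
}

#' Simulate multi-state 2D Brownian trajectories
#'
#' A state label sequence is drawn per track from the Markov chain, then each
#' displacement is a zero-mean Gaussian with per-axis variance `2 * D_axis *
#' tau` (so the 2D mean squared displacement per step is `4 D tau` for an
#' isotropic state). Positions are cumulative sums starting at the origin.
#'
#' @param n_tracks number of trajectories
#' @param track_length number of displacements per trajectory, >= 1
#' @param D per-state apparent diffusion coefficients in um^2/s: a length-K
#'   vector (isotropic) or a K x 2 matrix of (D_x, D_y) for anisotropy
#' @param transition_matrix K x K row-stochastic state-switch matrix;
#'   defaults to [sticky_transition_matrix] with `p_stay = 0.95`
#' @param initial_distribution first-label distribution (default stationary)
#' @param tau frame interval in seconds (default 0.02, i.e. 50 frames/s)
#' @param seed optional integer seed; recorded in the output metadata
#' @return list with elements `tracks` (a [track_set]) and `truth` (list with
#'   `state_sequence` per track, `D`, `transition_matrix`, `diffusion_types`)
#' @export
simulate_bm_tracks <- function(n_tracks, track_length, D,
                               transition_matrix = NULL,
                               initial_distribution = NULL,
                               tau = 0.02, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (track_length < 1L) stop("track_length must be >= 1")
  if (n_tracks < 1L) stop("n_tracks must be >= 1")
  if (tau <= 0) stop("tau must be > 0")
  K <- if (is.matrix(D)) nrow(D) else length(D)
  Dm <- normalize_D(D, K)
  P <- transition_matrix %||% sticky_transition_matrix(K)
  sd_step <- sqrt(2 * Dm * tau)   # K x 2 per-axis step standard deviations
  pos_list <- vector("list", n_tracks)
  z_list <- vector("list", n_tracks)
  for (i in seq_len(n_tracks)) {
    z <- simulate_state_sequence(P, initial_distribution, track_length)
    dx <- rnorm(track_length, 0, sd_step[z, 1L])
    dy <- rnorm(track_length, 0, sd_step[z, 2L])
    pos_list[[i]] <- data.frame(
      track_id = i,
      frame = 0:track_length,
      x_um = c(0, cumsum(dx)),
      y_um = c(0, cumsum(dy)))
    z_list[[i]] <- z
  }
  tracks <- track_set(do.call(rbind, pos_list), tau,
                      metadata = list(seed = seed, simulator = "bm"))
  truth <- list(state_sequence = z_list,
                D = Dm,
                transition_matrix = P,
                diffusion_types = rep("BM", K),
                anomalous_exponents = rep(1, K))
  list(tracks = tracks, truth = truth)
}

#' Refine a transition matrix for sub-step simulation
#'
#' Divides every off-diagonal entry by `Texp` and returns the removed mass to
#' the diagonal, so that the expected number of switches per camera frame is
#' preserved when the chain is run at `Texp`-fold time resolution.
#'
#' @param P row-stochastic matrix
#' @param Texp integer sub-step factor, >= 1
#' @return refined row-stochastic matrix
#' @export
refine_transition_matrix <- function(P, Texp) {
  stopifnot(Texp >= 1)
  Pf <- P / Texp
  diag(Pf) <- 0
  diag(Pf) <- 1 - rowSums(Pf)
  Pf
}

#' Simulate Brownian trajectories with motion blur and localization error
#'
#' Emulates a camera integrating over the exposure: a fine trajectory with
#' `Texp` sub-steps per frame is generated from the `Texp`-refined transition
#' matrix, each reported position is the average of its `Texp` fine positions,
#' and isotropic Gaussian localization noise of standard deviation
#' `localization_sigma` is added per axis. The ground-truth label of an output
#' step is the majority label among its fine steps (ties resolved toward the
#' earlier label).
#'
#' @inheritParams simulate_bm_tracks
#' @param Texp integer number of sub-steps per camera frame, >= 2 (the
#'   degenerate `Texp = 1` reduces to [simulate_bm_tracks] plus noise)
#' @param localization_sigma per-axis localization error in um, >= 0
#' @return same structure as [simulate_bm_tracks]
#' @export
simulate_motion_blur_tracks <- function(n_tracks, track_length, D,
                                        transition_matrix = NULL,
                                        initial_distribution = NULL,
                                        tau = 0.02, Texp = 10L,
                                        localization_sigma = 0.03,
                                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (Texp < 1L) stop("Texp must be >= 1")
  if (localization_sigma < 0) stop("localization_sigma must be >= 0")
  if (track_length < 1L) stop("track_length must be >= 1")
  if (tau <= 0) stop("tau must be > 0")
  K <- if (is.matrix(D)) nrow(D) else length(D)
  Dm <- normalize_D(D, K)
  P <- transition_matrix %||% sticky_transition_matrix(K)
  Pf <- refine_transition_matrix(P, Texp)
  tau_f <- tau / Texp
  sd_step <- sqrt(2 * Dm * tau_f)
  # one extra block so the averaged track has track_length displacements
  n_blocks <- track_length + 1L
  n_fine <- n_blocks * Texp
  pos_list <- vector("list", n_tracks)
  z_list <- vector("list", n_tracks)
  for (i in seq_len(n_tracks)) {
    zf <- simulate_state_sequence(Pf, initial_distribution, n_fine)
    fx <- cumsum(rnorm(n_fine, 0, sd_step[zf, 1L]))
    fy <- cumsum(rnorm(n_fine, 0, sd_step[zf, 2L]))
    grp <- rep(seq_len(n_blocks), each = Texp)
    bx <- tapply(fx, grp, mean) + rnorm(n_blocks, 0, localization_sigma)
    by <- tapply(fy, grp, mean) + rnorm(n_blocks, 0, localization_sigma)
    pos_list[[i]] <- data.frame(
      track_id = i,
      frame = 0:track_length,
      x_um = as.numeric(bx),
      y_um = as.numeric(by))
    # displacement j spans blocks j and j+1; its label is the majority label
    # of block j+1 (the exposure the step lands in)
    z_list[[i]] <- majority_labels(zf, Texp)[-1L]
  }
  tracks <- track_set(do.call(rbind, pos_list), tau,
                      metadata = list(seed = seed, simulator = "motion_blur",
                                      Texp = Texp,
                                      localization_sigma = localization_sigma))
  truth <- list(state_sequence = z_list,
                D = Dm,
                transition_matrix = P,
                diffusion_types = rep("BM", K),
                anomalous_exponents = rep(1, K))
  list(tracks = tracks, truth = truth)
}

majority_labels <- function(z_fine, Texp) {
  n_out <- length(z_fine) %/% Texp
  vapply(seq_len(n_out), function(j) {
    zz <- z_fine[seq((j - 1L) * Texp + 1L, j * Texp)]
    tab <- table(zz)
    win <- names(tab)[tab == max(tab)]
    if (length(win) > 1L) {
      # tie: earliest-appearing label wins
      win <- as.character(zz[match(TRUE, as.character(zz) %in% win)])
    }
    as.integer(win)
  }, integer(1))
}
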