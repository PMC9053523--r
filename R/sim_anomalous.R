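#' Exact fractional Gaussian noise
#'
#' Draws pairs of independent standard fractional-Gaussian-noise sequences
#' (unit variance per increment, unit lag) with Hurst exponent `H`, using
#' circulant embedding of the autocovariance (Davies-Harte / Dietrich-Newsam:
#' the real and imaginary parts of one FFT synthesis give two independent
#' exact samples). Falls back to Cholesky factorisation of the Toeplitz
#' covariance when the embedding is not nonnegative-definite.
#'
#' @param n sequence length (number of increments)
#' @param H Hurst exponent in (0, 1)
#' @param n_pairs how many independent pairs to draw
#' @return array of dim (n, 2, n_pairs); unit-variance correlated noise
#' @keywords internal
fgn_sample <- function(n, H, n_pairs = 1L) {
  stopifnot(n >= 1L, H > 0, H < 1)
  k <- 0:n
  gam <- 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
  out <- array(0, dim = c(n, 2L, n_pairs))
  if (n == 1L) {
    out[1L, , ] <- rnorm(2L * n_pairs)
    return(out)
  }
  m <- 2L * n
  circ <- c(gam, gam[seq(n, 2L)])        # first row of the circulant
  lam <- Re(fft(circ))
  if (min(lam) < -1e-8 * max(lam)) {
    # embedding indefinite: exact Cholesky route
    Sigma <- stats::toeplitz(gam[seq_len(n)])
    L <- chol(Sigma)
    for (p in seq_len(n_pairs)) {
      out[, 1L, p] <- as.numeric(crossprod(L, rnorm(n)))
      out[, 2L, p] <- as.numeric(crossprod(L, rnorm(n)))
    }
    return(out)
  }
  lam <- pmax(lam, 0)
  sq <- sqrt(lam)
  for (p in seq_len(n_pairs)) {
    w <- sq * complex(real = rnorm(m), imaginary = rnorm(m))
    y <- fft(w) / sqrt(m)
    out[, 1L, p] <- Re(y[seq_len(n)])
    out[, 2L, p] <- Im(y[seq_len(n)])
  }
  out
}

#' Simulate 2D fractional Brownian motion
#'
#' Each axis is an independent fractional Brownian motion with process
#' covariance `D_H * (t1^(2H) + t2^(2H) - |t1 - t2|^(2H))`, so the per-axis
#' MSD is `2 * D_H * t^(2H)` and the ensemble MSD exponent is `alpha = 2 H`.
#' Generation is exact (circulant embedding of the increment covariance), not
#' an Euler scheme.
#'
#' @param n_steps number of increments
#' @param H Hurst exponent in (0, 1); `H = 0.5` recovers Brownian motion
#' @param D_H generalized diffusion coefficient (um^2 s^(-2H)), > 0
#' @param tau frame interval in seconds
#' @return (n_steps + 1) x 2 matrix of positions (um), starting at the origin
#' @export
simulate_fbm <- function(n_steps, H, D_H = 1, tau = 0.02) {
  if (!(H > 0 && H < 1)) stop("H must be in (0, 1)")
  stopifnot(n_steps >= 1L, D_H > 0, tau > 0)
  inc <- fgn_sample(n_steps, H)[, , 1L] * sqrt(2 * D_H) * tau^H
  if (n_steps == 1L) inc <- matrix(inc, 1L, 2L)
  rbind(c(0, 0), cbind(cumsum(inc[, 1L]), cumsum(inc[, 2L])))
}

#' Truncated power-law waiting times
#'
#' Inverse-CDF sampling from `psi(t) ~ t^(-sigma)` on `[t_min, t_max]`.
#'
#' @keywords internal
rpowerlaw <- function(n, sigma, t_min, t_max) {
  stopifnot(t_min > 0, t_max > t_min)
  u <- runif(n)
  if (abs(sigma - 1) < 1e-12) {
    exp(log(t_min) + u * (log(t_max) - log(t_min)))
  } else {
    a <- t_min^(1 - sigma); b <- t_max^(1 - sigma)
    (a + u * (b - a))^(1 / (1 - sigma))
  }
}

#' Simulate a 2D continuous-time random walk
#'
#' The particle waits at its position for a power-law time `psi(t) ~
#' t^(-sigma)` (lower cutoff `tau`, upper cutoff `1000 tau`) and then jumps by
#' a zero-mean Gaussian displacement with fixed per-axis variance.  The
#' resulting motion, observed on the regular frame grid, is subdiffusive with
#' ensemble MSD exponent `alpha = sigma - 1` in (0, 1].
#'
#' @param n_frames number of frame intervals to report
#' @param sigma_exponent waiting-time power-law index; `alpha = sigma - 1`
#'   must lie in (0, 1]
#' @param step_variance per-axis jump variance (um^2)
#' @param tau frame interval (s)
#' @param t_min_frames lower waiting-time cutoff in frames (default 1; the
#'   anomalous-scaling regime starts at lags well above this cutoff, so
#'   studies of the deep subdiffusive regime may want a sub-frame cutoff)
#' @param t_max_frames upper waiting-time cutoff in frames (default 1000)
#' @return (n_frames + 1) x 2 position matrix on the frame grid
#' @export
simulate_ctrw <- function(n_frames, sigma_exponent, step_variance = 0.01,
                          tau = 0.02, t_min_frames = 1, t_max_frames = 1000) {
  alpha <- sigma_exponent - 1
  if (!(alpha > 0 && alpha <= 1)) stop("sigma_exponent must give alpha = sigma - 1 in (0, 1]")
  stopifnot(n_frames >= 1L, step_variance > 0, tau > 0,
            t_min_frames > 0, t_max_frames > t_min_frames)
  horizon <- n_frames * tau
  t_jump <- numeric(0); t_now <- 0
  while (t_now <= horizon) {
    w <- rpowerlaw(64L, sigma_exponent, t_min_frames * tau, t_max_frames * tau)
    t_jump <- c(t_jump, t_now + cumsum(w))
    t_now <- t_jump[length(t_jump)]
  }
  t_jump <- t_jump[t_jump <= horizon]
  n_jump <- length(t_jump)
  sd_j <- sqrt(step_variance)
  jx <- c(0, cumsum(rnorm(n_jump, 0, sd_j)))
  jy <- c(0, cumsum(rnorm(n_jump, 0, sd_j)))
  grid <- seq(0, n_frames) * tau
  idx <- findInterval(grid, t_jump) + 1L   # position after all jumps <= grid time
  cbind(jx[idx], jy[idx])
}

#' Simulate a 2D Levy walk
#'
#' Flight durations follow a truncated power law `psi(t) ~ t^(-sigma)`; within
#' a flight the particle moves at constant speed `v` along a uniformly random
#' heading, so `|dx| / t = v` exactly for every completed flight.  Observed on
#' the frame grid the walk is superdiffusive (`alpha = 4 - sigma` for
#' `2 < sigma < 3`, ballistic `alpha = 2` for `sigma <= 2`).
#'
#' @param n_frames number of frame intervals to report
#' @param sigma_exponent flight-duration power-law index in (1, 3]
#' @param speed flight speed v in um/s, > 0
#' @param tau frame interval (s)
#' @param t_max_frames upper flight-duration cutoff in frames (default 1000)
#' @return (n_frames + 1) x 2 position matrix on the frame grid, with
#'   attribute `flights` (data.frame: duration, heading) for diagnostics
#' @export
simulate_lw <- function(n_frames, sigma_exponent, speed = 1, tau = 0.02,
                        t_max_frames = 1000) {
  if (speed <= 0) stop("speed must be > 0")
  stopifnot(n_frames >= 1L, sigma_exponent > 1, tau > 0)
  horizon <- n_frames * tau
  dur <- numeric(0)
  while (sum(dur) <= horizon) {
    dur <- c(dur, rpowerlaw(64L, sigma_exponent, tau, t_max_frames * tau))
  }
  cum_end <- cumsum(dur)
  n_fl <- match(TRUE, cum_end > horizon)
  dur <- dur[seq_len(n_fl)]
  heading <- runif(n_fl, 0, 2 * pi)
  # piecewise-linear path sampled on the frame grid
  t_start <- c(0, cumsum(dur))[seq_len(n_fl)]
  x_start <- c(0, cumsum(speed * dur * cos(heading)))[seq_len(n_fl)]
  y_start <- c(0, cumsum(speed * dur * sin(heading)))[seq_len(n_fl)]
  grid <- seq(0, n_frames) * tau
  seg <- findInterval(grid, t_start)
  dt <- grid - t_start[seg]
  pos <- cbind(x_start[seg] + speed * dt * cos(heading[seg]),
               y_start[seg] + speed * dt * sin(heading[seg]))
  attr(pos, "flights") <- data.frame(duration = dur, heading = heading)
  pos
}

valid_alpha_range <- function(type) {
  switch(type,
         BM   = c(1, 1),
         FBM  = c(0 + 1e-6, 2 - 1e-6),
         CTRW = c(1e-6, 1),
         LW   = c(1, 2),
         stop("unknown diffusion type: ", type))
}

#' Simulate Markov-switching mixtures of diffusion types
#'
#' State labels follow the Markov chain; within each dwell the displacements
#' are generated by that state's process.  FBM correlation is maintained
#' within a dwell and reset at state switches.  For non-Brownian states the
#' supplied `D` is the *apparent* diffusion coefficient: the per-axis
#' single-step displacement variance is calibrated to `2 * D * tau`.
#'
#' @param states list of per-state descriptors, each a list with `type`
#'   (one of "BM", "FBM", "CTRW", "LW"), `D` (apparent um^2/s) and, for
#'   anomalous types, `alpha`
#' @param n_tracks,track_length,transition_matrix,initial_distribution,tau,seed
#'   as in [simulate_bm_tracks]
#' @return list with `tracks` ([track_set]) and `truth` (as in
#'   [simulate_bm_tracks], plus per-state `diffusion_types` and
#'   `anomalous_exponents`)
#' @export
simulate_mixed_type_tracks <- function(states, n_tracks, track_length,
                                       transition_matrix = NULL,
                                       initial_distribution = NULL,
                                       tau = 0.02, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(states) >= 1L, n_tracks >= 1L, track_length >= 1L, tau > 0)
  K <- length(states)
  for (s in states) {
    if (is.null(s$type) || is.null(s$D) || s$D <= 0)
      stop("each state needs a type and a positive apparent D")
    a <- s$alpha %||% 1
    rng <- valid_alpha_range(s$type)
    if (a < rng[1] || a > rng[2])
      stop("alpha ", a, " outside the valid range for ", s$type)
    if (s$type %in% c("CTRW", "LW"))
      warning("state of type ", s$type, " requested: the Gaussian-emission ",
              "HMM assumptions do not hold for this type", call. = FALSE)
  }
  P <- transition_matrix %||% sticky_transition_matrix(K)
  pos_list <- vector("list", n_tracks)
  z_list <- vector("list", n_tracks)
  for (i in seq_len(n_tracks)) {
    z <- simulate_state_sequence(P, initial_distribution, track_length)
    inc <- matrix(0, track_length, 2L)
    r <- rle(z)
    at <- 1L
    for (j in seq_along(r$lengths)) {
      len <- r$lengths[j]
      st <- states[[r$values[j]]]
      rows <- seq(at, at + len - 1L)
      inc[rows, ] <- dwell_increments(st, len, tau)
      at <- at + len
    }
    pos_list[[i]] <- data.frame(
      track_id = i,
      frame = 0:track_length,
      x_um = c(0, cumsum(inc[, 1L])),
      y_um = c(0, cumsum(inc[, 2L])))
    z_list[[i]] <- z
  }
  tracks <- track_set(do.call(rbind, pos_list), tau,
                      metadata = list(seed = seed, simulator = "mixed_type"))
  truth <- list(
    state_sequence = z_list,
    D = normalize_D(vapply(states, `[[`, numeric(1), "D"), K),
    transition_matrix = P,
    diffusion_types = vapply(states, `[[`, character(1), "type"),
    anomalous_exponents = vapply(states, function(s) s$alpha %||% 1, numeric(1)))
  list(tracks = tracks, truth = truth)
}

# per-dwell displacement generation, per-axis single-step sd sqrt(2 D tau)
dwell_increments <- function(state, len, tau) {
  sd_step <- sqrt(2 * state$D * tau)
  switch(state$type,
    BM = matrix(rnorm(2L * len, 0, sd_step), len, 2L),
    FBM = {
      H <- (state$alpha %||% 1) / 2
      g <- fgn_sample(len, H)[, , 1L]
      if (len == 1L) g <- matrix(g, 1L, 2L)
      g * sd_step
    },
    CTRW = {
      p <- simulate_ctrw(len, sigma_exponent = (state$alpha %||% 0.5) + 1,
                         step_variance = 2 * state$D * tau, tau = tau)
      diff(p)
    },
    LW = {
      p <- simulate_lw(len, sigma_exponent = 4 - (state$alpha %||% 1.5),
                       speed = 2 * sqrt(state$D / tau), tau = tau)
      diff(unclass(p))
    })
}
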