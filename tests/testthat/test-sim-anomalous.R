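test_that("fractional Brownian motion has the exact process covariance", {
  # H = 0.5 is Brownian: increment lag-1 autocorrelation ~ 0
  set.seed(1)
  p <- simulate_fbm(10000, H = 0.5, D_H = 0.5)
  d <- diff(p)
  expect_equal(cor(d[-1, 1], d[-nrow(d), 1]), 0, tolerance = 0.02)

  # H = 0.25: sample covariance at (5 tau, 10 tau) matches
  # D_H (t1^2H + t2^2H - |t1-t2|^2H) within Monte-Carlo CI
  H <- 0.25; DH <- 0.5; tau <- 0.02
  paths <- replicate(10000, simulate_fbm(10, H, DH, tau)[c(6, 11), 1])
  prod <- paths[1, ] * paths[2, ]
  closed <- DH * ((5 * tau)^(2 * H) + (10 * tau)^(2 * H) - (5 * tau)^(2 * H))
  expect_lt(abs(mean(prod) - closed), 3 * sd(prod) / sqrt(length(prod)))

  # ensemble MSD log-log slope recovers alpha = 2H
  set.seed(2)
  paths2 <- replicate(2000, simulate_fbm(100, H, DH, tau), simplify = FALSE)
  expect_equal(msd_alpha(paths2, 20), 0.5, tolerance = 0.05)

  # increment correlation sign follows the Hurst exponent
  set.seed(3)
  d_sub <- diff(simulate_fbm(5000, 0.3, 0.5))
  d_sup <- diff(simulate_fbm(5000, 0.7, 0.5))
  expect_lt(cor(d_sub[-1, 1], d_sub[-nrow(d_sub), 1]), -0.05)
  expect_gt(cor(d_sup[-1, 1], d_sup[-nrow(d_sup), 1]), 0.05)

  expect_error(simulate_fbm(10, H = 1.2), "H must")
})

test_that("CTRW waiting times and MSD scaling match the power law", {
  set.seed(4)
  # sigma = 2 (alpha = 1): diffusive scaling at the default cutoffs
  pc <- replicate(3000, simulate_ctrw(100, sigma_exponent = 2), simplify = FALSE)
  expect_equal(msd_alpha(pc, 50), 1, tolerance = 0.1)

  # sigma = 1.5 (alpha = 0.5): subdiffusive regime; the scaling window sits
  # well above the waiting-time lower cutoff, so probe it with a sub-frame
  # cutoff
  pc2 <- replicate(4000, simulate_ctrw(100, sigma_exponent = 1.5,
                                       t_min_frames = 0.01),
                   simplify = FALSE)
  expect_equal(msd_alpha(pc2, 50), 0.5, tolerance = 0.1)

  # drawn waiting times: Hill tail-index estimate within 10%
  w <- sptstates:::rpowerlaw(50000, sigma = 1.5, t_min = 0.02,
                             t_max = 0.02 * 1e7)
  ws <- sort(w, decreasing = TRUE)
  k <- 500   # deep tail, clear of the upper cutoff
  hill <- 1 / mean(log(ws[1:k] / ws[k + 1]))
  expect_equal(hill, 0.5, tolerance = 0.1)   # tail index sigma - 1

  # particle is immobile between jumps: positions piecewise constant
  p1 <- simulate_ctrw(200, sigma_exponent = 1.2)
  d1 <- diff(p1)
  expect_gt(mean(rowSums(d1^2) == 0), 0.3)

  expect_error(simulate_ctrw(10, sigma_exponent = 2.5), "alpha")
})

test_that("Levy walks fly at constant speed with uniform headings", {
  set.seed(5)
  v <- 1.7; tau <- 0.02
  p <- simulate_lw(500, sigma_exponent = 2.5, speed = v, tau = tau)
  d <- diff(unclass(p))
  speeds <- sqrt(rowSums(d^2)) / tau
  # within a flight the gridded speed equals v exactly; turns make it smaller
  expect_lt(max(speeds), v * (1 + 1e-9))
  expect_gt(mean(abs(speeds - v) < 1e-9 * v), 0.5)

  # headings uniform on the circle (Rayleigh test, n = 1e4)
  heads <- unlist(replicate(400, attr(simulate_lw(60, 2.5, speed = 1),
                                      "flights")$heading, simplify = FALSE))
  n <- length(heads)
  rbar2 <- (mean(cos(heads)))^2 + (mean(sin(heads)))^2
  p_rayleigh <- exp(-n * rbar2)
  expect_gt(p_rayleigh, 0.01)

  # superdiffusive ensemble MSD
  set.seed(6)
  pl <- replicate(800, unclass(simulate_lw(100, 2.5, speed = 1)),
                  simplify = FALSE)
  expect_gt(msd_alpha(pl, 20), 1.2)

  expect_error(simulate_lw(10, 2.5, speed = 0), "speed")
})

test_that("mixed-type simulation calibrates apparent D and keeps FBM memory", {
  # single-state BM "mixture" reduces to the plain BM simulator
  sim <- simulate_mixed_type_tracks(list(list(type = "BM", D = 0.8)),
                                    n_tracks = 10, track_length = 3000,
                                    seed = 7)
  d <- do.call(rbind, displacements_from_tracks(sim$tracks))
  expect_equal(var(d[, 1]), 2 * 0.8 * 0.02, tolerance = 0.03)

  # single-state FBM: per-step variance 2 D tau and the fGn lag-1
  # autocorrelation 2^(2H-1) - 1
  simf <- simulate_mixed_type_tracks(
    list(list(type = "FBM", D = 0.3, alpha = 0.5)),
    n_tracks = 5, track_length = 4000, seed = 8)
  df <- do.call(rbind, displacements_from_tracks(simf$tracks))
  expect_equal(var(df[, 1]), 2 * 0.3 * 0.02, tolerance = 0.03)
  rho1 <- 2^(2 * 0.25 - 1) - 1
  expect_equal(cor(df[-1, 1], df[-nrow(df), 1]), rho1, tolerance = 0.04)

  # two-state BM + FBM mixture carries coherent ground truth
  states <- list(list(type = "FBM", D = 0.045, alpha = 0.5),
                 list(type = "BM", D = 0.90))
  mix <- simulate_mixed_type_tracks(states, 20, 100, seed = 9)
  expect_equal(mix$truth$diffusion_types, c("FBM", "BM"))
  expect_equal(unname(mix$truth$D[, 1]), c(0.045, 0.90))
  expect_equal(vapply(mix$truth$state_sequence, length, integer(1)),
               rep(100L, 20))

  # CTRW / LW states are allowed but flagged
  expect_warning(
    simulate_mixed_type_tracks(list(list(type = "LW", D = 0.5, alpha = 1.5)),
                               2, 50, seed = 10),
    "assumptions")

  # invalid alpha for a type errors
  expect_error(
    simulate_mixed_type_tracks(list(list(type = "CTRW", D = 1, alpha = 1.5)),
                               2, 10),
    "valid range")

  # bit-reproducible under a fixed seed
  a <- simulate_mixed_type_tracks(states, 3, 20, seed = 11)
  b <- simulate_mixed_type_tracks(states, 3, 20, seed = 11)
  expect_identical(a$tracks$positions, b$tracks$positions)
  expect_identical(a$truth$state_sequence, b$truth$state_sequence)
})
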