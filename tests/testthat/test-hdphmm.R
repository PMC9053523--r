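test_that("blocked state draws match brute-force enumeration on T = 3", {
  set.seed(1)
  P <- matrix(c(0.8, 0.2, 0.3, 0.7), 2, byrow = TRUE)
  pi0 <- c(0.7, 0.3)
  emis <- list(list(mu = c(0, 0), Sigma = diag(0.01, 2)),
               list(mu = c(0, 0), Sigma = diag(0.1, 2)))
  x <- rbind(c(0.05, 0), c(0.2, -0.1), c(0, 0.02))

  # exact posterior over the 8 label sequences by enumeration
  dens <- function(xi, e) {
    exp(-0.5 * sum(xi^2) / e$Sigma[1, 1]) / (2 * pi * e$Sigma[1, 1])
  }
  seqs <- as.matrix(expand.grid(1:2, 1:2, 1:2))
  post <- apply(seqs, 1, function(z) {
    pi0[z[1]] * P[z[1], z[2]] * P[z[2], z[3]] *
      dens(x[1, ], emis[[z[1]]]) * dens(x[2, ], emis[[z[2]]]) *
      dens(x[3, ], emis[[z[3]]])
  })
  post <- post / sum(post)

  n_draw <- 30000
  draws <- replicate(n_draw, sample_state_sequence(x, P, emis, pi0))
  key <- draws[1, ] + 2 * (draws[2, ] - 1) + 4 * (draws[3, ] - 1)
  key_ref <- seqs[, 1] + 2 * (seqs[, 2] - 1) + 4 * (seqs[, 3] - 1)
  emp <- tabulate(key, 8)[key_ref] / n_draw
  expect_lt(max(abs(emp - post)), 0.01)
})

test_that("degenerate state-sampling cases behave", {
  x <- matrix(rnorm(20), 10, 2)
  # single-state model
  e1 <- list(list(mu = c(0, 0), Sigma = diag(2)))
  expect_equal(sample_state_sequence(x, matrix(1, 1, 1), e1), rep(1L, 10))
  # a state with zero transition probability and zero initial mass never appears
  P <- matrix(c(1, 0, 1, 0), 2, byrow = TRUE)
  e2 <- list(list(mu = c(0, 0), Sigma = diag(2)),
             list(mu = c(0, 0), Sigma = diag(2)))
  z <- sample_state_sequence(x, P, e2, pi0 = c(1, 0))
  expect_true(all(z == 1L))
})

test_that("NIW conjugate updates match an independent decomposition", {
  prior <- list(kappa = 1, mean = c(0.1, -0.2), dof = 4,
                scale = matrix(c(0.5, 0.1, 0.1, 0.8), 2))

  # empty update returns the prior
  expect_identical(niw_posterior_update(NULL, prior), prior)
  expect_identical(niw_posterior_update(matrix(0, 0, 2), prior), prior)

  x <- rbind(c(0.3, 0.5), c(-0.2, 0.1), c(0.4, -0.6), c(0.05, 0.2),
             c(-0.15, 0.35))
  post <- niw_posterior_update(x, prior)

  # pseudo-count and dof updates
  expect_equal(post$kappa, 1 + 3 + 2)   # kappa + N with N = 5
  expect_equal(post$dof, prior$dof + 5)

  # independent sufficient-statistics oracle: scatter about the sample mean
  # plus the prior-mean shrinkage term
  N <- nrow(x); xbar <- colMeans(x)
  S <- crossprod(sweep(x, 2, xbar))
  shrink <- (prior$kappa * N / (prior$kappa + N)) *
    tcrossprod(xbar - prior$mean)
  expect_equal(post$mean,
               (prior$kappa * prior$mean + N * xbar) / (prior$kappa + N),
               tolerance = 1e-12)
  expect_equal(post$scale * post$dof,
               prior$dof * prior$scale + S + shrink, tolerance = 1e-10)
})

test_that("emission draws have the closed-form NIW moments", {
  set.seed(2)
  niw <- list(kappa = 5, mean = c(0.2, -0.1), dof = 20,
              scale = matrix(c(0.4, 0.05, 0.05, 0.3), 2))
  draws <- replicate(10000, sample_emission(niw), simplify = FALSE)
  # E[Sigma] = dof * scale / (dof - d - 1)
  S_mean <- Reduce(`+`, lapply(draws, `[[`, "Sigma")) / length(draws)
  expect_equal(S_mean, niw$dof * niw$scale / (niw$dof - 3), tolerance = 0.02)
  # E[mu] = theta
  mu_mean <- colMeans(do.call(rbind, lapply(draws, `[[`, "mu")))
  expect_equal(mu_mean, niw$mean, tolerance = 0.02)
  # every draw SPD (Cholesky succeeds)
  expect_true(all(vapply(draws, function(d)
    !inherits(try(chol(d$Sigma), silent = TRUE), "try-error"), logical(1))))
})

test_that("transition rows follow the sticky Dirichlet posterior", {
  set.seed(3)
  L <- 3; a <- 1; kappa <- 5
  beta <- c(0.5, 0.3, 0.2)
  zero <- matrix(0L, L, L)
  draws <- replicate(20000, sample_transition_rows(beta, a, kappa, zero),
                     simplify = "array")
  # rows sum to one exactly
  expect_lt(max(abs(apply(draws[, , 1:50], c(1, 3), sum) - 1)), 1e-12)
  # E[pi_jj] = (a beta_j + kappa) / (a + kappa)
  for (j in 1:L)
    expect_equal(mean(draws[j, j, ]), (a * beta[j] + kappa) / (a + kappa),
                 tolerance = 0.005)
  # kappa = 0 reduces to the plain HDP prior Dir(a beta)
  d0 <- replicate(100000, sample_transition_rows(beta, a, 0, zero)[1, ])
  expect_lt(max(abs(rowMeans(d0) - beta)), 0.005)
})

test_that("global weights and table counts follow the weak-limit law", {
  set.seed(4)
  # prior draw is symmetric Dirichlet(gamma / L)
  b <- replicate(20000, sample_beta(2, 4))
  expect_equal(rowMeans(b), rep(0.25, 4), tolerance = 0.005)
  expect_lt(max(abs(colSums(b) - 1)), 1e-12)

  # table-count law: compare against an explicit Chinese-restaurant seating
  # oracle that tracks table sizes (different construction, same law)
  w <- 2.5; n <- 40; reps <- 4000
  beta <- c(0.5, 0.5)
  counts <- matrix(0L, 2, 2); counts[1, 2] <- n
  m_impl <- replicate(reps,
    sample_table_counts(beta, alpha = w / beta[2], sticky_kappa = 0,
                        counts = counts)$m[1, 2])
  crp_tables <- function(n, w) {
    sizes <- integer(0)
    for (i in seq_len(n)) {
      p <- c(sizes, w)
      k <- sample.int(length(p), 1, prob = p)
      if (k > length(sizes)) sizes <- c(sizes, 1L)
      else sizes[k] <- sizes[k] + 1L
    }
    length(sizes)
  }
  m_oracle <- replicate(reps, crp_tables(n, w))
  expect_equal(mean(m_impl), mean(m_oracle), tolerance = 0.05)
  expect_equal(sd(m_impl), sd(m_oracle), tolerance = 0.1)

  # sticky override correction removes self-transition tables
  counts2 <- matrix(0L, 2, 2); counts2[1, 1] <- n
  tc <- replicate(reps, unlist(
    sample_table_counts(beta, alpha = 1, sticky_kappa = 9,
                        counts = counts2)[c("m", "m_bar")])[c(1, 5)])
  expect_true(all(tc[2, ] <= tc[1, ]))
  expect_lt(mean(tc[2, ]), mean(tc[1, ]))
})

test_that("the sampler recovers a single-state dataset's D exactly enough", {
  sim <- simulate_bm_tracks(20, 500, D = 1.0, tau = 0.02, seed = 5)
  ch <- hdphmm_fit(sim$tracks, quick_config(seed = 6))
  expect_equal(as.integer(estimate_num_states(ch)), 1L)
  s <- summarize_chain(ch)
  # conjugate-posterior oracle: D concentrates at the empirical variance
  d <- do.call(rbind, displacements_from_tracks(sim$tracks))
  D_hat <- mean(c(var(d[, 1]), var(d[, 2]))) / (2 * 0.02)
  expect_equal(s$pooled$D[1], D_hat, tolerance = 0.05)
  expect_equal(s$pooled$D[1], 1.0, tolerance = 0.05)
})

test_that("chains are bit-reproducible under a fixed seed", {
  sim <- two_state_bm(30, 30, seed = 7)
  c1 <- hdphmm_fit(sim$tracks, quick_config(100L, 50L, 5L, seed = 8))
  c2 <- hdphmm_fit(sim$tracks, quick_config(100L, 50L, 5L, seed = 8))
  expect_identical(lapply(c1$samples, `[[`, "z"),
                   lapply(c2$samples, `[[`, "z"))
  expect_identical(lapply(c1$samples, `[[`, "Sigma"),
                   lapply(c2$samples, `[[`, "Sigma"))
})

test_that("posterior samples satisfy the structural invariants", {
  sim <- two_state_bm(30, 30, seed = 9)
  ch <- hdphmm_fit(sim$tracks, quick_config(100L, 50L, 5L, seed = 10))
  for (s in ch$samples) {
    expect_equal(sum(s$beta), 1, tolerance = 1e-9)
    expect_lt(max(abs(rowSums(s$pi) - 1)), 1e-9)
    expect_true(all(apply(s$Sigma, 3, function(S)
      S[1, 2] == S[2, 1] && det(S) > 0 && S[1, 1] > 0)))
    expect_true(s$occupied >= 1 && s$occupied <= ch$config$L)
    expect_equal(length(s$z), ch$n_steps_total)
  }
})

test_that("config validation rejects bad hyperparameters", {
  expect_error(hdphmm_config(gamma = -1))
  expect_error(hdphmm_config(L = 1))
  expect_error(hdphmm_config(burn_in = 100, n_iterations = 50))
  expect_error(hdphmm_config(niw_scale = matrix(c(1, 2, 2, 1), 2)))
  expect_error(hdphmm_config(thin = 0))
})
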