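make_track <- function(n_steps, seed = 1) {
  set.seed(seed)
  d <- matrix(rnorm(2 * n_steps, 0, 0.1), n_steps, 2)
  df <- data.frame(track_id = 1, frame = 0:n_steps,
                   x_um = c(0, cumsum(d[, 1])), y_um = c(0, cumsum(d[, 2])))
  track_set(df, 0.02)
}

test_that("segment extraction respects run boundaries and the length filter", {
  ts <- make_track(50)

  # one state throughout: a single 50-step segment at min_length 40
  segs <- extract_segments(ts, list(rep(1L, 50)), min_length = 40)
  expect_length(segs, 1L)
  expect_equal(segs[[1]]$length, 50L)
  expect_equal(nrow(segs[[1]]$coords), 51L)

  # switch after step 20: both runs (20 and 30) fall below 40
  labs <- c(rep(1L, 20), rep(2L, 30))
  segs2 <- extract_segments(ts, list(labs), min_length = 40)
  expect_length(segs2, 0L)
  expect_equal(attr(segs2, "dropped"), 2L)

  # the same labels pass at min_length 20
  segs3 <- extract_segments(ts, list(labs), min_length = 20)
  expect_length(segs3, 2L)
  expect_equal(vapply(segs3, `[[`, integer(1), "state"), c(1L, 2L))

  # misaligned labels error
  expect_error(extract_segments(ts, list(rep(1L, 49))), "misaligned")
  expect_error(extract_segments(ts, rep(1L, 49)), "misaligned")
})

test_that("normalization centres, scales and preserves aspect ratio", {
  set.seed(2)
  seg <- cbind(cumsum(rnorm(30, 0, 1)), cumsum(rnorm(30, 0, 0.2)))
  nz <- normalize_segment(seg)
  expect_equal(colMeans(nz), c(0, 0), tolerance = 1e-9)
  expect_equal(mean(nz^2), 1, tolerance = 1e-9)

  # scale and translation invariance: 10x scaled, shifted copy maps equally
  nz2 <- normalize_segment(seg * 10 + 3)
  expect_equal(nz, nz2, tolerance = 1e-9)

  # anisotropy (per-axis variance ratio) is preserved, not erased
  expect_equal(var(nz[, 1]) / var(nz[, 2]), var(seg[, 1]) / var(seg[, 2]),
               tolerance = 1e-9)

  # immobile segment excluded
  expect_null(normalize_segment(matrix(1, 5, 2)))
})

test_that("windowing slices long segments into model-sized pieces", {
  seg <- cbind(cumsum(rnorm(96, 0, 0.1)), cumsum(rnorm(96, 0, 0.1)))
  Xw <- sptstates:::windows_of_segment(rbind(0, apply(seg, 2, cumsum)), 40)
  expect_equal(dim(Xw), c(2L, 40L, 4L))   # trailing 16 steps dropped
  expect_null(sptstates:::windows_of_segment(seg[1:20, ], 40))
})

test_that("a small trained classifier produces valid, deterministic output", {
  corpus <- make_classifier_corpus(150, 20, seed = 3)
  clf <- train_diffusion_classifier(corpus, units = c(12L, 8L), epochs = 8,
                                    seed = 4)
  expect_s3_class(clf$model, "lstm_model")
  expect_true(all(dim(clf$confusion) <= c(4, 4)))

  ts <- make_track(60, seed = 5)
  segs <- extract_segments(ts, list(rep(1L, 60)), min_length = 20)
  pr <- classify_segments(clf, segs)
  expect_equal(sum(pr[1, clf$types]), 1, tolerance = 1e-6)
  # duplicate segments get identical probabilities
  pr2 <- classify_segments(clf, c(segs, segs))
  expect_equal(unlist(pr2[1, clf$types]), unlist(pr2[2, clf$types]),
               tolerance = 1e-12)

  # class imbalance is refused
  bad <- corpus
  bad$y[bad$y == 2L][1:60] <- 1L
  expect_error(train_diffusion_classifier(bad), "imbalance")
})

test_that("state-level probabilities are length-weighted segment averages", {
  seg_probs <- data.frame(track_id = c("a", "a"), state = c(1L, 1L),
                          length = c(40, 60),
                          BM = c(1, 0), FBM = c(0, 1),
                          CTRW = c(0, 0), LW = c(0, 0))
  st <- state_type_probability(seg_probs)
  expect_equal(unlist(st[1, c("BM", "FBM", "CTRW", "LW")]),
               c(BM = 0.4, FBM = 0.6, CTRW = 0, LW = 0))

  # single segment: its own probability vector
  st1 <- state_type_probability(seg_probs[1, ])
  expect_equal(st1$BM, 1)

  # equal lengths reduce to the unweighted mean
  seg_probs$length <- c(50, 50)
  expect_equal(state_type_probability(seg_probs)$BM, 0.5)

  # rows stay on the simplex
  expect_equal(sum(st[1, c("BM", "FBM", "CTRW", "LW")]), 1)
})

test_that("alpha regression output respects the type's valid range", {
  reg <- train_alpha_regressor("FBM", n_tracks = 300, n_steps = 20,
                               units = c(8L, 6L), epochs = 4, seed = 6)
  ts <- make_track(40, seed = 7)
  segs <- extract_segments(ts, list(rep(1L, 40)), min_length = 20)
  ra <- regress_alpha(reg, segs)
  expect_true(all(ra$per_segment$alpha >= reg$alpha_range[1]))
  expect_true(all(ra$per_segment$alpha <= reg$alpha_range[2]))
  expect_equal(nrow(ra$per_state), 1L)
})

test_that("mixture states are typed correctly end to end", {
  # subdiffusive FBM (alpha 0.5) + Brownian mixture; segments cut at the
  # ground-truth labels isolate the classifier's discrimination
  corpus <- make_classifier_corpus(600, 20, seed = 31)
  clf <- train_diffusion_classifier(corpus, units = c(24L, 12L), epochs = 12,
                                    seed = 32)
  expect_gt(clf$accuracy, 0.4)   # well above the 0.25 chance level

  states <- list(list(type = "FBM", D = 0.045, alpha = 0.5),
                 list(type = "BM", D = 0.90))
  mix <- simulate_mixed_type_tracks(states, 300, 100,
                                    sticky_transition_matrix(2, 0.95),
                                    seed = 33)
  segs <- extract_segments(mix$tracks, mix$truth$state_sequence,
                           min_length = 20)
  st <- state_type_probability(classify_segments(clf, segs))
  st <- st[order(st$state), ]
  types <- c("BM", "FBM", "CTRW", "LW")
  # the FBM state's top type is FBM; the BM state's top type is BM
  expect_equal(types[which.max(st[1, types])], "FBM")
  expect_equal(types[which.max(st[2, types])], "BM")
  # rows remain on the simplex
  expect_equal(unname(rowSums(st[, types])), c(1, 1), tolerance = 1e-9)
})
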