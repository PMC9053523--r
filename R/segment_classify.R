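DIFFUSION_TYPES <- c("BM", "FBM", "CTRW", "LW")

#' Extract same-state trajectory segments
#'
#' Cuts every displacement run into maximal sub-runs of constant state label
#' and returns each as a coordinate segment (run length + 1 positions).
#' Segments shorter than `min_length` steps are dropped (counted in the
#' `dropped` attribute).
#'
#' @param tracks a [track_set]
#' @param labels list of per-run integer label vectors, aligned one label per
#'   displacement with the runs of [displacements_from_tracks]; or a single
#'   flat vector over all runs
#' @param min_length minimum segment length in steps (paper-style default 40)
#' @return list of segments, each a list with `coords` ((len + 1) x 2
#'   matrix), `state`, `track_id`, `length` (steps); attribute `dropped`
#'   counts sub-runs below `min_length`
#' @export
extract_segments <- function(tracks, labels, min_length = 40L) {
  stopifnot(inherits(tracks, "track_set"), min_length >= 1L)
  pos <- tracks$positions
  disp <- displacements_from_tracks(tracks)
  lens <- vapply(disp, nrow, integer(1))
  if (!is.list(labels)) {
    if (length(labels) != sum(lens))
      stop("labels (", length(labels), ") misaligned with displacements (",
           sum(lens), ")")
    labels <- split(labels, rep(seq_along(lens), lens))
  }
  if (length(labels) != length(disp) ||
      !all(vapply(labels, length, integer(1)) == lens))
    stop("labels misaligned with displacement runs")
  segs <- list(); dropped <- 0L
  for (r in seq_along(disp)) {
    id <- attr(disp[[r]], "track_id")
    # rebuild run coordinates from cumulative displacements
    coords <- rbind(c(0, 0), apply(disp[[r]], 2L, cumsum))
    if (lens[r] == 1L) coords <- rbind(c(0, 0), matrix(disp[[r]], 1L, 2L))
    rl <- rle(as.integer(labels[[r]]))
    at <- 1L
    for (j in seq_along(rl$lengths)) {
      len <- rl$lengths[j]
      if (len >= min_length) {
        segs[[length(segs) + 1L]] <- list(
          coords = coords[at:(at + len), , drop = FALSE],
          state = rl$values[j], track_id = id, length = len)
      } else dropped <- dropped + 1L
      at <- at + len
    }
  }
  attr(segs, "dropped") <- dropped
  segs
}

#' Normalize a coordinate segment
#'
#' Centres each dimension at zero and rescales by the pooled (both-axis)
#' standard deviation so the overall variance is one while the aspect ratio
#' (anisotropy cue) is preserved. Degenerate segments (all positions equal)
#' return `NULL`.
#'
#' @param coords n x 2 coordinate matrix, n >= 2
#' @return normalized n x 2 matrix, or `NULL` for a degenerate segment
#' @export
normalize_segment <- function(coords) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2L, nrow(coords) >= 2L)
  cc <- sweep(coords, 2L, colMeans(coords))
  s <- sqrt(mean(cc^2))
  if (!is.finite(s) || s == 0) return(NULL)
  cc / s
}

# network input features for one normalized (n+1) x 2 coordinate segment:
# the coordinates and their first differences, n x 4. The differences carry
# no extra information but expose the increment autocorrelation directly.
segment_features <- function(nz) {
  cbind(nz[-1L, , drop = FALSE], diff(nz))
}

# stack per-segment windows into the (n, T, 4) array the LSTM expects
windows_of_segment <- function(coords, n_steps) {
  n <- nrow(coords) - 1L
  n_win <- n %/% n_steps
  if (n_win == 0L) return(NULL)
  out <- array(0, dim = c(n_win, n_steps, 4L))
  ok <- logical(n_win)
  for (w in seq_len(n_win)) {
    piece <- coords[((w - 1L) * n_steps + 1L):(w * n_steps + 1L), , drop = FALSE]
    nz <- normalize_segment(piece)
    if (is.null(nz)) next
    out[w, , ] <- segment_features(nz)
    ok[w] <- TRUE
  }
  if (!any(ok)) return(NULL)
  out[ok, , , drop = FALSE]
}

#' Simulate a labelled diffusion-type training corpus
#'
#' Balanced single-state tracks of a fixed length for the four diffusion
#' types. Anomalous exponents are drawn uniformly over each type's valid
#' range (FBM excludes a band around the Brownian point alpha = 1, where the
#' class is not identifiable). All tracks are normalized with
#' [normalize_segment], so the corpus is scale-free.
#'
#' @param n_per_class tracks per class
#' @param n_steps steps per track (20 or 40 in the paper's networks)
#' @param tau frame interval (s)
#' @param types classes to include (default all four)
#' @param seed RNG seed
#' @return list with `X` (array n x n_steps x 4: normalized coordinates and
#'   their increments), `y` (integer class index into `types`), `alpha`
#'   (per-track exponent), `types`
#' @export
make_classifier_corpus <- function(n_per_class, n_steps, tau = 0.02,
                                   types = DIFFUSION_TYPES, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_tot <- n_per_class * length(types)
  X <- array(0, dim = c(n_tot, n_steps, 4L))
  y <- integer(n_tot); alpha <- numeric(n_tot)
  row <- 0L
  for (ci in seq_along(types)) {
    type <- types[ci]
    made <- 0L
    while (made < n_per_class) {
      a <- switch(type,
        BM = 1,
        FBM = {  # avoid the BM-identical point
          aa <- runif(1, 0.1, 1.9)
          while (abs(aa - 1) < 0.1) aa <- runif(1, 0.1, 1.9)
          aa
        },
        CTRW = runif(1, 0.1, 1.0),
        LW = runif(1, 1.1, 2.0))
      p <- switch(type,
        BM = {
          d <- matrix(rnorm(2L * n_steps, 0, sqrt(2 * 0.5 * tau)), n_steps, 2L)
          rbind(c(0, 0), apply(d, 2L, cumsum))
        },
        FBM = simulate_fbm(n_steps, H = a / 2, D_H = 0.5, tau = tau),
        CTRW = simulate_ctrw(n_steps, sigma_exponent = a + 1,
                             step_variance = 2 * 0.5 * tau, tau = tau),
        LW = unclass(simulate_lw(n_steps, sigma_exponent = 4 - a,
                                 speed = 2 * sqrt(0.5 / tau), tau = tau)))
      nz <- normalize_segment(p)
      if (is.null(nz)) next   # e.g. a CTRW track that never jumped
      row <- row + 1L; made <- made + 1L
      X[row, , ] <- segment_features(nz)
      y[row] <- ci
      alpha[row] <- a
    }
  }
  list(X = X, y = y, alpha = alpha, types = types)
}

#' Train the diffusion-type classifier
#'
#' Two stacked LSTM layers (default 100 and 50 units) and a dense softmax
#' head over the four diffusion types, trained on a balanced simulated
#' corpus of normalized fixed-length tracks. Refuses corpora whose class
#' sizes differ by more than 10%.
#'
#' @param corpus a corpus from [make_classifier_corpus] (or one of identical
#'   structure)
#' @param units LSTM layer widths
#' @param epochs,batch_size,lr,seed training controls (see [lstm_train])
#' @param holdout_fraction fraction reserved for the reported confusion
#'   matrix
#' @param verbose print progress
#' @return a `diffusion_classifier`: the fitted `lstm_model` plus `types`,
#'   `confusion` (held-out counts), `accuracy` (held-out), and the corpus
#'   descriptor
#' @export
train_diffusion_classifier <- function(corpus, units = c(100L, 50L),
                                       epochs = 15L, batch_size = 128L,
                                       lr = 1e-3, holdout_fraction = 0.1,
                                       seed = 1L, verbose = FALSE) {
  tab <- table(corpus$y)
  if (max(tab) > 1.1 * min(tab))
    stop("class imbalance exceeds 10%: ", paste(tab, collapse = "/"))
  if (!is.null(seed)) set.seed(seed)
  n <- length(corpus$y)
  ho <- sample.int(n, max(1L, floor(holdout_fraction * n)))
  tr <- setdiff(seq_len(n), ho)
  model <- lstm_train(corpus$X[tr, , , drop = FALSE], corpus$y[tr],
                      units = units, task = "classification",
                      epochs = epochs, batch_size = batch_size, lr = lr,
                      seed = seed, verbose = verbose)
  pr <- lstm_predict(model, corpus$X[ho, , , drop = FALSE])
  pred <- max.col(pr)
  conf <- table(truth = corpus$types[corpus$y[ho]],
                predicted = corpus$types[pred])
  structure(list(model = model, types = corpus$types,
                 confusion = conf,
                 accuracy = mean(pred == corpus$y[ho]),
                 corpus_descriptor = list(n = n,
                                          n_steps = dim(corpus$X)[2L]),
                 seed = seed),
            class = "diffusion_classifier")
}

#' Train an anomalous-exponent regression network
#'
#' Same two-layer LSTM architecture with a scalar head, trained on
#' fixed-length normalized tracks of one anomalous type with alpha drawn
#' uniformly over (0.1, 1.9) for FBM or (0.1, 1.0) for CTRW.
#'
#' @param type "FBM" or "CTRW" (the types whose exponent is identifiable
#'   from short segments)
#' @param n_tracks training-corpus size
#' @param n_steps steps per track
#' @param tau frame interval (s)
#' @param units,epochs,batch_size,lr,seed,verbose training controls
#' @return an `alpha_regressor`: `lstm_model` plus `type` and `alpha_range`
#' @export
train_alpha_regressor <- function(type = c("FBM", "CTRW"), n_tracks = 20000L,
                                  n_steps = 40L, tau = 0.02,
                                  units = c(100L, 50L), epochs = 12L,
                                  batch_size = 128L, lr = 1e-3, seed = 1L,
                                  verbose = FALSE) {
  type <- match.arg(type)
  if (!is.null(seed)) set.seed(seed)
  rng <- if (type == "FBM") c(0.1, 1.9) else c(0.1, 1.0)
  X <- array(0, dim = c(n_tracks, n_steps, 4L))
  alpha <- numeric(n_tracks)
  made <- 0L
  while (made < n_tracks) {
    a <- runif(1, rng[1], rng[2])
    p <- if (type == "FBM") simulate_fbm(n_steps, H = a / 2, D_H = 0.5, tau = tau)
         else simulate_ctrw(n_steps, sigma_exponent = a + 1,
                            step_variance = 2 * 0.5 * tau, tau = tau)
    nz <- normalize_segment(p)
    if (is.null(nz)) next
    made <- made + 1L
    X[made, , ] <- segment_features(nz)
    alpha[made] <- a
  }
  model <- lstm_train(X, alpha, units = units, task = "regression",
                      epochs = epochs, batch_size = batch_size, lr = lr,
                      seed = seed, verbose = verbose)
  structure(list(model = model, type = type, alpha_range = rng, seed = seed),
            class = "alpha_regressor")
}

#' Classify segments by diffusion type
#'
#' Segments longer than the network input length are split into
#' non-overlapping windows of that length (trailing remainder dropped) and
#' window probabilities are averaged; each window is normalized
#' independently. Segments shorter than the input length are rejected.
#'
#' @param classifier a `diffusion_classifier`
#' @param segments list of segments from [extract_segments]
#' @return data.frame with one row per usable segment: `track_id`, `state`,
#'   `length` and one probability column per type
#' @export
classify_segments <- function(classifier, segments) {
  stopifnot(inherits(classifier, "diffusion_classifier"))
  n_steps <- classifier$model$spec$input_steps
  rows <- list()
  for (sg in segments) {
    if (sg$length < n_steps) next
    Xw <- windows_of_segment(sg$coords, n_steps)
    if (is.null(Xw)) next
    pr <- lstm_predict(classifier$model, Xw)
    p <- colMeans(pr)   # equal-length windows: plain mean
    rows[[length(rows) + 1L]] <- data.frame(
      track_id = as.character(sg$track_id), state = sg$state,
      length = sg$length, t(p))
  }
  if (length(rows) == 0L)
    stop("no segment is at least ", n_steps, " steps long")
  out <- do.call(rbind, rows)
  names(out)[-(1:3)] <- classifier$types
  out
}

#' Length-weighted per-state diffusion-type probabilities
#'
#' The probability vector of a state is the average of its segments'
#' classification probabilities weighted by segment length.
#'
#' @param segment_probs data.frame from [classify_segments]
#' @param types type columns (default the four standard types)
#' @return data.frame with one row per state: `state`, `n_segments`,
#'   `total_steps` and the probability columns (each row sums to one)
#' @export
state_type_probability <- function(segment_probs, types = DIFFUSION_TYPES) {
  stopifnot(all(types %in% names(segment_probs)))
  states <- sort(unique(segment_probs$state))
  rows <- lapply(states, function(st) {
    d <- segment_probs[segment_probs$state == st, , drop = FALSE]
    w <- d$length / sum(d$length)
    p <- colSums(as.matrix(d[types]) * w)
    data.frame(state = st, n_segments = nrow(d), total_steps = sum(d$length),
               t(p / sum(p)))
  })
  out <- do.call(rbind, rows)
  names(out)[-(1:3)] <- types
  out
}

#' Estimate the anomalous exponent of segments and states
#'
#' Applies a regression network to every usable segment (windowed like
#' [classify_segments]), clips estimates to the type's valid range, and
#' reports per-state length-weighted means.
#'
#' @param regressor an `alpha_regressor`
#' @param segments list of segments from [extract_segments]
#' @return list with `per_segment` (data.frame: track_id, state, length,
#'   alpha) and `per_state` (data.frame: state, alpha)
#' @export
regress_alpha <- function(regressor, segments) {
  stopifnot(inherits(regressor, "alpha_regressor"))
  n_steps <- regressor$model$spec$input_steps
  rows <- list()
  for (sg in segments) {
    if (sg$length < n_steps) next
    Xw <- windows_of_segment(sg$coords, n_steps)
    if (is.null(Xw)) next
    a <- mean(lstm_predict(regressor$model, Xw))
    a <- min(max(a, regressor$alpha_range[1]), regressor$alpha_range[2])
    rows[[length(rows) + 1L]] <- data.frame(
      track_id = as.character(sg$track_id), state = sg$state,
      length = sg$length, alpha = a)
  }
  if (length(rows) == 0L)
    stop("no segment is at least ", n_steps, " steps long")
  per_segment <- do.call(rbind, rows)
  per_state <- do.call(rbind, lapply(split(per_segment, per_segment$state),
    function(d) data.frame(state = d$state[1L],
                           alpha = sum(d$alpha * d$length) / sum(d$length))))
  rownames(per_state) <- NULL
  list(per_segment = per_segment, per_state = per_state)
}
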