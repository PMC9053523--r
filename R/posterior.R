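#' Modal number of occupied states
#'
#' Mode over retained posterior samples of the number of states whose
#' assigned-step fraction is at least `min_weight`. The floor screens out
#' "state dust": transient captures of a handful of steps by freshly
#' prior-drawn empty states, an artefact of the weak-limit truncation that
#' would otherwise inflate the strict (>= 1 step) occupied count. The
#' default 0.5% sits well below real minority populations this method is
#' used to find (a few percent) and well above typical dust (~0.1%). Set
#' `min_weight = 0` for the strict count. Ties break toward the smaller
#' count (parsimony) and are flagged.
#'
#' @param chain an `hdphmm_chain` from [hdphmm_fit]
#' @param min_weight minimum fraction of steps for a state to count
#' @return integer mode, with attributes `trace` (per-sample counts) and
#'   `tie` (logical)
#' @export
estimate_num_states <- function(chain, min_weight = 0.005) {
  stopifnot(inherits(chain, "hdphmm_chain"), length(chain$samples) >= 1L)
  floor_steps <- min_weight * chain$n_steps_total
  ks <- vapply(chain$samples, function(s)
    sum(s$n_steps > 0L & s$n_steps >= floor_steps), integer(1))
  tab <- table(ks)
  winners <- as.integer(names(tab)[tab == max(tab)])
  out <- min(winners)
  attr(out, "trace") <- ks
  attr(out, "tie") <- length(winners) > 1L
  out
}

#' Match occupied states across iterations
#'
#' Relabels each retained sample's occupied states against a reference sample
#' (the first whose occupied count equals the modal count) by minimum total
#' `|log D|` distance assignment, where D is the per-state mean apparent
#' diffusion coefficient. States in samples whose occupied count differs from
#' the reference are matched greedily as far as possible and the surplus is
#' reported unmatched (reference label `NA`).
#'
#' @param chain an `hdphmm_chain`
#' @return list per retained sample: `occupied_states` (raw state indices)
#'   and `ref_label` (matched reference label, NA if unmatched)
#' @export
match_states_across_iterations <- function(chain) {
  stopifnot(inherits(chain, "hdphmm_chain"))
  tau <- chain$tau
  K_mode <- as.integer(estimate_num_states(chain))
  d_of <- function(s) {
    occ <- which(s$n_steps > 0L)
    Dbar <- vapply(occ, function(k)
      (s$Sigma[1, 1, k] + s$Sigma[2, 2, k]) / (4 * tau), numeric(1))
    list(occ = occ, Dbar = Dbar)
  }
  ks <- attr(estimate_num_states(chain), "trace")
  ref_idx <- match(K_mode, ks)
  ref <- d_of(chain$samples[[ref_idx]])
  # reference = the non-dust states of that sample, ordered by ascending D
  floor_steps <- 0.005 * chain$n_steps_total
  keep <- chain$samples[[ref_idx]]$n_steps[ref$occ] >= floor_steps
  ref_D <- sort(ref$Dbar[keep])
  lapply(chain$samples, function(s) {
    cur <- d_of(s)
    n1 <- length(cur$occ); n2 <- length(ref_D)
    n <- max(n1, n2)
    big <- 1e6
    cost <- matrix(big, n, n)
    for (i in seq_len(n1)) for (j in seq_len(n2))
      cost[i, j] <- abs(log(cur$Dbar[i]) - log(ref_D[j]))
    perm <- solve_assignment(cost)
    ref_label <- ifelse(perm[seq_len(n1)] <= n2, perm[seq_len(n1)], NA_integer_)
    list(occupied_states = cur$occ, ref_label = as.integer(ref_label))
  })
}

#' Summarise a posterior chain into state-level quantities
#'
#' For every retained sample, each occupied state is reported with its
#' per-axis apparent diffusion coefficient `D_axis = Sigma[axis, axis] /
#' (2 tau)` and its weight (fraction of steps assigned). States are matched
#' across iterations (see [match_states_across_iterations]) and pooled means
#' and standard deviations are computed per matched state, ordered by
#' ascending mean D.
#'
#' @param chain an `hdphmm_chain`
#' @param tau frame interval in seconds (default: the chain's own)
#' @return list with `per_iteration` (data.frame: iter, state, D_x, D_y,
#'   weight, mu_x, mu_y), `pooled` (data.frame of matched-state means/SDs)
#'   and `K` (modal occupied count)
#' @export
summarize_chain <- function(chain, tau = NULL) {
  stopifnot(inherits(chain, "hdphmm_chain"))
  if (length(chain$samples) == 0L) stop("chain has no retained samples")
  tau <- tau %||% chain$tau
  matching <- match_states_across_iterations(chain)
  Tt <- chain$n_steps_total
  rows <- vector("list", length(chain$samples))
  for (i in seq_along(chain$samples)) {
    s <- chain$samples[[i]]
    m <- matching[[i]]
    occ <- m$occupied_states
    rows[[i]] <- data.frame(
      iter = s$iter,
      state = m$ref_label,
      D_x = vapply(occ, function(k) s$Sigma[1, 1, k] / (2 * tau), numeric(1)),
      D_y = vapply(occ, function(k) s$Sigma[2, 2, k] / (2 * tau), numeric(1)),
      weight = s$n_steps[occ] / Tt,
      mu_x = s$mu[occ, 1L],
      mu_y = s$mu[occ, 2L])
  }
  per_iter <- do.call(rbind, rows)
  matched <- per_iter[!is.na(per_iter$state), , drop = FALSE]
  agg <- function(f) {
    out <- stats::aggregate(cbind(D_x, D_y, weight) ~ state, matched, f)
    out[order(out$state), , drop = FALSE]
  }
  mns <- agg(mean); sds <- agg(sd)
  pooled <- data.frame(
    state = mns$state,
    D_x = mns$D_x, D_y = mns$D_y, D = (mns$D_x + mns$D_y) / 2,
    D_x_sd = sds$D_x, D_y_sd = sds$D_y,
    weight = mns$weight, weight_sd = sds$weight)
  pooled <- pooled[order(pooled$D), , drop = FALSE]
  rownames(pooled) <- NULL
  list(per_iteration = per_iter, pooled = pooled,
       K = as.integer(estimate_num_states(chain)))
}

#' Per-step modal state labels
#'
#' Majority vote across retained posterior samples for every displacement;
#' the label alphabet is the raw sampler labels (consistent within a chain).
#'
#' @param chain an `hdphmm_chain`
#' @return integer vector over all displacement runs (concatenated in run
#'   order), with attribute `run_length`
#' @export
posterior_state_labels <- function(chain) {
  stopifnot(inherits(chain, "hdphmm_chain"))
  Z <- vapply(chain$samples, `[[`, integer(chain$n_steps_total), "z")
  if (is.null(dim(Z))) Z <- matrix(Z, ncol = length(chain$samples))
  lab <- apply(Z, 1L, function(v) {
    tab <- tabulate(v)
    which.max(tab)
  })
  attr(lab, "run_length") <- chain$runs$run_length
  lab
}

#' Normalized Hamming distance under optimal label matching
#'
#' Fraction of positions at which two equal-length label sequences disagree,
#' minimised over injective relabelings of one alphabet onto the other
#' (optimal assignment), so the distance is invariant to global label
#' permutations of either argument.
#'
#' @param z_true,z_est integer label vectors (or lists of per-track vectors,
#'   flattened in order) of equal total length
#' @return list with `nhd` in \[0, 1\] and `mapping` (est label -> matched true
#'   label, NA where unmatched)
#' @export
normalized_hamming <- function(z_true, z_est) {
  if (is.list(z_true)) z_true <- unlist(z_true)
  if (is.list(z_est)) z_est <- unlist(z_est)
  if (length(z_true) != length(z_est))
    stop("sequences must have equal total length")
  lt <- sort(unique(z_true)); le <- sort(unique(z_est))
  n <- max(length(lt), length(le))
  conf <- matrix(0, n, n)
  for (i in seq_along(le)) for (j in seq_along(lt))
    conf[i, j] <- sum(z_est == le[i] & z_true == lt[j])
  perm <- solve_assignment(-conf)
  matches <- sum(conf[cbind(seq_len(n), perm)])
  mapping <- stats::setNames(
    ifelse(perm[seq_along(le)] <= length(lt), lt[perm[seq_along(le)]], NA),
    le)
  list(nhd = 1 - matches / length(z_true), mapping = mapping)
}

#' State-assignment accuracy as a function of track length
#'
#' For each requested track length, simulates `floor(total_steps /
#' track_length)` tracks with the supplied simulator, fits the sticky
#' HDP-HMM, and reports the assignment accuracy `1 - NHD` of the per-step
#' modal posterior labels against the simulation ground truth.
#'
#' @param simulator function(n_tracks, track_length) returning a list with
#'   `tracks` (a [track_set]) and `truth` (with `state_sequence`)
#' @param track_lengths integer vector of lengths (steps); lengths < 2 are
#'   skipped
#' @param total_steps fixed step budget shared by every length (default
#'   30000)
#' @param config an [hdphmm_config] used for every fit
#' @return data.frame with `track_length`, `n_tracks`, `accuracy`
#' @export
accuracy_vs_track_length <- function(simulator, track_lengths,
                                     total_steps = 30000L,
                                     config = hdphmm_config()) {
  track_lengths <- as.integer(track_lengths)
  keep <- track_lengths >= 2L
  if (!all(keep)) warning("track lengths < 2 skipped")
  track_lengths <- track_lengths[keep]
  out <- data.frame(track_length = track_lengths,
                    n_tracks = NA_integer_, accuracy = NA_real_)
  for (i in seq_along(track_lengths)) {
    len <- track_lengths[i]
    n_tracks <- max(1L, total_steps %/% len)
    sim <- simulator(n_tracks, len)
    chain <- hdphmm_fit(sim$tracks, config)
    z_hat <- posterior_state_labels(chain)
    z_true <- unlist(sim$truth$state_sequence)
    out$n_tracks[i] <- n_tracks
    out$accuracy[i] <- 1 - normalized_hamming(z_true, z_hat)$nhd
  }
  out
}

#' Posterior-sample autocorrelation diagnostic
#'
#' Standard ACF of a scalar posterior trace, an effective-sample-size
#' estimate `n / (1 + 2 sum(acf))` over the initial positive ACF sequence,
#' and the suggested thinning interval (first lag with |ACF| < 0.1).
#'
#' @param series numeric posterior trace (e.g. a state's D per iteration),
#'   length >= 50
#' @param max_lag largest lag to evaluate (default `min(100, n/2)`)
#' @return list with `acf` (named vector, lags 1..max_lag), `ess`,
#'   `suggested_thin`, and `flag` (NULL, "too_few_samples" or
#'   "zero_variance")
#' @export
autocorrelation_diagnostic <- function(series, max_lag = NULL) {
  n <- length(series)
  if (n < 50L)
    return(list(acf = NULL, ess = NA_real_, suggested_thin = NA_integer_,
                flag = "too_few_samples"))
  if (stats::sd(series) == 0)
    return(list(acf = NULL, ess = NA_real_, suggested_thin = NA_integer_,
                flag = "zero_variance"))
  max_lag <- max_lag %||% min(100L, n %/% 2L)
  a <- stats::acf(series, lag.max = max_lag, plot = FALSE)$acf[-1L]
  names(a) <- seq_along(a)
  below <- which(abs(a) < 0.1)
  thin <- if (length(below)) below[1L] else max_lag + 1L
  pos <- a[seq_len(max(which(a > 0), 1L))]
  ess <- n / (1 + 2 * sum(pos[pos > 0]))
  list(acf = a, ess = ess, suggested_thin = as.integer(thin), flag = NULL)
}
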