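RESULTS_SCHEMA_VERSION <- "1.0"

#' Read trajectories from CSV
#'
#' Expects a header `track_id,frame,x_um,y_um`, one row per localization,
#' 0-based frames, coordinates in micrometres. The frame interval comes from
#' (in order of precedence) the `tau` argument, or a JSON sidecar
#' `<path>.json` with a `frame_interval_s` field. A `pixel_size_um` argument
#' converts pixel-unit coordinates to micrometres at import.
#'
#' @param path CSV file path
#' @param tau frame interval in seconds (overrides the sidecar)
#' @param pixel_size_um optional pixel size; when given, x/y are multiplied
#'   by it (e.g. 0.0485 for a 48.5 nm camera pixel)
#' @return a [track_set]
#' @export
read_tracks <- function(path, tau = NULL, pixel_size_um = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("track_id", "frame", "x_um", "y_um")
  miss <- setdiff(required, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  for (col in c("frame", "x_um", "y_um"))
    if (!is.numeric(df[[col]])) stop("column ", col, " is not numeric")
  meta <- list()
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  tau <- tau %||% meta$frame_interval_s
  if (is.null(tau)) stop("frame interval unknown: pass tau= or provide a ",
                         "JSON sidecar with frame_interval_s")
  if (!is.null(pixel_size_um)) {
    df$x_um <- df$x_um * pixel_size_um
    df$y_um <- df$y_um * pixel_size_um
  }
  track_set(df, tau, metadata = meta)
}

#' Write trajectories to CSV (+ JSON sidecar)
#'
#' @param tracks a [track_set]
#' @param path output CSV path; the sidecar goes to `<path>.json`
#' @param ground_truth optional list stored in the sidecar
#' @return `path`, invisibly
#' @export
write_tracks <- function(tracks, path, ground_truth = NULL) {
  stopifnot(inherits(tracks, "track_set"))
  utils::write.csv(tracks$positions, path, row.names = FALSE)
  sidecar <- c(list(frame_interval_s = tracks$tau),
               tracks$metadata[setdiff(names(tracks$metadata), "frame_interval_s")])
  if (!is.null(ground_truth))
    sidecar$ground_truth <- ground_truth_serializable(ground_truth)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = 9, null = "null")
  invisible(path)
}

#' Ground-truth labels from a parsed JSON sidecar
#'
#' `jsonlite` simplifies equal-length per-track label vectors into a matrix
#' (tracks x steps); this restores the per-track list form regardless.
#'
#' @param ground_truth the `ground_truth` element of a parsed sidecar
#' @return list of integer label vectors, one per track
#' @export
sidecar_state_sequence <- function(ground_truth) {
  ss <- ground_truth$state_sequence
  if (is.matrix(ss)) ss <- lapply(seq_len(nrow(ss)), function(i) ss[i, ])
  lapply(ss, as.integer)
}

ground_truth_serializable <- function(truth) {
  list(state_sequence = truth$state_sequence,
       D = unname(as.matrix(truth$D)),
       transition_matrix = unname(as.matrix(truth$transition_matrix)),
       diffusion_types = truth$diffusion_types,
       anomalous_exponents = truth$anomalous_exponents)
}

#' Persist an analysis result bundle as JSON
#'
#' Floats are serialized with 9 significant digits and the schema version is
#' recorded; [read_results] round-trips the file.
#'
#' @param bundle named list (see [run_pipeline] for the canonical fields)
#' @param path output JSON path
#' @return `path`, invisibly
#' @export
write_results <- function(bundle, path) {
  bundle$schema_version <- RESULTS_SCHEMA_VERSION
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = 9,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Run the full analysis pipeline
#'
#' Fit the sticky HDP-HMM, summarise the posterior, extract same-state
#' segments and (optionally) classify their diffusion type and regress the
#' anomalous exponent. Deterministic for a fixed config and seed.
#'
#' @param tracks a [track_set]
#' @param config an [hdphmm_config]
#' @param classifier optional `diffusion_classifier`
#' @param regressors optional named list of `alpha_regressor`s (names "FBM",
#'   "CTRW"); used for states whose top predicted type has a regressor
#' @param min_segment_length minimum same-state segment length in steps
#' @return a result bundle: list with `summary` (pooled state summary),
#'   `n_states`, `transition_matrix` (posterior mean over retained samples),
#'   `state_labels` (per-step modal labels), `type_probabilities` and
#'   `alpha_estimates` (when a classifier/regressor is supplied), and
#'   `provenance`
#' @export
run_pipeline <- function(tracks, config = hdphmm_config(), classifier = NULL,
                         regressors = NULL, min_segment_length = 40L) {
  stopifnot(inherits(tracks, "track_set"))
  chain <- hdphmm_fit(tracks, config)
  summ <- summarize_chain(chain)
  labels <- posterior_state_labels(chain)
  P_mean <- Reduce(`+`, lapply(chain$samples, `[[`, "pi")) /
    length(chain$samples)
  bundle <- list(
    n_states = summ$K,
    summary = summ$pooled,
    transition_matrix = unname(P_mean),
    state_labels = as.integer(labels),
    run_lengths = chain$runs$run_length,
    track_ids = chain$runs$track_id,
    provenance = list(
      seed = config$seed,
      tau = tracks$tau,
      n_tracks = length(tracks),
      n_steps = chain$n_steps_total,
      config = config[c("gamma", "alpha", "sticky_kappa", "L", "niw_kappa",
                        "niw_dof", "n_iterations", "burn_in", "thin")],
      package_version = as.character(utils::packageVersion("sptstates"))))
  if (!is.null(classifier)) {
    segs <- extract_segments(tracks, labels_to_runs(labels), min_segment_length)
    if (length(segs) > 0L) {
      seg_probs <- classify_segments(classifier, segs)
      bundle$type_probabilities <- state_type_probability(seg_probs,
                                                          classifier$types)
      if (!is.null(regressors)) {
        top <- classifier$types[max.col(as.matrix(
          bundle$type_probabilities[classifier$types]))]
        alphas <- lapply(seq_along(top), function(i) {
          ty <- top[i]
          if (is.null(regressors[[ty]])) return(NULL)
          st <- bundle$type_probabilities$state[i]
          ra <- regress_alpha(regressors[[ty]],
                              Filter(function(s) s$state == st, segs))
          data.frame(state = st, type = ty, alpha = ra$per_state$alpha)
        })
        alphas <- do.call(rbind, Filter(Negate(is.null), alphas))
        bundle$alpha_estimates <- alphas
      }
    }
  }
  attr(bundle, "chain") <- chain
  bundle
}

labels_to_runs <- function(labels) {
  rl <- attr(labels, "run_length")
  split(as.integer(labels), rep(seq_along(rl), rl))
}
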