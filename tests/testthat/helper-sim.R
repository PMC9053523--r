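# shared builders for small test fixtures (all generated in code)

two_state_bm <- function(n_tracks = 100, track_length = 50,
                         D = c(0.135, 1.8), p_stay = 0.95, seed = 1) {
  simulate_bm_tracks(n_tracks, track_length, D,
                     sticky_transition_matrix(length(D), p_stay),
                     tau = 0.02, seed = seed)
}

quick_config <- function(n_iterations = 400L, burn_in = 200L, thin = 10L,
                         seed = 1L, ...) {
  hdphmm_config(n_iterations = n_iterations, burn_in = burn_in, thin = thin,
                seed = seed, ...)
}

tiny_track_df <- function() {
  data.frame(track_id = c(1, 1, 1, 2, 2),
             frame = c(0, 1, 2, 0, 1),
             x_um = c(0, 1, 1, 0, 0.5),
             y_um = c(0, 0, 2, 0, -0.5))
}

# sticky mass used for motion-blur fits (increased relative to the 0.1x
# default because exposure averaging correlates consecutive displacements)
BLUR_STICKY_FACTOR <- 0.5
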