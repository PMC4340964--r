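# Small in-code fixtures shared across test files.

# A bold_run whose flattened voxel x TR matrix is `mat`, on a 1 x 1 x V grid.
run_from_matrix <- function(mat, tr = 2, voxel_mm = 2, session_id = 1L) {
  bold_run(
    array(mat, c(1, 1, nrow(mat), ncol(mat))),
    tr_seconds = tr, voxel_mm = voxel_mm, session_id = session_id
  )
}

# Reduced simulation world for fast cohort tests: same design, smaller grid.
tiny_synth <- function(identity_effect = 0.5, noise_sd = 1, n_sessions = 5,
                       ...) {
  synth_params(
    grid_shape = c(10, 10, 10),
    regions = list(
      region_spec("face_region", as.matrix(expand.grid(3:5, 3:5, 4:6)),
        face_amplitude = 2, cup_amplitude = 0.5,
        identity_effect = identity_effect
      ),
      region_spec("cup_region", as.matrix(expand.grid(7:9, 7:9, 4:6)),
        face_amplitude = 0.5, cup_amplitude = 2
      )
    ),
    noise_sd = noise_sd, n_sessions = n_sessions, ...
  )
}

# Hand-built schedule: explicit rows, bypassing the generator.
manual_schedule <- function(conditions, durations, session_id = 1L,
                            params = design_params()) {
  onsets <- cumsum(c(0L, durations[-length(durations)])) + 1L
  df <- data.frame(
    condition = conditions, onset_tr = as.integer(onsets),
    duration_trs = as.integer(durations), stringsAsFactors = FALSE
  )
  facemvpa:::new_block_schedule(df, session_id, params)
}
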