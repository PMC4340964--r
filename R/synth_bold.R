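#' Hemodynamic response parameters (canonical double-gamma)
#'
#' The canonical shape: a gamma density peaking near 6 s minus a scaled gamma
#' undershoot near 16 s. The functional form is the field's default since the
#' analysis chain only requires a plausible, fixed impulse response.
#'
#' @param peak_delay,undershoot_delay gamma shape-equivalent delays, seconds.
#' @param peak_disp,undershoot_disp dispersions, seconds.
#' @param undershoot_ratio relative undershoot amplitude (1/6 canonical).
#' @param length_seconds kernel support.
#' @export
hrf_params <- function(peak_delay = 6, undershoot_delay = 16, peak_disp = 1,
                       undershoot_disp = 1, undershoot_ratio = 1 / 6,
                       length_seconds = 32) {
  structure(
    list(
      peak_delay = peak_delay, undershoot_delay = undershoot_delay,
      peak_disp = peak_disp, undershoot_disp = undershoot_disp,
      undershoot_ratio = undershoot_ratio, length_seconds = length_seconds
    ),
    class = "hrf_params"
  )
}

hrf_eval <- function(t, p) {
  a1 <- p$peak_delay / p$peak_disp
  a2 <- p$undershoot_delay / p$undershoot_disp
  stats::dgamma(t, shape = a1, scale = p$peak_disp) -
    p$undershoot_ratio * stats::dgamma(t, shape = a2, scale = p$undershoot_disp)
}

#' Sample the HRF kernel at TR resolution
#'
#' @param params an [hrf_params()] object.
#' @param tr_seconds sampling interval (> 0).
#' @return numeric kernel sampled at `0, TR, 2 TR, ...`, normalized to unit
#'   peak; the value at t = 0 is 0.
#' @export
hrf_kernel <- function(params = hrf_params(), tr_seconds = 2) {
  if (!is.numeric(tr_seconds) || tr_seconds <= 0) {
    stop_config("tr_seconds must be positive")
  }
  t <- seq(0, params$length_seconds, by = tr_seconds)
  k <- hrf_eval(t, params)
  k / max(k)
}

#' Region specification for the simulator
#'
#' A named set of voxels with mean responses per superordinate category and
#' optional within-category pattern effects. The identity effect is realized
#' as a per-voxel preference map drawn once per subject: each voxel gets a
#' Rademacher sign s, and identity 1 responds at `faces + s d/2`, identity 2
#' at `faces - s d/2` (`d = identity_effect`) — the simplest spatial code a
#' linear classifier can exploit. `cup_effect` is analogous for cup types.
#'
#' @param name region label.
#' @param voxel_coords n x 3 integer matrix of 1-based grid coordinates.
#' @param face_amplitude,cup_amplitude mean response (signal units) to faces
#'   and cups.
#' @param identity_effect,cup_effect within-category pattern separation d
#'   (signal units, >= 0).
#' @export
region_spec <- function(name, voxel_coords, face_amplitude, cup_amplitude,
                        identity_effect = 0, cup_effect = 0) {
  voxel_coords <- as.matrix(voxel_coords)
  storage.mode(voxel_coords) <- "integer"
  if (ncol(voxel_coords) != 3) stop_config("voxel_coords must be n x 3")
  if (identity_effect < 0 || cup_effect < 0) {
    stop_config("pattern effects must be >= 0")
  }
  structure(
    list(
      name = name, voxel_coords = voxel_coords,
      face_amplitude = face_amplitude, cup_amplitude = cup_amplitude,
      identity_effect = identity_effect, cup_effect = cup_effect
    ),
    class = "region_spec"
  )
}

#' Simulation parameters
#'
#' Defaults describe a small synthetic brain: a 12x12x12 grid of 2 mm
#' isotropic voxels holding a 48-voxel face-selective region (faces respond
#' at 2, cups at 0.5 signal units over a baseline of 100) carrying an
#' identity pattern of scale `identity_effect`, and a mirror-image
#' cup-selective region. Noise is i.i.d. Gaussian per voxel-TR (optionally
#' AR(1)); each session gets a random linear drift and a global offset.
#'
#' @param grid_shape voxel counts per axis.
#' @param voxel_mm isotropic voxel size, mm.
#' @param regions list of [region_spec()]; defaults built for `grid_shape`.
#' @param identity_effect,cup_effect pattern scales injected into the default
#'   regions (ignored when `regions` is supplied).
#' @param baseline mean signal level (keeps percent signal change defined).
#' @param noise_sd thermal noise standard deviation, signal units.
#' @param drift_amplitude sd of the per-session linear drift's total rise.
#' @param session_offset_sd sd of the per-session global offset.
#' @param ar_rho AR(1) noise coefficient (0 = white noise).
#' @param hrf an [hrf_params()] object.
#' @param n_sessions sessions per subject (5 or 6 in the emulated design).
#' @export
synth_params <- function(grid_shape = c(12, 12, 12), voxel_mm = 2,
                         regions = NULL, identity_effect = 0.5,
                         cup_effect = 0.25, baseline = 100, noise_sd = 1,
                         drift_amplitude = 0.5, session_offset_sd = 0.3,
                         ar_rho = 0, hrf = hrf_params(), n_sessions = 5) {
  if (noise_sd < 0) stop_config("noise_sd must be >= 0")
  if (is.null(regions)) {
    regions <- default_regions(grid_shape, identity_effect, cup_effect)
  }
  for (r in regions) {
    if (any(r$voxel_coords < 1) ||
      any(sweep(r$voxel_coords, 2, grid_shape, ">"))) {
      stop_config("region '", r$name, "' has voxels outside the grid")
    }
  }
  structure(
    list(
      grid_shape = as.integer(grid_shape), voxel_mm = voxel_mm,
      regions = regions, baseline = baseline, noise_sd = noise_sd,
      drift_amplitude = drift_amplitude,
      session_offset_sd = session_offset_sd, ar_rho = ar_rho, hrf = hrf,
      n_sessions = as.integer(n_sessions)
    ),
    class = "synth_params"
  )
}

cuboid_coords <- function(xr, yr, zr) {
  as.matrix(expand.grid(x = xr, y = yr, z = zr))
}

default_regions <- function(grid_shape, identity_effect, cup_effect) {
  if (any(grid_shape < 10)) stop_config("default regions need a grid >= 10 per axis")
  list(
    region_spec("face_region", cuboid_coords(3:6, 3:6, 4:6),
      face_amplitude = 2, cup_amplitude = 0.5,
      identity_effect = identity_effect
    ),
    region_spec("cup_region", cuboid_coords(7:10, 7:10, 4:6),
      face_amplitude = 0.5, cup_amplitude = 2,
      cup_effect = cup_effect
    )
  )
}

#' One session of simulated BOLD data
#'
#' Container for a 4-D voxel grid: `data` is an `x, y, z, t` array, with TR
#' and voxel size metadata.
#' @param data 4-D numeric array.
#' @param tr_seconds repetition time.
#' @param voxel_mm isotropic voxel size.
#' @param session_id integer session label.
#' @export
bold_run <- function(data, tr_seconds, voxel_mm, session_id = 1L) {
  stopifnot(length(dim(data)) == 4)
  structure(
    list(
      data = data, tr_seconds = tr_seconds, voxel_mm = voxel_mm,
      session_id = as.integer(session_id)
    ),
    class = "bold_run"
  )
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<bold_run> session %d: %dx%dx%d voxels (%g mm), %d TRs (TR %g s)\n",
    x$session_id, d[1], d[2], d[3], x$voxel_mm, d[4], x$tr_seconds
  ))
  invisible(x)
}

n_trs.bold_run <- function(run) dim(run$data)[4]

# Per-condition amplitude map over the flattened grid, given the per-subject
# preference signs for each region.
condition_amplitudes <- function(params, pref_signs) {
  nvox <- prod(params$grid_shape)
  amp <- matrix(0, nrow = nvox, ncol = length(TASK_CONDITIONS),
    dimnames = list(NULL, TASK_CONDITIONS)
  )
  for (i in seq_along(params$regions)) {
    r <- params$regions[[i]]
    idx <- coords_to_index(r$voxel_coords, params$grid_shape)
    s <- pref_signs[[i]]
    amp[idx, "identity1"] <- amp[idx, "identity1"] +
      r$face_amplitude + s$identity * r$identity_effect / 2
    amp[idx, "identity2"] <- amp[idx, "identity2"] +
      r$face_amplitude - s$identity * r$identity_effect / 2
    amp[idx, "cup1"] <- amp[idx, "cup1"] +
      r$cup_amplitude + s$cup * r$cup_effect / 2
    amp[idx, "cup2"] <- amp[idx, "cup2"] +
      r$cup_amplitude - s$cup * r$cup_effect / 2
  }
  amp
}

coords_to_index <- function(coords, grid_shape) {
  coords <- as.matrix(coords)
  (coords[, 3] - 1L) * grid_shape[1] * grid_shape[2] +
    (coords[, 2] - 1L) * grid_shape[1] + coords[, 1]
}

index_to_coords <- function(idx, grid_shape) {
  idx0 <- idx - 1L
  cbind(
    x = idx0 %% grid_shape[1] + 1L,
    y = (idx0 %/% grid_shape[1]) %% grid_shape[2] + 1L,
    z = idx0 %/% (grid_shape[1] * grid_shape[2]) + 1L
  )
}

# Boxcar (0/1 per TR) for one condition of a schedule.
condition_boxcar <- function(schedule, condition, n_trs) {
  box <- numeric(n_trs)
  rows <- which(schedule$condition == condition)
  for (i in rows) {
    on <- schedule$onset_tr[i]
    box[on:(on + schedule$duration_trs[i] - 1L)] <- 1
  }
  box
}

# Boxcar convolved with the HRF kernel, truncated to the session length.
convolved_regressor <- function(schedule, condition, kernel, n_trs) {
  box <- condition_boxcar(schedule, condition, n_trs)
  stats::convolve(box, rev(kernel), type = "open")[seq_len(n_trs)]
}

#' Simulate one subject's multi-session BOLD data
#'
#' Each session is the sum of (i) per-condition HRF-convolved boxcars scaled
#' by each voxel's condition amplitude, (ii) the baseline, (iii) a linear
#' drift, (iv) a session-wide offset, and (v) Gaussian noise. The
#' identity-preference map is drawn once per subject so the multivoxel code
#' is stable across sessions — the property leave-one-session-out decoding
#' must exploit.
#'
#' @param params a [synth_params()] object.
#' @param schedules list of `block_schedule`, one per session; defaults to
#'   seeded schedules derived from `seed`.
#' @param seed integer; everything (schedules included, when defaulted) is
#'   deterministic given the seed.
#' @param design a [design_params()] object used when `schedules` is NULL.
#' @return list with `runs` (list of [bold_run()]), `schedules`,
#'   `ground_truth` (list of [roi_mask()] per region), `params` and `seed`.
#' @export
simulate_subject <- function(params = synth_params(), schedules = NULL,
                             seed = 1, design = design_params()) {
  if (is.null(schedules)) {
    schedules <- lapply(seq_len(params$n_sessions), function(s) {
      generate_session_schedule(design, seed = seed * 1000L + s, session_id = s)
    })
  }
  if (length(schedules) != params$n_sessions) {
    stop_config(
      "got ", length(schedules), " schedules for ",
      params$n_sessions, " sessions"
    )
  }
  kernel <- hrf_kernel(params$hrf, attr(schedules[[1]], "params")$tr_seconds)
  nvox <- prod(params$grid_shape)
  runs <- vector("list", params$n_sessions)
  with_seed(seed, {
    pref_signs <- lapply(params$regions, function(r) {
      n <- nrow(r$voxel_coords)
      list(
        identity = sample(c(-1, 1), n, replace = TRUE),
        cup = sample(c(-1, 1), n, replace = TRUE)
      )
    })
    amp <- condition_amplitudes(params, pref_signs)
    for (s in seq_len(params$n_sessions)) {
      sched <- schedules[[s]]
      n_trs <- attr(sched, "n_trs")
      reg <- vapply(
        TASK_CONDITIONS,
        function(cond) convolved_regressor(sched, cond, kernel, n_trs),
        numeric(n_trs)
      )
      signal <- amp %*% t(reg) # voxels x TRs
      drift_rise <- rnorm(1, 0, params$drift_amplitude)
      drift <- drift_rise * seq(-0.5, 0.5, length.out = n_trs)
      offset <- rnorm(1, 0, params$session_offset_sd)
      noise <- matrix(rnorm(nvox * n_trs, 0, params$noise_sd), nvox, n_trs)
      if (params$ar_rho != 0) {
        for (t in 2:n_trs) {
          noise[, t] <- params$ar_rho * noise[, t - 1] +
            sqrt(1 - params$ar_rho^2) * noise[, t]
        }
      }
      vol <- signal + noise + params$baseline + offset +
        matrix(drift, nvox, n_trs, byrow = TRUE)
      runs[[s]] <- bold_run(
        array(vol, c(params$grid_shape, n_trs)),
        tr_seconds = attr(sched, "params")$tr_seconds,
        voxel_mm = params$voxel_mm,
        session_id = attr(sched, "session_id")
      )
    }
  })
  ground_truth <- lapply(params$regions, function(r) {
    roi_mask(r$name, r$voxel_coords,
      statistic = rep(NA_real_, nrow(r$voxel_coords)),
      voxel_mm = params$voxel_mm, grid_shape = params$grid_shape
    )
  })
  names(ground_truth) <- vapply(params$regions, `[[`, "", "name")
  list(
    runs = runs, schedules = schedules, ground_truth = ground_truth,
    params = params, seed = seed
  )
}
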