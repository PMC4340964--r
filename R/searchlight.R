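#' Search-light configuration
#'
#' A cubic box (default 3x3x3 voxels = 27 voxels = 216 mm^3 at 2 mm) moved
#' over an analysis mask. With `step = 1` the boxes overlap and every voxel's
#' final value is the average of the accuracies of all boxes that contained
#' it; with `step = 3` the boxes tile the mask and each voxel is classified
#' exactly once (the control scheme).
#'
#' @param box_edge box edge length, voxels (odd).
#' @param step center-to-center step, voxels.
#' @param min_voxels_per_box boxes clipped by the mask boundary are kept
#'   only if at least this many voxels remain.
#' @export
searchlight_config <- function(box_edge = 3, step = 1, min_voxels_per_box = 10) {
  if (box_edge %% 2 != 1) stop_config("box_edge must be odd")
  if (step < 1) stop_config("step must be >= 1")
  structure(
    list(
      box_edge = as.integer(box_edge), step = as.integer(step),
      min_voxels_per_box = as.integer(min_voxels_per_box)
    ),
    class = "searchlight_config"
  )
}

box_members <- function(center, half, mask_arr, grid_shape) {
  xr <- max(1, center[1] - half):min(grid_shape[1], center[1] + half)
  yr <- max(1, center[2] - half):min(grid_shape[2], center[2] + half)
  zr <- max(1, center[3] - half):min(grid_shape[3], center[3] + half)
  cc <- cuboid_coords(xr, yr, zr)
  idx <- coords_to_index(cc, grid_shape)
  idx[mask_arr[idx]]
}

#' Overlapping-box search-light decoding for one subject
#'
#' Runs the full leave-one-session-out decoding chain inside every box:
#' sessions are preprocessed once over the mask, block patterns extracted
#' once, and per box the patterns are restricted to the box's voxels, the
#' per-condition global-signal subtraction re-applied for that voxel set,
#' and the SVM cross-validated. Box accuracies are accumulated with running
#' sums per member voxel (the result is independent of box visiting order);
#' the per-voxel map is the mean of all accuracies the voxel received.
#'
#' @param runs decoding sessions, list of [bold_run()].
#' @param schedules matching schedules.
#' @param mask an [roi_mask()] giving the analysis volume; centers are
#'   placed on mask voxels at the configured step.
#' @param cfg a [searchlight_config()].
#' @param decode_cfg a [decode_config()].
#' @return `accuracy_map`: arrays `accuracy` (NA outside the covered mask)
#'   and `n_boxes` (how many boxes contained each voxel).
#' @export
run_searchlight <- function(runs, schedules, mask,
                            cfg = searchlight_config(),
                            decode_cfg = decode_config()) {
  if (is.null(mask) || nrow(mask$coords) == 0) stop_config("empty analysis mask")
  grid_shape <- dim(runs[[1]]$data)[1:3]
  mask_arr <- array(FALSE, grid_shape)
  mask_arr[mask$coords] <- TRUE
  # patterns over the whole mask, cocktail subtraction deferred to the box
  sets <- mapply(function(run, sched) {
    pre <- preprocess_session(run, decode_cfg, mask)
    extract_block_patterns(pre, sched,
      classes = decode_cfg$class_pair,
      cfg = decode_cfg, subtract_condition_mean = FALSE
    )
  }, runs, schedules, SIMPLIFY = FALSE)
  voxel_index <- sets[[1]]$voxel_index
  col_of <- integer(prod(grid_shape))
  col_of[voxel_index] <- seq_along(voxel_index)

  half <- (cfg$box_edge - 1L) %/% 2L
  if (cfg$step == 1) {
    centers <- mask$coords
  } else {
    # tile from the mask's bounding-box corner so step = box_edge gives a
    # non-overlapping cover of the mask
    lo <- apply(mask$coords, 2, min)
    keep <- rep(TRUE, nrow(mask$coords))
    for (a in 1:3) {
      keep <- keep & (mask$coords[, a] - lo[a] - half) %% cfg$step == 0
    }
    centers <- mask$coords[keep, , drop = FALSE]
  }
  acc_sum <- numeric(prod(grid_shape))
  n_boxes <- integer(prod(grid_shape))
  for (b in seq_len(nrow(centers))) {
    members <- box_members(centers[b, ], half, mask_arr, grid_shape)
    if (length(members) < cfg$min_voxels_per_box) next
    cols <- col_of[members]
    box_sets <- lapply(sets, function(s) {
      pats <- s$patterns[, cols, drop = FALSE]
      for (cond in unique(s$labels)) {
        sel <- s$labels == cond
        pats[sel, ] <- pats[sel, , drop = FALSE] - mean(pats[sel, ])
      }
      list(patterns = pats, labels = s$labels, session_id = s$session_id)
    })
    acc <- loso_decode(box_sets, decode_cfg)$accuracy
    acc_sum[members] <- acc_sum[members] + acc
    n_boxes[members] <- n_boxes[members] + 1L
  }
  accuracy <- array(NA_real_, grid_shape)
  covered <- n_boxes > 0
  accuracy[covered] <- acc_sum[covered] / n_boxes[covered]
  structure(
    list(
      accuracy = accuracy, n_boxes = array(n_boxes, grid_shape),
      config = cfg
    ),
    class = "accuracy_map"
  )
}

#' Group-level search-light inference
#'
#' Per voxel with coverage in at least two subjects: one-sample one-tailed
#' t of the subjects' accuracies against chance (0.5), then
#' Benjamini-Hochberg across voxels at level `q`.
#'
#' @param maps list of per-subject `accuracy_map`.
#' @param q FDR level.
#' @param chance chance accuracy (0.5 for a pair).
#' @return list: arrays `t` and `p` (NA where undefined), logical array
#'   `significant`, the BH `threshold`, and `n_excluded` voxels dropped for
#'   insufficient subject coverage.
#' @export
group_searchlight_stats <- function(maps, q = 0.05, chance = 0.5) {
  if (length(maps) < 2) stop_config("need >= 2 subjects")
  grid_shape <- dim(maps[[1]]$accuracy)
  stack <- vapply(maps, function(m) as.numeric(m$accuracy),
    numeric(prod(grid_shape)))
  n_sub <- rowSums(!is.na(stack))
  eligible <- which(n_sub >= 2)
  n_excluded <- sum(n_sub > 0 & n_sub < 2)
  tv <- pv <- rep(NA_real_, prod(grid_shape))
  for (i in eligible) {
    res <- one_sample_t(stack[i, !is.na(stack[i, ])], chance, tail = "one")
    tv[i] <- res$statistic
    pv[i] <- res$p
  }
  bh <- bh_fdr(pv[eligible], q)
  sig <- rep(FALSE, prod(grid_shape))
  sig[eligible] <- bh$significant
  list(
    t = array(tv, grid_shape), p = array(pv, grid_shape),
    significant = array(sig, grid_shape), threshold = bh$threshold,
    n_excluded = n_excluded
  )
}
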