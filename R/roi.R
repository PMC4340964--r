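#' Region-of-interest mask
#'
#' A named set of grid voxels with per-voxel selectivity statistics. Volume
#' is `n voxels x voxel_mm^3`; with 2 mm isotropic voxels a 20-voxel ROI is
#' 160 mm^3 and a 3x3x3 search-light box 216 mm^3.
#'
#' @param name label.
#' @param coords n x 3 integer matrix of 1-based grid coordinates.
#' @param statistic per-voxel statistic (same order as `coords`).
#' @param voxel_mm isotropic voxel size, mm.
#' @param grid_shape dimensions of the parent grid.
#' @param peak coordinate of the seed peak (1 x 3), if any.
#' @param undersized TRUE when greedy growth exhausted candidates early.
#' @export
roi_mask <- function(name, coords, statistic = NULL, voxel_mm = 2,
                     grid_shape = NULL, peak = NULL, undersized = FALSE) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "integer"
  if (nrow(coords) && anyDuplicated(split(coords, row(coords)))) {
    stop_config("ROI coordinates must be unique")
  }
  structure(
    list(
      name = name, coords = coords,
      statistic = statistic %||% rep(NA_real_, nrow(coords)),
      voxel_mm = voxel_mm, grid_shape = grid_shape, peak = peak,
      undersized = undersized
    ),
    class = "roi_mask"
  )
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf(
    "<roi_mask> '%s': %d voxels (%g mm^3)%s\n",
    x$name, nrow(x$coords), roi_volume_mm3(x),
    if (x$undersized) " [under-sized]" else ""
  ))
  invisible(x)
}

#' @rdname roi_mask
#' @param roi an `roi_mask`.
#' @export
roi_volume_mm3 <- function(roi) nrow(roi$coords) * roi$voxel_mm^3

#' ROI construction configuration
#'
#' @param threshold_p uncorrected significance level applied to the map's z
#'   values (0.001 for the well-localized regions, 0.01 for weak-signal ones
#'   in the emulated protocol).
#' @param target_sizes voxel counts for the size-equalized analysis.
#' @param connectivity 6 (faces), 18 (faces+edges) or 26 (faces+edges+
#'   corners) neighborhood.
#' @param direction `"positive"` selects map > threshold (faces > cups);
#'   `"negative"` flips the map's sign first (cups > faces).
#' @export
roi_config <- function(threshold_p = 0.001,
                       target_sizes = c(10, 20, 30, 40, 50),
                       connectivity = 26,
                       direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  if (threshold_p <= 0 || threshold_p >= 1) {
    stop_config("threshold_p must lie in (0, 1)")
  }
  if (!connectivity %in% c(6, 18, 26)) {
    stop_config("connectivity must be 6, 18 or 26")
  }
  structure(
    list(
      threshold_p = threshold_p, target_sizes = target_sizes,
      connectivity = connectivity, direction = direction
    ),
    class = "roi_config"
  )
}

neighbor_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
    "6" = d == 1, "18" = d >= 1 & d <= 2, "26" = d >= 1
  )
  g[keep, , drop = FALSE]
}

# Signed statistic array and suprathreshold predicate for a config.
directed_stat <- function(map, cfg) {
  s <- if (cfg$direction == "negative") -map$z else map$z
  list(stat = s, thr = qnorm(1 - cfg$threshold_p))
}

# Lexicographic (x, y, z) order for deterministic tie-breaks.
lex_order <- function(coords) {
  order(coords[, 1], coords[, 2], coords[, 3])
}

find_peak <- function(stat_arr, supra_idx, grid_shape) {
  vals <- stat_arr[supra_idx]
  best <- supra_idx[vals == max(vals)]
  if (length(best) > 1) {
    cc <- index_to_coords(best, grid_shape)
    best <- best[lex_order(cc)[1]]
  }
  best
}

#' Fixed-size contiguous ROI by greedy peak growth
#'
#' Greedy growth from the suprathreshold peak: starting at the global
#' maximum of the thresholded map, repeatedly admit the suprathreshold
#' neighbor (under the configured connectivity) with the highest statistic
#' until `target_size` voxels are reached or the frontier empties (the mask
#' is then returned smaller and flagged `undersized`). Ties and the peak are
#' broken by lexicographic coordinate order, so the result is deterministic.
#'
#' @param map a `stat_map` (t/z over a grid).
#' @param cfg an [roi_config()].
#' @param target_size desired voxel count (e.g. 20 voxels = 160 mm^3 at 2 mm).
#' @param name mask label.
#' @return an [roi_mask()], or NULL when no voxel passes the threshold
#'   (the region is "not localizable" for this subject).
#' @export
localize_roi <- function(map, cfg = roi_config(), target_size = 20,
                         name = "roi") {
  if (target_size < 1) stop_config("target_size must be >= 1")
  ds <- directed_stat(map, cfg)
  grid_shape <- dim(ds$stat)
  supra <- which(ds$stat > ds$thr & is.finite(ds$stat))
  if (length(supra) == 0) {
    return(NULL)
  }
  supra_set <- logical(length(ds$stat))
  supra_set[supra] <- TRUE
  offs <- neighbor_offsets(cfg$connectivity)
  peak <- find_peak(ds$stat, supra, grid_shape)

  in_mask <- logical(length(ds$stat))
  in_frontier <- logical(length(ds$stat))
  mask <- integer(0)
  frontier <- peak
  in_frontier[peak] <- TRUE
  while (length(mask) < target_size && length(frontier) > 0) {
    fvals <- ds$stat[frontier]
    best <- frontier[fvals == max(fvals)]
    if (length(best) > 1) {
      cc <- index_to_coords(best, grid_shape)
      best <- best[lex_order(cc)[1]]
    }
    frontier <- frontier[frontier != best]
    in_frontier[best] <- FALSE
    mask <- c(mask, best)
    in_mask[best] <- TRUE
    nb <- sweep_neighbors(best, offs, grid_shape)
    nb <- nb[supra_set[nb] & !in_mask[nb] & !in_frontier[nb]]
    if (length(nb)) {
      frontier <- c(frontier, nb)
      in_frontier[nb] <- TRUE
    }
  }
  roi_mask(
    name, index_to_coords(mask, grid_shape),
    statistic = ds$stat[mask], voxel_mm = map$voxel_mm,
    grid_shape = grid_shape, peak = index_to_coords(peak, grid_shape),
    undersized = length(mask) < target_size
  )
}

# Valid grid neighbors of a linear index.
sweep_neighbors <- function(idx, offs, grid_shape) {
  c0 <- index_to_coords(idx, grid_shape)
  nb <- sweep(offs, 2, as.numeric(c0), "+")
  ok <- nb[, 1] >= 1 & nb[, 1] <= grid_shape[1] &
    nb[, 2] >= 1 & nb[, 2] <= grid_shape[2] &
    nb[, 3] >= 1 & nb[, 3] <= grid_shape[3]
  coords_to_index(nb[ok, , drop = FALSE], grid_shape)
}

#' Full-size ROI: the peak's suprathreshold connected component
#'
#' Breadth-first flood fill over suprathreshold voxels starting from the
#' peak; disjoint suprathreshold clusters are not included. This is the
#' "no equalization" control ROI.
#'
#' @inheritParams localize_roi
#' @export
full_size_roi <- function(map, cfg = roi_config(), name = "roi_full") {
  ds <- directed_stat(map, cfg)
  grid_shape <- dim(ds$stat)
  supra <- which(ds$stat > ds$thr & is.finite(ds$stat))
  if (length(supra) == 0) {
    return(NULL)
  }
  supra_set <- logical(length(ds$stat))
  supra_set[supra] <- TRUE
  offs <- neighbor_offsets(cfg$connectivity)
  peak <- find_peak(ds$stat, supra, grid_shape)
  visited <- logical(length(ds$stat))
  visited[peak] <- TRUE
  queue <- peak
  comp <- integer(0)
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    comp <- c(comp, v)
    nb <- sweep_neighbors(v, offs, grid_shape)
    nb <- nb[supra_set[nb] & !visited[nb]]
    visited[nb] <- TRUE
    queue <- c(queue, nb)
  }
  comp <- sort(comp)
  roi_mask(
    name, index_to_coords(comp, grid_shape),
    statistic = ds$stat[comp], voxel_mm = map$voxel_mm,
    grid_shape = grid_shape, peak = index_to_coords(peak, grid_shape)
  )
}

#' Summarize a set of subjects' ROIs (localization table)
#'
#' One row per region: number of subjects in which it was localizable, mean
#' statistic over admitted voxels, and the mean peak coordinate.
#'
#' @param roi_lists list (subjects) of named lists of [roi_mask()] or NULL.
#' @return data frame with columns `roi`, `n_subjects`, `mean_statistic`,
#'   `peak_x`, `peak_y`, `peak_z`.
#' @export
roi_summary_table <- function(roi_lists) {
  regions <- unique(unlist(lapply(roi_lists, names)))
  rows <- lapply(regions, function(rn) {
    masks <- Filter(Negate(is.null), lapply(roi_lists, `[[`, rn))
    if (length(masks) == 0) {
      return(data.frame(
        roi = rn, n_subjects = 0L, mean_statistic = NA_real_,
        peak_x = NA_real_, peak_y = NA_real_, peak_z = NA_real_
      ))
    }
    peaks <- do.call(rbind, lapply(masks, `[[`, "peak"))
    data.frame(
      roi = rn, n_subjects = length(masks),
      mean_statistic = mean(vapply(masks, function(m) mean(m$statistic), 0)),
      peak_x = mean(peaks[, 1]), peak_y = mean(peaks[, 2]),
      peak_z = mean(peaks[, 3])
    )
  })
  do.call(rbind, rows)
}
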