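NIFTI_DATATYPES <- list(
  "2" = list(what = "integer", size = 1, signed = FALSE), # uint8
  "4" = list(what = "integer", size = 2, signed = TRUE), # int16
  "8" = list(what = "integer", size = 4, signed = TRUE), # int32
  "16" = list(what = "double", size = 4, signed = TRUE), # float32
  "64" = list(what = "double", size = 8, signed = TRUE) # float64
)

#' Write a volume as NIfTI-1
#'
#' Minimal single-file (.nii) NIfTI-1 writer: 3-D or 4-D arrays, float64 by
#' default (uint8 for integer masks) so round-trips are lossless, isotropic
#' voxel size recorded in
#' pixdim and a diagonal sform. Sufficient for lossless round-trips of the
#' package's own volumes; no compression.
#'
#' @param x [bold_run()], [roi_mask()], or plain 3-D/4-D numeric array.
#' @param path output path ending in `.nii`.
#' @param voxel_mm isotropic voxel size (taken from the object when it
#'   carries one).
#' @param tr_seconds repetition time stored in pixdim[5] for 4-D data.
#' @export
write_volume <- function(x, path, voxel_mm = 2, tr_seconds = 0) {
  if (inherits(x, "bold_run")) {
    return(write_volume(x$data, path, x$voxel_mm, x$tr_seconds))
  }
  if (inherits(x, "roi_mask")) {
    if (is.null(x$grid_shape)) stop_config("mask has no grid_shape")
    arr <- array(0L, x$grid_shape)
    arr[x$coords] <- 1L
    return(write_volume(arr, path, x$voxel_mm))
  }
  nd <- length(dim(x))
  if (!nd %in% c(3, 4)) stop_config("expected a 3-D or 4-D array")
  datatype <- if (is.integer(x) && all(x %in% 0:255)) 2L else 64L
  dt <- NIFTI_DATATYPES[[as.character(datatype)]]
  con <- file(path, "wb")
  on.exit(close(con))
  dims <- c(nd, dim(x), rep(1L, 7 - nd))
  writeBin(348L, con, size = 4) # sizeof_hdr
  writeBin(raw(36), con) # unused fields through dim_info
  writeBin(as.integer(dims), con, size = 2)
  writeBin(raw(14), con) # intent params + intent_code
  writeBin(as.integer(datatype), con, size = 2)
  writeBin(as.integer(dt$size * 8), con, size = 2) # bitpix
  writeBin(0L, con, size = 2) # slice_start
  pixdim <- c(1, rep(voxel_mm, 3), tr_seconds, 0, 0, 0)
  writeBin(pixdim, con, size = 4)
  writeBin(352, con, size = 4) # vox_offset (float)
  writeBin(c(1, 0), con, size = 4) # scl_slope, scl_inter
  writeBin(raw(4), con) # slice_end, slice_code, xyzt_units (defaults)
  writeBin(c(0, 0, 0, 0), con, size = 4) # cal_max/min, slice_duration, toffset
  writeBin(raw(8), con) # glmax, glmin
  writeBin(raw(104), con) # descrip(80) + aux_file(24)
  writeBin(c(0L, 1L), con, size = 2) # qform_code 0, sform_code 1
  writeBin(rep(0, 6), con, size = 4) # quaternions
  srow <- rbind(
    c(voxel_mm, 0, 0, 0),
    c(0, voxel_mm, 0, 0),
    c(0, 0, voxel_mm, 0)
  )
  writeBin(as.numeric(t(srow)), con, size = 4)
  writeBin(raw(16), con) # intent_name
  writeChar("n+1", con, nchars = 3, eos = NULL)
  writeBin(raw(1 + 4), con) # magic NUL + extension flag
  if (dt$what == "integer") {
    writeBin(as.integer(x), con, size = dt$size)
  } else {
    writeBin(as.numeric(x), con, size = dt$size)
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Counterpart of [write_volume()]; also reads files produced by other
#' NIfTI-1 writers using datatypes uint8/int16/int32/float32/float64, either
#' endianness, with scl_slope/scl_inter applied.
#'
#' @param path `.nii` file.
#' @return list with `data` (array), `voxel_mm`, `tr_seconds`.
#' @export
read_volume <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  sizeof_hdr <- readBin(con, "integer", 1, size = 4)
  endian <- .Platform$endian
  if (sizeof_hdr != 348L) {
    endian <- setdiff(c("big", "little"), endian)
    seek(con, 0)
    sizeof_hdr <- readBin(con, "integer", 1, size = 4, endian = endian)
    if (sizeof_hdr != 348L) {
      stop_config("malformed NIfTI header at offset 0: sizeof_hdr != 348")
    }
  }
  seek(con, 40)
  dims <- readBin(con, "integer", 8, size = 2, endian = endian)
  nd <- dims[1]
  if (nd < 3 || nd > 7) stop_config("malformed NIfTI header at offset 40: ndim ", nd)
  seek(con, 70)
  datatype <- readBin(con, "integer", 1, size = 2, endian = endian)
  dt <- NIFTI_DATATYPES[[as.character(datatype)]]
  if (is.null(dt)) {
    stop_config("unsupported NIfTI datatype at offset 70: ", datatype)
  }
  seek(con, 76)
  pixdim <- readBin(con, "double", 8, size = 4, endian = endian)
  vox_offset <- readBin(con, "double", 1, size = 4, endian = endian)
  scl_slope <- readBin(con, "double", 1, size = 4, endian = endian)
  scl_inter <- readBin(con, "double", 1, size = 4, endian = endian)
  seek(con, 344)
  magic_raw <- readBin(con, "raw", 3)
  magic <- if (any(magic_raw == 0)) "" else rawToChar(magic_raw)
  if (!magic %in% c("n+1", "ni1")) {
    stop_config("malformed NIfTI header at offset 344: bad magic")
  }
  n <- prod(dims[2:(nd + 1)])
  seek(con, vox_offset)
  data <- readBin(con, dt$what, n,
    size = dt$size, signed = dt$signed, endian = endian
  )
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    data <- data * scl_slope + scl_inter
  }
  list(
    data = array(data, dims[2:(nd + 1)]),
    voxel_mm = pixdim[2],
    tr_seconds = if (nd >= 4) pixdim[5] else 0
  )
}

#' @rdname read_volume
#' @param session_id session label for the returned run.
#' @export
read_bold_run <- function(path, session_id = 1L) {
  v <- read_volume(path)
  if (length(dim(v$data)) != 4) stop_config("expected a 4-D volume")
  bold_run(v$data, v$tr_seconds, v$voxel_mm, session_id)
}

#' @rdname read_volume
#' @param name mask label.
#' @export
read_roi_mask <- function(path, name = "mask") {
  v <- read_volume(path)
  if (length(dim(v$data)) != 3) stop_config("expected a 3-D volume")
  coords <- which(v$data != 0, arr.ind = TRUE)
  colnames(coords) <- c("x", "y", "z")
  roi_mask(name, coords,
    voxel_mm = v$voxel_mm,
    grid_shape = dim(v$data)
  )
}

#' Pipeline configuration
#'
#' Bundles every stage's parameters plus the global seed. The seed and a
#' hash of the configuration are embedded in all output tables for
#' provenance.
#'
#' @param design [design_params()].
#' @param synth [synth_params()].
#' @param roi [roi_config()].
#' @param decode [decode_config()].
#' @param searchlight [searchlight_config()] or NULL to skip the stage.
#' @param n_subjects subjects to simulate.
#' @param roi_size equalized ROI size for the main analysis.
#' @param alpha,n_comparisons group-test level and Bonferroni family size
#'   (12 regions in the emulated study).
#' @param seed global seed; subject s uses `seed * 1000 + s`.
#' @export
pipeline_config <- function(design = design_params(), synth = synth_params(),
                            roi = roi_config(), decode = decode_config(),
                            searchlight = NULL, n_subjects = 16,
                            roi_size = 20, alpha = 0.05,
                            n_comparisons = 12, seed = 1) {
  structure(
    list(
      design = design, synth = synth, roi = roi, decode = decode,
      searchlight = searchlight, n_subjects = n_subjects,
      roi_size = roi_size, alpha = alpha, n_comparisons = n_comparisons,
      seed = seed
    ),
    class = "pipeline_config"
  )
}

config_hash <- function(config) {
  # digest-free stable hash: md5 of the deparsed configuration
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(unclass(config)), tmp)
  unname(tools::md5sum(tmp))
}

#' Single-subject pipeline: simulate, localize, decode
#'
#' The experiment's analysis sequence for one synthetic subject: simulate
#' all sessions; fit the two-regressor localizer GLM on session 1 only and
#' grow the fixed-size face-selective ROI from its faces > cups map; then
#' run leave-one-session-out identity decoding on the remaining sessions
#' (the localizer session never enters decoding). Optionally also computes
#' the cup-pair decoding, percent signal change, and a search-light map.
#'
#' @param config a [pipeline_config()].
#' @param subject_seed seed for this subject.
#' @param with_psc,with_cups,with_searchlight toggles for optional stages.
#' @return list: `accuracy` (face pair; NA if the ROI was not localizable),
#'   `roi`, `psc`, `cup_accuracy`, `searchlight` map, and `provenance`
#'   naming the localizer and decoding sessions.
#' @export
run_subject_pipeline <- function(config, subject_seed,
                                 with_psc = FALSE, with_cups = FALSE,
                                 with_searchlight = FALSE) {
  sim <- simulate_subject(config$synth,
    seed = subject_seed,
    design = config$design
  )
  loc_idx <- 1L
  dec_idx <- setdiff(seq_along(sim$runs), loc_idx)
  glm <- fit_block_glm(sim$runs[[loc_idx]], sim$schedules[[loc_idx]],
    hrf = config$synth$hrf
  )
  map <- contrast_map(glm, c(1, -1), name = "faces>cups")
  roi <- localize_roi(map, config$roi, config$roi_size, name = "face_roi")
  res <- list(
    accuracy = NA_real_, roi = roi,
    provenance = list(
      localizer_sessions = loc_idx, decoding_sessions = dec_idx,
      seed = subject_seed
    )
  )
  if (is.null(roi)) {
    return(res)
  }
  dcfg <- config$decode
  res$accuracy <- decode_roi(
    sim$runs[dec_idx], sim$schedules[dec_idx], roi, dcfg
  )$accuracy
  if (with_cups) {
    ccfg <- decode_config(
      lag_trs = dcfg$lag_trs, discard_trs = dcfg$discard_trs,
      svm_cost = dcfg$svm_cost, class_pair = CUP_CONDITIONS
    )
    cup_map <- contrast_map(glm, c(-1, 1), name = "cups>faces")
    cup_cfg <- config$roi
    cup_roi <- localize_roi(cup_map, cup_cfg, config$roi_size, name = "cup_roi")
    res$cup_roi <- cup_roi
    res$cup_accuracy <- if (is.null(cup_roi)) {
      NA_real_
    } else {
      decode_roi(sim$runs[dec_idx], sim$schedules[dec_idx], cup_roi, ccfg)$accuracy
    }
  }
  if (with_psc) {
    res$psc <- plateau_psc(sim$runs[dec_idx], sim$schedules[dec_idx], roi,
      lag_trs = dcfg$lag_trs
    )
  }
  if (with_searchlight && !is.null(config$searchlight)) {
    res$searchlight <- run_searchlight(
      sim$runs[dec_idx], sim$schedules[dec_idx], roi,
      config$searchlight, dcfg
    )
  }
  res
}

#' Run the full multi-subject experiment
#'
#' Simulates `n_subjects` subjects, runs each through
#' [run_subject_pipeline()], assembles the accuracy and percent-signal-
#' change tables, the localization summary, and the group test of
#' accuracies against chance, and (when `out_dir` is given) writes
#' everything as CSV/JSON stamped with the seed and configuration hash.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (NULL for no files).
#' @param verbose print per-stage progress and wall time.
#' @return list: `accuracy_table` (subject, roi, class_pair, accuracy,
#'   n_folds), `psc_table`, `roi_table`, `group_test`, `config_hash`.
#' @export
run_experiment <- function(config = pipeline_config(), out_dir = NULL,
                           verbose = FALSE) {
  t0 <- Sys.time()
  hash <- config_hash(config)
  subjects <- seq_len(config$n_subjects)
  results <- lapply(subjects, function(s) {
    t1 <- Sys.time()
    r <- run_subject_pipeline(config, config$seed * 1000L + s,
      with_psc = TRUE
    )
    if (verbose) {
      message(sprintf(
        "subject %d: accuracy %s [%.1f s]", s,
        format(r$accuracy, digits = 3),
        as.numeric(difftime(Sys.time(), t1, units = "secs"))
      ))
    }
    r
  })
  acc <- vapply(results, `[[`, 0, "accuracy")
  n_folds <- config$synth$n_sessions - 1L
  accuracy_table <- data.frame(
    subject = subjects, roi = "face_roi",
    class_pair = paste(config$decode$class_pair, collapse = "_vs_"),
    accuracy = acc, n_folds = n_folds,
    seed = config$seed, config_hash = hash
  )
  psc_rows <- do.call(rbind, lapply(subjects, function(s) {
    p <- results[[s]]$psc
    if (is.null(p)) {
      return(NULL)
    }
    data.frame(
      subject = s, roi = "face_roi", condition = names(p$conditions),
      psc = vapply(p$conditions, `[[`, 0, "plateau"),
      seed = config$seed, config_hash = hash
    )
  }))
  roi_table <- roi_summary_table(lapply(results, function(r) {
    list(face_roi = r$roi)
  }))
  roi_table$seed <- config$seed
  roi_table$config_hash <- hash
  ok <- !is.na(acc)
  group_test <- if (sum(ok) >= 2) one_sample_t(acc[ok], 0.5, "one") else NULL
  out <- list(
    accuracy_table = accuracy_table, psc_table = psc_rows,
    roi_table = roi_table, group_test = group_test, config_hash = hash,
    elapsed_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(accuracy_table, file.path(out_dir, "accuracy.csv"),
      row.names = FALSE
    )
    if (!is.null(psc_rows)) {
      utils::write.csv(psc_rows, file.path(out_dir, "psc.csv"),
        row.names = FALSE
      )
    }
    utils::write.csv(roi_table, file.path(out_dir, "roi_summary.csv"),
      row.names = FALSE
    )
    jsonlite::write_json(
      list(
        seed = config$seed, config_hash = hash,
        n_subjects = config$n_subjects,
        group_t = group_test$statistic %||% NA,
        group_df = group_test$df %||% NA,
        group_p = group_test$p %||% NA,
        mean_accuracy = mean(acc, na.rm = TRUE)
      ),
      file.path(out_dir, "group_stats.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  out
}
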