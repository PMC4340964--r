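#' Decoding configuration
#'
#' The multivoxel chain's tunable constants: a 2-TR (4 s) hemodynamic lag
#' applied by index shift, the first 2 TRs of each 8-TR block discarded as
#' contaminated by the preceding block (leaving 6 TRs to average), and a
#' linear support vector machine with the regularization constant fixed at
#' 1 and no inner tuning.
#'
#' @param lag_trs hemodynamic lag, whole TRs.
#' @param discard_trs leading block TRs dropped before averaging.
#' @param svm_cost SVM regularization constant C.
#' @param class_pair the two condition labels to discriminate.
#' @export
decode_config <- function(lag_trs = 2, discard_trs = 2, svm_cost = 1,
                          class_pair = FACE_CONDITIONS) {
  if (length(class_pair) != 2) stop_config("class_pair must name two conditions")
  if (discard_trs < 0 || lag_trs < 0) stop_config("lags must be >= 0")
  structure(
    list(
      lag_trs = as.integer(lag_trs), discard_trs = as.integer(discard_trs),
      svm_cost = svm_cost, class_pair = class_pair
    ),
    class = "decode_config"
  )
}

#' Session-wise preprocessing for pattern analysis
#'
#' Per voxel, over the full session and for each session separately (so no
#' information can leak across cross-validation folds): remove a linear
#' trend, standardize to zero mean and unit variance, then shift the series
#' by the hemodynamic lag so that the sample attributed to TR t is read from
#' t + `lag_trs`; the trailing `lag_trs` samples are dropped. Raw
#' intensities (not GLM coefficients) feed the classifier.
#'
#' @param run a [bold_run()].
#' @param cfg a [decode_config()].
#' @param roi optional [roi_mask()]; when given, only its voxels are kept.
#' @return `preprocessed_session`: matrix `data` (voxels x TRs after shift),
#'   `voxel_index` (linear grid indices), `session_id`, `flagged_voxels`
#'   (zero-variance voxels, variance-floored).
#' @export
preprocess_session <- function(run, cfg = decode_config(), roi = NULL) {
  grid_shape <- dim(run$data)[1:3]
  n_trs <- dim(run$data)[4]
  if (n_trs <= cfg$lag_trs) stop_config("session shorter than the lag")
  dat <- matrix(run$data, prod(grid_shape), n_trs)
  voxel_index <- if (is.null(roi)) {
    seq_len(nrow(dat))
  } else {
    coords_to_index(roi$coords, grid_shape)
  }
  dat <- dat[voxel_index, , drop = FALSE]
  dat0 <- dat
  # linear detrend: residuals of each voxel on (1, t)
  tt <- seq_len(n_trs)
  X <- cbind(1, tt - mean(tt))
  dat <- dat - t(X %*% qr.coef(qr(X), t(dat)))
  # z-score per voxel (sd with n-1 denominator, the usual z-score function);
  # voxels whose detrended variance is zero to numerical precision (relative
  # to the raw series scale) get a variance floor and are flagged, so
  # rounding noise is never amplified to unit variance
  scale0 <- apply(dat0, 1, function(r) max(abs(r - mean(r)), 1))
  sds <- apply(dat, 1, sd)
  flagged <- which(sds <= 1e-10 * scale0)
  sds[flagged] <- 1
  dat <- (dat - rowMeans(dat)) / sds
  # hemodynamic shift by index offset
  if (cfg$lag_trs > 0) {
    dat <- dat[, (cfg$lag_trs + 1):n_trs, drop = FALSE]
  }
  structure(
    list(
      data = dat, voxel_index = voxel_index, grid_shape = grid_shape,
      session_id = run$session_id, lag_trs = cfg$lag_trs,
      flagged_voxels = flagged
    ),
    class = "preprocessed_session"
  )
}

#' Extract one multivoxel pattern per block
#'
#' For every block of the requested classes: drop the first `discard_trs`
#' TRs, average the remaining TRs voxel-wise (8-TR blocks with 2 discarded
#' give 6 averaged TRs, one data point per block). Then, per condition and
#' per session, the scalar mean intensity over that condition's voxels and
#' blocks ("global signal") is subtracted from every entry, so a uniform
#' activation difference between conditions cannot drive classification.
#'
#' @param pre a `preprocessed_session`.
#' @param schedule the session's `block_schedule`.
#' @param classes condition labels to extract.
#' @param cfg a [decode_config()].
#' @param subtract_condition_mean set FALSE to skip the global-signal step
#'   (the search-light applies it per box instead).
#' @return `pattern_set`: matrix `patterns` (blocks x voxels), `labels`,
#'   `session_id`, `trs_averaged`.
#' @export
extract_block_patterns <- function(pre, schedule, classes = TASK_CONDITIONS,
                                   cfg = decode_config(),
                                   subtract_condition_mean = TRUE) {
  rows <- which(schedule$condition %in% classes)
  if (length(rows) == 0) stop_config("no blocks of the requested classes")
  if (any(schedule$duration_trs[rows] <= cfg$discard_trs)) {
    stop_config("block shorter than discard_trs + 1")
  }
  n_avail <- ncol(pre$data)
  pats <- vapply(rows, function(r) {
    trs <- schedule$onset_tr[r] + seq_len(schedule$duration_trs[r]) - 1L
    trs <- trs[-seq_len(cfg$discard_trs)]
    trs <- trs[trs <= n_avail] # shift-truncated tail
    rowMeans(pre$data[, trs, drop = FALSE])
  }, numeric(nrow(pre$data)))
  pats <- if (nrow(pre$data) == 1) matrix(pats, ncol = 1) else t(pats)
  labels <- schedule$condition[rows]
  trs_averaged <- schedule$duration_trs[rows] - cfg$discard_trs
  if (subtract_condition_mean) {
    for (cond in unique(labels)) {
      sel <- labels == cond
      pats[sel, ] <- pats[sel, , drop = FALSE] - mean(pats[sel, ])
    }
  }
  structure(
    list(
      patterns = pats, labels = labels, session_id = pre$session_id,
      trs_averaged = trs_averaged, voxel_index = pre$voxel_index
    ),
    class = "pattern_set"
  )
}

# Pool pattern_sets from several sessions into one frame.
bind_pattern_sets <- function(sets) {
  list(
    patterns = do.call(rbind, lapply(sets, `[[`, "patterns")),
    labels = unlist(lapply(sets, `[[`, "labels")),
    sessions = unlist(lapply(sets, function(s) {
      rep(s$session_id, length(s$labels))
    }))
  )
}

svm_train <- function(X, y01, cost) {
  linsvm_fit(X, ifelse(y01, 1, -1), C = cost)
}

svm_predict <- function(model, X) {
  as.numeric(X %*% model$w + model$b) > 0
}

#' Leave-one-session-out linear SVM decoding
#'
#' One fold per session: the classifier is trained on all other sessions'
#' block patterns and tested on the held-out session (for a class pair, 10
#' test patterns per fold — 5 per class). Accuracy is the mean over folds of
#' the fraction of correctly labelled test patterns.
#'
#' @param pattern_sets list of `pattern_set`, one per session.
#' @param cfg a [decode_config()]; its `class_pair` defines the two classes.
#' @return list: `accuracy` (mean over folds), `fold_accuracy`, `n_folds`.
#' @export
loso_decode <- function(pattern_sets, cfg = decode_config()) {
  pooled <- bind_pattern_sets(pattern_sets)
  keep <- pooled$labels %in% cfg$class_pair
  X <- pooled$patterns[keep, , drop = FALSE]
  y <- pooled$labels[keep] == cfg$class_pair[2]
  sess <- pooled$sessions[keep]
  folds <- sort(unique(sess))
  if (length(folds) < 2) stop_config("need >= 2 sessions for cross-validation")
  for (f in folds) {
    if (length(unique(y[sess == f])) < 2) {
      stop_config("session ", f, " lacks one of the classes")
    }
  }
  fold_acc <- vapply(folds, function(f) {
    test <- sess == f
    model <- svm_train(X[!test, , drop = FALSE], y[!test], cfg$svm_cost)
    mean(svm_predict(model, X[test, , drop = FALSE]) == y[test])
  }, numeric(1))
  list(accuracy = mean(fold_acc), fold_accuracy = fold_acc,
    n_folds = length(folds))
}

#' ROI decoding for one subject from raw runs
#'
#' Convenience wrapper running the full chain (preprocess each session,
#' extract patterns within the ROI, leave-one-session-out SVM) on a set of
#' sessions.
#'
#' @param runs list of [bold_run()] (the decoding sessions only — the
#'   localizer session must not be among them).
#' @param schedules matching schedules.
#' @param roi an [roi_mask()].
#' @param cfg a [decode_config()].
#' @export
decode_roi <- function(runs, schedules, roi, cfg = decode_config()) {
  sets <- mapply(function(run, sched) {
    pre <- preprocess_session(run, cfg, roi)
    extract_block_patterns(pre, sched, classes = cfg$class_pair, cfg = cfg)
  }, runs, schedules, SIMPLIFY = FALSE)
  loso_decode(sets, cfg)
}
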