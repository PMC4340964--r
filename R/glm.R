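#' Fit a block-design general linear model
#'
#' Ordinary least squares of every voxel's time series on HRF-convolved
#' condition boxcars plus, per session, an intercept and a linear drift term.
#' For localization the model has two condition regressors (faces, cups);
#' for the univariate analysis four (identity 1/2, cup type 1/2).
#'
#' @param runs list of [bold_run()] (or a single run).
#' @param schedules matching list of `block_schedule`.
#' @param conditions named condition groups: each design column pools the
#'   schedule conditions listed under it, e.g.
#'   `list(faces = c("identity1","identity2"), cups = c("cup1","cup2"))`.
#' @param hrf an [hrf_params()] object.
#' @return `glm_result`: per-voxel `coefficients` (voxels x regressors),
#'   `sigma2`, `df`, the design matrix `X`, regressor names and grid
#'   metadata.
#' @export
fit_block_glm <- function(runs, schedules,
                          conditions = list(
                            faces = FACE_CONDITIONS,
                            cups = CUP_CONDITIONS
                          ),
                          hrf = hrf_params()) {
  if (inherits(runs, "bold_run")) runs <- list(runs)
  if (inherits(schedules, "block_schedule")) schedules <- list(schedules)
  if (length(runs) < 1) stop_config("need at least one run")
  if (length(runs) != length(schedules)) {
    stop_config("runs and schedules differ in length")
  }
  present <- unique(unlist(lapply(schedules, function(s) s$condition)))
  missing <- setdiff(unlist(conditions), present)
  if (length(missing)) {
    stop_config("conditions absent from schedules: ", paste(missing, collapse = ", "))
  }
  grid_shape <- dim(runs[[1]]$data)[1:3]
  pieces <- mapply(function(run, sched) {
    n_trs <- dim(run$data)[4]
    kernel <- hrf_kernel(hrf, run$tr_seconds)
    cols <- vapply(conditions, function(group) {
      rowSums(vapply(
        group,
        function(cond) convolved_regressor(sched, cond, kernel, n_trs),
        numeric(n_trs)
      ))
    }, numeric(n_trs))
    list(
      Y = t(matrix(run$data, prod(grid_shape), n_trs)), # TRs x voxels
      cond = cols,
      drift = cbind(1, seq(-0.5, 0.5, length.out = n_trs))
    )
  }, runs, schedules, SIMPLIFY = FALSE)

  Y <- do.call(rbind, lapply(pieces, `[[`, "Y"))
  Xc <- do.call(rbind, lapply(pieces, `[[`, "cond"))
  n_sess <- length(pieces)
  drift <- matrix(0, nrow(Y), 2 * n_sess)
  row0 <- 0
  for (s in seq_len(n_sess)) {
    d <- pieces[[s]]$drift
    drift[row0 + seq_len(nrow(d)), 2 * s - c(1, 0)] <- d
    row0 <- row0 + nrow(d)
  }
  X <- cbind(Xc, drift)
  colnames(X) <- c(
    names(conditions),
    paste0(rep(c("intercept_s", "drift_s"), n_sess),
      rep(seq_len(n_sess), each = 2))
  )
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_config("design matrix rank-deficient; collinear columns: ",
      paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrX, Y) # regressors x voxels
  resid <- Y - X %*% beta
  df <- nrow(X) - ncol(X)
  if (df <= 0) stop_config("no residual degrees of freedom")
  sigma2 <- colSums(resid^2) / df
  structure(
    list(
      coefficients = t(beta), sigma2 = sigma2, df = df, X = X,
      regressors = names(conditions), grid_shape = grid_shape,
      voxel_mm = runs[[1]]$voxel_mm, xtx_inv = chol2inv(qr.R(qrX))
    ),
    class = "glm_result"
  )
}

#' Contrast t / z map from a fitted GLM
#'
#' Per voxel, t = c'b / se(c'b) with se from the voxel's residual variance;
#' z is the normal quantile matching the t tail probability. Weights are
#' given for the condition regressors only (drift terms get weight 0); the
#' canonical localizer contrast is faces > cups, `c(1, -1)`.
#'
#' @param glm a `glm_result`.
#' @param weights numeric contrast weights, one per condition regressor.
#' @param name contrast label.
#' @return `stat_map`: arrays `t` and `z` over the grid plus metadata.
#'   Voxels with zero residual variance get infinite t (with a warning) and
#'   are listed in `flagged`.
#' @export
contrast_map <- function(glm, weights, name = "contrast") {
  k <- length(glm$regressors)
  if (length(weights) != k) {
    stop_config("need ", k, " contrast weights, got ", length(weights))
  }
  cvec <- c(weights, rep(0, ncol(glm$X) - k))
  num <- as.numeric(glm$coefficients %*% cvec)
  cvar <- as.numeric(t(cvec) %*% glm$xtx_inv %*% cvec)
  se <- sqrt(glm$sigma2 * cvar)
  tval <- ifelse(se > 0, num / se, ifelse(num == 0, 0, sign(num) * Inf))
  flagged <- which(se == 0 & num != 0)
  if (length(flagged)) {
    warning(length(flagged), " voxel(s) with zero residual variance; t set to +/-Inf")
  }
  # z via the t tail probability, numerically stable in log space
  zval <- sign(tval) * qnorm(
    pmin(t_tail_prob(abs(tval), glm$df), 0.5),
    lower.tail = FALSE
  )
  zval[tval == 0] <- 0
  stat_map(
    t = array(tval, glm$grid_shape), z = array(zval, glm$grid_shape),
    df = glm$df, weights = weights, name = name, voxel_mm = glm$voxel_mm,
    flagged = flagged
  )
}

#' Statistic map container
#' @param t,z arrays of t and z values over the voxel grid.
#' @param df residual degrees of freedom.
#' @param weights contrast weights.
#' @param name contrast label.
#' @param voxel_mm voxel size.
#' @param flagged indices of degenerate voxels.
#' @export
stat_map <- function(t, z, df, weights, name, voxel_mm, flagged = integer(0)) {
  structure(
    list(
      t = t, z = z, df = df, weights = weights, name = name,
      voxel_mm = voxel_mm, flagged = flagged
    ),
    class = "stat_map"
  )
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf(
    "<stat_map> '%s': %s grid, df = %g, t range [%.3g, %.3g]\n",
    x$name, paste(dim(x$t), collapse = "x"), x$df,
    min(x$t), max(x$t)
  ))
  invisible(x)
}

#' Event-locked percent signal change with block-plateau averaging
#'
#' For each condition, time series are averaged over the ROI's voxels,
#' event-locked to block onsets and averaged across blocks; the plateau is
#' the mean over TRs 4..10 (1-based, inclusive — 7 samples) from block
#' onset, which spans the 8-TR block and the early following fixation.
#' Percent signal change is `100 (plateau - baseline) / baseline` with the
#' baseline the mean over all fixation TRs of the session (fixation TRs are
#' lagged by `lag_trs` to account for hemodynamic delay).
#'
#' @param runs list of [bold_run()].
#' @param schedules matching schedules.
#' @param roi an [roi_mask()] selecting voxels to average (NULL = whole grid).
#' @param conditions conditions to extract.
#' @param window_trs event-locked window length, TRs.
#' @param plateau_trs plateau TR indices (1-based from onset).
#' @param lag_trs hemodynamic lag applied to the fixation baseline TRs.
#' @return `plateau_psc`: per condition the event-locked mean time course in
#'   percent signal change and its plateau mean.
#' @export
plateau_psc <- function(runs, schedules, roi = NULL,
                        conditions = TASK_CONDITIONS, window_trs = 12,
                        plateau_trs = 4:10, lag_trs = 2) {
  if (inherits(runs, "bold_run")) runs <- list(runs)
  if (inherits(schedules, "block_schedule")) schedules <- list(schedules)
  if (max(plateau_trs) > window_trs) {
    stop_config("plateau window exceeds the event-locked window")
  }
  present <- unique(unlist(lapply(schedules, function(s) s$condition)))
  missing <- setdiff(conditions, present)
  if (length(missing)) {
    stop_config("conditions absent from schedules: ", paste(missing, collapse = ", "))
  }
  grid_shape <- dim(runs[[1]]$data)[1:3]
  courses <- lapply(conditions, function(cond) list(sum = 0, n = 0))
  names(courses) <- conditions
  for (i in seq_along(runs)) {
    dat <- matrix(runs[[i]]$data, prod(grid_shape))
    series <- if (is.null(roi)) {
      colMeans(dat)
    } else {
      colMeans(dat[coords_to_index(roi$coords, grid_shape), , drop = FALSE])
    }
    n_trs <- length(series)
    sched <- schedules[[i]]
    fix_rows <- which(sched$condition == "fixation")
    fix_trs <- unlist(lapply(fix_rows, function(r) {
      seq(sched$onset_tr[r], length.out = sched$duration_trs[r]) + lag_trs
    }))
    fix_trs <- fix_trs[fix_trs <= n_trs]
    baseline <- mean(series[fix_trs])
    psc_series <- 100 * (series - baseline) / baseline
    for (cond in conditions) {
      rows <- which(sched$condition == cond)
      for (r in rows) {
        idx <- sched$onset_tr[r] + seq_len(window_trs) - 1L
        if (max(idx) > n_trs) next # truncated final block
        courses[[cond]]$sum <- courses[[cond]]$sum + psc_series[idx]
        courses[[cond]]$n <- courses[[cond]]$n + 1L
      }
    }
  }
  out <- lapply(courses, function(cc) {
    tc <- cc$sum / cc$n
    list(timecourse = tc, plateau = mean(tc[plateau_trs]), n_blocks = cc$n)
  })
  structure(
    list(conditions = out, plateau_trs = plateau_trs, window_trs = window_trs),
    class = "plateau_psc"
  )
}

#' @export
print.plateau_psc <- function(x, ...) {
  cat("<plateau_psc> plateau TRs", paste(range(x$plateau_trs), collapse = ".."), "\n")
  for (nm in names(x$conditions)) {
    cat(sprintf(
      "  %-10s plateau PSC %7.3f%% (%d blocks)\n",
      nm, x$conditions[[nm]]$plateau, x$conditions[[nm]]$n_blocks
    ))
  }
  invisible(x)
}
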