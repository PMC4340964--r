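# Independent brute-force oracles. Each reimplements the operation it checks
# in the most literal way available, sharing no code with the package path.

# Ordinary least squares by explicit normal equations.
oracle_ols <- function(X, y) {
  solve(t(X) %*% X) %*% t(X) %*% y
}

# Contrast t from the normal-equations fit.
oracle_contrast_t <- function(X, y, cvec) {
  beta <- oracle_ols(X, y)
  resid <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  s2 <- sum(resid^2) / df
  drop(t(cvec) %*% beta) / sqrt(s2 * drop(t(cvec) %*% solve(t(X) %*% X) %*% cvec))
}

# Benjamini-Hochberg by a literal step-up scan.
oracle_bh <- function(pvals, q) {
  m <- length(pvals)
  ord <- order(pvals)
  thr <- 0
  for (k in m:1) {
    if (pvals[ord[k]] <= k * q / m) {
      thr <- pvals[ord[k]]
      break
    }
  }
  list(significant = pvals <= thr & thr > 0, threshold = thr)
}

# Pearson correlation from the explicit sum formula.
oracle_pearson <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  n <- length(a)
  num <- n * sum(a * b) - sum(a) * sum(b)
  den <- sqrt(n * sum(a^2) - sum(a)^2) * sqrt(n * sum(b^2) - sum(b)^2)
  num / den
}

# Greedy fixed-size ROI growth replayed step by step with naive scans.
oracle_greedy_roi <- function(stat_arr, thr, target_size, connectivity = 26) {
  gs <- dim(stat_arr)
  all_coords <- as.matrix(expand.grid(x = 1:gs[1], y = 1:gs[2], z = 1:gs[3]))
  supra <- all_coords[stat_arr[all_coords] > thr, , drop = FALSE]
  if (nrow(supra) == 0) {
    return(NULL)
  }
  lex_pick <- function(coords) {
    coords[order(coords[, 1], coords[, 2], coords[, 3])[1], , drop = FALSE]
  }
  vals <- stat_arr[supra]
  peak <- lex_pick(supra[vals == max(vals), , drop = FALSE])
  adjacent <- function(a, b) {
    d <- abs(a - b)
    if (connectivity == 26) all(d <= 1) && any(d > 0) else sum(d) == 1
  }
  mask <- peak
  while (nrow(mask) < target_size) {
    frontier <- supra[apply(supra, 1, function(v) {
      in_mask <- any(apply(mask, 1, function(m) all(m == v)))
      if (in_mask) {
        return(FALSE)
      }
      any(apply(mask, 1, function(m) adjacent(m, v)))
    }), , drop = FALSE]
    if (nrow(frontier) == 0) break
    fv <- stat_arr[frontier]
    mask <- rbind(mask, lex_pick(frontier[fv == max(fv), , drop = FALSE]))
  }
  unname(mask)
}

# Connected component of the peak by naive repeated scanning.
oracle_flood_fill <- function(stat_arr, thr, connectivity = 26) {
  gs <- dim(stat_arr)
  all_coords <- as.matrix(expand.grid(x = 1:gs[1], y = 1:gs[2], z = 1:gs[3]))
  supra <- all_coords[stat_arr[all_coords] > thr, , drop = FALSE]
  if (nrow(supra) == 0) {
    return(NULL)
  }
  vals <- stat_arr[supra]
  peak <- supra[which.max(vals), ]
  in_comp <- apply(supra, 1, function(v) all(v == peak))
  repeat {
    grew <- FALSE
    for (i in which(!in_comp)) {
      d <- abs(sweep(supra[in_comp, , drop = FALSE], 2, supra[i, ]))
      adj <- if (connectivity == 26) {
        any(apply(d, 1, function(r) all(r <= 1) && any(r > 0)))
      } else {
        any(rowSums(d) == 1)
      }
      if (adj) {
        in_comp[i] <- TRUE
        grew <- TRUE
      }
    }
    if (!grew) break
  }
  supra[in_comp, , drop = FALSE]
}

# Step-by-step preprocessing: naive per-voxel loops.
oracle_preprocess <- function(mat, lag) {
  n <- ncol(mat)
  out <- mat
  for (v in seq_len(nrow(mat))) {
    fit <- lm(y ~ t, data = data.frame(y = mat[v, ], t = seq_len(n)))
    r <- residuals(fit)
    out[v, ] <- (r - mean(r)) / sd(r)
  }
  out[, (lag + 1):n, drop = FALSE]
}

# Search-light per-voxel averages by a naive triple loop over all centers.
oracle_searchlight_means <- function(mask_coords, grid_shape, box_acc_fn,
                                     box_edge = 3, min_voxels = 10) {
  half <- (box_edge - 1) / 2
  in_mask <- array(FALSE, grid_shape)
  in_mask[mask_coords] <- TRUE
  received <- vector("list", prod(grid_shape))
  for (r in seq_len(nrow(mask_coords))) {
    cx <- mask_coords[r, ]
    members <- NULL
    for (dx in -half:half) {
      for (dy in -half:half) {
        for (dz in -half:half) {
          v <- cx + c(dx, dy, dz)
          if (all(v >= 1) && all(v <= grid_shape) && in_mask[rbind(v)]) {
            members <- rbind(members, v)
          }
        }
      }
    }
    if (nrow(members) < min_voxels) next
    acc <- box_acc_fn(members)
    for (i in seq_len(nrow(members))) {
      li <- (members[i, 3] - 1) * grid_shape[1] * grid_shape[2] +
        (members[i, 2] - 1) * grid_shape[1] + members[i, 1]
      received[[li]] <- c(received[[li]], acc)
    }
  }
  out <- array(NA_real_, grid_shape)
  for (li in seq_along(received)) {
    if (length(received[[li]])) out[li] <- mean(received[[li]])
  }
  out
}
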