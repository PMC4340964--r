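test_that("toy fit matches the normal-equations oracle", {
  set.seed(11)
  sched <- manual_schedule(
    c("identity1", "fixation", "cup1", "fixation"), c(6, 4, 6, 4)
  )
  mat <- matrix(rnorm(2 * 20, mean = 100), nrow = 2) # 2 voxels, 20 TRs
  run <- run_from_matrix(mat)
  glm <- fit_block_glm(run, sched,
    conditions = list(faces = "identity1", cups = "cup1")
  )
  for (v in 1:2) {
    beta_o <- oracle_ols(glm$X, mat[v, ])
    expect_equal(unname(glm$coefficients[v, 1:2]),
      unname(beta_o[1:2, 1]),
      tolerance = 1e-10
    )
  }
  # contrast t against the same oracle
  map <- contrast_map(glm, c(1, -1))
  cvec <- c(1, -1, rep(0, ncol(glm$X) - 2))
  for (v in 1:2) {
    expect_equal(as.numeric(map$t)[v],
      oracle_contrast_t(glm$X, mat[v, ], cvec),
      tolerance = 1e-10
    )
  }
})

test_that("fitted values plus residuals reconstruct the data (OLS identity)", {
  set.seed(12)
  sched <- manual_schedule(
    c("identity1", "fixation", "identity2", "fixation"), c(6, 4, 6, 4)
  )
  mat <- matrix(rnorm(3 * 20, 100), nrow = 3)
  glm <- fit_block_glm(run_from_matrix(mat), sched,
    conditions = list(
      faces = c("identity1", "identity2")
    )
  )
  qrX <- qr(glm$X)
  beta_full <- qr.coef(qrX, t(mat))
  recon <- glm$X %*% beta_full + (t(mat) - glm$X %*% beta_full)
  expect_equal(recon, t(mat), tolerance = 1e-12)
  # residual df bookkeeping
  expect_equal(glm$df, 20 - ncol(glm$X))
})

test_that("contrast behaves under null weights, offsets and degenerate voxels", {
  set.seed(13)
  sched <- manual_schedule(
    c("identity1", "fixation", "cup1", "fixation"), c(6, 4, 6, 4)
  )
  mat <- matrix(rnorm(4 * 20, 100), nrow = 4)
  toy_conds <- list(faces = "identity1", cups = "cup1")
  glm <- fit_block_glm(run_from_matrix(mat), sched, conditions = toy_conds)
  expect_true(all(contrast_map(glm, c(0, 0))$t == 0))
  # adding a constant to every time series leaves t unchanged
  glm2 <- fit_block_glm(run_from_matrix(mat + 50), sched, conditions = toy_conds)
  expect_equal(contrast_map(glm, c(1, -1))$t,
    contrast_map(glm2, c(1, -1))$t,
    tolerance = 1e-8
  )
  expect_error(contrast_map(glm, c(1, 0, 0)), "weights")
  # rank-deficient design is named
  sched_dup <- manual_schedule(
    c("identity1", "fixation", "identity1", "fixation"), c(6, 4, 6, 4)
  )
  expect_error(
    fit_block_glm(run_from_matrix(mat), sched_dup,
      conditions = list(a = "identity1", b = "identity1")
    ),
    "collinear"
  )
})

test_that("faces > cups t is positive inside a synthetic face region", {
  p <- tiny_synth(identity_effect = 0, n_sessions = 1)
  sim <- simulate_subject(p, seed = 4)
  glm <- fit_block_glm(sim$runs[[1]], sim$schedules[[1]], hrf = p$hrf)
  map <- contrast_map(glm, c(1, -1))
  face_t <- map$t[sim$ground_truth$face_region$coords]
  expect_true(all(face_t > 3))
  cup_t <- map$t[sim$ground_truth$cup_region$coords]
  expect_true(all(cup_t < -3))
})

test_that("plateau PSC matches a hand-computed convolution oracle", {
  # constant series -> zero PSC everywhere
  sched <- manual_schedule(
    rep(c("identity1", "fixation"), 5), rep(c(8, 4), 5)
  )
  const_run <- run_from_matrix(matrix(7, 1, 60))
  psc0 <- plateau_psc(const_run, sched,
    conditions = "identity1", lag_trs = 0
  )
  expect_equal(psc0$conditions$identity1$plateau, 0)
  expect_equal(psc0$plateau_trs, 4:10) # 7 samples, TR 4..10 inclusive
  expect_length(psc0$plateau_trs, 7)

  # noiseless boxcar of amplitude a on baseline b: oracle = direct
  # convolution arithmetic on the emitted design
  a <- 3
  b <- 100
  kernel <- hrf_kernel(hrf_params(), 2)
  box <- numeric(60)
  for (r in which(sched$condition == "identity1")) {
    box[sched$onset_tr[r] + 0:7] <- 1
  }
  neural <- a * box
  sig <- numeric(60)
  for (t in 1:60) {
    for (u in 1:t) {
      if (t - u + 1 <= length(kernel)) {
        sig[t] <- sig[t] + neural[u] * kernel[t - u + 1]
      }
    }
  }
  series <- sig + b
  run <- run_from_matrix(matrix(series, 1))
  psc <- plateau_psc(run, sched, conditions = "identity1", lag_trs = 0)
  fix_trs <- unlist(lapply(which(sched$condition == "fixation"), function(r) {
    sched$onset_tr[r] + 0:3
  }))
  baseline <- mean(series[fix_trs])
  locked <- rowMeans(vapply(
    which(sched$condition == "identity1"),
    function(r) series[sched$onset_tr[r] + 0:11], numeric(12)
  ))
  expected <- mean(100 * (locked[4:10] - baseline) / baseline)
  expect_equal(psc$conditions$identity1$plateau, expected, tolerance = 1e-10)
  expect_error(
    plateau_psc(run, sched, conditions = "cup1"),
    "absent"
  )
})
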