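test_that("preprocessing removes trends and standardizes", {
  # pure linear ramp -> all zeros after detrending
  ramp <- matrix(seq_len(50), nrow = 1) * 3 + 7
  pre <- preprocess_session(run_from_matrix(ramp), decode_config(lag_trs = 0))
  expect_equal(max(abs(pre$data)), 0, tolerance = 1e-10)
  expect_equal(pre$flagged_voxels, 1L) # zero variance after detrend

  set.seed(31)
  mat <- matrix(rnorm(5 * 60, 100), nrow = 5)
  cfg <- decode_config(lag_trs = 0)
  pre <- preprocess_session(run_from_matrix(mat), cfg)
  expect_equal(unname(rowMeans(pre$data)), rep(0, 5), tolerance = 1e-10)
  expect_equal(unname(apply(pre$data, 1, sd)), rep(1, 5), tolerance = 1e-10)
})

test_that("preprocessing equals the naive step-by-step oracle", {
  set.seed(32)
  mat <- matrix(rnorm(4 * 40, 100, 3), nrow = 4)
  cfg <- decode_config(lag_trs = 2)
  pre <- preprocess_session(run_from_matrix(mat), cfg)
  expect_equal(ncol(pre$data), 38) # trailing lag samples dropped
  expect_equal(unname(pre$data), unname(oracle_preprocess(mat, 2)),
    tolerance = 1e-10
  )
  expect_error(
    preprocess_session(run_from_matrix(mat[, 1:2, drop = FALSE]), cfg),
    "shorter"
  )
})

test_that("block patterns average 6 of 8 TRs and zero out condition means", {
  sched <- manual_schedule(
    c(
      "identity1", "identity2", "fixation",
      "identity2", "identity1", "fixation"
    ),
    c(8, 8, 4, 8, 8, 4)
  )
  set.seed(33)
  mat <- matrix(rnorm(3 * 40, 100), nrow = 3)
  cfg <- decode_config(lag_trs = 0)
  pre <- preprocess_session(run_from_matrix(mat), cfg)
  ps <- extract_block_patterns(pre, sched, cfg = cfg)
  expect_equal(dim(ps$patterns), c(4, 3))
  expect_true(all(ps$trs_averaged == 6))
  # per condition the grand mean over voxels x blocks is zero
  for (cond in unique(ps$labels)) {
    expect_equal(mean(ps$patterns[ps$labels == cond, ]), 0, tolerance = 1e-12)
  }
  # hand-computed oracle on one block: mean of TRs 3..8 minus condition mean
  raw_avg <- function(r) rowMeans(pre$data[, sched$onset_tr[r] + 2:7])
  id1_mean <- mean(c(raw_avg(1), raw_avg(5)))
  expect_equal(ps$patterns[1, ], raw_avg(1) - id1_mean, tolerance = 1e-12)

  # identical constant patterns collapse to zero after mean subtraction
  const <- run_from_matrix(matrix(rep(c(1, 2, 3), 40), nrow = 3))
  pre_c <- preprocess_session(const, cfg)
  ps_c <- extract_block_patterns(pre_c, sched, cfg = cfg)
  expect_equal(max(abs(ps_c$patterns)), 0, tolerance = 1e-10)

  expect_error(
    extract_block_patterns(pre, sched, cfg = decode_config(discard_trs = 8)),
    "shorter"
  )
})

test_that("LOSO decoding: folds, separability, and permutation null", {
  make_sets <- function(sep, seeds) {
    lapply(seeds, function(s) {
      set.seed(s)
      pats <- matrix(rnorm(10 * 6), 10, 6)
      labels <- rep(c("identity1", "identity2"), each = 5)
      pats[labels == "identity2", 1] <-
        pats[labels == "identity2", 1] + sep
      structure(
        list(patterns = pats, labels = labels, session_id = s),
        class = "pattern_set"
      )
    })
  }
  res <- loso_decode(make_sets(50, 1:5))
  expect_equal(res$n_folds, 5)
  expect_length(res$fold_accuracy, 5)
  expect_equal(res$accuracy, 1.0) # linearly separable
  # label permutation within session -> chance on average
  accs <- vapply(1:500, function(seed) {
    sets <- make_sets(50, seed * 10 + 1:3)
    sets <- lapply(sets, function(s) {
      set.seed(seed + s$session_id)
      s$labels <- sample(s$labels)
      while (length(unique(s$labels[1:5])) == 1) s$labels <- sample(s$labels)
      s
    })
    loso_decode(sets)$accuracy
  }, numeric(1))
  expect_lte(abs(mean(accs) - 0.5), 3 * sd(accs) / sqrt(length(accs)))

  expect_error(loso_decode(make_sets(1, 1)), "2 sessions")
  one_class <- make_sets(1, 1:2)
  one_class[[1]]$labels <- rep("identity1", 10)
  expect_error(loso_decode(one_class), "lacks")
})

test_that("accuracy is invariant to a session-wide scalar offset", {
  p <- tiny_synth(identity_effect = 0.4, n_sessions = 4)
  sim <- simulate_subject(p, seed = 5)
  roi <- sim$ground_truth$face_region
  cfg <- decode_config()
  base <- decode_roi(sim$runs, sim$schedules, roi, cfg)$accuracy
  # shift all patterns of session 2 by a constant after preprocessing:
  # equivalent path, using extract + manual offset before mean subtraction
  sets <- mapply(function(run, sched) {
    pre <- preprocess_session(run, cfg, roi)
    extract_block_patterns(pre, sched,
      classes = cfg$class_pair, cfg = cfg,
      subtract_condition_mean = FALSE
    )
  }, sim$runs, sim$schedules, SIMPLIFY = FALSE)
  sets[[2]]$patterns <- sets[[2]]$patterns + 11.5
  sets <- lapply(sets, function(s) {
    for (cond in unique(s$labels)) {
      sel <- s$labels == cond
      s$patterns[sel, ] <- s$patterns[sel, , drop = FALSE] -
        mean(s$patterns[sel, ])
    }
    s
  })
  expect_equal(loso_decode(sets, cfg)$accuracy, base)
})

test_that("no leakage: preprocessing statistics are session-local", {
  # altering session 2's data leaves session 1's patterns bit-identical
  p <- tiny_synth(n_sessions = 2)
  sim <- simulate_subject(p, seed = 6)
  roi <- sim$ground_truth$face_region
  cfg <- decode_config()
  pats1 <- function(runs) {
    pre <- preprocess_session(runs[[1]], cfg, roi)
    extract_block_patterns(pre, sim$schedules[[1]], cfg = cfg)$patterns
  }
  before <- pats1(sim$runs)
  sim$runs[[2]]$data <- sim$runs[[2]]$data * 5 + 3
  expect_identical(before, pats1(sim$runs))
})
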