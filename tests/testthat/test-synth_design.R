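test_that("default session has the stated block composition", {
  sched <- generate_session_schedule(design_params(), seed = 1)
  sup <- facemvpa:::superordinate(sched$condition)
  expect_equal(sum(sup == "faces"), 10)
  expect_equal(sum(sup == "cups"), 10)
  expect_equal(sum(sup == "fixation"), 10)
  for (cond in c("identity1", "identity2", "cup1", "cup2")) {
    expect_equal(sum(sched$condition == cond), 5)
  }
  expect_true(all(sched$duration_trs[sup != "fixation"] == 8))
  expect_true(all(sched$duration_trs[sup == "fixation"] == 4))
  # total task duration: oracle = sum of block durations of the emitted schedule
  expect_equal(attr(sched, "n_trs"), sum(sched$duration_trs))
  expect_equal(attr(sched, "n_trs"), 200)
})

test_that("schedules are contiguous, alternating and deterministic over seeds", {
  for (seed in 1:100) {
    sched <- generate_session_schedule(design_params(), seed = seed)
    # non-overlapping and contiguous in time
    expect_equal(
      sched$onset_tr,
      cumsum(c(1L, sched$duration_trs[-nrow(sched)]))
    )
    # triplet structure: every third block is fixation, the two stimulation
    # blocks of a triplet span both superordinate categories
    sup <- facemvpa:::superordinate(sched$condition)
    trip <- matrix(sup, nrow = 3)
    expect_true(all(trip[3, ] == "fixation"))
    expect_true(all(apply(trip[1:2, , drop = FALSE], 2, function(x) {
      setequal(x, c("faces", "cups"))
    })))
    # no two consecutive non-fixation blocks share a category
    nf <- sup[sup != "fixation"]
    runs <- rle(nf)$lengths
    expect_true(all(runs <= 2) || all(diff(which(sup == "fixation")) == 3))
    # counterbalancing: half the triplets are faces-first
    expect_equal(sum(trip[1, ] == "faces"), 5)
  }
  s1 <- generate_session_schedule(design_params(), seed = 42)
  s2 <- generate_session_schedule(design_params(), seed = 42)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
})

test_that("degenerate and invalid designs are handled", {
  empty <- generate_session_schedule(
    design_params(blocks_per_condition = 0), seed = 1
  )
  expect_equal(nrow(empty), 0)
  expect_equal(attr(empty, "n_trs"), 0)
  expect_error(design_params(block_seconds = 15), "divisible")
  expect_error(design_params(stim_seconds = 0.4), "divide")
  expect_error(design_params(tr_seconds = 0), "positive")
})

test_that("trial sequences satisfy the one-back construction", {
  sched <- generate_session_schedule(design_params(), seed = 3)
  trials <- generate_trial_sequence(sched, seed = 3)
  expect_length(trials, 20) # stimulation blocks only
  for (blk in trials) {
    expect_equal(nrow(blk), 16)
    expect_true(all(blk$image_id %in% 1:8))
    k <- sum(blk$is_oneback_target)
    expect_true(k >= 0 && k <= 4)
    tgt <- which(blk$is_oneback_target)
    expect_true(all(tgt >= 2))
    if (length(tgt) > 1) expect_true(all(diff(tgt) > 1))
    for (t in 2:16) {
      if (blk$is_oneback_target[t]) {
        expect_equal(blk$image_id[t], blk$image_id[t - 1])
      } else {
        expect_false(blk$image_id[t] == blk$image_id[t - 1])
      }
    }
    expect_true(all(abs(blk$jitter_x) <= 20 & abs(blk$jitter_y) <= 20))
  }
  expect_identical(trials, generate_trial_sequence(sched, seed = 3))
})

test_that("one-back target counts stay in [0, 4] over many seeded blocks", {
  # oracle: exhaustive count over generated blocks (500 sessions x 20 blocks)
  sched <- generate_session_schedule(design_params(), seed = 1)
  counts <- unlist(lapply(1:500, function(seed) {
    vapply(
      generate_trial_sequence(sched, seed = seed),
      function(blk) sum(blk$is_oneback_target), integer(1)
    )
  }))
  expect_length(counts, 10000)
  expect_true(all(counts >= 0 & counts <= 4))
  expect_setequal(unique(counts), 0:4)
})

test_that("schedule sidecars round-trip losslessly", {
  scheds <- lapply(1:3, function(s) {
    generate_session_schedule(design_params(), seed = s, session_id = s)
  })
  path <- withr::local_tempfile(fileext = ".csv")
  write_schedule_csv(scheds, path)
  back <- read_schedule_csv(path)
  expect_length(back, 3)
  for (i in 1:3) {
    expect_equal(as.data.frame(back[[i]]), as.data.frame(scheds[[i]]))
    expect_equal(attr(back[[i]], "session_id"), attr(scheds[[i]], "session_id"))
    expect_equal(attr(back[[i]], "n_trs"), attr(scheds[[i]], "n_trs"))
  }
  jpath <- withr::local_tempfile(fileext = ".json")
  p <- design_params(pad_trs_start = 2)
  write_design_json(p, jpath)
  expect_equal(read_design_json(jpath), p)
})
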