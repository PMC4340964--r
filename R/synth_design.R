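#' Block-design parameters
#'
#' The stated experimental design: TR 2 s; 16 s stimulation blocks (8 TRs) of
#' four conditions (two face identities, two cup types), 8 s fixation blocks;
#' per session 10 face blocks (5 per identity), 10 cup blocks (5 per type) and
#' 10 fixation blocks arranged in triplets faces-cups-fixation or
#' cups-faces-fixation; 16 one-second trials per block (0.3 s stimulus +
#' 0.7 s inter-stimulus interval) with 0-4 one-back repeat targets and a
#' spatial jitter of up to 20 pixels per axis.
#'
#' `pad_trs_start`/`pad_trs_end` add lead-in/lead-out fixation TRs: the
#' printed total session length exceeds the sum of the block durations by
#' 12 s, which the block table does not account for, so padding is exposed as
#' configuration with default 0 rather than guessed.
#'
#' @param tr_seconds repetition time in seconds.
#' @param block_seconds stimulation block duration (must be a multiple of
#'   `tr_seconds`).
#' @param fixation_seconds fixation block duration.
#' @param blocks_per_condition stimulation blocks per condition per session.
#' @param n_conditions number of stimulation conditions (2 identities + 2 cup
#'   types).
#' @param stim_seconds,isi_seconds trial stimulus and inter-stimulus times;
#'   their sum must divide `block_seconds`.
#' @param max_oneback_targets maximum one-back targets per block.
#' @param jitter_pixels maximum absolute stimulus jitter per axis, pixels.
#' @param pad_trs_start,pad_trs_end extra fixation TRs before/after the task.
#' @return object of class `design_params`.
#' @export
design_params <- function(tr_seconds = 2, block_seconds = 16,
                          fixation_seconds = 8, blocks_per_condition = 5,
                          n_conditions = 4, stim_seconds = 0.3,
                          isi_seconds = 0.7, max_oneback_targets = 4,
                          jitter_pixels = 20, pad_trs_start = 0,
                          pad_trs_end = 0) {
  p <- structure(
    list(
      tr_seconds = tr_seconds, block_seconds = block_seconds,
      fixation_seconds = fixation_seconds,
      blocks_per_condition = blocks_per_condition,
      n_conditions = n_conditions, stim_seconds = stim_seconds,
      isi_seconds = isi_seconds, max_oneback_targets = max_oneback_targets,
      jitter_pixels = jitter_pixels, pad_trs_start = pad_trs_start,
      pad_trs_end = pad_trs_end
    ),
    class = "design_params"
  )
  validate_design_params(p)
  p
}

validate_design_params <- function(p) {
  if (p$tr_seconds <= 0) stop_config("tr_seconds must be positive")
  if (p$block_seconds %% p$tr_seconds != 0) {
    stop_config("block_seconds must be divisible by tr_seconds")
  }
  if (p$fixation_seconds %% p$tr_seconds != 0) {
    stop_config("fixation_seconds must be divisible by tr_seconds")
  }
  trial <- p$stim_seconds + p$isi_seconds
  n_trials <- p$block_seconds / trial
  if (abs(n_trials - round(n_trials)) > 1e-9) {
    stop_config("stim_seconds + isi_seconds must divide block_seconds")
  }
  if (p$blocks_per_condition < 0) stop_config("blocks_per_condition must be >= 0")
  if (p$max_oneback_targets < 0) stop_config("max_oneback_targets must be >= 0")
  if (p$pad_trs_start < 0 || p$pad_trs_end < 0) stop_config("padding must be >= 0")
  invisible(p)
}

block_trs <- function(p) as.integer(p$block_seconds / p$tr_seconds)
fixation_trs <- function(p) as.integer(p$fixation_seconds / p$tr_seconds)
trials_per_block <- function(p) {
  as.integer(round(p$block_seconds / (p$stim_seconds + p$isi_seconds)))
}

#' Generate one session's block schedule
#'
#' Blocks are arranged in triplets of faces-cups-fixation or
#' cups-faces-fixation so that two blocks of the same superordinate category
#' are never consecutive. Counterbalancing: half the triplets are faces-first,
#' half cups-first, in a seeded random order. Identity (and cup-type)
#' assignment within the face (cup) blocks is a seeded random permutation of
#' 5 + 5 labels.
#'
#' @param params a [design_params()] object.
#' @param seed integer; the schedule is deterministic given the seed.
#' @return a `block_schedule`: data frame with columns `condition`,
#'   `onset_tr` (1-based TR index), `duration_trs`, plus attributes
#'   `session_id`, `n_trs` and `params`.
#' @export
generate_session_schedule <- function(params = design_params(), seed = 1,
                                      session_id = 1L) {
  validate_design_params(params)
  bpc <- params$blocks_per_condition
  n_triplets <- bpc * 2L # one face + one cup block per triplet
  if (n_triplets == 0L) {
    sched <- data.frame(
      condition = character(0), onset_tr = integer(0),
      duration_trs = integer(0), stringsAsFactors = FALSE
    )
    return(new_block_schedule(sched, session_id, params))
  }
  with_seed(seed, {
    faces_first <- sample(rep(c(TRUE, FALSE), length.out = n_triplets))
    identities <- sample(rep(FACE_CONDITIONS, each = bpc))
    cups <- sample(rep(CUP_CONDITIONS, each = bpc))
  })
  btr <- block_trs(params)
  ftr <- fixation_trs(params)
  conds <- character(0)
  durs <- integer(0)
  for (i in seq_len(n_triplets)) {
    pair <- if (faces_first[i]) c(identities[i], cups[i]) else c(cups[i], identities[i])
    conds <- c(conds, pair, "fixation")
    durs <- c(durs, btr, btr, ftr)
  }
  onsets <- params$pad_trs_start + cumsum(c(0L, durs[-length(durs)])) + 1L
  sched <- data.frame(
    condition = conds, onset_tr = as.integer(onsets),
    duration_trs = as.integer(durs), stringsAsFactors = FALSE
  )
  new_block_schedule(sched, session_id, params)
}

new_block_schedule <- function(df, session_id, params) {
  n_trs <- params$pad_trs_start + sum(df$duration_trs) + params$pad_trs_end
  structure(df,
    class = c("block_schedule", "data.frame"),
    session_id = as.integer(session_id), n_trs = as.integer(n_trs),
    params = params
  )
}

#' @export
print.block_schedule <- function(x, ...) {
  cat(sprintf(
    "<block_schedule> session %d: %d blocks, %d TRs\n",
    attr(x, "session_id"), nrow(x), attr(x, "n_trs")
  ))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Generate within-block trial sequences
#'
#' Each stimulation block gets 16 trials drawn from its condition's 8 image
#' identifiers. The number of one-back targets per block is uniform on
#' 0..`max_oneback_targets`; a target repeats the immediately preceding
#' image, targets are never adjacent to one another, and non-target trials
#' never accidentally repeat the previous image. Each trial gets an integer
#' spatial jitter uniform on `[-jitter_pixels, jitter_pixels]` per axis.
#'
#' @param schedule a `block_schedule`.
#' @param seed integer seed; sequences are deterministic given the seed.
#' @param n_images images available per condition.
#' @return list with one data frame per stimulation block (columns
#'   `image_id`, `is_oneback_target`, `jitter_x`, `jitter_y`), named by the
#'   block's row index in the schedule.
#' @export
generate_trial_sequence <- function(schedule, seed = 1, n_images = 8) {
  params <- attr(schedule, "params")
  n_trials <- trials_per_block(params)
  stim_rows <- which(schedule$condition != "fixation")
  with_seed(seed, {
    out <- lapply(stim_rows, function(i) {
      k <- sample(0:params$max_oneback_targets, 1)
      targets <- sample_target_positions(k, n_trials)
      ids <- integer(n_trials)
      ids[1] <- sample.int(n_images, 1)
      for (t in 2:n_trials) {
        if (targets[t]) {
          ids[t] <- ids[t - 1]
        } else {
          ids[t] <- sample(setdiff(seq_len(n_images), ids[t - 1]), 1)
        }
      }
      data.frame(
        image_id = ids,
        is_oneback_target = targets,
        jitter_x = sample(-params$jitter_pixels:params$jitter_pixels, n_trials,
          replace = TRUE
        ),
        jitter_y = sample(-params$jitter_pixels:params$jitter_pixels, n_trials,
          replace = TRUE
        ),
        stringsAsFactors = FALSE
      )
    })
  })
  names(out) <- as.character(stim_rows)
  out
}

# k target positions among trials 2..n, no two adjacent (rejection sampling;
# k <= 4 of 15 candidate slots, so acceptance is fast).
sample_target_positions <- function(k, n_trials) {
  targets <- logical(n_trials)
  if (k == 0) {
    return(targets)
  }
  repeat {
    pos <- sort(sample(2:n_trials, k))
    if (k == 1 || all(diff(pos) > 1)) break
  }
  targets[pos] <- TRUE
  targets
}

#' Read/write schedule sidecars
#'
#' The sidecar is a CSV with columns `session_id`, `condition`, `onset_tr`,
#' `duration_trs`; one file can hold several sessions. Round-trips are
#' lossless given the design parameters.
#'
#' @param schedules list of `block_schedule` objects.
#' @param path output CSV path.
#' @export
write_schedule_csv <- function(schedules, path) {
  if (inherits(schedules, "block_schedule")) schedules <- list(schedules)
  rows <- do.call(rbind, lapply(schedules, function(s) {
    cbind(session_id = attr(s, "session_id"), as.data.frame(s))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @param params the [design_params()] the schedules were generated under.
#' @export
read_schedule_csv <- function(path, params = design_params()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$session_id), function(d) {
    d <- d[order(d$onset_tr), c("condition", "onset_tr", "duration_trs")]
    rownames(d) <- NULL
    new_block_schedule(d, d$session_id[1] %||% unique(df$session_id)[1], params)
  }) -> out
  # session id column was dropped above; recover from split names
  for (i in seq_along(out)) {
    attr(out[[i]], "session_id") <- as.integer(names(out)[i])
  }
  unname(out)
}

#' Serialize design parameters as JSON
#' @export
write_design_json <- function(params, path) {
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_design_json
#' @export
read_design_json <- function(path) {
  do.call(design_params, jsonlite::read_json(path, simplifyVector = TRUE))
}
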