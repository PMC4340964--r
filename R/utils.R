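#' @useDynLib facemvpa, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats pbeta qnorm rnorm runif sd var
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library functions never disturb user randomness.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("facemvpa_config_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Condition label vocabulary shared across modules.
FACE_CONDITIONS <- c("identity1", "identity2")
CUP_CONDITIONS <- c("cup1", "cup2")
TASK_CONDITIONS <- c(FACE_CONDITIONS, CUP_CONDITIONS)

superordinate <- function(condition) {
  ifelse(condition %in% FACE_CONDITIONS, "faces",
    ifelse(condition %in% CUP_CONDITIONS, "cups", "fixation")
  )
}
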