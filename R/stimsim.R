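#' Stimulus image sets
#'
#' A set of grayscale images of identical dimensions (each identity or cup
#' type is represented by 8 different images in the emulated experiment).
#' Images are numeric matrices on any common intensity scale — Pearson
#' correlation is invariant to affine rescaling, so 0-255 versus 0-1 is
#' cosmetic.
#'
#' @param images list of numeric matrices with identical dimensions.
#' @param label set name.
#' @export
image_set <- function(images, label = "set") {
  if (length(images) < 2) stop_config("an image set needs n >= 2 images")
  d <- dim(images[[1]])
  for (im in images) {
    if (!is.matrix(im) || !identical(dim(im), d)) {
      stop_config("all images must be matrices of identical dimensions")
    }
  }
  structure(list(images = images, label = label, dim = d),
    class = "image_set"
  )
}

#' Pixel correlation between two images
#'
#' Pearson correlation over flattened pixel intensities.
#' @param a,b numeric matrices of identical dimensions.
#' @return correlation in `[-1, 1]`, or NA with a warning when an image is
#'   constant (undefined correlation).
#' @export
pixel_correlation <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop_config("image dimensions differ")
  va <- as.numeric(a)
  vb <- as.numeric(b)
  if (sd(va) == 0 || sd(vb) == 0) {
    warning("constant image: pixel correlation undefined, reported as NA")
    return(NA_real_)
  }
  stats::cor(va, vb)
}

within_set_correlations <- function(s) {
  n <- length(s$images)
  out <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      out <- c(out, pixel_correlation(s$images[[i]], s$images[[j]]))
    }
  }
  out
}

between_set_correlations <- function(s1, s2) {
  out <- numeric(0)
  for (a in s1$images) {
    for (b in s2$images) {
      out <- c(out, pixel_correlation(a, b))
    }
  }
  out
}

#' Compare low-level similarity within and between two image sets
#'
#' Computes all within-set pairwise pixel correlations (n(n-1)/2 per set;
#' 28 for n = 8) and all between-set correlations (n1 n2; 64 for 8 x 8),
#' then Welch two-tailed tests of: set 1 within vs between, set 2 within vs
#' between, and within vs within. A face-like stimulus pair should show no
#' significant within/between difference; a systematic low-level difference
#' between the sets shows up as lower between-set correlation.
#'
#' @param s1,s2 [image_set()] objects with equal image dimensions.
#' @return `similarity_report`: correlation vectors, means, standard errors
#'   of the mean and the three Welch tests.
#' @export
compare_sets <- function(s1, s2) {
  within1 <- within_set_correlations(s1)
  within2 <- within_set_correlations(s2)
  between <- between_set_correlations(s1, s2)
  sem <- function(x) sd(x) / sqrt(length(x))
  structure(
    list(
      labels = c(s1$label, s2$label),
      within1 = within1, within2 = within2, between = between,
      means = c(
        within1 = mean(within1), within2 = mean(within2),
        between = mean(between)
      ),
      sems = c(
        within1 = sem(within1), within2 = sem(within2),
        between = sem(between)
      ),
      tests = list(
        within1_vs_between = welch_t(within1, between, tail = "two"),
        within2_vs_between = welch_t(within2, between, tail = "two"),
        within1_vs_within2 = welch_t(within1, within2, tail = "two")
      )
    ),
    class = "similarity_report"
  )
}

#' @export
print.similarity_report <- function(x, ...) {
  cat(sprintf(
    "<similarity_report> %s vs %s\n", x$labels[1], x$labels[2]
  ))
  cat(sprintf(
    "  within %s:  r = %.3f (SEM %.3f), %d pairs\n",
    x$labels[1], x$means["within1"], x$sems["within1"], length(x$within1)
  ))
  cat(sprintf(
    "  within %s:  r = %.3f (SEM %.3f), %d pairs\n",
    x$labels[2], x$means["within2"], x$sems["within2"], length(x$within2)
  ))
  cat(sprintf(
    "  between:   r = %.3f (SEM %.3f), %d pairs\n",
    x$means["between"], x$sems["between"], length(x$between)
  ))
  for (nm in names(x$tests)) {
    tst <- x$tests[[nm]]
    cat(sprintf(
      "  %s: t(%.2f) = %.2f, p = %.3g\n", nm, tst$df, tst$statistic, tst$p
    ))
  }
  invisible(x)
}

#' Write a similarity report to JSON and CSV
#'
#' @param report a `similarity_report`.
#' @param json_path,csv_path output paths (NULL to skip either).
#' @export
write_similarity_report <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(
        labels = report$labels, means = as.list(report$means),
        sems = as.list(report$sems),
        tests = lapply(report$tests, function(t) {
          list(statistic = t$statistic, df = t$df, p = t$p, tail = t$tail)
        })
      ),
      json_path, auto_unbox = TRUE, digits = NA
    )
  }
  if (!is.null(csv_path)) {
    df <- data.frame(
      comparison = names(report$tests),
      statistic = vapply(report$tests, `[[`, 0, "statistic"),
      df = vapply(report$tests, `[[`, 0, "df"),
      p = vapply(report$tests, `[[`, 0, "p")
    )
    utils::write.csv(df, csv_path, row.names = FALSE)
  }
  invisible(report)
}

#' Generate a synthetic stimulus image set
#'
#' Stand-in for real photograph sets (none ship with the package): each set
#' shares a smooth random base image (the "identity") and each exemplar adds
#' seeded exemplar-specific smooth variation, so within-set correlations
#' exceed between-set ones by a controllable margin.
#'
#' @param n images per set.
#' @param dim image height/width, pixels.
#' @param exemplar_sd sd of exemplar variation relative to base sd 1.
#' @param seed integer seed.
#' @param base optional base image to share with another set.
#' @return an [image_set()]; the base is attached as attribute `base`.
#' @export
synth_image_set <- function(n = 8, dim = c(32, 32), exemplar_sd = 0.4,
                            seed = 1, base = NULL, label = "synthetic") {
  smooth_noise <- function() {
    m <- matrix(rnorm(prod(dim)), dim[1], dim[2])
    # crude separable smoothing for spatial coherence
    k <- c(1, 4, 6, 4, 1) / 16
    m <- apply(m, 2, function(col) stats::filter(col, k, circular = TRUE))
    t(apply(m, 1, function(row) stats::filter(row, k, circular = TRUE)))
  }
  with_seed(seed, {
    if (is.null(base)) base <- smooth_noise()
    images <- lapply(seq_len(n), function(i) {
      im <- base + exemplar_sd * smooth_noise()
      (im - min(im)) / (max(im) - min(im)) * 255
    })
  })
  out <- image_set(images, label)
  attr(out, "base") <- base
  out
}

#' Read and write portable graymaps (PGM)
#'
#' Minimal PGM support (ASCII `P2` and binary `P5`, maxval <= 255) so image
#' sets can round-trip through plain files without an image library.
#'
#' @param path file path.
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2)
  if (!magic %in% c("P2", "P5")) stop_config("not a PGM file: ", path)
  tokens <- character(0)
  # header: width, height, maxval; '#' comments allowed
  while (length(tokens) < 3) {
    ch <- readChar(con, 1)
    if (ch == "#") {
      while (readChar(con, 1) != "\n") NULL
    } else if (grepl("[0-9]", ch)) {
      tok <- ch
      repeat {
        nxt <- readChar(con, 1)
        if (!grepl("[0-9]", nxt)) break
        tok <- paste0(tok, nxt)
      }
      tokens <- c(tokens, tok)
    }
  }
  w <- as.integer(tokens[1])
  h <- as.integer(tokens[2])
  if (magic == "P5") {
    vals <- as.integer(readBin(con, "raw", w * h))
  } else {
    vals <- scan(con, integer(), n = w * h, quiet = TRUE)
  }
  # PGM is row-major (rows = image lines); store as h x w matrix
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' @rdname read_pgm
#' @param image numeric matrix (values clamped to 0..255 and rounded).
#' @param ascii write ASCII `P2` (TRUE) or binary `P5`.
#' @export
write_pgm <- function(image, path, ascii = TRUE) {
  vals <- round(pmin(pmax(image, 0), 255))
  h <- nrow(image)
  w <- ncol(image)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(w, h), "255"), con)
    utils::write.table(vals, con,
      row.names = FALSE, col.names = FALSE
    )
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(paste0("P5\n", w, " ", h, "\n255\n"), con, eos = NULL)
    writeBin(as.raw(as.integer(t(vals))), con)
  }
  invisible(path)
}
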