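#' @include AllClasses.R
NULL

#' Angular velocity from joint angles
#'
#' Differentiates the angle matrix of a recording by central differences,
#' with one-sided differences at the first and last sample, so the output
#' has the same number of rows as the input.  Units are degrees/second
#' (degree increments times the sampling rate).
#'
#' An optional moving-average smoother (odd window, in samples) can be
#' applied to the angles before differentiation; it is off by default.
#'
#' @param recording a \code{\linkS4class{RawRecording}}.
#' @param smoothWindow odd integer moving-average window applied to the
#'   angles before differencing, or \code{NULL} (default) for none.
#' @return numeric matrix, time x 10, degrees/second.
#' @examples
#' ramp <- RawRecording(matrix(seq(0, 10, length.out = 11), 11, 10), rate = 125)
#' computeVelocity(ramp)[5, 1]  # 125 deg/s on a 0..10 degree ramp
#' @export
computeVelocity <- function(recording, smoothWindow = NULL) {
  stopifnot(is(recording, "RawRecording"))
  a <- recording@angles
  if (nrow(a) < 2L)
    stop("computeVelocity: recording must have at least 2 samples")
  if (!is.null(smoothWindow)) {
    w <- as.integer(smoothWindow)
    if (w < 1L || w %% 2L == 0L)
      stop("smoothWindow must be an odd positive integer")
    if (w > 1L) {
      k <- rep(1 / w, w)
      a <- apply(a, 2, function(col)
        stats::filter(col, k, sides = 2) |>
          (\(f) { f[is.na(f)] <- col[is.na(f)]; as.numeric(f) })())
    }
  }
  n <- nrow(a)
  v <- matrix(0, n, ncol(a), dimnames = dimnames(a))
  if (n > 2L)
    v[2:(n - 1L), ] <- (a[3:n, , drop = FALSE] - a[1:(n - 2L), , drop = FALSE]) / 2
  v[1L, ] <- a[2L, ] - a[1L, ]
  v[n, ] <- a[n, ] - a[n - 1L, ]
  v * recording@rate
}

.segmentWindow <- function(vel, thresholdFraction, onsetMode) {
  av <- abs(vel)
  if (onsetMode == "global") {
    peak <- max(av)
    if (peak == 0)
      stop("segmentTrial: no movement (velocity is identically zero)")
    hit <- which(apply(av >= thresholdFraction * peak, 1L, any))
  } else {
    peaks <- apply(av, 2L, max)
    if (all(peaks == 0))
      stop("segmentTrial: no movement (velocity is identically zero)")
    use <- which(peaks > 0)
    hitm <- sweep(av[, use, drop = FALSE], 2L,
                  thresholdFraction * peaks[use], `>=`)
    hit <- which(apply(hitm, 1L, any))
  }
  c(min(hit), max(hit))
}

#' @rdname segmentTrial
#' @export
setMethod("segmentTrial", "RawRecording",
  function(x, thresholdFraction = 0.05,
           onsetMode = c("global", "per_joint")) {
    onsetMode <- match.arg(onsetMode)
    vel <- computeVelocity(x)
    w <- .segmentWindow(vel, thresholdFraction, onsetMode)
    new("GraspTrial",
        velocity = vel[w[1]:w[2], , drop = FALSE],
        onset = as.integer(w[1]), offset = as.integer(w[2]),
        rate = x@rate, subjectId = x@subjectId, objectId = x@objectId,
        graspType = x@graspType, repetition = x@repetition)
  })

#' @rdname segmentTrial
#' @export
setMethod("segmentTrial", "GraspTrial",
  function(x, thresholdFraction = 0.05,
           onsetMode = c("global", "per_joint")) {
    onsetMode <- match.arg(onsetMode)
    w <- .segmentWindow(x@velocity, thresholdFraction, onsetMode)
    new("GraspTrial",
        velocity = x@velocity[w[1]:w[2], , drop = FALSE],
        onset = x@onset + as.integer(w[1]) - 1L,
        offset = x@onset + as.integer(w[2]) - 1L,
        rate = x@rate, subjectId = x@subjectId, objectId = x@objectId,
        graspType = x@graspType, repetition = x@repetition)
  })

#' Zero-pad a segmented trial to the fixed profile length
#'
#' Grasp movements are represented on a common grid of \code{length} samples
#' (default 151, the number of 125 Hz samples in the longest grasp, 1.208 s);
#' shorter trials are padded with zero velocity at the tail.  A trial longer
#' than \code{length} is an error: the configured maximum must be raised to
#' the dataset-wide longest trial.
#'
#' @param trial a \code{\linkS4class{GraspTrial}}.
#' @param length target number of rows (default 151).
#' @return numeric matrix, \code{length} x 10, degrees/second; rows beyond
#'   the trial are exactly zero.
#' @export
padToFixed <- function(trial, length = 151L) {
  stopifnot(is(trial, "GraspTrial"))
  length <- as.integer(length)
  v <- trial@velocity
  if (nrow(v) > length)
    stop(sprintf(
      "padToFixed: trial has %d samples, longer than the fixed length %d",
      nrow(v), length))
  out <- matrix(0, length, ncol(v), dimnames = list(NULL, colnames(v)))
  out[seq_len(nrow(v)), ] <- v
  out
}

## ----------------------------------------------------------------- file I/O

.trialColumns <- function() c("subject", "object", "grasp_type", "repetition",
                              "rate", "t", jointLabels())

#' Read and write trial files
#'
#' Trials are stored as a single CSV per session: one row per time sample,
#' with columns \code{subject, object, grasp_type, repetition, rate, t}
#' followed by the ten joint-angle columns named by \code{\link{jointLabels}}
#' (degrees).  Rows belonging to one (subject, object, repetition) triple
#' form one recording, ordered by \code{t}.
#'
#' The round trip is lossless for labels, rate and angles at the stored
#' precision.
#'
#' @param path file path.
#' @param recordings list of \code{\linkS4class{RawRecording}}.
#' @param digits significant digits used when writing angles.
#' @return \code{readTrials}: a list of \code{RawRecording} (empty list for
#'   an empty file); \code{writeTrials}: \code{path}, invisibly.
#' @export
readTrials <- function(path) {
  if (!file.exists(path)) stop("readTrials: no such file: ", path)
  if (file.size(path) == 0) return(list())
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character")
  need <- .trialColumns()
  if (!identical(names(df), need))
    stop("readTrials: malformed header; expected columns ",
         paste(need, collapse = ","), " but found ",
         paste(names(df), collapse = ","))
  if (nrow(df) == 0) return(list())
  numcols <- c("rate", "t", jointLabels())
  for (cc in numcols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("readTrials: non-numeric value in column %s at data row %d",
                   cc, min(bad)))
    df[[cc]] <- v
  }
  key <- interaction(df$subject, df$object, df$repetition, drop = TRUE,
                     lex.order = TRUE)
  lapply(split(seq_len(nrow(df)), key), function(idx) {
    d <- df[idx[order(df$t[idx])], , drop = FALSE]
    m <- as.matrix(d[, jointLabels()])
    rownames(m) <- NULL
    RawRecording(m, rate = d$rate[1],
                 subjectId = d$subject[1], objectId = d$object[1],
                 graspType = d$grasp_type[1],
                 repetition = as.integer(d$repetition[1]))
  }) |> unname()
}

#' @rdname readTrials
#' @export
writeTrials <- function(recordings, path, digits = 10) {
  stopifnot(all(vapply(recordings, is, logical(1), "RawRecording")))
  rows <- lapply(recordings, function(r) {
    n <- nrow(r@angles)
    data.frame(subject = r@subjectId, object = r@objectId,
               grasp_type = r@graspType, repetition = r@repetition,
               rate = r@rate, t = seq_len(n) - 1L,
               signif(r@angles, digits), check.names = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- as.data.frame(stats::setNames(
      rep(list(numeric(0)), length(.trialColumns())), .trialColumns()))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
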