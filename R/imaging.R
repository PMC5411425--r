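#' @include render.R
NULL

.fingerDetectionError <- function(count) {
  stop(structure(class = c("fingerDetectionError", "error", "condition"),
                 list(message = sprintf(
                        "finger detection found %d peak(s), need 5", count),
                      call = sys.call(-1), count = count)))
}

.asEBImage <- function(mask) EBImage::Image(t(mask))

.largestComponent <- function(mask) {
  lab <- EBImage::bwlabel(.asEBImage(mask))
  m <- EBImage::imageData(lab)
  if (max(m) == 0) stop("segmentHand: no foreground component")
  keep <- which.max(tabulate(m[m > 0]))
  t(m == keep) * 1L
}

.fillHoles <- function(mask) {
  f <- EBImage::fillHull(EBImage::bwlabel(.asEBImage(mask)))
  t(EBImage::imageData(f) > 0) * 1L
}

#' Segment the hand from a chroma-keyed image
#'
#' Computes the standard green-screen alpha matte (foreground opacity
#' \code{1 - (G - max(R, B))}, clamped to 0..1), keeps the largest
#' connected component of the half-level-thresholded matte, fills interior
#' holes, and (optionally) rejects images whose principal axis tilts more
#' than \code{maxTilt} degrees from vertical -- the capture protocol fixes
#' hand orientation with a wristband and a fixed camera, so a large tilt
#' indicates a bad capture rather than something to correct.
#'
#' The returned mask is soft: interior pixels are 1, background 0, and
#' boundary pixels within one pixel of the component keep their full
#' fractional opacity.  Thresholding at 0.5 recovers the binary
#' silhouette; the fractional fringe carries the subpixel edge position
#' used by \code{\link{digitOutline}}, and is deliberately not floored --
#' truncating small fringe opacities would distort the reconstructed
#' subpixel edge.  Opacity away from the component is discarded entirely
#' (the largest-component rule), so stray background noise cannot leak in.
#'
#' @param image H x W x 3 numeric array in 0..1 (RGB).
#' @param greenDominance minimum opacity for a pixel to seed the
#'   foreground component (default 0.2; values below 0.5 defer to the
#'   half-level threshold).
#' @param maxTilt maximum principal-axis deviation from vertical, degrees;
#'   \code{NULL} disables the check.
#' @return numeric H x W matrix in 0..1 (hand = 1, soft edges).
#' @export
segmentHand <- function(image, greenDominance = 0.2, maxTilt = 15) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  alpha <- 1 - (image[, , 2] - pmax(image[, , 1], image[, , 3]))
  alpha <- pmin(pmax(alpha, 0), 1)       # matrix first: keeps dims
  bin <- (alpha >= max(greenDominance, 0.5)) * 1L
  if (!any(bin == 1L)) stop("segmentHand: no foreground component")
  comp <- .fillHoles(.largestComponent(bin))
  ## keep the component, its filled holes, and its soft one-pixel fringe
  ker <- EBImage::makeBrush(3, "box")
  support <- t(EBImage::imageData(EBImage::dilate(.asEBImage(comp), ker)))
  mask <- alpha * (support > 0)
  mask[comp == 1L & alpha < 0.5] <- 1
  if (!is.null(maxTilt)) {
    idx <- which(comp == 1L, arr.ind = TRUE)
    cc <- scale(idx, scale = FALSE)
    ev <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)$vectors[, 1]
    tilt <- abs(atan2(ev[2], ev[1])) * 180 / pi  # from vertical (row axis)
    tilt <- min(tilt, 180 - tilt)
    if (tilt > maxTilt)
      stop(sprintf(
        "segmentHand: principal axis tilted %.1f deg from vertical (max %g)",
        tilt, maxTilt))
  }
  mask
}

#' Crop the mask at the wrist
#'
#' Detects the wrist as the row of narrowest horizontal width within the
#' lower fraction of the hand component, provided that width is a genuine
#' neck (narrower than \code{neckRatio} times the component's median row
#' width); rows below the wrist line are removed (replaced by background).
#' Already-cropped masks have no neck and pass through unchanged, so the
#' operation is idempotent.  A \code{fixedRow} override keeps rows up to
#' and including that row instead of detecting.
#'
#' @param mask (soft) mask matrix from \code{\link{segmentHand}}; widths
#'   are measured on the half-level threshold.
#' @param fraction lower fraction of the component searched (default 0.25).
#' @param neckRatio neck acceptance ratio (default 0.8).
#' @param fixedRow optional fixed crop row (rows below are removed).
#' @return mask matrix of the same size, with attribute
#'   \code{"wristRow"} (NA when nothing was cropped).
#' @export
cropWrist <- function(mask, fraction = 0.25, neckRatio = 0.8,
                      fixedRow = NULL) {
  widths <- rowSums(mask >= 0.5)
  rows <- which(widths > 0)
  if (!length(rows)) stop("cropWrist: empty mask")
  if (!is.null(fixedRow)) {
    cut <- as.integer(fixedRow)
  } else {
    lower <- rows[rows > stats::quantile(rows, 1 - fraction)]
    if (!length(lower)) lower <- rows[length(rows)]
    wmin <- lower[which.min(widths[lower])]
    if (widths[wmin] >= neckRatio * stats::median(widths[rows])) {
      out <- mask
      attr(out, "wristRow") <- NA_integer_
      return(out)
    }
    cut <- wmin - 1L
  }
  out <- mask
  if (cut < nrow(mask)) out[(cut + 1L):nrow(mask), ] <- 0L
  attr(out, "wristRow") <- cut
  out
}

#' Centroid of a (possibly soft) mask
#'
#' Opacity-weighted mean of the foreground pixel coordinates, returned as
#' \code{c(x, y)} where x is the column index and y the row index
#' (image convention, y growing downward).  For a binary mask this is the
#' plain pixel centroid; soft edges contribute fractionally, making the
#' centroid subpixel-stable across resolutions.
#'
#' @param mask numeric matrix in 0..1.
#' @return numeric \code{c(x, y)}.
#' @export
maskCentroid <- function(mask) {
  tot <- sum(mask)
  if (tot <= 0) stop("maskCentroid: empty mask")
  rows <- seq_len(nrow(mask)); cols <- seq_len(ncol(mask))
  c(x = sum(colSums(mask) * cols) / tot,
    y = sum(rowSums(mask) * rows) / tot)
}

## bilinear interpolation of a matrix at (col, row) = (x, y) positions
.bilinearSample <- function(m, x, y) {
  x0 <- pmin(pmax(floor(x), 1), ncol(m) - 1L)
  y0 <- pmin(pmax(floor(y), 1), nrow(m) - 1L)
  fx <- pmin(pmax(x - x0, 0), 1); fy <- pmin(pmax(y - y0, 0), 1)
  m[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
    m[cbind(y0, x0 + 1)] * fx * (1 - fy) +
    m[cbind(y0 + 1, x0)] * (1 - fx) * fy +
    m[cbind(y0 + 1, x0 + 1)] * fx * fy
}

## farthest half-level crossing distance of rays cast from the centroid
## (pixel coordinates, angles in degrees, y measured upward on screen,
## i.e. against the row axis), measured on the bilinearly interpolated
## soft mask.  The 0.5 level of an antialiased coverage field sits on the
## true silhouette boundary independent of pixel size, which makes this
## measurement scale-invariant; the outermost coarse sample at or above
## the half level is refined by bisection to subpixel precision.
.rayEdgeDistance <- function(mask, centroid, angles, step = 0.25) {
  H <- nrow(mask); W <- ncol(mask)
  ts <- seq(step, sqrt(H^2 + W^2), by = step)
  r <- vapply(angles, function(a) {
    ux <- cos(a * pi / 180); uy <- -sin(a * pi / 180)
    xs <- centroid[1] + ts * ux; ys <- centroid[2] + ts * uy
    ok <- xs >= 1 & xs <= W & ys >= 1 & ys <= H
    v <- numeric(length(ts))
    v[ok] <- .bilinearSample(mask, xs[ok], ys[ok])
    idx <- which(v >= 0.5)
    if (!length(idx)) return(NA_real_)
    i <- max(idx)
    lo <- ts[i]
    if (i == length(ts)) return(lo)
    hi <- ts[i + 1L]
    for (it in 1:16) {
      mid <- (lo + hi) / 2
      if (.bilinearSample(mask, centroid[1] + mid * ux,
                          centroid[2] + mid * uy) >= 0.5)
        lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
  miss <- !is.finite(r)
  if (all(miss)) stop("no ray meets the outline")
  if (any(miss))
    r[miss] <- stats::approx(which(!miss), r[!miss],
                             xout = which(miss), rule = 2)$y
  r
}

#' Centroid-normalized digit-edge radial profile
#'
#' Measures the centroid-to-outline distance of the digit region (the
#' upward half-plane from the centroid) on a fixed angular grid from the
#' thumb side (large polar angle) to the pinky side.  For each grid angle
#' a ray is cast from the centroid and its farthest half-level crossing of
#' the bilinearly interpolated soft mask is found by marching and refined
#' to subpixel precision by bisection; because the half level of an
#' antialiased coverage image sits on the true silhouette boundary
#' regardless of pixel size, the measurement is stable across
#' resolutions.  Before measuring, the mask is smoothed by a Gaussian
#' whose standard deviation is a fixed fraction of the image width
#' (default 0.4 percent): because the blur has constant physical (not
#' pixel) size, images of the same scene at different resolutions yield
#' the half level of the same smooth field, which suppresses the residual
#' grazing-incidence sensitivity of rays nearly tangent to finger flanks
#' and makes the profile reproducible across scales; the same blur
#' restores a gradable edge on hard binary masks.
#' Distances are divided by
#' the minimum over the grid, so the profile minimum is exactly 1 and the
#' profile is invariant to uniform scaling and translation of the image.
#'
#' @param mask (soft) mask matrix (wrist-cropped).
#' @param centroid optional \code{c(x, y)}; computed from the mask when
#'   missing.
#' @param angleRange angular window in degrees (default 15..165).
#' @param angleStep grid step in degrees (default 1).
#' @param blurSigma Gaussian blur SD in pixels applied before sampling;
#'   defaults to 0.4 percent of the image width so the blur has a fixed
#'   physical size independent of resolution.  Set to 0 to measure the
#'   mask's own soft edges directly.
#' @return a \code{\linkS4class{RadialProfile}}.
#' @export
digitOutline <- function(mask, centroid = NULL, angleRange = c(15, 165),
                         angleStep = 1, blurSigma = 0.004 * ncol(mask)) {
  if (is.null(centroid)) centroid <- maskCentroid(mask)
  if (is.null(names(centroid))) names(centroid) <- c("x", "y")
  sm <- if (blurSigma > 0)
    t(EBImage::imageData(EBImage::gblur(.asEBImage(mask * 1.0),
                                        sigma = blurSigma)))
  else unclass(mask * 1.0)
  grid <- seq(angleRange[2], angleRange[1], by = -angleStep)
  r <- .rayEdgeDistance(sm, c(centroid["x"], centroid["y"]), grid)
  if (any(!is.finite(r)))
    stop("digitOutline: some rays do not meet the outline; ",
         "is the centroid inside the silhouette?")
  new("RadialProfile", angle = grid, distance = r / min(r),
      centroid = c(centroid["x"], centroid["y"]),
      minDistance = min(r))
}

## local maxima (plateau-aware) with prominences
.peaksWithProminence <- function(x) {
  n <- length(x)
  d <- diff(x)
  sgn <- sign(d)
  ## carry the last nonzero slope through plateaus
  for (i in seq_along(sgn))
    if (sgn[i] == 0 && i > 1) sgn[i] <- sgn[i - 1]
  peaks <- which(diff(sgn) < 0) + 1L
  peaks <- peaks[peaks > 1L & peaks < n]
  prom <- vapply(peaks, function(p) {
    h <- x[p]
    lmin <- h; i <- p
    while (i > 1L && x[i] <= h) { i <- i - 1L; lmin <- min(lmin, x[i]) }
    ## a side that runs off the profile without rising above the peak
    ## imposes no constraint (topographic-prominence convention)
    lbase <- if (i == 1L && x[i] <= h) -Inf else lmin
    rmin <- h; i <- p
    while (i < n && x[i] <= h) { i <- i + 1L; rmin <- min(rmin, x[i]) }
    rbase <- if (i == n && x[i] <= h) -Inf else rmin
    base <- max(lbase, rbase)
    if (!is.finite(base)) base <- min(x)
    h - base
  }, numeric(1))
  list(peaks = peaks, prominence = prom)
}

#' Split a radial profile into five finger segments
#'
#' Fingertips appear as the five most prominent local maxima of the radial
#' profile (prominence at least \code{prominence}); the profile is cut at
#' the valleys between consecutive fingertips (at the center of each
#' valley floor) and at its ends, yielding one segment per finger ordered
#' thumb to pinky.  Segment
#' point counts are not fixed: a narrower or less flexed finger occupies
#' fewer grid angles, and that difference itself carries information.
#'
#' Fewer than five sufficiently prominent peaks (an occluded or over-flexed
#' finger) raises a \code{fingerDetectionError} naming the count found.
#'
#' @param profile a \code{\linkS4class{RadialProfile}}.
#' @param prominence minimum peak prominence in normalized distance units
#'   (default 0.05).
#' @return named list of five segments (thumb..pinky), each a list with
#'   \code{finger}, \code{distance}, \code{angle}, \code{n} and
#'   \code{peakAngle}.
#' @export
splitFingers <- function(profile, prominence = 0.05) {
  stopifnot(is(profile, "RadialProfile"))
  d <- profile@distance
  pk <- .peaksWithProminence(d)
  ok <- pk$peaks[pk$prominence >= prominence]
  okProm <- pk$prominence[pk$prominence >= prominence]
  if (length(ok) < 5L) .fingerDetectionError(length(ok))
  top <- ok[order(-okProm)][1:5]
  top <- sort(top)                       # thumb side first (grid order)
  cuts <- vapply(1:4, function(i) {
    seg <- top[i]:top[i + 1]
    ## cut at the center of the valley floor (all points within 2% of
    ## the valley minimum), which is stable when the floor is flat
    lo <- min(d[seg])
    floorIdx <- seg[d[seg] <= lo * 1.02]
    floorIdx[(length(floorIdx) + 1L) %/% 2L]
  }, integer(1))
  bounds <- c(0L, cuts, length(d))
  segs <- lapply(1:5, function(i) {
    idx <- (bounds[i] + 1L):bounds[i + 1L]
    list(finger = .digitNames()[i], distance = d[idx],
         angle = profile@angle[idx], n = length(idx),
         peakAngle = profile@angle[top[i]])
  })
  names(segs) <- .digitNames()
  segs
}

#' Euclidean error between two finger outlines
#'
#' The element-wise Euclidean norm of the difference between the two
#' normalized distance sequences; when point counts differ the shorter
#' sequence is padded with zeros at the tail to the longer length, so a
#' missing extent of finger outline (less abduction or flexion) inflates
#' the error rather than being ignored.
#'
#' @param template,entry finger segments from \code{\link{splitFingers}}
#'   with matching \code{finger} labels.
#' @return non-negative scalar; symmetric in its arguments.
#' @export
fingerError <- function(template, entry) {
  if (!identical(template$finger, entry$finger))
    stop("fingerError: finger labels differ (",
         template$finger, " vs ", entry$finger, ")")
  a <- template$distance; b <- entry$distance
  n <- max(length(a), length(b))
  pad <- function(v) c(v, rep(0, n - length(v)))
  sqrt(sum((pad(a) - pad(b))^2))
}

#' Full image pipeline: silhouette to finger segments
#'
#' Convenience wrapper running \code{\link{segmentHand}},
#' \code{\link{cropWrist}}, \code{\link{maskCentroid}},
#' \code{\link{digitOutline}} and \code{\link{splitFingers}}.
#'
#' @param image RGB array.
#' @param prominence peak prominence floor for finger separation.
#' @param ... passed to \code{\link{segmentHand}}.
#' @return list with \code{mask}, \code{profile} and \code{fingers}.
#' @export
handProfile <- function(image, prominence = 0.05, ...) {
  mask <- cropWrist(segmentHand(image, ...))
  profile <- digitOutline(mask)
  list(mask = mask, profile = profile,
       fingers = splitFingers(profile, prominence = prominence))
}

#' Verify an entry posture image against a template image
#'
#' Both images are reduced to per-finger normalized outlines; the Euclidean
#' error is computed per finger and summed; the entry is accepted iff the
#' total error is strictly less than the threshold \code{Tp}.  A finger
#' detection failure in either image yields a rejection carrying the
#' reason.
#'
#' @param templateImage,entryImage RGB arrays (see
#'   \code{\link{renderPosture}} for the synthetic source).
#' @param Tp maximum total error admitted (strict).
#' @param prominence peak prominence floor.
#' @param ... passed to \code{\link{segmentHand}}.
#' @return list of class \code{PostureScore}: \code{perFinger} (named
#'   numeric), \code{total}, \code{accept}, \code{reason}.
#' @export
postureVerify <- function(templateImage, entryImage, Tp = 0.8,
                          prominence = 0.05, ...) {
  res <- tryCatch({
    tf <- handProfile(templateImage, prominence = prominence, ...)$fingers
    ef <- handProfile(entryImage, prominence = prominence, ...)$fingers
    per <- vapply(.digitNames(), function(d)
      fingerError(tf[[d]], ef[[d]]), numeric(1))
    list(perFinger = per, total = sum(per),
         accept = sum(per) < Tp, reason = NA_character_)
  }, fingerDetectionError = function(e) {
    list(perFinger = stats::setNames(rep(NA_real_, 5), .digitNames()),
         total = NA_real_, accept = FALSE, reason = conditionMessage(e))
  })
  class(res) <- "PostureScore"
  res
}

#' @export
print.PostureScore <- function(x, ...) {
  if (is.na(x$total))
    cat("PostureScore: rejected --", x$reason, "\n")
  else
    cat(sprintf("PostureScore: total error %.3f -> %s\n", x$total,
                if (x$accept) "accept" else "reject"))
  invisible(x)
}

#' Select the k best postures and their combined error rate
#'
#' Postures are ranked by mean authentic replication error (ascending); the
#' combined biometric requires all k selected postures to pass, so an
#' attempt's combined statistic is its maximum error over the selected
#' postures.  The combined EER is computed from the negated maxima (accept
#' iff every error is below the threshold).
#'
#' @param scores data.frame with columns \code{posture}, \code{attempt}
#'   (attempt key, shared across postures of one entry), \code{authentic}
#'   (logical) and \code{error}.
#' @param k number of postures to combine.
#' @return list with \code{selected} (posture ids, best first),
#'   \code{ranking} (per-posture mean authentic error) and \code{eer}
#'   (an \code{\linkS4class{EERResult}} on the combined statistic).
#' @export
bestPostures <- function(scores, k = 1L) {
  need <- c("posture", "attempt", "authentic", "error")
  stopifnot(is.data.frame(scores), all(need %in% names(scores)))
  scores <- scores[!is.na(scores$error), ]
  auth <- scores[scores$authentic, ]
  meanErr <- tapply(auth$error, auth$posture, mean)
  ranking <- sort(meanErr)
  if (k > length(ranking))
    stop("bestPostures: k exceeds the number of postures with authentic attempts")
  selected <- names(ranking)[seq_len(k)]
  sel <- scores[scores$posture %in% selected, ]
  comb <- stats::aggregate(error ~ attempt + authentic, data = sel, FUN = max)
  res <- computeEER(-comb$error[comb$authentic],
                    -comb$error[!comb$authentic])
  list(selected = selected, ranking = ranking, eer = res)
}
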