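#' @include handmodel.R
NULL

.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else if (exists(".Random.seed", .GlobalEnv))
            rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  expr
}

## squared distance from points (X, Y) to segment p-q
.segDist2 <- function(X, Y, p, q) {
  vx <- q[1] - p[1]; vy <- q[2] - p[2]
  l2 <- vx^2 + vy^2
  if (l2 == 0) return((X - p[1])^2 + (Y - p[2])^2)
  t <- pmin(1, pmax(0, ((X - p[1]) * vx + (Y - p[2]) * vy) / l2))
  (X - (p[1] + t * vx))^2 + (Y - (p[2] + t * vy))^2
}

#' Render a hand posture as a chroma-keyed silhouette
#'
#' Draws the virtual hand -- palm, wrist stub and five digit capsules -- as
#' a white silhouette on a uniform (by default green) background, emulating
#' a photographed hand posture against a keying screen.  Finger capsule
#' lengths are the projection of the flexed planar chain onto the palm
#' plane (each phalanx contributes its length times the cosine of the
#' cumulative flexion), so flexion shortens the rendered finger; the thumb
#' is drawn straight at its default abduction, as posture protocols keep it.
#' An interdigital webbing band above the palm joins the finger bases (as
#' on a real hand), so the valleys between fingers bottom out on a smooth
#' edge rather than in deep slivers; a finger never retracts below the
#' webbing -- its tip cap always protrudes and stays detectable.
#'
#' When \code{jitterSd > 0} the joint angles receive independent Gaussian
#' jitter, and digit splay angles receive jitter of \code{splayJitterSd},
#' emulating imperfect replication of a posture; with a \code{seed} the
#' render is deterministic.
#'
#' @param posture named 10-vector of joint angles, degrees.
#' @param geometry a \code{\linkS4class{HandGeometry}}.
#' @param resolution image side in pixels (square output, >= 64).
#' @param jitterSd SD of joint-angle jitter, degrees (default 0).
#' @param splayJitterSd SD of digit splay jitter, degrees.
#' @param splayOffsets fixed per-digit splay offsets, degrees (length 5),
#'   e.g. a subject's own abduction tendencies.
#' @param webbingHeight height of the interdigital webbing band above the
#'   palm edge, mm (default 22).
#' @param background background RGB triple in 0..1 (default pure green).
#' @param seed optional seed making the jitter reproducible.
#' @return H x W x 3 numeric array in 0..1, antialiased (edge pixels blend
#'   foreground and background by coverage); the coverage silhouette is
#'   attached as attribute \code{"silhouette"}.
#' @export
renderPosture <- function(posture, geometry = handGeometry(),
                          resolution = 320L, jitterSd = 0,
                          splayJitterSd = jitterSd / 2,
                          splayOffsets = NULL, webbingHeight = 22,
                          background = c(0, 1, 0), seed = NULL) {
  resolution <- as.integer(resolution)
  if (resolution < 64L) stop("renderPosture: resolution must be >= 64")
  if (is.null(names(posture))) names(posture) <- jointLabels()
  .withSeed(seed, {
    if (jitterSd > 0)
      posture <- posture + stats::rnorm(10, sd = jitterSd)
    splay <- geometry@splay
    if (!is.null(splayOffsets)) splay <- splay + splayOffsets
    if (splayJitterSd > 0)
      splay <- splay + stats::rnorm(5, sd = splayJitterSd)
  })
  deg2rad <- pi / 180

  ## world window, mm
  xr <- c(-130, 130); yr <- c(-150, 110)
  W <- H <- resolution
  xs <- xr[1] + (seq_len(W) - 0.5) * diff(xr) / W
  ys <- yr[2] - (seq_len(H) - 0.5) * diff(yr) / H
  X <- matrix(xs, H, W, byrow = TRUE)
  Y <- matrix(ys, H, W)

  px <- diff(xr) / W                     # mm per pixel (square pixels)

  ## antialiased coverage primitives (fraction of the pixel inside)
  ## NB: pmax/pmin keep the attributes of their first argument, so the
  ## matrix operand must come first to preserve dims
  capCov <- function(p, q, R)
    pmin(pmax(0.5 + (R - sqrt(.segDist2(X, Y, p, q))) / px, 0), 1)
  rectCov <- function(x1, x2, y1, y2) {
    cx <- pmax(pmin(X + px / 2, x2) - pmax(X - px / 2, x1), 0) / px
    cy <- pmax(pmin(Y + px / 2, y2) - pmax(Y - px / 2, y1), 0) / px
    cx * cy
  }

  palm <- geometry@palm
  pxr <- range(palm[, 1]); pyr <- range(palm[, 2])
  cov <- rectCov(pxr[1], pxr[2], pyr[1], pyr[2])
  ## wrist stub below the palm, narrower, so wrist cropping has a neck
  wristHw <- 0.275 * diff(pxr)
  cov <- pmax(cov, rectCov(-wristHw, wristHw, pyr[1] - 40, pyr[1]))

  ## interdigital webbing band joining the finger bases
  wx <- range(geometry@mcpBases[-1L, "x"])
  cov <- pmax(cov, rectCov(wx[1] - geometry@fingerRadius,
                           wx[2] + geometry@fingerRadius,
                           pyr[2], pyr[2] + webbingHeight))

  ## thumb: straight capsule at its (possibly offset/jittered) splay
  tb <- geometry@mcpBases["thumb", ]
  tu <- c(sin(splay[1] * deg2rad), cos(splay[1] * deg2rad))
  tip <- tb + sum(geometry@thumbLengths) * tu
  cov <- pmax(cov, capCov(tb, tip, geometry@thumbRadius))

  ## fingers: projected lengths under cumulative flexion
  cum <- .fingerJointAngles(posture)
  for (k in 2:5) {
    d <- .digitNames()[k]
    lens <- geometry@fingerLengths[d, ]
    h <- sum(lens * cos(cum[, d] * deg2rad))
    h <- max(h, webbingHeight + geometry@fingerRadius)
    u <- c(sin(splay[k] * deg2rad), cos(splay[k] * deg2rad))
    b <- geometry@mcpBases[d, ]
    cov <- pmax(cov, capCov(b, b + h * u, geometry@fingerRadius))
  }

  img <- array(0, dim = c(H, W, 3))
  for (ch in 1:3)
    img[, , ch] <- cov + (1 - cov) * background[ch]
  attr(img, "silhouette") <- cov
  img
}
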