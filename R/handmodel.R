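#' @include evaluation.R
NULL

## simple-polygon test: no two non-adjacent edges intersect
.simplePolygon <- function(p) {
  n <- nrow(p)
  if (n < 3L) return(FALSE)
  seg <- cbind(p, p[c(2:n, 1L), ])
  inter <- function(a, b) {
    d1 <- a[3:4] - a[1:2]; d2 <- b[3:4] - b[1:2]
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < 1e-12) return(FALSE)
    t <- ((b[1] - a[1]) * d2[2] - (b[2] - a[2]) * d2[1]) / den
    u <- ((b[1] - a[1]) * d1[2] - (b[2] - a[2]) * d1[1]) / den
    t > 1e-9 && t < 1 - 1e-9 && u > 1e-9 && u < 1 - 1e-9
  }
  for (i in seq_len(n - 2L))
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next
      if (inter(seg[i, ], seg[j, ])) return(FALSE)
    }
  TRUE
}

.digitNames <- function() c("thumb", "index", "middle", "ring", "pinky")

#' Default planar hand geometry
#'
#' A parameterized average adult hand used by the virtual-hand model and
#' the silhouette renderer: an 80 x 90 mm palm, finger phalanx lengths of
#' roughly 35--50 mm (proximal), 20--28 mm (middle) and 18--22 mm (distal),
#' and a two-segment thumb.  All dimensions are in millimetres and can be
#' overridden.
#'
#' @param fingerLengths 4 x 3 matrix (index/middle/ring/pinky x
#'   proximal/middle/distal), mm.
#' @param thumbLengths length-2 numeric (proximal, distal), mm.
#' @param palmWidth,palmHeight palm outline dimensions, mm.
#' @param splay default abduction angles, degrees from vertical
#'   (thumb, index, middle, ring, pinky); positive leans toward the pinky
#'   side.
#' @param fingerRadius,thumbRadius capsule radii used by the renderer, mm.
#' @return a \code{\linkS4class{HandGeometry}}.
#' @examples
#' handGeometry()
#' @export
handGeometry <- function(fingerLengths = rbind(index  = c(45, 25, 20),
                                               middle = c(50, 28, 22),
                                               ring   = c(45, 25, 20),
                                               pinky  = c(35, 20, 18)),
                         thumbLengths = c(40, 30),
                         palmWidth = 80, palmHeight = 90,
                         splay = c(-30, -8, -2.5, 3, 9),
                         fingerRadius = 8, thumbRadius = 9) {
  hw <- palmWidth / 2
  palm <- cbind(x = c(-hw, hw, hw, -hw),
                y = c(-palmHeight, -palmHeight, 0, 0))
  mcpBases <- rbind(thumb  = c(-hw + 2, -40),
                    index  = c(-0.75 * hw, 0),
                    middle = c(-0.25 * hw, 0),
                    ring   = c(0.25 * hw, 0),
                    pinky  = c(0.75 * hw, 0))
  colnames(mcpBases) <- c("x", "y")
  new("HandGeometry",
      fingerLengths = as.matrix(fingerLengths),
      thumbLengths = as.numeric(thumbLengths),
      palm = palm, mcpBases = mcpBases, splay = as.numeric(splay),
      fingerRadius = fingerRadius, thumbRadius = thumbRadius)
}

#' Read / write a hand geometry as JSON
#'
#' @param geometry a \code{\linkS4class{HandGeometry}}.
#' @param path file path.
#' @return \code{readHandGeometry}: a \code{HandGeometry};
#'   \code{writeHandGeometry}: \code{path}, invisibly.
#' @export
writeHandGeometry <- function(geometry, path) {
  stopifnot(is(geometry, "HandGeometry"))
  x <- list(fingerLengths = geometry@fingerLengths,
            thumbLengths = geometry@thumbLengths,
            palm = geometry@palm, mcpBases = geometry@mcpBases,
            splay = geometry@splay,
            fingerRadius = geometry@fingerRadius,
            thumbRadius = geometry@thumbRadius)
  jsonlite::write_json(x, path, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname writeHandGeometry
#' @export
readHandGeometry <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fl <- as.matrix(x$fingerLengths)
  rownames(fl) <- .digitNames()[-1]
  mb <- as.matrix(x$mcpBases)
  dimnames(mb) <- list(.digitNames(), c("x", "y"))
  palm <- as.matrix(x$palm); colnames(palm) <- c("x", "y")
  new("HandGeometry", fingerLengths = fl,
      thumbLengths = as.numeric(x$thumbLengths), palm = palm,
      mcpBases = mb, splay = as.numeric(x$splay),
      fingerRadius = as.numeric(x$fingerRadius),
      thumbRadius = as.numeric(x$thumbRadius))
}

#' Integrate a movement synergy to an end posture
#'
#' The final position of each joint is the time integral of its velocity
#' profile (rectangle rule) scaled by a gain, relative to a flat-hand zero
#' posture: angle_j = gain * sum_t v_j(t) / rate, in degrees.
#'
#' @param synergy 10 x L velocity matrix (degrees/second up to scale).
#' @param gain scalar multiplier (>= 0 in normal use).
#' @param rate sampling rate of the synergy's time axis, samples/second.
#' @return named numeric vector of 10 joint angles, degrees.
#' @export
integrateSynergy <- function(synergy, gain = 1, rate = 125) {
  stopifnot(is.matrix(synergy), nrow(synergy) == 10L, rate > 0)
  ang <- gain * rowSums(synergy) / rate
  names(ang) <- jointLabels()
  ang
}

#' Largest admissible gain for a postural synergy
#'
#' The synergy's integrated posture is scaled by the largest gain such that
#' (1) every joint angle stays within the range of motion
#' (default -10 to 90 degrees, the glove calibration range) -- a closed-form
#' bound, the minimum over joints of ROM limit over integrated angle -- and
#' (2) no finger's distal interphalangeal (DIP) joint crosses the upper palm
#' edge on the virtual hand; when it does, the gain is reduced in 0.01
#' decrements until the DIP no longer crosses.
#'
#' Finger DIP angles are not measured by the glove and are coupled to the
#' PIP as DIP = 2/3 PIP, a standard anatomical approximation.
#'
#' @param synergy 10 x L velocity matrix.
#' @param geometry a \code{\linkS4class{HandGeometry}}.
#' @param rate samples/second.
#' @param romLower,romUpper range-of-motion bounds, degrees.
#' @param step gain decrement (default 0.01).
#' @return list with \code{gain}, \code{posture} (at that gain),
#'   \code{romGain} (the ROM-only bound g0) and \code{reduced} (logical,
#'   whether the palm criterion forced a reduction).
#' @export
selectGain <- function(synergy, geometry = handGeometry(), rate = 125,
                       romLower = -10, romUpper = 90, step = 0.01) {
  unit <- integrateSynergy(synergy, gain = 1, rate = rate)
  if (all(unit == 0))
    stop("selectGain: degenerate synergy (integrates to the zero posture)")
  bound <- ifelse(unit > 0, romUpper / unit,
                  ifelse(unit < 0, romLower / unit, Inf))
  g0 <- min(bound)
  g <- g0
  reduced <- FALSE
  repeat {
    if (g < 0)
      stop("selectGain: no compliant non-negative gain")
    posture <- unit * g
    chains <- forwardKinematics(geometry, posture)
    crossed <- vapply(chains[-1L], function(ch) crossesPalm(geometry, ch),
                      logical(1))
    if (!any(crossed)) break
    g <- g - step
    reduced <- TRUE
  }
  list(gain = g, posture = unit * g, romGain = g0, reduced = reduced)
}

.fingerJointAngles <- function(posture) {
  ## cumulative flexion at (proximal, middle, distal) segment of each finger
  fingers <- .digitNames()[-1]
  mcp <- posture[c("I_MCP", "M_MCP", "R_MCP", "P_MCP")]
  pip <- posture[c("I_PIP", "M_PIP", "R_PIP", "P_PIP")]
  dip <- (2 / 3) * pip
  cum <- rbind(mcp, mcp + pip, mcp + pip + dip)
  colnames(cum) <- fingers
  cum
}

#' Planar forward kinematics of the hand
#'
#' Each digit is a planar chain from its MCP base: segments are rotated by
#' the cumulative flexion toward the palm, so a 90 degree MCP flexion with
#' straight interphalangeal joints displaces the fingertip perpendicular to
#' the digit axis by the full remaining chain length.  Positions are in mm.
#'
#' @param geometry a \code{\linkS4class{HandGeometry}}.
#' @param posture named 10-vector of joint angles, degrees (see
#'   \code{\link{integrateSynergy}}).
#' @return named list of matrices, one per digit (thumb, index, middle,
#'   ring, pinky); fingers have rows MCP, PIP, DIP, tip; the thumb rows
#'   MCP, IP, tip.  Each matrix carries attributes \code{axis} (the digit's
#'   unit reference direction) and \code{dipRow}.
#' @export
forwardKinematics <- function(geometry, posture) {
  stopifnot(is(geometry, "HandGeometry"), length(posture) == 10L)
  if (is.null(names(posture))) names(posture) <- jointLabels()
  deg2rad <- pi / 180
  out <- list()
  ## digit reference axes from the default splay (degrees from vertical)
  axes <- cbind(sin(geometry@splay * deg2rad), cos(geometry@splay * deg2rad))
  cum <- .fingerJointAngles(posture)
  for (k in seq_along(.digitNames())) {
    d <- .digitNames()[k]
    base <- geometry@mcpBases[d, ]
    u <- axes[k, ]                       # axial (straight-digit) direction
    w <- c(u[2], -u[1])                  # flexion direction, toward palm
    if (d == "thumb") {
      cumAng <- cumsum(posture[c("T_MCP", "T_IP")]) * deg2rad
      lens <- geometry@thumbLengths
    } else {
      cumAng <- cum[, d] * deg2rad
      lens <- geometry@fingerLengths[d, ]
    }
    axial <- cumsum(lens * cos(cumAng))
    perp <- cumsum(lens * sin(cumAng))
    pts <- rbind(c(0, 0), cbind(perp, axial))
    chain <- sweep(pts %*% rbind(w, u), 2L, base, `+`)
    rn <- if (d == "thumb") c("MCP", "IP", "tip")
          else c("MCP", "PIP", "DIP", "tip")
    dimnames(chain) <- list(rn, c("x", "y"))
    attr(chain, "axis") <- u
    attr(chain, "base") <- base
    attr(chain, "dipRow") <- if (d == "thumb") 2L else 3L
    out[[d]] <- chain
  }
  out
}

#' Does a digit's DIP joint cross the upper palm edge?
#'
#' TRUE iff the DIP joint position lies strictly on the palm side of the
#' upper palm edge, i.e. its axial coordinate along the digit's reference
#' axis (measured from the MCP base, which sits on the edge) is negative.
#' A DIP exactly on the edge does not count as crossing.
#'
#' @param geometry a \code{\linkS4class{HandGeometry}}.
#' @param chain one digit chain from \code{\link{forwardKinematics}}.
#' @return logical.
#' @export
crossesPalm <- function(geometry, chain) {
  dip <- chain[attr(chain, "dipRow"), ]
  base <- attr(chain, "base")
  axis <- attr(chain, "axis")
  sum((dip - base) * axis) < 0
}
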