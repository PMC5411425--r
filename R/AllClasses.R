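#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------- utilities

.checkAngleMatrix <- function(m, what = "angles", minRows = 2) {
  msgs <- character()
  if (!is.matrix(m) || !is.numeric(m))
    return(sprintf("%s must be a numeric matrix", what))
  if (ncol(m) != 10L)
    msgs <- c(msgs, sprintf("%s must have 10 columns (one per joint)", what))
  if (nrow(m) < minRows)
    msgs <- c(msgs, sprintf("%s must have at least %d time samples", what, minRows))
  if (!all(is.finite(m)))
    msgs <- c(msgs, sprintf("%s must be finite", what))
  msgs
}

## ------------------------------------------------------------- RawRecording

#' RawRecording: one glove recording of a grasp
#'
#' Joint angles (degrees) over time for the ten instrumented hand joints,
#' sampled at a fixed rate, together with the labels identifying the trial
#' (subject, object, grasp type, repetition).
#'
#' @slot angles numeric matrix, time x 10, degrees; columns in
#'   \code{\link{jointLabels}} order.
#' @slot rate sampling rate in samples/second (default 125).
#' @slot subjectId,objectId,graspType character labels.
#' @slot repetition integer repetition index.
#'
#' @seealso \code{\link{RawRecording}} (constructor),
#'   \code{\link{computeVelocity}}, \code{\link{segmentTrial}}
#' @name RawRecording-class
#' @aliases RawRecording-class
#' @exportClass RawRecording
setClass("RawRecording",
  representation(angles = "matrix", rate = "numeric",
                 subjectId = "character", objectId = "character",
                 graspType = "character", repetition = "integer"),
  validity = function(object) {
    msgs <- .checkAngleMatrix(object@angles)
    if (length(object@rate) != 1L || !is.finite(object@rate) || object@rate <= 0)
      msgs <- c(msgs, "rate must be a single positive number")
    if (length(msgs)) msgs else TRUE
  })

#' Construct a RawRecording
#'
#' @param angles time x 10 numeric matrix of joint angles in degrees
#'   (columns in \code{\link{jointLabels}} order).
#' @param rate sampling rate, samples/second.
#' @param subjectId,objectId,graspType trial labels.
#' @param repetition repetition index.
#' @return a \code{\linkS4class{RawRecording}}.
#' @examples
#' rec <- RawRecording(matrix(0, 20, 10), rate = 125)
#' rec
#' @export
RawRecording <- function(angles, rate = 125, subjectId = "S1",
                         objectId = "O1", graspType = NA_character_,
                         repetition = 1L) {
  angles <- as.matrix(angles)
  storage.mode(angles) <- "double"
  if (is.null(colnames(angles)) && ncol(angles) == 10L)
    colnames(angles) <- jointLabels()
  new("RawRecording", angles = angles, rate = as.numeric(rate),
      subjectId = as.character(subjectId), objectId = as.character(objectId),
      graspType = as.character(graspType), repetition = as.integer(repetition))
}

setMethod("show", "RawRecording", function(object) {
  cat(sprintf(
    "RawRecording: subject %s, object %s (%s), rep %d; %d samples @ %g Hz\n",
    object@subjectId, object@objectId, object@graspType, object@repetition,
    nrow(object@angles), object@rate))
})

## --------------------------------------------------------------- GraspTrial

#' GraspTrial: a segmented grasp movement
#'
#' Angular velocity (degrees/second) from movement onset to grasp completion,
#' as produced by \code{\link{segmentTrial}}.  \code{onset} and \code{offset}
#' index into the source recording.
#'
#' @slot velocity numeric matrix, T x 10, degrees/second.
#' @slot onset,offset integer sample indices into the source recording.
#' @slot rate sampling rate of the source recording.
#' @slot subjectId,objectId,graspType,repetition trial labels.
#' @name GraspTrial-class
#' @aliases GraspTrial-class
#' @exportClass GraspTrial
setClass("GraspTrial",
  representation(velocity = "matrix", onset = "integer", offset = "integer",
                 rate = "numeric", subjectId = "character",
                 objectId = "character", graspType = "character",
                 repetition = "integer"),
  validity = function(object) {
    msgs <- .checkAngleMatrix(object@velocity, "velocity", minRows = 1)
    if (object@offset < object@onset)
      msgs <- c(msgs, "offset must be >= onset")
    if (nrow(object@velocity) != object@offset - object@onset + 1L)
      msgs <- c(msgs, "velocity rows must equal offset - onset + 1")
    if (length(msgs)) msgs else TRUE
  })

setMethod("show", "GraspTrial", function(object) {
  cat(sprintf(
    "GraspTrial: subject %s, object %s, rep %d; samples %d..%d (%d kept)\n",
    object@subjectId, object@objectId, object@repetition,
    object@onset, object@offset, nrow(object@velocity)))
})

## --------------------------------------------------------------- SynergySet

#' SynergySet: ranked spatiotemporal synergies
#'
#' The result of a truncated singular value decomposition of a velocity
#' matrix: \code{n} ranked synergies, each a 10 x L matrix of per-joint
#' velocity profiles (the right singular vectors, reshaped), the full set of
#' singular values, and per-component variance fractions.  Signs are
#' canonicalized so the largest-magnitude element of each synergy is
#' positive.
#'
#' Accessors: \code{synergies(x)} (list of 10 x L matrices),
#' \code{singularValues(x)}, \code{varianceFractions(x)} (all components),
#' \code{nSynergies(x)}.
#'
#' @slot synergies list of \code{n} numeric matrices, 10 x L.
#' @slot loadings (10 L) x n matrix of flattened right singular vectors.
#' @slot scores G x n matrix of left singular vectors (sign-matched).
#' @slot singularValues all singular values, non-increasing.
#' @slot varianceFractions squared singular values over their total.
#' @slot n number of retained synergies.
#' @slot L fixed profile length in samples.
#' @slot joints joint labels.
#' @seealso \code{\link{extractSynergies}}, \code{\link{reconstruct}},
#'   \code{\link{varianceTable}}
#' @name SynergySet-class
#' @aliases SynergySet-class synergies singularValues varianceFractions nSynergies
#' @exportClass SynergySet
setClass("SynergySet",
  representation(synergies = "list", loadings = "matrix", scores = "matrix",
                 singularValues = "numeric", varianceFractions = "numeric",
                 n = "integer", L = "integer", joints = "character"),
  validity = function(object) {
    msgs <- character()
    if (length(object@synergies) != object@n)
      msgs <- c(msgs, "number of synergy matrices must equal n")
    if (any(diff(object@singularValues) > 1e-8))
      msgs <- c(msgs, "singular values must be non-increasing")
    vf <- object@varianceFractions
    if (any(vf < -1e-12 | vf > 1 + 1e-12))
      msgs <- c(msgs, "variance fractions must lie in [0, 1]")
    bad <- !vapply(object@synergies, function(s)
      is.matrix(s) && nrow(s) == 10L && ncol(s) == object@L, logical(1))
    if (any(bad))
      msgs <- c(msgs, "each synergy must be a 10 x L matrix")
    if (length(msgs)) msgs else TRUE
  })

setMethod("synergies", "SynergySet", function(x) x@synergies)
setMethod("singularValues", "SynergySet", function(x) x@singularValues)
setMethod("varianceFractions", "SynergySet", function(x) x@varianceFractions)
setMethod("nSynergies", "SynergySet", function(x) x@n)

setMethod("show", "SynergySet", function(object) {
  cat(sprintf("SynergySet: %d synergies (10 joints x %d samples)\n",
              object@n, object@L))
  vf <- object@varianceFractions[seq_len(min(object@n, 5L))]
  cat("  variance fractions:",
      paste(sprintf("%.3f", vf), collapse = " "),
      if (object@n > 5L) "...\n" else "\n")
})

## -------------------------------------------------------------- MatchResult

#' MatchResult: pairing of a template against an entry synergy set
#'
#' One row per matched pair: template rank, chosen entry synergy, the
#' maximizing time shift and the summed per-joint correlation at that shift.
#' Entry synergies are used at most once.
#'
#' @slot pairs data.frame with columns \code{templateIndex},
#'   \code{entryIndex}, \code{shift}, \code{score}.
#' @slot mask joint labels included in the comparison.
#' @slot maxShift maximum absolute shift searched, samples.
#' @seealso \code{\link{pairSynergies}}
#' @name MatchResult-class
#' @aliases MatchResult-class matchedPairs
#' @exportClass MatchResult
setClass("MatchResult",
  representation(pairs = "data.frame", mask = "character",
                 maxShift = "integer"),
  validity = function(object) {
    msgs <- character()
    p <- object@pairs
    need <- c("templateIndex", "entryIndex", "shift", "score")
    if (!all(need %in% names(p)))
      msgs <- c(msgs, "pairs must have templateIndex/entryIndex/shift/score")
    else {
      if (anyDuplicated(p$entryIndex))
        msgs <- c(msgs, "no entry synergy may be used twice")
      if (any(abs(p$shift) > object@maxShift))
        msgs <- c(msgs, "shifts must lie within [-maxShift, maxShift]")
      if (any(abs(p$score) > length(object@mask) + 1e-8))
        msgs <- c(msgs, "|score| cannot exceed the number of masked joints")
    }
    if (length(msgs)) msgs else TRUE
  })

setMethod("matchedPairs", "MatchResult", function(x) x@pairs)

setMethod("show", "MatchResult", function(object) {
  cat(sprintf("MatchResult: %d pairs, mask of %d joints, max shift %d\n",
              nrow(object@pairs), length(object@mask), object@maxShift))
  print(utils::head(object@pairs, 10))
})

## ----------------------------------------------------------------- ScoreSet

#' ScoreSet: authentic and imposter verification scores
#'
#' Percent-of-maximum summed-correlation scores collected over a population:
#' \code{trueScores} from subjects entering against their own templates,
#' \code{falseScores} from imposter attempts.  Provenance records subject,
#' session and attempt for each score.
#'
#' @slot trueScores,falseScores numeric vectors, percent of maximum
#'   (range -100..100).
#' @slot provenance data.frame, one row per score.
#' @slot mask joint labels used.
#' @slot synergyIndices template synergy ranks entering the score.
#' @seealso \code{\link{collectScores}}, \code{\link{computeEER}}
#' @name ScoreSet-class
#' @aliases ScoreSet-class trueScores falseScores
#' @exportClass ScoreSet
setClass("ScoreSet",
  representation(trueScores = "numeric", falseScores = "numeric",
                 provenance = "data.frame", mask = "character",
                 synergyIndices = "integer"),
  validity = function(object) {
    s <- c(object@trueScores, object@falseScores)
    if (length(s) && any(s < -100 - 1e-6 | s > 100 + 1e-6))
      "scores must be percent of maximum in [-100, 100]"
    else TRUE
  })

setMethod("trueScores", "ScoreSet", function(x) x@trueScores)
setMethod("falseScores", "ScoreSet", function(x) x@falseScores)

setMethod("show", "ScoreSet", function(object) {
  cat(sprintf(
    "ScoreSet: %d true / %d false conditions (mask %d joints, synergies %s)\n",
    length(object@trueScores), length(object@falseScores),
    length(object@mask), paste(object@synergyIndices, collapse = ",")))
})

## ---------------------------------------------------------------- EERResult

#' EERResult: FAR/FRR curves and the equal error rate
#'
#' False acceptance and false rejection rates (percent) evaluated over a
#' threshold grid, with the equal error rate at the interpolated crossing of
#' the two curves.  The decision rule is accept iff score > threshold
#' (strict), so FAR is non-increasing and FRR non-decreasing in the
#' threshold.
#'
#' @slot thresholds ascending threshold grid.
#' @slot far,frr rates in percent at each threshold.
#' @slot eer equal error rate, percent.
#' @slot eerThreshold threshold at the FAR/FRR crossing.
#' @seealso \code{\link{computeEER}}
#' @name EERResult-class
#' @aliases EERResult-class eer eerThreshold
#' @exportClass EERResult
setClass("EERResult",
  representation(thresholds = "numeric", far = "numeric", frr = "numeric",
                 eer = "numeric", eerThreshold = "numeric"),
  validity = function(object) {
    msgs <- character()
    if (is.unsorted(object@thresholds))
      msgs <- c(msgs, "thresholds must be ascending")
    if (any(diff(object@far) > 1e-9))
      msgs <- c(msgs, "FAR must be non-increasing in the threshold")
    if (any(diff(object@frr) < -1e-9))
      msgs <- c(msgs, "FRR must be non-decreasing in the threshold")
    if (object@eer < -1e-9 || object@eer > 100 + 1e-9)
      msgs <- c(msgs, "EER must lie in [0, 100]")
    if (length(msgs)) msgs else TRUE
  })

setMethod("eer", "EERResult", function(x) x@eer)
setMethod("eerThreshold", "EERResult", function(x) x@eerThreshold)

setMethod("show", "EERResult", function(object) {
  cat(sprintf("EERResult: EER %.2f%% at threshold %.2f (%d grid points)\n",
              object@eer, object@eerThreshold, length(object@thresholds)))
})

## -------------------------------------------------------- SynergyPopulation

#' SynergyPopulation: a simulated multi-subject dataset
#'
#' Per-subject registration (template) and entry sessions, stored both as
#' extracted \code{\linkS4class{SynergySet}}s and as the underlying
#' grasp-by-feature velocity matrices (needed when synergies are re-extracted
#' from object subsets), plus the planned posture-image protocol.
#'
#' @slot subjects list; see \code{\link{makePopulation}} for the layout.
#' @slot objects data.frame with columns \code{object}, \code{graspType}.
#' @slot params list of generator settings used.
#' @slot seed integer root seed.
#' @seealso \code{\link{makePopulation}}, \code{\link{collectScores}}
#' @name SynergyPopulation-class
#' @aliases SynergyPopulation-class
#' @exportClass SynergyPopulation
setClass("SynergyPopulation",
  representation(subjects = "list", objects = "data.frame",
                 params = "list", seed = "integer"),
  validity = function(object) {
    if (!all(c("object", "graspType") %in% names(object@objects)))
      "objects must have columns object and graspType"
    else TRUE
  })

setMethod("show", "SynergyPopulation", function(object) {
  nE <- vapply(object@subjects, function(s) length(s$entries), integer(1))
  nF <- vapply(object@subjects, function(s) length(s$followUps), integer(1))
  cat(sprintf(
    "SynergyPopulation: %d subjects, %d objects; entries/subject %s; follow-ups %s\n",
    length(object@subjects), nrow(object@objects),
    paste(unique(nE), collapse = "/"), paste(unique(nF), collapse = "/")))
})

## ------------------------------------------------------------- HandGeometry

#' HandGeometry: planar virtual-hand dimensions
#'
#' Segment lengths (mm) for the four fingers (proximal, middle, distal
#' phalanges) and the thumb (proximal, distal), the palm outline polygon,
#' the MCP base positions and default splay (abduction) angles, used by
#' \code{\link{forwardKinematics}} and the silhouette renderer.
#'
#' @slot fingerLengths 4 x 3 matrix (index/middle/ring/pinky x
#'   proximal/middle/distal), mm.
#' @slot thumbLengths length-2 numeric, mm.
#' @slot palm polygon matrix (x, y), mm; simple (non self-intersecting).
#' @slot mcpBases 5 x 2 matrix of digit base positions (thumb first), mm.
#' @slot splay default abduction angle per digit, degrees from the digit's
#'   reference axis (thumb first).
#' @slot fingerRadius,thumbRadius render capsule radii, mm.
#' @seealso \code{\link{handGeometry}}
#' @name HandGeometry-class
#' @aliases HandGeometry-class
#' @exportClass HandGeometry
setClass("HandGeometry",
  representation(fingerLengths = "matrix", thumbLengths = "numeric",
                 palm = "matrix", mcpBases = "matrix", splay = "numeric",
                 fingerRadius = "numeric", thumbRadius = "numeric"),
  validity = function(object) {
    msgs <- character()
    if (any(object@fingerLengths <= 0) || any(object@thumbLengths <= 0))
      msgs <- c(msgs, "segment lengths must be positive")
    if (object@fingerRadius <= 0 || object@thumbRadius <= 0)
      msgs <- c(msgs, "capsule radii must be positive")
    if (!.simplePolygon(object@palm))
      msgs <- c(msgs, "palm polygon must be simple")
    if (length(msgs)) msgs else TRUE
  })

setMethod("show", "HandGeometry", function(object) {
  cat(sprintf(
    "HandGeometry: palm %.0f x %.0f mm, finger radius %.0f mm\n",
    diff(range(object@palm[, 1])), diff(range(object@palm[, 2])),
    object@fingerRadius))
})

## ------------------------------------------------------------ RadialProfile

#' RadialProfile: centroid-normalized digit-edge distances
#'
#' Boundary distances from the mask centroid, restricted to the digit region
#' (the upward half-plane from the centroid), sampled on a fixed angular grid
#' ordered from the thumb side to the pinky side, and divided by the minimum
#' retained distance so the profile minimum is exactly 1.
#'
#' @slot angle polar angles of the samples, degrees, decreasing
#'   (thumb side first).
#' @slot distance normalized distances; \code{min(distance) == 1}.
#' @slot centroid (x, y) centroid in pixels, y measured upward.
#' @slot minDistance the normalizing raw distance, pixels.
#' @seealso \code{\link{digitOutline}}, \code{\link{splitFingers}}
#' @name RadialProfile-class
#' @aliases RadialProfile-class
#' @exportClass RadialProfile
setClass("RadialProfile",
  representation(angle = "numeric", distance = "numeric",
                 centroid = "numeric", minDistance = "numeric"),
  validity = function(object) {
    msgs <- character()
    if (length(object@angle) != length(object@distance))
      msgs <- c(msgs, "angle and distance must have equal length")
    if (length(object@distance) &&
        abs(min(object@distance) - 1) > 1e-9)
      msgs <- c(msgs, "minimum normalized distance must be exactly 1")
    if (length(msgs)) msgs else TRUE
  })

setMethod("show", "RadialProfile", function(object) {
  cat(sprintf(
    "RadialProfile: %d samples over %.0f..%.0f deg, max %.2f x min distance\n",
    length(object@distance), max(object@angle), min(object@angle),
    max(object@distance)))
})
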