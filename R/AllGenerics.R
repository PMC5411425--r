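#' @include AllGenerics.R
NULL

#' Canonical hand joint labels
#'
#' The ten instrumented joints in canonical order: thumb first, then index,
#' middle, ring and pinky; within each digit the metacarpophalangeal (MCP)
#' joint precedes the (proximal) interphalangeal joint.  The thumb carries an
#' IP joint where the four fingers carry PIP joints.
#'
#' @return Character vector of length 10:
#'   \code{T_MCP, T_IP, I_MCP, I_PIP, M_MCP, M_PIP, R_MCP, R_PIP, P_MCP, P_PIP}.
#' @examples
#' jointLabels()
#' @export
jointLabels <- function() {
  c("T_MCP", "T_IP",
    "I_MCP", "I_PIP",
    "M_MCP", "M_PIP",
    "R_MCP", "R_PIP",
    "P_MCP", "P_PIP")
}

#' @rdname SynergySet-class
#' @param x a \code{SynergySet} (or other object with the accessor).
#' @export
setGeneric("synergies", function(x) standardGeneric("synergies"))

#' @rdname SynergySet-class
#' @export
setGeneric("singularValues", function(x) standardGeneric("singularValues"))

#' @rdname SynergySet-class
#' @export
setGeneric("varianceFractions", function(x) standardGeneric("varianceFractions"))

#' @rdname SynergySet-class
#' @export
setGeneric("nSynergies", function(x) standardGeneric("nSynergies"))

#' @rdname ScoreSet-class
#' @param x a \code{ScoreSet}.
#' @export
setGeneric("trueScores", function(x) standardGeneric("trueScores"))

#' @rdname ScoreSet-class
#' @export
setGeneric("falseScores", function(x) standardGeneric("falseScores"))

#' @rdname EERResult-class
#' @param x an \code{EERResult}.
#' @export
setGeneric("eer", function(x) standardGeneric("eer"))

#' @rdname EERResult-class
#' @export
setGeneric("eerThreshold", function(x) standardGeneric("eerThreshold"))

#' @rdname MatchResult-class
#' @param x a \code{MatchResult}.
#' @export
setGeneric("matchedPairs", function(x) standardGeneric("matchedPairs"))

#' Segment a recording to the movement window
#'
#' Finds movement onset and offset as the first and last sample at which the
#' absolute angular velocity of any joint reaches a fraction (default 5\%) of
#' the peak velocity, and drops samples outside that window.
#'
#' With \code{onsetMode = "global"} the peak is the maximum of |velocity| over
#' all joints and times jointly, giving one shared extraction window per
#' trial; with \code{"per_joint"} each joint is compared against its own peak
#' and the window is the union of per-joint crossings.
#'
#' Segmenting an already-segmented \code{GraspTrial} with the same threshold
#' returns an identical trial (idempotence).
#'
#' @param x a \code{\linkS4class{RawRecording}} (velocities are derived via
#'   \code{\link{computeVelocity}}) or a \code{\linkS4class{GraspTrial}}.
#' @param thresholdFraction fraction of peak velocity defining onset/offset
#'   (default \code{0.05}).
#' @param onsetMode \code{"global"} (default) or \code{"per_joint"}.
#' @return a \code{\linkS4class{GraspTrial}}.
#' @seealso \code{\link{computeVelocity}}, \code{\link{padToFixed}}
#' @export
setGeneric("segmentTrial", function(x, thresholdFraction = 0.05,
                                    onsetMode = c("global", "per_joint"))
  standardGeneric("segmentTrial"))
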