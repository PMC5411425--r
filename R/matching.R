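#' @include synergy.R
NULL

#' Joint-configuration masks
#'
#' Named subsets of the ten joints used when comparing synergies: all
#' joints, the five MCP joints, the five (proximal) interphalangeal joints,
#' and the eight-joint sets with one digit removed.
#'
#' @param preset one of \code{"all"}, \code{"mcp_only"}, \code{"pip_only"},
#'   \code{"minus_thumb"}, \code{"minus_index"}, \code{"minus_middle"},
#'   \code{"minus_ring"}, \code{"minus_pinky"}, or a character vector of
#'   joint labels which is validated and returned as-is.
#' @return character vector of included joint labels.
#' @examples
#' jointMask("mcp_only")
#' jointMask("minus_pinky")
#' @export
jointMask <- function(preset = "all") {
  jl <- jointLabels()
  if (!length(preset)) stop("jointMask: mask must be non-empty")
  if (length(preset) > 1L || !preset %in% names(.maskPresets())) {
    bad <- setdiff(preset, jl)
    if (length(bad))
      stop("jointMask: unknown joint labels: ", paste(bad, collapse = ", "))
    return(jl[jl %in% preset])
  }
  .maskPresets()[[preset]]
}

.maskPresets <- function() {
  jl <- jointLabels()
  digits <- c(T = "T", I = "I", M = "M", R = "R", P = "P")
  minus <- lapply(digits, function(d) jl[!startsWith(jl, paste0(d, "_"))])
  c(list(all = jl,
         mcp_only = jl[endsWith(jl, "_MCP")],
         pip_only = jl[!endsWith(jl, "_MCP")]),
    stats::setNames(minus, c("minus_thumb", "minus_index", "minus_middle",
                             "minus_ring", "minus_pinky")))
}

#' Pearson correlation between two single-joint velocity profiles
#'
#' Plain product-moment correlation over the full fixed-length window.
#' If either profile has zero variance (e.g. a joint that is constant within
#' the compared window, as zero-padding can produce), the correlation is
#' defined as 0 rather than NaN.
#'
#' @param a,b numeric vectors of equal length.
#' @return scalar in [-1, 1].
#' @export
jointCorrelation <- function(a, b) {
  if (length(a) != length(b))
    stop("jointCorrelation: profiles must have equal length")
  a0 <- a - mean(a); b0 <- b - mean(b)
  den <- sqrt(sum(a0^2) * sum(b0^2))
  if (den == 0) return(0)
  sum(a0 * b0) / den
}

## Rowwise Pearson between two J x L matrices; zero-variance rows give 0.
.rowCorrelations <- function(A, B) {
  A0 <- A - rowMeans(A); B0 <- B - rowMeans(B)
  den <- sqrt(rowSums(A0^2) * rowSums(B0^2))
  num <- rowSums(A0 * B0)
  ifelse(den > 0, num / den, 0)
}

## Shift the columns of a J x L matrix by s samples with zero fill
## (s > 0: delayed, zeros at the head).
.shiftProfile <- function(m, s) {
  L <- ncol(m)
  out <- matrix(0, nrow(m), L)
  if (s >= 0) {
    if (s < L) out[, (1 + s):L] <- m[, 1:(L - s), drop = FALSE]
  } else {
    s <- -s
    if (s < L) out[, 1:(L - s)] <- m[, (1 + s):L, drop = FALSE]
  }
  out
}

#' Shift-aligned summed per-joint correlation
#'
#' Correlates a template synergy with an entry synergy joint by joint,
#' sums the correlations over the masked joints, and maximizes over integer
#' time shifts of the entry in [-maxShift, maxShift] samples (zero fill at
#' the vacated end).  With all ten joints included the maximum attainable
#' score is 10, reached when entry equals template.  Ties between shifts are
#' broken toward the smaller |shift|, then toward the negative shift.
#'
#' @param template,entry 10 x L synergy matrices (rows in
#'   \code{\link{jointLabels}} order).
#' @param mask a preset name or joint-label vector; see
#'   \code{\link{jointMask}}.
#' @param maxShift maximum absolute shift, samples (default 20, i.e. 160 ms
#'   at 125 Hz).
#' @return list with \code{shift}, \code{score}, and \code{perJoint}
#'   (named correlations at the best shift).
#' @export
shiftedSummedCorrelation <- function(template, entry, mask = "all",
                                     maxShift = 20L) {
  mask <- jointMask(mask)
  if (!length(mask)) stop("shiftedSummedCorrelation: empty mask")
  stopifnot(is.matrix(template), is.matrix(entry),
            all(dim(template) == dim(entry)), nrow(template) == 10L)
  L <- ncol(template)
  maxShift <- as.integer(maxShift)
  if (maxShift >= L) stop("shiftedSummedCorrelation: maxShift must be < L")
  keep <- match(mask, jointLabels())
  A <- template[keep, , drop = FALSE]
  E <- entry[keep, , drop = FALSE]
  shifts <- -maxShift:maxShift
  scores <- vapply(shifts, function(s)
    sum(.rowCorrelations(A, .shiftProfile(E, s))), numeric(1))
  best <- order(-scores, abs(shifts), shifts)[1]
  s <- shifts[best]
  pj <- .rowCorrelations(A, .shiftProfile(E, s))
  names(pj) <- mask
  list(shift = s, score = scores[best], perJoint = pj)
}

#' Pair template synergies with entry synergies
#'
#' Template synergies are processed in rank order (synergy 1 first); each
#' takes the still-available entry synergy with the highest shift-aligned
#' summed correlation and removes it from the pool, so no entry synergy is
#' used twice.  This is the greedy iterative-removal rule; the
#' \code{"optimal"} method instead maximizes the total score over all
#' one-to-one assignments (exhaustive enumeration, n <= 8) and is provided
#' for comparison only.
#'
#' @param template,entry \code{\linkS4class{SynergySet}}s sharing L.
#' @param mask joint mask; see \code{\link{jointMask}}.
#' @param maxShift maximum absolute shift, samples.
#' @param method \code{"greedy"} (default) or \code{"optimal"}.
#' @param upTo pair only the first \code{upTo} template synergies
#'   (default all); the greedy pool still draws from every entry synergy.
#' @return a \code{\linkS4class{MatchResult}}; the number of pairs is
#'   \code{min(upTo, n_template, n_entry)}.
#' @export
pairSynergies <- function(template, entry, mask = "all", maxShift = 20L,
                          method = c("greedy", "optimal"), upTo = NULL) {
  method <- match.arg(method)
  stopifnot(is(template, "SynergySet"), is(entry, "SynergySet"))
  if (template@L != entry@L)
    stop("pairSynergies: template and entry must share L")
  if (template@n < 1L || entry@n < 1L)
    stop("pairSynergies: empty synergy set")
  mask <- jointMask(mask)
  nT <- template@n; nE <- entry@n
  nPairs <- min(nT, nE)
  if (!is.null(upTo)) nPairs <- min(nPairs, as.integer(upTo))
  ts <- template@synergies; es <- entry@synergies

  scoreCache <- matrix(NA_real_, nT, nE)
  shiftCache <- matrix(NA_integer_, nT, nE)
  getScore <- function(i, j) {
    if (is.na(scoreCache[i, j])) {
      r <- shiftedSummedCorrelation(ts[[i]], es[[j]], mask, maxShift)
      scoreCache[i, j] <<- r$score
      shiftCache[i, j] <<- r$shift
    }
    scoreCache[i, j]
  }

  if (method == "greedy") {
    avail <- seq_len(nE)
    rows <- vector("list", nPairs)
    for (i in seq_len(nPairs)) {
      sc <- vapply(avail, function(j) getScore(i, j), numeric(1))
      j <- avail[which.max(sc)]
      rows[[i]] <- data.frame(templateIndex = i, entryIndex = j,
                              shift = shiftCache[i, j],
                              score = scoreCache[i, j])
      avail <- setdiff(avail, j)
    }
    pairs <- do.call(rbind, rows)
  } else {
    if (nPairs > 8L || nE > 8L)
      stop("pairSynergies: optimal assignment supported for n <= 8 only")
    for (i in seq_len(nPairs)) for (j in seq_len(nE)) getScore(i, j)
    perms <- .permutations(nE, nPairs)
    tot <- apply(perms, 1L, function(p)
      sum(scoreCache[cbind(seq_len(nPairs), p)]))
    p <- perms[which.max(tot), ]
    pairs <- data.frame(templateIndex = seq_len(nPairs), entryIndex = p,
                        shift = shiftCache[cbind(seq_len(nPairs), p)],
                        score = scoreCache[cbind(seq_len(nPairs), p)])
  }
  new("MatchResult", pairs = pairs, mask = mask,
      maxShift = as.integer(maxShift))
}

## all ordered selections of k items from 1..n (rows)
.permutations <- function(n, k = n) {
  if (k == 0L) return(matrix(integer(0), 1, 0))
  sub <- .permutations(n, k - 1L)
  out <- do.call(rbind, lapply(seq_len(n), function(j) {
    keep <- !apply(sub == j, 1L, any)
    if (!any(keep)) return(NULL)
    cbind(sub[keep, , drop = FALSE], j)
  }))
  out
}

#' Time-bin lengths for the chance shuffle
#'
#' The L-sample profile is cut into \code{bins} contiguous bins: the first
#' \code{bins - 1} of \code{binLength} samples and a final remainder bin
#' (11 samples for the defaults L = 151, 8 bins of 20).
#'
#' @param L profile length.
#' @param bins number of bins (default 8).
#' @param binLength samples per bin except the last (default 20).
#' @return integer vector of bin lengths summing to L.
#' @export
timeBinLengths <- function(L = 151L, bins = 8L, binLength = 20L) {
  L <- as.integer(L); bins <- as.integer(bins)
  binLength <- as.integer(binLength)
  last <- L - (bins - 1L) * binLength
  if (last < 1L || bins * binLength < L)
    stop("timeBinLengths: invalid binning for L = ", L)
  c(rep(binLength, bins - 1L), last)
}

.shuffleSynergy <- function(s, lens) {
  idx <- rep(seq_along(lens), lens)
  pieces <- split(seq_len(ncol(s)), idx)
  t(apply(s, 1L, function(row)
    unlist(lapply(pieces[sample.int(length(pieces))], function(p) row[p]),
           use.names = FALSE)))
}

#' Chance-level matching scores by time-bin shuffling
#'
#' Estimates the null distribution of the verification score: each joint's
#' velocity profile in each entry synergy is cut into contiguous time bins
#' which are permuted uniformly at random (independently per joint), the
#' shuffled entry is paired against the template exactly as a real entry
#' would be, and the percent-of-maximum score of the designated synergies is
#' recorded.  Repeated draws give the chance distribution against which
#' matched scores are judged.
#'
#' @param template,entry \code{\linkS4class{SynergySet}}s.
#' @param mask joint mask.
#' @param bins,binLength bin layout; see \code{\link{timeBinLengths}}.
#' @param draws number of shuffled draws.
#' @param synergyIndices template ranks scored (default 1).
#' @param maxShift maximum alignment shift.
#' @param seed optional integer seed for the permutations.
#' @return numeric vector of \code{draws} percent-of-maximum chance scores.
#' @export
chanceBaseline <- function(template, entry, mask = "all", bins = 8L,
                           binLength = 20L, draws = 100L,
                           synergyIndices = 1L, maxShift = 20L,
                           seed = NULL) {
  stopifnot(is(entry, "SynergySet"))
  lens <- timeBinLengths(entry@L, bins, binLength)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  vapply(seq_len(draws), function(k) {
    shuffled <- entry
    shuffled@synergies <- lapply(entry@synergies, .shuffleSynergy, lens)
    verifySynergies(template, shuffled, mask = mask,
                    synergyIndices = synergyIndices, Tm = 0,
                    maxShift = maxShift)$score
  }, numeric(1))
}

#' Verify an entry synergy set against a template
#'
#' Pairs the sets (greedy, rank order), sums the pair scores of the
#' designated template synergies (synergy 1 by default; \code{c(1, 2)} is
#' the supported two-synergy key, averaged for threshold comparability),
#' rescales to percent of the attainable maximum
#' (|mask| x number of indices), and accepts iff the score is strictly
#' greater than the threshold \code{Tm}.
#'
#' @param template,entry \code{\linkS4class{SynergySet}}s.
#' @param mask joint mask.
#' @param synergyIndices template ranks forming the key (default 1).
#' @param Tm acceptance threshold, percent of maximum (0..100).
#' @param maxShift maximum alignment shift, samples.
#' @return list with \code{accept} (logical), \code{score} (percent of
#'   maximum), and \code{match} (the \code{\linkS4class{MatchResult}}).
#' @examples
#' ## an entry identical to its template scores 100% and is accepted
#' ## for any threshold below 100
#' @export
verifySynergies <- function(template, entry, mask = "all",
                            synergyIndices = 1L, Tm = 70,
                            maxShift = 20L) {
  synergyIndices <- as.integer(synergyIndices)
  if (any(synergyIndices < 1L | synergyIndices > template@n))
    stop("verifySynergies: synergyIndices outside 1..n")
  mr <- pairSynergies(template, entry, mask = mask, maxShift = maxShift,
                      upTo = max(synergyIndices))
  p <- mr@pairs
  raw <- sum(p$score[match(synergyIndices, p$templateIndex)])
  maxScore <- length(mr@mask) * length(synergyIndices)
  score <- 100 * raw / maxScore
  list(accept = score > Tm, score = score, match = mr)
}
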