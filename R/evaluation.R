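#' @include matching.R
NULL

.scoreOne <- function(template, entry, mask, synergyIndices, maxShift) {
  verifySynergies(template, entry, mask = mask,
                  synergyIndices = synergyIndices, Tm = 0,
                  maxShift = maxShift)$score
}

## subjectSets: list of list(subjectId, template, trueEntries, falseEntries)
## trueEntries: this subject's own later sessions; falseEntries: the entry
## sessions other subjects present against this subject's template.
.collectFromSets <- function(subjectSets, mask, synergyIndices, maxShift) {
  maskv <- jointMask(mask)
  rows <- list(); ts <- numeric(0); fs <- numeric(0)
  for (s in subjectSets) {
    for (k in seq_along(s$trueEntries)) {
      sc <- .scoreOne(s$template, s$trueEntries[[k]], maskv,
                      synergyIndices, maxShift)
      ts <- c(ts, sc)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s$subjectId, claimant = s$subjectId, attempt = k,
        authentic = TRUE, score = sc)
    }
    for (k in seq_along(s$falseEntries)) {
      fe <- s$falseEntries[[k]]
      sc <- .scoreOne(s$template, fe$set, maskv, synergyIndices, maxShift)
      fs <- c(fs, sc)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s$subjectId, claimant = fe$claimant, attempt = k,
        authentic = FALSE, score = sc)
    }
  }
  new("ScoreSet", trueScores = ts, falseScores = fs,
      provenance = do.call(rbind, rows), mask = maskv,
      synergyIndices = as.integer(synergyIndices))
}

.populationSets <- function(population, objects = NULL, n = NULL) {
  allObj <- population@objects$object
  keep <- if (is.null(objects)) allObj else objects
  reuse <- is.null(objects) || setequal(keep, allObj)
  lapply(population@subjects, function(s) {
    if (reuse) {
      template <- s$template
      trueE <- c(s$entries, s$followUps)
      initE <- s$entries
    } else {
      idx <- match(keep, rownames(s$templateV))
      nn <- if (is.null(n)) min(10L, length(idx)) else min(n, length(idx))
      template <- extractSynergies(s$templateV[idx, , drop = FALSE], n = nn)
      trueE <- lapply(c(s$entryVs, s$followUpVs), function(V)
        extractSynergies(V[idx, , drop = FALSE], n = nn))
      initE <- lapply(s$entryVs, function(V)
        extractSynergies(V[idx, , drop = FALSE], n = nn))
    }
    list(subjectId = s$subjectId, template = template,
         trueEntries = trueE, initialEntries = initE)
  })
}

.withFalseEntries <- function(sets) {
  for (i in seq_along(sets)) {
    fe <- list()
    for (j in seq_along(sets)) {
      if (i == j) next
      for (e in sets[[j]]$initialEntries)
        fe[[length(fe) + 1L]] <- list(set = e,
                                      claimant = sets[[j]]$subjectId)
    }
    sets[[i]]$falseEntries <- fe
  }
  sets
}

#' Collect authentic and imposter scores over a population
#'
#' True scores come from every subject's later sessions (initial entry
#' repetitions plus any follow-up sessions) verified against that subject's
#' own registration template; false scores come from every other subject's
#' initial entry sessions presented against the template.  With the default
#' simulated design -- 10 subjects, 2 initial entry attempts each, 4 extra
#' follow-up attempts for 5 subjects -- this yields 40 true conditions
#' (5 x 2 + 5 x 6) and 180 false conditions (9 imposters x 2 repetitions x
#' 10 subjects).
#'
#' @param population a \code{\linkS4class{SynergyPopulation}}.
#' @param mask joint mask; see \code{\link{jointMask}}.
#' @param synergyIndices template synergy ranks forming the key.
#' @param maxShift maximum alignment shift, samples.
#' @return a \code{\linkS4class{ScoreSet}}.
#' @export
collectScores <- function(population, mask = "all", synergyIndices = 1L,
                          maxShift = 20L) {
  stopifnot(is(population, "SynergyPopulation"))
  if (!length(population@subjects))
    stop("collectScores: empty population")
  for (s in population@subjects)
    if (is.null(s$template))
      stop("collectScores: subject ", s$subjectId, " has no template")
  sets <- .withFalseEntries(.populationSets(population))
  .collectFromSets(sets, mask, synergyIndices, maxShift)
}

#' Equal error rate from authentic and imposter scores
#'
#' Evaluates empirical FAR and FRR over a threshold grid (the sorted union
#' of all observed scores, their midpoints, and flanking sentinels) under
#' the strict decision rule accept iff score > threshold.  The EER is the
#' value at the FAR/FRR crossing, linearly interpolated between the two
#' bracketing grid thresholds.
#'
#' @param x a \code{\linkS4class{ScoreSet}}, or a numeric vector of
#'   authentic scores.
#' @param falseScores imposter scores when \code{x} is a numeric vector.
#' @return an \code{\linkS4class{EERResult}}.
#' @examples
#' computeEER(c(90, 85, 95), c(10, 20, 15))  # perfectly separated: EER 0
#' @export
computeEER <- function(x, falseScores = NULL) {
  if (is(x, "ScoreSet")) {
    ts <- x@trueScores; fs <- x@falseScores
  } else {
    ts <- as.numeric(x); fs <- as.numeric(falseScores)
  }
  if (!length(ts) || !length(fs))
    stop("computeEER: both score lists must be non-empty")
  cand <- sort(unique(c(ts, fs)))
  mids <- if (length(cand) > 1L) (cand[-1] + cand[-length(cand)]) / 2
          else numeric(0)
  grid <- sort(unique(c(cand[1] - 1, cand, mids, cand[length(cand)] + 1)))
  far <- vapply(grid, function(t) 100 * mean(fs > t), numeric(1))
  frr <- vapply(grid, function(t) 100 * mean(ts <= t), numeric(1))
  d <- far - frr
  i <- max(which(d > 0))
  if (i == length(grid)) {      # cannot happen with sentinels, but be safe
    e <- far[i]; thr <- grid[i]
  } else if (d[i + 1] == 0) {
    e <- far[i + 1]; thr <- grid[i + 1]
  } else {
    frac <- d[i] / (d[i] - d[i + 1])
    thr <- grid[i] + frac * (grid[i + 1] - grid[i])
    e <- far[i] + frac * (far[i + 1] - far[i])
  }
  new("EERResult", thresholds = grid, far = far, frr = frr,
      eer = e, eerThreshold = thr)
}

#' Plot FAR and FRR curves with the EER point
#'
#' @param result an \code{\linkS4class{EERResult}}.
#' @param ... passed to \code{\link[graphics]{plot}}.
#' @export
plotEER <- function(result, ...) {
  stopifnot(is(result, "EERResult"))
  graphics::plot(result@thresholds, result@far, type = "s", col = "red",
                 xlab = "threshold (% of maximum correlation)",
                 ylab = "rate (%)", ylim = c(0, 100), ...)
  graphics::lines(result@thresholds, result@frr, type = "s", col = "blue")
  graphics::points(result@eerThreshold, result@eer, pch = 19)
  graphics::legend("right", c("FAR", "FRR"), col = c("red", "blue"), lty = 1)
  invisible(result)
}

#' Sweep joint configurations and synergy ranks
#'
#' Reproduces the configuration analysis: for every (synergy rank, joint
#' mask) cell, the mean and SD of the authentic matched correlation
#' (percent of maximum), the mean imposter correlation, and the EER.
#'
#' @param population a \code{\linkS4class{SynergyPopulation}}.
#' @param masks character vector of mask presets.
#' @param synergies synergy ranks to evaluate (default 1..10).
#' @param maxShift maximum alignment shift.
#' @return data.frame with one row per (synergy, mask).
#' @export
configurationSweep <- function(population,
                               masks = names(.maskPresets()),
                               synergies = 1:10, maxShift = 20L) {
  stopifnot(is(population, "SynergyPopulation"))
  if (length(population@subjects) < 2L)
    stop("configurationSweep: need at least 2 subjects")
  sets <- .withFalseEntries(.populationSets(population))
  maxRank <- max(synergies)
  out <- list()
  for (m in masks) {
    maskv <- jointMask(m)
    kmax <- length(maskv)
    tScores <- matrix(NA_real_, 0, maxRank)
    fScores <- matrix(NA_real_, 0, maxRank)
    for (s in sets) {
      for (e in s$trueEntries) {
        p <- pairSynergies(s$template, e, mask = maskv,
                           maxShift = maxShift, upTo = maxRank)@pairs
        tScores <- rbind(tScores, 100 * p$score / kmax)
      }
      for (fe in s$falseEntries) {
        p <- pairSynergies(s$template, fe$set, mask = maskv,
                           maxShift = maxShift, upTo = maxRank)@pairs
        fScores <- rbind(fScores, 100 * p$score / kmax)
      }
    }
    for (k in synergies) {
      out[[length(out) + 1L]] <- data.frame(
        synergy = k, mask = m,
        meanTrue = mean(tScores[, k]), sdTrue = stats::sd(tScores[, k]),
        meanFalse = mean(fScores[, k]),
        eer = computeEER(tScores[, k], fScores[, k])@eer)
    }
  }
  do.call(rbind, out)
}

#' Rank objects by their contribution to imposter rejection
#'
#' For each object, synergies are re-extracted from all grasps except that
#' object (for templates and entry sessions alike) and the mean imposter
#' (false-entry) correlation against the leave-one-out templates is
#' measured.  Objects whose omission decreases the false correlation the
#' most are ranked highest: they contribute most to distinguishing
#' imposters.  \code{direction = "increase"} ranks by the opposite reading.
#'
#' @param population a \code{\linkS4class{SynergyPopulation}}.
#' @param mask joint mask.
#' @param synergyIndices synergy ranks scored (default 1).
#' @param maxShift maximum alignment shift.
#' @param direction rank by the largest \code{"decrease"} (default) or
#'   \code{"increase"} in mean false correlation upon omission.
#' @return data.frame with columns \code{object}, \code{delta} (baseline
#'   minus leave-one-out mean false correlation) and \code{rank}; ordered
#'   by rank.
#' @export
rankObjects <- function(population, mask = "all", synergyIndices = 1L,
                        maxShift = 20L,
                        direction = c("decrease", "increase")) {
  direction <- match.arg(direction)
  stopifnot(is(population, "SynergyPopulation"))
  objs <- population@objects$object
  if (length(objs) < 2L) stop("rankObjects: need at least 2 objects")
  meanFalse <- function(objects) {
    sets <- .withFalseEntries(.populationSets(population, objects))
    fs <- unlist(lapply(sets, function(s)
      vapply(s$falseEntries, function(fe)
        .scoreOne(s$template, fe$set, jointMask(mask), synergyIndices,
                  maxShift), numeric(1))))
    mean(fs)
  }
  base <- meanFalse(NULL)
  delta <- vapply(objs, function(o) base - meanFalse(setdiff(objs, o)),
                  numeric(1))
  ord <- order(if (direction == "decrease") -delta else delta)
  data.frame(object = objs[ord], delta = delta[ord],
             rank = seq_along(objs), row.names = NULL)
}

#' EER as a function of the number of top-ranked objects
#'
#' Re-extracts synergies from the top-k ranked objects only and re-runs the
#' full verification evaluation, for each k.  At k equal to the full object
#' count this reproduces the all-objects EER exactly.
#'
#' @param population a \code{\linkS4class{SynergyPopulation}}.
#' @param ranking data.frame from \code{\link{rankObjects}}.
#' @param ks numbers of top objects to evaluate (default 1..G).
#' @param mask,synergyIndices,maxShift as in \code{\link{collectScores}}.
#' @return data.frame with columns \code{k} and \code{eer}.
#' @export
subsetCurve <- function(population, ranking, ks = NULL, mask = "all",
                        synergyIndices = 1L, maxShift = 20L) {
  stopifnot(is(population, "SynergyPopulation"),
            is.data.frame(ranking), "object" %in% names(ranking))
  G <- nrow(ranking)
  if (is.null(ks)) ks <- seq_len(G)
  ee <- vapply(ks, function(k) {
    objects <- if (k == G) NULL else ranking$object[seq_len(k)]
    sets <- .withFalseEntries(.populationSets(population, objects))
    ss <- .collectFromSets(sets, mask, synergyIndices, maxShift)
    computeEER(ss)@eer
  }, numeric(1))
  data.frame(k = ks, eer = ee)
}

#' EER from synergies restricted to one grasp type
#'
#' Synergies are re-extracted from the grasps of a single type (four
#' objects, five for the hook type in the default taxonomy) and the
#' standard evaluation is run.
#'
#' @param population a \code{\linkS4class{SynergyPopulation}}.
#' @param type grasp-type label present in the population's object table.
#' @param mask,synergyIndices,maxShift as in \code{\link{collectScores}}.
#' @return an \code{\linkS4class{EERResult}}; the \code{ScoreSet} used is
#'   attached as attribute \code{"scores"}.
#' @export
graspTypeEER <- function(population, type, mask = "all",
                         synergyIndices = 1L, maxShift = 20L) {
  stopifnot(is(population, "SynergyPopulation"))
  objects <- population@objects$object[population@objects$graspType == type]
  if (!length(objects))
    stop("graspTypeEER: unknown grasp type: ", type)
  sets <- .withFalseEntries(.populationSets(population, objects))
  ss <- .collectFromSets(sets, mask, synergyIndices, maxShift)
  res <- computeEER(ss)
  attr(res, "scores") <- ss
  res
}

#' Short-term stability of a subject's synergy key
#'
#' Matched synergy correlation (percent of maximum) of each of a subject's
#' later sessions -- initial entry repetitions and follow-up sessions --
#' against the registration template.
#'
#' @param population a \code{\linkS4class{SynergyPopulation}}.
#' @param subjectId subject to report on.
#' @param mask,synergyIndices,maxShift as in \code{\link{collectScores}}.
#' @return data.frame with columns \code{session}, \code{type}
#'   (\code{entry}/\code{followUp}) and \code{score}.
#' @export
stabilityReport <- function(population, subjectId, mask = "all",
                            synergyIndices = 1L, maxShift = 20L) {
  ids <- vapply(population@subjects, `[[`, character(1), "subjectId")
  idx <- match(subjectId, ids)
  if (is.na(idx)) stop("stabilityReport: unknown subject: ", subjectId)
  s <- population@subjects[[idx]]
  sess <- c(s$entries, s$followUps)
  types <- c(rep("entry", length(s$entries)),
             rep("followUp", length(s$followUps)))
  sc <- vapply(sess, function(e)
    .scoreOne(s$template, e, jointMask(mask), synergyIndices, maxShift),
    numeric(1))
  data.frame(session = seq_along(sess), type = types, score = sc)
}
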