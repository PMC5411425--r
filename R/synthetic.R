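#' @include imaging.R
NULL

#' The 25-object, six-grasp-type catalog
#'
#' Twenty-five everyday objects spanning six grasp types -- power,
#' precision, hook, tripod, lateral key and spherical -- with four objects
#' per type except hook, which has five.
#'
#' @return data.frame with columns \code{object} and \code{graspType}.
#' @examples
#' table(objectCatalog()$graspType)
#' @export
objectCatalog <- function() {
  data.frame(
    object = c("water_bottle", "screwdriver", "hammer", "soda_can",
               "cd", "petri_dish", "coin", "button",
               "bag_handle", "bracelet", "mug_handle", "bucket_handle",
               "suitcase_handle",
               "pen", "chalk", "fork", "straw",
               "key", "credit_card", "business_card", "usb_stick",
               "tennis_ball", "apple", "doorknob", "light_bulb"),
    graspType = rep(c("power", "precision", "hook", "tripod",
                      "lateral_key", "spherical"),
                    times = c(4, 4, 5, 4, 4, 4)))
}

## smooth per-joint bump dictionary, one flattened column per component
.rawBasis <- function(k, L) {
  t <- seq_len(L)
  vapply(seq_len(k), function(i) {
    prof <- vapply(seq_len(10L), function(j) {
      nb <- sample(1:3, 1)
      centers <- stats::runif(nb, 20, 110)
      widths <- stats::runif(nb, 7, 12)
      amps <- stats::rnorm(nb)
      rowSums(vapply(seq_len(nb), function(b)
        amps[b] * exp(-(t - centers[b])^2 / (2 * widths[b]^2)),
        numeric(L)))
    }, numeric(L))
    as.vector(prof)                      # joint-major, length 10 L
  }, numeric(10L * L))
}

.orthonormalize <- function(B) {
  Q <- qr.Q(qr(B))
  for (i in seq_len(ncol(Q))) {
    j <- which.max(abs(Q[, i]))
    if (Q[j, i] < 0) Q[, i] <- -Q[, i]
  }
  Q
}

.columnsToBasis <- function(Q, L) {
  lapply(seq_len(ncol(Q)), function(i) unflattenProfile(Q[, i], L))
}

#' Simulated subject: latent synergy basis and mixing weights
#'
#' A subject is modelled as k orthonormal smooth synergy components (sums
#' of Gaussian velocity bumps per joint, orthonormalized over the flattened
#' 10 L space) plus per-object mixing weights held fixed across
#' repetitions.  Weight columns are orthogonalized and standardized so that component i
#' carries exactly the configured fraction of weight variance:
#' \code{dominantShare} for synergy 1 (default 0.54) and the remainder
#' split evenly.
#'
#' @param seed integer seed; the same seed reproduces the subject
#'   bit-identically.
#' @param k number of latent components (default 5).
#' @param dominantShare fraction of weight variance on component 1.
#' @param noiseSd within-subject trial noise SD, degrees/second.
#' @param nObjects number of grasped objects (default 25).
#' @param L fixed profile length.
#' @param rate sampling rate, Hz.
#' @param weightScale overall weight scale in degrees/second (sets peak
#'   velocities to a few hundred deg/s, typical of rapid grasping).
#' @param subjectId label.
#' @return list of class \code{SubjectSpec}: \code{basis} (list of 10 x L
#'   matrices), \code{weights} (nObjects x k), \code{splayOffsets} (the
#'   subject's abduction tendencies, degrees), and the generator settings.
#' @export
makeSubject <- function(seed, k = 5L, dominantShare = 0.54, noiseSd = 5,
                        nObjects = 25L, L = 151L, rate = 125,
                        weightScale = 350, subjectId = paste0("S", seed)) {
  stopifnot(k >= 1L, k <= 10L * L, dominantShare > 0, dominantShare < 1)
  if (k > nObjects)
    stop("makeSubject: k must not exceed nObjects ",
         "(the weight columns are orthogonalized over objects)")
  out <- .withSeed(seed, {
    Q <- .orthonormalize(.rawBasis(k, L))
    W <- matrix(stats::rnorm(nObjects * k), nObjects, k)
    splay <- stats::rnorm(5, sd = 2)
    list(Q = Q, W = W, splay = splay)
  })
  shares <- if (k == 1L) 1 else
    c(dominantShare, rep((1 - dominantShare) / (k - 1), k - 1L))
  sds <- weightScale * sqrt(shares)
  ## orthogonalize the weight columns, then set their norms exactly:
  ## with orthonormal basis columns this makes the configured variance
  ## shares hold by construction in the mixed velocity matrix
  W <- .orthonormalize(out$W)
  for (i in seq_len(k))
    W[, i] <- W[, i] * sqrt(nObjects) * sds[i]
  spec <- list(subjectId = subjectId, basis = .columnsToBasis(out$Q, L),
               weights = W, k = k, dominantShare = dominantShare,
               noiseSd = noiseSd, L = L, rate = rate,
               weightScale = weightScale, splayOffsets = out$splay,
               seed = as.integer(seed))
  class(spec) <- "SubjectSpec"
  spec
}

#' @export
print.SubjectSpec <- function(x, ...) {
  cat(sprintf(
    "SubjectSpec %s: %d components (share %.2f on #1), %d objects, noise %.1f deg/s\n",
    x$subjectId, x$k, x$dominantShare, nrow(x$weights), x$noiseSd))
  invisible(x)
}

.smoothNoise <- function(L, ncols, sd, width = 3) {
  if (sd <= 0) return(matrix(0, L, ncols))
  kern <- exp(-(seq(-3 * width, 3 * width))^2 / (2 * width^2))
  kern <- kern / sqrt(sum(kern^2))       # preserves the marginal SD
  raw <- matrix(stats::rnorm(L * ncols), L, ncols)
  apply(raw, 2, function(col) {
    f <- stats::filter(col, kern, sides = 2, circular = TRUE)
    as.numeric(f) * sd
  })
}

#' Simulate glove recordings for one subject
#'
#' Each grasp's angular velocity is the weighted sum of the subject's
#' latent components (weights fixed per object across repetitions) plus
#' smooth within-subject noise; velocities are integrated (trapezoid rule)
#' to joint angles to produce recordings as a glove would capture them.
#'
#' @param subject a \code{SubjectSpec} from \code{\link{makeSubject}}.
#' @param objects data.frame as \code{\link{objectCatalog}}; row count must
#'   match the subject's weight matrix.
#' @param repetitions number of repetitions per object.
#' @param seed seed for the trial noise.
#' @param basis optional replacement basis (e.g. a drifted follow-up
#'   basis); defaults to the subject's own.
#' @return list of \code{\linkS4class{RawRecording}}, objects nested within
#'   repetition.
#' @export
simulateTrials <- function(subject, objects = objectCatalog(),
                           repetitions = 3L, seed = subject$seed + 1L,
                           basis = NULL) {
  stopifnot(inherits(subject, "SubjectSpec"),
            nrow(objects) == nrow(subject$weights))
  if (is.null(basis)) basis <- subject$basis
  L <- subject$L
  flat <- vapply(basis, function(s) flattenProfile(t(s)), numeric(10L * L))
  .withSeed(seed, {
    recs <- list()
    for (rep in seq_len(repetitions)) {
      for (o in seq_len(nrow(objects))) {
        v <- matrix(flat %*% subject$weights[o, ], L, 10L)
        v <- v + .smoothNoise(L, 10L, subject$noiseSd)
        ang <- apply(v, 2, function(col)
          c(0, cumsum((col[-1] + col[-L]) / 2)) / subject$rate)
        colnames(ang) <- jointLabels()
        recs[[length(recs) + 1L]] <- RawRecording(
          ang, rate = subject$rate, subjectId = subject$subjectId,
          objectId = objects$object[o], graspType = objects$graspType[o],
          repetition = rep)
      }
    }
    recs
  })
}

.driftBasis <- function(subject, drift, seed) {
  if (drift <= 0) return(subject$basis)
  L <- subject$L
  flat <- vapply(subject$basis, function(s) flattenProfile(t(s)),
                 numeric(10L * L))
  .withSeed(seed, {
    pert <- flat + drift * .orthonormalize(.rawBasis(subject$k, L))
    .columnsToBasis(.orthonormalize(pert), L)
  })
}

.sessionMatrix <- function(recordings, L = 151L,
                           thresholdFraction = 0.05) {
  profiles <- lapply(recordings, function(r)
    padToFixed(segmentTrial(r, thresholdFraction), L))
  buildVelocityMatrix(profiles,
                      rowLabels = vapply(recordings, function(r)
                        r@objectId, character(1)))
}

#' Generate a full simulated study population
#'
#' Builds the complete verification dataset: for every subject a
#' registration session (repetition 1, the template), two initial entry
#' sessions (repetitions 2 and 3) and -- for the follow-up subset -- extra
#' entry sessions recorded with a slightly drifted synergy basis.  Each
#' session is segmented, padded, assembled into its grasp-by-feature matrix
#' and decomposed into a \code{\linkS4class{SynergySet}}.  The posture
#' protocol (which subject performs which posture images, and who acts as
#' imposter for whom) is planned here and rendered on demand by
#' \code{\link{collectPostureScores}}.
#'
#' \code{subjectMode} controls the identity structure: independent random
#' bases per subject (default), bases orthonormalized jointly across
#' subjects (\code{"orthogonal"}, mutually orthogonal identities), or one
#' shared basis-and-weights for everyone (\code{"clones"}, no identity
#' information).
#'
#' @param nSubjects number of subjects (default 10).
#' @param objects object catalog (default \code{\link{objectCatalog}}).
#' @param repetitions grasping repetitions per object (default 3; the
#'   first is the template session).
#' @param followUpSubjects indices of subjects with a follow-up session.
#' @param followUpAttempts extra entry sessions for those subjects
#'   (default 4, giving 5 x 2 + 5 x 6 = 40 true conditions at the default
#'   design).
#' @param followUpDrift basis drift magnitude for follow-up sessions.
#' @param k,dominantShare,noiseSd,weightScale,L,rate generator settings;
#'   see \code{\link{makeSubject}}.
#' @param n synergies retained per session (default 10).
#' @param subjectMode \code{"independent"}, \code{"orthogonal"} or
#'   \code{"clones"}.
#' @param seed root seed; every random quantity derives from it.
#' @return a \code{\linkS4class{SynergyPopulation}}.
#' @export
makePopulation <- function(nSubjects = 10L, objects = objectCatalog(),
                           repetitions = 3L,
                           followUpSubjects = seq_len(min(5L, nSubjects)),
                           followUpAttempts = 4L, followUpDrift = 0.1,
                           k = 5L, dominantShare = 0.54, noiseSd = 5,
                           weightScale = 350, L = 151L, rate = 125,
                           n = 10L,
                           subjectMode = c("independent", "orthogonal",
                                           "clones"),
                           seed = 1L) {
  subjectMode <- match.arg(subjectMode)
  seed <- as.integer(seed)
  G <- nrow(objects)
  nKeep <- min(n, G)

  subjects <- lapply(seq_len(nSubjects), function(s)
    makeSubject(seed + 7919L * s, k = k, dominantShare = dominantShare,
                noiseSd = noiseSd, nObjects = G, L = L, rate = rate,
                weightScale = weightScale, subjectId = paste0("S", s)))

  if (subjectMode == "orthogonal") {
    allFlat <- .withSeed(seed + 13L,
      .orthonormalize(.rawBasis(nSubjects * k, L)))
    for (s in seq_len(nSubjects)) {
      cols <- ((s - 1L) * k + 1L):(s * k)
      subjects[[s]]$basis <- .columnsToBasis(
        allFlat[, cols, drop = FALSE], L)
    }
  } else if (subjectMode == "clones") {
    for (s in seq_len(nSubjects)) {
      subjects[[s]]$basis <- subjects[[1L]]$basis
      subjects[[s]]$weights <- subjects[[1L]]$weights
    }
  }

  built <- lapply(seq_len(nSubjects), function(s) {
    sub <- subjects[[s]]
    recs <- simulateTrials(sub, objects, repetitions,
                           seed = seed + 7919L * s + 1L)
    byRep <- split(recs, vapply(recs, function(r) r@repetition, integer(1)))
    Vs <- lapply(byRep, .sessionMatrix, L = L)
    fuVs <- list()
    if (s %in% followUpSubjects && followUpAttempts > 0L) {
      fb <- .driftBasis(sub, followUpDrift, seed + 7919L * s + 2L)
      fuRecs <- simulateTrials(sub, objects, followUpAttempts,
                               seed = seed + 7919L * s + 3L, basis = fb)
      fuByRep <- split(fuRecs,
                       vapply(fuRecs, function(r) r@repetition, integer(1)))
      fuVs <- lapply(fuByRep, .sessionMatrix, L = L)
    }
    list(subjectId = sub$subjectId, spec = sub,
         templateV = Vs[[1L]],
         template = extractSynergies(Vs[[1L]], n = nKeep),
         entryVs = unname(Vs[-1L]),
         entries = lapply(unname(Vs[-1L]), extractSynergies, n = nKeep),
         followUpVs = unname(fuVs),
         followUps = lapply(unname(fuVs), extractSynergies, n = nKeep))
  })

  nImp <- nSubjects %/% 2L
  plan <- if (nImp >= 1L)
    data.frame(victim = seq_len(nImp),
               performer = nSubjects - nImp + seq_len(nImp))
  else data.frame(victim = integer(0), performer = integer(0))

  new("SynergyPopulation", subjects = built, objects = objects,
      params = list(nSubjects = nSubjects, repetitions = repetitions,
                    followUpSubjects = followUpSubjects,
                    followUpAttempts = followUpAttempts,
                    followUpDrift = followUpDrift, k = k,
                    dominantShare = dominantShare, noiseSd = noiseSd,
                    weightScale = weightScale, L = L, rate = rate,
                    n = nKeep, subjectMode = subjectMode,
                    posturePlan = plan, postureAttempts = 2L),
      seed = seed)
}

#' Render the posture protocol and collect per-attempt errors
#'
#' For each subject and each requested synergy rank, the subject's
#' postural synergy (gain-limited end posture of the template synergy) is
#' rendered three times with the subject's own abduction offsets and small
#' joint jitter -- once as the stored template image and twice as authentic
#' entry attempts -- and scored against the template.  Imposter attempts
#' re-render the victim's posture with the imposter's abduction offsets
#' and larger jitter, emulating an imposter replicating a memorized
#' posture.  Attempts whose silhouette fails finger detection are recorded
#' with \code{NA} error and the failure reason.
#'
#' @param population a \code{\linkS4class{SynergyPopulation}}.
#' @param synergies synergy ranks to render (default 1:10).
#' @param resolution render resolution, pixels.
#' @param authenticJitter,imposterJitter joint-angle jitter SDs, degrees.
#' @param geometry a \code{\linkS4class{HandGeometry}}.
#' @param prominence finger-peak prominence floor.
#' @return data.frame with columns \code{posture} (synergy rank),
#'   \code{subject} (victim/template owner), \code{performer},
#'   \code{attempt}, \code{authentic}, \code{error}, \code{reason}.
#' @export
collectPostureScores <- function(population, synergies = 1:10,
                                 resolution = 320L, authenticJitter = 2,
                                 imposterJitter = 5,
                                 geometry = handGeometry(),
                                 prominence = 0.05) {
  stopifnot(is(population, "SynergyPopulation"))
  seed <- population@seed
  plan <- population@params$posturePlan
  nAtt <- population@params$postureAttempts
  subs <- population@subjects
  rows <- list()
  for (si in seq_along(subs)) {
    sub <- subs[[si]]
    spl <- sub$spec$splayOffsets
    syn <- synergies[synergies <= sub$template@n]
    for (p in syn) {
      posture <- selectGain(synergies(sub$template)[[p]], geometry,
                            rate = sub$spec$rate)$posture
      rseed <- function(tag) seed + 104729L * si + 1009L * p + tag
      tmpl <- renderPosture(posture, geometry, resolution,
                            jitterSd = authenticJitter,
                            splayOffsets = spl, seed = rseed(1L))
      tf <- tryCatch(handProfile(tmpl, prominence = prominence)$fingers,
                     fingerDetectionError = function(e) e)
      score <- function(img, performer, attempt, authentic) {
        if (inherits(tf, "fingerDetectionError"))
          return(data.frame(posture = p, subject = sub$subjectId,
                            performer = performer, attempt = attempt,
                            authentic = authentic, error = NA_real_,
                            reason = conditionMessage(tf)))
        ef <- tryCatch(handProfile(img, prominence = prominence)$fingers,
                       fingerDetectionError = function(e) e)
        if (inherits(ef, "fingerDetectionError"))
          data.frame(posture = p, subject = sub$subjectId,
                     performer = performer, attempt = attempt,
                     authentic = authentic, error = NA_real_,
                     reason = conditionMessage(ef))
        else
          data.frame(posture = p, subject = sub$subjectId,
                     performer = performer, attempt = attempt,
                     authentic = authentic,
                     error = sum(vapply(.digitNames(), function(d)
                       fingerError(tf[[d]], ef[[d]]), numeric(1))),
                     reason = NA_character_)
      }
      for (a in seq_len(nAtt)) {
        img <- renderPosture(posture, geometry, resolution,
                             jitterSd = authenticJitter,
                             splayOffsets = spl, seed = rseed(10L + a))
        rows[[length(rows) + 1L]] <-
          score(img, sub$subjectId, a, TRUE)
      }
      vrow <- which(plan$victim == si)
      if (length(vrow)) {
        imp <- subs[[plan$performer[vrow]]]
        for (a in seq_len(nAtt)) {
          img <- renderPosture(posture, geometry, resolution,
                               jitterSd = imposterJitter,
                               splayOffsets = imp$spec$splayOffsets,
                               seed = rseed(20L + a))
          rows[[length(rows) + 1L]] <-
            score(img, imp$subjectId, a, FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}
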