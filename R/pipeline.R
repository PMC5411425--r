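#' @include synthetic.R
NULL

#' Default end-to-end run configuration
#'
#' The settings of the standard simulated verification study: a
#' 10-subject population over the 25-object catalog, synergy-1 matching
#' over all ten joints with a 70% acceptance threshold, the 8-bin chance
#' shuffle, and (optionally) the postural-synergy image protocol.
#'
#' @param seed root seed for the run.
#' @return named list of class \code{RunConfig}.
#' @examples
#' defaultRunConfig()
#' @export
defaultRunConfig <- function(seed = 1L) {
  cfg <- list(
    seed = as.integer(seed),
    nSubjects = 10L, repetitions = 3L,
    followUpAttempts = 4L, followUpDrift = 0.1,
    k = 5L, dominantShare = 0.54, noiseSd = 5,
    weightScale = 350, L = 151L, rate = 125,
    subjectMode = "independent",
    mask = "all", synergyIndices = 1L, maxShift = 20L, Tm = 70,
    chanceDraws = 100L,
    postures = FALSE, postureSynergies = 1:10, resolution = 320L,
    authenticJitter = 2, imposterJitter = 5, Tp = 0.8)
  class(cfg) <- "RunConfig"
  cfg
}

#' @export
print.RunConfig <- function(x, ...) {
  cat("RunConfig:\n")
  for (nm in names(x))
    cat(sprintf("  %-18s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  invisible(x)
}

#' Read / write a run configuration as JSON
#'
#' Unknown fields in the file are rejected; missing fields take their
#' defaults, so a file holding only overrides is valid.
#'
#' @param config a \code{RunConfig} list.
#' @param path file path.
#' @return \code{readRunConfig}: a \code{RunConfig};
#'   \code{writeRunConfig}: \code{path}, invisibly.
#' @export
writeRunConfig <- function(config, path) {
  stopifnot(inherits(config, "RunConfig"))
  jsonlite::write_json(unclass(config), path, digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- defaultRunConfig()
  unknown <- setdiff(names(x), names(cfg))
  if (length(unknown))
    stop("readRunConfig: unknown fields: ", paste(unknown, collapse = ", "))
  for (nm in names(x)) {
    v <- x[[nm]]
    if (is.integer(cfg[[nm]])) v <- as.integer(v)
    cfg[[nm]] <- v
  }
  cfg
}

#' Run the full verification study end to end
#'
#' Simulates the population, extracts per-session synergies, collects
#' authentic and imposter scores, computes the EER, estimates the chance
#' baseline by time-bin shuffling, and summarizes the variance spectrum of
#' the first subject's template.  With \code{config$postures = TRUE} the
#' postural protocol is also rendered and scored.  The run is fully
#' deterministic given \code{config$seed}.
#'
#' @param config a \code{RunConfig}; see \code{\link{defaultRunConfig}}.
#' @param outDir optional directory; when given, the configuration,
#'   score provenance, EER summary and variance table are written there as
#'   JSON/CSV text files.
#' @return list with \code{population}, \code{scores}
#'   (\code{\linkS4class{ScoreSet}}), \code{eer}
#'   (\code{\linkS4class{EERResult}}), \code{acceptance} (fraction of
#'   authentic attempts accepted at \code{Tm}), \code{chance} (chance-score
#'   vector), \code{variance} (variance table of subject 1's template) and,
#'   when requested, \code{postureScores} and \code{postureEER}.
#' @export
runPipeline <- function(config = defaultRunConfig(), outDir = NULL) {
  stopifnot(inherits(config, "RunConfig"))
  population <- makePopulation(
    nSubjects = config$nSubjects, repetitions = config$repetitions,
    followUpAttempts = config$followUpAttempts,
    followUpDrift = config$followUpDrift, k = config$k,
    dominantShare = config$dominantShare, noiseSd = config$noiseSd,
    weightScale = config$weightScale, L = config$L, rate = config$rate,
    subjectMode = config$subjectMode, seed = config$seed)

  scores <- collectScores(population, mask = config$mask,
                          synergyIndices = config$synergyIndices,
                          maxShift = config$maxShift)
  eerRes <- computeEER(scores)
  acceptance <- mean(trueScores(scores) > config$Tm)

  s1 <- population@subjects[[1L]]
  s2 <- population@subjects[[min(2L, length(population@subjects))]]
  chance <- chanceBaseline(s1$template, s2$entries[[1L]],
                           mask = config$mask,
                           draws = config$chanceDraws,
                           synergyIndices = config$synergyIndices,
                           maxShift = config$maxShift,
                           seed = config$seed + 101L)
  variance <- varianceTable(s1$template)

  out <- list(population = population, scores = scores, eer = eerRes,
              acceptance = acceptance, chance = chance,
              variance = variance)

  if (isTRUE(config$postures)) {
    ps <- collectPostureScores(
      population, synergies = config$postureSynergies,
      resolution = config$resolution,
      authenticJitter = config$authenticJitter,
      imposterJitter = config$imposterJitter)
    out$postureScores <- ps
    ok <- ps[!is.na(ps$error), ]
    if (length(unique(ok$authentic)) == 2L)
      out$postureEER <- computeEER(-ok$error[ok$authentic],
                                   -ok$error[!ok$authentic])
  }

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeRunConfig(config, file.path(outDir, "config.json"))
    utils::write.csv(scores@provenance,
                     file.path(outDir, "scores.csv"), row.names = FALSE)
    utils::write.csv(variance,
                     file.path(outDir, "variance.csv"), row.names = FALSE)
    summary <- list(
      eer = eerRes@eer, eerThreshold = eerRes@eerThreshold,
      acceptanceRate = acceptance,
      chanceMean = mean(chance), chanceSd = stats::sd(chance),
      nTrue = length(trueScores(scores)),
      nFalse = length(falseScores(scores)))
    if (!is.null(out$postureEER))
      summary$postureEER <- out$postureEER@eer
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         digits = NA, auto_unbox = TRUE, pretty = TRUE)
    if (!is.null(out$postureScores))
      utils::write.csv(out$postureScores,
                       file.path(outDir, "postures.csv"),
                       row.names = FALSE)
  }
  out
}
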