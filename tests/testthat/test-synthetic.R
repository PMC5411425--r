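test_that("the object catalog spans 25 objects over six grasp types", {
  cat25 <- objectCatalog()
  expect_equal(nrow(cat25), 25L)
  expect_false(anyDuplicated(cat25$object) > 0)
  counts <- table(cat25$graspType)
  expect_equal(length(counts), 6L)
  expect_equal(as.integer(counts[c("power", "precision", "hook", "tripod",
                                   "lateral_key", "spherical")]),
               c(4L, 4L, 5L, 4L, 4L, 4L))
})

test_that("makeSubject is reproducible with an orthonormal smooth basis", {
  s1 <- makeSubject(seed = 42)
  s2 <- makeSubject(seed = 42)
  expect_equal(s1$basis, s2$basis)
  expect_equal(s1$weights, s2$weights)
  expect_length(s1$basis, 5)
  expect_equal(dim(s1$basis[[1]]), c(10L, 151L))
  ## flattened components are orthonormal
  flat <- vapply(s1$basis, function(b) flattenProfile(t(b)), numeric(1510))
  expect_equal(crossprod(flat), diag(5), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_length(s1$splayOffsets, 5)
})

test_that("subject weight columns carry the configured variance shares", {
  s <- makeSubject(seed = 43, dominantShare = 0.54, weightScale = 350)
  W <- s$weights
  ## orthogonal columns with exactly the configured energy split
  cp <- crossprod(W)
  expect_equal(cp, diag(diag(cp)), tolerance = 1e-6, ignore_attr = TRUE)
  shares <- diag(cp) / sum(diag(cp))
  expect_equal(unname(shares), c(0.54, rep(0.115, 4)), tolerance = 1e-10)
  expect_error(makeSubject(seed = 1, dominantShare = 1.2))
})

test_that("simulateTrials integrates the mixed velocities (trapezoid rule)", {
  s <- makeSubject(seed = 44, noiseSd = 0, nObjects = 3L, k = 2L)
  cat3 <- objectCatalog()[1:3, ]
  recs <- simulateTrials(s, cat3, repetitions = 2L)
  expect_length(recs, 6)
  expect_s4_class(recs[[1]], "RawRecording")
  expect_equal(recs[[1]]@rate, 125)
  expect_equal(vapply(recs[1:3], function(r) r@objectId, character(1)),
               cat3$object)
  ## zero noise: angles are the trapezoid integral of the latent mix
  flat <- vapply(s$basis, function(b) flattenProfile(t(b)), numeric(1510))
  v <- matrix(flat %*% s$weights[2, ], 151, 10)
  ang <- apply(v, 2, function(col)
    c(0, cumsum((col[-1] + col[-151]) / 2)) / 125)
  expect_equal(unname(recs[[2]]@angles), unname(ang), tolerance = 1e-9)
  ## repetitions of the same object share weights, differ only by noise
  sN <- makeSubject(seed = 44, noiseSd = 5, nObjects = 3L, k = 2L)
  rN <- simulateTrials(sN, cat3, repetitions = 2L)
  expect_false(identical(rN[[1]]@angles, rN[[4]]@angles))
  expect_error(simulateTrials(s, objectCatalog()), "nrow")
  expect_error(makeSubject(seed = 1, nObjects = 3L, k = 5L),
               "must not exceed")
})

test_that("makePopulation builds the documented session structure", {
  pop <- cachedPopulation()
  expect_s4_class(pop, "SynergyPopulation")
  expect_length(pop@subjects, 10)
  s1 <- pop@subjects[[1]]
  expect_equal(dim(s1$templateV), c(25L, 1510L))
  expect_s4_class(s1$template, "SynergySet")
  expect_equal(nSynergies(s1$template), 10L)
  expect_length(s1$entries, 2)            # repetitions 2 and 3
  ## follow-ups only for the first five subjects, 4 sessions each
  expect_length(s1$followUps, 4)
  expect_length(pop@subjects[[6]]$followUps, 0)
  ## the posture plan pairs 5 victims with the last 5 performers
  plan <- pop@params$posturePlan
  expect_equal(plan$victim, 1:5)
  expect_equal(plan$performer, 6:10)
})

test_that("orthogonal mode makes subject bases mutually orthogonal", {
  pop <- makePopulation(nSubjects = 3L, objects = objectCatalog()[1:6, ],
                        repetitions = 2L, followUpSubjects = integer(0),
                        k = 2L, n = 2L, subjectMode = "orthogonal",
                        seed = 11L)
  flats <- lapply(pop@subjects, function(s)
    vapply(s$spec$basis, function(b) flattenProfile(t(b)), numeric(1510)))
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(crossprod(flats[[i]], flats[[j]]),
                 matrix(0, 2, 2), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("clone mode gives every subject the same latent identity", {
  pop <- makePopulation(nSubjects = 3L, objects = objectCatalog()[1:6, ],
                        repetitions = 2L, followUpSubjects = integer(0),
                        k = 2L, n = 2L, subjectMode = "clones", seed = 12L)
  expect_equal(pop@subjects[[2]]$spec$basis, pop@subjects[[1]]$spec$basis)
  expect_equal(pop@subjects[[3]]$spec$weights,
               pop@subjects[[1]]$spec$weights)
  ## trial noise still differs between subjects
  expect_false(identical(pop@subjects[[1]]$templateV,
                         pop@subjects[[2]]$templateV))
})

test_that("population and subject print methods are informative", {
  expect_output(print(makeSubject(seed = 45)), "components")
  expect_output(show(smallPopulation()), "subjects")
})
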