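test_that("computeVelocity matches a hand-computed difference oracle", {
  set.seed(11)
  a <- matrix(rnorm(8 * 10), 8, 10)
  rec <- RawRecording(a, rate = 125)
  v <- computeVelocity(rec)
  expect_equal(dim(v), dim(a))
  ## interior: central differences; ends: one-sided
  for (j in 1:10) {
    expect_equal(unname(v[1, j]), (a[2, j] - a[1, j]) * 125)
    expect_equal(unname(v[8, j]), (a[8, j] - a[7, j]) * 125)
    for (i in 2:7)
      expect_equal(unname(v[i, j]), (a[i + 1, j] - a[i - 1, j]) / 2 * 125)
  }
})

test_that("computeVelocity reports 125 deg/s on a unit-per-sample ramp", {
  ramp <- RawRecording(matrix(seq(0, 10, length.out = 11), 11, 10),
                       rate = 125)
  v <- computeVelocity(ramp)
  expect_equal(unname(v[5, 1]), 125)
})

test_that("computeVelocity validates the smoothing window", {
  rec <- RawRecording(matrix(rnorm(50), 5, 10))
  expect_error(computeVelocity(rec, smoothWindow = 2), "odd")
  expect_error(computeVelocity(rec, smoothWindow = 0), "odd")
  expect_silent(computeVelocity(rec, smoothWindow = 3))
})

test_that("segmentTrial finds the 5%-of-peak window (brute-force oracle)", {
  set.seed(21)
  L <- 100
  ## quiet head and tail around a strong burst
  a <- matrix(0, L, 10)
  t <- seq_len(L)
  for (j in 1:10)
    a[, j] <- 40 * pnorm(t, mean = 50, sd = 6) + rnorm(L, sd = 0.01)
  rec <- RawRecording(a, rate = 125)
  tr <- segmentTrial(rec)
  ## oracle: recompute velocity and scan every sample directly
  v <- computeVelocity(rec)
  hit <- which(apply(abs(v) >= 0.05 * max(abs(v)), 1, any))
  expect_equal(tr@onset, min(hit))
  expect_equal(tr@offset, max(hit))
  expect_equal(tr@velocity, v[min(hit):max(hit), , drop = FALSE])
  expect_lt(tr@onset, 50)
  expect_gt(tr@offset, 50)
})

test_that("segmentTrial per-joint mode thresholds each joint by its own peak", {
  L <- 80
  a <- matrix(0, L, 10)
  t <- seq_len(L)
  a[, 1] <- 100 * pnorm(t, 40, 4)        # large movement
  a[, 2] <- 1 * pnorm(t, 15, 3)          # small, earlier movement
  rec <- RawRecording(a, rate = 125)
  glob <- segmentTrial(rec, onsetMode = "global")
  perj <- segmentTrial(rec, onsetMode = "per_joint")
  ## per-joint onset catches the small joint's early movement
  expect_lt(perj@onset, glob@onset)
})

test_that("segmentTrial rejects a motionless recording", {
  expect_error(segmentTrial(RawRecording(matrix(1, 10, 10))),
               "no movement")
})

test_that("segmentTrial is idempotent on a GraspTrial", {
  set.seed(31)
  a <- apply(matrix(rnorm(60 * 10, sd = 3), 60, 10), 2, cumsum)
  tr <- segmentTrial(RawRecording(a))
  tr2 <- segmentTrial(tr)
  expect_equal(tr2@velocity, tr@velocity)
  expect_equal(tr2@onset, tr@onset)
})

test_that("padToFixed zero-pads to length and rejects overlong trials", {
  set.seed(41)
  a <- apply(matrix(rnorm(60 * 10, sd = 3), 60, 10), 2, cumsum)
  tr <- segmentTrial(RawRecording(a))
  p <- padToFixed(tr, 151L)
  expect_equal(dim(p), c(151L, 10L))
  n <- nrow(tr@velocity)
  expect_equal(p[seq_len(n), ], unname(tr@velocity), ignore_attr = TRUE)
  expect_true(all(p[(n + 1):151, ] == 0))
  expect_error(padToFixed(tr, n - 1L), "longer than the fixed length")
})

test_that("trial CSV round trip preserves labels, rate and angles", {
  set.seed(51)
  recs <- lapply(1:3, function(i)
    RawRecording(matrix(rnorm(30 * 10), 30, 10), rate = 125,
                 subjectId = paste0("S", i), objectId = "pen",
                 graspType = "tripod", repetition = i))
  path <- tempfile(fileext = ".csv")
  writeTrials(recs, path)
  back <- readTrials(path)
  expect_length(back, 3)
  ## match by repetition label (order of the list is not part of the format)
  reps <- vapply(back, function(r) r@repetition, integer(1))
  for (i in 1:3) {
    b <- back[[which(reps == i)]]
    expect_equal(b@angles, recs[[i]]@angles, tolerance = 1e-8)
    expect_equal(b@rate, 125)
    expect_equal(b@subjectId, paste0("S", i))
    expect_equal(b@graspType, "tripod")
  }
})

test_that("readTrials rejects malformed files and accepts empty ones", {
  path <- tempfile(fileext = ".csv")
  writeLines("a,b,c", path)
  expect_error(readTrials(path), "malformed header")
  file.create(path2 <- tempfile(fileext = ".csv"))
  expect_equal(readTrials(path2), list())
  expect_error(readTrials(tempfile()), "no such file")
})

test_that("RawRecording validity rejects bad shapes", {
  expect_error(RawRecording(matrix(0, 5, 9)), "10 columns")
  expect_error(RawRecording(matrix(NA_real_, 5, 10)), "finite")
  expect_error(RawRecording(matrix(0, 5, 10), rate = -1), "positive")
})
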