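flatPosture <- function() setNames(rep(0, 10), jointLabels())

## build an RGB chroma-key image from a binary mask (white hand on green)
maskToImage <- function(m) {
  arr <- array(0, c(nrow(m), ncol(m), 3))
  arr[, , 1] <- m; arr[, , 3] <- m; arr[, , 2] <- 1
  arr
}

test_that("renderPosture produces a bounded, deterministic RGB array", {
  img <- renderPosture(flatPosture(), resolution = 160L)
  expect_equal(dim(img), c(160L, 160L, 3L))
  expect_true(all(img >= 0 & img <= 1))
  sil <- attr(img, "silhouette")
  expect_equal(dim(sil), c(160L, 160L))
  expect_gt(sum(sil), 0)
  ## the green channel of a chroma-keyed render is saturated everywhere
  expect_true(all(img[, , 2] == 1))
  ## jitter is reproducible under a seed, different across seeds
  j1 <- renderPosture(flatPosture(), resolution = 160L, jitterSd = 3, seed = 5)
  j2 <- renderPosture(flatPosture(), resolution = 160L, jitterSd = 3, seed = 5)
  j3 <- renderPosture(flatPosture(), resolution = 160L, jitterSd = 3, seed = 6)
  expect_identical(j1, j2)
  expect_false(identical(j1, j3))
  expect_error(renderPosture(flatPosture(), resolution = 32L), ">= 64")
})

test_that("segmentHand recovers the renderer's coverage silhouette exactly", {
  img <- renderPosture(flatPosture(), resolution = 160L)
  mask <- segmentHand(img)
  expect_equal(unclass(mask), unclass(attr(img, "silhouette")),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("segmentHand fills interior speckles and drops stray blobs", {
  img <- renderPosture(flatPosture(), resolution = 160L)
  ## a green speckle inside the palm (sensor dropout)
  img[110:112, 78:80, ] <- rep(c(0, 1, 0), each = 9)
  ## a white blob far from the hand
  img[5:8, 5:8, 1] <- 1; img[5:8, 5:8, 3] <- 1
  mask <- segmentHand(img)
  expect_true(all(mask[110:112, 78:80] == 1))   # hole filled
  expect_true(all(mask[5:8, 5:8] == 0))         # blob discarded
  ## all-background image has no component
  expect_error(segmentHand(maskToImage(matrix(0, 64, 64))), "no foreground")
})

test_that("segmentHand rejects a strongly tilted principal axis", {
  m <- matrix(0, 200, 200)
  for (i in 40:160) m[i, (i - 6):(i + 6)] <- 1   # 45-degree bar
  expect_error(segmentHand(maskToImage(m)), "tilted")
  ## a vertical bar at the same size passes
  v <- matrix(0, 200, 200); v[40:160, 94:106] <- 1
  expect_silent(segmentHand(maskToImage(v)))
})

test_that("cropWrist finds the narrowest neck row (width-scan oracle)", {
  ## neck and forearm sit entirely within the lower quarter of the
  ## component, as the renderer's wrist stub does
  m <- matrix(0, 100, 60)
  m[10:70, 10:50] <- 1        # palm, width 41
  m[71:78, 25:32] <- 1        # wrist neck, width 8
  m[79:90, 20:40] <- 1        # forearm, width 21
  out <- cropWrist(m)
  widths <- rowSums(m >= 0.5)
  rows <- which(widths > 0)
  lower <- rows[rows > quantile(rows, 0.75)]
  wmin <- lower[which.min(widths[lower])]
  expect_equal(attr(out, "wristRow"), wmin - 1L)
  expect_true(all(out[wmin:100, ] == 0))
  expect_equal(out[1:(wmin - 1L), ], m[1:(wmin - 1L), ], ignore_attr = TRUE)
  ## idempotent: a cropped mask has no neck left
  again <- cropWrist(out)
  expect_true(is.na(attr(again, "wristRow")))
  expect_equal(unclass(again), unclass(out), ignore_attr = TRUE)
  ## fixedRow override
  fx <- cropWrist(m, fixedRow = 30L)
  expect_true(all(fx[31:100, ] == 0))
  expect_error(cropWrist(matrix(0, 5, 5)), "empty mask")
})

test_that("maskCentroid matches the weighted-mean oracle and translates", {
  m <- matrix(0, 40, 40); m[11:20, 16:25] <- 1
  expect_equal(maskCentroid(m), c(x = 20.5, y = 15.5))
  ## soft weights: direct double-sum oracle
  set.seed(231)
  s <- matrix(runif(30 * 20), 30, 20)
  cc <- maskCentroid(s)
  idx <- which(s > -1, arr.ind = TRUE)
  expect_equal(unname(cc["x"]), sum(s * col(s)) / sum(s))
  expect_equal(unname(cc["y"]), sum(s * row(s)) / sum(s))
  ## translation equivariance
  m2 <- matrix(0, 40, 40); m2[16:25, 11:20] <- 1
  expect_equal(maskCentroid(m2), c(x = 15.5, y = 20.5))
  expect_error(maskCentroid(matrix(0, 4, 4)), "empty mask")
})

test_that("digitOutline of a disk is flat with minimum exactly 1", {
  n <- 200
  d <- sqrt((col(matrix(0, n, n)) - 100.5)^2 +
              (row(matrix(0, n, n)) - 120.5)^2)
  m <- pmin(pmax(60.5 - d, 0), 1)        # antialiased disk, radius 60
  p <- digitOutline(m, centroid = c(x = 100.5, y = 120.5))
  expect_s4_class(p, "RadialProfile")
  expect_equal(min(p@distance), 1)
  expect_lt(max(p@distance), 1.005)      # flat up to blur/grid effects
  expect_equal(p@minDistance, 60, tolerance = 0.05)
  ## RadialProfile validity pins the normalization
  bad <- p
  expect_error({bad@distance <- bad@distance + 0.5; validObject(bad)},
               "minimum")
})

test_that("splitFingers finds five ordered fingertips on a flat hand", {
  img <- renderPosture(flatPosture(), resolution = 320L)
  hp <- handProfile(img)
  f <- hp$fingers
  expect_named(f, c("thumb", "index", "middle", "ring", "pinky"))
  pk <- vapply(f, `[[`, numeric(1), "peakAngle")
  ## thumb-to-pinky runs from the large-angle side down
  expect_true(all(diff(pk) < 0))
  ## the middle finger points roughly upward
  expect_lt(abs(pk[["middle"]] - 90), 15)
  ## segments partition the grid
  expect_equal(sum(vapply(f, `[[`, integer(1), "n")),
               length(hp$profile@distance))
  ## a disk has no fingertip structure
  n <- 200
  d <- sqrt((col(matrix(0, n, n)) - 100.5)^2 +
              (row(matrix(0, n, n)) - 120.5)^2)
  disk <- pmin(pmax(60.5 - d, 0), 1)
  expect_error(splitFingers(digitOutline(disk)),
               class = "fingerDetectionError")
})

test_that("fingerError pads the shorter outline with zeros", {
  a <- list(finger = "index", distance = c(1, 1.2, 1.4))
  b <- list(finger = "index", distance = c(1, 1.2, 1.4, 1.1, 1.0))
  expect_equal(fingerError(a, b), sqrt(1.1^2 + 1.0^2))
  expect_equal(fingerError(a, b), fingerError(b, a))
  expect_equal(fingerError(a, a), 0)
  expect_error(fingerError(a, list(finger = "ring", distance = 1)),
               "labels differ")
})

test_that("postureVerify accepts identical images and rejects strictly", {
  img <- renderPosture(flatPosture(), resolution = 320L)
  r <- postureVerify(img, img)
  expect_s3_class(r, "PostureScore")
  expect_equal(r$total, 0)
  expect_true(r$accept)
  expect_true(is.na(r$reason))
  ## acceptance is strict: total 0 does not pass Tp = 0
  r0 <- postureVerify(img, img, Tp = 0)
  expect_false(r0$accept)
  ## a finger-detection failure is a reasoned rejection, not an error
  ## (vertical ellipse: upright principal axis, but no fingertip peaks)
  n <- 320
  d <- sqrt(((col(matrix(0, n, n)) - 160.5) / 50)^2 +
              ((row(matrix(0, n, n)) - 160.5) / 90)^2)
  ellImg <- maskToImage((d <= 1) * 1)
  rf <- postureVerify(img, ellImg)
  expect_false(rf$accept)
  expect_match(rf$reason, "finger")
  expect_output(print(rf), "rejected")
})

test_that("bestPostures ranks by authentic error and combines by maximum", {
  df <- expand.grid(posture = c("p1", "p2"), attempt = 1:4,
                    authentic = c(TRUE, FALSE),
                    stringsAsFactors = FALSE)
  ## p1 replicates well for authentics and poorly for imposters;
  ## p2 is uniformly mediocre
  df$error <- ifelse(df$posture == "p1",
                     ifelse(df$authentic, 0.1, 2.0),
                     ifelse(df$authentic, 0.5, 0.6))
  res <- bestPostures(df, k = 1L)
  expect_equal(res$selected, "p1")
  expect_equal(as.numeric(res$ranking), c(0.1, 0.5), tolerance = 1e-12)
  expect_equal(eer(res$eer), 0)
  expect_error(bestPostures(df, k = 3L), "exceeds")
})
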