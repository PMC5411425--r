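test_that("the default hand geometry is valid and dimensioned in mm", {
  g <- handGeometry()
  expect_s4_class(g, "HandGeometry")
  validObject(g)
  expect_equal(dim(g@fingerLengths), c(4L, 3L))
  expect_length(g@thumbLengths, 2)
  expect_equal(diff(range(g@palm[, "x"])), 80)
  expect_equal(diff(range(g@palm[, "y"])), 90)
  ## validity rejects a non-simple (self-intersecting) palm polygon
  bad <- g
  expect_error({bad@palm <- bad@palm[c(1, 3, 2, 4), ]; validObject(bad)},
               "simple")
  expect_error(handGeometry(fingerRadius = -1), "positive")
})

test_that("hand geometry JSON round trip is lossless", {
  g <- handGeometry(palmWidth = 72, splay = c(-25, -6, 0, 4, 11))
  path <- tempfile(fileext = ".json")
  writeHandGeometry(g, path)
  b <- readHandGeometry(path)
  expect_equal(b@fingerLengths, g@fingerLengths)
  expect_equal(b@thumbLengths, g@thumbLengths)
  expect_equal(b@palm, g@palm)
  expect_equal(b@mcpBases, g@mcpBases)
  expect_equal(b@splay, g@splay)
  expect_equal(b@fingerRadius, g@fingerRadius)
})

test_that("integrateSynergy is the rectangle rule scaled by gain/rate", {
  set.seed(211)
  syn <- matrix(rnorm(10 * 151), 10, 151)
  a <- integrateSynergy(syn, gain = 2.5, rate = 125)
  expect_equal(unname(a), 2.5 * rowSums(syn) / 125)
  expect_equal(names(a), jointLabels())
  ## doubling the gain doubles every angle
  expect_equal(integrateSynergy(syn, gain = 5), 2 * integrateSynergy(syn, 2.5))
})

test_that("forwardKinematics matches planar trigonometry oracles", {
  g <- handGeometry()
  zero <- setNames(rep(0, 10), jointLabels())
  ch <- forwardKinematics(g, zero)
  expect_named(ch, c("thumb", "index", "middle", "ring", "pinky"))
  ## straight digit: tip = base + total length along the reference axis
  for (k in 2:5) {
    d <- names(ch)[k]
    u <- c(sin(g@splay[k] * pi / 180), cos(g@splay[k] * pi / 180))
    tip <- g@mcpBases[d, ] + sum(g@fingerLengths[d, ]) * u
    expect_equal(unname(ch[[d]]["tip", ]), unname(tip), tolerance = 1e-10)
  }
  expect_equal(unname(ch$thumb["tip", ]),
               unname(g@mcpBases["thumb", ] +
                        sum(g@thumbLengths) *
                          c(sin(-30 * pi / 180), cos(-30 * pi / 180))),
               tolerance = 1e-10)
  ## 90 degree MCP flexion with straight IP joints: the whole chain past
  ## the MCP is displaced perpendicular to the digit axis, toward the palm
  p90 <- zero; p90["M_MCP"] <- 90
  ch90 <- forwardKinematics(g, p90)
  u <- attr(ch90$middle, "axis"); w <- c(u[2], -u[1])
  expect_equal(unname(ch90$middle["tip", ]),
               unname(g@mcpBases["middle", ] +
                        sum(g@fingerLengths["middle", ]) * w),
               tolerance = 1e-10)
  ## scaling all segment lengths scales the chain about its base
  g2 <- handGeometry(fingerLengths = 2 * handGeometry()@fingerLengths)
  p <- zero; p["I_MCP"] <- 35; p["I_PIP"] <- 50
  c1 <- forwardKinematics(g, p)$index
  c2 <- forwardKinematics(g2, p)$index
  b <- g@mcpBases["index", ]
  expect_equal(sweep(unclass(c2), 2, b) , 2 * sweep(unclass(c1), 2, b),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("crossesPalm is strict at the palm edge", {
  g <- handGeometry()
  zero <- setNames(rep(0, 10), jointLabels())
  ch <- forwardKinematics(g, zero)
  expect_false(crossesPalm(g, ch$index))
  ## fold the finger back far enough that the DIP goes below the edge
  p <- zero; p["I_MCP"] <- 90; p["I_PIP"] <- 90
  chF <- forwardKinematics(g, p)
  expect_true(crossesPalm(g, chF$index))
  ## 90/0: the DIP sits exactly at the edge height -- not a crossing
  p2 <- zero; p2["I_MCP"] <- 90
  expect_false(crossesPalm(g, forwardKinematics(g, p2)$index))
})

test_that("selectGain reproduces the closed-form ROM bound", {
  set.seed(221)
  for (rep in 1:5) {
    syn <- matrix(rnorm(10 * 151, sd = 2), 10, 151)
    r <- selectGain(syn)
    unit <- integrateSynergy(syn, gain = 1)
    bound <- ifelse(unit > 0, 90 / unit, ifelse(unit < 0, -10 / unit, Inf))
    expect_equal(r$romGain, min(bound), tolerance = 1e-12)
    ## the chosen gain keeps every joint inside the ROM
    expect_true(all(r$posture <= 90 + 1e-9 & r$posture >= -10 - 1e-9))
    expect_lte(r$gain, r$romGain + 1e-12)
    expect_identical(r$reduced, r$gain < r$romGain)
  }
})

test_that("selectGain is grid-maximal under the palm criterion", {
  set.seed(222)
  g <- handGeometry()
  compliant <- function(syn, gain) {
    posture <- integrateSynergy(syn, gain)
    if (any(posture > 90 + 1e-9 | posture < -10 - 1e-9)) return(FALSE)
    ch <- forwardKinematics(g, posture)
    !any(vapply(ch[-1], function(c) crossesPalm(g, c), logical(1)))
  }
  for (rep in 1:20) {
    syn <- matrix(rnorm(10 * 151, sd = 2), 10, 151)
    r <- selectGain(syn)
    expect_true(compliant(syn, r$gain))
    ## one step larger on the search grid must violate a constraint
    if (r$reduced) expect_false(compliant(syn, r$gain + 0.01))
  }
})

test_that("selectGain rejects a degenerate zero-posture synergy", {
  expect_error(selectGain(matrix(0, 10, 151)), "degenerate")
})
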