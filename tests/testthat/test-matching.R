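test_that("jointMask presets and explicit labels behave as documented", {
  expect_equal(jointMask("all"), jointLabels())
  expect_length(jointMask("mcp_only"), 5)
  expect_true(all(endsWith(jointMask("mcp_only"), "_MCP")))
  expect_length(jointMask("minus_thumb"), 8)
  expect_false(any(startsWith(jointMask("minus_thumb"), "T_")))
  expect_equal(jointMask(c("T_MCP", "I_PIP")), c("T_MCP", "I_PIP"))
  expect_error(jointMask("X_MCP"), "unknown joint")
  expect_error(jointMask(character(0)), "non-empty")
})

test_that("jointCorrelation matches cor() and zero-variance gives 0", {
  set.seed(121)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(jointCorrelation(a, b), cor(a, b))
  expect_equal(jointCorrelation(a, a), 1)
  expect_equal(jointCorrelation(a, rep(2, 50)), 0)
  expect_equal(jointCorrelation(rep(0, 50), rep(0, 50)), 0)
  expect_error(jointCorrelation(a, b[-1]), "equal length")
})

test_that("a synergy against itself scores the maximum 10 at shift 0", {
  syn <- bumpSynergy(seed = 2)
  r <- shiftedSummedCorrelation(syn, syn)
  expect_equal(r$score, 10, tolerance = 1e-10)
  expect_equal(r$shift, 0L)
  expect_equal(unname(r$perJoint), rep(1, 10), tolerance = 1e-10)
})

test_that("a delayed entry is re-aligned at the opposite shift", {
  syn <- bumpSynergy(seed = 3)            # support away from both ends
  delayed <- cbind(matrix(0, 10, 5), syn[, 1:(151 - 5)])
  r <- shiftedSummedCorrelation(syn, delayed)
  expect_equal(r$shift, -5L)
  expect_equal(r$score, 10, tolerance = 1e-10)
})

test_that("shiftedSummedCorrelation matches the brute-force oracle", {
  set.seed(131)
  for (rep in 1:10) {
    A <- matrix(rnorm(10 * 60), 10, 60)
    B <- matrix(rnorm(10 * 60), 10, 60)
    r <- shiftedSummedCorrelation(A, B, maxShift = 10L)
    expect_equal(r$score,
                 oracleSummedCorrelation(A, B, maxShift = 10L),
                 tolerance = 1e-10)
  }
  ## masked variant
  A <- matrix(rnorm(10 * 60), 10, 60)
  B <- matrix(rnorm(10 * 60), 10, 60)
  r <- shiftedSummedCorrelation(A, B, mask = "mcp_only", maxShift = 8L)
  expect_equal(r$score,
               oracleSummedCorrelation(A, B, jointMask("mcp_only"), 8L),
               tolerance = 1e-10)
})

test_that("all-constant profiles tie at score 0 and break to shift 0", {
  A <- matrix(1, 10, 50)
  B <- matrix(2, 10, 50)
  r <- shiftedSummedCorrelation(A, B)
  expect_equal(r$score, 0)
  expect_equal(r$shift, 0L)
})

test_that("shiftedSummedCorrelation validates its arguments", {
  syn <- bumpSynergy()
  expect_error(shiftedSummedCorrelation(syn, syn, maxShift = 151),
               "maxShift")
  expect_error(shiftedSummedCorrelation(syn, syn[, 1:100]))
})

test_that("greedy pairing follows the rank-order iterative-removal rule", {
  for (seed in c(141, 142, 143)) {
    tpl <- randomSynergySet(4, seed = seed)
    ent <- randomSynergySet(4, seed = seed + 50)
    mr <- pairSynergies(tpl, ent)
    p <- matchedPairs(mr)
    expect_equal(p$templateIndex, 1:4)
    expect_false(anyDuplicated(p$entryIndex) > 0)
    ## oracle: re-run the greedy rule with independently computed scores
    avail <- 1:4
    for (i in 1:4) {
      sc <- vapply(avail, function(j)
        oracleSummedCorrelation(synergies(tpl)[[i]], synergies(ent)[[j]]),
        numeric(1))
      expect_equal(p$entryIndex[i], avail[which.max(sc)])
      expect_equal(p$score[i], max(sc), tolerance = 1e-10)
      avail <- setdiff(avail, avail[which.max(sc)])
    }
  }
})

test_that("optimal pairing matches exhaustive assignment enumeration", {
  for (seed in c(151, 152)) {
    tpl <- randomSynergySet(3, seed = seed)
    ent <- randomSynergySet(4, seed = seed + 50)
    mr <- pairSynergies(tpl, ent, method = "optimal")
    tot <- sum(matchedPairs(mr)$score)
    ## oracle: enumerate every one-to-one assignment
    perms <- oraclePermutations(4, 3)
    best <- max(apply(perms, 1, function(pp)
      sum(vapply(1:3, function(i)
        oracleSummedCorrelation(synergies(tpl)[[i]],
                                synergies(ent)[[pp[i]]]),
        numeric(1)))))
    expect_equal(tot, best, tolerance = 1e-10)
    ## the optimal total is never below the greedy total
    expect_gte(tot + 1e-10,
               sum(matchedPairs(pairSynergies(tpl, ent))$score))
  }
})

test_that("pairSynergies upTo limits the pair count", {
  tpl <- randomSynergySet(5, seed = 161)
  ent <- randomSynergySet(5, seed = 162)
  expect_equal(nrow(matchedPairs(pairSynergies(tpl, ent, upTo = 2))), 2L)
})

test_that("timeBinLengths gives 7 bins of 20 plus an 11-sample last bin", {
  lens <- timeBinLengths()
  expect_length(lens, 8)
  expect_equal(lens, c(rep(20L, 7), 11L))
  expect_equal(sum(lens), 151L)
  expect_error(timeBinLengths(L = 300L), "invalid binning")
})

test_that("chanceBaseline is seeded, sized, and bounded", {
  tpl <- randomSynergySet(3, seed = 171)
  ent <- randomSynergySet(3, seed = 172)
  c1 <- chanceBaseline(tpl, ent, draws = 20L, seed = 7)
  c2 <- chanceBaseline(tpl, ent, draws = 20L, seed = 7)
  expect_equal(c1, c2)
  expect_length(c1, 20)
  expect_true(all(c1 >= -100 & c1 <= 100))
  ## shuffling destroys alignment: chance stays below the matched score
  matched <- verifySynergies(tpl, tpl)$score
  expect_lt(mean(c1), matched)
})

test_that("verifySynergies accepts iff score strictly exceeds Tm", {
  s <- randomSynergySet(3, seed = 181)
  r <- verifySynergies(s, s, Tm = 99.9)
  expect_true(r$accept)
  expect_equal(r$score, 100, tolerance = 1e-8)
  ## a score exactly equal to the threshold is rejected
  r2 <- verifySynergies(s, randomSynergySet(3, seed = 182), Tm = 0)
  r3 <- verifySynergies(s, randomSynergySet(3, seed = 182), Tm = r2$score)
  expect_false(r3$accept)
  expect_error(verifySynergies(s, s, synergyIndices = 4L), "outside 1..n")
})

test_that("MatchResult validity rejects a reused entry synergy", {
  tpl <- randomSynergySet(2, seed = 191)
  mr <- pairSynergies(tpl, tpl)
  bad <- mr
  expect_error({bad@pairs$entryIndex <- c(1L, 1L); validObject(bad)},
               "twice")
})
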