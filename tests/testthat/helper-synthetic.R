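## shared fixtures, built once per test run and memoized

.synkeyTestCache <- new.env(parent = emptyenv())

## the full default simulated study population (the study conditions)
cachedPopulation <- function() {
  if (is.null(.synkeyTestCache$pop))
    .synkeyTestCache$pop <- makePopulation(seed = 1L)
  .synkeyTestCache$pop
}

## authentic/imposter movement scores over the default population
cachedScores <- function() {
  if (is.null(.synkeyTestCache$scores))
    .synkeyTestCache$scores <- collectScores(cachedPopulation())
  .synkeyTestCache$scores
}

## a small, fast population for unit tests that only need the shape
smallPopulation <- function() {
  if (is.null(.synkeyTestCache$small))
    .synkeyTestCache$small <- makePopulation(
      nSubjects = 4L, objects = objectCatalog()[1:10, ],
      followUpSubjects = 1:2, followUpAttempts = 1L, n = 4L, seed = 3L)
  .synkeyTestCache$small
}

## a deterministic random synergy set with n synergies
randomSynergySet <- function(n, seed, G = max(n, 6L), L = 151L) {
  set.seed(seed)
  profiles <- replicate(G, matrix(rnorm(L * 10L), L, 10L), simplify = FALSE)
  extractSynergies(buildVelocityMatrix(profiles), n = n)
}

## a smooth nonconstant 10 x L synergy whose support avoids both ends,
## so small shifts lose nothing to the zero fill
bumpSynergy <- function(L = 151L, seed = 1L) {
  set.seed(seed)
  t <- seq_len(L)
  m <- t(vapply(seq_len(10L), function(j) {
    c0 <- runif(1, 50, 100)
    rnorm(1, 1, 0.2) * exp(-(t - c0)^2 / (2 * runif(1, 6, 10)^2))
  }, numeric(L)))
  rownames(m) <- jointLabels()
  m
}

## shift columns with zero fill (independent re-implementation for oracles)
oracleShift <- function(m, s) {
  L <- ncol(m)
  out <- matrix(0, nrow(m), L)
  if (s >= 0) {
    if (s < L) out[, (1 + s):L] <- m[, 1:(L - s), drop = FALSE]
  } else if (-s < L) out[, 1:(L + s)] <- m[, (1 - s):L, drop = FALSE]
  out
}

## brute-force shift-aligned summed correlation (oracle)
oracleSummedCorrelation <- function(A, B, mask = jointLabels(),
                                    maxShift = 20L) {
  keep <- match(mask, jointLabels())
  best <- -Inf
  for (s in -maxShift:maxShift) {
    Bs <- oracleShift(B, s)
    sc <- sum(vapply(keep, function(j) {
      a <- A[j, ]; b <- Bs[j, ]
      if (sd(a) == 0 || sd(b) == 0) 0 else cor(a, b)
    }, numeric(1)))
    if (sc > best) best <- sc
  }
  best
}

## all permutations of 1..n taken k at a time (oracle enumeration)
oraclePermutations <- function(n, k) {
  if (k == 0L) return(matrix(integer(0), 1, 0))
  sub <- oraclePermutations(n, k - 1L)
  do.call(rbind, lapply(seq_len(n), function(j) {
    keep <- rowSums(sub == j) == 0
    if (!any(keep)) return(NULL)
    cbind(sub[keep, , drop = FALSE], j)
  }))
}
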