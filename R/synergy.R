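#' @include kinematics.R
NULL

#' Flatten / unflatten a fixed-length velocity profile
#'
#' A fixed profile (L x 10, columns = joints) is flattened joint-major:
#' joint 1 samples 1..L, then joint 2, and so on, giving a length-10L
#' vector.  \code{unflattenProfile} inverts this, returning the 10 x L
#' synergy layout (rows = joints).
#'
#' @param profile L x 10 matrix (rows = samples, columns = joints).
#' @param v length-10L numeric vector.
#' @param L profile length in samples.
#' @return \code{flattenProfile}: numeric vector of length 10 L;
#'   \code{unflattenProfile}: 10 x L matrix with joint row names.
#' @export
flattenProfile <- function(profile) {
  stopifnot(is.matrix(profile), ncol(profile) == 10L)
  as.vector(profile)
}

#' @rdname flattenProfile
#' @export
unflattenProfile <- function(v, L = length(v) %/% 10L) {
  stopifnot(length(v) == 10L * L)
  m <- t(matrix(v, L, 10L))
  rownames(m) <- jointLabels()
  m
}

#' Assemble the grasp-by-feature velocity matrix
#'
#' Stacks fixed-length velocity profiles into the matrix V (one row per
#' grasp, 10 L columns in joint-major order) on which the synergy
#' decomposition operates.  With the defaults of the accompanying dataset
#' design -- 25 grasped objects, 10 joints, 151 samples -- V is 25 x 1510.
#'
#' @param profiles list of L x 10 matrices from \code{\link{padToFixed}},
#'   all sharing L and joint order.
#' @param rowLabels optional character labels (e.g. object names).
#' @return G x (10 L) numeric matrix with attribute \code{L}.
#' @export
buildVelocityMatrix <- function(profiles, rowLabels = NULL) {
  if (!length(profiles)) stop("buildVelocityMatrix: no profiles")
  Ls <- vapply(profiles, nrow, integer(1))
  if (length(unique(Ls)) != 1L)
    stop("buildVelocityMatrix: profiles have inconsistent lengths: ",
         paste(unique(Ls), collapse = ", "))
  if (!all(vapply(profiles, ncol, integer(1)) == 10L))
    stop("buildVelocityMatrix: profiles must have 10 joint columns")
  V <- t(vapply(profiles, flattenProfile, numeric(10L * Ls[1])))
  if (length(profiles) == 1L) V <- matrix(V, nrow = 1L)
  rownames(V) <- rowLabels
  attr(V, "L") <- as.integer(Ls[1])
  V
}

.velL <- function(V) {
  L <- attr(V, "L")
  if (is.null(L)) L <- ncol(V) %/% 10L
  as.integer(L)
}

#' Extract ranked spatiotemporal synergies by truncated SVD
#'
#' Performs the (economy) singular value decomposition of the velocity
#' matrix V and keeps the first \code{n} right singular vectors, each
#' reshaped to a 10 x L per-joint velocity pattern.  V is decomposed as
#' given -- no mean-centering by default, matching the model
#' V = U diag(lambda) R' applied to raw velocities; \code{center = TRUE}
#' subtracts column means first, for comparison.
#'
#' The variance fraction of component i is lambda_i^2 over the sum of all
#' squared singular values.  Each synergy's sign is canonicalized so its
#' largest-magnitude element is positive (singular vectors are defined up
#' to sign; ties in singular values are thereby rendered reproducible).
#'
#' @param V matrix from \code{\link{buildVelocityMatrix}}.
#' @param n number of synergies to retain (default 10).
#' @param center subtract column means before decomposing (default FALSE).
#' @return a \code{\linkS4class{SynergySet}}.
#' @examples
#' prof <- matrix(rnorm(151 * 10), 151, 10)
#' V <- buildVelocityMatrix(replicate(5, prof + matrix(rnorm(1510), 151, 10),
#'                                    simplify = FALSE))
#' extractSynergies(V, n = 3)
#' @export
extractSynergies <- function(V, n = 10L, center = FALSE) {
  stopifnot(is.matrix(V), all(is.finite(V)))
  n <- as.integer(n)
  r <- min(dim(V))
  if (n < 1L || n > r)
    stop(sprintf("extractSynergies: n must be in 1..%d (min dim of V)", r))
  L <- .velL(V)
  if (ncol(V) != 10L * L)
    stop("extractSynergies: V must have 10 x L columns")
  if (center) V <- sweep(V, 2L, colMeans(V))
  sv <- svd(V, nu = n, nv = n)
  d <- sv$d
  loadings <- sv$v
  scores <- sv$u
  ## sign canonicalization: largest-magnitude loading element positive
  for (i in seq_len(n)) {
    j <- which.max(abs(loadings[, i]))
    if (loadings[j, i] < 0) {
      loadings[, i] <- -loadings[, i]
      scores[, i] <- -scores[, i]
    }
  }
  tot <- sum(d^2)
  vf <- if (tot > 0) d^2 / tot else rep(0, length(d))
  syn <- lapply(seq_len(n), function(i) unflattenProfile(loadings[, i], L))
  new("SynergySet", synergies = syn, loadings = loadings, scores = scores,
      singularValues = d, varianceFractions = vf, n = n, L = L,
      joints = jointLabels())
}

#' Rank-n reconstruction of the velocity matrix
#'
#' Recomposes V~ = U_S diag(lambda_1..lambda_n) R_S' from a synergy set
#' extracted from V.  By the Eckart--Young theorem the squared Frobenius
#' error ||V - V~||^2 equals the sum of the squared discarded singular
#' values.
#'
#' @param V the matrix the set was extracted from.
#' @param set a \code{\linkS4class{SynergySet}} derived from \code{V}.
#' @return G x (10 L) matrix of rank at most n.
#' @export
reconstruct <- function(V, set) {
  stopifnot(is(set, "SynergySet"))
  if (!is.matrix(V) || nrow(V) != nrow(set@scores) ||
      ncol(V) != nrow(set@loadings))
    stop("reconstruct: V does not match the shape the set was derived from")
  n <- set@n
  Vt <- set@scores %*% (set@singularValues[seq_len(n)] *
                        t(set@loadings))
  dimnames(Vt) <- dimnames(V)
  attr(Vt, "L") <- set@L
  Vt
}

#' Per-synergy and cumulative variance fractions
#'
#' @param set a \code{\linkS4class{SynergySet}}.
#' @param all report all components (default) or the retained n only.
#' @return data.frame with columns \code{synergy}, \code{fraction},
#'   \code{cumulative}; the cumulative column is non-decreasing and sums
#'   to at most 1.
#' @export
varianceTable <- function(set, all = TRUE) {
  stopifnot(is(set, "SynergySet"))
  vf <- set@varianceFractions
  if (!all) vf <- vf[seq_len(set@n)]
  data.frame(synergy = seq_along(vf), fraction = vf,
             cumulative = cumsum(vf))
}

#' Plot the variance accounted for by each synergy
#'
#' Bar plot of per-component variance fractions with the cumulative curve
#' overlaid, in the style commonly used to report how much of a grasping
#' dataset the leading synergies explain.
#'
#' @param set a \code{\linkS4class{SynergySet}}.
#' @param ... passed to \code{\link[graphics]{barplot}}.
#' @return invisibly, the variance table.
#' @export
plotVariance <- function(set, ...) {
  tab <- varianceTable(set)
  mid <- graphics::barplot(tab$fraction, names.arg = tab$synergy,
                           xlab = "synergy", ylab = "fraction of variance",
                           ylim = c(0, 1), ...)
  graphics::lines(mid, tab$cumulative, type = "b", pch = 19)
  invisible(tab)
}

## -------------------------------------------------------- CSV serialization

#' Read and write synergy sets as CSV
#'
#' Human-readable long format: one row per (synergy, joint, sample) with the
#' velocity value, preceded by per-synergy metadata columns; singular values
#' and variance fractions for all components are carried in the
#' \code{singular_value}/\code{variance_fraction} columns of each synergy's
#' first row block.  The round trip restores synergies, singular values and
#' variance fractions to stored precision (scores are not serialized; a set
#' read from CSV supports matching and verification but not
#' \code{\link{reconstruct}}).
#'
#' @param set a \code{\linkS4class{SynergySet}}.
#' @param path file path.
#' @return \code{readSynergySet}: a \code{SynergySet};
#'   \code{writeSynergySet}: \code{path}, invisibly.
#' @export
writeSynergySet <- function(set, path) {
  stopifnot(is(set, "SynergySet"))
  blocks <- lapply(seq_len(set@n), function(i) {
    s <- set@synergies[[i]]
    data.frame(synergy = i,
               joint = rep(rownames(s), each = ncol(s)),
               sample = rep(seq_len(ncol(s)), times = nrow(s)),
               velocity = as.vector(t(s)))
  })
  df <- do.call(rbind, blocks)
  meta <- data.frame(component = seq_along(set@singularValues),
                     singular_value = set@singularValues,
                     variance_fraction = set@varianceFractions)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# synkey synergy set: n=%d L=%d components=%d",
                     set@n, set@L, nrow(meta)), con)
  writeLines("# spectrum: component,singular_value,variance_fraction", con)
  writeLines(sprintf("#S %d,%.15g,%.15g", meta$component,
                     meta$singular_value, meta$variance_fraction), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSynergySet
#' @export
readSynergySet <- function(path) {
  lines <- readLines(path)
  head1 <- lines[1]
  m <- regmatches(head1,
                  regexec("n=(\\d+) L=(\\d+) components=(\\d+)", head1))[[1]]
  if (length(m) != 4L) stop("readSynergySet: malformed header")
  n <- as.integer(m[2]); L <- as.integer(m[3])
  spec <- lines[startsWith(lines, "#S ")]
  sm <- do.call(rbind, strsplit(sub("^#S ", "", spec), ","))
  d <- as.numeric(sm[, 2]); vf <- as.numeric(sm[, 3])
  body <- lines[!startsWith(lines, "#")]
  df <- utils::read.csv(text = body)
  syn <- lapply(split(df, df$synergy), function(b) {
    m <- matrix(b$velocity[order(match(b$joint, jointLabels()), b$sample)],
                nrow = 10L, ncol = L, byrow = TRUE)
    rownames(m) <- jointLabels()
    m
  })
  loadings <- vapply(syn, function(s) flattenProfile(t(s)), numeric(10L * L))
  new("SynergySet", synergies = unname(syn), loadings = loadings,
      scores = matrix(numeric(0), 0, n), singularValues = d,
      varianceFractions = vf, n = n, L = L, joints = jointLabels())
}
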