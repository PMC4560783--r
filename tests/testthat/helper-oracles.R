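# Independent oracles and small fixture builders used across the suite.
# All fixtures are generated in code; nothing is read from disk.

# naive double-loop time-averaged MSD (the oracle timeAveragedMSD is
# checked against)
naiveTAMSD <- function(P, maxLag) {
  N <- nrow(P)
  vapply(seq_len(maxLag), function(n) {
    s <- 0
    for (t in seq_len(N - n)) s <- s + sum((P[t + n, ] - P[t, ])^2)
    s / (N - n)
  }, numeric(1))
}

# brute-force hull-surface membership: a point is on the convex hull surface
# iff some plane through three points supports the whole set and contains it
bruteHullSurface3D <- function(P, tol = 1e-9) {
  n <- nrow(P)
  on <- rep(FALSE, n)
  idx <- utils::combn(n, 3)
  for (k in seq_len(ncol(idx))) {
    i <- idx[1, k]; j <- idx[2, k]; l <- idx[3, k]
    u <- P[j, ] - P[i, ]; v <- P[l, ] - P[i, ]
    nrm <- c(u[2] * v[3] - u[3] * v[2],
             u[3] * v[1] - u[1] * v[3],
             u[1] * v[2] - u[2] * v[1])
    nn <- sqrt(sum(nrm^2))
    if (nn < tol) next
    nrm <- nrm / nn
    s <- as.numeric(sweep(P, 2, P[i, ]) %*% nrm)
    if (all(s <= tol) || all(s >= -tol)) on[abs(s) <= tol] <- TRUE
  }
  which(on)
}

# static ensemble: immobile loci at given anchors plus localization noise
staticEnsemble <- function(nLoci = 20, nFrames = 30, rho = 0, dt = 1,
                           seed = 1, spread = 5, nDims = 3) {
  set.seed(seed)
  anchors <- matrix(runif(nLoci * nDims, -spread, spread), nLoci, nDims)
  pos <- array(rep(anchors, nFrames), c(nLoci, nDims, nFrames))
  pos <- aperm(pos, c(1, 3, 2))
  if (rho > 0) pos <- pos + array(rnorm(length(pos), 0, rho), dim(pos))
  LocusEnsemble(x = pos[, , 1], y = pos[, , 2],
                z = if (nDims == 3) pos[, , 3] else NULL,
                timeS = (seq_len(nFrames) - 1) * dt,
                nucleusId = "static", condition = "fixed")
}

# apply a rigid drift + in-plane rotation (about the per-frame COM) to an
# ensemble; returns the transformed ensemble
applyRigidMotion <- function(ens, drift = NULL, theta = NULL) {
  dims <- coordDims(ens)
  nF <- nFrames(ens); nL <- nLoci(ens)
  arr <- array(NA_real_, c(nL, nF, length(dims)))
  for (j in seq_along(dims))
    arr[, , j] <- SummarizedExperiment::assay(ens, dims[j])
  if (is.null(drift)) drift <- matrix(0, nF, length(dims))
  if (is.null(theta)) theta <- numeric(nF)
  for (t in seq_len(nF)) {
    com <- colMeans(matrix(arr[, t, ], nL, length(dims)))
    R <- matrix(c(cos(theta[t]), sin(theta[t]),
                  -sin(theta[t]), cos(theta[t])), 2, 2)
    xy <- sweep(matrix(arr[, t, 1:2], nL, 2), 2, com[1:2])
    arr[, t, 1:2] <- xy %*% t(R) + rep(com[1:2], each = nL)
    for (j in seq_along(dims)) arr[, t, j] <- arr[, t, j] + drift[t, j]
  }
  LocusEnsemble(x = arr[, , 1], y = arr[, , 2],
                z = if (length(dims) == 3) arr[, , 3] else NULL,
                timeS = frameTimes(ens), nucleusId = nucleusId(ens),
                condition = conditionLabel(ens), locusIds = locusIds(ens))
}

# ensemble coordinates as a loci x frames x dims array
ensArray <- function(ens) {
  dims <- coordDims(ens)
  arr <- array(NA_real_, c(nLoci(ens), nFrames(ens), length(dims)))
  for (j in seq_along(dims))
    arr[, , j] <- SummarizedExperiment::assay(ens, dims[j])
  arr
}
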