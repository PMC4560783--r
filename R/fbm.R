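## Fractional Brownian motion synthesis by circulant embedding of the
## fractional Gaussian noise covariance (exact covariance, no kernel
## approximation). One FFT yields two independent fGn samples (real and
## imaginary parts), which are paired across spatial axes.

## Autocovariance of unit-variance fGn at integer lags 0..n for Hurst H.
.fgnAutocov <- function(n, H) {
  k <- 0:n
  0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
}

## Draw `paths` independent unit-variance fGn series of length n.
## Returns an n x paths matrix. Circulant embedding: eigenvalues of the
## embedded covariance are non-negative for fGn; if rounding makes tiny
## negatives we clamp, and genuinely negative spectra trigger grid doubling.
.fgnSample <- function(n, H, paths) {
  m <- n
  repeat {
    g <- .fgnAutocov(m, H)
    circ <- c(g, rev(g[2:m]))          # length 2m
    lam <- Re(fft(circ))
    if (min(lam) > -1e-8 * max(lam)) break
    m <- 2L * m
  }
  lam <- pmax(lam, 0)
  M <- 2L * m
  nPairs <- ceiling(paths / 2)
  out <- matrix(0, nrow = n, ncol = 2L * nPairs)
  scale <- sqrt(lam / M)
  for (j in seq_len(nPairs)) {
    a <- complex(real = rnorm(M), imaginary = rnorm(M)) * scale
    x <- fft(a)
    out[, 2L * j - 1L] <- Re(x)[seq_len(n)]
    out[, 2L * j] <- Im(x)[seq_len(n)]
  }
  out[, seq_len(paths), drop = FALSE]
}

#' Simulate a fractional Brownian motion trajectory
#'
#' Draws one locus trajectory under fractional Brownian motion with Hurst
#' index H = alpha/2, using exact-covariance circulant embedding of the
#' increment process. The amplitude convention follows the generalized
#' diffusion law MSD_total(tau) = dAlpha * tau^alpha summed over the
#' \code{nDims} axes (each axis carries dAlpha/nDims); for alpha = 1 this is
#' Brownian motion with ordinary diffusion coefficient D = dAlpha/(2*nDims).
#'
#' @param alpha anomalous exponent in (0, 2).
#' @param dAlpha generalized diffusion coefficient, um^2 s^-alpha (>= 0;
#'   0 gives a static locus).
#' @param dt frame interval, s.
#' @param nFrames number of positions (>= 2).
#' @param nDims 2 or 3 spatial dimensions.
#' @param seed optional integer seed; \code{NULL} uses the current RNG state.
#' @param locusId identifier for the returned trajectory.
#' @return A [Trajectory-class] starting at the origin.
#' @examples
#' tr <- simulateFBMTrajectory(alpha = 0.5, dAlpha = 2.8e-4, dt = 1,
#'                             nFrames = 200, seed = 1)
#' @export
simulateFBMTrajectory <- function(alpha, dAlpha, dt, nFrames, nDims = 2,
                                  seed = NULL, locusId = "locus") {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 2)
    stop("alpha must lie in the open interval (0, 2)")
  if (nFrames < 2L) stop("nFrames must be >= 2")
  if (dAlpha < 0) stop("dAlpha must be >= 0")
  nDims <- as.integer(nDims)
  stopifnot(nDims %in% c(2L, 3L))
  if (!is.null(seed)) set.seed(as.integer(seed))
  nInc <- nFrames - 1L
  timeS <- (seq_len(nFrames) - 1) * dt
  if (dAlpha == 0) {
    coords <- matrix(0, nFrames, nDims)
  } else {
    H <- alpha / 2
    inc <- .fgnSample(nInc, H, nDims) *
      sqrt((dAlpha / nDims) * dt^alpha)
    coords <- rbind(0, apply(inc, 2L, cumsum))
  }
  colnames(coords) <- c("x", "y", "z")[seq_len(nDims)]
  Trajectory(coords, timeS, locusId)
}

## Deterministic child seed for locus i under master seed s (kept < 2^31).
.childSeed <- function(s, i) {
  as.integer((as.numeric(s) * 48271 + 7919 * as.numeric(i)) %% 2147483629)
}

#' Simulate a population of loci in one nucleus
#'
#' Composes the FBM draw with per-locus exponents alpha_i ~
#' Normal(alphaMean, alphaSd^2) clipped to [0.05, 1.95], uniform placement
#' inside the bounding ellipsoid, optional rigid nuclear motion (centre-of-
#' mass random-walk drift plus cumulative in-plane rotation about the moving
#' COM), and i.i.d. Gaussian localization noise applied last (localization
#' error is a detection-stage effect, so it is added after the rigid motion).
#'
#' @param preset a [PopulationPreset-class].
#' @return list with elements \code{ensemble} (a [LocusEnsemble-class]) and
#'   \code{manifest} (a [GroundTruthManifest-class] recording every injected
#'   parameter).
#' @examples
#' p <- PopulationPreset(nLoci = 20, nFrames = 50, seed = 7)
#' sim <- simulatePopulation(p)
#' sim$ensemble
#' @export
simulatePopulation <- function(preset) {
  stopifnot(is(preset, "PopulationPreset"))
  validObject(preset)
  set.seed(preset@seed)
  nL <- preset@nLoci; nF <- preset@nFrames; d <- preset@nDims
  alphas <- pmin(pmax(rnorm(nL, preset@alphaMean, preset@alphaSd), 0.05), 1.95)

  ## anchor positions uniform in the ellipsoid (rejection sampling)
  radii <- preset@nucleusRadii[seq_len(d)]
  centers <- matrix(NA_real_, nL, d)
  filled <- 0L
  while (filled < nL) {
    cand <- matrix(runif(3L * nL * d, -1, 1), ncol = d)
    ok <- rowSums(cand^2) <= 1
    take <- min(sum(ok), nL - filled)
    if (take > 0) {
      centers[filled + seq_len(take), ] <-
        cand[which(ok)[seq_len(take)], , drop = FALSE] %*% diag(radii, d)
      filled <- filled + take
    }
  }

  pos <- array(0, dim = c(nL, nF, d))
  for (i in seq_len(nL)) {
    tr <- simulateFBMTrajectory(alphas[i], preset@dAlpha, preset@dt, nF,
                                nDims = d, seed = .childSeed(preset@seed, i))
    pos[i, , ] <- sweep(coords(tr), 2L, -centers[i, ])
  }

  ## rigid motion: cumulative in-plane rotation about the per-frame ensemble
  ## COM, then a random-walk drift of the whole nucleus
  theta <- preset@rotationRate * (seq_len(nF) - 1)
  drift <- matrix(0, nF, d)
  if (preset@driftAmplitude > 0)
    drift <- apply(matrix(rnorm(nF * d, 0, preset@driftAmplitude), nF, d),
                   2L, cumsum)
  drift[1, ] <- 0
  if (preset@rotationRate != 0) {
    for (t in seq_len(nF)) {
      com <- colMeans(matrix(pos[, t, ], nL, d))
      R <- matrix(c(cos(theta[t]), sin(theta[t]),
                    -sin(theta[t]), cos(theta[t])), 2, 2)
      xy <- sweep(matrix(pos[, t, 1:2], nL, 2), 2L, com[1:2])
      pos[, t, 1:2] <- xy %*% t(R) + rep(com[1:2], each = nL)
    }
  }
  for (j in seq_len(d))
    pos[, , j] <- pos[, , j] + rep(drift[, j], each = nL)

  if (preset@rho > 0)
    pos <- pos + array(rnorm(length(pos), 0, preset@rho), dim = dim(pos))

  ids <- sprintf("locus_%03d", seq_len(nL))
  timeS <- (seq_len(nF) - 1) * preset@dt
  ens <- LocusEnsemble(x = pos[, , 1], y = pos[, , 2],
                       z = if (d == 3L) pos[, , 3] else NULL,
                       timeS = timeS,
                       nucleusId = preset@name, condition = preset@name,
                       locusIds = ids)
  per <- data.frame(locus_id = ids, alpha = alphas,
                    d_alpha = rep(preset@dAlpha, nL),
                    center_x = centers[, 1], center_y = centers[, 2],
                    center_z = if (d == 3L) centers[, 3] else 0)
  man <- new("GroundTruthManifest", perLocus = per, driftPath = drift,
             rotationPath = theta, presetId = preset@name,
             seed = preset@seed)
  list(ensemble = ens, manifest = man)
}
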