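## Time-averaged MSD and single-locus power-law fitting.

#' Time-averaged mean square displacement
#'
#' MSD(n * dt) = mean over t of |r(t + n dt) - r(t)|^2, averaged over the
#' entire measured time of a gap-free trajectory. By default only x-y plane
#' motion enters (the confocal z axis carries larger measurement errors and
#' is assumed independent); lags are limited to a fraction of the
#' trajectory length to control the estimator's variance.
#'
#' @param traj a [Trajectory-class].
#' @param dims "xy" (default) or "xyz".
#' @param maxLagFraction largest lag as a fraction of the trajectory length
#'   (default 0.25).
#' @param maxLag optional hard cap on the lag index (overrides the
#'   fraction when smaller).
#' @return An [MSDCurve-class].
#' @examples
#' tr <- Trajectory(cbind(x = c(0, 1, 1), y = c(0, 0, 1)), 0:2)
#' msdValues(timeAveragedMSD(tr, maxLagFraction = 1))
#' @export
timeAveragedMSD <- function(traj, dims = c("xy", "xyz"),
                            maxLagFraction = 0.25, maxLag = NULL) {
  stopifnot(is(traj, "Trajectory"))
  dims <- match.arg(dims)
  N <- nFrames(traj)
  if (N < 2L) stop("trajectory must contain at least 2 frames")
  P <- coords(traj)
  if (dims == "xyz") {
    if (!"z" %in% colnames(P)) stop("trajectory has no z coordinate")
  } else P <- P[, c("x", "y"), drop = FALSE]
  nMax <- max(1L, floor(maxLagFraction * N))
  if (!is.null(maxLag)) nMax <- min(nMax, as.integer(maxLag))
  nMax <- min(nMax, N - 1L)
  dt <- frameInterval(traj)
  msd <- numeric(nMax)
  for (n in seq_len(nMax)) {
    d <- P[(n + 1L):N, , drop = FALSE] - P[seq_len(N - n), , drop = FALSE]
    msd[n] <- mean(rowSums(d * d))
  }
  new("MSDCurve", tau = seq_len(nMax) * dt, msd = msd,
      nPairs = N - seq_len(nMax), locusId = traj@locusId, dims = dims)
}

#' MSD divided by lag time
#'
#' Pointwise MSD(tau)/tau, the presentation in which normal diffusion is a
#' horizontal line on log-log axes and anomalous diffusion has slope
#' alpha - 1 (negative for subdiffusion, positive for superdiffusion).
#'
#' @param curve an [MSDCurve-class].
#' @return An [MSDCurve-class] whose \code{msd} slot holds MSD/tau
#'   (um^2/s).
#' @export
msdOverTau <- function(curve) {
  stopifnot(is(curve, "MSDCurve"), all(curve@tau > 0))
  new("MSDCurve", tau = curve@tau, msd = curve@msd / curve@tau,
      nPairs = curve@nPairs, locusId = curve@locusId, dims = curve@dims)
}

.logLogFit <- function(tau, y) {
  lt <- log(tau); ly <- log(y)
  fit <- lm(ly ~ lt)
  tss <- sum((ly - mean(ly))^2)
  rss <- sum(fit$residuals^2)
  list(alpha = unname(coef(fit)[2]),
       dAlpha = exp(unname(coef(fit)[1])),
       sigma = sqrt(mean(fit$residuals^2)),
       r.squared = if (tss > 0) 1 - rss / tss else 1)
}

.windowSelect <- function(tau, window) {
  if (is.null(window)) rep(TRUE, length(tau))
  else tau >= window[1] & tau <= window[2]
}

#' Fit the generalized diffusion power law to an MSD curve
#'
#' Ordinary least squares of log(MSD - noiseOffset) against log(tau):
#' the slope is the anomalous exponent alpha and exp(intercept) the
#' generalized diffusion coefficient D_alpha (um^2 s^-alpha). The static
#' localization-error term (2 * d * rho^2 for d analysed axes) should be
#' passed as \code{noiseOffset}; without it, noise biases alpha downwards
#' at short lags. Note that D_alpha values are only comparable between
#' processes sharing the same exponent (its units depend on alpha).
#'
#' @param curve an [MSDCurve-class].
#' @param window numeric \code{c(tau_min, tau_max)} in seconds, or NULL for
#'   all lags.
#' @param noiseOffset static-error term subtracted before the log fit, um^2.
#' @return A [DiffusionFit-class].
#' @export
fitPowerLaw <- function(curve, window = NULL, noiseOffset = 0) {
  stopifnot(is(curve, "MSDCurve"))
  sel <- .windowSelect(curve@tau, window)
  if (sum(sel) < 4L) stop("fewer than 4 lag points in the fit window")
  y <- curve@msd[sel] - noiseOffset
  tau <- curve@tau[sel]
  if (any(y <= 0)) {
    warning("non-positive noise-corrected MSD in window; shrinking window")
    keep <- y > 0
    y <- y[keep]; tau <- tau[keep]
    if (length(y) < 4L)
      stop("fewer than 4 usable lag points after noise correction")
  }
  f <- .logLogFit(tau, y)
  new("DiffusionFit", alpha = f$alpha, dAlpha = f$dAlpha,
      window = range(tau), noiseOffset = noiseOffset,
      goodness = list(sigma = f$sigma, r.squared = f$r.squared,
                      nPoints = length(tau)))
}

#' Localization precision from fixed-cell loci
#'
#' Estimates the per-axis s.d. of the position measurement error rho from
#' immobile (fixed-cell) loci, either as the pooled s.d. of positions about
#' each locus's mean ("positions") or from the flat TAMSD plateau, which
#' equals 2 * d * rho^2 in d dimensions ("msd"). The two routes agree on
#' genuinely static data; apparent drift (a non-flat plateau) triggers a
#' warning.
#'
#' @param ensembles a [LocusEnsemble-class] or list of them, from fixed
#'   cells.
#' @param method "positions" or "msd".
#' @param dims "xy" or "xyz" for the msd route.
#' @return A [StaticPrecision-class].
#' @export
measureStaticPrecision <- function(ensembles,
                                   method = c("positions", "msd"),
                                   dims = "xy") {
  method <- match.arg(method)
  if (is(ensembles, "LocusEnsemble")) ensembles <- list(ensembles)
  trajs <- unlist(lapply(ensembles, trajectories), recursive = FALSE)
  nL <- length(trajs)
  if (method == "positions") {
    ss <- 0; nn <- 0
    for (tr in trajs) {
      P <- coords(tr)
      if (dims == "xy") P <- P[, c("x", "y"), drop = FALSE]
      dev <- sweep(P, 2L, colMeans(P))
      ss <- ss + sum(dev^2)
      nn <- nn + (nrow(P) - 1L) * ncol(P)
    }
    rhoHat <- sqrt(ss / nn)
  } else {
    d <- nchar(dims)
    curves <- lapply(trajs, timeAveragedMSD, dims = dims)
    tau <- curves[[1]]@tau
    m <- colMeans(do.call(rbind, lapply(curves, slot, "msd")))
    rhoHat <- sqrt(mean(m) / (2 * d))
    half <- length(m) %/% 2
    if (half >= 1 && mean(m[(half + 1):length(m)]) >
          1.5 * mean(m[seq_len(half)]))
      warning("MSD plateau is not flat: loci may drift, rho overestimated")
  }
  new("StaticPrecision", rho = rhoHat, method = method, nLoci = nL)
}

## local log-log slopes by centred finite differences; end points one-sided
.localSlopes <- function(tau, y) {
  lt <- log(tau); ly <- log(y)
  n <- length(lt)
  s <- numeric(n)
  if (n >= 3L)
    s[2:(n - 1)] <- (ly[3:n] - ly[1:(n - 2)]) / (lt[3:n] - lt[1:(n - 2)])
  s[1] <- (ly[2] - ly[1]) / (lt[2] - lt[1])
  s[n] <- (ly[n] - ly[n - 1]) / (lt[n] - lt[n - 1])
  s
}

#' Ensemble diffusion estimate by the MLSD procedure
#'
#' Estimates the population mean and variance of the anomalous exponent and
#' the generalized diffusion coefficient from hundreds of short
#' trajectories analysed together (single trajectories shorter than ~1e4
#' points cannot be fitted individually without large errors):
#'
#' 1. per-locus time-averaged MSDs on a common lag grid (supplied);
#' 2. subtract the static-error term 2 * d * rho^2 from every curve;
#' 3. fit the arithmetic ensemble-mean MSD (exponent alpha_MSD) and the
#'    mean-log, i.e. geometric-mean, MSD (exponent alpha_MLSD); the
#'    geometric mean is unbiased by exponent spread, so
#'    alpha_mean = alpha_MLSD, while trajectories with large exponents
#'    dominate the arithmetic mean;
#' 4. the pointwise difference of local log-log slopes,
#'    eps(tau) = s_MSD(tau) - s_MLSD(tau), follows sigma_alpha^2 * ln(tau)
#'    for a normal exponent population; a no-intercept regression of eps on
#'    ln(tau) yields the exponent variance (clamped at 0 with a warning if
#'    the regression turns negative);
#' 5. D_alpha is the prefactor of the average-particle (geometric-mean)
#'    curve fit.
#'
#' Estimates retain full precision; any rounding (the conventional one
#' decimal for exponents) is left to the presentation layer.
#'
#' @param curves list of [MSDCurve-class] on a common lag grid (>= 20).
#' @param rho per-axis localization s.d. in um (0 for noise-free data).
#' @param window numeric \code{c(tau_min, tau_max)} fit window in seconds,
#'   or NULL for all common lags.
#' @return An [EnsembleDiffusionEstimate-class].
#' @export
mlsdEnsembleEstimate <- function(curves, rho = 0, window = NULL) {
  if (length(curves) < 20L)
    stop("MLSD ensemble estimation needs >= 20 trajectories")
  tau <- curves[[1]]@tau
  for (cv in curves)
    if (length(cv@tau) != length(tau) || max(abs(cv@tau - tau)) > 1e-9)
      stop("MSD curves must share a common lag grid")
  d <- nchar(curves[[1]]@dims)
  offset <- 2 * d * rho^2
  M <- do.call(rbind, lapply(curves, slot, "msd")) - offset
  sel <- .windowSelect(tau, window)
  if (sum(sel) < 4L) stop("fewer than 4 lag points in the fit window")
  tau <- tau[sel]
  M <- M[, sel, drop = FALSE]
  meanCurve <- colMeans(M)
  Ml <- M
  bad <- Ml <= 0
  if (any(bad)) {
    warning(sprintf(
      "%d noise-corrected MSD values were non-positive and were excluded from the log average",
      sum(bad)))
    Ml[bad] <- NA_real_
  }
  mlsdCurve <- exp(colMeans(log(Ml), na.rm = TRUE))
  if (any(meanCurve <= 0) || any(!is.finite(mlsdCurve)))
    stop("ensemble curves are non-positive after noise correction; check rho")
  fMean <- .logLogFit(tau, meanCurve)
  fMlsd <- .logLogFit(tau, mlsdCurve)
  eps <- .localSlopes(tau, meanCurve) - .localSlopes(tau, mlsdCurve)
  lt <- log(tau)
  alphaVar <- sum(eps * lt) / sum(lt^2)
  if (alphaVar < 0) {
    warning("epsilon fit returned a negative exponent variance; clamped to 0")
    alphaVar <- 0
  }
  new("EnsembleDiffusionEstimate",
      alphaMsd = fMean$alpha, alphaMlsd = fMlsd$alpha,
      alphaMean = fMlsd$alpha, alphaVar = alphaVar, dAlpha = fMlsd$dAlpha,
      rho = rho, nLoci = length(curves), window = range(tau),
      curves = list(tau = tau, meanMsd = meanCurve, mlsd = mlsdCurve))
}

#' Per-locus MSD curves of an ensemble
#'
#' Convenience wrapper computing [timeAveragedMSD()] for every trajectory on
#' the shared frame grid.
#'
#' @inheritParams timeAveragedMSD
#' @param ensemble a [LocusEnsemble-class].
#' @return list of [MSDCurve-class].
#' @export
ensembleMSD <- function(ensemble, dims = c("xy", "xyz"),
                        maxLagFraction = 0.25, maxLag = NULL) {
  dims <- match.arg(dims)
  lapply(trajectories(ensemble), timeAveragedMSD, dims = dims,
         maxLagFraction = maxLagFraction, maxLag = maxLag)
}

#' Classify ensemble diffusion as normal, sub- or superdiffusive
#'
#' The motion is called normal when the interval
#' alphaMean +/- 2 * sqrt(alphaVar / nLoci) contains 1, subdiffusive when it
#' lies below 1, and superdiffusive above.
#'
#' @param est an [EnsembleDiffusionEstimate-class].
#' @return "normal", "subdiffusive" or "superdiffusive".
#' @export
classifyDiffusion <- function(est) {
  stopifnot(is(est, "EnsembleDiffusionEstimate"), est@nLoci >= 1L)
  half <- 2 * sqrt(est@alphaVar / est@nLoci)
  lo <- est@alphaMean - half; hi <- est@alphaMean + half
  if (hi < 1) "subdiffusive" else if (lo > 1) "superdiffusive" else "normal"
}
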