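#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors metadata DataFrame
#' @importFrom stats coef cov fft lm mad median residuals rnorm runif sd
#'   setNames spline t.test var
#' @importFrom utils head read.csv tail write.table
#' @importFrom graphics hist lines legend
#' @importFrom grDevices chull dev.off png
NULL

## ---------------------------------------------------------------------------
## Trajectory
## ---------------------------------------------------------------------------

#' Single-locus trajectory
#'
#' Time-ordered positions of one nuclear locus on a uniform frame grid,
#' in micrometres. Coordinates are stage coordinates; the z axis is optional
#' (2D confocal plane data).
#'
#' @slot locusId character scalar identifying the locus.
#' @slot timeS numeric vector of acquisition times in seconds, uniformly
#'   spaced (gap-free contract: no missing frames).
#' @slot coords numeric matrix, one row per frame, columns \code{x}, \code{y}
#'   and optionally \code{z}, in micrometres.
#'
#' @export
setClass("Trajectory",
  slots = c(locusId = "character", timeS = "numeric", coords = "matrix"))

setValidity("Trajectory", function(object) {
  msg <- character()
  if (length(object@locusId) != 1L) msg <- c(msg, "locusId must be a scalar")
  n <- length(object@timeS)
  if (nrow(object@coords) != n)
    msg <- c(msg, "coords must have one row per time point")
  if (!all(is.finite(object@timeS)) || !all(is.finite(object@coords)))
    msg <- c(msg, "times and coordinates must be finite")
  cn <- colnames(object@coords)
  if (is.null(cn) || !all(cn[1:2] == c("x", "y")) ||
      !(ncol(object@coords) %in% c(2L, 3L)) ||
      (ncol(object@coords) == 3L && cn[3] != "z"))
    msg <- c(msg, "coords columns must be x, y and optionally z")
  if (n >= 3L) {
    dt <- diff(object@timeS)
    if (any(abs(dt - dt[1]) > 1e-6 * max(abs(dt[1]), 1e-12)))
      msg <- c(msg, "time points must be uniformly spaced (gap-free)")
  }
  if (n >= 2L && diff(object@timeS)[1] <= 0)
    msg <- c(msg, "time must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Construct a Trajectory
#'
#' @param coords numeric matrix (frames x 2 or 3) of positions in um; column
#'   names \code{x}, \code{y}\code{[, z]} are imposed if absent.
#' @param timeS numeric vector of times in seconds (uniform spacing).
#' @param locusId character scalar.
#' @return A [Trajectory-class] object.
#' @export
Trajectory <- function(coords, timeS, locusId = "locus") {
  coords <- as.matrix(coords)
  if (is.null(colnames(coords)))
    colnames(coords) <- c("x", "y", "z")[seq_len(ncol(coords))]
  new("Trajectory", locusId = as.character(locusId),
      timeS = as.numeric(timeS), coords = coords)
}

## ---------------------------------------------------------------------------
## LocusEnsemble
## ---------------------------------------------------------------------------

#' Ensemble of locus trajectories in one nucleus
#'
#' All trajectories of one nucleus on a common frame grid, stored as a
#' \linkS4class{SummarizedExperiment}: rows are loci, columns are frames,
#' and the assays \code{x}, \code{y} (and optionally \code{z}) hold the
#' coordinates in micrometres. \code{colData} carries \code{frame} and
#' \code{time_s}; metadata carries \code{nucleus_id}, \code{dt} (frame
#' interval, s) and a free-text \code{condition} label.
#'
#' @export
setClass("LocusEnsemble", contains = "SummarizedExperiment")

setValidity("LocusEnsemble", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("x", "y") %in% an))
    msg <- c(msg, "assays must include 'x' and 'y'")
  if (nrow(object) < 1L) msg <- c(msg, "ensemble must contain >= 1 trajectory")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("frame", "time_s") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'frame' and 'time_s'")
  else {
    ts <- cd$time_s
    if (length(ts) >= 3L) {
      dtv <- diff(ts)
      if (any(abs(dtv - dtv[1]) > 1e-6 * max(abs(dtv[1]), 1e-12)))
        msg <- c(msg, "frame grid must be uniform")
    }
  }
  for (a in an)
    if (!all(is.finite(SummarizedExperiment::assay(object, a))))
      msg <- c(msg, sprintf("assay '%s' contains non-finite values", a))
  if (length(msg)) msg else TRUE
})

#' Construct a LocusEnsemble
#'
#' @param x,y,z numeric matrices (loci x frames) of coordinates in um;
#'   \code{z} may be \code{NULL} for 2D data.
#' @param timeS numeric vector of frame times in seconds.
#' @param nucleusId,condition character labels.
#' @param locusIds character vector of locus identifiers (defaults to
#'   rownames of \code{x} or \code{locus_1 ...}).
#' @return A [LocusEnsemble-class].
#' @export
LocusEnsemble <- function(x, y, z = NULL, timeS, nucleusId = "nucleus",
                          condition = "", locusIds = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (is.null(locusIds)) {
    locusIds <- rownames(x)
    if (is.null(locusIds)) locusIds <- paste0("locus_", seq_len(nrow(x)))
  }
  dimnames(x) <- dimnames(y) <- NULL
  rownames(x) <- locusIds
  assays <- list(x = x, y = y)
  if (!is.null(z)) {
    z <- as.matrix(z); dimnames(z) <- NULL; rownames(z) <- locusIds
    assays$z <- z
  }
  timeS <- as.numeric(timeS)
  dt <- if (length(timeS) >= 2L) timeS[2] - timeS[1] else NA_real_
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    colData = S4Vectors::DataFrame(frame = seq_along(timeS) - 1L,
                                   time_s = timeS),
    metadata = list(nucleus_id = nucleusId, dt = dt, condition = condition))
  rownames(se) <- locusIds
  new("LocusEnsemble", se)
}

## ---------------------------------------------------------------------------
## MSD / diffusion results
## ---------------------------------------------------------------------------

#' Time-averaged MSD curve
#'
#' @slot tau numeric lag times in seconds (strictly increasing).
#' @slot msd numeric mean square displacements in um^2.
#' @slot nPairs integer count of displacement pairs averaged per lag.
#' @slot locusId character scalar.
#' @slot dims which coordinates entered the MSD ("xy" or "xyz").
#' @export
setClass("MSDCurve",
  slots = c(tau = "numeric", msd = "numeric", nPairs = "integer",
            locusId = "character", dims = "character"))

setValidity("MSDCurve", function(object) {
  msg <- character()
  if (length(object@tau) != length(object@msd))
    msg <- c(msg, "tau and msd must have equal length")
  if (any(object@msd < 0)) msg <- c(msg, "msd must be >= 0")
  if (is.unsorted(object@tau, strictly = TRUE))
    msg <- c(msg, "tau must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Power-law fit of an MSD curve
#'
#' Parameters of the generalized diffusion law MSD(tau) = D_alpha * tau^alpha
#' obtained by ordinary least squares on log-log axes after subtraction of
#' the static localization-noise offset.
#'
#' @slot alpha anomalous exponent (dimensionless).
#' @slot dAlpha generalized diffusion coefficient, um^2 s^-alpha.
#' @slot window numeric length-2 fit window \code{[tau_min, tau_max]} in s.
#' @slot noiseOffset subtracted static-error term, um^2.
#' @slot goodness list of residual diagnostics (sigma, r.squared, nPoints).
#' @export
setClass("DiffusionFit",
  slots = c(alpha = "numeric", dAlpha = "numeric", window = "numeric",
            noiseOffset = "numeric", goodness = "list"))

#' Ensemble-level diffusion estimate (MLSD procedure)
#'
#' @slot alphaMsd exponent of the arithmetic ensemble-mean MSD.
#' @slot alphaMlsd exponent of the mean-log (geometric-mean) MSD.
#' @slot alphaMean population mean exponent (= alphaMlsd).
#' @slot alphaVar population variance of the exponent from the epsilon fit.
#' @slot dAlpha generalized diffusion coefficient from the average-particle
#'   curve, um^2 s^-alphaMean.
#' @slot rho per-axis localization s.d. used for the noise offset, um.
#' @slot nLoci number of trajectories entering the estimate.
#' @slot window fit window in seconds.
#' @slot curves list with elements \code{tau}, \code{meanMsd}, \code{mlsd}
#'   (noise-corrected aggregate curves, for plotting/diagnostics).
#' @export
setClass("EnsembleDiffusionEstimate",
  slots = c(alphaMsd = "numeric", alphaMlsd = "numeric", alphaMean = "numeric",
            alphaVar = "numeric", dAlpha = "numeric", rho = "numeric",
            nLoci = "integer", window = "numeric", curves = "list"))

setValidity("EnsembleDiffusionEstimate", function(object) {
  if (length(object@alphaVar) && object@alphaVar < 0)
    "alphaVar must be >= 0" else TRUE
})

#' Static localization precision
#'
#' Per-axis standard deviation of the position measurement error, estimated
#' from fixed-cell (immobile) loci.
#'
#' @slot rho per-axis s.d. in um.
#' @slot method "positions" (pooled s.d. about per-locus means) or "msd"
#'   (from the flat TAMSD plateau 2*d*rho^2).
#' @slot nLoci number of static loci pooled.
#' @export
setClass("StaticPrecision",
  slots = c(rho = "numeric", method = "character", nLoci = "integer"))

## ---------------------------------------------------------------------------
## Registration
## ---------------------------------------------------------------------------

#' Whole-nucleus rigid-motion estimate
#'
#' Per-frame centre of mass of all loci and the cumulative in-plane rotation
#' angle relative to the reference frame. No out-of-plane rotation is
#' estimated (surface-adhering cells).
#'
#' @slot com numeric matrix (frames x 2 or 3) of centre-of-mass positions, um.
#' @slot angle numeric vector of rotation angles in radians (0 at the
#'   reference frame).
#' @slot referenceFrame integer index (1-based) of the reference frame.
#' @slot rotationReliable logical; FALSE when < 3 loci or near-collinear
#'   configurations make the rotation estimate unreliable.
#' @export
setClass("RigidMotionEstimate",
  slots = c(com = "matrix", angle = "numeric", referenceFrame = "integer",
            rotationReliable = "logical"))

setValidity("RigidMotionEstimate", function(object) {
  msg <- character()
  if (nrow(object@com) != length(object@angle))
    msg <- c(msg, "com and angle must cover the same frames")
  if (length(object@angle) &&
      abs(object@angle[object@referenceFrame]) > 1e-12)
    msg <- c(msg, "angle at the reference frame must be 0")
  if (!all(is.finite(object@com)) || !all(is.finite(object@angle)))
    msg <- c(msg, "estimates must be finite")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Geometry
## ---------------------------------------------------------------------------

#' Scanned territory of one locus
#'
#' Convex-hull volume (3D) or area (2D) of a trajectory over a time window:
#' the nuclear territory the locus explored.
#'
#' @slot locusId character scalar.
#' @slot value volume in um^3 (3D) or area in um^2 (2D).
#' @slot dims "3D" or "2D".
#' @slot duration analysed window length in seconds.
#' @slot degenerate TRUE when fewer than 4 non-coplanar (3 non-collinear)
#'   points were available, in which case value is 0.
#' @export
setClass("ScannedVolume",
  slots = c(locusId = "character", value = "numeric", dims = "character",
            duration = "numeric", degenerate = "logical"))

#' Internal/peripheral hull classification
#'
#' Per-timepoint peripheral sets (loci on the ensemble convex hull) and the
#' final internal set: loci that never touched the hull at any time point.
#'
#' @slot peripheralByFrame list (one character vector per frame) of loci on
#'   the hull at that frame.
#' @slot internalFinal character vector: intersection over frames of the
#'   internal sets.
#' @slot peripheralFinal character vector: the complement.
#' @slot nFramesOnHull named integer: frames each locus spent on the hull.
#' @slot dims "3D" or "2D".
#' @export
setClass("HullClassification",
  slots = c(peripheralByFrame = "list", internalFinal = "character",
            peripheralFinal = "character", nFramesOnHull = "integer",
            dims = "character"))

## ---------------------------------------------------------------------------
## Synthetic-data presets and manifests
## ---------------------------------------------------------------------------

#' Population preset for the trajectory simulator
#'
#' Defines the statistical conditions of a simulated nucleus: per-locus
#' anomalous exponents drawn from Normal(alphaMean, alphaSd^2) clipped to
#' [0.05, 1.95], a common generalized diffusion coefficient, imaging cadence,
#' localization noise, and rigid nuclear motion.
#'
#' @slot name preset identifier.
#' @slot alphaMean population mean anomalous exponent (0, 2).
#' @slot alphaSd population s.d. of the exponent (>= 0).
#' @slot dAlpha generalized diffusion coefficient, um^2 s^-alpha (> 0).
#' @slot nLoci,nFrames counts (nFrames >= 10).
#' @slot dt frame interval, s (> 0).
#' @slot rho per-axis localization s.d., um (>= 0).
#' @slot driftAmplitude s.d. of the COM random-walk step, um per frame.
#' @slot rotationRate cumulative in-plane rotation, radians per frame.
#' @slot nucleusRadii semi-axes of the bounding ellipsoid, um (length 3).
#' @slot nDims 2 or 3 spatial dimensions.
#' @slot seed master seed; per-locus child seeds are derived from it.
#' @export
setClass("PopulationPreset",
  slots = c(name = "character", alphaMean = "numeric", alphaSd = "numeric",
            dAlpha = "numeric", nLoci = "integer", nFrames = "integer",
            dt = "numeric", rho = "numeric", driftAmplitude = "numeric",
            rotationRate = "numeric", nucleusRadii = "numeric",
            nDims = "integer", seed = "integer"))

setValidity("PopulationPreset", function(object) {
  msg <- character()
  if (!(object@alphaMean > 0 && object@alphaMean < 2))
    msg <- c(msg, "alphaMean must lie in (0, 2)")
  if (object@alphaSd < 0) msg <- c(msg, "alphaSd must be >= 0")
  if (object@dAlpha < 0) msg <- c(msg, "dAlpha must be >= 0")
  if (object@nFrames < 10L) msg <- c(msg, "nFrames must be >= 10")
  if (object@dt <= 0) msg <- c(msg, "dt must be > 0")
  if (object@rho < 0) msg <- c(msg, "rho must be >= 0")
  if (!(object@nDims %in% c(2L, 3L))) msg <- c(msg, "nDims must be 2 or 3")
  if (length(object@nucleusRadii) != 3L)
    msg <- c(msg, "nucleusRadii must have length 3")
  if (length(msg)) msg else TRUE
})

#' @rdname PopulationPreset-class
#' @param name,alphaMean,alphaSd,dAlpha,nLoci,nFrames,dt,rho,driftAmplitude,rotationRate,nucleusRadii,nDims,seed
#'   see slot documentation.
#' @return A [PopulationPreset-class].
#' @export
PopulationPreset <- function(name = "preset", alphaMean = 0.5, alphaSd = 0.1,
                             dAlpha = 2.8e-4, nLoci = 100, nFrames = 100,
                             dt = 18.5, rho = 0.02, driftAmplitude = 0,
                             rotationRate = 0, nucleusRadii = c(8, 6, 3),
                             nDims = 3, seed = 1) {
  new("PopulationPreset", name = name, alphaMean = alphaMean,
      alphaSd = alphaSd, dAlpha = dAlpha, nLoci = as.integer(nLoci),
      nFrames = as.integer(nFrames), dt = dt, rho = rho,
      driftAmplitude = driftAmplitude, rotationRate = rotationRate,
      nucleusRadii = nucleusRadii, nDims = as.integer(nDims),
      seed = as.integer(seed))
}

#' Ground truth manifest of a simulated ensemble
#'
#' Records every injected parameter of a simulated population so downstream
#' estimators can be scored against the truth.
#'
#' @slot perLocus data.frame with columns locus_id, alpha, d_alpha and the
#'   locus anchor position.
#' @slot driftPath numeric matrix (frames x dims) of the injected COM drift.
#' @slot rotationPath numeric vector of injected cumulative angles (radians).
#' @slot presetId character preset identifier.
#' @slot seed integer master seed.
#' @export
setClass("GroundTruthManifest",
  slots = c(perLocus = "data.frame", driftPath = "matrix",
            rotationPath = "numeric", presetId = "character",
            seed = "integer"))

## ---------------------------------------------------------------------------
## Continuous photobleaching
## ---------------------------------------------------------------------------

#' Continuous-photobleaching trace
#'
#' Fluorescence intensity at a fixed confocal spot sampled uniformly in time
#' (typically 1 kHz for ~60 s).
#'
#' @slot timeS numeric times, s, uniform spacing.
#' @slot intensity numeric intensities, arbitrary units, >= 0.
#' @export
setClass("CPTrace", slots = c(timeS = "numeric", intensity = "numeric"))

setValidity("CPTrace", function(object) {
  msg <- character()
  n <- length(object@timeS)
  if (n < 100L) msg <- c(msg, "trace must contain >= 100 samples")
  if (length(object@intensity) != n)
    msg <- c(msg, "time and intensity must have equal length")
  if (any(object@intensity < 0)) msg <- c(msg, "intensity must be >= 0")
  if (n >= 3L) {
    dtv <- diff(object@timeS)
    if (any(abs(dtv - dtv[1]) > 1e-6 * dtv[1]))
      msg <- c(msg, "sampling must be uniform")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname CPTrace-class
#' @param timeS,intensity numeric vectors.
#' @return A [CPTrace-class].
#' @export
CPTrace <- function(timeS, intensity) {
  new("CPTrace", timeS = as.numeric(timeS), intensity = as.numeric(intensity))
}

#' Parameters of the two-population photobleaching model
#'
#' The bleaching of a bound (immobile) and a freely diffusing fluorophore
#' pool under constant illumination. The bleach coefficient at the spot
#' centre is named \code{bleachRate} (it is unrelated to the anomalous
#' diffusion exponent).
#'
#' @slot boundFraction0 initial bound fraction, in [0, 1].
#' @slot kOn,kOff binding/unbinding rates, 1/s (>= 0).
#' @slot bleachRate bleach coefficient at the spot centre, 1/s (>= 0).
#' @slot freeDiffusionD diffusion coefficient of the free pool, um^2/s.
#' @slot psfWidth Gaussian PSF width (s.d.), um.
#' @slot duration,sampleDt measurement length and sampling interval, s.
#' @slot noiseSd additive Gaussian noise s.d., intensity a.u.
#' @slot amplitude initial detected intensity, a.u.
#' @slot preTriggerS baseline recorded before the laser is switched on, s.
#' @slot seed integer seed for the noise.
#' @export
setClass("CPModelParams",
  slots = c(boundFraction0 = "numeric", kOn = "numeric", kOff = "numeric",
            bleachRate = "numeric", freeDiffusionD = "numeric",
            psfWidth = "numeric", duration = "numeric", sampleDt = "numeric",
            noiseSd = "numeric", amplitude = "numeric",
            preTriggerS = "numeric", seed = "integer"))

setValidity("CPModelParams", function(object) {
  msg <- character()
  if (object@boundFraction0 < 0 || object@boundFraction0 > 1)
    msg <- c(msg, "boundFraction0 must lie in [0, 1]")
  for (s in c("kOn", "kOff", "bleachRate", "freeDiffusionD", "noiseSd",
              "preTriggerS"))
    if (slot(object, s) < 0) msg <- c(msg, sprintf("%s must be >= 0", s))
  if (object@sampleDt <= 0) msg <- c(msg, "sampleDt must be > 0")
  if (object@duration <= object@sampleDt)
    msg <- c(msg, "duration must exceed sampleDt")
  if (object@psfWidth <= 0) msg <- c(msg, "psfWidth must be > 0")
  if (length(msg)) msg else TRUE
})

#' @rdname CPModelParams-class
#' @param boundFraction0,kOn,kOff,bleachRate,freeDiffusionD,psfWidth,duration,sampleDt,noiseSd,amplitude,preTriggerS,seed
#'   see slot documentation.
#' @return A [CPModelParams-class].
#' @export
CPModelParams <- function(boundFraction0 = 0.37, kOn = 0.01, kOff = 0.01,
                          bleachRate = 2, freeDiffusionD = 20,
                          psfWidth = 0.2, duration = 60, sampleDt = 1e-3,
                          noiseSd = 0, amplitude = 100, preTriggerS = 0,
                          seed = 1) {
  new("CPModelParams", boundFraction0 = boundFraction0, kOn = kOn,
      kOff = kOff, bleachRate = bleachRate, freeDiffusionD = freeDiffusionD,
      psfWidth = psfWidth, duration = duration, sampleDt = sampleDt,
      noiseSd = noiseSd, amplitude = amplitude, preTriggerS = preTriggerS,
      seed = as.integer(seed))
}

#' Exponential-plus-linear fit of a CP trace
#'
#' Parameters of I(t) = a*exp(-b*t) + c*t + d fitted after bleach onset.
#' The free fraction is d / (a + d): the extrapolated free-pool intensity at
#' onset over the total initial intensity.
#'
#' @slot a bound-component amplitude, a.u. (>= 0).
#' @slot b bound bleach rate, 1/s (>= 0).
#' @slot c free-pool slow decay slope, a.u./s (negative expected).
#' @slot d free-component intercept, a.u. (>= 0).
#' @slot freeFraction d/(a+d), in [0, 1].
#' @slot freeFractionLinear alternative estimator: intercept of the
#'   long-time linear fit over the initial intensity.
#' @slot onsetTime detected bleach onset, s.
#' @slot degenerate TRUE when no exponential component is resolvable.
#' @slot diagnostics list (residual sd, convergence, n points).
#' @export
setClass("CPFit",
  slots = c(a = "numeric", b = "numeric", c = "numeric", d = "numeric",
            freeFraction = "numeric", freeFractionLinear = "numeric",
            onsetTime = "numeric", degenerate = "logical",
            diagnostics = "list"))

setValidity("CPFit", function(object) {
  msg <- character()
  if (object@a < 0 || object@d < 0) msg <- c(msg, "a and d must be >= 0")
  if (object@freeFraction < 0 || object@freeFraction > 1)
    msg <- c(msg, "freeFraction must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
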