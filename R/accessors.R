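## Accessor methods. Slot access stays inside the package; users go through
## these.

#' @rdname ChromDyn-accessors
#' @aliases nLoci,LocusEnsemble-method
setMethod("nLoci", "LocusEnsemble", function(object) nrow(object))

#' @rdname ChromDyn-accessors
setMethod("nFrames", "LocusEnsemble", function(object) ncol(object))

#' @rdname ChromDyn-accessors
setMethod("frameTimes", "LocusEnsemble", function(object)
  SummarizedExperiment::colData(object)$time_s)

#' @rdname ChromDyn-accessors
setMethod("frameInterval", "LocusEnsemble", function(object)
  S4Vectors::metadata(object)$dt)

#' @rdname ChromDyn-accessors
setMethod("nucleusId", "LocusEnsemble", function(object)
  S4Vectors::metadata(object)$nucleus_id)

#' @rdname ChromDyn-accessors
setMethod("conditionLabel", "LocusEnsemble", function(object)
  S4Vectors::metadata(object)$condition)

#' @rdname ChromDyn-accessors
setMethod("locusIds", "LocusEnsemble", function(object) rownames(object))

#' @rdname ChromDyn-accessors
setMethod("coordDims", "LocusEnsemble", function(object)
  intersect(c("x", "y", "z"), SummarizedExperiment::assayNames(object)))

#' @rdname ChromDyn-accessors
setMethod("getTrajectory", "LocusEnsemble", function(object, i) {
  if (is.character(i)) i <- match(i, rownames(object))
  stopifnot(length(i) == 1L, !is.na(i), i >= 1L, i <= nrow(object))
  dims <- coordDims(object)
  coords <- vapply(dims, function(a)
    as.numeric(SummarizedExperiment::assay(object, a)[i, ]),
    numeric(ncol(object)))
  Trajectory(coords, frameTimes(object), rownames(object)[i])
})

#' @rdname ChromDyn-accessors
setMethod("trajectories", "LocusEnsemble", function(object) {
  dims <- coordDims(object)
  mats <- lapply(dims, function(a) SummarizedExperiment::assay(object, a))
  timeS <- frameTimes(object)
  ids <- rownames(object)
  setNames(lapply(seq_len(nrow(object)), function(i) {
    coords <- vapply(mats, function(m) as.numeric(m[i, ]),
                     numeric(ncol(object)))
    colnames(coords) <- dims
    Trajectory(coords, timeS, ids[i])
  }), ids)
})

#' @rdname ChromDyn-accessors
setMethod("nFrames", "Trajectory", function(object) length(object@timeS))

#' @rdname ChromDyn-accessors
setMethod("frameTimes", "Trajectory", function(object) object@timeS)

#' @rdname ChromDyn-accessors
setMethod("frameInterval", "Trajectory", function(object)
  if (length(object@timeS) >= 2L) object@timeS[2] - object@timeS[1] else
    NA_real_)

#' @rdname ChromDyn-accessors
setMethod("locusIds", "Trajectory", function(object) object@locusId)

#' @rdname ChromDyn-accessors
setMethod("coordDims", "Trajectory", function(object)
  colnames(object@coords))

#' Coordinates of a trajectory
#' @param object a [Trajectory-class].
#' @return numeric matrix (frames x dims), um.
#' @export
coords <- function(object) {
  stopifnot(is(object, "Trajectory"))
  object@coords
}

#' @rdname ChromDyn-accessors
setMethod("alphaMean", "EnsembleDiffusionEstimate",
          function(object) object@alphaMean)

#' @rdname ChromDyn-accessors
setMethod("alphaSd", "EnsembleDiffusionEstimate",
          function(object) sqrt(object@alphaVar))

#' @rdname ChromDyn-accessors
setMethod("dAlpha", "EnsembleDiffusionEstimate", function(object)
  object@dAlpha)

#' @rdname ChromDyn-accessors
setMethod("rho", "EnsembleDiffusionEstimate", function(object) object@rho)

#' @rdname ChromDyn-accessors
setMethod("rho", "StaticPrecision", function(object) object@rho)

#' @rdname ChromDyn-accessors
setMethod("alphaMean", "PopulationPreset", function(object) object@alphaMean)

#' @rdname ChromDyn-accessors
setMethod("alphaSd", "PopulationPreset", function(object) object@alphaSd)

#' @rdname ChromDyn-accessors
setMethod("dAlpha", "PopulationPreset", function(object) object@dAlpha)

#' @rdname ChromDyn-accessors
setMethod("rho", "PopulationPreset", function(object) object@rho)

#' @rdname ChromDyn-accessors
setMethod("nLoci", "PopulationPreset", function(object) object@nLoci)

#' @rdname ChromDyn-accessors
setMethod("nFrames", "PopulationPreset", function(object) object@nFrames)

#' @rdname ChromDyn-accessors
setMethod("frameInterval", "PopulationPreset", function(object) object@dt)

#' @rdname ChromDyn-accessors
setMethod("alpha", "DiffusionFit", function(object) object@alpha)

#' @rdname ChromDyn-accessors
setMethod("dAlpha", "DiffusionFit", function(object) object@dAlpha)

#' @rdname ChromDyn-accessors
setMethod("freeFraction", "CPFit", function(object) object@freeFraction)

#' @rdname ChromDyn-accessors
setMethod("groundTruth", "GroundTruthManifest", function(object)
  object@perLocus)

#' Lag times and MSD values of an MSDCurve
#' @param object an [MSDCurve-class].
#' @return named list with tau (s), msd (um^2) and nPairs.
#' @export
msdValues <- function(object) {
  stopifnot(is(object, "MSDCurve"))
  list(tau = object@tau, msd = object@msd, nPairs = object@nPairs)
}

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory '%s': %d frames, dt = %.4g s, dims = %s\n",
              object@locusId, length(object@timeS),
              frameInterval(object), paste(coordDims(object), collapse = "")))
})

setMethod("show", "LocusEnsemble", function(object) {
  cat(sprintf(
    "LocusEnsemble '%s' (%s): %d loci x %d frames, dt = %.4g s, dims = %s\n",
    nucleusId(object), conditionLabel(object), nLoci(object),
    nFrames(object), frameInterval(object),
    paste(coordDims(object), collapse = "")))
})

setMethod("show", "MSDCurve", function(object) {
  cat(sprintf("MSDCurve '%s' (%s): %d lags, tau %.4g..%.4g s\n",
              object@locusId, object@dims, length(object@tau),
              min(object@tau), max(object@tau)))
})

setMethod("show", "DiffusionFit", function(object) {
  cat(sprintf(
    "DiffusionFit: alpha = %.3f, D_alpha = %.3g um^2 s^-alpha (window %.3g..%.3g s)\n",
    object@alpha, object@dAlpha, object@window[1], object@window[2]))
})

setMethod("show", "EnsembleDiffusionEstimate", function(object) {
  cat(sprintf(
    paste0("EnsembleDiffusionEstimate (%d loci):\n",
           "  alpha_MSD  = %.3f\n  alpha_MLSD = %.3f\n",
           "  mean alpha = %.3f, sd alpha = %.3f\n",
           "  D_alpha    = %.3g um^2 s^-alpha, rho = %.3g um\n"),
    object@nLoci, object@alphaMsd, object@alphaMlsd, object@alphaMean,
    sqrt(object@alphaVar), object@dAlpha, object@rho))
})

setMethod("show", "RigidMotionEstimate", function(object) {
  cat(sprintf(
    "RigidMotionEstimate: %d frames, rotation %s, max |angle| = %.4g rad\n",
    nrow(object@com),
    if (object@rotationReliable) "reliable" else "UNRELIABLE",
    max(abs(object@angle))))
})

setMethod("show", "CPTrace", function(object) {
  cat(sprintf("CPTrace: %d samples at %.4g s, %.4g s total\n",
              length(object@timeS), object@timeS[2] - object@timeS[1],
              diff(range(object@timeS))))
})

setMethod("show", "CPFit", function(object) {
  cat(sprintf(
    paste0("CPFit: I(t) = %.3g exp(-%.3g t) + %.3g t + %.3g\n",
           "  free fraction = %.3f (linear-extrapolation estimate %.3f)\n",
           "  onset = %.3g s%s\n"),
    object@a, object@b, object@c, object@d, object@freeFraction,
    object@freeFractionLinear, object@onsetTime,
    if (object@degenerate) " [degenerate: no exponential component]" else ""))
})

setMethod("show", "PopulationPreset", function(object) {
  cat(sprintf(
    paste0("PopulationPreset '%s': %d loci x %d frames, dt = %.4g s\n",
           "  alpha ~ N(%.2f, %.2f^2), D_alpha = %.3g um^2 s^-alpha\n",
           "  rho = %.3g um, drift = %.3g um/frame, rotation = %.3g rad/frame",
           ", seed = %d\n"),
    object@name, object@nLoci, object@nFrames, object@dt, object@alphaMean,
    object@alphaSd, object@dAlpha, object@rho, object@driftAmplitude,
    object@rotationRate, object@seed))
})

setMethod("show", "GroundTruthManifest", function(object) {
  cat(sprintf("GroundTruthManifest '%s': %d loci, seed %d\n",
              object@presetId, nrow(object@perLocus), object@seed))
})

setMethod("show", "HullClassification", function(object) {
  cat(sprintf(
    "HullClassification (%s): %d internal, %d peripheral over %d frames\n",
    object@dims, length(object@internalFinal),
    length(object@peripheralFinal), length(object@peripheralByFrame)))
})

setMethod("show", "ScannedVolume", function(object) {
  unit <- if (object@dims == "3D") "um^3" else "um^2"
  cat(sprintf("ScannedVolume '%s': %.4g %s over %.4g s%s\n",
              object@locusId, object@value, unit, object@duration,
              if (object@degenerate) " [degenerate]" else ""))
})

setMethod("show", "StaticPrecision", function(object) {
  cat(sprintf("StaticPrecision: rho = %.4g um (%s, %d loci)\n",
              object@rho, object@method, object@nLoci))
})
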