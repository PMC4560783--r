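## Whole-nucleus rigid-motion estimation and correction.
##
## Drift is the per-frame unweighted centre of mass of all loci; rotation is
## the closed-form 2D orthogonal Procrustes angle mapping each COM-centred
## frame onto the COM-centred reference frame (cumulative-from-reference
## convention, which avoids accumulating frame-to-frame errors). Cells are
## surface-adhering, so no out-of-plane rotation is estimated: z is
## translated by the COM but never rotated.

.ensCoordArray <- function(ensemble) {
  dims <- coordDims(ensemble)
  arr <- array(NA_real_, c(nLoci(ensemble), nFrames(ensemble), length(dims)),
               dimnames = list(locusIds(ensemble), NULL, dims))
  for (j in seq_along(dims))
    arr[, , j] <- SummarizedExperiment::assay(ensemble, dims[j])
  arr
}

.rot2 <- function(theta)
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)

#' Estimate whole-nucleus drift and in-plane rotation
#'
#' @param ensemble a [LocusEnsemble-class] (gap-free, shared frame grid).
#' @param referenceFrame 1-based index of the frame the rotation angles are
#'   referenced to (angle = 0 there).
#' @return A [RigidMotionEstimate-class]. With fewer than 3 loci the
#'   rotation cannot be estimated: angles are returned as 0 with a warning
#'   and \code{rotationReliable = FALSE}; near-collinear configurations are
#'   flagged the same way.
#' @export
estimateRigidMotion <- function(ensemble, referenceFrame = 1L) {
  stopifnot(is(ensemble, "LocusEnsemble"))
  referenceFrame <- as.integer(referenceFrame)
  stopifnot(referenceFrame >= 1L, referenceFrame <= nFrames(ensemble))
  arr <- .ensCoordArray(ensemble)
  nF <- dim(arr)[2]; nD <- dim(arr)[3]
  com <- t(vapply(seq_len(nF),
                  function(t) colMeans(matrix(arr[, t, ], ncol = nD)),
                  numeric(nD)))
  colnames(com) <- dimnames(arr)[[3]]
  angle <- numeric(nF)
  reliable <- TRUE
  if (nLoci(ensemble) < 3L) {
    warning("fewer than 3 loci: rotation not estimable, COM-only estimate")
    reliable <- FALSE
  } else {
    ref <- sweep(matrix(arr[, referenceFrame, 1:2], ncol = 2), 2L,
                 com[referenceFrame, 1:2])
    ev <- eigen(cov(ref), symmetric = TRUE, only.values = TRUE)$values
    if (ev[1] <= 0 || ev[2] / ev[1] < 1e-8) {
      warning("near-collinear locus configuration: rotation unreliable")
      reliable <- FALSE
    }
    for (t in seq_len(nF)) {
      cur <- sweep(matrix(arr[, t, 1:2], ncol = 2), 2L, com[t, 1:2])
      angle[t] <- atan2(sum(ref[, 1] * cur[, 2] - ref[, 2] * cur[, 1]),
                        sum(ref[, 1] * cur[, 1] + ref[, 2] * cur[, 2]))
    }
    angle[referenceFrame] <- 0
  }
  new("RigidMotionEstimate", com = com, angle = angle,
      referenceFrame = referenceFrame, rotationReliable = reliable)
}

.applyMotion <- function(coordsMat, dims, motion) {
  ## coordsMat: frames x dims matrix for one locus; returns corrected matrix
  nF <- nrow(coordsMat)
  out <- coordsMat
  for (j in seq_along(dims))
    out[, j] <- coordsMat[, j] - motion@com[, j]
  xy <- out[, 1:2, drop = FALSE]
  ## multiply by the inverse rotation matrix
  ca <- cos(-motion@angle); sa <- sin(-motion@angle)
  out[, 1] <- ca * xy[, 1] - sa * xy[, 2]
  out[, 2] <- sa * xy[, 1] + ca * xy[, 2]
  out
}

#' Remove estimated rigid motion from an ensemble
#'
#' Subtracts the per-frame centre of mass and multiplies each trajectory by
#' the inverse in-plane rotation matrix. After correction the ensemble COM
#' sits at the origin in every frame and the residual ensemble rotation is
#' zero to solver tolerance; internal (relative) locus motion is preserved.
#' The operation is idempotent.
#'
#' @param ensemble a [LocusEnsemble-class].
#' @param motion a [RigidMotionEstimate-class] covering the same frames
#'   (estimated from \code{ensemble} when omitted).
#' @return The corrected [LocusEnsemble-class].
#' @export
correctEnsemble <- function(ensemble, motion = NULL) {
  stopifnot(is(ensemble, "LocusEnsemble"))
  if (is.null(motion)) motion <- estimateRigidMotion(ensemble)
  stopifnot(is(motion, "RigidMotionEstimate"))
  if (nrow(motion@com) != nFrames(ensemble))
    stop("motion estimate does not cover the ensemble's frames")
  arr <- .ensCoordArray(ensemble)
  dims <- dimnames(arr)[[3]]
  for (i in seq_len(dim(arr)[1]))
    arr[i, , ] <- .applyMotion(matrix(arr[i, , ], ncol = length(dims)),
                               dims, motion)
  LocusEnsemble(x = arr[, , 1], y = arr[, , 2],
                z = if (length(dims) == 3L) arr[, , 3] else NULL,
                timeS = frameTimes(ensemble), nucleusId = nucleusId(ensemble),
                condition = conditionLabel(ensemble),
                locusIds = locusIds(ensemble))
}

#' Correct a sparse locus using co-observed reference loci
#'
#' Transforms a target trajectory (for example a single gene locus) by the
#' rigid motion estimated from a reference ensemble (for example the
#' co-observed telomeres of the same nucleus). A reference locus sharing the
#' target's id is excluded from the motion estimation.
#'
#' @param target a [Trajectory-class] on the reference's frame grid.
#' @param reference a [LocusEnsemble-class].
#' @param referenceFrame forwarded to [estimateRigidMotion()].
#' @return The corrected [Trajectory-class].
#' @export
correctByReference <- function(target, reference, referenceFrame = 1L) {
  stopifnot(is(target, "Trajectory"), is(reference, "LocusEnsemble"))
  if (nFrames(target) != nFrames(reference) ||
      max(abs(frameTimes(target) - frameTimes(reference))) > 1e-9)
    stop("target and reference must share the frame grid")
  drop <- which(locusIds(reference) == target@locusId)
  if (length(drop) && nLoci(reference) - length(drop) >= 1L)
    reference <- reference[-drop, ]
  motion <- estimateRigidMotion(reference, referenceFrame)
  dims <- coordDims(target)
  refDims <- coordDims(reference)
  if (!all(dims %in% refDims))
    stop("reference lacks coordinate axes present in the target")
  motionSub <- new("RigidMotionEstimate",
                   com = motion@com[, dims, drop = FALSE],
                   angle = motion@angle,
                   referenceFrame = motion@referenceFrame,
                   rotationReliable = motion@rotationReliable)
  Trajectory(.applyMotion(coords(target), dims, motionSub),
             frameTimes(target), target@locusId)
}
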