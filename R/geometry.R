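## Scanned territories and internal/peripheral locus classification.

#' Territory scanned by one locus
#'
#' Convex-hull volume of a trajectory's positions within a time window: the
#' nuclear territory the locus explored. 3D coordinates give a volume in
#' um^3; 2D data fall back to the hull area in um^2 (explicitly labelled,
#' never silently mixed with volumes). Fewer than 4 non-coplanar points
#' (3 non-collinear in 2D) give 0 with a degenerate flag.
#'
#' @param traj a [Trajectory-class].
#' @param window window length in seconds counted from the first frame, or
#'   \code{c(start, end)} in absolute time; NULL uses the whole trajectory.
#' @return A [ScannedVolume-class].
#' @examples
#' tet <- Trajectory(cbind(x = c(0, 1, 0, 0), y = c(0, 0, 1, 0),
#'                         z = c(0, 0, 0, 1)), 0:3)
#' scannedVolume(tet)  # 1/6 um^3
#' @export
scannedVolume <- function(traj, window = NULL) {
  stopifnot(is(traj, "Trajectory"))
  tS <- frameTimes(traj)
  if (is.null(window)) {
    sel <- rep(TRUE, length(tS))
  } else if (length(window) == 1L) {
    sel <- tS - tS[1] <= window
  } else sel <- tS >= window[1] & tS <= window[2]
  if (!any(sel)) stop("trajectory does not cover the requested window")
  P <- coords(traj)[sel, , drop = FALSE]
  duration <- diff(range(tS[sel]))
  if ("z" %in% colnames(P)) {
    h <- .hull3d(P)
    if (h$degenerate)
      return(new("ScannedVolume", locusId = traj@locusId, value = 0,
                 dims = "3D", duration = duration, degenerate = TRUE))
    new("ScannedVolume", locusId = traj@locusId, value = h$volume,
        dims = "3D", duration = duration, degenerate = FALSE)
  } else {
    warning("2D trajectory: reporting scanned area (um^2), not volume")
    h <- .hull2d(P)
    new("ScannedVolume", locusId = traj@locusId, value = h$area,
        dims = "2D", duration = duration, degenerate = h$degenerate)
  }
}

#' Scanned territories of all loci in an ensemble
#'
#' @inheritParams scannedVolume
#' @param ensemble a [LocusEnsemble-class].
#' @return data.frame with locus_id, value (um^3, or um^2 for 2D data),
#'   dims, duration and degenerate flag.
#' @export
scannedVolumes <- function(ensemble, window = NULL) {
  res <- lapply(trajectories(ensemble), function(tr)
    suppressWarnings(scannedVolume(tr, window)))
  data.frame(locus_id = vapply(res, slot, character(1), "locusId"),
             value = vapply(res, slot, numeric(1), "value"),
             dims = vapply(res, slot, character(1), "dims"),
             duration = vapply(res, slot, numeric(1), "duration"),
             degenerate = vapply(res, slot, logical(1), "degenerate"),
             row.names = NULL)
}

#' Classify loci as internal or peripheral by per-frame convex hulls
#'
#' At every time point the convex hull of all loci is computed; loci on the
#' hull are peripheral for that frame, the rest internal. The final internal
#' set is the intersection over all frames (loci that never touched the
#' hull); everything else is finally peripheral. "Touching" means being a
#' hull vertex, with a 1e-9 um surface-distance tolerance for numerically
#' coincident points. The hull is a periphery proxy: internal loci are those
#' that in all likelihood never approached the nuclear lamina during the
#' measurement.
#'
#' @param ensemble a [LocusEnsemble-class] with >= 5 loci (with fewer, the
#'   hull trivially contains nearly all loci and classification is refused).
#' @param touchTol surface-distance tolerance in um.
#' @return A [HullClassification-class].
#' @export
classifyInternalPeripheral <- function(ensemble, touchTol = 1e-9) {
  stopifnot(is(ensemble, "LocusEnsemble"))
  if (nLoci(ensemble) < 5L)
    stop("classification needs >= 5 loci: with fewer, the hull includes ",
         "nearly all points")
  arr <- .ensCoordArray(ensemble)
  has3d <- dim(arr)[3] == 3L
  ids <- locusIds(ensemble)
  nF <- dim(arr)[2]
  periByFrame <- vector("list", nF)
  onCount <- setNames(integer(length(ids)), ids)
  for (t in seq_len(nF)) {
    P <- matrix(arr[, t, ], ncol = dim(arr)[3])
    idx <- if (has3d) .hullSurfacePoints(P, .hull3d(P), touchTol)
           else .hull2dBoundary(P, touchTol)
    periByFrame[[t]] <- ids[idx]
    onCount[idx] <- onCount[idx] + 1L
  }
  internal <- ids[onCount == 0L]
  new("HullClassification", peripheralByFrame = periByFrame,
      internalFinal = internal,
      peripheralFinal = setdiff(ids, internal),
      nFramesOnHull = onCount, dims = if (has3d) "3D" else "2D")
}
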