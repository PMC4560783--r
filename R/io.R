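## Trajectory table and CP trace I/O.
##
## Canonical CSV schema (comma separated, '.' decimal, header required):
##   nucleus_id, locus_id, frame, time_s, x_um, y_um[, z_um]
## Coordinates are absolute stage coordinates in micrometres; unit-less
## (pixel) input is refused. An "imaris-export" dialect maps common column
## names of Imaris spot/track exports onto the canonical schema
## (best-effort: the exact export naming varies between versions).

.imarisMap <- c("Position X" = "x_um", "Position.X" = "x_um", "posx" = "x_um",
                "Position Y" = "y_um", "Position.Y" = "y_um", "posy" = "y_um",
                "Position Z" = "z_um", "Position.Z" = "z_um", "posz" = "z_um",
                "Time" = "frame", "TrackID" = "locus_id",
                "Track.ID" = "locus_id", "ID" = "locus_id")

.fmtNum <- function(x) sprintf("%.17g", x)  # lossless double round-trip

#' Read locus trajectories from CSV
#'
#' Parses a trajectory table, groups loci by nucleus, and enforces the
#' gap-free contract: trajectories with missing time points are excluded
#' (with a logged reason), mirroring the selection applied to tracked data.
#'
#' @param path CSV file.
#' @param dialect "canonical" (schema above) or "imaris-export" (best-effort
#'   column mapping; positions must already be in um).
#' @param dt frame interval in seconds, used when the file has no
#'   \code{time_s} column (time is then frame * dt).
#' @param condition free-text condition label attached to each ensemble.
#' @return Named list of [LocusEnsemble-class], one per nucleus, with an
#'   attribute \code{"rejected"}: a data.frame (nucleus_id, locus_id,
#'   reason) of excluded trajectories.
#' @export
readTrajectories <- function(path, dialect = c("canonical", "imaris-export"),
                             dt = NULL, condition = "") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (dialect == "imaris-export") {
    hit <- intersect(names(.imarisMap), colnames(df))
    colnames(df)[match(hit, colnames(df))] <- .imarisMap[hit]
    if (!"nucleus_id" %in% colnames(df)) df$nucleus_id <- "nucleus_1"
  }
  need <- c("nucleus_id", "locus_id", "frame", "x_um", "y_um")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (any(grepl("_px$|pixel", colnames(df), ignore.case = TRUE)))
    stop("pixel-unit columns detected; convert to stage coordinates in um")
  for (cc in intersect(c("frame", "time_s", "x_um", "y_um", "z_um"),
                       colnames(df))) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !is.na(df[[cc]]))
    if (length(bad))
      stop(sprintf("malformed value in column '%s' at data line %d", cc,
                   bad[1]))
    df[[cc]] <- v
  }
  hasZ <- "z_um" %in% colnames(df) && !all(is.na(df$z_um))
  rejected <- data.frame(nucleus_id = character(), locus_id = character(),
                         reason = character())
  out <- list()
  for (nuc in unique(df$nucleus_id)) {
    sub <- df[df$nucleus_id == nuc, , drop = FALSE]
    keep <- list()
    for (loc in unique(sub$locus_id)) {
      tr <- sub[sub$locus_id == loc, , drop = FALSE]
      tr <- tr[order(tr$frame), , drop = FALSE]
      if (nrow(tr) < 2L ||
          !all(diff(tr$frame) == 1)) {
        rejected <- rbind(rejected, data.frame(
          nucleus_id = nuc, locus_id = as.character(loc),
          reason = "missing time points"))
        message(sprintf("rejected locus '%s' (nucleus '%s'): missing time points",
                        loc, nuc))
        next
      }
      keep[[as.character(loc)]] <- tr
    }
    if (!length(keep)) next
    frames <- sort(unique(do.call(rbind, keep)$frame))
    full <- vapply(keep, function(tr)
      tr$frame[1] == frames[1] && nrow(tr) == length(frames), logical(1))
    if (!all(full)) {
      for (loc in names(keep)[!full]) {
        rejected <- rbind(rejected, data.frame(
          nucleus_id = nuc, locus_id = loc,
          reason = "not on the common frame grid"))
        message(sprintf("rejected locus '%s' (nucleus '%s'): not on the common frame grid",
                        loc, nuc))
      }
      keep <- keep[full]
      if (!length(keep)) next
    }
    if ("time_s" %in% colnames(sub)) {
      timeS <- keep[[1]]$time_s
    } else {
      if (is.null(dt))
        stop("no time_s column; supply dt to derive time as frame * dt")
      timeS <- frames * dt
    }
    xm <- t(vapply(keep, function(tr) tr$x_um, numeric(length(frames))))
    ym <- t(vapply(keep, function(tr) tr$y_um, numeric(length(frames))))
    zm <- if (hasZ)
      t(vapply(keep, function(tr) tr$z_um, numeric(length(frames)))) else NULL
    out[[as.character(nuc)]] <- LocusEnsemble(
      x = xm, y = ym, z = zm, timeS = timeS, nucleusId = as.character(nuc),
      condition = condition, locusIds = names(keep))
  }
  attr(out, "rejected") <- rejected
  out
}

#' Write locus ensembles to canonical CSV
#'
#' Inverse of [readTrajectories()] on the canonical dialect: coordinates are
#' serialized losslessly (17 significant digits) so a write/read cycle is
#' bit-identical. Per-nucleus frame intervals are preserved.
#'
#' @param ensembles a [LocusEnsemble-class] or a list of them.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeTrajectories <- function(ensembles, path) {
  if (is(ensembles, "LocusEnsemble")) ensembles <- list(ensembles)
  rows <- lapply(ensembles, function(ens) {
    dims <- coordDims(ens)
    nL <- nLoci(ens); nF <- nFrames(ens)
    df <- data.frame(
      nucleus_id = rep(nucleusId(ens), nL * nF),
      locus_id = rep(locusIds(ens), each = nF),
      frame = rep(SummarizedExperiment::colData(ens)$frame, times = nL),
      time_s = .fmtNum(rep(frameTimes(ens), times = nL)))
    for (a in dims)
      df[[paste0(a, "_um")]] <-
        .fmtNum(as.numeric(t(SummarizedExperiment::assay(ens, a))))
    df
  })
  cols <- unique(unlist(lapply(rows, colnames)))
  rows <- lapply(rows, function(df) {
    for (cc in setdiff(cols, colnames(df))) df[[cc]] <- NA
    df[, cols, drop = FALSE]
  })
  all <- if (length(rows)) do.call(rbind, rows) else
    as.data.frame(setNames(rep(list(character()), 7),
                           c("nucleus_id", "locus_id", "frame", "time_s",
                             "x_um", "y_um", "z_um")))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
  on.exit(close(con))
  write.table(all, con, sep = ",", row.names = FALSE, quote = FALSE,
              na = "")
  invisible(path)
}

#' Read / write a continuous-photobleaching trace
#'
#' Two-column CSV (\code{time_s}, \code{intensity}).
#'
#' @param path CSV file.
#' @return [CPTrace-class] for the reader; the path, invisibly, for the
#'   writer.
#' @export
readCPTrace <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path)
  if (!all(c("time_s", "intensity") %in% colnames(df)))
    stop("CP trace CSV must have columns time_s, intensity")
  CPTrace(df$time_s, df$intensity)
}

#' @rdname readCPTrace
#' @param trace a [CPTrace-class].
#' @export
writeCPTrace <- function(trace, path) {
  stopifnot(is(trace, "CPTrace"))
  df <- data.frame(time_s = .fmtNum(trace@timeS),
                   intensity = .fmtNum(trace@intensity))
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize / restore a ground-truth manifest
#'
#' Writes the per-locus truth table, the injected drift and rotation paths
#' and the preset identity to a directory as plain text, losslessly (17
#' significant digits), so the manifest round-trips bit-exactly.
#'
#' @param manifest a [GroundTruthManifest-class].
#' @param dir output directory (created if needed).
#' @return the directory (writer) or a [GroundTruthManifest-class] (reader).
#' @export
writeManifest <- function(manifest, dir) {
  stopifnot(is(manifest, "GroundTruthManifest"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  per <- manifest@perLocus
  for (cc in colnames(per))
    if (is.numeric(per[[cc]])) per[[cc]] <- .fmtNum(per[[cc]])
  write.table(per, file.path(dir, "per_locus.csv"), sep = ",",
              row.names = FALSE, quote = FALSE)
  dp <- as.data.frame(manifest@driftPath)
  colnames(dp) <- paste0("drift_", c("x", "y", "z")[seq_len(ncol(dp))])
  dp[] <- lapply(dp, .fmtNum)
  dp$angle_rad <- .fmtNum(manifest@rotationPath)
  write.table(dp, file.path(dir, "rigid_motion.csv"), sep = ",",
              row.names = FALSE, quote = FALSE)
  writeLines(c(paste0("preset_id: ", manifest@presetId),
               paste0("seed: ", manifest@seed)),
             file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' @rdname writeManifest
#' @export
readManifest <- function(dir) {
  per <- read.csv(file.path(dir, "per_locus.csv"),
                  stringsAsFactors = FALSE)
  rm_ <- read.csv(file.path(dir, "rigid_motion.csv"))
  kv <- readLines(file.path(dir, "manifest.txt"))
  getv <- function(key) sub(paste0("^", key, ": "), "",
                            grep(paste0("^", key, ": "), kv, value = TRUE))
  driftCols <- grep("^drift_", colnames(rm_), value = TRUE)
  new("GroundTruthManifest", perLocus = per,
      driftPath = unname(as.matrix(rm_[, driftCols, drop = FALSE])),
      rotationPath = rm_$angle_rad, presetId = getv("preset_id"),
      seed = as.integer(getv("seed")))
}
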