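## Incremental 3D convex hull (triangle faces, outward normals).
## Point counts here are small (<= a few hundred loci or frames), so the
## O(n * faces) incremental construction is ample. Returns the hull vertex
## indices, the triangular face list, the enclosed volume, and a degenerate
## flag for inputs of affine rank < 3.

.faceNormal <- function(pts, f) {
  a <- pts[f[1], ]; b <- pts[f[2], ]; c_ <- pts[f[3], ]
  u <- b - a; v <- c_ - a
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

## orient face so its normal points away from the interior point q
.orientFace <- function(pts, f, q) {
  n <- .faceNormal(pts, f)
  if (sum(n * (q - pts[f[1], ])) > 0) f[c(1, 3, 2)] else f
}

.hull3d <- function(pts, tol = 1e-9) {
  pts <- unname(as.matrix(pts))
  n <- nrow(pts)
  degenerate <- list(vertices = integer(), faces = NULL, volume = 0,
                     degenerate = TRUE)
  if (n < 4L) return(degenerate)
  scale <- max(1, max(abs(pts)))
  ## initial simplex: spread extremes
  i1 <- which.min(pts[, 1])
  d1 <- rowSums(sweep(pts, 2L, pts[i1, ])^2)
  i2 <- which.max(d1)
  if (sqrt(d1[i2]) <= tol * scale) return(degenerate)
  u <- pts[i2, ] - pts[i1, ]
  rel <- sweep(pts, 2L, pts[i1, ])
  cr <- cbind(rel[, 2] * u[3] - rel[, 3] * u[2],
              rel[, 3] * u[1] - rel[, 1] * u[3],
              rel[, 1] * u[2] - rel[, 2] * u[1])
  dLine <- sqrt(rowSums(cr^2)) / sqrt(sum(u^2))
  i3 <- which.max(dLine)
  if (dLine[i3] <= tol * scale) return(degenerate)
  nrm <- .faceNormal(pts, c(i1, i2, i3))
  nrm <- nrm / sqrt(sum(nrm^2))
  dPlane <- abs(rel %*% nrm)
  i4 <- which.max(dPlane)
  if (dPlane[i4] <= tol * scale) return(degenerate)
  q <- colMeans(pts[c(i1, i2, i3, i4), ])
  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  faces <- t(apply(faces, 1L, function(f) .orientFace(pts, f, q)))
  rest <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  for (p in rest) {
    nf <- nrow(faces)
    vis <- logical(nf)
    for (k in seq_len(nf)) {
      nrm <- .faceNormal(pts, faces[k, ])
      vis[k] <- sum(nrm * (pts[p, ] - pts[faces[k, 1], ])) >
        tol * scale * sqrt(sum(nrm^2))
    }
    if (!any(vis)) next
    ## horizon: edges of visible faces not shared with another visible face
    edges <- do.call(rbind, lapply(which(vis), function(k) {
      f <- faces[k, ]
      rbind(f[c(1, 2)], f[c(2, 3)], f[c(3, 1)])
    }))
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    horizon <- edges[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    faces <- faces[!vis, , drop = FALSE]
    newF <- t(apply(horizon, 1L, function(e)
      .orientFace(pts, c(e[1], e[2], p), q)))
    faces <- rbind(faces, newF)
  }
  verts <- sort(unique(as.integer(faces)))
  vol <- 0
  for (k in seq_len(nrow(faces))) {
    a <- pts[faces[k, 1], ]; b <- pts[faces[k, 2], ]; c_ <- pts[faces[k, 3], ]
    vol <- vol + (a[1] * (b[2] * c_[3] - b[3] * c_[2]) -
                  a[2] * (b[1] * c_[3] - b[3] * c_[1]) +
                  a[3] * (b[1] * c_[2] - b[2] * c_[1])) / 6
  }
  list(vertices = verts, faces = faces, volume = abs(vol), degenerate = FALSE)
}

## indices of points lying on the hull surface (vertices plus points within
## `touchTol` of a face plane from inside, i.e. numerically coincident)
.hullSurfacePoints <- function(pts, hull, touchTol = 1e-9) {
  pts <- unname(as.matrix(pts))
  if (hull$degenerate) return(seq_len(nrow(pts)))
  on <- rep(FALSE, nrow(pts))
  on[hull$vertices] <- TRUE
  others <- which(!on)
  if (length(others)) {
    nf <- nrow(hull$faces)
    normals <- matrix(0, nf, 3)
    offs <- numeric(nf)
    for (k in seq_len(nf)) {
      nrm <- .faceNormal(pts, hull$faces[k, ])
      nrm <- nrm / sqrt(sum(nrm^2))
      normals[k, ] <- nrm
      offs[k] <- sum(nrm * pts[hull$faces[k, 1], ])
    }
    sd_ <- pts[others, , drop = FALSE] %*% t(normals) -
      rep(offs, each = length(others))
    on[others] <- apply(sd_, 1L, max) >= -touchTol
  }
  which(on)
}

## 2D analogue: polygon area of the convex hull
.hull2d <- function(pts, tol = 1e-9) {
  pts <- unname(as.matrix(pts))[, 1:2, drop = FALSE]
  n <- nrow(pts)
  if (n < 3L) return(list(vertices = integer(), area = 0, degenerate = TRUE))
  h <- grDevices::chull(pts[, 1], pts[, 2])
  if (length(h) < 3L)
    return(list(vertices = h, area = 0, degenerate = TRUE))
  xs <- pts[h, 1]; ys <- pts[h, 2]
  area <- abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
  if (area <= tol^2)
    return(list(vertices = h, area = 0, degenerate = TRUE))
  list(vertices = sort(h), area = area, degenerate = FALSE)
}

## points on the 2D hull boundary (vertices plus edge-coincident points)
.hull2dBoundary <- function(pts, tol = 1e-9) {
  pts <- unname(as.matrix(pts))[, 1:2, drop = FALSE]
  h <- grDevices::chull(pts[, 1], pts[, 2])
  if (length(h) < 3L) return(seq_len(nrow(pts)))
  on <- rep(FALSE, nrow(pts)); on[h] <- TRUE
  hc <- c(h, h[1])
  for (i in which(!on)) {
    p <- pts[i, ]
    for (k in seq_along(h)) {
      a <- pts[hc[k], ]; b <- pts[hc[k + 1], ]
      ab <- b - a
      cr <- ab[1] * (p[2] - a[2]) - ab[2] * (p[1] - a[1])
      if (abs(cr) / sqrt(sum(ab^2)) <= tol) {
        tpar <- sum((p - a) * ab) / sum(ab^2)
        if (tpar >= -tol && tpar <= 1 + tol) { on[i] <- TRUE; break }
      }
    }
  }
  which(on)
}
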