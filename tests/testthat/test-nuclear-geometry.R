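test_that("scanned volume matches closed-form geometry", {
  tet <- Trajectory(cbind(x = c(0, 1, 0, 0), y = c(0, 0, 1, 0),
                          z = c(0, 0, 0, 1)), 0:3)
  sv <- scannedVolume(tet)
  expect_equal(sv@value, 1 / 6, tolerance = 1e-12)
  expect_false(sv@degenerate)

  cube <- expand.grid(x = 0:1, y = 0:1, z = 0:1)
  trc <- Trajectory(as.matrix(cube), 0:7)
  expect_equal(scannedVolume(trc)@value, 1, tolerance = 1e-12)

  ## collinear points are degenerate with volume 0
  lin <- Trajectory(cbind(x = 0:5, y = 2 * (0:5), z = 3 * (0:5)), 0:5)
  svl <- scannedVolume(lin)
  expect_equal(svl@value, 0)
  expect_true(svl@degenerate)

  ## 2D input falls back to an area with a warning
  sq <- Trajectory(cbind(x = c(0, 2, 2, 0), y = c(0, 0, 2, 2)), 0:3)
  expect_warning(sv2 <- scannedVolume(sq), "area")
  expect_equal(sv2@value, 4)
  expect_identical(sv2@dims, "2D")
})

test_that("scanned volume is monotone in the window length", {
  tr <- simulateFBMTrajectory(1, 1e-2, dt = 1, nFrames = 60, nDims = 3,
                              seed = 81)
  vols <- vapply(c(10, 20, 40, 59), function(w)
    scannedVolume(tr, window = w)@value, numeric(1))
  expect_true(all(diff(vols) >= 0))
})

test_that("slower anomalous motion scans smaller territories", {
  ## Brownian vs FBM(alpha = 0.5) at equal generalized coefficient
  volFor <- function(alpha, seedBase) {
    mean(vapply(1:40, function(i)
      scannedVolume(simulateFBMTrajectory(alpha, 1e-3, dt = 18.5,
                                          nFrames = 49, nDims = 3,
                                          seed = seedBase + i))@value,
      numeric(1)))
  }
  expect_gt(volFor(1, 9000), volFor(0.5, 9500))
})

test_that("hull classification separates a centre locus from corner loci", {
  corners <- as.matrix(expand.grid(x = c(0, 4), y = c(0, 4), z = c(0, 4)))
  pts <- rbind(corners, c(2, 2, 2))
  nF <- 6
  ens <- LocusEnsemble(x = matrix(pts[, 1], 9, nF), y = matrix(pts[, 2], 9, nF),
                       z = matrix(pts[, 3], 9, nF), timeS = 0:(nF - 1),
                       locusIds = c(paste0("corner_", 1:8), "centre"))
  cl <- classifyInternalPeripheral(ens)
  expect_identical(cl@internalFinal, "centre")
  expect_setequal(cl@peripheralFinal, paste0("corner_", 1:8))
  expect_identical(unname(cl@nFramesOnHull["centre"]), 0L)
  expect_true(all(cl@nFramesOnHull[paste0("corner_", 1:8)] == nF))
})

test_that("touching the hull in a single frame excludes a locus for good", {
  corners <- as.matrix(expand.grid(x = c(0, 4), y = c(0, 4), z = c(0, 4)))
  nF <- 5
  xc <- matrix(2, 1, nF); yc <- matrix(2, 1, nF); zc <- matrix(2, 1, nF)
  zc[1, 3] <- 4.5          # pokes through the top face in frame 3 only
  ens <- LocusEnsemble(x = rbind(matrix(corners[, 1], 8, nF), xc),
                       y = rbind(matrix(corners[, 2], 8, nF), yc),
                       z = rbind(matrix(corners[, 3], 8, nF), zc),
                       timeS = 0:(nF - 1),
                       locusIds = c(paste0("c", 1:8), "wanderer"))
  cl <- classifyInternalPeripheral(ens)
  expect_false("wanderer" %in% cl@internalFinal)
  expect_identical(unname(cl@nFramesOnHull["wanderer"]), 1L)
})

test_that("classification equals the brute-force supporting-plane oracle", {
  p <- PopulationPreset(alphaMean = 0.7, alphaSd = 0.1, dAlpha = 5e-3,
                        nLoci = 50, nFrames = 20, dt = 1, rho = 0,
                        nucleusRadii = c(4, 3, 2), seed = 91)
  ens <- simulatePopulation(p)$ensemble
  arr <- ensArray(ens)
  cl <- classifyInternalPeripheral(ens)
  ids <- locusIds(ens)
  for (t in seq_len(nFrames(ens))) {
    oracle <- sort(ids[bruteHullSurface3D(matrix(arr[, t, ], 50, 3))])
    expect_identical(sort(cl@peripheralByFrame[[t]]), oracle)
  }
  ## no final-internal locus ever sits on a frame hull
  expect_true(all(cl@nFramesOnHull[cl@internalFinal] == 0L))
})

test_that("hull quantities are invariant under rotation and translation", {
  p <- PopulationPreset(nLoci = 30, nFrames = 10, dAlpha = 5e-3, dt = 1,
                        rho = 0, seed = 95)
  ens <- simulatePopulation(p)$ensemble
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  arr <- ensArray(ens)
  rot <- arr
  for (t in seq_len(dim(arr)[2]))
    rot[, t, ] <- matrix(arr[, t, ], 30, 3) %*% t(R) +
      rep(c(5, -3, 2), each = 30)
  ens2 <- LocusEnsemble(x = rot[, , 1], y = rot[, , 2], z = rot[, , 3],
                        timeS = frameTimes(ens), locusIds = locusIds(ens))
  cl1 <- classifyInternalPeripheral(ens)
  cl2 <- classifyInternalPeripheral(ens2)
  expect_identical(cl1@internalFinal, cl2@internalFinal)
  v1 <- scannedVolumes(ens)$value
  v2 <- scannedVolumes(ens2)$value
  expect_equal(v1, v2, tolerance = 1e-9)
})

test_that("classification refuses fewer than 5 loci", {
  ens <- staticEnsemble(nLoci = 4, nFrames = 5, seed = 97)
  expect_error(classifyInternalPeripheral(ens), ">= 5 loci")
})
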