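test_that("FBM ensemble MSD follows the generalized diffusion law", {
  ## alpha = 1 degenerates to Brownian motion: total MSD at tau = 10 s must
  ## equal dAlpha * 10 (Monte Carlo against the closed form)
  dA <- 2.8e-4
  set.seed(101)
  sq <- vapply(seq_len(10000), function(i) {
    tr <- simulateFBMTrajectory(1, dA, dt = 1, nFrames = 11, nDims = 2)
    sum(coords(tr)[11, ]^2)
  }, numeric(1))
  expect_lt(abs(mean(sq) / (dA * 10) - 1), 0.02)

  ## anomalous case at the Fig-1b-style working point: MSD(100 s) for
  ## alpha = 0.5 equals dAlpha * 10 (2.8e-3 um^2) within sampling error
  set.seed(102)
  sq2 <- vapply(seq_len(400), function(i) {
    tr <- simulateFBMTrajectory(0.5, dA, dt = 1, nFrames = 101, nDims = 2)
    sum(coords(tr)[101, ]^2)
  }, numeric(1))
  mc <- mean(sq2)
  se <- sd(sq2) / sqrt(length(sq2))
  expect_lt(abs(mc - dA * 100^0.5), 3 * se)
})

test_that("FBM increments have the exact fractional Gaussian covariance", {
  alpha <- 0.7; H <- alpha / 2
  dA <- 1e-3; dt <- 1
  nInc <- 20
  set.seed(103)
  incs <- vapply(seq_len(4000), function(i) {
    diff(coords(simulateFBMTrajectory(alpha, dA, dt, nInc + 1, nDims = 2))[, 1])
  }, numeric(nInc))          # nInc x reps
  sig2 <- (dA / 2) * dt^alpha     # per-axis increment variance
  for (k in 0:3) {
    gk <- sig2 * 0.5 * (abs(k + 1)^(2 * H) - 2 * k^(2 * H) +
                          abs(k - 1)^(2 * H))
    prods <- incs[seq_len(nInc - k), , drop = FALSE] *
      incs[seq_len(nInc - k) + k, , drop = FALSE]
    emp <- mean(prods)
    se <- sd(as.numeric(prods)) / sqrt(length(prods))
    expect_lt(abs(emp - gk), 3.5 * se)
  }
})

test_that("degenerate and invalid FBM parameters are handled", {
  tr <- simulateFBMTrajectory(0.5, 0, dt = 1, nFrames = 20, seed = 1)
  expect_true(all(coords(tr) == 0))
  expect_error(simulateFBMTrajectory(0, 1e-3, 1, 10), "alpha")
  expect_error(simulateFBMTrajectory(2, 1e-3, 1, 10), "alpha")
  expect_error(simulateFBMTrajectory(1, 1e-3, 1, 1), "nFrames")
})

test_that("population generator honours its preset", {
  ## zero spread: every manifest alpha equals the mean
  p0 <- PopulationPreset(alphaMean = 0.6, alphaSd = 0, nLoci = 15,
                         nFrames = 20, seed = 5)
  sim0 <- simulatePopulation(p0)
  expect_equal(groundTruth(sim0$manifest)$alpha, rep(0.6, 15))

  ## imaging cadence: 100 frames at 18.5 s span 1831.5 s (~31 min)
  p1 <- PopulationPreset(nLoci = 12, nFrames = 100, dt = 18.5, seed = 6)
  sim1 <- simulatePopulation(p1)
  expect_equal(max(frameTimes(sim1$ensemble)), 1831.5)

  ## static loci with noise: per-locus TAMSD flat at the 2*d*rho^2 floor
  p2 <- PopulationPreset(alphaMean = 0.5, dAlpha = 0, rho = 0.02,
                         nLoci = 60, nFrames = 60, dt = 1, seed = 7)
  sim2 <- simulatePopulation(p2)
  curves <- ensembleMSD(sim2$ensemble, dims = "xy")
  M <- do.call(rbind, lapply(curves, function(cv) msdValues(cv)$msd))
  floorVal <- 2 * 2 * 0.02^2
  expect_lt(abs(mean(M) / floorVal - 1), 0.05)
  ## flat: each lag's ensemble mean stays near the floor
  expect_true(all(abs(colMeans(M) / floorVal - 1) < 0.15))
  ## and matches the brute-force TAMSD of the same static trajectories
  tr1 <- getTrajectory(sim2$ensemble, 1)
  expect_equal(msdValues(timeAveragedMSD(tr1))$msd,
               naiveTAMSD(coords(tr1)[, 1:2], 15))

  ## determinism under a fixed master seed
  simA <- simulatePopulation(p2)
  expect_identical(ensArray(simA$ensemble), ensArray(sim2$ensemble))
})

test_that("ground-truth manifest round-trips losslessly", {
  p <- PopulationPreset(alphaMean = 0.75, alphaSd = 0.12, nLoci = 10,
                        nFrames = 15, driftAmplitude = 0.03,
                        rotationRate = 0.01, seed = 11)
  sim <- simulatePopulation(p)
  dir <- file.path(tempdir(), "manifest_rt")
  writeManifest(sim$manifest, dir)
  back <- readManifest(dir)
  expect_identical(back@perLocus$alpha, sim$manifest@perLocus$alpha)
  expect_identical(back@perLocus$locus_id, sim$manifest@perLocus$locus_id)
  expect_identical(back@driftPath, sim$manifest@driftPath)
  expect_identical(back@rotationPath, sim$manifest@rotationPath)
  expect_identical(back@presetId, sim$manifest@presetId)
})

test_that("CP solver reproduces closed-form limiting behaviour", {
  ## no bleaching: constant intensity
  pc <- CPModelParams(bleachRate = 0, duration = 5, sampleDt = 0.01)
  tr <- solveCPModel(pc)
  expect_lt(diff(range(tr@intensity)), 1e-6 * 100)

  ## bound-only, no exchange, near-flat PSF: exact exponential decay
  pe <- CPModelParams(boundFraction0 = 1, kOn = 0, kOff = 0, bleachRate = 1,
                      psfWidth = 100, duration = 5, sampleDt = 0.01)
  tre <- solveCPModel(pe, rMax = 1, detectionPsfPower = 1)
  expect_lt(max(abs(tre@intensity / 100 - exp(-tre@timeS))), 1e-4)
})

test_that("simulated CP traces decompose into the expected components", {
  ## all-free limit: no resolvable exponential, free fraction 1
  pf <- CPModelParams(boundFraction0 = 0, kOn = 0, kOff = 0, bleachRate = 2,
                      duration = 60, sampleDt = 2e-3)
  ff <- suppressWarnings(fitCP(solveCPModel(pf), onset = 0))
  expect_true(ff@degenerate)
  expect_equal(freeFraction(ff), 1)

  ## all-bound limit, replenishment off: decays to ~0, free fraction ~0
  pb <- CPModelParams(boundFraction0 = 1, kOn = 0, kOff = 0, bleachRate = 2,
                      duration = 60, sampleDt = 2e-3)
  trb <- solveCPModel(pb)
  expect_lt(tail(trb@intensity, 1), 2)
  fb <- suppressWarnings(fitCP(trb, onset = 0))
  expect_lt(freeFraction(fb), 0.05)

  ## slow exchange: fitted free fraction matches the generating one
  ps <- CPModelParams(boundFraction0 = 0.37, kOn = 0.005, kOff = 0.005,
                      bleachRate = 2, duration = 60, sampleDt = 2e-3)
  fs <- suppressWarnings(fitCP(solveCPModel(ps), onset = 0))
  expect_lt(abs(freeFraction(fs) - 0.63), 0.02)
})
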