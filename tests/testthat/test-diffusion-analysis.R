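test_that("time-averaged MSD matches hand evaluation and the naive oracle", {
  tr <- Trajectory(cbind(x = c(0, 1, 1), y = c(0, 0, 1)), 0:2)
  cv <- timeAveragedMSD(tr, maxLagFraction = 1)
  expect_equal(msdValues(cv)$msd, c(1, 2))
  expect_equal(msdValues(cv)$tau, c(1, 2))
  expect_equal(msdValues(cv)$nPairs, c(2L, 1L))

  ## static trajectory
  st <- Trajectory(cbind(x = rep(2, 10), y = rep(-1, 10)), 0:9)
  expect_true(all(msdValues(timeAveragedMSD(st))$msd == 0))

  ## exact equality with the double-loop oracle on a 200-frame trajectory
  tr2 <- simulateFBMTrajectory(0.8, 1e-3, dt = 2, nFrames = 200, nDims = 3,
                               seed = 21)
  cv2 <- timeAveragedMSD(tr2, dims = "xyz")
  expect_equal(msdValues(cv2)$msd, naiveTAMSD(coords(tr2), 50))
  cv2xy <- timeAveragedMSD(tr2, dims = "xy")
  expect_equal(msdValues(cv2xy)$msd, naiveTAMSD(coords(tr2)[, 1:2], 50))

  expect_error(timeAveragedMSD(Trajectory(cbind(x = 0, y = 0), 0)),
               "2 frames")
})

test_that("MSD/tau turns power laws into the expected log-log slopes", {
  tau <- 1:50
  mk <- function(msd) new("MSDCurve", tau = as.numeric(tau), msd = msd,
                          nPairs = rep(1L, 50), locusId = "c", dims = "xy")
  slope <- function(cv) {
    v <- msdValues(cv)
    unname(coef(lm(log(v$msd) ~ log(v$tau)))[2])
  }
  expect_equal(msdValues(msdOverTau(mk(2 * tau)))$msd, rep(2, 50))
  expect_equal(slope(msdOverTau(mk(tau^0.5))), -0.5, tolerance = 1e-12)
  expect_equal(slope(msdOverTau(mk(tau^1.3))), 0.3, tolerance = 1e-12)
})

test_that("power-law fit recovers exact parameters and handles noise floors", {
  tau <- seq(1, 100, by = 1)
  cv <- new("MSDCurve", tau = tau, msd = 3 * tau^0.7,
            nPairs = rep(1L, 100), locusId = "c", dims = "xy")
  f <- fitPowerLaw(cv)
  expect_equal(f@alpha, 0.7, tolerance = 1e-12)
  expect_equal(f@dAlpha, 3, tolerance = 1e-12)

  ## static-locus curve minus its own offset is degenerate
  flat <- new("MSDCurve", tau = tau, msd = rep(2 * 2 * 0.02^2, 100),
              nPairs = rep(1L, 100), locusId = "s", dims = "xy")
  expect_error(suppressWarnings(fitPowerLaw(flat,
                                            noiseOffset = 2 * 2 * 0.02^2)))

  ## with a noise floor the uncorrected fit is biased low at short lags,
  ## the offset-corrected fit is not
  rho <- 0.02
  msdTrue <- 1e-3 * tau
  meas <- msdTrue + 2 * 2 * rho^2
  cvN <- new("MSDCurve", tau = tau, msd = meas, nPairs = rep(1L, 100),
             locusId = "n", dims = "xy")
  fRaw <- fitPowerLaw(cvN, window = c(1, 20))
  fCor <- fitPowerLaw(cvN, window = c(1, 20), noiseOffset = 2 * 2 * rho^2)
  expect_lt(fRaw@alpha, 0.9)
  expect_equal(fCor@alpha, 1, tolerance = 1e-9)

  expect_error(fitPowerLaw(cvN, window = c(1, 3)), "4 lag points")
})

test_that("static precision is recovered by both estimation routes", {
  p <- PopulationPreset(alphaMean = 0.5, dAlpha = 0, rho = 0.02, nLoci = 80,
                        nFrames = 50, dt = 1, seed = 31)
  ens <- simulatePopulation(p)$ensemble
  sp1 <- measureStaticPrecision(ens, method = "positions")
  sp2 <- measureStaticPrecision(ens, method = "msd")
  expect_equal(rho(sp1), 0.02, tolerance = 0.05)
  expect_equal(rho(sp2), 0.02, tolerance = 0.05)
  ## the two routes agree within 5%
  expect_lt(abs(rho(sp1) - rho(sp2)) / rho(sp1), 0.05)

  ## zero-noise static loci give rho = 0
  p0 <- PopulationPreset(alphaMean = 0.5, dAlpha = 0, rho = 0, nLoci = 10,
                         nFrames = 20, dt = 1, seed = 32)
  expect_equal(rho(measureStaticPrecision(simulatePopulation(p0)$ensemble)),
               0)
})

test_that("MLSD estimate is exact in the zero-spread limit", {
  ## lags well below the trajectory length keep the finite-trajectory
  ## fluctuations of the single-locus TAMSDs from mimicking exponent spread
  p <- PopulationPreset(alphaMean = 0.5, alphaSd = 0, dAlpha = 5e-4,
                        nLoci = 200, nFrames = 400, dt = 1, rho = 0,
                        seed = 41)
  sim <- simulatePopulation(p)
  est <- mlsdEnsembleEstimate(ensembleMSD(sim$ensemble, dims = "xy",
                                          maxLag = 25),
                              rho = 0)
  expect_equal(est@alphaMsd, 0.5, tolerance = 0.03)
  expect_equal(est@alphaMlsd, 0.5, tolerance = 0.03)
  expect_lt(alphaSd(est), 0.07)       # epsilon ~ 0 without exponent spread
  expect_identical(est@alphaMean, est@alphaMlsd)
})

test_that("MLSD recovers the exponent distribution of mixed populations", {
  for (cfg in list(c(0.6, 0.15), c(0.75, 0.1), c(1.0, 0.2))) {
    p <- PopulationPreset(alphaMean = cfg[1], alphaSd = cfg[2],
                          dAlpha = 5e-4, nLoci = 300, nFrames = 100,
                          dt = 18.5, rho = 0, seed = 50 + round(10 * cfg[1]))
    sim <- simulatePopulation(p)
    gt <- groundTruth(sim$manifest)
    est <- mlsdEnsembleEstimate(ensembleMSD(sim$ensemble, dims = "xy"),
                                rho = 0)
    expect_lt(abs(alphaMean(est) - mean(gt$alpha)), 0.05)
    expect_lt(abs(alphaSd(est) - sd(gt$alpha)), 0.05)
    ## exponent spread makes the arithmetic-mean exponent exceed the MLSD one
    expect_gt(est@alphaMsd, est@alphaMlsd - 0.02)
  }
})

test_that("noise offset keeps the MLSD mean exponent unbiased", {
  p <- PopulationPreset(alphaMean = 1, alphaSd = 0.2, dAlpha = 1e-3,
                        nLoci = 250, nFrames = 100, dt = 18.5, rho = 0.02,
                        seed = 61)
  sim <- simulatePopulation(p)
  curves <- ensembleMSD(sim$ensemble, dims = "xy")
  gt <- groundTruth(sim$manifest)
  withOffset <- mlsdEnsembleEstimate(curves, rho = 0.02, window = c(7, Inf))
  expect_lt(abs(alphaMean(withOffset) - mean(gt$alpha)), 0.05)
})

test_that("diffusion classification follows the confidence interval rule", {
  mk <- function(am, av, n) new("EnsembleDiffusionEstimate",
    alphaMsd = am, alphaMlsd = am, alphaMean = am, alphaVar = av,
    dAlpha = 1e-3, rho = 0, nLoci = as.integer(n), window = c(1, 100),
    curves = list())
  expect_identical(classifyDiffusion(mk(0.5, 0.01, 300)), "subdiffusive")
  expect_identical(classifyDiffusion(mk(1.0, 0.04, 300)), "normal")
  expect_identical(classifyDiffusion(mk(1.3, 0.01, 300)), "superdiffusive")
  ## wide interval straddling 1 reads as normal
  expect_identical(classifyDiffusion(mk(0.98, 0.5, 20)), "normal")
})

test_that("MLSD input contracts are enforced", {
  cvs <- ensembleMSD(simulatePopulation(
    PopulationPreset(nLoci = 25, nFrames = 40, dt = 1, seed = 71))$ensemble)
  expect_error(mlsdEnsembleEstimate(cvs[1:5]), ">= 20")
  short <- cvs
  short[[1]] <- new("MSDCurve", tau = msdValues(cvs[[1]])$tau[1:5],
                    msd = msdValues(cvs[[1]])$msd[1:5],
                    nPairs = rep(1L, 5), locusId = "x", dims = "xy")
  expect_error(mlsdEnsembleEstimate(short), "common lag grid")
})
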