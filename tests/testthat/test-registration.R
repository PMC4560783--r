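test_that("pure translation is recovered as a COM path with zero rotation", {
  ens <- staticEnsemble(nLoci = 10, nFrames = 15, rho = 0, seed = 2)
  drift <- cbind(seq(0, 1.4, length.out = 15),
                 seq(0, 2.8, length.out = 15),
                 rep(0, 15))
  moved <- applyRigidMotion(ens, drift = drift)
  m <- estimateRigidMotion(moved)
  base <- estimateRigidMotion(ens)
  expect_equal(m@com[, 1] - base@com[1, 1], drift[, 1], tolerance = 1e-9)
  expect_equal(m@com[, 2] - base@com[1, 2], drift[, 2], tolerance = 1e-9)
  expect_equal(m@angle, rep(0, 15), tolerance = 1e-9)
})

test_that("rigid rotation about the COM is recovered frame by frame", {
  ens <- staticEnsemble(nLoci = 12, nFrames = 20, rho = 0, seed = 3)
  theta <- 0.1 * (0:19)
  rot <- applyRigidMotion(ens, theta = theta)
  m <- estimateRigidMotion(rot)
  expect_equal(m@angle, theta, tolerance = 1e-6)
})

test_that("correction removes rigid motion and is idempotent", {
  ens <- staticEnsemble(nLoci = 15, nFrames = 20, rho = 0, seed = 4)
  drift <- cbind(cumsum(rnorm(20, 0, 0.1)), cumsum(rnorm(20, 0, 0.1)),
                 rep(0, 20))
  drift[1, ] <- 0
  moved <- applyRigidMotion(ens, drift = drift, theta = 0.05 * (0:19))
  corr <- correctEnsemble(moved)
  ## rigidly moving static loci become constant: all TAMSDs are 0
  curves <- ensembleMSD(corr, dims = "xy", maxLagFraction = 0.5)
  expect_lt(max(vapply(curves, function(cv) max(msdValues(cv)$msd),
                       numeric(1))), 1e-18)
  ## COM at the origin in every frame
  m2 <- estimateRigidMotion(corr)
  expect_lt(max(abs(m2@com)), 1e-12)
  expect_lt(max(abs(m2@angle)), 1e-9)
  ## idempotence
  corr2 <- correctEnsemble(corr)
  expect_lt(max(abs(ensArray(corr2) - ensArray(corr))), 1e-9)
})

test_that("correction commutes with a global translation of the input", {
  sim <- simulatePopulation(PopulationPreset(nLoci = 10, nFrames = 15,
                                             seed = 8))
  ens <- sim$ensemble
  shifted <- applyRigidMotion(ens, drift = matrix(rep(c(3, -2, 1),
                                                      each = 15), 15, 3))
  expect_equal(ensArray(correctEnsemble(shifted)),
               ensArray(correctEnsemble(ens)), tolerance = 1e-9)
})

test_that("injected drift and rotation are recovered below the noise floor", {
  rho <- 0.02
  nL <- 60; nF <- 40
  ens <- staticEnsemble(nLoci = nL, nFrames = nF, rho = 0, seed = 5)
  set.seed(55)
  drift <- cbind(cumsum(rnorm(nF, 0, 0.05)), cumsum(rnorm(nF, 0, 0.05)),
                 cumsum(rnorm(nF, 0, 0.02)))
  drift <- sweep(drift, 2, drift[1, ])
  theta <- cumsum(c(0, rnorm(nF - 1, 0, 0.01)))
  moved <- applyRigidMotion(ens, drift = drift, theta = theta)
  noisy <- LocusEnsemble(
    x = SummarizedExperiment::assay(moved, "x") + rnorm(nL * nF, 0, rho),
    y = SummarizedExperiment::assay(moved, "y") + rnorm(nL * nF, 0, rho),
    z = SummarizedExperiment::assay(moved, "z") + rnorm(nL * nF, 0, rho),
    timeS = frameTimes(moved))
  m <- estimateRigidMotion(noisy)
  base <- estimateRigidMotion(ens)
  comErr <- m@com[, 1:2] - drift[, 1:2] -
    rep(base@com[1, 1:2], each = nF)
  expect_lt(sqrt(mean(comErr^2)), rho)          # RMSE below noise floor
  expect_lt(sqrt(mean((m@angle - theta)^2)), 0.01)
})

test_that("fewer than 3 loci yields a COM-only estimate with a warning", {
  ens <- staticEnsemble(nLoci = 2, nFrames = 10, rho = 0, seed = 6)
  expect_warning(m <- estimateRigidMotion(ens), "fewer than 3 loci")
  expect_false(m@rotationReliable)
  expect_equal(m@angle, rep(0, 10))
  ## collinear configurations flag the rotation as unreliable
  line <- LocusEnsemble(x = matrix(rep(1:5, 8), 5, 8),
                        y = matrix(rep(2 * (1:5), 8), 5, 8),
                        timeS = 0:7)
  expect_warning(m2 <- estimateRigidMotion(line), "collinear")
  expect_false(m2@rotationReliable)
})

test_that("a sparse locus is corrected by co-observed reference loci", {
  ref <- staticEnsemble(nLoci = 10, nFrames = 12, rho = 0, seed = 7)
  theta <- 0.08 * (0:11)
  rotRef <- applyRigidMotion(ref, theta = theta)
  ## a static target inside the rotating nucleus traces the rotation;
  ## correction must recover its true (constant) relative position
  target0 <- getTrajectory(rotRef, 3)
  corrected <- correctByReference(
    Trajectory(coords(target0), frameTimes(target0), "gene_locus"),
    rotRef)
  expect_lt(max(apply(coords(corrected), 2, function(v) diff(range(v)))),
            1e-9)

  ## a duplicated reference locus is excluded from the fit yet ends up
  ## identical to that locus's own corrected form
  dup <- Trajectory(coords(getTrajectory(rotRef, 5)),
                    frameTimes(rotRef), locusIds(rotRef)[5])
  corrDup <- correctByReference(dup, rotRef)
  refMinus <- rotRef[-5, ]
  ## apply the same reference-only motion to the full ensemble's locus 5
  m <- estimateRigidMotion(refMinus)
  corrEns5 <- correctEnsemble(rotRef, m)
  expect_equal(coords(corrDup),
               coords(getTrajectory(corrEns5, 5)), tolerance = 1e-12)

  ## frame-grid mismatch is a contract error
  short <- Trajectory(coords(dup)[1:6, ], frameTimes(rotRef)[1:6], "x")
  expect_error(correctByReference(short, rotRef), "frame grid")
})
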