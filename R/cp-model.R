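## Two-population continuous-photobleaching model.
##
## A bound (immobile) pool C_b(r,t) and a freely diffusing pool C_f(r,t)
## under constant confocal illumination with Gaussian excitation profile
## PSF(r) = exp(-r^2 / (2 w^2)):
##
##   dC_f/dt = D Lap C_f - k_on C_f + k_off C_b - k_bleach PSF(r) C_f
##   dC_b/dt =            k_on C_f - k_off C_b  - k_bleach PSF(r) C_b
##
## solved by finite volumes on a spherically symmetric radial grid with
## zero-flux boundaries (the nucleus is a closed reservoir; replenishment of
## the spot is by diffusion from the unbleached outskirts). The detected
## intensity is the detection-profile-weighted count of unbleached
## fluorophores; the detection profile of the small-pinhole point
## measurement is narrower than the bleaching beam (see solveCPModel's
## detectionPsfPower).

.cpGrid <- function(psfWidth, rMax = NULL, nr = 120L) {
  if (is.null(rMax)) rMax <- max(15 * psfWidth, 3)
  edges <- seq(0, rMax, length.out = nr + 1L)
  mid <- (edges[-1] + edges[-(nr + 1L)]) / 2
  shellVol <- 4 / 3 * pi * (edges[-1]^3 - edges[-(nr + 1L)]^3)
  faceArea <- 4 * pi * edges^2            # at edges, first/last give 0 flux
  list(nr = nr, dr = edges[2] - edges[1], mid = mid, shellVol = shellVol,
       faceArea = faceArea)
}

## States are interleaved (cf_1, cb_1, cf_2, cb_2, ...) so the Jacobian is
## banded (half-bandwidth 2), which lets lsoda avoid dense-Jacobian cost.
.cpRhs <- function(t, y, parms) {
  nr <- parms$nr
  cf <- y[parms$iF]
  cb <- y[parms$iB]
  ## diffusive fluxes across interior faces (zero at r = 0 and r = rMax)
  grad <- diff(cf) / parms$dr
  flux <- parms$D * parms$faceArea[2:nr] * grad
  divr <- (c(flux, 0) - c(0, flux)) / parms$shellVol
  bleach <- parms$kb * parms$psf
  dy <- numeric(2L * nr)
  dy[parms$iF] <- divr - parms$kon * cf + parms$koff * cb - bleach * cf
  dy[parms$iB] <- parms$kon * cf - parms$koff * cb - bleach * cb
  list(dy)
}

#' Numerically solve the two-population photobleaching model
#'
#' Integrates the coupled bound/free reaction-diffusion-bleaching equations
#' on a radial grid and returns the noiseless detected-intensity trace. This
#' solver is the reference model behind [simulateCPTrace()] and the oracle
#' against which the simplified exponential-plus-linear analysis of
#' [fitCP()] is validated.
#'
#' @param params a [CPModelParams-class]. The noise and pre-trigger fields
#'   are ignored here (the solver is deterministic and starts at laser-on).
#' @param nr number of radial grid shells.
#' @param rMax domain radius, um. The default (5 um) is nucleus-sized: the
#'   free pool is a large but finite reservoir whose slow depletion produces
#'   the near-linear long-time decay.
#' @param detectionPsfPower the detected signal is weighted by
#'   PSF(r)^detectionPsfPower, while bleaching goes with the excitation
#'   profile PSF(r) alone. The default 4 models a small-pinhole confocal
#'   point measurement whose detection profile is substantially narrower
#'   than the bleaching beam (detection s.d. half the excitation s.d.);
#'   2 would be the plain excitation-times-detection product with equal
#'   widths.
#' @return A [CPTrace-class] sampled at \code{sampleDt}, scaled so
#'   I(0) = \code{amplitude}.
#' @examples
#' tr <- solveCPModel(CPModelParams(boundFraction0 = 0.4, duration = 10,
#'                                  sampleDt = 0.01))
#' @export
solveCPModel <- function(params, nr = 200L, rMax = 5,
                         detectionPsfPower = 4) {
  stopifnot(is(params, "CPModelParams"))
  validObject(params)
  g <- .cpGrid(params@psfWidth, rMax, nr)
  psf <- exp(-g$mid^2 / (2 * params@psfWidth^2))
  iF <- seq(1L, 2L * g$nr, by = 2L)
  parms <- list(nr = g$nr, dr = g$dr, shellVol = g$shellVol,
                faceArea = g$faceArea, psf = psf, D = params@freeDiffusionD,
                kon = params@kOn, koff = params@kOff, kb = params@bleachRate,
                iF = iF, iB = iF + 1L)
  y0 <- numeric(2L * g$nr)
  y0[parms$iF] <- 1 - params@boundFraction0
  y0[parms$iB] <- params@boundFraction0
  ## integrate on a coarse grid (the deterministic trace is smooth), then
  ## interpolate to the requested sampling
  dtSolve <- max(params@sampleDt, min(0.05, params@duration / 200))
  tSolve <- unique(c(seq(0, params@duration, by = dtSolve), params@duration))
  sol <- deSolve::ode(y = y0, times = tSolve, func = .cpRhs, parms = parms,
                      method = "lsoda", jactype = "bandint", bandup = 2L,
                      banddown = 2L, rtol = 1e-8, atol = 1e-10)
  if (attr(sol, "istate")[1] < 0)
    stop("CP model integration failed to converge; ",
         "try a finer grid or smaller rates (istate = ",
         attr(sol, "istate")[1], ")")
  w <- psf^detectionPsfPower * g$shellVol
  conc <- sol[, -1, drop = FALSE]
  intens <- conc[, parms$iF, drop = FALSE] %*% w +
    conc[, parms$iB, drop = FALSE] %*% w
  tOut <- seq(0, params@duration, by = params@sampleDt)
  iOut <- spline(tSolve, as.numeric(intens), xout = tOut)$y
  iOut <- pmax(iOut, 0)
  CPTrace(tOut, iOut / iOut[1] * params@amplitude)
}

#' Simulate a continuous-photobleaching trace
#'
#' Generates a measured-looking CP trace from the numeric two-population
#' model: an optional dark pre-trigger baseline, the deterministic
#' model trace from laser-on, and additive Gaussian detection noise
#' (clamped at zero intensity). In the slow-exchange regime
#' (kOn, kOff much smaller than bleachRate) the noiseless trace is well
#' described by I(t) = a exp(-b t) + c t + d with free fraction d/(a+d)
#' equal to 1 - boundFraction0.
#'
#' @param params a [CPModelParams-class]; \code{preTriggerS} seconds of
#'   near-zero baseline are prepended and noise of s.d. \code{noiseSd} added.
#' @param ... forwarded to [solveCPModel()].
#' @return A [CPTrace-class].
#' @export
simulateCPTrace <- function(params, ...) {
  stopifnot(is(params, "CPModelParams"))
  det <- solveCPModel(params, ...)
  nPre <- round(params@preTriggerS / params@sampleDt)
  intens <- c(rep(0, nPre), det@intensity)
  timeS <- (seq_along(intens) - 1) * params@sampleDt
  if (params@noiseSd > 0) {
    set.seed(params@seed)
    intens <- intens + rnorm(length(intens), 0, params@noiseSd)
  }
  CPTrace(timeS, pmax(intens, 0))
}
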