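## End-to-end orchestration over synthetic presets or ingested data, and
## condition comparison.

#' Run the full analysis pipeline
#'
#' For each condition, either simulates a population from its
#' [PopulationPreset-class] or ingests a trajectory CSV, then: corrects
#' rigid nuclear motion, computes per-locus time-averaged MSDs, runs the
#' MLSD ensemble estimate, classifies the diffusion, fits per-locus power
#' laws (population comparison only, not absolute values), and quantifies
#' scanned territories and internal/peripheral classes. Optionally analyses
#' continuous-photobleaching traces. Deterministic given the seeds in the
#' presets/params.
#'
#' @param conditions named list; each element is either a
#'   [PopulationPreset-class] or a path to a canonical trajectory CSV.
#' @param window MLSD fit window \code{c(tau_min, tau_max)} in s, or NULL.
#' @param rho per-axis localization s.d. in um used for the noise offset
#'   (a preset's own rho is used for its condition when \code{rho = NULL}).
#' @param dims "xy" or "xyz" for the MSD analysis.
#' @param scanWindow window (s) for scanned volumes, or NULL for full length.
#' @param cpParams optional list of [CPModelParams-class] (or paths to CP
#'   trace CSVs) to analyse.
#' @param outDir optional directory: per-locus tables, summaries, the
#'   resolved configuration and log-log MSD/tau plots are written there.
#' @return list with one report per condition (ensemble estimate,
#'   classification, per-locus table, scanned volumes, hull classification,
#'   manifest when simulated) plus an optional \code{cp} summary.
#' @export
runPipeline <- function(conditions, window = NULL, rho = NULL, dims = "xy",
                        scanWindow = NULL, cpParams = NULL, outDir = NULL) {
  stopifnot(is.list(conditions), length(conditions) >= 1L)
  if (is.null(names(conditions)))
    names(conditions) <- paste0("condition_", seq_along(conditions))
  for (nm in names(conditions)) {
    x <- conditions[[nm]]
    if (is.character(x) && !file.exists(x))
      stop("input file for condition '", nm, "' not found: ", x)
  }
  if (!is.null(outDir)) dir.create(outDir, showWarnings = FALSE,
                                   recursive = TRUE)
  reports <- list()
  for (nm in names(conditions)) {
    x <- conditions[[nm]]
    manifest <- NULL
    if (is(x, "PopulationPreset")) {
      sim <- simulatePopulation(x)
      ens <- sim$ensemble
      manifest <- sim$manifest
      condRho <- if (is.null(rho)) x@rho else rho
    } else {
      ensList <- readTrajectories(x, condition = nm)
      if (!length(ensList)) stop("no usable trajectories in ", x)
      ens <- ensList[[1]]
      condRho <- if (is.null(rho)) 0 else rho
    }
    corrected <- correctEnsemble(ens)
    curves <- ensembleMSD(corrected, dims = dims)
    est <- mlsdEnsembleEstimate(curves, rho = condRho, window = window)
    label <- classifyDiffusion(est)
    perLocus <- data.frame(
      locus_id = locusIds(corrected),
      alpha = vapply(curves, function(cv) {
        f <- tryCatch(fitPowerLaw(cv, window = window,
                                  noiseOffset = 2 * nchar(dims) * condRho^2),
                      error = function(e) NULL)
        if (is.null(f)) NA_real_ else f@alpha
      }, numeric(1)),
      row.names = NULL)
    vols <- scannedVolumes(corrected, window = scanWindow)
    hull <- if (nLoci(corrected) >= 5L)
      classifyInternalPeripheral(corrected) else NULL
    reports[[nm]] <- list(
      condition = nm, ensemble = corrected, estimate = est,
      classification = label, perLocus = perLocus, scannedVolumes = vols,
      hullClassification = hull, manifest = manifest)
    if (!is.null(outDir)) {
      write.table(perLocus, file.path(outDir, paste0(nm, "_per_locus.csv")),
                  sep = ",", row.names = FALSE, quote = FALSE)
      write.table(vols, file.path(outDir, paste0(nm, "_volumes.csv")),
                  sep = ",", row.names = FALSE, quote = FALSE)
      writeLines(c(
        sprintf("condition: %s", nm),
        sprintf("n_loci: %d", est@nLoci),
        sprintf("alpha_mean: %.6g", est@alphaMean),
        sprintf("alpha_sd: %.6g", sqrt(est@alphaVar)),
        sprintf("alpha_msd: %.6g", est@alphaMsd),
        sprintf("alpha_mlsd: %.6g", est@alphaMlsd),
        sprintf("d_alpha_um2_per_s_alpha: %.6g", est@dAlpha),
        sprintf("rho_um: %.6g", est@rho),
        sprintf("classification: %s", label),
        sprintf("alpha_mean_rounded: %.1f", est@alphaMean)),
        file.path(outDir, paste0(nm, "_summary.txt")))
      grDevices::png(file.path(outDir, paste0(nm, "_msd_over_tau.png")),
                     width = 600, height = 480)
      plotMSDOverTau(est, main = nm)
      grDevices::dev.off()
    }
  }
  cp <- NULL
  if (!is.null(cpParams)) {
    fits <- lapply(cpParams, function(p) {
      tr <- if (is.character(p)) readCPTrace(p) else simulateCPTrace(p)
      fitCP(tr)
    })
    cp <- summarizeCP(fits)
    if (!is.null(outDir)) {
      write.table(
        data.frame(trace = seq_along(fits),
                   free_fraction = cp$freeFractions),
        file.path(outDir, "cp_free_fractions.csv"), sep = ",",
        row.names = FALSE, quote = FALSE)
    }
  }
  out <- list(reports = reports, cp = cp)
  if (!is.null(outDir)) {
    cfg <- c(sprintf("window: %s",
                     if (is.null(window)) "all" else
                       paste(window, collapse = ":")),
             sprintf("rho: %s", if (is.null(rho)) "per-preset" else rho),
             sprintf("dims: %s", dims),
             vapply(names(conditions), function(nm) {
               x <- conditions[[nm]]
               if (is(x, "PopulationPreset"))
                 sprintf("condition %s: preset seed=%d", nm, x@seed)
               else sprintf("condition %s: file %s", nm, x)
             }, character(1)))
    writeLines(cfg, file.path(outDir, "run_config.txt"))
  }
  out
}

#' Compare per-locus exponent distributions between two conditions
#'
#' Two-sample t-test on the per-locus anomalous exponents of two pipeline
#' reports (or raw numeric vectors). Welch's unequal-variance test is the
#' default; the pooled-variance Student test is available.
#'
#' @param a,b pipeline condition reports (elements of
#'   \code{runPipeline()$reports}) or numeric vectors of per-locus alpha.
#' @param varEqual FALSE (Welch, default) or TRUE (Student).
#' @return data.frame with the group means, their difference and confidence
#'   interval, the t statistic, degrees of freedom and p-value.
#' @export
compareConditions <- function(a, b, varEqual = FALSE) {
  getAlpha <- function(x) {
    if (is.numeric(x)) x
    else if (is.list(x) && !is.null(x$perLocus)) x$perLocus$alpha
    else stop("inputs must be numeric vectors or pipeline condition reports")
  }
  av <- getAlpha(a); bv <- getAlpha(b)
  av <- av[is.finite(av)]; bv <- bv[is.finite(bv)]
  if (length(av) < 2L || length(bv) < 2L)
    stop("need >= 2 loci per condition")
  tt <- t.test(av, bv, var.equal = varEqual)
  data.frame(mean_a = mean(av), mean_b = mean(bv),
             difference = mean(av) - mean(bv),
             conf_low = tt$conf.int[1], conf_high = tt$conf.int[2],
             t = unname(tt$statistic), df = unname(tt$parameter),
             p_value = tt$p.value)
}

#' Log-log MSD/tau plot
#'
#' Plots the ensemble-mean and geometric-mean (average particle) MSD divided
#' by lag time on log-log axes; normal diffusion is horizontal, subdiffusion
#' slopes downwards with slope alpha - 1.
#'
#' @param est an [EnsembleDiffusionEstimate-class].
#' @param ... further arguments to [plot()].
#' @export
plotMSDOverTau <- function(est, ...) {
  stopifnot(is(est, "EnsembleDiffusionEstimate"))
  tau <- est@curves$tau
  graphics::plot(tau, est@curves$meanMsd / tau, log = "xy", type = "b",
                 pch = 15, xlab = expression(tau ~ "(s)"),
                 ylab = expression(MSD / tau ~ (mu * m^2 ~ s^-1)), ...)
  graphics::lines(tau, est@curves$mlsd / tau, type = "b", pch = 1,
                  col = "grey40")
  graphics::legend("bottomleft", legend = c("ensemble mean", "average particle"),
                   pch = c(15, 1), col = c("black", "grey40"), bty = "n")
}
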