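## Metropolis Monte Carlo sampling of periodic fluids. The sampler stands in
## for a molecular-dynamics engine: the distribution-matching loop only needs
## equilibrium configurations, and a nominal "sampling time" maps onto
## production sweeps through sweepsPerPs (default: 1 ps = 10 sweeps).

#' Sampler configuration
#'
#' @param nSweepsEquil Equilibration sweeps (one sweep = N single-molecule
#'   move attempts).
#' @param nSweepsProd Production sweeps.
#' @param sampleEvery Record a frame every this many production sweeps.
#' @param dTrans Initial maximum translation displacement, nm.
#' @param dRot Initial maximum rotation angle, degrees (water3 only).
#' @param cutoff Interaction cutoff, nm; capped at L/2 at run time.
#' @param tune Auto-tune move sizes toward ~40\% acceptance during
#'   equilibration (frozen for production).
#' @param seed Integer RNG seed.
#' @return A list of sampler settings.
#' @export
samplerConfig <- function(nSweepsEquil = 500L, nSweepsProd = 2500L,
                          sampleEvery = 5L, dTrans = 0.015, dRot = 15,
                          cutoff = 1.0, tune = TRUE, seed = 1L) {
  stopifnot(nSweepsEquil >= 0, nSweepsProd >= 1, sampleEvery >= 1,
            dTrans > 0, dRot > 0, cutoff > 0)
  list(nSweepsEquil = as.integer(nSweepsEquil),
       nSweepsProd = as.integer(nSweepsProd),
       sampleEvery = as.integer(sampleEvery),
       dTrans = dTrans, dRot = dRot, cutoff = cutoff,
       tune = isTRUE(tune), seed = as.integer(seed))
}

#' Nominal sampling time to production sweeps
#'
#' The adaptive-budget rule of the optimizer is expressed in nominal
#' picoseconds for MD-adapter compatibility; the internal sampler maps
#' 1 ps to \code{sweepsPerPs} production sweeps.
#'
#' @param ps Nominal sampling time, ps.
#' @param sweepsPerPs Sweeps per nominal picosecond (default 10).
#' @return Integer number of sweeps.
#' @export
psToSweeps <- function(ps, sweepsPerPs = 10) as.integer(round(ps * sweepsPerPs))

siteCharges <- function(params, speciesName) {
  if (speciesName == "water3") c(params@q, -params@q / 2, -params@q / 2) else 0
}

siteMasses <- function(speciesName, molarMass = NULL) {
  if (speciesName == "water3")
    c(dffitConstants$massO, dffitConstants$massH, dffitConstants$massH)
  else if (!is.null(molarMass)) molarMass else 39.948
}

#' Initialize a cubic simulation box on a perturbed lattice
#'
#' The edge length follows from the molecule count, mass density and molar
#' mass: \eqn{L = (n M / (\rho N_A))^{1/3}}. Molecules are placed on a simple
#' cubic lattice with a small random jitter (no overlaps closer than
#' 0.8 sigma); water molecules get random rigid orientations.
#'
#' @param n Number of molecules.
#' @param density Mass density in g/cm^3 (default interpretation), or the
#'   reduced number density \eqn{\rho^* = N\sigma^3/V} when
#'   \code{reduced = TRUE} (then \code{sigma} must be supplied).
#' @param speciesName \code{"lj"} or \code{"water3"}.
#' @param temperature Kelvin.
#' @param params \linkS4class{ForceFieldParams} (geometry for water3; sigma
#'   for the overlap check).
#' @param seed Integer seed for placement jitter and orientations.
#' @param molarMass Molar mass for \code{"lj"}, g/mol (default 39.948).
#' @param reduced Interpret \code{density} as reduced number density.
#' @param cutoff Cutoff the run will use; an error is raised if it exceeds
#'   L/2 (minimum-image validity).
#' @return List with \code{box} (a \linkS4class{SimulationBox}) and
#'   \code{coords} (site matrix, natoms x 3, nm).
#' @examples
#' b <- initializeBox(64, 0.9971, "water3", 298, tip3pParams(), seed = 1)
#' b$box
#' @export
initializeBox <- function(n, density, speciesName = c("lj", "water3"),
                          temperature = 298, params, seed = 1L,
                          molarMass = 39.948, reduced = FALSE,
                          cutoff = NULL) {
  speciesName <- match.arg(speciesName)
  stopifnot(n >= 1, density > 0)
  if (reduced) {
    if (missing(params)) stop("reduced density requires 'params' for sigma")
    L <- params@sigma * (n / density)^(1 / 3)
  } else {
    M <- if (speciesName == "water3") dffitConstants$massWater else molarMass
    vol_nm3 <- n * M / (density * dffitConstants$avogadro) * 1e21
    L <- vol_nm3^(1 / 3)
  }
  if (!is.null(cutoff) && cutoff > L / 2)
    stop(sprintf(paste0("cutoff %.3f nm exceeds L/2 = %.3f nm; use a smaller ",
                        "cutoff or more molecules"), cutoff, L / 2))
  box <- new("SimulationBox", L = L, n = as.integer(n),
             species = speciesName, temperature = as.numeric(temperature))

  if (exists(".Random.seed", envir = globalenv())) {
    oldSeed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", oldSeed, envir = globalenv()))
  }
  set.seed(seed)
  ncell <- ceiling(n^(1 / 3))
  spacing <- L / ncell
  idx <- seq_len(n)
  ijk <- arrayInd(idx, c(ncell, ncell, ncell)) - 1L
  jitterAmp <- max(0, min(0.05 * spacing, (spacing - 0.8 * params@sigma) / 2))
  centers <- (ijk + 0.5) * spacing +
    matrix(stats::runif(3 * n, -jitterAmp, jitterAmp), ncol = 3)
  centers <- centers %% L

  if (speciesName == "lj") {
    coords <- centers
  } else {
    geom <- buildSiteGeometry(params)@positions
    coords <- matrix(0, nrow = 3 * n, ncol = 3)
    for (k in seq_len(n)) {
      R <- randomRotationMatrix()
      local <- geom %*% t(R)
      coords[(3 * k - 2):(3 * k), ] <-
        sweep(local, 2, centers[k, ], "+")
    }
  }
  list(box = box, coords = coords)
}

randomRotationMatrix <- function() {
  ## uniform random rotation via QR of a Gaussian matrix
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Run Metropolis Monte Carlo sampling
#'
#' Canonical-ensemble sampling at the box temperature with single-molecule
#' translation (plus rigid rotation for water3) moves and Metropolis
#' acceptance \eqn{\min(1, e^{-\Delta U / k_B T})}. Both the Lennard-Jones
#' and Coulomb terms are truncated and shifted at the cutoff. Frames are
#' recorded every \code{sampleEvery} production sweeps. Fully reproducible
#' from the seed.
#'
#' @param box A \linkS4class{SimulationBox}.
#' @param coords Initial site matrix from \code{\link{initializeBox}}.
#' @param params A \linkS4class{ForceFieldParams}.
#' @param config A \code{\link{samplerConfig}}.
#' @return A \linkS4class{Trajectory}; \code{meta} carries acceptance rate,
#'   tuned move sizes and the maximum relative drift between the cached and
#'   recomputed total energy.
#' @export
runMetropolis <- function(box, coords, params, config = samplerConfig()) {
  cutoff <- min(config$cutoff, box@L / 2)
  m <- if (box@species == "water3") 3L else 1L
  res <- cpp_run_mc(coords, m, siteCharges(params, box@species),
                    params@sigma, params@epsilon,
                    siteMasses(box@species), box@L, box@temperature,
                    config$nSweepsEquil, config$nSweepsProd,
                    config$sampleEvery, config$dTrans, config$dRot,
                    cutoff, TRUE, config$seed, config$tune)
  if (is.finite(res$acceptanceRate) &&
      (res$acceptanceRate < 0.05 || res$acceptanceRate > 0.95))
    warning(sprintf("production acceptance rate %.3f outside [0.05, 0.95]",
                    res$acceptanceRate))
  new("Trajectory", coords = res$frames, box = box,
      samplingSweeps = as.numeric(config$nSweepsProd),
      seed = as.numeric(config$seed),
      meta = list(acceptanceRate = res$acceptanceRate,
                  dTransFinal = res$dTransFinal,
                  dRotFinal = res$dRotFinal,
                  maxEnergyDrift = res$maxEnergyDrift,
                  finalEnergy = res$finalEnergy,
                  cutoff = cutoff))
}

#' Total potential energy of a configuration
#'
#' Sum of molecule-pair energies over all unordered pairs under the minimum
#' image convention, with the truncated-and-shifted scheme at \code{cutoff}.
#'
#' @param coords Site matrix (natoms x 3), nm.
#' @param box A \linkS4class{SimulationBox}.
#' @param params A \linkS4class{ForceFieldParams}.
#' @param cutoff Cutoff, nm (capped at L/2).
#' @param shift Shift terms to zero at the cutoff (default TRUE).
#' @return Energy, kJ/mol.
#' @export
totalEnergy <- function(coords, box, params, cutoff = 1.0, shift = TRUE) {
  m <- if (box@species == "water3") 3L else 1L
  minSep <- minSiteSeparation(coords, box@L)
  if (nrow(coords) > m && minSep < 1e-6)
    stop("overlapping sites (separation < 1e-6 nm)")
  cpp_total_energy(coords, m, siteCharges(params, box@species),
                   params@sigma, params@epsilon, box@L,
                   min(cutoff, box@L / 2), shift)
}

minSiteSeparation <- function(coords, L) {
  n <- nrow(coords)
  if (n < 2) return(Inf)
  ## cheap check on a subsample for large systems
  take <- if (n > 200) sample.int(n, 200) else seq_len(n)
  x <- coords[take, , drop = FALSE]
  d <- Inf
  for (i in seq_len(nrow(x) - 1)) {
    dx <- sweep(x[-seq_len(i), , drop = FALSE], 2, x[i, ], "-")
    dx <- dx - L * round(dx / L)
    d <- min(d, sqrt(min(rowSums(dx^2))))
  }
  d
}

#' Virial pressure from a trajectory
#'
#' \eqn{P = \rho k_B T + \langle \sum_{i<j} F_{ij} \cdot R_{ij} \rangle / (3V)}
#' with molecule-pair forces from the truncated potential (the shift does not
#' alter forces) and minimum-image center-of-mass separations. The block SD
#' is the population standard deviation of per-block pressures.
#'
#' @param trajectory A \linkS4class{Trajectory}.
#' @param params A \linkS4class{ForceFieldParams}.
#' @param cutoff Cutoff, nm (default: the trajectory's own, else 1.0).
#' @param nBlocks Blocks for the uncertainty (default 10; 0 disables).
#' @return List with \code{pressure} (bar), \code{sd} (bar; NA if
#'   \code{nBlocks} < 2) and \code{idealPart} (rho kT, bar).
#' @export
#' @name virialPressure
setMethod("virialPressure", "Trajectory",
  function(trajectory, params, cutoff = NULL, nBlocks = 10L) {
    box <- trajectory@box
    if (nFrames(trajectory) < 1L) stop("empty trajectory")
    if (is.null(cutoff))
      cutoff <- if (!is.null(trajectory@meta$cutoff)) trajectory@meta$cutoff
                else min(1.0, box@L / 2)
    m <- if (box@species == "water3") 3L else 1L
    W <- cpp_virial(trajectory@coords, dim(trajectory@coords), m,
                    siteCharges(params, box@species),
                    params@sigma, params@epsilon, siteMasses(box@species),
                    box@L, min(cutoff, box@L / 2))
    V <- box@L^3
    rhokT <- box@n / V * dffitConstants$kB * box@temperature
    toBar <- dffitConstants$barPerKjMolNm3
    pFrames <- (rhokT + W / (3 * V)) * toBar
    sdP <- NA_real_
    if (nBlocks >= 2L && length(pFrames) >= nBlocks) {
      nb <- as.integer(nBlocks)
      use <- length(pFrames) - length(pFrames) %% nb
      blocks <- colMeans(matrix(pFrames[seq_len(use)], ncol = nb))
      sdP <- sqrt(mean((blocks - mean(blocks))^2))
    }
    list(pressure = mean(pFrames), sd = sdP, idealPart = rhokT * toBar)
  })
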