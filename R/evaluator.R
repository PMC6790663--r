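## Glue between the optimizer and the internal sampler: one closure samples
## a candidate parameter set at a given nominal budget and returns its
## block-averaged distribution function(s).

#' Build a sampling + distribution-function evaluator
#'
#' Returns the closure \code{function(searchVector, budgetPs, seed)} that
#' the optimizer calls per individual: it converts the search vector to
#' parameters, initializes a box of \code{n} molecules at \code{density},
#' runs the Metropolis sampler for \code{psToSweeps(budgetPs)} production
#' sweeps, and computes the requested block distribution function(s).
#'
#' @param speciesName \code{"lj"} or \code{"water3"}.
#' @param n Number of molecules.
#' @param density Mass density (g/cm^3) or reduced density (with
#'   \code{reduced = TRUE}, interpreted with each candidate's own sigma is
#'   wrong, so the box is fixed from \code{referenceParams}).
#' @param temperature Kelvin.
#' @param rdfScheme,edfScheme Bin schemes; supply the ones the fitness kind
#'   needs (NULL to skip).
#' @param referenceParams \linkS4class{ForceFieldParams} fixing the box
#'   geometry (and, for 3-vectors, the fixed d and a).
#' @param nBlocks Blocks for uncertainties (default 10).
#' @param cutoff Interaction cutoff, nm.
#' @param reduced Interpret \code{density} as reduced number density
#'   (computed with \code{referenceParams@sigma}).
#' @param equilSweeps Equilibration sweeps per evaluation.
#' @param sampleEvery Sweeps between recorded frames.
#' @param molarMass Molar mass for \code{"lj"}, g/mol.
#' @return Closure returning a named list with \code{$rdf} and/or
#'   \code{$edf}.
#' @export
makeSamplerEvaluator <- function(speciesName, n, density, temperature,
                                 rdfScheme = NULL, edfScheme = NULL,
                                 referenceParams, nBlocks = 10L,
                                 cutoff = 1.0, reduced = FALSE,
                                 equilSweeps = 500L, sampleEvery = 5L,
                                 molarMass = 39.948) {
  force(list(speciesName, n, density, temperature, rdfScheme, edfScheme,
             referenceParams, nBlocks, cutoff, reduced, equilSweeps,
             sampleEvery, molarMass))
  function(searchVector, budgetPs, seed) {
    params <- if (is(searchVector, "ForceFieldParams")) searchVector
      else if (length(searchVector) %in% c(3L, 5L))
        fromSearchVector(searchVector, referenceParams)
      else forceFieldParams(searchVector[[1]], searchVector[[2]],
                            d = referenceParams@d, a = referenceParams@a)
    init <- initializeBox(n, density, speciesName, temperature,
                          params = referenceParams, seed = seed,
                          molarMass = molarMass, reduced = reduced,
                          cutoff = NULL)
    nProd <- psToSweeps(budgetPs)
    ## frame count must divide into blocks
    nProd <- max(nProd, nBlocks * sampleEvery)
    traj <- runMetropolis(init$box, init$coords, params,
                          samplerConfig(nSweepsEquil = equilSweeps,
                                        nSweepsProd = nProd,
                                        sampleEvery = sampleEvery,
                                        cutoff = cutoff, seed = seed))
    out <- list()
    if (!is.null(rdfScheme))
      out$rdf <- blockDistribution(traj, function(t) rdf(t, rdfScheme),
                                   nBlocks)
    if (!is.null(edfScheme))
      out$edf <- blockDistribution(traj, function(t)
        edf(t, params, edfScheme, cutoff = cutoff), nBlocks)
    out
  }
}

#' Generate a target fixture: trajectory plus ground-truth manifest
#'
#' Stands in for the replicate target runs of a reference engine:
#' \code{"ideal_gas"} places molecules uniformly at random (its radial
#' distribution function is analytically 1); \code{"lj_fluid"} and
#' \code{"water3"} run the Metropolis sampler at the given parameters. The
#' manifest records the generating parameters as ground truth for recovery
#' experiments. Three replicates (seeds) of one spec constitute a target set
#' for threshold derivation.
#'
#' @param kind \code{"ideal_gas"}, \code{"lj_fluid"} or \code{"water3"}.
#' @param params Generating \linkS4class{ForceFieldParams}.
#' @param n Number of molecules.
#' @param density Mass density (g/cm^3) or reduced (see \code{reduced}).
#' @param temperature Kelvin.
#' @param frames Frames to record for \code{"ideal_gas"}.
#' @param budgetPs Nominal sampling budget for the MC kinds.
#' @param seed Integer seed.
#' @param reduced Interpret density as reduced number density.
#' @param cutoff Interaction cutoff, nm.
#' @param molarMass Molar mass for LJ species, g/mol.
#' @return List with \code{trajectory} (a \linkS4class{Trajectory}) and
#'   \code{manifest} (generating parameters and conditions).
#' @export
generateFixture <- function(kind = c("ideal_gas", "lj_fluid", "water3"),
                            params, n = 100L, density = 0.9971,
                            temperature = 298, frames = 100L,
                            budgetPs = 250, seed = 1L, reduced = FALSE,
                            cutoff = 1.0, molarMass = 39.948) {
  kind <- match.arg(kind)
  speciesName <- if (kind == "water3") "water3" else "lj"
  if (kind == "ideal_gas") {
    init <- initializeBox(n, density, speciesName, temperature,
                          params = params, seed = seed,
                          molarMass = molarMass, reduced = reduced)
    L <- init$box@L
    if (exists(".Random.seed", envir = globalenv())) {
      oldSeed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", oldSeed, envir = globalenv()))
    }
    set.seed(seed)
    coords <- array(stats::runif(n * 3 * frames, 0, L), dim = c(n, 3, frames))
    traj <- new("Trajectory", coords = coords, box = init$box,
                samplingSweeps = NA_real_, seed = as.numeric(seed),
                meta = list(kind = "ideal_gas"))
  } else {
    init <- initializeBox(n, density, speciesName, temperature,
                          params = params, seed = seed,
                          molarMass = molarMass, reduced = reduced)
    nProd <- psToSweeps(budgetPs)
    traj <- runMetropolis(init$box, init$coords, params,
                          samplerConfig(nSweepsProd = nProd,
                                        cutoff = cutoff, seed = seed))
  }
  manifest <- list(kind = kind,
                   params = list(sigma_nm = params@sigma,
                                 epsilon_kjmol = params@epsilon,
                                 q_e = params@q, d_nm = params@d,
                                 a_deg = params@a),
                   n = n, density = density, reduced = reduced,
                   temperature = temperature, seed = seed,
                   budgetPs = if (kind == "ideal_gas") NA else budgetPs)
  list(trajectory = traj, manifest = manifest)
}
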