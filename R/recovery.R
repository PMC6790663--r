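#' Parameter-recovery experiment for a Lennard-Jones fluid
#'
#' The self-contained validation loop: generate three replicate target
#' trajectories of an LJ fluid at known (sigma, epsilon), derive the energy
#' distribution function targets with block uncertainties and the replicate
#' threshold, then optimize (sigma, epsilon) from a +5\% perturbed start
#' with the EDF fitness. Ground truth is the generating parameter set, so
#' the recovered relative errors measure the whole pipeline.
#'
#' Study conditions (defaults): N = 100 particles at reduced density 0.6 and
#' reduced temperature 1.5 (sigma = 0.34 nm, epsilon = 1 kJ/mol, so
#' T = 180.4 K), cutoff 0.9 nm, energy bins from definition (1, 8, 5),
#' 250 nominal ps (2500 sweeps) per evaluation, 10 blocks, SD floor 1e-4
#' (sub-single-count scale at this budget, protecting sparse tail bins).
#'
#' @param masterSeed Integer master seed for the whole experiment.
#' @param truth Generating \linkS4class{ForceFieldParams}.
#' @param n Particles.
#' @param rhoStar Reduced density.
#' @param temperature Kelvin.
#' @param cutoff Cutoff, nm.
#' @param startFactor Multiplicative perturbation of the start (default 1.05).
#' @param budgetPs Initial per-individual budget, nominal ps.
#' @param maxBudgetPs Per-individual budget cap. The default allows one
#'   doubling above the target budget: since the targets are sampled at
#'   \code{budgetPs}, the expected fitness of a truth-level candidate scales
#'   as \eqn{\sigma_c/\sigma_t + \sigma_t/\sigma_c} and is minimized near
#'   matched sampling, so larger candidate budgets raise the fitness floor
#'   while multiplying the run time.
#' @param maxGenerations Generation cap.
#' @param sigmaFloor SD floor for the fitness.
#' @param scheme Energy \linkS4class{BinScheme}.
#' @return List: \code{result} (\linkS4class{OptimizationResult}),
#'   \code{threshold}, \code{relErr} (named relative errors of sigma,
#'   epsilon), \code{truth}.
#' @export
ljRecoveryExperiment <- function(masterSeed = 1L,
                                 truth = forceFieldParams(0.34, 1.0),
                                 n = 100L, rhoStar = 0.6,
                                 temperature = 180.4, cutoff = 0.9,
                                 startFactor = 1.05, budgetPs = 250,
                                 maxBudgetPs = 500, maxGenerations = 20L,
                                 sigmaFloor = 1e-4,
                                 scheme = edfBinEdges(1, 8, 5)) {
  targetDf <- function(seed, budget = budgetPs) {
    init <- initializeBox(n, rhoStar, "lj", temperature, params = truth,
                          reduced = TRUE, seed = seed)
    tr <- runMetropolis(init$box, init$coords, truth,
                        samplerConfig(nSweepsProd = psToSweeps(budget),
                                      cutoff = cutoff, seed = seed))
    blockDistribution(tr, function(t) edf(t, truth, scheme, cutoff = cutoff))
  }
  tdfs <- lapply(1:3, function(r) targetDf(deriveSeed(masterSeed, 1000L, r)))
  thr <- dfThreshold(tdfs, sigmaFloor = sigmaFloor)
  ev <- makeSamplerEvaluator("lj", n, rhoStar, temperature,
                             edfScheme = scheme, referenceParams = truth,
                             reduced = TRUE, cutoff = cutoff)
  cfg <- optimizationConfig(2L, "EDF", threshold = thr$value,
                            initialBudgetPs = budgetPs,
                            maxBudgetPs = maxBudgetPs,
                            masterSeed = masterSeed,
                            maxGenerations = maxGenerations,
                            sigmaFloor = sigmaFloor)
  start <- c(truth@sigma * startFactor, truth@epsilon * startFactor)
  res <- optimizeParameters(list(edf = tdfs[[1]]), start, cfg, ev)
  relErr <- c(sigma = (res@bestParams@sigma - truth@sigma) / truth@sigma,
              epsilon = (res@bestParams@epsilon - truth@epsilon) /
                truth@epsilon)
  list(result = res, threshold = thr$value, relErr = relErr, truth = truth)
}
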