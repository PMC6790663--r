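#' @import methods
NULL

#' Rigid three-site (or monatomic) pair-potential parameters
#'
#' The five physical parameters of a rigid 3-site water-like model:
#' Lennard-Jones \code{sigma} (nm) and \code{epsilon} (kJ/mol) on the
#' oxygen-like site, the oxygen partial charge \code{q} (e, negative by
#' convention), the O--H bond length \code{d} (nm) and the H--O--H angle
#' \code{a} (degrees). The hydrogen-site charge is always \code{-q/2}
#' (derived, never stored) and hydrogen van der Waals parameters are
#' identically zero. A monatomic Lennard-Jones species uses \code{sigma},
#' \code{epsilon} with \code{q = 0}.
#'
#' @slot sigma Lennard-Jones diameter, nm (> 0).
#' @slot epsilon Lennard-Jones well depth, kJ/mol (>= 0).
#' @slot q Oxygen-site charge, e.
#' @slot d O--H bond length, nm (> 0).
#' @slot a H--O--H angle, degrees (0 < a <= 180).
#' @export
setClass("ForceFieldParams",
  representation(sigma = "numeric", epsilon = "numeric", q = "numeric",
                 d = "numeric", a = "numeric"),
  prototype(sigma = 0.3, epsilon = 0.5, q = 0, d = 0.1, a = 109.47))

setValidity("ForceFieldParams", function(object) {
  msgs <- character(0)
  for (s in c("sigma", "epsilon", "q", "d", "a")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v))
      msgs <- c(msgs, sprintf("'%s' must be a single finite number", s))
  }
  if (length(msgs)) return(msgs)
  if (object@sigma <= 0)  msgs <- c(msgs, "'sigma' must be > 0")
  if (object@epsilon < 0) msgs <- c(msgs, "'epsilon' must be >= 0")
  if (object@d <= 0)      msgs <- c(msgs, "'d' must be > 0")
  if (object@a <= 0 || object@a > 180)
    msgs <- c(msgs, "'a' must satisfy 0 < a <= 180 degrees")
  if (length(msgs)) msgs else TRUE
})

#' Molecule-local site geometry
#'
#' Three site positions (nm) in a molecule-local frame together with the
#' site charges (e): the realization of \code{d}, \code{a} and \code{q} as
#' coordinates. Oxygen at the origin, hydrogens symmetric about the bisector.
#'
#' @slot positions 3 x 3 numeric matrix, one site per row (O, H1, H2), nm.
#' @slot charges length-3 numeric, e; sums to zero.
#' @export
setClass("SiteGeometry",
  representation(positions = "matrix", charges = "numeric"))

setValidity("SiteGeometry", function(object) {
  if (!is.numeric(object@positions) || !all(dim(object@positions) == c(3, 3)))
    return("'positions' must be a 3 x 3 numeric matrix")
  if (length(object@charges) != 3L)
    return("'charges' must have length 3")
  if (abs(sum(object@charges)) > 1e-10)
    return("site charges must sum to zero")
  TRUE
})

#' Cubic periodic simulation box
#'
#' @slot L Cubic edge length, nm.
#' @slot n Number of molecules.
#' @slot species \code{"lj"} (monatomic) or \code{"water3"} (rigid 3-site).
#' @slot temperature Kelvin.
#' @export
setClass("SimulationBox",
  representation(L = "numeric", n = "integer", species = "character",
                 temperature = "numeric"))

setValidity("SimulationBox", function(object) {
  if (object@L <= 0) return("'L' must be > 0")
  if (object@n < 1L) return("'n' must be >= 1")
  if (!object@species %in% c("lj", "water3"))
    return("'species' must be 'lj' or 'water3'")
  if (object@temperature <= 0) return("'temperature' must be > 0")
  TRUE
})

#' Trajectory of molecular configurations
#'
#' Frames of explicit site coordinates (nm), wrapped into the primary box,
#' with box metadata. \code{coords} has dimension (sites, 3, frames) where
#' sites = n molecules x sites per molecule (1 for \code{"lj"}, 3 for
#' \code{"water3"}, ordered O, H1, H2 within each molecule).
#'
#' @slot coords numeric array (natoms, 3, nframes), nm.
#' @slot box A \linkS4class{SimulationBox}.
#' @slot samplingSweeps Production sweeps this trajectory represents.
#' @slot seed RNG seed the trajectory was generated from (NA if external).
#' @slot meta List of diagnostics (acceptance rate, energy drift, ...).
#' @export
setClass("Trajectory",
  representation(coords = "array", box = "SimulationBox",
                 samplingSweeps = "numeric", seed = "numeric",
                 meta = "list"),
  prototype(samplingSweeps = NA_real_, seed = NA_real_, meta = list()))

setValidity("Trajectory", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 3L)
    return("'coords' must be an (natoms, 3, nframes) array")
  spm <- if (object@box@species == "water3") 3L else 1L
  if (d[1] != object@box@n * spm)
    return(sprintf("coords has %d sites; box declares %d molecules x %d sites",
                   d[1], object@box@n, spm))
  TRUE
})

#' Histogram bin scheme for distribution functions
#'
#' Strictly increasing bin edges, radial (nm) or energy (kJ/mol internally;
#' energy schemes are constructed from kcal/mol region definitions and span
#' exactly -30.02 to 30.22 kcal/mol).
#'
#' @slot kind \code{"radial"} or \code{"energy"}.
#' @slot edges Strictly increasing numeric vector of bin edges.
#' @slot meta Provenance: \code{bin_size} and \code{domain} for radial,
#'   \code{i}, \code{j}, \code{k} and \code{id} for energy schemes.
#' @export
setClass("BinScheme",
  representation(kind = "character", edges = "numeric", meta = "list"),
  prototype(meta = list()))

setValidity("BinScheme", function(object) {
  if (!object@kind %in% c("radial", "energy"))
    return("'kind' must be 'radial' or 'energy'")
  if (length(object@edges) < 2L)
    return("a scheme needs at least one bin (two edges)")
  if (any(diff(object@edges) <= 0))
    return("'edges' must be strictly increasing")
  TRUE
})

#' A binned distribution function with optional per-bin uncertainties
#'
#' Values are densities: dimensionless g(r) for the radial kind; average
#' pair count per molecule per unit energy (mol/kJ) for the energy kind.
#' Uncertainties, when present, are per-bin standard deviations across
#' trajectory blocks (population SD, divisor n_blocks).
#'
#' @slot scheme A \linkS4class{BinScheme}.
#' @slot values Per-bin density, >= 0, one per bin.
#' @slot uncertainties Per-bin block SD (length 0 when absent).
#' @slot nBlocks Number of blocks used (0 when no uncertainties).
#' @slot meta List: nFrames, nMolecules, rho0 (molecules/nm^3, radial kind),
#'   droppedFraction (energy kind: fraction of pair energies outside the span).
#' @export
setClass("DistributionFunction",
  representation(scheme = "BinScheme", values = "numeric",
                 uncertainties = "numeric", nBlocks = "integer",
                 meta = "list"),
  prototype(uncertainties = numeric(0), nBlocks = 0L, meta = list()))

setValidity("DistributionFunction", function(object) {
  nb <- length(object@scheme@edges) - 1L
  if (length(object@values) != nb)
    return("length(values) must equal the number of bins")
  if (any(object@values < -1e-12))
    return("'values' must be non-negative")
  if (length(object@uncertainties) &&
      length(object@uncertainties) != nb)
    return("length(uncertainties) must equal the number of bins")
  if (length(object@uncertainties) && any(object@uncertainties < 0))
    return("'uncertainties' must be non-negative")
  if (object@scheme@kind == "radial") {
    r0 <- object@meta$rho0
    if (is.null(r0) || !is.finite(r0) || r0 <= 0)
      return("radial distribution functions must record meta$rho0 > 0")
  }
  TRUE
})

#' Result of one distribution-matching optimization run
#'
#' @slot bestParams The best \linkS4class{ForceFieldParams} found.
#' @slot bestFitness Fitness of \code{bestParams} (at its own budget).
#' @slot converged TRUE iff the final best fitness reached the threshold.
#' @slot threshold The convergence threshold used.
#' @slot history List of per-generation records (generation, budgetSweeps,
#'   individuals matrix, fitnesses, bestFitness, averageFitness).
#' @slot totalBudget Total production sweeps consumed across all evaluations.
#' @slot fitnessKind \code{"RDF"}, \code{"EDF"} or \code{"RxE"}.
#' @export
setClass("OptimizationResult",
  representation(bestParams = "ForceFieldParams", bestFitness = "numeric",
                 converged = "logical", threshold = "numeric",
                 history = "list", totalBudget = "numeric",
                 fitnessKind = "character"))
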