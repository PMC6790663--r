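## Radial and energy distribution functions as histograms with block-based
## per-bin uncertainties. Values are densities (per nm, or per kJ/mol), so
## the bin-width weighting of the fitness is meaningful across non-uniform
## energy bins. Both orderings of each molecule pair are counted, matching
## the per-reference-molecule definition of the distributions.

#' Uniform radial bin scheme
#'
#' Uniform edges from 0 to \code{domain} (default 1.5 nm). The study set of
#' radial bin sizes is (1, 2, 4, 5, 10, 20, 40, 50, 100, 200, 500) x 1e-5 nm;
#' \code{rdfBinSizes} returns it.
#'
#' @param binSize Bin width, nm.
#' @param domain Upper limit of the scheme, nm.
#' @return A \linkS4class{BinScheme} of kind \code{"radial"}.
#' @examples
#' rdfBinEdges(0.01)          # 150 bins
#' length(rdfBinSizes())      # 11 studied sizes
#' @export
rdfBinEdges <- function(binSize, domain = 1.5) {
  if (binSize <= 0) stop("'binSize' must be > 0")
  nb <- domain / binSize
  if (abs(nb - round(nb)) > 1e-9) {
    nb <- floor(nb)
    message(sprintf("binSize does not divide domain; truncating to %d bins", nb))
  } else nb <- round(nb)
  edges <- seq(0, by = binSize, length.out = nb + 1)
  new("BinScheme", kind = "radial", edges = edges,
      meta = list(bin_size = binSize, domain = domain))
}

#' @rdname rdfBinEdges
#' @export
rdfBinSizes <- function() c(1, 2, 4, 5, 10, 20, 40, 50, 100, 200, 500) * 1e-5

## Energy bin system: five contiguous regions in kcal/mol with region-wise
## bin sizes indexed by (i, j, k); converted to kJ/mol at construction.
EDF_REGIONS <- list(
  lo = c(-30.02, -0.22, -0.02, 0.02, 0.22),
  hi = c(-0.22, -0.02, 0.02, 0.22, 30.22))
EDF_I <- c(1, 2, 4, 10, 20)
EDF_J <- c(1, 2, 4, 8, 20, 40, 100, 200)
EDF_K <- c(1, 2, 4, 10, 20)

#' Energy bin scheme from the (i, j, k) definition system
#'
#' Five contiguous regions spanning -30.02 to 30.22 kcal/mol. The outer
#' regions always use 0.04 kcal/mol bins; the inner regions use
#' 0.002 x I_i, 0.0002 x J_j and 0.002 x K_k kcal/mol with
#' I = (1, 2, 4, 10, 20), J = (1, 2, 4, 8, 20, 40, 100, 200) and
#' K = (1, 2, 4, 10, 20). Edges are converted to kJ/mol (1 cal = 4.184 J)
#' at construction; region boundaries are exact. \code{binDefinitionId}
#' maps a triple to its definition ID, \code{5*8*(i-1) + 5*(j-1) + k},
#' a bijection onto 1..200.
#'
#' @param i,j,k Region bin-size indices: i in 1..5, j in 1..8, k in 1..5.
#' @return \code{edfBinEdges}: a \linkS4class{BinScheme} of kind
#'   \code{"energy"} whose \code{meta} records the triple and its ID;
#'   \code{binDefinitionId}: an integer in 1..200.
#' @examples
#' binDefinitionId(1, 8, 5)   # 40
#' edfBinEdges(1, 8, 5)
#' @export
edfBinEdges <- function(i, j, k) {
  checkIdx <- function(v, n, nm) {
    if (length(v) != 1 || is.na(v) || v < 1 || v > n || v != round(v))
      stop(sprintf("'%s' must be an integer in 1..%d", nm, n))
  }
  checkIdx(i, 5L, "i"); checkIdx(j, 8L, "j"); checkIdx(k, 5L, "k")
  sizes <- c(0.04, 0.002 * EDF_I[i], 0.0002 * EDF_J[j], 0.002 * EDF_K[k], 0.04)
  edges_kcal <- numeric(0)
  for (r in 1:5) {
    lo <- EDF_REGIONS$lo[r]; hi <- EDF_REGIONS$hi[r]
    nb <- round((hi - lo) / sizes[r])
    e <- lo + sizes[r] * seq(0, nb)
    e[length(e)] <- hi                       # exact region boundary
    edges_kcal <- c(edges_kcal[-length(edges_kcal)], e)
  }
  new("BinScheme", kind = "energy",
      edges = edges_kcal * dffitConstants$kcalToKj,
      meta = list(i = i, j = j, k = k, id = binDefinitionId(i, j, k)))
}

#' @rdname edfBinEdges
#' @export
binDefinitionId <- function(i, j, k) {
  if (any(c(i, j, k) != round(c(i, j, k))) ||
      i < 1 || i > 5 || j < 1 || j > 8 || k < 1 || k > 5)
    stop("indices must satisfy i in 1..5, j in 1..8, k in 1..5")
  as.integer(5 * 8 * (i - 1) + 5 * (j - 1) + k)
}

trajCom <- function(trajectory) {
  m <- if (species(trajectory) == "water3") 3L else 1L
  if (m == 1L) trajectory@coords
  else cpp_com(trajectory@coords, dim(trajectory@coords), m,
               siteMasses("water3"))
}

subsetFrames <- function(trajectory, frames) {
  new("Trajectory", coords = trajectory@coords[, , frames, drop = FALSE],
      box = trajectory@box, samplingSweeps = trajectory@samplingSweeps,
      seed = trajectory@seed, meta = trajectory@meta)
}

#' Radial distribution function of molecule centers
#'
#' Histogram estimator of g(r) over minimum-image center-of-mass distances:
#' for each bin, value = (pair count, both orderings) /
#' (n_frames n 4 pi r_mid^2 dr rho0) with rho0 = n/V and r_mid the bin
#' center. The scheme domain must not exceed L/2 (minimum-image validity).
#'
#' @param trajectory A \linkS4class{Trajectory}.
#' @param scheme A radial \linkS4class{BinScheme}.
#' @param ... Unused.
#' @return A \linkS4class{DistributionFunction} without uncertainties
#'   (see \code{\link{blockDistribution}}).
#' @export
#' @name rdf
setMethod("rdf", "Trajectory", function(trajectory, scheme, ...) {
  if (binKind(scheme) != "radial") stop("scheme must be of kind 'radial'")
  nf <- nFrames(trajectory)
  if (nf < 1L) stop("empty trajectory")
  L <- boxLength(trajectory)
  edges <- binEdges(scheme)
  if (max(edges) > L / 2 + 1e-9)
    stop(sprintf("scheme domain %.3f nm exceeds L/2 = %.3f nm (minimum image)",
                 max(edges), L / 2))
  com <- trajCom(trajectory)
  counts <- 2 * cpp_rdf_counts(com, dim(com), L, edges)
  n <- nMolecules(trajectory)
  rho0 <- n / L^3
  rmid <- (edges[-1] + edges[-length(edges)]) / 2
  dr <- diff(edges)
  vals <- counts / (nf * n * 4 * pi * rmid^2 * dr * rho0)
  new("DistributionFunction", scheme = scheme, values = vals,
      meta = list(nFrames = nf, nMolecules = n, rho0 = rho0))
})

#' Energy distribution function of molecule pairs
#'
#' For every frame and unordered molecule pair inside the interaction domain
#' (first-site minimum-image distance below the cutoff), the pair energy u is
#' computed with the truncated-shifted scheme and binned. Bin value =
#' (count, both orderings) / (n_frames n de), a density per kJ/mol per
#' molecule; its integral is the mean number of in-range partners per
#' molecule. Pairs outside the scheme's span are dropped; their fraction is
#' recorded in \code{meta$droppedFraction}.
#'
#' @param trajectory A \linkS4class{Trajectory}.
#' @param params A \linkS4class{ForceFieldParams}.
#' @param scheme An energy \linkS4class{BinScheme}.
#' @param cutoff Interaction cutoff, nm (default: trajectory's own, else 1.0).
#' @param ... Unused.
#' @return A \linkS4class{DistributionFunction} without uncertainties.
#' @export
#' @name edf
setMethod("edf", "Trajectory", function(trajectory, params, scheme,
                                        cutoff = NULL, ...) {
  if (binKind(scheme) != "energy") stop("scheme must be of kind 'energy'")
  nf <- nFrames(trajectory)
  if (nf < 1L) stop("empty trajectory")
  box <- trajectory@box
  if (is.null(cutoff))
    cutoff <- if (!is.null(trajectory@meta$cutoff)) trajectory@meta$cutoff
              else min(1.0, box@L / 2)
  m <- if (box@species == "water3") 3L else 1L
  res <- cpp_edf_counts(trajectory@coords, dim(trajectory@coords), m,
                        siteCharges(params, box@species),
                        params@sigma, params@epsilon, box@L,
                        min(cutoff, box@L / 2), TRUE, binEdges(scheme))
  n <- nMolecules(trajectory)
  de <- binWidths(scheme)
  vals <- 2 * res$counts / (nf * n * de)
  dropped <- if (res$total > 0) res$dropped / res$total else 0
  if (dropped > 0)
    message(sprintf("edf: %.3g%% of in-range pair energies outside bin span",
                    100 * dropped))
  new("DistributionFunction", scheme = scheme, values = vals,
      meta = list(nFrames = nf, nMolecules = n, cutoff = cutoff,
                  droppedFraction = dropped))
})

#' Block-averaged distribution function with per-bin uncertainties
#'
#' Splits the trajectory into \code{nBlocks} consecutive equal blocks,
#' evaluates \code{compute} on each, and returns the per-bin mean as the
#' value and the population standard deviation across blocks (divisor
#' n_blocks) as the uncertainty.
#'
#' @param trajectory A \linkS4class{Trajectory}.
#' @param compute Closure taking a trajectory and returning a
#'   \linkS4class{DistributionFunction}, e.g.
#'   \code{function(t) rdf(t, scheme)}.
#' @param nBlocks Number of blocks (>= 2; default 10).
#' @return A \linkS4class{DistributionFunction} with uncertainties.
#' @examples
#' \dontrun{
#' target <- blockDistribution(traj, function(t) rdf(t, rdfBinEdges(0.01)))
#' }
#' @export
blockDistribution <- function(trajectory, compute, nBlocks = 10L) {
  nBlocks <- as.integer(nBlocks)
  if (nBlocks < 2L) stop("'nBlocks' must be >= 2 (block SD undefined)")
  nf <- nFrames(trajectory)
  per <- nf %/% nBlocks
  if (per < 1L) stop("fewer frames than blocks")
  if (nf %% nBlocks != 0L)
    message(sprintf("dropping %d trailing frame(s) not filling a block",
                    nf %% nBlocks))
  dfs <- vector("list", nBlocks)
  for (b in seq_len(nBlocks)) {
    fr <- ((b - 1L) * per + 1L):(b * per)
    dfs[[b]] <- compute(subsetFrames(trajectory, fr))
  }
  vals <- sapply(dfs, dfValues)
  mu <- rowMeans(vals)
  sdv <- sqrt(rowMeans((vals - mu)^2))
  proto <- dfs[[1]]
  meta <- proto@meta
  meta$nFrames <- nf
  dropped <- vapply(dfs, function(d)
    if (is.null(d@meta$droppedFraction)) 0 else d@meta$droppedFraction, 0)
  if (any(dropped > 0)) meta$droppedFraction <- mean(dropped)
  new("DistributionFunction", scheme = proto@scheme, values = mu,
      uncertainties = sdv, nBlocks = nBlocks, meta = meta)
}
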