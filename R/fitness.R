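## The uncertainty-weighted objective comparing candidate and target
## distribution functions, and the replicate-derived convergence threshold.

#' Uncertainty-weighted distribution-function fitness
#'
#' \deqn{fitness = \sum_i \frac{(\rho_i^{cand} - \rho_i^{target})^2}
#'   {\sigma_i^{cand}\,\sigma_i^{target}} \Delta x_i}
#' where the sums run over bins of the scheme shared by both distribution
#' functions, \eqn{\sigma} are the per-bin block SDs, and \eqn{\Delta x_i}
#' the bin widths. Bins where the uncertainty product is zero contribute 0
#' when the squared difference is also zero, and raise an error otherwise
#' (unless \code{sigmaFloor} is set, which clamps each SD from below).
#' With \code{weighted = FALSE}, all SDs are replaced by 1, the
#' unweighted ("without uncertainty") variant.
#'
#' @param cand,target \linkS4class{DistributionFunction}s sharing one scheme,
#'   both carrying uncertainties (unless \code{weighted = FALSE}).
#' @param weighted Use the block-SD weights (default TRUE).
#' @param sigmaFloor Optional lower clamp for the SDs (default 0 = off).
#' @param perBin Return the per-bin contributions as an attribute.
#' @return A non-negative number. With \code{perBin = TRUE}, the attribute
#'   \code{"perBin"} holds each bin's contribution.
#' @export
fitnessEq1 <- function(cand, target, weighted = TRUE, sigmaFloor = 0,
                       perBin = FALSE) {
  sameScheme(cand, target)
  dx <- binWidths(cand)
  dv <- dfValues(cand) - dfValues(target)
  if (weighted) {
    if (!length(dfUncertainties(cand)) || !length(dfUncertainties(target)))
      stop("both distribution functions must carry uncertainties; ",
           "use blockDistribution() or weighted = FALSE")
    sp <- pmax(dfUncertainties(cand), sigmaFloor) *
          pmax(dfUncertainties(target), sigmaFloor)
  } else {
    sp <- rep(1, length(dv))
  }
  contrib <- numeric(length(dv))
  zero <- sp == 0
  if (any(zero & dv != 0))
    stop("zero uncertainty product with nonzero value difference in bin(s) ",
         paste(utils::head(which(zero & dv != 0), 5), collapse = ", "),
         "; consider sigmaFloor")
  ok <- !zero
  contrib[ok] <- dv[ok]^2 / sp[ok] * dx[ok]
  f <- sum(contrib)
  if (perBin) attr(f, "perBin") <- contrib
  f
}

sameScheme <- function(a, b) {
  ea <- binEdges(a); eb <- binEdges(b)
  if (binKind(a) != binKind(b) || length(ea) != length(eb) ||
      any(abs(ea - eb) > 1e-9))
    stop("candidate and target must share an identical bin scheme")
  invisible(TRUE)
}

#' Product fitness over radial and energy distribution functions
#'
#' The product of the two uncertainty-weighted fitnesses,
#' \eqn{fitness^{R \times E} = fitness^{RDF} \cdot fitness^{EDF}}.
#'
#' @param candRdf,targetRdf Radial \linkS4class{DistributionFunction} pair.
#' @param candEdf,targetEdf Energy \linkS4class{DistributionFunction} pair.
#' @param ... Passed to \code{\link{fitnessEq1}}.
#' @return A non-negative number.
#' @export
fitnessRxE <- function(candRdf, targetRdf, candEdf, targetEdf, ...) {
  fitnessEq1(candRdf, targetRdf, ...) * fitnessEq1(candEdf, targetEdf, ...)
}

#' Convergence threshold from replicate target runs
#'
#' The threshold is the statistical floor of distinguishability: the largest
#' fitness among all unordered pairs of replicate target distribution
#' functions. \code{thresholdValue} applies the max rule to precomputed
#' pairwise fitnesses.
#'
#' @param targetDfs List of (usually three) replicate
#'   \linkS4class{DistributionFunction}s of one kind, with uncertainties.
#' @param ... Passed to \code{\link{fitnessEq1}}.
#' @param pairwise Numeric vector of pairwise fitness values.
#' @return \code{dfThreshold}: list with \code{value} (the max) and
#'   \code{pairwise} (all pairwise fitnesses); \code{thresholdValue}: the max.
#' @examples
#' thresholdValue(c(0.36, 0.38, 0.38))   # 0.38
#' @export
dfThreshold <- function(targetDfs, ...) {
  if (length(targetDfs) < 2L)
    stop("at least two replicate target DFs are required")
  pw <- c()
  nms <- c()
  for (i in seq_len(length(targetDfs) - 1L))
    for (j in (i + 1L):length(targetDfs)) {
      pw <- c(pw, fitnessEq1(targetDfs[[i]], targetDfs[[j]], ...))
      nms <- c(nms, paste0(i, "-", j))
    }
  names(pw) <- nms
  list(value = thresholdValue(pw), pairwise = pw)
}

#' @rdname dfThreshold
#' @export
thresholdValue <- function(pairwise) {
  if (!length(pairwise)) stop("no pairwise fitness values supplied")
  max(pairwise)
}
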