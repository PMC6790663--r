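## Covariance matrix adaptation evolution strategy: the combined rank-one +
## rank-mu update with cumulative step-size adaptation, following the
## canonical default parameterization. Only fitness *rankings* enter the
## update, so any strictly monotone transform of the objective leaves the
## iterates unchanged.

#' Initialize a CMA-ES state
#'
#' @param mean Initial search distribution mean (numeric vector).
#' @param sigma Initial global step size.
#' @param lambda Population size (default \code{4 + floor(3 log n)}).
#' @return An environment holding the strategy state; advance it with
#'   \code{\link{cmaAsk}} / \code{\link{cmaTell}}.
#' @export
cmaInit <- function(mean, sigma, lambda = NULL) {
  n <- length(mean)
  if (is.null(lambda)) lambda <- 4L + floor(3 * log(n))
  lambda <- as.integer(lambda)
  if (lambda < 4L) stop("'lambda' must be >= 4")
  mu <- lambda %/% 2L
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mueff <- 1 / sum(w^2)
  st <- new.env(parent = emptyenv())
  st$n <- n; st$lambda <- lambda; st$mu <- mu; st$weights <- w
  st$mueff <- mueff
  st$cs <- (mueff + 2) / (n + mueff + 5)
  st$ds <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + st$cs
  st$cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
  st$c1 <- 2 / ((n + 1.3)^2 + mueff)
  st$cmu <- min(1 - st$c1,
                2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
  st$chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))
  st$mean <- as.numeric(mean); st$sigma <- sigma
  st$C <- diag(n); st$pc <- numeric(n); st$ps <- numeric(n)
  st$counteval <- 0L
  st$B <- diag(n); st$D <- rep(1, n)
  st
}

#' @rdname cmaInit
#' @param state A CMA-ES state from \code{\link{cmaInit}}.
#' @return \code{cmaAsk}: an n x lambda matrix of proposals (uses the R RNG).
#' @export
cmaAsk <- function(state) {
  Z <- matrix(stats::rnorm(state$n * state$lambda), nrow = state$n)
  Y <- state$B %*% (state$D * Z)
  X <- state$mean + state$sigma * Y
  attr(X, "Y") <- Y
  X
}

#' @rdname cmaInit
#' @param X Proposal matrix returned by \code{cmaAsk}.
#' @param fitnesses Numeric vector of length lambda (to be minimized).
#' @return \code{cmaTell}: the updated state (invisibly).
#' @export
cmaTell <- function(state, X, fitnesses) {
  if (length(fitnesses) != state$lambda)
    stop("need one fitness per proposed individual")
  ord <- order(fitnesses)              # stable: ties keep proposal order
  Y <- attr(X, "Y")
  if (is.null(Y)) Y <- (X - state$mean) / state$sigma
  sel <- ord[seq_len(state$mu)]
  ybar <- as.numeric(Y[, sel, drop = FALSE] %*% state$weights)
  state$mean <- state$mean + state$sigma * ybar
  state$counteval <- state$counteval + state$lambda

  Cinvsqrt <- state$B %*% ((1 / state$D) * t(state$B))
  state$ps <- (1 - state$cs) * state$ps +
    sqrt(state$cs * (2 - state$cs) * state$mueff) *
    as.numeric(Cinvsqrt %*% ybar)
  hsig <- sqrt(sum(state$ps^2)) /
    sqrt(1 - (1 - state$cs)^(2 * state$counteval / state$lambda)) /
    state$chiN < 1.4 + 2 / (state$n + 1)
  state$pc <- (1 - state$cc) * state$pc +
    hsig * sqrt(state$cc * (2 - state$cc) * state$mueff) * ybar

  Ysel <- Y[, sel, drop = FALSE]
  rankMu <- Ysel %*% (state$weights * t(Ysel))
  state$C <- (1 - state$c1 - state$cmu) * state$C +
    state$c1 * (tcrossprod(state$pc) +
                (1 - hsig) * state$cc * (2 - state$cc) * state$C) +
    state$cmu * rankMu
  state$sigma <- state$sigma *
    exp((state$cs / state$ds) * (sqrt(sum(state$ps^2)) / state$chiN - 1))

  state$C <- (state$C + t(state$C)) / 2
  eg <- eigen(state$C, symmetric = TRUE)
  if (min(eg$values) <= 0 ||
      max(eg$values) / max(min(eg$values), .Machine$double.xmin) > 1e14) {
    message("cmaTell: degenerate covariance; restarting with inflated step")
    state$C <- diag(state$n)
    state$B <- diag(state$n); state$D <- rep(1, state$n)
    state$pc <- numeric(state$n); state$ps <- numeric(state$n)
    state$sigma <- state$sigma * 2
  } else {
    state$B <- eg$vectors
    state$D <- sqrt(eg$values)
  }
  invisible(state)
}

#' Sampling-budget doubling rule
#'
#' The per-individual sampling budget doubles when the best fitness of the
#' current generation is worse than the previous generation's best AND the
#' scaling factor times the current average fitness exceeds the average
#' fitness of two generations ago. The rule needs at least three generations
#' of history; a doubled budget is capped at \code{maxBudget}.
#'
#' @param history List of generation records, each with \code{bestFitness}
#'   and \code{averageFitness}.
#' @param scalingFactor 2 (single-kind fitness) or 4 (product fitness).
#' @param currentBudget Current per-individual budget.
#' @param maxBudget Budget cap.
#' @return List with \code{double} (logical) and \code{budget} (the budget
#'   to use next generation).
#' @export
shouldDoubleBudget <- function(history, scalingFactor, currentBudget,
                               maxBudget) {
  t <- length(history)
  if (t < 3L)
    return(list(double = FALSE, budget = currentBudget))
  bestT <- history[[t]]$bestFitness
  bestP <- history[[t - 1L]]$bestFitness
  avgT <- history[[t]]$averageFitness
  avgPP <- history[[t - 2L]]$averageFitness
  fire <- (bestT > bestP) && (scalingFactor * avgT > avgPP)
  budget <- if (fire) min(2 * currentBudget, maxBudget) else currentBudget
  list(double = fire, budget = budget)
}

#' Optimization configuration
#'
#' @param nParams 3 or 5 (which parameters are fitted; 2 for a bare LJ pair).
#' @param fitnessKind \code{"RDF"}, \code{"EDF"} or \code{"RxE"}.
#' @param threshold Convergence bar: optimization stops when the best
#'   fitness of a generation is at or below it (for \code{"RxE"}, pass the
#'   product of the two single-kind thresholds).
#' @param populationSize Individuals per generation (default 12 x nParams).
#' @param initialStep Initial CMA-ES step size in scaled space (default 0.01).
#' @param scalingFactor Budget-rule factor; defaults to 4 for \code{"RxE"},
#'   2 otherwise.
#' @param initialBudgetPs Initial per-individual sampling budget, nominal ps
#'   (default 250).
#' @param maxBudgetPs Budget cap, nominal ps (default 1e5, i.e. 100 ns).
#' @param masterSeed Master seed; per-individual streams are derived from it.
#' @param maxGenerations Safety cap on generations.
#' @param sigmaFloor Lower clamp for per-bin SDs in the fitness (see
#'   \code{\link{fitnessEq1}}; default 0 = off). Use the same floor when
#'   deriving the threshold.
#' @return A list of optimizer settings.
#' @export
optimizationConfig <- function(nParams, fitnessKind = c("EDF", "RDF", "RxE"),
                               threshold,
                               populationSize = 12L * nParams,
                               initialStep = 0.01,
                               scalingFactor = NULL,
                               initialBudgetPs = 250,
                               maxBudgetPs = 1e5,
                               masterSeed = 1L,
                               maxGenerations = 50L,
                               sigmaFloor = 0) {
  fitnessKind <- match.arg(fitnessKind)
  if (is.null(scalingFactor))
    scalingFactor <- if (fitnessKind == "RxE") 4 else 2
  stopifnot(populationSize >= 4, initialStep > 0, scalingFactor > 1,
            initialBudgetPs > 0, initialBudgetPs <= maxBudgetPs)
  list(nParams = as.integer(nParams), fitnessKind = fitnessKind,
       threshold = threshold, populationSize = as.integer(populationSize),
       initialStep = initialStep, scalingFactor = scalingFactor,
       initialBudgetPs = initialBudgetPs, maxBudgetPs = maxBudgetPs,
       masterSeed = as.integer(masterSeed),
       maxGenerations = as.integer(maxGenerations),
       sigmaFloor = sigmaFloor)
}

#' Distribution-matching parameter optimization
#'
#' The main loop: per generation, CMA-ES proposes \code{populationSize}
#' search vectors around the current distribution (initial mean = the scaled
#' start, initial covariance = initialStep^2 I); each individual is sampled
#' at the current budget and its distribution function(s) compared with the
#' targets through the uncertainty-weighted fitness; the run stops when the
#' generation's best fitness reaches the threshold, else the budget-doubling
#' rule and the CMA-ES update are applied and the loop continues. Individuals
#' whose parameters are invalid (or whose evaluation fails) receive a penalty
#' fitness (10 x the largest finite fitness seen) so the population size
#' stays constant. Fully reproducible from \code{masterSeed}.
#'
#' @param targetDfs Named list of target \linkS4class{DistributionFunction}s
#'   with uncertainties: \code{$rdf} and/or \code{$edf} as the fitness kind
#'   requires.
#' @param start Starting \linkS4class{ForceFieldParams} (or a bare numeric
#'   search vector).
#' @param config An \code{\link{optimizationConfig}}.
#' @param evaluator Closure \code{function(searchVector, budgetPs, seed)}
#'   returning a named list with \code{$rdf} and/or \code{$edf} candidate
#'   distribution functions (with uncertainties), e.g. from
#'   \code{\link{makeSamplerEvaluator}}. It must signal an error for
#'   unphysical parameter vectors.
#' @param toParams Conversion from a search vector to
#'   \linkS4class{ForceFieldParams} used for reporting; default uses
#'   \code{\link{fromSearchVector}} with \code{start} as reference.
#' @return An \linkS4class{OptimizationResult}.
#' @export
optimizeParameters <- function(targetDfs, start, config, evaluator,
                               toParams = NULL) {
  x0 <- if (is(start, "ForceFieldParams")) {
    if (config$nParams %in% c(3L, 5L))
      as.numeric(toSearchVector(start, config$nParams))
    else c(start@sigma, start@epsilon)        # bare LJ pair
  } else as.numeric(start)
  if (is.null(toParams)) {
    ref <- if (is(start, "ForceFieldParams")) start else NULL
    toParams <- function(v) {
      if (length(v) %in% c(3L, 5L) && !is.null(ref)) fromSearchVector(v, ref)
      else forceFieldParams(v[[1]], v[[2]],
                            if (length(v) >= 3) v[[3]] else 0)
    }
  }
  kind <- config$fitnessKind
  needRdf <- kind %in% c("RDF", "RxE")
  needEdf <- kind %in% c("EDF", "RxE")
  if (needRdf && is.null(targetDfs$rdf)) stop("targetDfs$rdf required")
  if (needEdf && is.null(targetDfs$edf)) stop("targetDfs$edf required")

  sf <- if (is.null(config$sigmaFloor)) 0 else config$sigmaFloor
  evalFitness <- function(cand) {
    f <- 1
    if (needRdf) f <- f * fitnessEq1(cand$rdf, targetDfs$rdf, sigmaFloor = sf)
    if (needEdf) f <- f * fitnessEq1(cand$edf, targetDfs$edf, sigmaFloor = sf)
    f
  }

  set.seed(deriveSeed(config$masterSeed, 0L, 0L))
  st <- cmaInit(x0, config$initialStep, config$populationSize)
  budget <- config$initialBudgetPs
  history <- list()
  totalBudget <- 0
  bestF <- Inf
  bestX <- x0
  maxFinite <- 1
  converged <- FALSE

  for (gen in seq_len(config$maxGenerations)) {
    X <- cmaAsk(st)
    fits <- numeric(config$populationSize)
    for (i in seq_len(config$populationSize)) {
      sd_i <- deriveSeed(config$masterSeed, gen, i)
      f <- tryCatch({
        cand <- evaluator(X[, i], budget, sd_i)
        evalFitness(cand)
      }, error = function(e) {
        message(sprintf("generation %d individual %d penalized: %s",
                        gen, i, conditionMessage(e)))
        NA_real_
      })
      fits[i] <- f
      totalBudget <- totalBudget + budget
    }
    if (any(is.finite(fits))) maxFinite <- max(maxFinite,
                                               max(fits[is.finite(fits)]))
    fits[!is.finite(fits)] <- maxFinite * 10
    genBest <- min(fits)
    rec <- list(generation = gen, budgetPs = budget, individuals = X,
                fitnesses = fits, bestFitness = genBest,
                averageFitness = mean(fits))
    history[[gen]] <- rec
    if (genBest < bestF) {
      bestF <- genBest
      bestX <- X[, which.min(fits)]
    }
    if (genBest <= config$threshold) { converged <- TRUE; break }
    budget <- shouldDoubleBudget(history, config$scalingFactor,
                                 budget, config$maxBudgetPs)$budget
    cmaTell(st, X, fits)
  }

  new("OptimizationResult", bestParams = toParams(bestX),
      bestFitness = bestF, converged = converged,
      threshold = as.numeric(config$threshold), history = history,
      totalBudget = totalBudget, fitnessKind = kind)
}

#' Generation summary of an optimization run
#'
#' @param result An \linkS4class{OptimizationResult}.
#' @return A data.frame with one row per generation: budget, best and
#'   average fitness.
#' @export
generationSummary <- function(result) {
  do.call(rbind, lapply(result@history, function(r)
    data.frame(generation = r$generation, budgetPs = r$budgetPs,
               bestFitness = r$bestFitness,
               averageFitness = r$averageFitness)))
}

#' Per-parameter error ratios against a reference set
#'
#' (fitted - reference) / reference, per parameter, the standard way to
#' report how close a fitted parameter set came to the generating one.
#'
#' @param fitted,reference \linkS4class{ForceFieldParams}.
#' @return Named numeric vector (sigma, epsilon, q, d, a).
#' @export
errorRatios <- function(fitted, reference) {
  f <- c(fitted@sigma, fitted@epsilon, fitted@q, fitted@d, fitted@a)
  r <- c(reference@sigma, reference@epsilon, reference@q, reference@d,
         reference@a)
  stats::setNames((f - r) / r, c("sigma", "epsilon", "q", "d", "a"))
}
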