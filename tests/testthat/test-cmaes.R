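sphereRun <- function(seed, n = 5, lambda = 60, sigma0 = 0.01,
                      maxGen = 200, tol = 1e-10, transform = identity) {
  set.seed(seed)
  st <- cmaInit(rep(1, n), sigma0, lambda)
  best <- Inf; gen <- 0; means <- list()
  while (gen < maxGen && best > tol) {
    gen <- gen + 1
    X <- cmaAsk(st)
    f <- colSums(X^2)
    best <- min(best, min(f))
    cmaTell(st, X, transform(f))
    means[[gen]] <- st$mean
  }
  list(gen = gen, best = best, means = means)
}

test_that("CMA-ES solves the 5-D sphere from a tiny initial step", {
  r <- sphereRun(1)
  expect_lt(r$best, 1e-10)
  expect_lte(r$gen, 200)
})

test_that("the update depends only on fitness rankings", {
  a <- sphereRun(42, maxGen = 25, tol = 0)
  b <- sphereRun(42, maxGen = 25, tol = 0, transform = exp)
  expect_equal(a$means, b$means, tolerance = 1e-12)
  # rank-degenerate case: equal fitnesses move the mean to the
  # recombination mean of the first mu proposals (stable ordering)
  set.seed(5)
  st <- cmaInit(c(0, 0), 0.5, 8)
  X <- cmaAsk(st)
  Y <- attr(X, "Y")
  cmaTell(st, X, rep(1, 8))
  expected <- as.numeric(0.5 * (Y[, 1:4] %*% st$weights))
  expect_equal(st$mean, expected, tolerance = 1e-12)
})

test_that("population sizing follows 12 x the number of parameters", {
  cfg5 <- optimizationConfig(5, "EDF", threshold = 1)
  expect_identical(cfg5$populationSize, 60L)
  expect_identical(optimizationConfig(3, "RDF", threshold = 1)$populationSize,
                   36L)
  expect_identical(cfg5$initialStep, 0.01)
  expect_identical(optimizationConfig(5, "RxE", threshold = 1)$scalingFactor,
                   4)
  expect_identical(cfg5$scalingFactor, 2)
  expect_identical(cfg5$initialBudgetPs, 250)
  expect_identical(cfg5$maxBudgetPs, 1e5)
})

test_that("the budget-doubling rule follows its truth table and cap", {
  rec <- function(best, avg) list(bestFitness = best, averageFitness = avg)
  # fewer than three generations: inapplicable
  h <- list(rec(1, 2), rec(1.2, 2))
  expect_false(shouldDoubleBudget(h, 2, 250, 1e5)$double)
  # best improved: never fires regardless of averages
  h <- list(rec(2, 10), rec(1.5, 10), rec(1.4, 100))
  expect_false(shouldDoubleBudget(h, 2, 250, 1e5)$double)
  # printed example: best worsened and 2 * 0.9 = 1.8 > 1.5 -> double
  h <- list(rec(0.9, 1.5), rec(1.0, 1.2), rec(1.2, 0.9))
  out <- shouldDoubleBudget(h, 2, 250, 1e5)
  expect_true(out$double)
  expect_equal(out$budget, 500)
  # averages comfortable: no doubling even though best worsened
  h <- list(rec(0.9, 5.0), rec(1.0, 1.2), rec(1.2, 0.9))
  expect_false(shouldDoubleBudget(h, 2, 250, 1e5)$double)
  # scaling factor 4 widens the trigger: 2 * 0.9 < 3.0 but 4 * 0.9 > 3.0
  h2 <- list(rec(0.9, 3.0), rec(1.0, 1.2), rec(1.2, 0.9))
  expect_false(shouldDoubleBudget(h2, 2, 250, 1e5)$double)
  expect_true(shouldDoubleBudget(h2, 4, 250, 1e5)$double)
  # the cap: doubling never exceeds, and at the cap it stays put
  h <- list(rec(0.9, 1.5), rec(1.0, 1.2), rec(1.2, 0.9))
  expect_equal(shouldDoubleBudget(h, 2, 6e4, 1e5)$budget, 1e5)
  expect_equal(shouldDoubleBudget(h, 2, 1e5, 1e5)$budget, 1e5)
})

test_that("the optimization loop is reproducible and bookkept", {
  # cheap analytic evaluator: a deterministic pseudo-DF whose values depend
  # smoothly on the parameters, plus seed-dependent noise
  edges <- seq(0, 1, 0.25)
  mkdf <- function(v, seed) {
    set.seed(seed)
    makeDF(abs(v[1] * (1:4) / 4 + v[2] + rnorm(4, 0, 1e-3)), edges,
           kind = "energy", unc = rep(0.05, 4), nBlocks = 10)
  }
  target <- mkdf(c(0.5, 1.0), 1234)
  ev <- function(v, budgetPs, seed) {
    if (v[2] < 0) stop("unphysical")
    list(edf = mkdf(v, seed))
  }
  cfg <- optimizationConfig(2, "EDF", threshold = 0.05,
                            populationSize = 8, initialStep = 0.05,
                            initialBudgetPs = 250, masterSeed = 9,
                            maxGenerations = 40)
  r1 <- optimizeParameters(list(edf = target), c(0.7, 1.2), cfg, ev,
                           toParams = function(v)
                             forceFieldParams(v[1], v[2]))
  r2 <- optimizeParameters(list(edf = target), c(0.7, 1.2), cfg, ev,
                           toParams = function(v)
                             forceFieldParams(v[1], v[2]))
  expect_identical(generationSummary(r1), generationSummary(r2))
  expect_identical(r1@bestParams@sigma, r2@bestParams@sigma)
  gs <- generationSummary(r1)
  # budget is non-decreasing and capped
  expect_true(all(diff(gs$budgetPs) >= 0))
  expect_true(all(gs$budgetPs <= cfg$maxBudgetPs))
  # per-generation invariants of the records
  for (rec in r1@history) {
    expect_equal(rec$bestFitness, min(rec$fitnesses))
    expect_equal(rec$averageFitness, mean(rec$fitnesses))
  }
  # convergence flag consistent with the threshold
  expect_identical(r1@converged, r1@bestFitness <= r1@threshold)
  expect_true(r1@converged)   # self-consistent target is reachable
})

test_that("invalid individuals are penalized, not fatal", {
  edges <- seq(0, 1, 0.5)
  target <- makeDF(c(1, 1), edges, kind = "energy", unc = c(0.1, 0.1),
                   nBlocks = 10)
  ev <- function(v, budgetPs, seed) {
    if (v[1] < 0.65) stop("unphysical parameters")    # frequent failures
    makeDFv <- makeDF(abs(v[1:2]), edges, kind = "energy",
                      unc = c(0.1, 0.1), nBlocks = 10)
    list(edf = makeDFv)
  }
  cfg <- optimizationConfig(2, "EDF", threshold = 1e-6, populationSize = 6,
                            initialStep = 0.1, masterSeed = 3,
                            maxGenerations = 4)
  expect_message(
    r <- optimizeParameters(list(edf = target), c(0.7, 1.0), cfg, ev,
                            toParams = function(v)
                              forceFieldParams(max(v[1], 0.01), abs(v[2]))),
    "penalized")
  expect_length(r@history[[1]]$fitnesses, 6L)
  expect_false(r@converged)                 # hit maxGenerations
  expect_length(r@history, 4L)
})

test_that("a start at the generating optimum converges immediately", {
  edges <- seq(0, 1, 0.25)
  mk <- function(seed) {
    set.seed(seed)
    makeDF(abs(1 + rnorm(4, 0, 0.01)), edges, kind = "energy",
           unc = rep(0.02, 4), nBlocks = 10)
  }
  reps <- lapply(1:3, mk)
  thr <- dfThreshold(reps)
  ev <- function(v, budgetPs, seed) list(edf = mk(seed))
  cfg <- optimizationConfig(2, "EDF", threshold = thr$value,
                            populationSize = 6, initialStep = 0.01,
                            masterSeed = 21, maxGenerations = 10)
  r <- optimizeParameters(list(edf = reps[[1]]), c(1, 1), cfg, ev,
                          toParams = function(v) forceFieldParams(1, 1))
  expect_true(r@converged)
  expect_lte(length(r@history), 3L)
})
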