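test_that("box initialization reproduces density arithmetic and determinism", {
  w <- tip3pParams()
  b <- initializeBox(1000, 0.9971, "water3", 298, params = w, seed = 1)
  expect_equal(boxLength(b$box), 3.107, tolerance = 1e-3)
  # 8 molecules on a 2x2x2 lattice: all centers distinct, inside the box
  p <- forceFieldParams(0.34, 1)
  b8 <- initializeBox(8, 0.4, "lj", 150, params = p, reduced = TRUE, seed = 2)
  expect_equal(nrow(b8$coords), 8)
  expect_true(all(b8$coords >= 0 & b8$coords <= boxLength(b8$box)))
  b8b <- initializeBox(8, 0.4, "lj", 150, params = p, reduced = TRUE, seed = 2)
  expect_identical(b8$coords, b8b$coords)
  expect_error(
    initializeBox(8, 0.4, "lj", 150, params = p, reduced = TRUE, seed = 2,
                  cutoff = 5), "cutoff")
})

test_that("no two initial molecules overlap below 0.8 sigma", {
  p <- forceFieldParams(0.34, 1)
  init <- initializeBox(64, 0.7, "lj", 150, params = p, reduced = TRUE,
                        seed = 5)
  L <- boxLength(init$box)
  dmin <- Inf
  for (i in 1:63) for (j in (i + 1):64) {
    d <- minImage(init$coords[i, ] - init$coords[j, ], L)
    dmin <- min(dmin, sqrt(sum(d^2)))
  }
  expect_gte(dmin, 0.8 * 0.34)
})

test_that("the sampler is deterministic and conserves its energy ledger", {
  p <- forceFieldParams(0.34, 0.8)
  init <- initializeBox(27, 0.4, "lj", 200, params = p, reduced = TRUE,
                        seed = 3)
  cfg <- samplerConfig(nSweepsEquil = 200, nSweepsProd = 2000,
                       sampleEvery = 10, cutoff = 0.8, seed = 42)
  t1 <- runMetropolis(init$box, init$coords, p, cfg)
  t2 <- runMetropolis(init$box, init$coords, p, cfg)
  expect_identical(t1@coords, t2@coords)
  # cached vs recomputed total energy (checked every 1000 sweeps internally)
  expect_lte(t1@meta$maxEnergyDrift, 1e-8)
  # final cached energy equals a fresh full recomputation
  lastFrame <- t1@coords[, , nFrames(t1)]
  expect_equal(totalEnergy(lastFrame, t1@box, p, cutoff = 0.8),
               t1@meta$finalEnergy, tolerance = 1e-8)
})

test_that("total energy matches closed forms and minimum-image invariance", {
  p <- forceFieldParams(0.34, 1.3)
  box <- new("SimulationBox", L = 3.0, n = 2L, species = "lj",
             temperature = 100)
  r <- 2^(1 / 6) * 0.34
  coords <- rbind(c(0.5, 0.5, 0.5), c(0.5 + r, 0.5, 0.5))
  rc <- 1.02
  shiftConst <- 4 * 1.3 * ((0.34 / rc)^12 - (0.34 / rc)^6)
  expect_equal(totalEnergy(coords, box, p, cutoff = rc),
               -1.3 - shiftConst, tolerance = 1e-12)
  # doubling the box leaves the minimum-image pair unchanged
  box2 <- new("SimulationBox", L = 6.0, n = 2L, species = "lj",
              temperature = 100)
  expect_equal(totalEnergy(coords, box2, p, cutoff = rc),
               totalEnergy(coords, box, p, cutoff = rc))
  # a single molecule has zero energy
  box1 <- new("SimulationBox", L = 3.0, n = 1L, species = "lj",
              temperature = 100)
  expect_equal(totalEnergy(coords[1, , drop = FALSE], box1, p), 0)
  # near-overlapping sites are rejected
  expect_error(totalEnergy(rbind(c(0, 0, 0), c(1e-8, 0, 0)), box, p),
               "overlap")
})

test_that("an LJ fluid's mean energy agrees with an independent R sampler", {
  sigma <- 0.34; eps <- 0.9; Tk <- 1.5 * eps / 0.0083144621
  n <- 20; rhoStar <- 0.1; rcut <- 0.9
  p <- forceFieldParams(sigma, eps)
  init <- initializeBox(n, rhoStar, "lj", Tk, params = p, reduced = TRUE,
                        seed = 4)
  traj <- runMetropolis(init$box, init$coords, p,
                        samplerConfig(nSweepsEquil = 400, nSweepsProd = 3000,
                                      sampleEvery = 3, cutoff = rcut,
                                      seed = 10))
  ePkg <- vapply(seq_len(nFrames(traj)), function(f)
    totalEnergy(traj@coords[, , f], traj@box, p, cutoff = rcut), 0)
  eOracle <- naiveLJMC(init$coords, boxLength(init$box), sigma, eps, Tk,
                       rcut, nSweeps = 600, dTrans = 0.25, seed = 99)
  eOracle <- eOracle[-(1:150)]
  blockSd <- function(x, nb = 10) {
    bm <- colMeans(matrix(x[seq_len(length(x) - length(x) %% nb)], ncol = nb))
    sqrt(mean((bm - mean(bm))^2))
  }
  joint <- sqrt(blockSd(ePkg)^2 + blockSd(eOracle)^2)
  expect_lt(abs(mean(ePkg) - mean(eOracle)), 4 * joint + 0.05 * abs(mean(eOracle)))
})

test_that("ideal-gas sampling recovers flat g(r) and P = rho k T", {
  p0 <- forceFieldParams(0.34, 0)   # epsilon = 0, q = 0: no interactions
  init <- initializeBox(64, 0.3, "lj", 200, params = p0, reduced = TRUE,
                        seed = 6)
  # every move has dU = 0, so acceptance is exactly 1 and the extreme-rate
  # warning fires
  expect_warning(
    traj <- runMetropolis(init$box, init$coords, p0,
                          samplerConfig(nSweepsEquil = 200,
                                        nSweepsProd = 1500,
                                        sampleEvery = 5, cutoff = 0.9,
                                        seed = 11)),
    "acceptance")
  expect_equal(traj@meta$acceptanceRate, 1)
  g <- blockDistribution(traj,
                         function(t) rdf(t, rdfBinEdges(0.1, 1.0)), 10)
  vals <- dfValues(g); unc <- dfUncertainties(g)
  use <- binEdges(g)[-1] > 0.3     # skip tiny-count inner shells
  expect_true(all(abs(vals[use] - 1) <= 3 * pmax(unc[use], 0.05)))
  pr <- virialPressure(traj, p0)
  expect_equal(pr$pressure, pr$idealPart, tolerance = 1e-10)

  # pressure is intensive: duplicated system at the same state point
  init2 <- initializeBox(128, 0.3, "lj", 200, params = p0, reduced = TRUE,
                         seed = 7)
  traj2 <- suppressWarnings(
    runMetropolis(init2$box, init2$coords, p0,
                  samplerConfig(nSweepsEquil = 100, nSweepsProd = 500,
                                sampleEvery = 5, cutoff = 0.9, seed = 12)))
  pr2 <- virialPressure(traj2, p0)
  expect_equal(pr2$pressure, pr$pressure, tolerance = 1e-6)
})

test_that("the two-particle virial equals the hand-computed r.f", {
  p <- forceFieldParams(0.34, 1.1)
  r <- 0.4
  box <- new("SimulationBox", L = 3.0, n = 2L, species = "lj",
             temperature = 150)
  coords <- array(0, dim = c(2, 3, 1))
  coords[1, , 1] <- c(1, 1, 1)
  coords[2, , 1] <- c(1 + r, 1, 1)
  traj <- new("Trajectory", coords = coords, box = box)
  pr <- virialPressure(traj, p, cutoff = 1.0, nBlocks = 0L)
  fr <- 24 * 1.1 * (2 * (0.34 / r)^12 - (0.34 / r)^6) / r   # dU/dr * -1
  expected <- (2 / 27 * 0.0083144621 * 150 + fr * r / (3 * 27)) * 16.6054
  expect_equal(pr$pressure, expected, tolerance = 1e-9)
})

test_that("two-particle visit distribution obeys the Boltzmann measure", {
  # detailed-balance smoke test: the pair-distance distribution must follow
  # r^2 exp(-u/kT) for r below L/2
  p <- forceFieldParams(0.34, 1.2)
  Tk <- 150
  box <- new("SimulationBox", L = 1.4, n = 2L, species = "lj",
             temperature = Tk)
  coords <- rbind(c(0.3, 0.3, 0.3), c(0.72, 0.3, 0.3))
  rcut <- 0.7
  traj <- runMetropolis(box, coords, p,
                        samplerConfig(nSweepsEquil = 2000,
                                      nSweepsProd = 1e5, sampleEvery = 20,
                                      cutoff = rcut, seed = 21))
  d <- traj@coords[1, , ] - traj@coords[2, , ]
  d <- d - 1.4 * round(d / 1.4)
  r <- sqrt(colSums(d^2))
  edges <- seq(0.3, 0.7, by = 0.05)
  obs <- table(cut(r[r >= 0.3 & r < 0.7], edges))
  # expected bin mass: integrate r^2 exp(-u(r)/kT) across each bin (the
  # Boltzmann factor varies steeply over the repulsive wall)
  uShift <- 4 * 1.2 * ((0.34 / rcut)^12 - (0.34 / rcut)^6)
  dens <- function(x) x^2 * exp(-(4 * 1.2 * ((0.34 / x)^12 - (0.34 / x)^6) -
                                    uShift) / (0.0083144621 * Tk))
  pExp <- vapply(seq_len(length(edges) - 1), function(b)
    integrate(dens, edges[b], edges[b + 1])$value, 0)
  pExp <- pExp / sum(pExp)
  keep <- pExp > 1e-4
  expect_gt(suppressWarnings(
    chisq.test(as.numeric(obs[keep]), p = pExp[keep] / sum(pExp[keep]))
  )$p.value, 0.01)
})
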