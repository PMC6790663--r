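test_that("radial bin schemes cover the studied definitions", {
  expect_length(binEdges(rdfBinEdges(0.01, 1.5)), 151)    # 150 bins
  expect_length(binWidths(rdfBinEdges(0.5, 1.5)), 3)
  schemes <- lapply(rdfBinSizes(), rdfBinEdges)
  expect_length(schemes, 11)
  expect_true(all(vapply(schemes, function(s)
    abs(max(binEdges(s)) - 1.5) < 1e-9, TRUE)))
  expect_error(rdfBinEdges(-0.1), "> 0")
  expect_message(rdfBinEdges(0.4, 1.5), "truncat")
})

test_that("energy bin schemes follow the five-region definition table", {
  toKj <- 4.184
  sc <- edfBinEdges(1, 8, 5)
  e <- binEdges(sc) / toKj
  # exact region boundaries
  for (b in c(-30.02, -0.22, -0.02, 0.02, 0.22, 30.22))
    expect_true(any(abs(e - b) < 1e-9))
  # j = 8: the near-zero region is one bin of width 0.04 kcal/mol
  mid <- which(abs(e + 0.02) < 1e-9)
  expect_equal(e[mid + 1] - e[mid], 0.04, tolerance = 1e-9)
  # outer region has 29.8 / 0.04 = 745 bins
  expect_equal(sum(e < -0.22 - 1e-9), 745)
  # k = 5: (0.02, 0.22) at 0.04 kcal/mol = 5 bins
  expect_equal(sum(e > 0.02 + 1e-9 & e < 0.22 + 1e-9), 5)
  # i = 5: (-0.22, -0.02) at 0.04 kcal/mol = 5 bins (5 left edges)
  e5 <- binEdges(edfBinEdges(5, 1, 1)) / toKj
  expect_equal(sum(e5 >= -0.22 - 1e-9 & e5 < -0.02 - 1e-9), 5)
  expect_error(edfBinEdges(0, 1, 1), "1..5")
  expect_error(edfBinEdges(1, 9, 1), "1..8")
})

test_that("bin definition IDs are the printed formula and bijective", {
  expect_identical(binDefinitionId(1, 8, 5), 40L)
  expect_identical(binDefinitionId(1, 1, 1), 1L)
  expect_identical(binDefinitionId(5, 8, 5), 200L)
  ids <- c()
  for (i in 1:5) for (j in 1:8) for (k in 1:5)
    ids <- c(ids, binDefinitionId(i, j, k))
  expect_identical(sort(ids), 1:200)
  expect_length(ids, 200)
  expect_error(binDefinitionId(6, 1, 1), "i in 1..5")
  # the scheme file records its triple
  expect_identical(edfBinEdges(1, 8, 5)@meta$id, 40L)
})

test_that("rdf matches the naive double-loop oracle exactly", {
  traj <- ljFixtureTraj(n = 8, rhoStar = 0.3, seed = 2, frames = 5)
  sch <- rdfBinEdges(0.1, floor(10 * boxLength(traj) / 2) / 10)
  expect_equal(dfValues(rdf(traj, sch)), naiveRdf(traj, binEdges(sch)),
               tolerance = 1e-12)
  # water as well (center of mass, 3 sites)
  w <- tip3pParams()
  init <- initializeBox(8, 0.9, "water3", 298, params = w, seed = 3)
  wtraj <- runMetropolis(init$box, init$coords, w,
                         samplerConfig(nSweepsEquil = 50, nSweepsProd = 25,
                                       sampleEvery = 5,
                                       cutoff = boxLength(init$box) / 2,
                                       seed = 4))
  wsch <- rdfBinEdges(0.05, 0.3)
  expect_equal(dfValues(rdf(wtraj, wsch)), naiveRdf(wtraj, binEdges(wsch)),
               tolerance = 1e-12)
  expect_error(rdf(wtraj, rdfBinEdges(0.05, 1.5)), "L/2")
  expect_error(rdf(wtraj, edfBinEdges(1, 1, 1)), "radial")
})

test_that("a single known pair lands in one rdf bin at the predicted height", {
  box <- new("SimulationBox", L = 4, n = 2L, species = "lj",
             temperature = 100)
  coords <- array(0, dim = c(2, 3, 1))
  coords[1, , 1] <- c(1, 1, 1); coords[2, , 1] <- c(1.47, 1, 1)
  traj <- new("Trajectory", coords = coords, box = box)
  sch <- rdfBinEdges(0.1, 2.0)
  vals <- dfValues(rdf(traj, sch))
  hit <- which(vals > 0)
  expect_identical(hit, 5L)                        # r = 0.47 in [0.4, 0.5)
  rho0 <- 2 / 64
  expect_equal(vals[5], 2 / (1 * 2 * 4 * pi * 0.45^2 * 0.1 * rho0),
               tolerance = 1e-12)
  expect_true(all(vals[-5] == 0))
})

test_that("edf matches the naive oracle and conserves pair mass", {
  p <- forceFieldParams(0.34, 0.8)
  traj <- ljFixtureTraj(n = 8, rhoStar = 0.3, seed = 5, frames = 5, params = p)
  rcut <- traj@meta$cutoff
  sch <- edfBinEdges(1, 8, 5)
  d <- edf(traj, p, sch, cutoff = rcut)
  expect_equal(dfValues(d), naiveEdf(traj, p, binEdges(sch), rcut),
               tolerance = 1e-12)
  # integral = mean number of in-range partners per molecule (both orderings)
  L <- boxLength(traj)
  nPairsInRange <- 0
  for (f in seq_len(nFrames(traj))) {
    fr <- traj@coords[, , f]
    for (i in 1:7) for (j in (i + 1):8) {
      dd <- minImage(fr[i, ] - fr[j, ], L)
      if (sqrt(sum(dd^2)) < rcut) nPairsInRange <- nPairsInRange + 1
    }
  }
  mass <- sum(dfValues(d) * binWidths(d)) +
    d@meta$droppedFraction * sum(dfValues(d) * binWidths(d)) /
      max(1 - d@meta$droppedFraction, 1e-12)
  expect_equal(mass, 2 * nPairsInRange / (nFrames(traj) * 8),
               tolerance = 1e-9)
})

test_that("an ideal gas concentrates all edf mass in the zero bin", {
  p0 <- forceFieldParams(0.3, 0)
  fx <- generateFixture("ideal_gas", p0, n = 30, density = 0.2,
                        reduced = TRUE, frames = 10, seed = 8)
  sch <- edfBinEdges(1, 1, 1)
  d <- edf(fx$trajectory, p0, sch, cutoff = 0.9)
  hot <- which(dfValues(d) > 0)
  expect_length(hot, 1L)
  e <- binEdges(sch)
  expect_true(e[hot] <= 0 && 0 < e[hot + 1])
  expect_equal(d@meta$droppedFraction, 0)
})

test_that("two constructed molecules give the closed-form edf height", {
  p <- forceFieldParams(0.34, 1.3)
  box <- new("SimulationBox", L = 4, n = 2L, species = "lj",
             temperature = 100)
  coords <- array(0, dim = c(2, 3, 1))
  r <- 2^(1 / 6) * 0.34
  coords[1, , 1] <- c(1, 1, 1); coords[2, , 1] <- c(1 + r, 1, 1)
  traj <- new("Trajectory", coords = coords, box = box)
  sch <- edfBinEdges(1, 1, 1)
  rcut <- 1.0
  u <- naiveMolPairEnergy(matrix(coords[1, , 1], 1),
                          matrix(coords[2, , 1], 1), p, 4, rcut)
  d <- edf(traj, p, sch, cutoff = rcut)
  hit <- which(dfValues(d) > 0)
  expect_length(hit, 1L)
  e <- binEdges(sch)
  expect_true(e[hit] <= u && u < e[hit + 1])
  expect_equal(dfValues(d)[hit], 2 / (1 * 2 * (e[hit + 1] - e[hit])),
               tolerance = 1e-12)
})

test_that("block statistics use the population SD and are consistent", {
  # two constructed blocks with values {1, 3} -> mean 2, SD 1
  box <- new("SimulationBox", L = 4, n = 2L, species = "lj",
             temperature = 100)
  coords <- array(0, dim = c(2, 3, 2))
  coords[1, , 1] <- c(1, 1, 1); coords[2, , 1] <- c(1.45, 1, 1)
  coords[1, , 2] <- c(1, 1, 1); coords[2, , 2] <- c(1.45, 1, 1)
  traj <- new("Trajectory", coords = coords, box = box)
  fake <- local({
    i <- 0
    function(t) {
      i <<- i + 1
      makeDF(rep(if (i == 1) 1 else 3, 4), seq(0, 1, 0.25))
    }
  })
  d <- blockDistribution(traj, fake, nBlocks = 2)
  expect_equal(dfValues(d), rep(2, 4))
  expect_equal(dfUncertainties(d), rep(1, 4))

  # identical blocks -> zero uncertainty
  traj4 <- new("Trajectory",
               coords = array(rep(coords[, , 1], 4), dim = c(2, 3, 4)),
               box = box)
  sch <- rdfBinEdges(0.1, 1.9)
  db <- blockDistribution(traj4, function(t) rdf(t, sch), nBlocks = 2)
  expect_equal(dfUncertainties(db), rep(0, 19))
  # mean over equal blocks equals the single-pass value
  expect_equal(dfValues(db), dfValues(rdf(traj4, sch)))
  expect_equal(nBlocks(db), 2L)
  expect_error(blockDistribution(traj4, function(t) rdf(t, sch), 1), ">= 2")
  expect_message(blockDistribution(traj4, function(t) rdf(t, sch), 3),
                 "trailing")
})

test_that("ideal-gas g(r) is flat at large r", {
  p0 <- forceFieldParams(0.3, 0)
  fx <- generateFixture("ideal_gas", p0, n = 60, density = 0.15,
                        reduced = TRUE, frames = 400, seed = 9)
  L <- boxLength(fx$trajectory)
  sch <- rdfBinEdges(0.1, floor(L / 2 * 10) / 10)
  g <- rdf(fx$trajectory, sch)
  far <- (binEdges(sch)[-1] + binEdges(sch)[-length(binEdges(sch))]) / 2 >
    0.3 * L
  expect_lt(mean(abs(dfValues(g)[far] - 1)), 0.02)
})
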