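# Naive reference implementations, written straight from the defining
# formulas and kept independent of the package's compiled paths.

minImage <- function(d, L) d - L * round(d / L)

# Truncated-shifted site-site energy of two molecules under minimum image.
# mols are site matrices (m x 3); LJ acts between first sites only.
naiveMolPairEnergy <- function(a, b, params, L, rcut, shift = TRUE) {
  kC <- 138.935458
  m <- nrow(a)
  qs <- if (m == 3) c(params@q, -params@q / 2, -params@q / 2) else 0
  dOO <- minImage(a[1, ] - b[1, ], L)
  rOO <- sqrt(sum(dOO^2))
  e <- 0
  if (rOO < rcut) {
    lj <- function(r) 4 * params@epsilon *
      ((params@sigma / r)^12 - (params@sigma / r)^6)
    e <- e + lj(rOO) - if (shift && is.finite(rcut)) lj(rcut) else 0
  }
  if (m == 3 && params@q != 0) {
    for (i in 1:3) for (j in 1:3) {
      d <- minImage(a[i, ] - b[j, ], L)
      r <- sqrt(sum(d^2))
      if (r < rcut)
        e <- e + kC * qs[i] * qs[j] *
          (1 / r - if (shift && is.finite(rcut)) 1 / rcut else 0)
    }
  }
  e
}

naiveComFrame <- function(frame, m, masses) {
  n <- nrow(frame) / m
  t(vapply(seq_len(n), function(k) {
    rows <- ((k - 1) * m + 1):(k * m)
    colSums(frame[rows, , drop = FALSE] * masses) / sum(masses)
  }, numeric(3)))
}

# g(r) by explicit double loop over frames and ordered pairs.
naiveRdf <- function(traj, edges) {
  m <- if (species(traj) == "water3") 3L else 1L
  masses <- if (m == 3L) c(15.9994, 1.00794, 1.00794) else 1
  L <- boxLength(traj)
  n <- nMolecules(traj)
  nf <- nFrames(traj)
  counts <- numeric(length(edges) - 1)
  for (f in seq_len(nf)) {
    com <- naiveComFrame(traj@coords[, , f, drop = FALSE][, , 1], m, masses)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      r <- sqrt(sum(minImage(com[i, ] - com[j, ], L)^2))
      b <- findInterval(r, edges, rightmost.closed = FALSE)
      if (b >= 1 && b <= length(counts) && r < edges[length(edges)])
        counts[b] <- counts[b] + 1
    }
  }
  rho0 <- n / L^3
  rmid <- (edges[-1] + edges[-length(edges)]) / 2
  counts / (nf * n * 4 * pi * rmid^2 * diff(edges) * rho0)
}

# EDF density by explicit loops; pairs are in-domain iff first-site
# minimum-image distance < rcut.
naiveEdf <- function(traj, params, edges, rcut) {
  m <- if (species(traj) == "water3") 3L else 1L
  L <- boxLength(traj)
  n <- nMolecules(traj)
  nf <- nFrames(traj)
  counts <- numeric(length(edges) - 1)
  for (f in seq_len(nf)) {
    fr <- traj@coords[, , f, drop = FALSE][, , 1]
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      a <- fr[((i - 1) * m + 1):(i * m), , drop = FALSE]
      b <- fr[((j - 1) * m + 1):(j * m), , drop = FALSE]
      dOO <- minImage(a[1, ] - b[1, ], L)
      if (sqrt(sum(dOO^2)) >= rcut) next
      u <- naiveMolPairEnergy(a, b, params, L, rcut)
      bin <- findInterval(u, edges, rightmost.closed = FALSE)
      if (bin >= 1 && bin <= length(counts) && u < edges[length(edges)])
        counts[bin] <- counts[bin] + 2      # both orderings
    }
  }
  counts / (nf * n * diff(edges))
}

# Short independent Metropolis chain for an LJ fluid (R implementation,
# direct O(N^2) total-energy evaluation at every step).
naiveLJMC <- function(coords, L, sigma, eps, temperature, rcut,
                      nSweeps, dTrans, seed) {
  set.seed(seed)
  kB <- 0.0083144621
  n <- nrow(coords)
  ljshift <- 4 * eps * ((sigma / rcut)^12 - (sigma / rcut)^6)
  pairE <- function(xi, xj) {
    r <- sqrt(sum(minImage(xi - xj, L)^2))
    if (r >= rcut) return(0)
    4 * eps * ((sigma / r)^12 - (sigma / r)^6) - ljshift
  }
  totE <- function(x) {
    e <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) e <- e + pairE(x[i, ], x[j, ])
    e
  }
  molE <- function(x, k) {
    e <- 0
    for (j in seq_len(n)) if (j != k) e <- e + pairE(x[k, ], x[j, ])
    e
  }
  energies <- numeric(nSweeps)
  for (s in seq_len(nSweeps)) {
    for (mv in seq_len(n)) {
      k <- sample.int(n, 1)
      old <- coords[k, ]
      eOld <- molE(coords, k)
      coords[k, ] <- (old + runif(3, -dTrans, dTrans)) %% L
      eNew <- molE(coords, k)
      if (!(eNew - eOld <= 0 ||
            runif(1) < exp(-(eNew - eOld) / (kB * temperature))))
        coords[k, ] <- old
    }
    energies[s] <- totE(coords)
  }
  energies
}

# Small helper: a DistributionFunction built directly from numbers.
makeDF <- function(values, edges, kind = "radial", unc = NULL,
                   nBlocks = 0L, rho0 = 1) {
  sc <- new("BinScheme", kind = kind, edges = edges)
  meta <- if (kind == "radial") list(rho0 = rho0) else list()
  new("DistributionFunction", scheme = sc, values = values,
      uncertainties = if (is.null(unc)) numeric(0) else unc,
      nBlocks = as.integer(nBlocks), meta = meta)
}

ljFixtureTraj <- function(n = 20, rhoStar = 0.4, seed = 1, frames = 30,
                          params = forceFieldParams(0.34, 0.8),
                          temperature = 200, cutoff = 0.8) {
  init <- initializeBox(n, rhoStar, "lj", temperature, params = params,
                        reduced = TRUE, seed = seed)
  runMetropolis(init$box, init$coords, params,
                samplerConfig(nSweepsEquil = 100, nSweepsProd = frames * 5,
                              sampleEvery = 5, cutoff = cutoff, seed = seed))
}
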