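// Metropolis Monte Carlo engine for periodic LJ and rigid 3-site fluids.
// Units: nm, kJ/mol, elementary charge, Kelvin.
// Site layout: molecule k occupies rows [k*m, k*m + m), first site is the
// LJ-bearing (oxygen-like) site. Molecules are kept intact across the
// periodic boundary: wrapping translates the whole molecule by the image
// shift of its first site.

#include <Rcpp.h>
#include <random>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double KB = 0.0083144621;   // kJ/mol/K
static const double KCOUL = 138.935458;  // kJ mol^-1 nm e^-2

static inline double mimg(double dx, double L) {
  return dx - L * std::nearbyint(dx / L);
}

struct PairParams {
  int m;                       // sites per molecule
  std::vector<double> q;       // site charges (length m)
  double sigma, eps, L, rcut;
  bool shift;
  bool hasCharge;
  double ljShift, qk;          // precomputed shift constants
  double sigma2, rcut2;
  PairParams(int m_, const NumericVector& q_, double sigma_, double eps_,
             double L_, double rcut_, bool shift_)
      : m(m_), q(q_.begin(), q_.end()), sigma(sigma_), eps(eps_), L(L_),
        rcut(rcut_), shift(shift_) {
    hasCharge = false;
    for (double c : q) if (c != 0.0) hasCharge = true;
    ljShift = 0.0;
    if (shift && R_finite(rcut)) {
      double t = (sigma / rcut) * (sigma / rcut);
      double sr6 = t * t * t;
      ljShift = 4.0 * eps * (sr6 * sr6 - sr6);
    }
    qk = (shift && R_finite(rcut)) ? 1.0 / rcut : 0.0;
    sigma2 = sigma * sigma;
    rcut2 = R_finite(rcut) ? rcut * rcut : R_PosInf;
  }
};

// Interaction energy of molecules i and j under minimum image.
// The pair is "in domain" iff the first-site distance is below the cutoff;
// the LJ term acts between first sites only, Coulomb between all site pairs
// (each Coulomb term individually truncated-shifted).
static double molPairEnergyPtr(const double* a, const double* b,
                               const PairParams& p,
                               bool* inDomain = nullptr) {
  const int m = p.m;
  double dx = mimg(a[0] - b[0], p.L);
  double dy = mimg(a[1] - b[1], p.L);
  double dz = mimg(a[2] - b[2], p.L);
  double r2 = dx * dx + dy * dy + dz * dz;
  bool dom = r2 < p.rcut2;
  if (inDomain) *inDomain = dom;
  double e = 0.0;
  if (dom) {
    double t = p.sigma2 / r2;
    double sr6 = t * t * t;
    e += 4.0 * p.eps * (sr6 * sr6 - sr6) - p.ljShift;
  }
  if (p.hasCharge && m > 1) {
    for (int s = 0; s < m; ++s) {
      if (p.q[s] == 0.0) continue;
      for (int t = 0; t < m; ++t) {
        if (p.q[t] == 0.0) continue;
        double ddx = mimg(a[3 * s] - b[3 * t], p.L);
        double ddy = mimg(a[3 * s + 1] - b[3 * t + 1], p.L);
        double ddz = mimg(a[3 * s + 2] - b[3 * t + 2], p.L);
        double r = std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz);
        if (r < p.rcut)
          e += KCOUL * p.q[s] * p.q[t] * (1.0 / r - p.qk);
      }
    }
  }
  return e;
}

static inline double molPairEnergy(const double* x, int i, int j,
                                   const PairParams& p,
                                   bool* inDomain = nullptr) {
  return molPairEnergyPtr(x + 3 * p.m * i, x + 3 * p.m * j, p, inDomain);
}

// Energy of molecule k with all others.
static double molEnergy(const double* x, int k, int n, const PairParams& p) {
  double e = 0.0;
  for (int j = 0; j < n; ++j)
    if (j != k) e += molPairEnergy(x, k, j, p);
  return e;
}

// Energy change when molecule k's sites move from oldMol to the coordinates
// currently in x (single pass over the other molecules).
static double molEnergyDelta(const double* x, const double* oldMol, int k,
                             int n, const PairParams& p) {
  double d = 0.0;
  const double* newMol = x + 3 * p.m * k;
  for (int j = 0; j < n; ++j) {
    if (j == k) continue;
    const double* b = x + 3 * p.m * j;
    d += molPairEnergyPtr(newMol, b, p) - molPairEnergyPtr(oldMol, b, p);
  }
  return d;
}

static double totalEnergy(const double* x, int n, const PairParams& p) {
  double e = 0.0;
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j)
      e += molPairEnergy(x, i, j, p);
  return e;
}

// [[Rcpp::export]]
double cpp_total_energy(NumericMatrix coords, int m, NumericVector charges,
                        double sigma, double eps, double L, double rcut,
                        bool shift) {
  int n = coords.nrow() / m;
  // column-major R matrix -> row-contiguous site buffer
  std::vector<double> x(3 * coords.nrow());
  for (int i = 0; i < coords.nrow(); ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = coords(i, d);
  PairParams p(m, charges, sigma, eps, L, rcut, shift);
  return totalEnergy(x.data(), n, p);
}

// Pair energies of all unordered in-domain molecule pairs of one frame.
// [[Rcpp::export]]
NumericVector cpp_pair_energies(NumericMatrix coords, int m,
                                NumericVector charges, double sigma,
                                double eps, double L, double rcut,
                                bool shift) {
  int n = coords.nrow() / m;
  std::vector<double> x(3 * coords.nrow());
  for (int i = 0; i < coords.nrow(); ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = coords(i, d);
  PairParams p(m, charges, sigma, eps, L, rcut, shift);
  std::vector<double> out;
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j) {
      bool dom = false;
      double e = molPairEnergy(x.data(), i, j, p, &dom);
      if (dom) out.push_back(e);
    }
  return wrap(out);
}

// Histogram counts of in-domain pair energies over all frames, plus the
// number of in-domain pairs falling outside the bin span.
// [[Rcpp::export]]
List cpp_edf_counts(NumericVector coordsArr, IntegerVector dims, int m,
                    NumericVector charges, double sigma, double eps,
                    double L, double rcut, bool shift, NumericVector edges) {
  int natoms = dims[0], nframes = dims[2];
  int n = natoms / m;
  int nbins = edges.size() - 1;
  std::vector<double> counts(nbins, 0.0);
  double dropped = 0.0, total = 0.0;
  PairParams p(m, charges, sigma, eps, L, rcut, shift);
  std::vector<double> x(3 * natoms);
  for (int f = 0; f < nframes; ++f) {
    // coordsArr is (natoms, 3, nframes) column-major
    const double* base = coordsArr.begin() + (size_t)f * natoms * 3;
    for (int i = 0; i < natoms; ++i)
      for (int d = 0; d < 3; ++d) x[3 * i + d] = base[i + (size_t)d * natoms];
    for (int i = 0; i < n - 1; ++i)
      for (int j = i + 1; j < n; ++j) {
        bool dom = false;
        double e = molPairEnergy(x.data(), i, j, p, &dom);
        if (!dom) continue;
        total += 1.0;
        if (e < edges[0] || e >= edges[nbins]) { dropped += 1.0; continue; }
        int lo = 0, hi = nbins;           // find bin: edges[b] <= e < edges[b+1]
        while (hi - lo > 1) {
          int mid = (lo + hi) / 2;
          if (e < edges[mid]) hi = mid; else lo = mid;
        }
        counts[lo] += 1.0;
      }
  }
  return List::create(_["counts"] = wrap(counts), _["dropped"] = dropped,
                      _["total"] = total);
}

// Center-of-mass coordinates per molecule per frame (molecules intact, so
// no minimum-image handling is needed within a molecule).
// [[Rcpp::export]]
NumericVector cpp_com(NumericVector coordsArr, IntegerVector dims, int m,
                      NumericVector masses) {
  int natoms = dims[0], nframes = dims[2];
  int n = natoms / m;
  double M = 0.0;
  for (int s = 0; s < m; ++s) M += masses[s];
  NumericVector out((size_t)n * 3 * nframes);
  out.attr("dim") = IntegerVector::create(n, 3, nframes);
  for (int f = 0; f < nframes; ++f) {
    const double* base = coordsArr.begin() + (size_t)f * natoms * 3;
    double* ob = out.begin() + (size_t)f * n * 3;
    for (int k = 0; k < n; ++k)
      for (int d = 0; d < 3; ++d) {
        double c = 0.0;
        for (int s = 0; s < m; ++s)
          c += masses[s] * base[k * m + s + (size_t)d * natoms];
        ob[k + (size_t)d * n] = c / M;
      }
  }
  return out;
}

// Minimum-image distance histogram of molecule-center pairs over frames.
// [[Rcpp::export]]
NumericVector cpp_rdf_counts(NumericVector comArr, IntegerVector dims,
                             double L, NumericVector edges) {
  int n = dims[0], nframes = dims[2];
  int nbins = edges.size() - 1;
  NumericVector counts(nbins);
  double rmax = edges[nbins];
  for (int f = 0; f < nframes; ++f) {
    const double* base = comArr.begin() + (size_t)f * n * 3;
    for (int i = 0; i < n - 1; ++i)
      for (int j = i + 1; j < n; ++j) {
        double dx = mimg(base[i] - base[j], L);
        double dy = mimg(base[i + n] - base[j + n], L);
        double dz = mimg(base[i + 2 * n] - base[j + 2 * n], L);
        double r = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (r < edges[0] || r >= rmax) continue;
        int lo = 0, hi = nbins;
        while (hi - lo > 1) {
          int mid = (lo + hi) / 2;
          if (r < edges[mid]) hi = mid; else lo = mid;
        }
        counts[lo] += 1.0;
      }
  }
  return counts;
}

// Per-frame molecular virial W = sum_{i<j} F_ij . R_ij with F_ij the total
// site-site force between molecules i and j (forces from the unshifted
// potential inside the cutoff) and R_ij the minimum-image center separation.
// [[Rcpp::export]]
NumericVector cpp_virial(NumericVector coordsArr, IntegerVector dims, int m,
                         NumericVector charges, double sigma, double eps,
                         NumericVector masses, double L, double rcut) {
  int natoms = dims[0], nframes = dims[2];
  int n = natoms / m;
  double M = 0.0;
  for (int s = 0; s < m; ++s) M += masses[s];
  bool hasCharge = false;
  for (double c : charges) if (c != 0.0) hasCharge = true;
  NumericVector W(nframes);
  std::vector<double> x(3 * natoms), com(3 * n);
  for (int f = 0; f < nframes; ++f) {
    const double* base = coordsArr.begin() + (size_t)f * natoms * 3;
    for (int i = 0; i < natoms; ++i)
      for (int d = 0; d < 3; ++d) x[3 * i + d] = base[i + (size_t)d * natoms];
    for (int k = 0; k < n; ++k)
      for (int d = 0; d < 3; ++d) {
        double c = 0.0;
        for (int s = 0; s < m; ++s) c += masses[s] * x[3 * (k * m + s) + d];
        com[3 * k + d] = c / M;
      }
    double w = 0.0;
    for (int i = 0; i < n - 1; ++i)
      for (int j = i + 1; j < n; ++j) {
        const double* a = x.data() + 3 * m * i;
        const double* b = x.data() + 3 * m * j;
        double F[3] = {0.0, 0.0, 0.0};   // force on molecule i from j
        // LJ between first sites
        {
          double dx = mimg(a[0] - b[0], L);
          double dy = mimg(a[1] - b[1], L);
          double dz = mimg(a[2] - b[2], L);
          double r2 = dx * dx + dy * dy + dz * dz;
          double r = std::sqrt(r2);
          if (r < rcut) {
            double t = sigma * sigma / r2;
            double sr6 = t * t * t;
            double fmag = 24.0 * eps * (2.0 * sr6 * sr6 - sr6) / r2;
            F[0] += fmag * dx; F[1] += fmag * dy; F[2] += fmag * dz;
          }
        }
        if (hasCharge && m > 1) {
          for (int s = 0; s < m; ++s) {
            if (charges[s] == 0.0) continue;
            for (int t = 0; t < m; ++t) {
              if (charges[t] == 0.0) continue;
              double dx = mimg(a[3 * s] - b[3 * t], L);
              double dy = mimg(a[3 * s + 1] - b[3 * t + 1], L);
              double dz = mimg(a[3 * s + 2] - b[3 * t + 2], L);
              double r2 = dx * dx + dy * dy + dz * dz;
              double r = std::sqrt(r2);
              if (r < rcut) {
                double fmag = KCOUL * charges[s] * charges[t] / (r2 * r);
                F[0] += fmag * dx; F[1] += fmag * dy; F[2] += fmag * dz;
              }
            }
          }
        }
        double Rx = mimg(com[3 * i] - com[3 * j], L);
        double Ry = mimg(com[3 * i + 1] - com[3 * j + 1], L);
        double Rz = mimg(com[3 * i + 2] - com[3 * j + 2], L);
        w += F[0] * Rx + F[1] * Ry + F[2] * Rz;
      }
    W[f] = w;
  }
  return W;
}

// Rotate molecule sites (m x 3, row-contiguous) about its center of mass by
// angle about unit axis (Rodrigues).
static void rotateMolecule(double* mol, int m, const double* masses,
                           double Mtot, const double axis[3], double angle) {
  double com[3] = {0, 0, 0};
  for (int s = 0; s < m; ++s)
    for (int d = 0; d < 3; ++d) com[d] += masses[s] * mol[3 * s + d];
  for (int d = 0; d < 3; ++d) com[d] /= Mtot;
  double c = std::cos(angle), sn = std::sin(angle);
  for (int s = 0; s < m; ++s) {
    double v[3];
    for (int d = 0; d < 3; ++d) v[d] = mol[3 * s + d] - com[d];
    double kdv = axis[0] * v[0] + axis[1] * v[1] + axis[2] * v[2];
    double kxv[3] = {axis[1] * v[2] - axis[2] * v[1],
                     axis[2] * v[0] - axis[0] * v[2],
                     axis[0] * v[1] - axis[1] * v[0]};
    for (int d = 0; d < 3; ++d)
      mol[3 * s + d] = com[d] + v[d] * c + kxv[d] * sn + axis[d] * kdv * (1 - c);
  }
}

// [[Rcpp::export]]
List cpp_run_mc(NumericMatrix init, int m, NumericVector charges,
                double sigma, double eps, NumericVector masses, double L,
                double temperature, int nEquil, int nProd, int sampleEvery,
                double dTrans, double dRot, double rcut, bool shift,
                int seed, bool tune) {
  int natoms = init.nrow();
  int n = natoms / m;
  PairParams p(m, charges, sigma, eps, L, rcut, shift);
  double beta = 1.0 / (KB * temperature);
  double Mtot = 0.0;
  std::vector<double> ms(masses.begin(), masses.end());
  for (double v : ms) Mtot += v;

  std::vector<double> x(3 * natoms);
  for (int i = 0; i < natoms; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = init(i, d);

  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> runif(0.0, 1.0);

  double U = totalEnergy(x.data(), n, p);
  double maxDrift = 0.0;
  double dRotRad = dRot * M_PI / 180.0;

  int nframes = nProd / sampleEvery;
  NumericVector frames((size_t)natoms * 3 * nframes);
  frames.attr("dim") = IntegerVector::create(natoms, 3, nframes);
  int frameIdx = 0;

  long accepted = 0, attempted = 0;     // production window
  long accWin = 0, attWin = 0;          // tuning window
  std::vector<double> trial(3 * m);

  long totalSweeps = (long)nEquil + nProd;
  for (long sweep = 1; sweep <= totalSweeps; ++sweep) {
    bool production = sweep > nEquil;
    for (int mv = 0; mv < n; ++mv) {
      int k = (int)(runif(rng) * n);
      if (k == n) k = n - 1;
      double* mol = x.data() + 3 * m * k;
      for (int s = 0; s < 3 * m; ++s) trial[s] = mol[s];
      // translation
      double tx = (2.0 * runif(rng) - 1.0) * dTrans;
      double ty = (2.0 * runif(rng) - 1.0) * dTrans;
      double tz = (2.0 * runif(rng) - 1.0) * dTrans;
      for (int s = 0; s < m; ++s) {
        mol[3 * s] += tx; mol[3 * s + 1] += ty; mol[3 * s + 2] += tz;
      }
      if (m > 1) {
        // Marsaglia uniform axis
        double a1, a2, ss;
        do {
          a1 = 2.0 * runif(rng) - 1.0;
          a2 = 2.0 * runif(rng) - 1.0;
          ss = a1 * a1 + a2 * a2;
        } while (ss >= 1.0);
        double root = 2.0 * std::sqrt(1.0 - ss);
        double axis[3] = {a1 * root, a2 * root, 1.0 - 2.0 * ss};
        double ang = (2.0 * runif(rng) - 1.0) * dRotRad;
        rotateMolecule(mol, m, ms.data(), Mtot, axis, ang);
      }
      double dU = molEnergyDelta(x.data(), trial.data(), k, n, p);
      bool accept = dU <= 0.0 || runif(rng) < std::exp(-beta * dU);
      if (accept) {
        // wrap whole molecule by the image shift of its first site
        for (int d = 0; d < 3; ++d) {
          double shiftd = L * std::floor(mol[d] / L);
          if (shiftd != 0.0)
            for (int s = 0; s < m; ++s) mol[3 * s + d] -= shiftd;
        }
        U += dU;
        if (production) ++accepted;
        ++accWin;
      } else {
        for (int s = 0; s < 3 * m; ++s) mol[s] = trial[s];
      }
      if (production) ++attempted;
      ++attWin;
    }
    if (tune && !production && sweep % 50 == 0 && attWin > 0) {
      double acc = (double)accWin / attWin;
      if (acc > 0.45) {
        dTrans = std::min(dTrans * 1.3, L / 4.0);
        dRotRad = std::min(dRotRad * 1.3, M_PI);
      } else if (acc < 0.35) {
        dTrans /= 1.3;
        dRotRad /= 1.3;
      }
      accWin = 0; attWin = 0;
    }
    if (sweep % 1000 == 0) {
      double Uf = totalEnergy(x.data(), n, p);
      double drift = std::fabs(U - Uf) / std::max(1.0, std::fabs(Uf));
      if (drift > maxDrift) maxDrift = drift;
    }
    if (production) {
      long ps = sweep - nEquil;
      if (ps % sampleEvery == 0 && frameIdx < nframes) {
        double* fb = frames.begin() + (size_t)frameIdx * natoms * 3;
        for (int i = 0; i < natoms; ++i)
          for (int d = 0; d < 3; ++d) fb[i + (size_t)d * natoms] = x[3 * i + d];
        ++frameIdx;
      }
    }
  }
  double accRate = attempted > 0 ? (double)accepted / attempted : NA_REAL;
  return List::create(_["frames"] = frames, _["acceptanceRate"] = accRate,
                      _["dTransFinal"] = dTrans,
                      _["dRotFinal"] = dRotRad * 180.0 / M_PI,
                      _["maxEnergyDrift"] = maxDrift,
                      _["finalEnergy"] = U);
}
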