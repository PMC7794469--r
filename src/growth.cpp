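#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Sequential growth of confined self-avoiding bead chains with Rosenbluth
// importance weights, optional per-pair contact biasing (constrained mode),
// optional per-bead spherical scaffolds (fixture generation), and systematic
// resampling at checkpoint lengths.  All randomness comes from R's RNG so a
// single set.seed() call on the R side makes runs bit-reproducible.

static inline double sq(double x) { return x * x; }

// uniform unit vector (2 RNG draws)
static inline void rand_dir(double &x, double &y, double &z) {
  double u = unif_rand();
  double v = unif_rand();
  z = 2.0 * u - 1.0;
  double r = std::sqrt(std::max(0.0, 1.0 - z * z));
  double phi = 2.0 * M_PI * v;
  x = r * std::cos(phi);
  y = r * std::sin(phi);
}

// uniform point in sphere centered at (cx,cy,cz) with radius R (3 draws)
static inline void rand_in_sphere(double R, double cx, double cy, double cz,
                                  double &x, double &y, double &z) {
  double dx, dy, dz;
  rand_dir(dx, dy, dz);
  double r = R * std::cbrt(unif_rand());
  x = cx + r * dx;
  y = cy + r * dy;
  z = cz + r * dz;
}

static inline double logsumexp(const std::vector<double> &lw) {
  double m = -std::numeric_limits<double>::infinity();
  for (double v : lw) if (v > m) m = v;
  if (!std::isfinite(m)) return m;
  double s = 0.0;
  for (double v : lw) if (std::isfinite(v)) s += std::exp(v - m);
  return m + std::log(s);
}

// [[Rcpp::export]]
List cpp_grow_ensemble(int n_beads, int n_chains, int K,
                       double bond, double dc, double radius,
                       IntegerVector checkpoints, double ess_frac,
                       NumericMatrix qeff,
                       NumericMatrix anchor_centers,
                       NumericVector anchor_radii) {
  const bool use_targets = qeff.nrow() == n_beads;
  const bool use_anchors = anchor_centers.nrow() == n_beads;
  const double bond2_min = sq(bond) * (1.0 - 1e-12);
  const double dc2 = sq(dc);
  const double R2 = sq(radius);

  // per-target-bead partner lists (0-based, partners j <= t-2 with qeff>0)
  std::vector<std::vector<int>> partners(n_beads);
  if (use_targets) {
    for (int t = 2; t < n_beads; ++t)
      for (int j = 0; j <= t - 2; ++j)
        if (qeff(j, t) > 0.0) partners[t].push_back(j);
  }

  // coords[k] is contiguous x0,y0,z0,x1,... for chain k
  std::vector<std::vector<double>> X(n_chains,
      std::vector<double>(3 * (size_t)n_beads, 0.0));
  std::vector<double> logw(n_chains, 0.0);
  std::vector<bool> alive(n_chains, true);
  int n_resamples = 0, n_deaths = 0;

  std::vector<double> tx(K), ty(K), tz(K), tw(K);
  std::vector<int> cp(checkpoints.begin(), checkpoints.end());
  size_t cp_next = 0;

  for (int t = 0; t < n_beads; ++t) {
    for (int k = 0; k < n_chains; ++k) {
      if (!alive[k]) continue;
      std::vector<double> &xk = X[k];
      if (t == 0) {
        // uniform within confinement (and the bead-0 scaffold if given)
        bool placed = false;
        for (int tries = 0; tries < 10000 && !placed; ++tries) {
          double x, y, z;
          if (use_anchors) {
            rand_in_sphere(anchor_radii[0], anchor_centers(0, 0),
                           anchor_centers(0, 1), anchor_centers(0, 2),
                           x, y, z);
            if (sq(x) + sq(y) + sq(z) > R2) continue;
          } else {
            rand_in_sphere(radius, 0.0, 0.0, 0.0, x, y, z);
          }
          xk[0] = x; xk[1] = y; xk[2] = z;
          placed = true;
        }
        if (!placed) { alive[k] = false; logw[k] = R_NegInf; ++n_deaths; }
        continue;
      }
      const double px = xk[3 * (t - 1)], py = xk[3 * (t - 1) + 1],
                   pz = xk[3 * (t - 1) + 2];
      int n_valid = 0;
      double wsum = 0.0;
      for (int i = 0; i < K; ++i) {
        double dx, dy, dz;
        rand_dir(dx, dy, dz);
        double x = px + bond * dx, y = py + bond * dy, z = pz + bond * dz;
        tw[i] = 0.0;
        if (sq(x) + sq(y) + sq(z) > R2) continue;
        if (use_anchors) {
          double ax = x - anchor_centers(t, 0), ay = y - anchor_centers(t, 1),
                 az = z - anchor_centers(t, 2);
          if (sq(ax) + sq(ay) + sq(az) > sq(anchor_radii[t])) continue;
        }
        bool clash = false;
        for (int j = t - 2; j >= 0; --j) {  // adjacent bead is at bond by construction
          double d2 = sq(x - xk[3 * j]) + sq(y - xk[3 * j + 1]) +
                      sq(z - xk[3 * j + 2]);
          if (d2 < bond2_min) { clash = true; break; }
        }
        if (clash) continue;
        ++n_valid;
        double L = 1.0;
        if (use_targets && !partners[t].empty()) {
          for (int j : partners[t]) {
            double d2 = sq(x - xk[3 * j]) + sq(y - xk[3 * j + 1]) +
                        sq(z - xk[3 * j + 2]);
            double q = qeff(j, t);
            L *= (d2 < dc2) ? q : (1.0 - q);
            if (L == 0.0) break;
          }
        }
        tx[i] = x; ty[i] = y; tz[i] = z; tw[i] = L;
        wsum += L;
      }
      double u_pick = unif_rand();  // consumed whether or not the chain survives,
                                    // so null and empty-target paths match exactly
      if (n_valid == 0 || wsum <= 0.0) {
        alive[k] = false; logw[k] = R_NegInf; ++n_deaths;
        continue;
      }
      double target = u_pick * wsum, acc = 0.0;
      int pick = -1;
      for (int i = 0; i < K; ++i) {
        if (tw[i] <= 0.0) continue;
        acc += tw[i];
        if (acc >= target) { pick = i; break; }
      }
      if (pick < 0) { for (int i = K - 1; i >= 0; --i) if (tw[i] > 0.0) { pick = i; break; } }
      xk[3 * t] = tx[pick]; xk[3 * t + 1] = ty[pick]; xk[3 * t + 2] = tz[pick];
      logw[k] += std::log(wsum / K);
    }

    // checkpoint resampling once bead count t+1 is reached
    if (cp_next < cp.size() && (t + 1) == cp[cp_next]) {
      ++cp_next;
      if (ess_frac > 0.0 && (t + 1) < n_beads) {
        double lse = logsumexp(logw);
        if (std::isfinite(lse)) {
          double s1 = 0.0, s2 = 0.0;
          std::vector<double> w(n_chains, 0.0);
          for (int k = 0; k < n_chains; ++k) {
            if (std::isfinite(logw[k])) {
              w[k] = std::exp(logw[k] - lse);
              s1 += w[k]; s2 += sq(w[k]);
            }
          }
          double ess = (s2 > 0.0) ? sq(s1) / s2 : 0.0;
          if (ess < ess_frac * n_chains) {
            // systematic resampling proportional to weights
            std::vector<int> src(n_chains);
            double u0 = unif_rand() / n_chains, cum = 0.0;
            int j = 0;
            for (int k = 0; k < n_chains; ++k) {
              double pos = u0 + (double)k / n_chains;
              while (cum + w[j] < pos && j < n_chains - 1) { cum += w[j]; ++j; }
              src[k] = j;
            }
            std::vector<std::vector<double>> Xnew(n_chains);
            for (int k = 0; k < n_chains; ++k) Xnew[k] = X[src[k]];
            X.swap(Xnew);
            double lw_new = lse - std::log((double)n_chains);  // total weight preserved
            for (int k = 0; k < n_chains; ++k) {
              logw[k] = lw_new;
              alive[k] = true;
            }
            ++n_resamples;
          }
        }
      }
    }
  }

  int n_alive = 0;
  for (int k = 0; k < n_chains; ++k) if (alive[k]) ++n_alive;
  NumericVector coords(Dimension(n_beads, 3, n_chains));
  for (int k = 0; k < n_chains; ++k)
    for (int t = 0; t < n_beads; ++t)
      for (int d = 0; d < 3; ++d)
        coords[t + n_beads * d + (size_t)n_beads * 3 * k] = X[k][3 * t + d];
  return List::create(_["coords"] = coords,
                      _["logw"] = NumericVector(logw.begin(), logw.end()),
                      _["alive"] = LogicalVector(alive.begin(), alive.end()),
                      _["n_alive"] = n_alive,
                      _["n_resamples"] = n_resamples,
                      _["n_deaths"] = n_deaths);
}

// Weighted contact probability map: p(i,j) = sum_k w_k I[d_ij^(k) < dc] / sum_k w_k
// coords: array (n_beads, 3, n_chains); weights: length n_chains
// [[Rcpp::export]]
NumericMatrix cpp_contact_map(NumericVector coords, NumericVector weights,
                              double dc) {
  IntegerVector dim = coords.attr("dim");
  const int n = dim[0], nc = dim[2];
  const double dc2 = sq(dc);
  NumericMatrix P(n, n);
  double wtot = 0.0;
  for (int k = 0; k < nc; ++k) wtot += weights[k];
  const double *C = REAL(coords);
  for (int k = 0; k < nc; ++k) {
    const double w = weights[k];
    if (w <= 0.0) continue;
    const double *xk = C + (size_t)3 * n * k;
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double d2 = sq(xk[i] - xk[j]) + sq(xk[i + n] - xk[j + n]) +
                    sq(xk[i + 2 * n] - xk[j + 2 * n]);
        if (d2 < dc2) P(i, j) += w;
      }
    }
  }
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      P(i, j) /= wtot;
      P(j, i) = P(i, j);
    }
  }
  for (int i = 0; i < n; ++i) P(i, i) = 1.0;
  return P;
}

// Per-chain contact indicators over upper-triangle pairs (column-major
// upper.tri order: (1,2),(1,3),(2,3),(1,4),...).  Rows = pairs, cols = chains.
// [[Rcpp::export]]
NumericMatrix cpp_contact_indicators(NumericVector coords, double dc) {
  IntegerVector dim = coords.attr("dim");
  const int n = dim[0], nc = dim[2];
  const double dc2 = sq(dc);
  const int np = n * (n - 1) / 2;
  NumericMatrix I(np, nc);
  const double *C = REAL(coords);
  for (int k = 0; k < nc; ++k) {
    const double *xk = C + (size_t)3 * n * k;
    int p = 0;
    for (int j = 1; j < n; ++j) {
      for (int i = 0; i < j; ++i) {
        double d2 = sq(xk[i] - xk[j]) + sq(xk[i + n] - xk[j + n]) +
                    sq(xk[i + 2 * n] - xk[j + 2 * n]);
        I(p, k) = (d2 < dc2) ? 1.0 : 0.0;
        ++p;
      }
    }
  }
  return I;
}
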