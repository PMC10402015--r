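// Cellular Potts engine kernels.
//
// Conventions (documented in the package vignette):
//  - the lattice is an integer matrix; 0 = medium, >0 = cell identity
//  - sites outside the matrix are immutable medium (the confinement wall)
//  - interfacial energy runs over 2nd-order (8-neighbour Moore) site pairs
//    with differing identities; J(cell,cell) = Jcc, J(cell,medium) = Jcm,
//    J(medium,medium) = 0
//  - one Monte Carlo step (MCS) = side^2 random copy attempts
//  - all randomness comes from R's RNG stream, so set.seed() governs
//    the whole simulation
#include <Rcpp.h>
#include <vector>
#include <utility>
#include <map>
using namespace Rcpp;

// Moore neighbourhood; the first 4 entries are a half-plane so that
// iterating d < 4 over in-bounds neighbours visits each pair once.
static const int DR[8] = { 0, 1, 1,  1,  0, -1, -1, -1 };
static const int DC[8] = { 1, 0, 1, -1, -1,  0, -1,  1 };

static inline double jpair(int a, int b, double Jcc, double Jcm) {
  if (a == b) return 0.0;
  if (a == 0 || b == 0) return Jcm;
  return Jcc;
}

// spin at (r, c), out-of-bounds = wall medium
static inline int spin_at(const IntegerMatrix &lat, int r, int c) {
  if (r < 0 || c < 0 || r >= lat.nrow() || c >= lat.ncol()) return 0;
  return lat(r, c);
}

// [[Rcpp::export]]
double cpm_total_energy(const IntegerMatrix &lat,
                        const NumericVector &area,
                        const NumericVector &target,
                        double Jcc, double Jcm, double lambda) {
  const int nr = lat.nrow(), nc = lat.ncol();
  double e = 0.0;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      const int s = lat(r, c);
      for (int d = 0; d < 8; ++d) {
        const int rr = r + DR[d], cc = c + DC[d];
        const bool inb = (rr >= 0 && cc >= 0 && rr < nr && cc < nc);
        if (inb && d >= 4) continue;        // in-bounds pairs: half-plane only
        e += jpair(s, inb ? lat(rr, cc) : 0, Jcc, Jcm);
      }
    }
  }
  for (int i = 0; i < area.size(); ++i) {
    const double da = area[i] - target[i];
    e += lambda * da * da;
  }
  return e;
}

// energy change if site (tr, tc) takes identity `snew`
static double delta_energy(const IntegerMatrix &lat,
                           const NumericVector &area,
                           const NumericVector &target,
                           int tr, int tc, int snew,
                           double Jcc, double Jcm, double lambda) {
  const int sold = lat(tr, tc);
  double de = 0.0;
  for (int d = 0; d < 8; ++d) {
    const int nb = spin_at(lat, tr + DR[d], tc + DC[d]);
    de += jpair(snew, nb, Jcc, Jcm) - jpair(sold, nb, Jcc, Jcm);
  }
  if (sold > 0) {
    const double a = area[sold - 1], t = target[sold - 1];
    de += lambda * ((a - 1 - t) * (a - 1 - t) - (a - t) * (a - t));
  }
  if (snew > 0) {
    const double a = area[snew - 1], t = target[snew - 1];
    de += lambda * ((a + 1 - t) * (a + 1 - t) - (a - t) * (a - t));
  }
  return de;
}

// [[Rcpp::export]]
double cpm_delta_energy(const IntegerMatrix &lat,
                        const NumericVector &area,
                        const NumericVector &target,
                        int tr, int tc, int snew,
                        double Jcc, double Jcm, double lambda) {
  if (lat(tr, tc) == snew)
    stop("copy proposal must change the site identity");
  return delta_energy(lat, area, target, tr, tc, snew, Jcc, Jcm, lambda);
}

// Local connectivity test: removing (tr, tc) from the cell that owns it must
// leave the owner's sites within the Moore neighbourhood in one connected
// piece (Moore adjacency among the 8 surrounding positions). Copies that
// fail would fragment the cell and are rejected outright.
static bool connectivity_ok(const IntegerMatrix &lat, int tr, int tc) {
  const int owner = lat(tr, tc);
  if (owner <= 0) return true;            // medium has no connectivity rule
  bool own[8];
  int nown = 0;
  for (int d = 0; d < 8; ++d) {
    own[d] = (spin_at(lat, tr + DR[d], tc + DC[d]) == owner);
    if (own[d]) ++nown;
  }
  if (nown == 0) return true;             // last site: the cell vanishes
  // flood fill among the 8 neighbour positions
  int start = 0;
  while (!own[start]) ++start;
  bool seen[8] = {false};
  std::vector<int> stack;
  stack.push_back(start);
  seen[start] = true;
  int reached = 1;
  while (!stack.empty()) {
    const int d = stack.back(); stack.pop_back();
    const int r1 = DR[d], c1 = DC[d];
    for (int d2 = 0; d2 < 8; ++d2) {
      if (seen[d2] || !own[d2]) continue;
      const int dr = DR[d2] - r1, dc = DC[d2] - c1;
      if (dr >= -1 && dr <= 1 && dc >= -1 && dc <= 1) {
        seen[d2] = true;
        stack.push_back(d2);
        ++reached;
      }
    }
  }
  return reached == nown;
}

// [[Rcpp::export]]
bool cpm_connectivity_ok(const IntegerMatrix &lat, int tr, int tc) {
  return connectivity_ok(lat, tr, tc);
}

// Exact connectivity: BFS over the owner's sites excluding (tr, tc);
// TRUE iff the remaining sites form one Moore-connected component. The
// local test above is sufficient but not necessary (cells with internal
// loops fail it at every site); the engine uses it as a fast path and
// falls back to this exact test, so only genuinely fragmenting copies are
// rejected.
static bool connected_after_removal(const IntegerMatrix &lat, int tr, int tc,
                                    int owner_area,
                                    std::vector<int> &visited, int &gen,
                                    std::vector<int> &stack) {
  const int nr = lat.nrow(), nc = lat.ncol();
  const int owner = lat(tr, tc);
  if (owner_area <= 2) return true;  // 0 or 1 remaining sites
  ++gen;
  int start = -1;
  for (int d = 0; d < 8; ++d) {
    const int rr = tr + DR[d], cc = tc + DC[d];
    if (rr >= 0 && cc >= 0 && rr < nr && cc < nc && lat(rr, cc) == owner) {
      start = rr + nr * cc;
      break;
    }
  }
  if (start < 0) return true;
  const int forbidden = tr + nr * tc;
  visited[forbidden] = gen;   // treat the removed site as already seen
  visited[start] = gen;
  stack.clear();
  stack.push_back(start);
  int reached = 1;
  while (!stack.empty()) {
    const int cur = stack.back(); stack.pop_back();
    const int cr = cur % nr, cc2 = cur / nr;
    for (int d = 0; d < 8; ++d) {
      const int rr = cr + DR[d], c3 = cc2 + DC[d];
      if (rr < 0 || c3 < 0 || rr >= nr || c3 >= nc) continue;
      const int id1 = rr + nr * c3;
      if (visited[id1] != gen && lat(rr, c3) == owner) {
        visited[id1] = gen;
        stack.push_back(id1);
        ++reached;
      }
    }
  }
  return reached == owner_area - 1;
}

// [[Rcpp::export]]
bool cpm_connected_after_removal(const IntegerMatrix &lat, int tr, int tc) {
  const int owner = lat(tr, tc);
  if (owner <= 0) return true;
  int area = 0;
  for (int i = 0; i < lat.size(); ++i) if (lat[i] == owner) ++area;
  std::vector<int> visited((size_t) lat.size(), 0);
  std::vector<int> stack;
  int gen = 0;
  return connected_after_removal(lat, tr, tc, area, visited, gen, stack);
}

// One or more Monte Carlo steps of Metropolis copy dynamics.
// Modifies `lat` and `area` in place. Returns the accepted-move count and
// the per-cell attempt-averaged area over the call (used by the decision
// layer, which ticks on the MCS timescale).
// [[Rcpp::export]]
List cpm_run_mcs(IntegerMatrix lat, NumericVector area,
                 const NumericVector &target,
                 double Jcc, double Jcm, double kBT, double lambda,
                 int nsweep = 1) {
  const int nr = lat.nrow(), nc = lat.ncol();
  const int ncell = area.size();
  const R_xlen_t nattempt = (R_xlen_t) nr * nc * nsweep;
  std::vector<double> sumA(ncell, 0.0);
  std::vector<R_xlen_t> lastT(ncell, 0);
  std::vector<int> visited((size_t) nr * nc, 0);
  std::vector<int> bfs_stack;
  int gen = 0;
  int accepted = 0;

  for (R_xlen_t t = 0; t < nattempt; ++t) {
    int idx = (int) (unif_rand() * nr * nc);
    if (idx >= nr * nc) idx = nr * nc - 1;
    const int tr = idx % nr, tc = idx / nr;
    int d = (int) (unif_rand() * 8.0);
    if (d > 7) d = 7;
    const int snew = spin_at(lat, tr + DR[d], tc + DC[d]);
    const int sold = lat(tr, tc);
    if (snew == sold) continue;
    if (sold > 0 && !connectivity_ok(lat, tr, tc) &&
        !connected_after_removal(lat, tr, tc, (int) area[sold - 1],
                                 visited, gen, bfs_stack)) continue;
    const double de = delta_energy(lat, area, target, tr, tc, snew,
                                   Jcc, Jcm, lambda);
    if (de > 0.0 && unif_rand() >= std::exp(-de / kBT)) continue;
    lat(tr, tc) = snew;
    if (sold > 0) {
      sumA[sold - 1] += area[sold - 1] * (double) (t - lastT[sold - 1]);
      lastT[sold - 1] = t;
      area[sold - 1] -= 1.0;
    }
    if (snew > 0) {
      sumA[snew - 1] += area[snew - 1] * (double) (t - lastT[snew - 1]);
      lastT[snew - 1] = t;
      area[snew - 1] += 1.0;
    }
    ++accepted;
  }

  NumericVector avg(ncell);
  for (int i = 0; i < ncell; ++i) {
    sumA[i] += area[i] * (double) (nattempt - lastT[i]);
    avg[i] = nattempt > 0 ? sumA[i] / (double) nattempt : area[i];
  }
  return List::create(_["accepted"] = accepted, _["avg_area"] = avg);
}

// Interfacial census: per-cell count of cell-medium Moore pairs (wall
// included) and the list of cell-cell contacts with their pair counts.
// [[Rcpp::export]]
List cpm_interfaces(const IntegerMatrix &lat, int max_id) {
  const int nr = lat.nrow(), nc = lat.ncol();
  IntegerVector medium_pairs(max_id);
  std::map<std::pair<int, int>, int> cc;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      const int s = lat(r, c);
      for (int d = 0; d < 8; ++d) {
        const int rr = r + DR[d], cc2 = c + DC[d];
        const bool inb = (rr >= 0 && cc2 >= 0 && rr < nr && cc2 < nc);
        if (inb && d >= 4) continue;
        const int nb = inb ? lat(rr, cc2) : 0;
        if (s == nb) continue;
        if (s == 0 || nb == 0) {
          const int cell = s > 0 ? s : nb;
          if (cell <= max_id) medium_pairs[cell - 1] += 1;
        } else {
          std::pair<int, int> key(std::min(s, nb), std::max(s, nb));
          cc[key] += 1;
        }
      }
    }
  }
  const int n = (int) cc.size();
  IntegerVector ci(n), cj(n), np(n);
  int k = 0;
  for (std::map<std::pair<int, int>, int>::const_iterator it = cc.begin();
       it != cc.end(); ++it, ++k) {
    ci[k] = it->first.first;
    cj[k] = it->first.second;
    np[k] = it->second;
  }
  return List::create(_["medium_pairs"] = medium_pairs,
                      _["i"] = ci, _["j"] = cj, _["npairs"] = np);
}

// Per-cell site count and centroid from a full lattice scan (the
// bookkeeping oracle for incrementally maintained areas).
// [[Rcpp::export]]
List cpm_census(const IntegerMatrix &lat, int max_id) {
  const int nr = lat.nrow(), nc = lat.ncol();
  IntegerVector count(max_id);
  NumericVector sr(max_id), sc(max_id);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      const int s = lat(r, c);
      if (s > 0 && s <= max_id) {
        count[s - 1] += 1;
        sr[s - 1] += r;
        sc[s - 1] += c;
      }
    }
  }
  NumericVector cr(max_id), ccol(max_id);
  for (int i = 0; i < max_id; ++i) {
    if (count[i] > 0) {
      cr[i] = sr[i] / count[i];
      ccol[i] = sc[i] / count[i];
    } else {
      cr[i] = NA_REAL;
      ccol[i] = NA_REAL;
    }
  }
  return List::create(_["area"] = count,
                      _["centroid_row"] = cr, _["centroid_col"] = ccol);
}

// Number of Moore-connected components per cell identity (1 everywhere
// when no cell is fragmented).
// [[Rcpp::export]]
IntegerVector cpm_fragments(const IntegerMatrix &lat, int max_id) {
  const int nr = lat.nrow(), nc = lat.ncol();
  IntegerVector comps(max_id);
  std::vector<bool> seen((size_t) nr * nc, false);
  std::vector<int> stack;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      const int s = lat(r, c);
      const size_t id0 = (size_t) r + (size_t) nr * c;
      if (s <= 0 || s > max_id || seen[id0]) continue;
      comps[s - 1] += 1;
      seen[id0] = true;
      stack.push_back(r + nr * c);
      while (!stack.empty()) {
        const int cur = stack.back(); stack.pop_back();
        const int cr = cur % nr, cc2 = cur / nr;
        for (int d = 0; d < 8; ++d) {
          const int rr = cr + DR[d], c3 = cc2 + DC[d];
          if (rr < 0 || c3 < 0 || rr >= nr || c3 >= nc) continue;
          const size_t id1 = (size_t) rr + (size_t) nr * c3;
          if (!seen[id1] && lat(rr, c3) == s) {
            seen[id1] = true;
            stack.push_back(rr + nr * c3);
          }
        }
      }
    }
  }
  return comps;
}
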