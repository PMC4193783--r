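// Core Cellular Potts Model kernel: three-term Hamiltonian (contact energy,
// area constraint, chemotactic field coupling) and Metropolis dynamics on a
// bounded 2-D lattice. Label 0 marks the inaccessible boundary ring; cells
// are labelled 1..N and carry a type 1..nt. All randomness comes from R's
// RNG so set.seed() controls every run.
#include <Rcpp.h>
using namespace Rcpp;

namespace {

inline int type_of(int lab, const int* type) {
  // boundary sites have "type" 0; J row/column 0 is the boundary row
  return lab == 0 ? 0 : type[lab - 1];
}

struct Params {
  const double* J;   // (nt+1) x (nt+1), column-major
  const double* mu;  // length nt (type-indexed, 1-based types)
  const double* atarget; // length nt
  double lambda;
  int ntp1;          // nt + 1 (leading dimension of J)
  inline double Jat(int t1, int t2) const { return J[t1 + ntp1 * t2]; }
  inline double muat(int t) const { return t == 0 ? 0.0 : mu[t - 1]; }
  inline double At(int t) const { return atarget[t - 1]; }
};

// Energy change for copying the label at (nx,ny) onto interior site (x,y).
// Only terms touching (x,y) change, so this is O(1). Coordinates 0-based.
inline double delta_local(const int* lab, const int* type, const double* field,
                          const Params& p, const std::vector<int>& area,
                          int W, int x, int y, int nx, int ny) {
  const int so = lab[x + W * y];
  const int sn = lab[nx + W * ny];
  if (so == sn) return 0.0;
  const int to = type_of(so, type);
  const int tn = type_of(sn, type);
  static const int dx[4] = {1, -1, 0, 0};
  static const int dy[4] = {0, 0, 1, -1};
  double dH = 0.0;
  for (int d = 0; d < 4; ++d) {
    const int s2 = lab[(x + dx[d]) + W * (y + dy[d])];
    const int t2 = type_of(s2, type);
    if (sn != s2) dH += p.Jat(tn, t2);
    if (so != s2) dH -= p.Jat(to, t2);
  }
  // area terms: the shrinking cell so loses one site, the growing cell sn
  // gains one (sn == 0 never reaches here; boundary copies are rejected
  // before the energy is evaluated)
  const double Ao = p.At(to);
  const double An = p.At(tn);
  const double ao = (double)area[so];
  const double an = (double)area[sn];
  dH += p.lambda * ((ao - 1 - Ao) * (ao - 1 - Ao) - (ao - Ao) * (ao - Ao));
  dH += p.lambda * ((an + 1 - An) * (an + 1 - An) - (an - An) * (an - An));
  // chemotactic coupling: each occupied site contributes -mu(type) * C(site)
  dH += -(p.muat(tn) - p.muat(to)) * field[x + W * y];
  return dH;
}

void recount(const int* lab, int W, int H, int N, std::vector<int>& area,
             std::vector<double>& sumx, std::vector<double>& sumy) {
  area.assign(N + 1, 0);
  sumx.assign(N + 1, 0.0);
  sumy.assign(N + 1, 0.0);
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      const int s = lab[x + W * y];
      if (s > 0) {
        area[s] += 1;
        sumx[s] += x + 1;  // 1-based site coordinates, as seen from R
        sumy[s] += y + 1;
      }
    }
}

struct UnionFind {
  std::vector<int> parent;
  void reset(int n) {
    parent.resize(n + 1);
    for (int i = 0; i <= n; ++i) parent[i] = i;
  }
  int find(int i) {
    while (parent[i] != i) {
      parent[i] = parent[parent[i]];
      i = parent[i];
    }
    return i;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[a] = b;
  }
};

// Clusters: connected components of the cell-adjacency graph restricted to
// same-type edges; two cells are adjacent iff any of their sites are
// 4-neighbours. Cells with zero area (possible when vanishing is allowed)
// are ignored.
int count_clusters_core(const int* lab, const int* type, int W, int H, int N,
                        UnionFind& uf, std::vector<char>& seen) {
  uf.reset(N);
  seen.assign(N + 1, 0);
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      const int s = lab[x + W * y];
      if (s == 0) continue;
      seen[s] = 1;
      if (x + 1 < W) {
        const int s2 = lab[(x + 1) + W * y];
        if (s2 > 0 && s2 != s && type[s - 1] == type[s2 - 1]) uf.unite(s, s2);
      }
      if (y + 1 < H) {
        const int s2 = lab[x + W * (y + 1)];
        if (s2 > 0 && s2 != s && type[s - 1] == type[s2 - 1]) uf.unite(s, s2);
      }
    }
  int n = 0;
  for (int i = 1; i <= N; ++i)
    if (seen[i] && uf.find(i) == i) ++n;
  return n;
}

}  // namespace

// [[Rcpp::export]]
double cpm_total_energy_cpp(IntegerMatrix labels, IntegerVector type,
                            NumericMatrix field, NumericMatrix J,
                            NumericVector mu, double lambda,
                            NumericVector atarget) {
  const int W = labels.nrow(), H = labels.ncol();
  const int N = type.size();
  const int* lab = labels.begin();
  const int* ty = type.begin();
  Params p{J.begin(), mu.begin(), atarget.begin(), lambda, (int)mu.size() + 1};
  double E = 0.0;
  // contact term, each 4-neighbour pair counted once
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      const int s = lab[x + W * y];
      if (x + 1 < W) {
        const int s2 = lab[(x + 1) + W * y];
        if (s != s2) E += p.Jat(type_of(s, ty), type_of(s2, ty));
      }
      if (y + 1 < H) {
        const int s2 = lab[x + W * (y + 1)];
        if (s != s2) E += p.Jat(type_of(s, ty), type_of(s2, ty));
      }
      if (s > 0) E += -p.muat(type_of(s, ty)) * field[x + W * y];
    }
  std::vector<int> area;
  std::vector<double> sx, sy;
  recount(lab, W, H, N, area, sx, sy);
  for (int i = 1; i <= N; ++i) {
    const double d = area[i] - p.At(ty[i - 1]);
    E += lambda * d * d;
  }
  return E;
}

// [[Rcpp::export]]
double cpm_delta_energy_cpp(IntegerMatrix labels, IntegerVector type,
                            NumericMatrix field, NumericMatrix J,
                            NumericVector mu, double lambda,
                            NumericVector atarget, int x, int y, int nx,
                            int ny) {
  const int W = labels.nrow(), H = labels.ncol();
  if (x < 2 || x > W - 1 || y < 2 || y > H - 1)
    stop("site (x, y) must be an interior lattice site");
  if (std::abs(x - nx) + std::abs(y - ny) != 1)
    stop("(nx, ny) must be one of the four neighbours of (x, y)");
  const int* lab = labels.begin();
  if (lab[(nx - 1) + W * (ny - 1)] == 0)
    stop("cannot copy the boundary sentinel onto an interior site");
  std::vector<int> area;
  std::vector<double> sx, sy;
  recount(lab, W, H, (int)type.size(), area, sx, sy);
  Params p{J.begin(), mu.begin(), atarget.begin(), lambda, (int)mu.size() + 1};
  return delta_local(lab, type.begin(), field.begin(), p, area, W, x - 1,
                     y - 1, nx - 1, ny - 1);
}

// [[Rcpp::export]]
int cpm_count_clusters_cpp(IntegerMatrix labels, IntegerVector type) {
  UnionFind uf;
  std::vector<char> seen;
  return count_clusters_core(labels.begin(), type.begin(), labels.nrow(),
                             labels.ncol(), (int)type.size(), uf, seen);
}

// Single Metropolis attempt at a given site/neighbour pair. When apply is
// true and the move is accepted the labels matrix is modified in place.
// [[Rcpp::export]]
List cpm_attempt_cpp(IntegerMatrix labels, IntegerVector type,
                     NumericMatrix field, NumericMatrix J, NumericVector mu,
                     double lambda, double temp, NumericVector atarget,
                     int x, int y, int nx, int ny, bool allow_vanish,
                     bool apply) {
  const int W = labels.nrow(), H = labels.ncol();
  if (x < 2 || x > W - 1 || y < 2 || y > H - 1)
    stop("site (x, y) must be an interior lattice site");
  int* lab = labels.begin();
  const int so = lab[(x - 1) + W * (y - 1)];
  const int sn = lab[(nx - 1) + W * (ny - 1)];
  if (so == sn)  // same-cell copy: no state change, always accepted
    return List::create(_["accepted"] = true, _["delta"] = 0.0,
                        _["changed"] = false);
  if (sn == 0)  // boundary sentinel may not invade the interior
    return List::create(_["accepted"] = false, _["delta"] = NA_REAL,
                        _["changed"] = false);
  std::vector<int> area;
  std::vector<double> sx, sy;
  recount(lab, W, H, (int)type.size(), area, sx, sy);
  if (!allow_vanish && area[so] == 1)
    return List::create(_["accepted"] = false, _["delta"] = NA_REAL,
                        _["changed"] = false);
  Params p{J.begin(), mu.begin(), atarget.begin(), lambda, (int)mu.size() + 1};
  const double dH = delta_local(lab, type.begin(), field.begin(), p, area, W,
                                x - 1, y - 1, nx - 1, ny - 1);
  const bool accepted = dH <= 0.0 || unif_rand() < std::exp(-dH / temp);
  if (accepted && apply) lab[(x - 1) + W * (y - 1)] = sn;
  return List::create(_["accepted"] = accepted, _["delta"] = dH,
                      _["changed"] = accepted && apply);
}

// Main driver: n_mcs sweeps of (interior site count) elementary attempts.
// Records cluster count and per-cell area/centroid every `cadence` MCS.
// If monitor_cell > 0, reports the first MCS at which that cell's centroid
// x-coordinate exceeds monitor_x (checked after every MCS, and at MCS 0).
// [[Rcpp::export]]
List cpm_run_cpp(IntegerMatrix labels_in, IntegerVector type,
                 NumericMatrix field, NumericMatrix J, NumericVector mu,
                 double lambda, double temp, NumericVector atarget,
                 int n_mcs, int cadence, bool allow_vanish,
                 bool record_initial, int monitor_cell, double monitor_x,
                 bool stop_at_crossing, int mcs_offset) {
  IntegerMatrix labels = clone(labels_in);
  const int W = labels.nrow(), H = labels.ncol();
  const int N = type.size();
  int* lab = labels.begin();
  const int* ty = type.begin();
  const double* fld = field.begin();
  Params p{J.begin(), mu.begin(), atarget.begin(), lambda, (int)mu.size() + 1};

  std::vector<int> area;
  std::vector<double> sumx, sumy;
  recount(lab, W, H, N, area, sumx, sumy);

  const int Wi = W - 2, Hi = H - 2;       // interior extent
  const long n_per_mcs = (long)Wi * Hi;   // attempts per MCS
  static const int dx[4] = {1, -1, 0, 0};
  static const int dy[4] = {0, 0, 1, -1};

  // records fall on the absolute clock: (mcs + mcs_offset) % cadence == 0
  const int n_periodic = cadence > 0
      ? (n_mcs + mcs_offset) / cadence - mcs_offset / cadence : 0;
  const int nrec = (record_initial ? 1 : 0) + n_periodic;
  IntegerVector rec_mcs(nrec), rec_ncl(nrec);
  IntegerMatrix rec_area(nrec, N);
  NumericMatrix rec_cx(nrec, N), rec_cy(nrec, N);
  UnionFind uf;
  std::vector<char> seen;
  int irec = 0;
  auto record = [&](int mcs) {
    rec_mcs[irec] = mcs;
    rec_ncl[irec] = count_clusters_core(lab, ty, W, H, N, uf, seen);
    for (int i = 0; i < N; ++i) {
      rec_area(irec, i) = area[i + 1];
      rec_cx(irec, i) = area[i + 1] > 0 ? sumx[i + 1] / area[i + 1] : NA_REAL;
      rec_cy(irec, i) = area[i + 1] > 0 ? sumy[i + 1] / area[i + 1] : NA_REAL;
    }
    ++irec;
  };
  if (record_initial) record(0);

  int crossing = -1;
  if (monitor_cell > 0 && area[monitor_cell] > 0 &&
      sumx[monitor_cell] / area[monitor_cell] > monitor_x)
    crossing = 0;

  long n_accepted = 0;
  const long n_attempts = (long)n_mcs * n_per_mcs;
  for (int mcs = 1; mcs <= n_mcs; ++mcs) {
    for (long a = 0; a < n_per_mcs; ++a) {
      // one uniform draw picks (site, direction) jointly
      long u = (long)(unif_rand() * (double)(n_per_mcs * 4));
      if (u >= n_per_mcs * 4) u = n_per_mcs * 4 - 1;
      const int d = (int)(u & 3L);
      const long site = u >> 2;
      const int x = 1 + (int)(site % Wi);
      const int y = 1 + (int)(site / Wi);
      const int nx = x + dx[d], ny = y + dy[d];
      const int so = lab[x + W * y];
      const int sn = lab[nx + W * ny];
      if (so == sn) { ++n_accepted; continue; }
      if (sn == 0) continue;
      if (!allow_vanish && area[so] == 1) continue;
      const double dH =
          delta_local(lab, ty, fld, p, area, W, x, y, nx, ny);
      if (dH <= 0.0 || unif_rand() < std::exp(-dH / temp)) {
        lab[x + W * y] = sn;
        area[so] -= 1; area[sn] += 1;
        sumx[so] -= x + 1; sumy[so] -= y + 1;
        sumx[sn] += x + 1; sumy[sn] += y + 1;
        ++n_accepted;
      }
    }
    if (monitor_cell > 0 && crossing < 0 && area[monitor_cell] > 0 &&
        sumx[monitor_cell] / area[monitor_cell] > monitor_x) {
      crossing = mcs;
      if (stop_at_crossing) break;
    }
    if (cadence > 0 && (mcs + mcs_offset) % cadence == 0) record(mcs);
    if (mcs % 256 == 0) checkUserInterrupt();
  }

  if (irec < nrec) {
    rec_mcs = head(rec_mcs, irec);
    rec_ncl = head(rec_ncl, irec);
  }
  IntegerVector out_area(N);
  NumericVector out_cx(N), out_cy(N);
  for (int i = 0; i < N; ++i) {
    out_area[i] = area[i + 1];
    out_cx[i] = area[i + 1] > 0 ? sumx[i + 1] / area[i + 1] : NA_REAL;
    out_cy[i] = area[i + 1] > 0 ? sumy[i + 1] / area[i + 1] : NA_REAL;
  }
  return List::create(
      _["labels"] = labels, _["rec_mcs"] = rec_mcs,
      _["rec_n_clusters"] = rec_ncl, _["rec_area"] = rec_area,
      _["rec_cx"] = rec_cx, _["rec_cy"] = rec_cy, _["area"] = out_area,
      _["cx"] = out_cx, _["cy"] = out_cy, _["n_attempts"] = (double)n_attempts,
      _["n_accepted"] = (double)n_accepted,
      _["crossing_mcs"] = crossing < 0 ? NA_INTEGER : crossing);
}
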