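// Hot paths of the cellular Potts engine: Metropolis copy attempts,
// explicit/relaxation diffusion of the nutrient fields, the per-cell
// metabolism scan, reflected mutation walks, and periodic centroids.
// All randomness comes from R's RNG so set.seed() governs trajectories.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// cell types: 0 = none/medium, 1 = tissue cell (c), 2 = vessel (EC)
static inline int region_type(int id, const IntegerVector& ctype) {
  return id == 0 ? 0 : ctype[id - 1];
}

struct JSet {
  double cc, cec, cm, ecm, ecec, rho_cam_ec, rho_mas_m;
};

// Effective contact energy between two *different* regions a, b (ids).
static inline double jeff(int a, int b, const IntegerVector& ctype,
                          const NumericMatrix& pheno, const JSet& J) {
  int ta = a == 0 ? 0 : ctype[a - 1];
  int tb = b == 0 ? 0 : ctype[b - 1];
  if (ta == 1 && tb == 1) {
    double ra = pheno(a - 1, 2), rb = pheno(b - 1, 2);
    return J.cc - (ra < rb ? ra : rb);
  }
  if ((ta == 1 && tb == 0) || (ta == 0 && tb == 1)) {
    double rm = ta == 1 ? pheno(a - 1, 3) : pheno(b - 1, 3);
    return J.cm - (rm < J.rho_mas_m ? rm : J.rho_mas_m);
  }
  if ((ta == 1 && tb == 2) || (ta == 2 && tb == 1)) {
    double rc = ta == 1 ? pheno(a - 1, 2) : pheno(b - 1, 2);
    return J.cec - (rc < J.rho_cam_ec ? rc : J.rho_cam_ec);
  }
  if ((ta == 2 && tb == 0) || (ta == 0 && tb == 2)) return J.ecm;
  if (ta == 2 && tb == 2) return J.ecec;
  return 0.0; // medium-medium never reached (equal ids are excluded)
}

static const int MOORE_DX[8] = {1, -1, 0, 0, 1, 1, -1, -1};
static const int MOORE_DY[8] = {0, 0, 1, -1, 1, -1, 1, -1};

static inline int wrap(int a, int n) {
  a %= n;
  return a < 0 ? a + n : a;
}

// floor-based floating modulus into [0, m); avoids fmod (whose symbol
// version can exceed the host glibc when building under a newer sysroot)
static inline double dmod(double x, double m) {
  double y = x - std::floor(x / m) * m;
  return (y >= m) ? y - m : y;
}

// Result codes: 0 rejected, 1 accepted, 2 skipped (identity copy)
static int attempt_copy_core(IntegerMatrix& grid, const IntegerVector& ctype,
                             IntegerVector& V, const NumericVector& VT,
                             const NumericMatrix& pheno,
                             const NumericMatrix& g, const NumericMatrix& o2,
                             const NumericMatrix& lac,
                             double temp, const JSet& J, int nb,
                             int x, int y, int nx, int ny,
                             bool execute, double* dh_out) {
  const int W = grid.nrow(), H = grid.ncol();
  int s = grid(x, y), t = grid(nx, ny);
  if (dh_out) *dh_out = NA_REAL;
  if (s == t) return 2;
  if (region_type(s, ctype) == 2 || region_type(t, ctype) == 2) return 0;

  double dh = 0.0;
  // volume term, normalized by target volume
  if (s != 0) {
    double vt = VT[s - 1];
    if (vt <= 0) vt = 1e-9;
    double lam = pheno(s - 1, 0), v = V[s - 1];
    dh += lam / vt * ((v + 1 - vt) * (v + 1 - vt) - (v - vt) * (v - vt));
  }
  if (t != 0) {
    double vt = VT[t - 1];
    if (vt <= 0) vt = 1e-9;
    double lam = pheno(t - 1, 0), v = V[t - 1];
    dh += lam / vt * ((v - 1 - vt) * (v - 1 - vt) - (v - vt) * (v - vt));
  }
  // adhesion: pairs incident to the overwritten site
  for (int k = 0; k < nb; ++k) {
    int qx = wrap(nx + MOORE_DX[k], W), qy = wrap(ny + MOORE_DY[k], H);
    int n = grid(qx, qy);
    if (n != s) dh += jeff(s, n, ctype, pheno, J);
    if (n != t) dh -= jeff(t, n, ctype, pheno, J);
  }
  // chemotaxis: extending cell attracted up-gradient, retracting cell
  // penalized for losing high-concentration sites (symmetric convention)
  double dg = g(nx, ny) - g(x, y);
  double do2 = o2(nx, ny) - o2(x, y);
  double dl = lac(nx, ny) - lac(x, y);
  if (s != 0 && ctype[s - 1] == 1) {
    dh -= pheno(s - 1, 4) * dg + pheno(s - 1, 5) * do2 + pheno(s - 1, 6) * dl;
  }
  if (t != 0 && ctype[t - 1] == 1) {
    dh += pheno(t - 1, 4) * dg + pheno(t - 1, 5) * do2 + pheno(t - 1, 6) * dl;
  }
  if (dh_out) *dh_out = dh;

  bool accept;
  if (dh < 0) {
    accept = true;
  } else {
    double z = dh / temp;
    accept = (z < 700.0) && (unif_rand() < std::exp(-z));
  }
  if (accept && execute) {
    grid(nx, ny) = s;
    if (s != 0) V[s - 1] += 1;
    if (t != 0) V[t - 1] -= 1;
  }
  return accept ? 1 : 0;
}

// [[Rcpp::export]]
int cpp_copy_attempts(IntegerMatrix grid, IntegerVector ctype,
                      IntegerVector V, NumericVector VT, NumericMatrix pheno,
                      NumericMatrix g, NumericMatrix o2, NumericMatrix lac,
                      double temp, double j_cc, double j_cec, double j_cm,
                      double j_ecm, double j_ecec,
                      double rho_cam_ec, double rho_mas_m,
                      int nattempts, int nb) {
  const int W = grid.nrow(), H = grid.ncol();
  JSet J = {j_cc, j_cec, j_cm, j_ecm, j_ecec, rho_cam_ec, rho_mas_m};
  int accepted = 0;
  for (int a = 0; a < nattempts; ++a) {
    int x = (int)(unif_rand() * W); if (x == W) x = W - 1;
    int y = (int)(unif_rand() * H); if (y == H) y = H - 1;
    int k = (int)(unif_rand() * nb); if (k == nb) k = nb - 1;
    int nx = wrap(x + MOORE_DX[k], W), ny = wrap(y + MOORE_DY[k], H);
    int res = attempt_copy_core(grid, ctype, V, VT, pheno, g, o2, lac,
                                temp, J, nb, x, y, nx, ny, true, nullptr);
    if (res == 1) ++accepted;
  }
  return accepted;
}

// [[Rcpp::export]]
List cpp_attempt_at(IntegerMatrix grid, IntegerVector ctype,
                    IntegerVector V, NumericVector VT, NumericMatrix pheno,
                    NumericMatrix g, NumericMatrix o2, NumericMatrix lac,
                    double temp, double j_cc, double j_cec, double j_cm,
                    double j_ecm, double j_ecec,
                    double rho_cam_ec, double rho_mas_m, int nb,
                    int x, int y, int nx, int ny, bool execute) {
  JSet J = {j_cc, j_cec, j_cm, j_ecm, j_ecec, rho_cam_ec, rho_mas_m};
  double dh;
  int res = attempt_copy_core(grid, ctype, V, VT, pheno, g, o2, lac,
                              temp, J, nb, x, y, nx, ny, execute, &dh);
  return List::create(_["accepted"] = res == 1, _["skipped"] = res == 2,
                      _["delta_h"] = dh);
}

// Explicit 5-point diffusion substeps (or relaxation to quasi-steady state
// when relax = true), with Dirichlet clamps re-applied after every sweep.
// clamp_idx is 0-based linear (column-major) indexing.
// [[Rcpp::export]]
int cpp_diffuse(NumericMatrix field, double mu, int nsub,
                IntegerVector clamp_idx, NumericVector clamp_val,
                bool relax, double tol, int maxiter) {
  const int W = field.nrow(), H = field.ncol(), N = W * H;
  double* f = REAL(field);
  std::vector<double> buf(N);
  const int nclamp = clamp_idx.size();
  for (int c = 0; c < nclamp; ++c) f[clamp_idx[c]] = clamp_val[c];
  int iters = relax ? maxiter : nsub;
  int done = 0;
  for (int it = 0; it < iters; ++it) {
    double maxch = 0.0;
    for (int y = 0; y < H; ++y) {
      int yu = (y + 1 == H ? 0 : y + 1), yd = (y == 0 ? H - 1 : y - 1);
      const double* row = f + (size_t)W * y;
      const double* rup = f + (size_t)W * yu;
      const double* rdn = f + (size_t)W * yd;
      double* out = buf.data() + (size_t)W * y;
      for (int x = 0; x < W; ++x) {
        int xr = (x + 1 == W ? 0 : x + 1), xl = (x == 0 ? W - 1 : x - 1);
        double lap = row[xr] + row[xl] + rup[x] + rdn[x] - 4.0 * row[x];
        out[x] = row[x] + mu * lap;
        if (relax) {
          double ch = std::fabs(mu * lap);
          if (ch > maxch) maxch = ch;
        }
      }
    }
    std::copy(buf.begin(), buf.end(), f);
    for (int c = 0; c < nclamp; ++c) f[clamp_idx[c]] = clamp_val[c];
    ++done;
    if (!std::isfinite(f[0])) stop("cpp_diffuse(): field diverged (NaN/Inf)");
    if (relax && maxch < tol) break;
  }
  return done;
}

// Per-cell metabolism: Michaelis-Menten glucose uptake on surface sites
// (availability-clamped), oxygen-limited respiration, lactate secretion.
// Cells are processed in ascending id order; each cell's transporter demand
// uses the field state it encounters (pre-consumption for that cell).
// Returns M x 8 matrix: Ug, Uo2, lactate secreted, Eprod, meanO2 (over all
// of the cell's sites, pre-uptake), surface count S, respired glucose,
// site count.
// [[Rcpp::export]]
NumericMatrix cpp_metabolize(IntegerMatrix grid, IntegerVector ctype,
                             NumericMatrix pheno, NumericVector hvec,
                             NumericMatrix g, NumericMatrix o2,
                             NumericMatrix lac,
                             double v_m, double k_m, double alpha_r,
                             double n0_cap) {
  const int W = grid.nrow(), H = grid.ncol();
  const int M = ctype.size();
  NumericMatrix out(M, 8);
  std::vector<std::vector<int>> surf(M);
  std::vector<double> o2sum(M, 0.0);
  std::vector<int> count(M, 0);
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < W; ++x) {
      int id = grid(x, y);
      if (id == 0 || ctype[id - 1] != 1) continue;
      o2sum[id - 1] += o2(x, y);
      count[id - 1] += 1;
      bool boundary = false;
      for (int k = 0; k < 8; ++k) {
        int qx = wrap(x + MOORE_DX[k], W), qy = wrap(y + MOORE_DY[k], H);
        if (grid(qx, qy) != id) { boundary = true; break; }
      }
      if (boundary) surf[id - 1].push_back(x + W * y);
    }
  }
  for (int i = 0; i < M; ++i) {
    if (ctype[i] != 1 || count[i] == 0) continue;
    double h = hvec[i];
    double n0 = pheno(i, 7);
    if (n0 > n0_cap) n0 = n0_cap;
    double ng = n0 * (alpha_r - 2.0) / (alpha_r - (alpha_r - 2.0) * h);
    const std::vector<int>& ss = surf[i];
    int S = (int)ss.size();
    if (S == 0) { out(i, 4) = o2sum[i] / count[i]; out(i, 7) = count[i]; continue; }
    double per_site = ng / (double)S * v_m;
    double Ug = 0, Uo2 = 0, Lsec = 0, Gresp = 0;
    for (int j = 0; j < S; ++j) {
      int idx = ss[j];
      double gx = REAL(g)[idx];
      if (gx <= 0) continue;
      double u = per_site * gx / (k_m + gx);
      if (u > gx) u = gx;
      double ferm = h * u, resp = (1.0 - h) * u;
      double need = 6.0 * resp;
      double o2x = REAL(o2)[idx];
      if (need > o2x) { // oxygen-limited: unrespirable glucose stays outside
        resp = o2x / 6.0;
        need = o2x;
        u = ferm + resp;
      }
      REAL(g)[idx] = gx - u;
      REAL(o2)[idx] = o2x - need;
      REAL(lac)[idx] += 2.0 * ferm;
      Ug += u; Uo2 += need; Lsec += 2.0 * ferm; Gresp += resp;
    }
    out(i, 0) = Ug;
    out(i, 1) = Uo2;
    out(i, 2) = Lsec;
    out(i, 3) = 2.0 * (Ug - Gresp) + alpha_r * Gresp;
    out(i, 4) = o2sum[i] / count[i];
    out(i, 5) = S;
    out(i, 6) = Gresp;
    out(i, 7) = count[i];
  }
  colnames(out) = CharacterVector::create("u_g", "u_o2", "lac_sec", "e_prod",
                                          "mean_o2", "surface", "g_resp",
                                          "sites");
  return out;
}

// Reflected Gaussian random walks (shared reflection rule with
// reflect_bounds()): n_walkers walkers advanced n_steps; returns final
// positions. Used for stationary-distribution checks.
// [[Rcpp::export]]
NumericVector cpp_reflect_walk(int n_walkers, int n_steps, double start,
                               double sigma, double lo, double hi) {
  NumericVector pos(n_walkers, start);
  double span = hi - lo;
  for (int s = 0; s < n_steps; ++s) {
    for (int i = 0; i < n_walkers; ++i) {
      double x = pos[i] + norm_rand() * sigma;
      double y = dmod(x - lo, 2.0 * span);
      if (y > span) y = 2.0 * span - y;
      pos[i] = y + lo;
    }
  }
  return pos;
}

// Periodic centroids per cell id (circular mean per axis), 1-based coords.
// [[Rcpp::export]]
NumericMatrix cpp_centroids(IntegerMatrix grid, int n_ids) {
  const int W = grid.nrow(), H = grid.ncol();
  const double tw = 2.0 * M_PI / W, th = 2.0 * M_PI / H;
  std::vector<double> cx(n_ids, 0), sx(n_ids, 0), cy(n_ids, 0), sy(n_ids, 0);
  std::vector<int> n(n_ids, 0);
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < W; ++x) {
      int id = grid(x, y);
      if (id == 0 || id > n_ids) continue;
      cx[id - 1] += std::cos(tw * x); sx[id - 1] += std::sin(tw * x);
      cy[id - 1] += std::cos(th * y); sy[id - 1] += std::sin(th * y);
      n[id - 1] += 1;
    }
  }
  NumericMatrix out(n_ids, 2);
  for (int i = 0; i < n_ids; ++i) {
    if (n[i] == 0) { out(i, 0) = NA_REAL; out(i, 1) = NA_REAL; continue; }
    double ax = std::atan2(sx[i], cx[i]) / tw;
    double ay = std::atan2(sy[i], cy[i]) / th;
    out(i, 0) = dmod(ax, (double)W) + 1.0;
    out(i, 1) = dmod(ay, (double)H) + 1.0;
  }
  return out;
}
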