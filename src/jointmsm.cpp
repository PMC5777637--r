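#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstring>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Small-matrix exponentials.
//
// The conditional chains are at most 4x4 and block upper triangular:
// the undamaged 2x2 activity block, a diagonal coupling into the damaged
// states, and the damaged 2x2 activity block. All 2x2 blocks of a generator
// have real eigenvalues (off-diagonal product >= 0), so exp(Qt) has a stable
// spectral closed form. Near-degenerate spectra fall back to scaling-and-
// squaring with a [6/6] Pade approximant.
// ---------------------------------------------------------------------------

static inline double sinch(double x) {
  if (std::fabs(x) < 1e-5) return 1.0 + x * x / 6.0;
  return std::sinh(x) / x;
}

// rates are clamped to keep the generator finite at extreme quadrature nodes
static inline double clamp_rate(double x) {
  return (x > 1e10) ? 1e10 : x;
}

// (exp(nu t) - exp(om t)) / (nu - om), given the two exponentials; stable for
// nu ~ om and free of overflow when nu, om <= 0.
static inline double phi_fn(double nu, double om, double t, double e_nu,
                            double e_om) {
  double d = (nu - om) * t;
  if (std::fabs(d) > 1e-3) return (e_nu - e_om) / (nu - om);
  return t * std::exp(0.5 * (nu + om) * t) * sinch(0.5 * d);
}

// exp(M t) for real 2x2 M (row-major). Stable for coinciding eigenvalues and
// overflow-safe when the eigenvalues are nonpositive (generator blocks).
static void expm2(const double M[4], double t, double P[4]) {
  double th = 0.5 * (M[0] + M[3]);
  double dd = 0.5 * (M[0] - M[3]);
  double disc = dd * dd + M[1] * M[2];
  double c, g;
  if (disc >= 0.0) {
    double del = std::sqrt(disc);
    double e1 = std::exp((th + del) * t), e2 = std::exp((th - del) * t);
    c = 0.5 * (e1 + e2);
    g = phi_fn(th + del, th - del, t, e1, e2);
  } else {
    double del = std::sqrt(-disc);
    double x = del * t;
    double eth = std::exp(th * t);
    double sinc = (std::fabs(x) < 1e-5) ? 1.0 - x * x / 6.0 : std::sin(x) / x;
    c = eth * std::cos(x);
    g = t * eth * sinc;
  }
  P[0] = c + g * (M[0] - th);
  P[1] = g * M[1];
  P[2] = g * M[2];
  P[3] = c + g * (M[3] - th);
}

static void matmul_n(const std::vector<double>& A, const std::vector<double>& B,
                     std::vector<double>& C, int n) {
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      double s = 0.0;
      for (int k = 0; k < n; ++k) s += A[i * n + k] * B[k * n + j];
      C[i * n + j] = s;
    }
}

// Solve A X = B (both n x n, row-major); Gaussian elimination, partial pivoting.
static bool solve_n(std::vector<double> A, std::vector<double>& B, int n) {
  for (int col = 0; col < n; ++col) {
    int piv = col;
    double best = std::fabs(A[col * n + col]);
    for (int r = col + 1; r < n; ++r) {
      double v = std::fabs(A[r * n + col]);
      if (v > best) { best = v; piv = r; }
    }
    if (best == 0.0) return false;
    if (piv != col) {
      for (int k = 0; k < n; ++k) {
        std::swap(A[piv * n + k], A[col * n + k]);
        std::swap(B[piv * n + k], B[col * n + k]);
      }
    }
    double d = A[col * n + col];
    for (int k = 0; k < n; ++k) { A[col * n + k] /= d; B[col * n + k] /= d; }
    for (int r = 0; r < n; ++r) {
      if (r == col) continue;
      double f = A[r * n + col];
      if (f == 0.0) continue;
      for (int k = 0; k < n; ++k) {
        A[r * n + k] -= f * A[col * n + k];
        B[r * n + k] -= f * B[col * n + k];
      }
    }
  }
  return true;
}

// exp(A) via scaling-and-squaring with a [6/6] Pade approximant.
static void expm_pade(std::vector<double> A, int n, std::vector<double>& P) {
  double norm = 0.0;
  for (int i = 0; i < n; ++i) {
    double rs = 0.0;
    for (int j = 0; j < n; ++j) rs += std::fabs(A[i * n + j]);
    if (rs > norm) norm = rs;
  }
  int s = 0;
  if (norm > 0.5) {
    s = (int)std::ceil(std::log2(norm / 0.5));
    double f = std::ldexp(1.0, -s);
    for (int k = 0; k < n * n; ++k) A[k] *= f;
  }
  // Pade [6/6] coefficients
  double c[7];
  c[0] = 1.0;
  for (int k = 0; k < 6; ++k)
    c[k + 1] = c[k] * (6.0 - k) / ((k + 1.0) * (12.0 - k));
  std::vector<double> A2(n * n), A4(n * n), A6(n * n), U(n * n), V(n * n),
      T(n * n);
  matmul_n(A, A, A2, n);
  matmul_n(A2, A2, A4, n);
  matmul_n(A4, A2, A6, n);
  // U = A (c1 I + c3 A2 + c5 A4) ; V = c0 I + c2 A2 + c4 A4 + c6 A6
  for (int k = 0; k < n * n; ++k)
    T[k] = c[3] * A2[k] + c[5] * A4[k];
  for (int i = 0; i < n; ++i) T[i * n + i] += c[1];
  matmul_n(A, T, U, n);
  for (int k = 0; k < n * n; ++k)
    V[k] = c[2] * A2[k] + c[4] * A4[k] + c[6] * A6[k];
  for (int i = 0; i < n; ++i) V[i * n + i] += c[0];
  // P = (V - U)^{-1} (V + U)
  std::vector<double> D(n * n), N(n * n);
  for (int k = 0; k < n * n; ++k) { D[k] = V[k] - U[k]; N[k] = V[k] + U[k]; }
  if (!solve_n(D, N, n)) stop("matrix exponential: singular Pade denominator");
  P = N;
  for (int k = 0; k < s; ++k) {
    matmul_n(P, P, T, n);
    P.swap(T);
  }
}

static inline double clamp01(double x) {
  if (x < 0.0) return 0.0;
  if (x > 1.0) return 1.0;
  return x;
}

// 2-state chain with rates l1 (1->2) and l2 (2->1).
static void pmat_stayer(double l1, double l2, double t, double P[4]) {
  l1 = clamp_rate(l1); l2 = clamp_rate(l2);
  double s = l1 + l2;
  if (s <= 0.0) { P[0] = 1; P[1] = 0; P[2] = 0; P[3] = 1; return; }
  double es = std::exp(-s * t);
  P[0] = (l2 + l1 * es) / s;
  P[1] = (l1 - l1 * es) / s;
  P[2] = (l2 - l2 * es) / s;
  P[3] = (l1 + l2 * es) / s;
  for (int k = 0; k < 4; ++k) P[k] = clamp01(P[k]);
}

// 4-state mover chain: 1 = inactive/undamaged, 2 = active/undamaged,
// 3 = inactive/damaged, 4 = active/damaged. Damage irreversible.
static void pmat_mover6(double l12, double l21, double l13, double l24,
                        double l34, double l43, double t, double P[16]) {
  l12 = clamp_rate(l12); l21 = clamp_rate(l21); l13 = clamp_rate(l13);
  l24 = clamp_rate(l24); l34 = clamp_rate(l34); l43 = clamp_rate(l43);
  double a11 = -(l12 + l13), a12 = l12, a21 = l21, a22 = -(l21 + l24);
  double s = l34 + l43;
  double tha = 0.5 * (a11 + a22), dda = 0.5 * (a11 - a22);
  double disca = dda * dda + a12 * a21;  // >= 0
  double dela = disca > 0.0 ? std::sqrt(disca) : 0.0;
  double scale = 1.0 + std::fabs(tha);
  if (dela <= 1e-6 * scale || s <= 1e-10 * scale) {
    // near-degenerate spectrum: generic route
    std::vector<double> Q(16, 0.0), E;
    Q[0] = a11 * t; Q[1] = a12 * t; Q[2] = l13 * t;
    Q[4] = a21 * t; Q[5] = a22 * t; Q[7] = l24 * t;
    Q[10] = -l34 * t; Q[11] = l34 * t;
    Q[14] = l43 * t; Q[15] = -l43 * t;
    expm_pade(Q, 4, E);
    for (int k = 0; k < 16; ++k) P[k] = clamp01(E[k]);
    P[8] = P[9] = P[12] = P[13] = 0.0;
    return;
  }
  double nu1 = tha + dela, nu2 = tha - dela;
  double ea1 = std::exp(nu1 * t), ea2 = std::exp(nu2 * t);
  double ca = 0.5 * (ea1 + ea2);
  double ga = phi_fn(nu1, nu2, t, ea1, ea2);
  double EA[4] = {ca + ga * (a11 - tha), ga * a12,
                  ga * a21, ca + ga * (a22 - tha)};
  double es = std::exp(-s * t);
  double EB[4] = {(l43 + l34 * es) / s, (l34 - l34 * es) / s,
                  (l43 - l43 * es) / s, (l34 + l43 * es) / s};
  // spectral projectors of the undamaged block (eigenvalues tha +/- dela)
  double PA1[4] = {0.5 * (1.0 + (a11 - tha) / dela), 0.5 * a12 / dela,
                   0.5 * a21 / dela, 0.5 * (1.0 + (a22 - tha) / dela)};
  double PA2[4] = {1.0 - PA1[0], -PA1[1], -PA1[2], 1.0 - PA1[3]};
  // damaged block: eigenvalue 0 with projector R1, -s with R2
  double RB1[4] = {l43 / s, l34 / s, l43 / s, l34 / s};
  double RB2[4] = {1.0 - RB1[0], -RB1[1], -RB1[2], 1.0 - RB1[3]};
  double nus[2] = {nu1, nu2};
  double oms[2] = {0.0, -s};
  double eas[2] = {ea1, ea2};
  double ebs[2] = {1.0, es};
  const double* PAs[2] = {PA1, PA2};
  const double* RBs[2] = {RB1, RB2};
  double C[4] = {0, 0, 0, 0};
  for (int i = 0; i < 2; ++i)
    for (int j = 0; j < 2; ++j) {
      double phi = phi_fn(nus[i], oms[j], t, eas[i], ebs[j]);
      double M0 = PAs[i][0] * l13, M1 = PAs[i][1] * l24;
      double M2 = PAs[i][2] * l13, M3 = PAs[i][3] * l24;
      C[0] += phi * (M0 * RBs[j][0] + M1 * RBs[j][2]);
      C[1] += phi * (M0 * RBs[j][1] + M1 * RBs[j][3]);
      C[2] += phi * (M2 * RBs[j][0] + M3 * RBs[j][2]);
      C[3] += phi * (M2 * RBs[j][1] + M3 * RBs[j][3]);
    }
  P[0] = clamp01(EA[0]); P[1] = clamp01(EA[1]);
  P[2] = clamp01(C[0]);  P[3] = clamp01(C[1]);
  P[4] = clamp01(EA[2]); P[5] = clamp01(EA[3]);
  P[6] = clamp01(C[2]);  P[7] = clamp01(C[3]);
  P[8] = P[9] = 0.0;
  P[10] = clamp01(EB[0]); P[11] = clamp01(EB[1]);
  P[12] = P[13] = 0.0;
  P[14] = clamp01(EB[2]); P[15] = clamp01(EB[3]);
}

// 3-state mover chain: 1 = inactive, 2 = active, 3 = damaged (absorbing).
static void pmat_mover5(double l12, double l21, double l13, double l23,
                        double t, double P[9]) {
  l12 = clamp_rate(l12); l21 = clamp_rate(l21);
  l13 = clamp_rate(l13); l23 = clamp_rate(l23);
  double T[4] = {-(l12 + l13), l12, l21, -(l21 + l23)};
  double E[4];
  expm2(T, t, E);
  P[0] = clamp01(E[0]); P[1] = clamp01(E[1]); P[2] = clamp01(1.0 - E[0] - E[1]);
  P[3] = clamp01(E[2]); P[4] = clamp01(E[3]); P[5] = clamp01(1.0 - E[2] - E[3]);
  P[6] = 0.0; P[7] = 0.0; P[8] = 1.0;
}

// ---------------------------------------------------------------------------
// Exported matrix-exponential utilities
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix expm_generator_cpp(NumericMatrix Q, double dt) {
  int n = Q.nrow();
  std::vector<double> A(n * n), P;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) A[i * n + j] = Q(i, j) * dt;
  expm_pade(A, n, P);
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) out(i, j) = P[i * n + j];
  return out;
}

// Closed-form transition matrices used inside the likelihood.
// kind: 1 = six-state mover (rates l12,l21,l13,l24,l34,l43),
//       2 = five-state mover (l12,l21,l13,l23), 3 = stayer (l1,l2).
// [[Rcpp::export]]
NumericMatrix pmat_closed_cpp(int kind, NumericVector rates, double dt) {
  if (kind == 1) {
    double P[16];
    pmat_mover6(rates[0], rates[1], rates[2], rates[3], rates[4], rates[5],
                dt, P);
    NumericMatrix out(4, 4);
    for (int i = 0; i < 4; ++i)
      for (int j = 0; j < 4; ++j) out(i, j) = P[i * 4 + j];
    return out;
  } else if (kind == 2) {
    double P[9];
    pmat_mover5(rates[0], rates[1], rates[2], rates[3], dt, P);
    NumericMatrix out(3, 3);
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) out(i, j) = P[i * 3 + j];
    return out;
  }
  double P[4];
  pmat_stayer(rates[0], rates[1], dt, P);
  NumericMatrix out(2, 2);
  for (int i = 0; i < 2; ++i)
    for (int j = 0; j < 2; ++j) out(i, j) = P[i * 2 + j];
  return out;
}

// ---------------------------------------------------------------------------
// Panel likelihood
// ---------------------------------------------------------------------------

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double lse2(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

struct SixExtras {
  double edam_ag, edam_al, eact, est_ag, est_al, alpha;
};
struct FiveExtras {
  double est_in, est_ac, alpha1, alpha2;
};

// log conditional probability product for one covariate group, six-state mover
static inline double grp_logp_six_mover(
    double E12, double E21, double E13, double eu, double eau, double ev,
    const SixExtras& ex, double dt, const int* from, const int* to,
    const int* cnt, int ntr) {
  double l12 = E12 * eu, l21 = E21 * eau, l13 = E13 * ev;
  double l24 = l13 * ex.eact;
  double l34 = l12 * ex.edam_ag, l43 = l21 * ex.edam_al;
  double P[16];
  pmat_mover6(l12, l21, l13, l24, l34, l43, dt, P);
  double lp = 0.0;
  for (int k = 0; k < ntr; ++k) {
    double p = P[(from[k] - 1) * 4 + (to[k] - 1)];
    if (p <= 0.0) return NEG_INF;
    lp += cnt[k] * std::log(p);
  }
  return lp;
}

static inline double grp_logp_six_stayer(
    double E12, double E21, double eu, double eau, const SixExtras& ex,
    double dt, const int* from, const int* to, const int* cnt, int ntr) {
  double l1 = E12 * eu * ex.est_ag, l2 = E21 * eau * ex.est_al;
  double P[4];
  pmat_stayer(l1, l2, dt, P);
  double lp = 0.0;
  for (int k = 0; k < ntr; ++k) {
    if (from[k] > 2 || to[k] > 2) return NEG_INF;  // damage impossible
    double p = P[(from[k] - 1) * 2 + (to[k] - 1)];
    if (p <= 0.0) return NEG_INF;
    lp += cnt[k] * std::log(p);
  }
  return lp;
}

static inline void five_rates(double M1, double M2, double O1, double O2,
                              double eu, double eau, double ev, double ev2,
                              double* l12, double* l21, double* l13,
                              double* l23, double* mu1, double* mu2) {
  *mu1 = M1 * eu;
  *mu2 = M2 * eau;
  double o13 = O1 * ev, o23 = O2 * ev2;
  double p13 = o13 / (1.0 + o13), p23 = o23 / (1.0 + o23);
  *l12 = (1.0 - p13) / *mu1;
  *l13 = p13 / *mu1;
  *l21 = (1.0 - p23) / *mu2;
  *l23 = p23 / *mu2;
}

static inline double grp_logp_five_mover(
    double M1, double M2, double O1, double O2, double eu, double eau,
    double ev, double ev2, double dt, const int* from, const int* to,
    const int* cnt, int ntr) {
  double l12, l21, l13, l23, mu1, mu2;
  five_rates(M1, M2, O1, O2, eu, eau, ev, ev2, &l12, &l21, &l13, &l23,
             &mu1, &mu2);
  double P[9];
  pmat_mover5(l12, l21, l13, l23, dt, P);
  double lp = 0.0;
  for (int k = 0; k < ntr; ++k) {
    double p = P[(from[k] - 1) * 3 + (to[k] - 1)];
    if (p <= 0.0) return NEG_INF;
    lp += cnt[k] * std::log(p);
  }
  return lp;
}

static inline double grp_logp_five_stayer(
    double M1, double M2, double eu, double eau, const FiveExtras& ex,
    double dt, const int* from, const int* to, const int* cnt, int ntr) {
  double mu4 = M1 * eu * ex.est_in, mu5 = M2 * eau * ex.est_ac;
  double P[4];
  pmat_stayer(1.0 / mu4, 1.0 / mu5, dt, P);
  double lp = 0.0;
  for (int k = 0; k < ntr; ++k) {
    if (from[k] > 2 || to[k] > 2) return NEG_INF;
    double p = P[(from[k] - 1) * 2 + (to[k] - 1)];
    if (p <= 0.0) return NEG_INF;
    lp += cnt[k] * std::log(p);
  }
  return lp;
}

// Marginal log-likelihood for the whole panel.
//
// variant: 1 = six-state, 2 = five-state.
// re_structure: 1 = observation level (independent (u,v) per interval),
//               2 = patient level (one (u,v) for all intervals).
// Index vectors are 0-based offsets; states are 1-based.
// eta: per-group linear predictors incl. baselines
//   six-state columns: log lambda12, log lambda21, log lambda13 at u=v=0
//   five-state columns: log mu1, log mu2, log odds13, log odds23 at u=v=0
// extras six: (bdam_ag, bdam_al, bact, bst_ag, bst_al, alpha, sd_u, sd_v, rho, pi)
// extras five: (bst_in, bst_ac, alpha1, alpha2, sd_u, sd_v, rho, pi)
// gh_x, gh_logw: standardized (probabilist) Gauss-Hermite nodes / log-weights.
// [[Rcpp::export]]
List panel_loglik_cpp(int variant, int re_structure, IntegerVector pat_ptr,
                      IntegerVector cstar, NumericVector int_dt,
                      IntegerVector int_grp_ptr, IntegerVector grp_tr_ptr,
                      IntegerVector tr_from, IntegerVector tr_to,
                      IntegerVector tr_count, NumericMatrix eta,
                      NumericVector extras, NumericVector gh_x,
                      NumericVector gh_logw) {
  const int n_pat = cstar.size();
  const int n_grp = eta.nrow();
  const int n_nodes = gh_x.size();

  SixExtras ex6 = {0, 0, 0, 0, 0, 0};
  FiveExtras ex5 = {0, 0, 0, 0};
  double sd_u, sd_v, rho, ppi;
  if (variant == 1) {
    ex6.edam_ag = std::exp(extras[0]);
    ex6.edam_al = std::exp(extras[1]);
    ex6.eact = std::exp(extras[2]);
    ex6.est_ag = std::exp(extras[3]);
    ex6.est_al = std::exp(extras[4]);
    ex6.alpha = extras[5];
    sd_u = extras[6]; sd_v = extras[7]; rho = extras[8]; ppi = extras[9];
  } else {
    ex5.est_in = std::exp(extras[0]);
    ex5.est_ac = std::exp(extras[1]);
    ex5.alpha1 = extras[2];
    ex5.alpha2 = extras[3];
    sd_u = extras[4]; sd_v = extras[5]; rho = extras[6]; ppi = extras[7];
  }
  const double alpha_u = (variant == 1) ? ex6.alpha : ex5.alpha1;
  const double alpha_v = (variant == 1) ? 1.0 : ex5.alpha2;
  const double vsd = sd_v * std::sqrt(1.0 - rho * rho);

  // per-group exponentiated baselines
  std::vector<double> E1(n_grp), E2(n_grp), E3(n_grp), E4;
  for (int g = 0; g < n_grp; ++g) {
    E1[g] = std::exp(eta(g, 0));
    E2[g] = std::exp(eta(g, 1));
    E3[g] = std::exp(eta(g, 2));
  }
  if (variant == 2) {
    E4.resize(n_grp);
    for (int g = 0; g < n_grp; ++g) E4[g] = std::exp(eta(g, 3));
  }

  // per-node quantities for u
  std::vector<double> eu(n_nodes), eau(n_nodes), vmean(n_nodes);
  for (int a = 0; a < n_nodes; ++a) {
    double u = sd_u * gh_x[a];
    eu[a] = std::exp(u);
    eau[a] = std::exp(alpha_u * u);
    vmean[a] = rho * sd_v * gh_x[a];
  }

  NumericVector per_pat(n_pat);
  double total = 0.0;

  std::vector<double> log_lik_int_m, log_lik_int_s;

  for (int p = 0; p < n_pat; ++p) {
    bool use_stayer = (cstar[p] == 0);
    double pm = 0.0, ps = 0.0;
    if (re_structure == 1) {
      for (int j = pat_ptr[p]; j < pat_ptr[p + 1]; ++j) {
        double dt = int_dt[j];
        double accm = NEG_INF, accs = NEG_INF;
        for (int a = 0; a < n_nodes; ++a) {
          for (int b = 0; b < n_nodes; ++b) {
            double v = vmean[a] + vsd * gh_x[b];
            double ev = std::exp(v);
            double ev2 = (variant == 1) ? ev : std::exp(alpha_v * v);
            double lm = 0.0, ls = use_stayer ? 0.0 : NEG_INF;
            for (int g = int_grp_ptr[j]; g < int_grp_ptr[j + 1]; ++g) {
              const int k0 = grp_tr_ptr[g], ntr = grp_tr_ptr[g + 1] - k0;
              const int* fr = &tr_from[k0];
              const int* to_ = &tr_to[k0];
              const int* ct = &tr_count[k0];
              if (lm > NEG_INF) {
                lm += (variant == 1)
                          ? grp_logp_six_mover(E1[g], E2[g], E3[g], eu[a],
                                               eau[a], ev, ex6, dt, fr, to_,
                                               ct, ntr)
                          : grp_logp_five_mover(E1[g], E2[g], E3[g], E4[g],
                                                eu[a], eau[a], ev, ev2, dt,
                                                fr, to_, ct, ntr);
              }
              if (use_stayer && ls > NEG_INF) {
                ls += (variant == 1)
                          ? grp_logp_six_stayer(E1[g], E2[g], eu[a], eau[a],
                                                ex6, dt, fr, to_, ct, ntr)
                          : grp_logp_five_stayer(E1[g], E2[g], eu[a], eau[a],
                                                 ex5, dt, fr, to_, ct, ntr);
              }
              if (lm == NEG_INF && (!use_stayer || ls == NEG_INF)) break;
            }
            double lw = gh_logw[a] + gh_logw[b];
            accm = lse2(accm, lw + lm);
            if (use_stayer) accs = lse2(accs, lw + ls);
          }
        }
        pm += accm;
        if (use_stayer) ps += accs;
      }
    } else {
      // patient-level random effects: one (u, v) wraps all intervals
      double accm = NEG_INF, accs = NEG_INF;
      for (int a = 0; a < n_nodes; ++a) {
        for (int b = 0; b < n_nodes; ++b) {
          double v = vmean[a] + vsd * gh_x[b];
          double ev = std::exp(v);
          double ev2 = (variant == 1) ? ev : std::exp(alpha_v * v);
          double lm = 0.0, ls = use_stayer ? 0.0 : NEG_INF;
          for (int j = pat_ptr[p]; j < pat_ptr[p + 1]; ++j) {
            double dt = int_dt[j];
            for (int g = int_grp_ptr[j]; g < int_grp_ptr[j + 1]; ++g) {
              const int k0 = grp_tr_ptr[g], ntr = grp_tr_ptr[g + 1] - k0;
              const int* fr = &tr_from[k0];
              const int* to_ = &tr_to[k0];
              const int* ct = &tr_count[k0];
              if (lm > NEG_INF) {
                lm += (variant == 1)
                          ? grp_logp_six_mover(E1[g], E2[g], E3[g], eu[a],
                                               eau[a], ev, ex6, dt, fr, to_,
                                               ct, ntr)
                          : grp_logp_five_mover(E1[g], E2[g], E3[g], E4[g],
                                                eu[a], eau[a], ev, ev2, dt,
                                                fr, to_, ct, ntr);
              }
              if (use_stayer && ls > NEG_INF) {
                ls += (variant == 1)
                          ? grp_logp_six_stayer(E1[g], E2[g], eu[a], eau[a],
                                                ex6, dt, fr, to_, ct, ntr)
                          : grp_logp_five_stayer(E1[g], E2[g], eu[a], eau[a],
                                                 ex5, dt, fr, to_, ct, ntr);
              }
            }
            if (lm == NEG_INF && (!use_stayer || ls == NEG_INF)) break;
          }
          double lw = gh_logw[a] + gh_logw[b];
          accm = lse2(accm, lw + lm);
          if (use_stayer) accs = lse2(accs, lw + ls);
        }
      }
      pm = accm;
      if (use_stayer) ps = accs;
    }
    double ll;
    if (!use_stayer) {
      ll = std::log1p(-ppi) + pm;
    } else if (ppi <= 0.0) {
      ll = pm;
    } else {
      ll = lse2(std::log1p(-ppi) + pm, std::log(ppi) + ps);
    }
    per_pat[p] = ll;
    total += ll;
  }
  return List::create(_["loglik"] = total, _["per_patient"] = per_pat);
}

// Conditional (on u, v) transition probability for a single joint and
// interval, vectorized over draws of (u, v). Used for Monte-Carlo checks of
// the quadrature integration.
// base six-state: (log l12, log l21, log l13) at u=v=0;
// base five-state: (log mu1, log mu2, log odds13, log odds23) at u=v=0.
// [[Rcpp::export]]
NumericVector cond_prob_vec_cpp(int variant, int mover, NumericVector base,
                                NumericVector extras, int from, int to,
                                double dt, NumericVector u, NumericVector v) {
  int n = u.size();
  NumericVector out(n);
  if (variant == 1) {
    SixExtras ex;
    ex.edam_ag = std::exp(extras[0]);
    ex.edam_al = std::exp(extras[1]);
    ex.eact = std::exp(extras[2]);
    ex.est_ag = std::exp(extras[3]);
    ex.est_al = std::exp(extras[4]);
    ex.alpha = extras[5];
    double E12 = std::exp(base[0]), E21 = std::exp(base[1]),
           E13 = std::exp(base[2]);
    for (int i = 0; i < n; ++i) {
      double eu = std::exp(u[i]), eau = std::exp(ex.alpha * u[i]),
             ev = std::exp(v[i]);
      if (mover == 1) {
        double l12 = E12 * eu, l21 = E21 * eau, l13 = E13 * ev;
        double P[16];
        pmat_mover6(l12, l21, l13, l13 * ex.eact, l12 * ex.edam_ag,
                    l21 * ex.edam_al, dt, P);
        out[i] = P[(from - 1) * 4 + (to - 1)];
      } else {
        if (from > 2 || to > 2) { out[i] = 0.0; continue; }
        double P[4];
        pmat_stayer(E12 * eu * ex.est_ag, E21 * eau * ex.est_al, dt, P);
        out[i] = P[(from - 1) * 2 + (to - 1)];
      }
    }
  } else {
    FiveExtras ex;
    ex.est_in = std::exp(extras[0]);
    ex.est_ac = std::exp(extras[1]);
    ex.alpha1 = extras[2];
    ex.alpha2 = extras[3];
    double M1 = std::exp(base[0]), M2 = std::exp(base[1]),
           O1 = std::exp(base[2]), O2 = std::exp(base[3]);
    for (int i = 0; i < n; ++i) {
      double eu = std::exp(u[i]), eau = std::exp(ex.alpha1 * u[i]),
             ev = std::exp(v[i]), ev2 = std::exp(ex.alpha2 * v[i]);
      if (mover == 1) {
        double l12, l21, l13, l23, mu1, mu2;
        five_rates(M1, M2, O1, O2, eu, eau, ev, ev2, &l12, &l21, &l13, &l23,
                   &mu1, &mu2);
        double P[9];
        pmat_mover5(l12, l21, l13, l23, dt, P);
        out[i] = P[(from - 1) * 3 + (to - 1)];
      } else {
        if (from > 2 || to > 2) { out[i] = 0.0; continue; }
        double mu4 = M1 * eu * ex.est_in, mu5 = M2 * eau * ex.est_ac;
        double P[4];
        pmat_stayer(1.0 / mu4, 1.0 / mu5, dt, P);
        out[i] = P[(from - 1) * 2 + (to - 1)];
      }
    }
  }
  return out;
}
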