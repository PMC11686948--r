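// Compiled core of the state-space metapopulation model: the deterministic
// stage-structured process simulator, the observation-level log likelihood,
// the prior, and an adaptive random-walk Metropolis-within-Gibbs sampler
// over (parameters, annual fecundity noise, initial colony sizes).
//
// Sampling scale: positive parameters (sign-constrained coefficient
// magnitudes, noise SDs, carrying capacities, initial sizes) are sampled as
// logs with the Jacobian folded into the prior; interval-bounded parameters
// (epizootic-year survival of unknown-status colonies) as logits.
//
// The process is deterministic given (parameters, eps series, initial
// sizes), which the sampler exploits: the no-noise fecundity predictor, the
// marine density dependence, the fecundity matrix, the trajectory with
// per-year age-structure checkpoints and the per-year observation log
// likelihood are all cached, and each single-parameter update recomputes
// only what it touches (an eps_t update re-simulates from year t only; a
// noise-SD update touches no trajectory at all).

#include <Rcpp.h>
#include <vector>
#include <cstring>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static const double LOG_SQRT_2PI = 0.918938533204672741780329736406;

static inline double invlogit(double x) { return 1.0 / (1.0 + std::exp(-x)); }
static inline double dnorm_log(double x, double mu, double sd) {
  double z = (x - mu) / sd;
  return -std::log(sd) - LOG_SQRT_2PI - 0.5 * z * z;
}

struct Model {
  int n, T, a_first;
  double phi_ad, phi_juv, re, alpha_const, rho, chick_pair;
  std::vector<std::vector<double> > Zf, Zr; // design matrices, n*T col-major
  std::vector<int> f_con, r_con;            // 1 = positive (log-sampled)
  std::vector<int> f_neg, r_neg;            // 1 = applied with negative sign
  // observations, grouped by year (CSR layout)
  std::vector<int> cen_start, cen_c; std::vector<double> cen_logy;
  std::vector<int> fec_start, fec_c;
  std::vector<double> fec_nests, fec_chicks, fec_lch;
  int hpai_t;
  std::vector<int> hpai_code;               // 0 affected, 1 unaffected, 2 unknown
  double hpai_phi_affected, hpai_lo, hpai_hi;
  double int_sd, coef_sd, sb_scale, so_scale, K_sd, P0_sd;
  std::vector<double> K_mu, P0_mu;
  int i_alpha0, i_fc, kf, i_beta0, i_rc, kr, i_lsb, i_lso;
  int i_lK, i_lP0, i_hp, n_hp, i_eps, p;
  double nu_num;                            // alpha_const - logit(re)
};

// sort observations into per-year buckets
static void to_csr(int T, const IntegerVector& tt,
                   const std::vector<NumericVector>& vals,
                   const IntegerVector& cc,
                   std::vector<int>& start, std::vector<int>& cidx,
                   std::vector<std::vector<double>*> out) {
  int m = tt.size();
  std::vector<int> count(T + 1, 0);
  for (int j = 0; j < m; ++j) count[tt[j] + 1]++;
  start.assign(T + 1, 0);
  for (int t = 0; t < T; ++t) start[t + 1] = start[t] + count[t + 1];
  std::vector<int> pos(start.begin(), start.end() - 1);
  cidx.assign(m, 0);
  for (size_t q = 0; q < out.size(); ++q) out[q]->assign(m, 0.0);
  for (int j = 0; j < m; ++j) {
    int k = pos[tt[j]]++;
    cidx[k] = cc[j];
    for (size_t q = 0; q < out.size(); ++q) (*out[q])[k] = vals[q][j];
  }
}

static Model parse_model(List md) {
  Model M;
  M.n = as<int>(md["n"]); M.T = as<int>(md["T"]);
  M.a_first = as<int>(md["a_first"]);
  M.phi_ad = as<double>(md["phi_ad"]); M.phi_juv = as<double>(md["phi_juv"]);
  M.re = as<double>(md["re"]); M.alpha_const = as<double>(md["alpha_const"]);
  M.rho = as<double>(md["rho"]); M.chick_pair = as<double>(md["chick_pair"]);
  M.nu_num = M.alpha_const - std::log(M.re / (1.0 - M.re));
  List Zf = md["Zf"], Zr = md["Zr"];
  for (int k = 0; k < Zf.size(); ++k) {
    NumericMatrix z = Zf[k];
    M.Zf.push_back(std::vector<double>(z.begin(), z.end()));
  }
  for (int k = 0; k < Zr.size(); ++k) {
    NumericMatrix z = Zr[k];
    M.Zr.push_back(std::vector<double>(z.begin(), z.end()));
  }
  M.f_con = as<std::vector<int> >(md["f_con"]);
  M.r_con = as<std::vector<int> >(md["r_con"]);
  M.f_neg = as<std::vector<int> >(md["f_neg"]);
  M.r_neg = as<std::vector<int> >(md["r_neg"]);
  {
    IntegerVector cc = md["cen_c"], tt = md["cen_t"];
    NumericVector ly = md["cen_logy"];
    std::vector<NumericVector> vals; vals.push_back(ly);
    std::vector<std::vector<double>*> out; out.push_back(&M.cen_logy);
    to_csr(M.T, tt, vals, cc, M.cen_start, M.cen_c, out);
  }
  {
    IntegerVector cc = md["fec_c"], tt = md["fec_t"];
    NumericVector nn = md["fec_nests"], ch = md["fec_chicks"], lc = md["fec_lch"];
    std::vector<NumericVector> vals;
    vals.push_back(nn); vals.push_back(ch); vals.push_back(lc);
    std::vector<std::vector<double>*> out;
    out.push_back(&M.fec_nests); out.push_back(&M.fec_chicks);
    out.push_back(&M.fec_lch);
    to_csr(M.T, tt, vals, cc, M.fec_start, M.fec_c, out);
  }
  M.hpai_t = as<int>(md["hpai_t"]);
  M.hpai_code = as<std::vector<int> >(md["hpai_code"]);
  M.hpai_phi_affected = as<double>(md["hpai_phi_affected"]);
  M.hpai_lo = as<double>(md["hpai_lo"]); M.hpai_hi = as<double>(md["hpai_hi"]);
  M.int_sd = as<double>(md["int_sd"]); M.coef_sd = as<double>(md["coef_sd"]);
  M.sb_scale = as<double>(md["sb_scale"]); M.so_scale = as<double>(md["so_scale"]);
  M.K_sd = as<double>(md["K_sd"]); M.P0_sd = as<double>(md["P0_sd"]);
  M.K_mu = as<std::vector<double> >(md["K_mu"]);
  M.P0_mu = as<std::vector<double> >(md["P0_mu"]);
  M.kf = (int) M.Zf.size(); M.kr = (int) M.Zr.size();
  M.i_alpha0 = 0;
  M.i_fc = 1;
  M.i_beta0 = M.i_fc + M.kf;
  M.i_rc = M.i_beta0 + 1;
  M.i_lsb = M.i_rc + M.kr;
  M.i_lso = M.i_lsb + 1;
  M.i_lK = M.i_lso + 1;
  M.i_lP0 = M.i_lK + M.n;
  M.i_hp = M.i_lP0 + M.n;
  M.n_hp = 0;
  if (M.hpai_t >= 0) {
    for (int i = 0; i < M.n; ++i) if (M.hpai_code[i] == 2) ++M.n_hp;
  }
  M.i_eps = M.i_hp + M.n_hp;
  M.p = M.i_eps + M.T;
  return M;
}

// full cached state of one chain
struct Work {
  std::vector<double> v;             // sampling scale, length p
  std::vector<double> fc, rc, K, P0, hpai_phi; // natural
  double sigma_b, sigma_obs;
  std::vector<double> LPF, ETA;      // n x T (LPF excludes eps)
  std::vector<double> B;             // n x T fecundity
  std::vector<double> P;             // n x T trajectory
  std::vector<double> J;             // n x a x T age-structure checkpoints
  std::vector<double> lly;           // per-year obs loglik
  double ll, lpr;
};

static void unpack_nat(const Model& M, Work& W) {
  const double* v = W.v.data();
  W.fc.resize(M.kf); W.rc.resize(M.kr);
  for (int k = 0; k < M.kf; ++k) {
    double raw = M.f_con[k] ? std::exp(v[M.i_fc + k]) : v[M.i_fc + k];
    W.fc[k] = M.f_neg[k] ? -raw : raw;
  }
  for (int k = 0; k < M.kr; ++k) {
    double raw = M.r_con[k] ? std::exp(v[M.i_rc + k]) : v[M.i_rc + k];
    W.rc[k] = M.r_neg[k] ? -raw : raw;
  }
  W.sigma_b = std::exp(v[M.i_lsb]);
  W.sigma_obs = std::exp(v[M.i_lso]);
  W.K.resize(M.n); W.P0.resize(M.n); W.hpai_phi.assign(M.n, M.phi_ad);
  for (int i = 0; i < M.n; ++i) {
    W.K[i] = std::exp(v[M.i_lK + i]);
    W.P0[i] = std::exp(v[M.i_lP0 + i]);
  }
  if (M.hpai_t >= 0) {
    int j = 0;
    for (int i = 0; i < M.n; ++i) {
      if (M.hpai_code[i] == 0) W.hpai_phi[i] = M.hpai_phi_affected;
      else if (M.hpai_code[i] == 2) {
        W.hpai_phi[i] = M.hpai_lo +
          (M.hpai_hi - M.hpai_lo) * invlogit(v[M.i_hp + j]);
        ++j;
      }
    }
  }
}

static void build_lpf(const Model& M, Work& W) {
  const int n = M.n, T = M.T;
  W.LPF.assign(n * T, W.v[M.i_alpha0]);
  for (int k = 0; k < M.kf; ++k) {
    const double c = W.fc[k]; const double* Z = M.Zf[k].data();
    for (int j = 0; j < n * T; ++j) W.LPF[j] += c * Z[j];
  }
}

static void build_eta(const Model& M, Work& W) {
  const int n = M.n, T = M.T;
  W.ETA.resize(n * T);
  std::vector<double> lpr(n * T, W.v[M.i_beta0]);
  for (int k = 0; k < M.kr; ++k) {
    const double c = W.rc[k]; const double* Z = M.Zr[k].data();
    for (int j = 0; j < n * T; ++j) lpr[j] += c * Z[j];
  }
  for (int j = 0; j < n * T; ++j) W.ETA[j] = invlogit(lpr[j]);
}

// fecundity columns t0..T-1 from LPF + eps
static void build_B(const Model& M, Work& W, int t0) {
  const int n = M.n;
  W.B.resize(n * M.T);
  for (int t = t0; t < M.T; ++t) {
    const double e = W.v[M.i_eps + t];
    for (int i = 0; i < n; ++i) W.B[i + n * t] = invlogit(W.LPF[i + n * t] + e);
  }
}

// trajectory from year t0 (t0 = 0 re-seeds the pre-breeder pools)
static void resim(const Model& M, Work& W, int t0) {
  const int n = M.n, T = M.T, a = M.a_first;
  W.P.resize(n * T); W.J.resize(n * a * T);
  if (t0 == 0) {
    // seed pre-breeder pools from year-0 fecundity (ridge-invariant)
    for (int i = 0; i < n; ++i) {
      W.P[i] = W.P0[i];
      double cohort = M.chick_pair * W.B[i] * W.P0[i];
      for (int q = 0; q < a; ++q) {
        W.J[(size_t)0 * n * a + i * a + q] = cohort;
        cohort *= M.phi_juv;
      }
    }
  }
  std::vector<double> E(n);
  for (int t = t0; t < T - 1; ++t) {
    const double* Jt = &W.J[(size_t)t * n * a];
    double* Jn = &W.J[(size_t)(t + 1) * n * a];
    double sumP = 0.0;
    for (int i = 0; i < n; ++i) sumP += W.P[i + n * t];
    for (int i = 0; i < n; ++i) {
      for (int q = a - 1; q >= 1; --q) Jn[i * a + q] = M.phi_juv * Jt[i * a + q - 1];
      if (a >= 2) {
        E[i] = M.phi_juv * Jt[i * a + a - 1] + Jn[i * a + a - 1];
        Jn[i * a + a - 1] = 0.0;
      } else {
        E[i] = M.phi_juv * Jt[i * a];
      }
      Jn[i * a + 0] = M.chick_pair * W.B[i + n * t] * W.P[i + n * t];
    }
    // conspecific-attraction redistribution, O(n) closed form:
    // arrivals_m = P_m * (S + (rho - 1) E_m / rs_m), rs_i = sumP + (rho-1) P_i
    double S = 0.0;
    if (sumP > 0.0) {
      for (int i = 0; i < n; ++i)
        S += E[i] / (sumP + (M.rho - 1.0) * W.P[i + n * t]);
    }
    for (int i = 0; i < n; ++i) {
      double Pi = W.P[i + n * t];
      double arr;
      if (sumP > 0.0) {
        double rs = sumP + (M.rho - 1.0) * Pi;
        arr = Pi * (S + (M.rho - 1.0) * E[i] / rs);
      } else {
        arr = E[i]; // empty system: the eligible pool stays natal
      }
      double dd = M.nu_num / W.K[i];
      double et = W.ETA[i + n * t];
      if (et > dd) dd = et;
      double phi = (t == M.hpai_t) ? W.hpai_phi[i] : M.phi_ad;
      // implicit within-season settlement: density dependence acts on the
      // post-settlement colony size, x = phi*P + arr * r(x); the map is
      // monotone and free of capacity overshoot for any steepness
      double base = phi * Pi;
      double x = base;
      if (arr > 0.0) {
        double lo = base, hi = base + arr;
        if (M.alpha_const - dd * hi > 36.0) {
          // far below capacity: r(hi) == 1 to double precision
          x = hi;
        } else if (M.alpha_const - dd * base < -36.0) {
          // far above capacity: recruitment is shut off
          x = base + arr * invlogit(M.alpha_const - dd * base);
        } else {
          // Newton with bisection safeguard; warm-start from the previous
          // trajectory's value when it lies in the bracket, else inside the
          // logistic transition zone
          x = W.P[i + n * (t + 1)];
          if (!(x > lo && x < hi)) {
            x = M.alpha_const / dd;
            if (x <= lo || x >= hi) x = 0.5 * (lo + hi);
          }
          for (int itn = 0; itn < 12; ++itn) {
            double rr = invlogit(M.alpha_const - dd * x);
            double f = x - base - arr * rr;
            if (std::fabs(f) < 1e-7 * (1.0 + arr)) break;
            if (f > 0.0) hi = x; else lo = x;
            double fp = 1.0 + arr * dd * rr * (1.0 - rr);
            double xn = x - f / fp;
            if (!(xn > lo && xn < hi)) xn = 0.5 * (lo + hi);
            if (std::fabs(xn - x) < 1e-12 * (1.0 + x)) { x = xn; break; }
            x = xn;
          }
        }
      }
      if (x < base) x = base;
      if (x > base + arr) x = base + arr;
      W.P[i + n * (t + 1)] = x;
      double fail = arr - (x - base);       // failed settlers retry
      Jn[i * a + a - 1] += (fail > 0.0) ? fail : 0.0;
    }
  }
}

// per-year observation log likelihood from year t0; refreshes W.ll
static void calc_lly(const Model& M, Work& W, int t0) {
  W.lly.resize(M.T);
  const double lso = std::log(W.sigma_obs);
  for (int t = t0; t < M.T; ++t) {
    double s = 0.0;
    for (int j = M.cen_start[t]; j < M.cen_start[t + 1]; ++j) {
      double Pv = W.P[M.cen_c[j] + M.n * t];
      double mu = std::log(Pv > 1e-300 ? Pv : 1e-300);
      double z = (M.cen_logy[j] - mu) / W.sigma_obs;
      s += -lso - LOG_SQRT_2PI - 0.5 * z * z;
    }
    for (int j = M.fec_start[t]; j < M.fec_start[t + 1]; ++j) {
      double b = W.B[M.fec_c[j] + M.n * t];
      if (b < 1e-12) b = 1e-12;
      if (b > 1.0 - 1e-12) b = 1.0 - 1e-12;
      s += M.fec_lch[j] + M.fec_chicks[j] * std::log(b) +
        (M.fec_nests[j] - M.fec_chicks[j]) * std::log(1.0 - b);
    }
    W.lly[t] = s;
  }
  double tot = 0.0;
  for (int t = 0; t < M.T; ++t) tot += W.lly[t];
  W.ll = tot;
}

// prior contribution of single parameter i (eps terms use current sigma_b;
// the sigma_b parameter itself carries only its half-normal + Jacobian, the
// eps block is handled explicitly where sigma_b changes)
static double prior_term(const Model& M, const Work& W, int i) {
  double v = W.v[i];
  if (i == M.i_alpha0 || i == M.i_beta0) return dnorm_log(v, 0.0, M.int_sd);
  if (i >= M.i_fc && i < M.i_fc + M.kf) {
    return M.f_con[i - M.i_fc] ? (-std::exp(v) + v)
                               : dnorm_log(v, 0.0, M.coef_sd);
  }
  if (i >= M.i_rc && i < M.i_rc + M.kr) {
    return M.r_con[i - M.i_rc] ? (-std::exp(v) + v)
                               : dnorm_log(v, 0.0, M.coef_sd);
  }
  if (i == M.i_lsb) {
    double s = std::exp(v);
    return -0.5 * s * s / (M.sb_scale * M.sb_scale) + v;
  }
  if (i == M.i_lso) {
    double s = std::exp(v);
    return -0.5 * s * s / (M.so_scale * M.so_scale) + v;
  }
  if (i >= M.i_lK && i < M.i_lK + M.n)
    return dnorm_log(v, M.K_mu[i - M.i_lK], M.K_sd);
  if (i >= M.i_lP0 && i < M.i_lP0 + M.n)
    return dnorm_log(v, M.P0_mu[i - M.i_lP0], M.P0_sd);
  if (i >= M.i_hp && i < M.i_hp + M.n_hp) {
    double u = invlogit(v);
    return std::log(u) + std::log(1.0 - u);
  }
  // eps block
  return dnorm_log(v, 0.0, W.sigma_b);
}

static double full_prior(const Model& M, const Work& W) {
  double lp = 0.0;
  for (int i = 0; i < M.p; ++i) lp += prior_term(M, W, i);
  return lp;
}

static void full_refresh(const Model& M, Work& W) {
  unpack_nat(M, W);
  build_lpf(M, W);
  build_eta(M, W);
  build_B(M, W, 0);
  resim(M, W, 0);
  calc_lly(M, W, 0);
  W.lpr = full_prior(M, W);
}

// [[Rcpp::export]]
List mpc_simulate_cpp(List md, NumericVector v) {
  Model M = parse_model(md);
  if (v.size() != M.p) stop("parameter vector has wrong length");
  Work W;
  W.v.assign(v.begin(), v.end());
  full_refresh(M, W);
  NumericMatrix Pm(M.n, M.T), Bm(M.n, M.T);
  std::copy(W.P.begin(), W.P.end(), Pm.begin());
  std::copy(W.B.begin(), W.B.end(), Bm.begin());
  return List::create(_["P"] = Pm, _["b"] = Bm, _["loglik"] = W.ll);
}

// [[Rcpp::export]]
double mpc_loglik_cpp(List md, NumericVector v) {
  Model M = parse_model(md);
  if (v.size() != M.p) stop("parameter vector has wrong length");
  Work W;
  W.v.assign(v.begin(), v.end());
  full_refresh(M, W);
  return W.ll;
}

// [[Rcpp::export]]
double mpc_logprior_cpp(List md, NumericVector v) {
  Model M = parse_model(md);
  if (v.size() != M.p) stop("parameter vector has wrong length");
  Work W;
  W.v.assign(v.begin(), v.end());
  unpack_nat(M, W);
  return full_prior(M, W);
}

// what an update of parameter i touches
enum UpdKind { UPD_FEC, UPD_REC, UPD_SB, UPD_SO, UPD_TRAJ0, UPD_HP, UPD_EPS };

static UpdKind upd_kind(const Model& M, int i) {
  if (i == M.i_alpha0 || (i >= M.i_fc && i < M.i_fc + M.kf)) return UPD_FEC;
  if (i == M.i_beta0 || (i >= M.i_rc && i < M.i_rc + M.kr)) return UPD_REC;
  if (i == M.i_lsb) return UPD_SB;
  if (i == M.i_lso) return UPD_SO;
  if (i >= M.i_hp && i < M.i_hp + M.n_hp) return UPD_HP;
  if (i >= M.i_eps) return UPD_EPS;
  return UPD_TRAJ0; // K or P0
}

// copy the prefix [0, t0) of the time-indexed caches (so that after a
// suffix recompute the proposal buffers hold complete arrays)
static void copy_prefix(const Model& M, const Work& cur, Work& prop, int t0,
                        bool copy_B) {
  const int n = M.n, a = M.a_first;
  prop.P.resize(cur.P.size()); prop.J.resize(cur.J.size());
  prop.lly.resize(cur.lly.size());
  if (copy_B) prop.B.resize(cur.B.size());
  if (t0 > 0) {
    std::memcpy(prop.J.data(), cur.J.data(), sizeof(double) * n * a * t0);
    std::memcpy(prop.lly.data(), cur.lly.data(), sizeof(double) * t0);
    if (copy_B)
      std::memcpy(prop.B.data(), cur.B.data(), sizeof(double) * n * t0);
  }
  // the full P array carries over: the prefix is reused as-is and the
  // suffix serves as a warm start for the settlement root finder
  std::memcpy(prop.P.data(), cur.P.data(), sizeof(double) * n * M.T);
  std::memcpy(prop.J.data() + (size_t)n * a * t0,
              cur.J.data() + (size_t)n * a * t0, sizeof(double) * n * a);
  (void) copy_B;
}

// Cholesky of a small SPD matrix (row-major d x d); returns false if not PD
static bool chol_small(const std::vector<double>& A, int d,
                       std::vector<double>& L) {
  L.assign(d * d, 0.0);
  for (int i = 0; i < d; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = A[i * d + j];
      for (int k = 0; k < j; ++k) s -= L[i * d + k] * L[j * d + k];
      if (i == j) {
        if (s <= 0.0) return false;
        L[i * d + i] = std::sqrt(s);
      } else {
        L[i * d + j] = s / L[j * d + j];
      }
    }
  }
  return true;
}

// online mean/covariance for an adaptive-Metropolis block
struct AMBlock {
  int d; long n;
  std::vector<double> mean, M2; // M2 row-major d x d
  double log_sc; int acc;
  explicit AMBlock(int d_) : d(d_), n(0), mean(d_, 0.0), M2(d_ * d_, 0.0),
    log_sc(std::log(2.38 / std::sqrt((double) std::max(d_, 1)))), acc(0) {}
  void update(const std::vector<double>& v, const std::vector<int>& idx) {
    ++n;
    std::vector<double> delta(d);
    for (int i = 0; i < d; ++i) delta[i] = v[idx[i]] - mean[i];
    for (int i = 0; i < d; ++i) mean[i] += delta[i] / n;
    for (int i = 0; i < d; ++i)
      for (int j = 0; j < d; ++j)
        M2[i * d + j] += delta[i] * (v[idx[j]] - mean[j]);
  }
  bool ready() const { return n >= 20L * d; }
  // draw a proposal step into `step`; false if covariance is degenerate
  bool draw_step(std::vector<double>& step) const {
    std::vector<double> C(d * d), L;
    for (int i = 0; i < d; ++i)
      for (int j = 0; j < d; ++j) {
        C[i * d + j] = M2[i * d + j] / (n - 1);
        if (i == j) C[i * d + j] += 1e-9 + 1e-6 * C[i * d + j];
      }
    if (!chol_small(C, d, L)) return false;
    std::vector<double> z(d);
    for (int i = 0; i < d; ++i) z[i] = norm_rand();
    double sc = std::exp(log_sc);
    step.assign(d, 0.0);
    for (int i = 0; i < d; ++i) {
      double s = 0.0;
      for (int k = 0; k <= i; ++k) s += L[i * d + k] * z[k];
      step[i] = sc * s;
    }
    return true;
  }
};

// [[Rcpp::export]]
List mpc_fit_cpp(List md, NumericVector init, int n_iter, int n_burn,
                 int thin, int adapt_batch = 50) {
  Model M = parse_model(md);
  if (init.size() != M.p) stop("init has wrong length");
  Work cur, prop;
  cur.v.assign(init.begin(), init.end());
  full_refresh(M, cur);
  if (!std::isfinite(cur.ll) || !std::isfinite(cur.lpr))
    stop("initial state has non-finite posterior density");
  prop = cur;

  std::vector<double> lsd(M.p, std::log(0.1));
  std::vector<int> acc(M.p, 0);
  std::vector<long> acc_tot(M.p, 0);
  long cmp_tot = 0, amF_tot = 0, amR_tot = 0, rd_tot0 = 0, rd_tot1 = 0;
  double ridge_lsd = std::log(0.1); int ridge_acc = 0;
  int batch = 0;

  // colony-mean design rows for the eps-compensated coefficient moves
  std::vector<std::vector<double> > zbar_f(M.kf, std::vector<double>(M.T, 0.0));
  for (int k = 0; k < M.kf; ++k)
    for (int t = 0; t < M.T; ++t) {
      double s = 0.0;
      for (int i = 0; i < M.n; ++i) s += M.Zf[k][i + M.n * t];
      zbar_f[k][t] = s / M.n;
    }
  std::vector<double> lsd_cmp(M.kf, std::log(0.1));
  std::vector<int> acc_cmp(M.kf, 0);

  // adaptive-covariance blocks over the two coefficient sets
  std::vector<int> blkF, blkR;
  blkF.push_back(M.i_alpha0);
  for (int k = 0; k < M.kf; ++k) blkF.push_back(M.i_fc + k);
  blkR.push_back(M.i_beta0);
  for (int k = 0; k < M.kr; ++k) blkR.push_back(M.i_rc + k);
  AMBlock amF((int) blkF.size()), amR((int) blkR.size());

  // decoupling directions for a single linear recruitment covariate: move
  // logit-eta at one reference covariate value while holding it fixed at
  // the other, so the two near-independent data constraints get their own
  // axes (the raw (intercept, slope) pair is nearly perfectly correlated)
  bool rec_dir_ok = (M.kr == 1 && !M.r_con[0]);
  double z_lo = 0.0, z_hi = 0.0;
  if (rec_dir_ok) {
    std::vector<double> zs(M.Zr[0]);
    std::sort(zs.begin(), zs.end());
    z_lo = zs[(size_t)(0.1 * (zs.size() - 1))];
    z_hi = zs[(size_t)(0.9 * (zs.size() - 1))];
    if (z_hi - z_lo < 1e-6) rec_dir_ok = false;
  }
  double lsd_rd[2] = {std::log(0.1), std::log(0.1)};
  int acc_rd[2] = {0, 0};

  // natural (signed) value of fecundity coefficient k from a sampling vector
  auto nat_fcoef = [&](const std::vector<double>& v, int k) {
    double c = M.f_con[k] ? std::exp(v[M.i_fc + k]) : v[M.i_fc + k];
    return M.f_neg[k] ? -c : c;
  };
  // evaluate a fully specified prop.v from scratch on the dirty side(s)
  auto eval_global = [&](bool fec_changed, bool rec_changed) {
    unpack_nat(M, prop);
    if (fec_changed) { build_lpf(M, prop); build_B(M, prop, 0); }
    else { prop.LPF = cur.LPF; prop.B = cur.B; }
    if (rec_changed) build_eta(M, prop); else prop.ETA = cur.ETA;
    copy_prefix(M, cur, prop, 0, false);
    resim(M, prop, 0);
    calc_lly(M, prop, 0);
  };
  auto accept_prop = [&](double dpr) {
    std::swap(cur.v, prop.v);
    std::swap(cur.fc, prop.fc); std::swap(cur.rc, prop.rc);
    std::swap(cur.K, prop.K); std::swap(cur.P0, prop.P0);
    std::swap(cur.hpai_phi, prop.hpai_phi);
    cur.sigma_b = prop.sigma_b; cur.sigma_obs = prop.sigma_obs;
    std::swap(cur.LPF, prop.LPF); std::swap(cur.ETA, prop.ETA);
    std::swap(cur.B, prop.B);
    std::swap(cur.P, prop.P); std::swap(cur.J, prop.J);
    std::swap(cur.lly, prop.lly);
    cur.ll = prop.ll;
    cur.lpr += dpr;
  };

  int n_keep = 0;
  for (int it = n_burn + 1; it <= n_iter; ++it)
    if ((it - n_burn) % thin == 0) ++n_keep;
  NumericMatrix draws(std::max(n_keep, 1), M.p);
  NumericMatrix latentP(std::max(n_keep, 1), M.n * M.T);
  NumericVector ll_keep(std::max(n_keep, 1));
  int keep = 0;
  RNGScope scope;

  for (int it = 1; it <= n_iter; ++it) {
    for (int i = 0; i < M.p; ++i) {
      UpdKind kind = upd_kind(M, i);
      // the eps block is large and fast-mixing: sweep alternating halves
      if (kind == UPD_EPS && ((i - M.i_eps) % 2) != (it % 2)) continue;
      double oldv = cur.v[i];
      double cand = oldv + std::exp(lsd[i]) * norm_rand();

      // prior delta (sigma_b also reweights every eps term)
      double dpr;
      if (kind == UPD_SB) {
        double sb_new = std::exp(cand);
        double d_eps = 0.0;
        for (int t = 0; t < M.T; ++t) {
          double e = cur.v[M.i_eps + t];
          d_eps += dnorm_log(e, 0.0, sb_new) - dnorm_log(e, 0.0, cur.sigma_b);
        }
        double s_old = cur.sigma_b;
        double hn_new = -0.5 * sb_new * sb_new / (M.sb_scale * M.sb_scale) + cand;
        double hn_old = -0.5 * s_old * s_old / (M.sb_scale * M.sb_scale) + oldv;
        dpr = d_eps + hn_new - hn_old;
      } else {
        double p_old = prior_term(M, cur, i);
        cur.v[i] = cand;
        double p_new = prior_term(M, cur, i);
        cur.v[i] = oldv;
        dpr = p_new - p_old;
      }

      double dll = 0.0;
      bool need_swap = false;
      if (kind == UPD_SB) {
        dll = 0.0; // likelihood untouched
      } else {
        prop.v = cur.v; prop.v[i] = cand;
        unpack_nat(M, prop);
        int t0 = 0;
        switch (kind) {
          case UPD_FEC:
            build_lpf(M, prop);
            prop.ETA = cur.ETA;
            build_B(M, prop, 0);
            break;
          case UPD_REC:
            prop.LPF = cur.LPF; prop.B = cur.B;
            build_eta(M, prop);
            break;
          case UPD_SO:
            prop.LPF = cur.LPF; prop.ETA = cur.ETA; prop.B = cur.B;
            prop.P = cur.P; prop.J = cur.J;
            break;
          case UPD_TRAJ0:
            prop.LPF = cur.LPF; prop.ETA = cur.ETA; prop.B = cur.B;
            break;
          case UPD_HP:
            prop.LPF = cur.LPF; prop.ETA = cur.ETA; prop.B = cur.B;
            t0 = M.hpai_t;
            break;
          case UPD_EPS: {
            prop.LPF = cur.LPF; prop.ETA = cur.ETA;
            t0 = i - M.i_eps;
            copy_prefix(M, cur, prop, t0, true);
            const double e = cand;
            for (int ci = 0; ci < M.n; ++ci)
              prop.B[ci + M.n * t0] = invlogit(prop.LPF[ci + M.n * t0] + e);
            for (int t = t0 + 1; t < M.T; ++t)
              for (int ci = 0; ci < M.n; ++ci)
                prop.B[ci + M.n * t] = cur.B[ci + M.n * t];
            break;
          }
          default: break;
        }
        if (kind == UPD_SO) {
          calc_lly(M, prop, 0);
        } else {
          if (kind != UPD_EPS) copy_prefix(M, cur, prop, t0, false);
          if (kind == UPD_EPS || kind == UPD_HP) {
            resim(M, prop, t0);
          } else {
            resim(M, prop, 0);
          }
          calc_lly(M, prop, t0);
          // prefix years keep their cached loglik
          if (t0 > 0) {
            double tot = 0.0;
            for (int t = 0; t < M.T; ++t) tot += prop.lly[t];
            prop.ll = tot;
          }
        }
        dll = prop.ll - cur.ll;
        need_swap = true;
      }

      double aprob = dll + dpr;
      if (std::isfinite(aprob) &&
          (aprob >= 0.0 || std::log(unif_rand()) < aprob)) {
        if (need_swap) {
          std::swap(cur.v, prop.v);
          std::swap(cur.fc, prop.fc); std::swap(cur.rc, prop.rc);
          std::swap(cur.K, prop.K); std::swap(cur.P0, prop.P0);
          std::swap(cur.hpai_phi, prop.hpai_phi);
          cur.sigma_b = prop.sigma_b; cur.sigma_obs = prop.sigma_obs;
          std::swap(cur.LPF, prop.LPF); std::swap(cur.ETA, prop.ETA);
          std::swap(cur.B, prop.B);
          std::swap(cur.P, prop.P); std::swap(cur.J, prop.J);
          std::swap(cur.lly, prop.lly);
          cur.ll = prop.ll;
        } else {
          cur.v[i] = cand;
          cur.sigma_b = std::exp(cand); // only UPD_SB reaches here
        }
        cur.lpr += dpr;
        ++acc[i]; ++acc_tot[i];
      }
    }
    // ridge move: shift the fecundity intercept against all annual noise
    // terms; fecundity, trajectory and likelihood are all unchanged, so
    // only the priors (and the cached no-noise predictor) move.
    {
      double d = std::exp(ridge_lsd) * norm_rand();
      double a0 = cur.v[M.i_alpha0];
      double dpr = dnorm_log(a0 + d, 0.0, M.int_sd) -
                   dnorm_log(a0, 0.0, M.int_sd);
      for (int t = 0; t < M.T; ++t) {
        double e = cur.v[M.i_eps + t];
        dpr += dnorm_log(e - d, 0.0, cur.sigma_b) -
               dnorm_log(e, 0.0, cur.sigma_b);
      }
      if (std::isfinite(dpr) && (dpr >= 0.0 || std::log(unif_rand()) < dpr)) {
        cur.v[M.i_alpha0] += d;
        for (int t = 0; t < M.T; ++t) cur.v[M.i_eps + t] -= d;
        for (size_t j = 0; j < cur.LPF.size(); ++j) cur.LPF[j] += d;
        cur.lpr += dpr;
        ++ridge_acc;
      }
    }
    // eps-compensated single-coefficient moves: shift one fecundity
    // coefficient and counter-shift the annual noise so each year's
    // colony-mean predictor is unchanged; the likelihood then responds only
    // to the cross-colony contrast, which is the identified direction.
    if (M.kf > 0) {
      int k = (int) std::floor(unif_rand() * M.kf);
      if (k >= M.kf) k = M.kf - 1;
      double delta = std::exp(lsd_cmp[k]) * norm_rand();
      prop.v = cur.v;
      prop.v[M.i_fc + k] += delta;
      double dc = nat_fcoef(prop.v, k) - nat_fcoef(cur.v, k);
      for (int t = 0; t < M.T; ++t)
        prop.v[M.i_eps + t] -= dc * zbar_f[k][t];
      unpack_nat(M, prop);
      double dpr = full_prior(M, prop) - full_prior(M, cur);
      build_lpf(M, prop); build_B(M, prop, 0);
      prop.ETA = cur.ETA;
      copy_prefix(M, cur, prop, 0, false);
      resim(M, prop, 0);
      calc_lly(M, prop, 0);
      double a = (prop.ll - cur.ll) + dpr;
      if (std::isfinite(a) && (a >= 0.0 || std::log(unif_rand()) < a)) {
        accept_prop(dpr); ++acc_cmp[k]; ++cmp_tot;
      }
    }
    // adaptive-covariance block move over the fecundity coefficients (with
    // the same eps compensation), striding along the learned ridge
    if (amF.ready()) {
      std::vector<double> step;
      if (amF.draw_step(step)) {
        prop.v = cur.v;
        for (size_t q = 0; q < blkF.size(); ++q) prop.v[blkF[q]] += step[q];
        double dpred0 = prop.v[M.i_alpha0] - cur.v[M.i_alpha0];
        std::vector<double> dck(M.kf);
        for (int k = 0; k < M.kf; ++k)
          dck[k] = nat_fcoef(prop.v, k) - nat_fcoef(cur.v, k);
        for (int t = 0; t < M.T; ++t) {
          double comp = dpred0;
          for (int k = 0; k < M.kf; ++k) comp += dck[k] * zbar_f[k][t];
          prop.v[M.i_eps + t] -= comp;
        }
        unpack_nat(M, prop);
        double dpr = full_prior(M, prop) - full_prior(M, cur);
        eval_global(true, false);
        double a = (prop.ll - cur.ll) + dpr;
        if (std::isfinite(a) && (a >= 0.0 || std::log(unif_rand()) < a)) {
          accept_prop(dpr); ++amF.acc; ++amF_tot;
        }
      }
    }
    // adaptive-covariance block move over the recruitment coefficients
    if (amR.ready()) {
      std::vector<double> step;
      if (amR.draw_step(step)) {
        prop.v = cur.v;
        for (size_t q = 0; q < blkR.size(); ++q) prop.v[blkR[q]] += step[q];
        unpack_nat(M, prop);
        double dpr = full_prior(M, prop) - full_prior(M, cur);
        eval_global(false, true);
        double a = (prop.ll - cur.ll) + dpr;
        if (std::isfinite(a) && (a >= 0.0 || std::log(unif_rand()) < a)) {
          accept_prop(dpr); ++amR.acc; ++amR_tot;
        }
      }
    }
    if (rec_dir_ok) {
      for (int q = 0; q < 2; ++q) {
        double zfix = (q == 0) ? z_lo : z_hi; // reference held fixed
        double delta = std::exp(lsd_rd[q]) * norm_rand();
        prop.v = cur.v;
        prop.v[M.i_beta0] += -zfix * delta;
        prop.v[M.i_rc] += delta;
        unpack_nat(M, prop);
        double dpr = full_prior(M, prop) - full_prior(M, cur);
        eval_global(false, true);
        double a = (prop.ll - cur.ll) + dpr;
        if (std::isfinite(a) && (a >= 0.0 || std::log(unif_rand()) < a)) {
          accept_prop(dpr); ++acc_rd[q];
          if (q == 0) ++rd_tot0; else ++rd_tot1;
        }
      }
    }
    amF.update(cur.v, blkF);
    amR.update(cur.v, blkR);

    // periodic full refresh caps floating-point drift of the caches
    if (it % 500 == 0) full_refresh(M, cur);
    if (it % adapt_batch == 0) {
      ++batch;
      double delta = std::min(0.05, 1.0 / std::sqrt((double) batch));
      for (int i = 0; i < M.p; ++i) {
        lsd[i] += (acc[i] / (double) adapt_batch > 0.44) ? delta : -delta;
        acc[i] = 0;
      }
      ridge_lsd += (ridge_acc / (double) adapt_batch > 0.44) ? delta : -delta;
      ridge_acc = 0;
      for (int k = 0; k < M.kf; ++k) {
        double tries = adapt_batch / (double) std::max(M.kf, 1);
        lsd_cmp[k] += (acc_cmp[k] / tries > 0.44) ? delta : -delta;
        acc_cmp[k] = 0;
      }
      amF.log_sc += (amF.acc / (double) adapt_batch > 0.25) ? delta : -delta;
      amF.acc = 0;
      amR.log_sc += (amR.acc / (double) adapt_batch > 0.25) ? delta : -delta;
      amR.acc = 0;
      for (int q = 0; q < 2; ++q) {
        lsd_rd[q] += (acc_rd[q] / (double) adapt_batch > 0.44) ? delta : -delta;
        acc_rd[q] = 0;
      }
    }
    if (it > n_burn && (it - n_burn) % thin == 0) {
      // natural-scale report
      Work& W = cur;
      for (int j = 0; j < M.p; ++j) {
        double out;
        if (j == M.i_alpha0 || j == M.i_beta0 || j >= M.i_eps) out = W.v[j];
        else if (j >= M.i_fc && j < M.i_fc + M.kf)
          out = M.f_con[j - M.i_fc] ? std::exp(W.v[j]) : W.v[j];
        else if (j >= M.i_rc && j < M.i_rc + M.kr)
          out = M.r_con[j - M.i_rc] ? std::exp(W.v[j]) : W.v[j];
        else if (j == M.i_lsb) out = W.sigma_b;
        else if (j == M.i_lso) out = W.sigma_obs;
        else if (j >= M.i_lK && j < M.i_lK + M.n) out = W.K[j - M.i_lK];
        else if (j >= M.i_lP0 && j < M.i_lP0 + M.n) out = W.P0[j - M.i_lP0];
        else {
          int q = j - M.i_hp;
          int cnt = -1, ci = -1;
          for (int z = 0; z < M.n; ++z) {
            if (M.hpai_code[z] == 2) { ++cnt; if (cnt == q) { ci = z; break; } }
          }
          out = W.hpai_phi[ci];
        }
        draws(keep, j) = out;
      }
      for (int j = 0; j < M.n * M.T; ++j) latentP(keep, j) = cur.P[j];
      ll_keep[keep] = cur.ll;
      ++keep;
    }
  }
  NumericVector acc_rate(M.p), lsd_out(M.p);
  for (int i = 0; i < M.p; ++i) {
    acc_rate[i] = acc_tot[i] / (double) n_iter;
    lsd_out[i] = lsd[i];
  }
  return List::create(_["draws"] = draws, _["latentP"] = latentP,
                      _["loglik"] = ll_keep, _["n_keep"] = keep,
                      _["accept"] = acc_rate, _["scales"] = lsd_out,
                      _["accept_extra"] = NumericVector::create(
                        _["cmp"] = cmp_tot / (double) (n_iter * std::max(M.kf, 1)),
                        _["amF"] = amF_tot / (double) n_iter,
                        _["amR"] = amR_tot / (double) n_iter,
                        _["rd0"] = rd_tot0 / (double) n_iter,
                        _["rd1"] = rd_tot1 / (double) n_iter));
}

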