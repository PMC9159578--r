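// Core numerical kernels: exact and approximate forward simulators for
// stochastic reaction networks, and the bootstrap / guided particle filters
// that estimate per-cell likelihoods for the pseudo-marginal Gibbs samplers.
//
// All randomness is drawn from R's RNG (norm_rand/unif_rand/R::qpois on
// Phi-transformed normals) so that every kernel is bit-reproducible under
// set.seed() and so that correlated auxiliary numbers can be supplied from R
// as pre-laid-out standard-normal arrays.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
#include <memory>

using namespace Rcpp;

static const double LOG_2PI = 1.8378770664093454836;

// ---------------------------------------------------------------------------
// Built-in propensity functions. id 0 = R callback; the rest are compiled
// fast paths used by the benchmark systems.
//   1 birth-death:     0 -> X at c1;  X -> 0 at c2*x
//   2 circadian:       0 -> mRNA at c1*(1 + a*sin(2*pi*t/24)); mRNA -> 0 at
//                      c2*m; mRNA -> mRNA + P at c3*m; P -> 0 at c4*p.
//                      kappa[0] = modulation amplitude a.
//   3 schlogl:         2X -> 3X at c1*x*(x-1)/2; 3X -> 2X at k1*x*(x-1)*(x-2)/6;
//                      0 -> X at k2; X -> 0 at k3*x   (combinatorial forms)
//   4 schlogl_sq:      as 3 but with x^2/2 and x^3/6 mass-action-in-
//                      concentration forms
// id 100 marks the Ornstein-Uhlenbeck SDE, handled directly by the Langevin
// stepper (drift th1*(th2 - x), diffusion th3); it has no jump propensities.

struct PropCtx {
  int id;
  int d;
  int R;
  Function *fn; // callback when id == 0
};

static inline void eval_prop(const PropCtx &ctx, const double *x,
                             const double *c, const double *k, double t,
                             double *h) {
  switch (ctx.id) {
  case 1:
    h[0] = c[0];
    h[1] = c[1] * x[0];
    return;
  case 2: {
    double mod = 1.0 + k[0] * std::sin(2.0 * M_PI * t / 24.0);
    if (mod < 0.0) mod = 0.0;
    h[0] = c[0] * mod;
    h[1] = c[1] * x[0];
    h[2] = c[2] * x[0];
    h[3] = c[3] * x[1];
    return;
  }
  case 3: {
    double xx = x[0];
    h[0] = c[0] * xx * (xx - 1.0) / 2.0;
    h[1] = k[0] * xx * (xx - 1.0) * (xx - 2.0) / 6.0;
    h[2] = k[1];
    h[3] = k[2] * xx;
    if (h[0] < 0.0) h[0] = 0.0;
    if (h[1] < 0.0) h[1] = 0.0;
    return;
  }
  case 4: {
    double xx = x[0];
    h[0] = c[0] * xx * xx / 2.0;
    h[1] = k[0] * xx * xx * xx / 6.0;
    h[2] = k[1];
    h[3] = k[2] * xx;
    return;
  }
  default:
    stop("unknown built-in propensity id %d", ctx.id);
  }
}

// R-callback propensity evaluation (slow path for user-defined networks)
static inline void eval_prop_cb(const PropCtx &ctx, const double *x,
                                const NumericVector &c, const NumericVector &k,
                                double t, double *h) {
  NumericVector xv(ctx.d);
  for (int i = 0; i < ctx.d; ++i) xv[i] = x[i];
  NumericVector hv = (*ctx.fn)(xv, c, k, t);
  if ((int)hv.size() != ctx.R)
    stop("propensity function returned %d values, expected %d", (int)hv.size(),
         ctx.R);
  for (int j = 0; j < ctx.R; ++j) h[j] = hv[j];
}

static inline void check_prop(const double *h, int R) {
  for (int j = 0; j < R; ++j) {
    if (!std::isfinite(h[j]))
      stop("propensity of reaction %d is non-finite", j + 1);
    if (h[j] < 0.0)
      stop("propensity of reaction %d is negative (%g)", j + 1, h[j]);
  }
}

struct Model {
  PropCtx ctx;
  std::vector<double> stoich; // d*R column-major (column = reaction)
  NumericVector c, kappa;
  Function *fn_store;
  Model(List net, NumericVector c_, NumericVector kappa_)
      : c(c_), kappa(kappa_), fn_store(NULL) {
    IntegerMatrix S = net["stoich"];
    ctx.d = S.nrow();
    ctx.R = S.ncol();
    ctx.id = as<int>(net["propId"]);
    stoich.resize(ctx.d * ctx.R);
    for (int j = 0; j < ctx.R; ++j)
      for (int i = 0; i < ctx.d; ++i) stoich[j * ctx.d + i] = S(i, j);
    if (ctx.id == 0) {
      fn_store = new Function(as<Function>(net["propFn"]));
      ctx.fn = fn_store;
    } else {
      ctx.fn = NULL;
    }
  }
  ~Model() { delete fn_store; }
  void prop(const double *x, double t, double *h) const {
    if (ctx.id == 0)
      eval_prop_cb(ctx, x, c, kappa, t, h);
    else
      eval_prop(ctx, x, c.begin(), kappa.begin(), t, h);
    check_prop(h, ctx.R);
  }
  // propensities with state clamped at zero (approximate integrators)
  void prop_clamped(const double *x, double t, double *h,
                    std::vector<double> &buf) const {
    bool neg = false;
    for (int i = 0; i < ctx.d; ++i)
      if (x[i] < 0.0) { neg = true; break; }
    if (!neg) { prop(x, t, h); return; }
    for (int i = 0; i < ctx.d; ++i) buf[i] = x[i] < 0.0 ? 0.0 : x[i];
    prop(buf.data(), t, h);
  }
};

// [[Rcpp::export(name = ".evalPropCpp")]]
NumericVector eval_prop_export(List net, NumericVector x, NumericVector c,
                               NumericVector kappa, double t) {
  Model m(net, c, kappa);
  NumericVector h(m.ctx.R);
  m.prop(REAL(x), t, REAL(h));
  return h;
}

// ---------------------------------------------------------------------------
// SSA direct method. Propensities must be time-invariant; recorded at
// out_times by last-event hold.

static void ssa_path(const Model &m, std::vector<double> &x, double t0,
                     const double *out, int nout, double *rec, int maxEvents) {
  int d = m.ctx.d, R = m.ctx.R;
  std::vector<double> h(R);
  double t = t0;
  int l = 0;
  long events = 0;
  while (l < nout) {
    m.prop(x.data(), t, h.data());
    double htot = 0.0;
    for (int j = 0; j < R; ++j) htot += h[j];
    double tnext;
    if (htot <= 0.0) {
      tnext = R_PosInf; // absorbing state
    } else {
      tnext = t + exp_rand() / htot;
    }
    while (l < nout && out[l] < tnext) {
      for (int i = 0; i < d; ++i) rec[l + i * nout] = x[i];
      ++l;
    }
    if (l >= nout) break;
    if (!std::isfinite(tnext)) break;
    t = tnext;
    double v = unif_rand() * htot, cum = 0.0;
    int j = 0;
    for (; j < R - 1; ++j) {
      cum += h[j];
      if (v <= cum) break;
    }
    for (int i = 0; i < d; ++i) x[i] += m.stoich[j * d + i];
    if (++events > maxEvents)
      stop("SSA event count exceeded cap (%d); runaway network?", maxEvents);
  }
}

// [[Rcpp::export(name = ".ssaCpp")]]
NumericMatrix ssa_cpp(List net, NumericVector c, NumericVector kappa,
                      NumericVector x0, double t0, NumericVector outTimes,
                      int maxEvents) {
  Model m(net, c, kappa);
  int nout = outTimes.size();
  NumericMatrix rec(nout, m.ctx.d);
  std::vector<double> x(x0.begin(), x0.end());
  ssa_path(m, x, t0, REAL(outTimes), nout, REAL(rec), maxEvents);
  return rec;
}

// ---------------------------------------------------------------------------
// Extrande: exact thinning for time-varying propensities. Within a lookahead
// window the state is constant, so the bound need only dominate the total
// propensity as a function of t for fixed state.
//   boundMode 0: analytic bound for the circadian network (sin term at +a)
//   boundMode 1: time-invariant propensities; bound = total at window start
//   boundMode 2: R callback bound(x, c, kappa, t0, t1) -> B

struct ExtrandeStats { long events, virtuals; };

static double extrande_bound(const Model &m, int boundMode, Function *boundFn,
                             const double *x, double t0, double t1,
                             std::vector<double> &h) {
  if (boundMode == 0) {
    // circadian: sup_t c1*(1+a*sin) = c1*(1+|a|), decays state-fixed
    const double *c = m.c.begin(), *k = m.kappa.begin();
    return c[0] * (1.0 + std::fabs(k[0])) + (c[1] + c[2]) * x[0] + c[3] * x[1];
  } else if (boundMode == 1) {
    m.prop(x, t0, h.data());
    double s = 0.0;
    for (int j = 0; j < m.ctx.R; ++j) s += h[j];
    return s;
  } else {
    NumericVector xv(m.ctx.d);
    for (int i = 0; i < m.ctx.d; ++i) xv[i] = x[i];
    return as<double>((*boundFn)(xv, m.c, m.kappa, t0, t1));
  }
}

static void extrande_path(const Model &m, std::vector<double> &x, double t0,
                          const double *out, int nout, double *rec,
                          double lookahead, int boundMode, Function *boundFn,
                          int maxEvents, ExtrandeStats *stats) {
  int d = m.ctx.d, R = m.ctx.R;
  std::vector<double> h(R);
  double t = t0;
  double tend = out[nout - 1];
  int l = 0;
  long events = 0, virtuals = 0;
  while (t < tend) {
    double L = std::min(lookahead, tend - t);
    double B = extrande_bound(m, boundMode, boundFn, x.data(), t, t + L, h);
    double tnext;
    bool fire = false;
    int j = -1;
    if (B <= 0.0) {
      tnext = t + L;
    } else {
      double dt = exp_rand() / B;
      if (dt > L) {
        tnext = t + L;
      } else {
        tnext = t + dt;
        m.prop(x.data(), tnext, h.data());
        double htot = 0.0;
        for (int r = 0; r < R; ++r) htot += h[r];
        if (htot > B * (1.0 + 1e-9))
          stop("Extrande bound violated at t = %g (total propensity %g > bound %g)",
               tnext, htot, B);
        double v = unif_rand() * B;
        if (v < htot) {
          fire = true;
          double cum = 0.0;
          for (j = 0; j < R - 1; ++j) {
            cum += h[j];
            if (v <= cum) break;
          }
        } else {
          ++virtuals;
        }
      }
    }
    while (l < nout && out[l] < tnext) {
      for (int i = 0; i < d; ++i) rec[l + i * nout] = x[i];
      ++l;
    }
    t = tnext;
    if (fire) {
      for (int i = 0; i < d; ++i) x[i] += m.stoich[j * d + i];
      if (++events > maxEvents)
        stop("Extrande event count exceeded cap (%d)", maxEvents);
    }
  }
  while (l < nout) {
    for (int i = 0; i < d; ++i) rec[l + i * nout] = x[i];
    ++l;
  }
  if (stats) { stats->events = events; stats->virtuals = virtuals; }
}

// [[Rcpp::export(name = ".extrandeCpp")]]
List extrande_cpp(List net, NumericVector c, NumericVector kappa,
                  NumericVector x0, double t0, NumericVector outTimes,
                  double lookahead, int boundMode, SEXP boundFn,
                  int maxEvents) {
  Model m(net, c, kappa);
  int nout = outTimes.size();
  NumericMatrix rec(nout, m.ctx.d);
  std::vector<double> x(x0.begin(), x0.end());
  Function *bf = NULL;
  std::unique_ptr<Function> bfh;
  if (boundMode == 2) {
    bfh.reset(new Function(boundFn));
    bf = bfh.get();
  }
  ExtrandeStats st = {0, 0};
  extrande_path(m, x, t0, REAL(outTimes), nout, REAL(rec), lookahead,
                boundMode, bf, maxEvents, &st);
  return List::create(_["states"] = rec, _["events"] = (double)st.events,
                      _["virtual"] = (double)st.virtuals);
}

// ---------------------------------------------------------------------------
// Fixed-step tau-leap and chemical Langevin (Euler-Maruyama) steppers.
// The `u` pointer, when non-NULL, supplies one standard normal per reaction
// per substep (tau-leap converts via qpois(pnorm(u))); NULL means fresh RNG.

static inline double normal_draw(const double *u, long &pos) {
  return u ? u[pos++] : norm_rand();
}

// one tau-leap substep; returns true if any species went negative
static bool tauleap_step(const Model &m, double *x, double t, double dt,
                         const double *u, long &upos, std::vector<double> &h,
                         std::vector<double> &buf) {
  int d = m.ctx.d, R = m.ctx.R;
  m.prop_clamped(x, t, h.data(), buf);
  for (int j = 0; j < R; ++j) {
    double lam = h[j] * dt;
    double kj;
    if (u) {
      double p = R::pnorm5(u[upos++], 0.0, 1.0, 1, 0);
      kj = R::qpois(p, lam, 1, 0);
    } else {
      kj = R::rpois(lam);
    }
    if (kj > 0.0)
      for (int i = 0; i < d; ++i) x[i] += m.stoich[j * d + i] * kj;
  }
  bool neg = false;
  for (int i = 0; i < d; ++i)
    if (x[i] < 0.0) neg = true;
  return neg;
}

// one Langevin substep; id 100 = OU SDE special case
static void langevin_step(const Model &m, double *x, double t, double dt,
                          const double *u, long &upos, std::vector<double> &h,
                          std::vector<double> &buf, bool driftOnly) {
  int d = m.ctx.d, R = m.ctx.R;
  double sdt = std::sqrt(dt);
  if (m.ctx.id == 100) {
    double th1 = m.c[0], th2 = m.c[1], th3 = m.c[2];
    double z = driftOnly ? 0.0 : normal_draw(u, upos);
    x[0] += th1 * (th2 - x[0]) * dt + (driftOnly ? 0.0 : th3 * sdt * z);
    if (u && driftOnly) upos++; // keep layout fixed
    return;
  }
  m.prop_clamped(x, t, h.data(), buf);
  for (int j = 0; j < R; ++j) {
    double zj = normal_draw(u, upos);
    double inc = h[j] * dt + (driftOnly ? 0.0 : std::sqrt(h[j]) * sdt * zj);
    for (int i = 0; i < d; ++i) x[i] += m.stoich[j * d + i] * inc;
  }
  for (int i = 0; i < d; ++i)
    if (!std::isfinite(x[i]))
      stop("non-finite state in Langevin step at t = %g", t);
}

// number of substeps for interval of length len with target step dt
static inline int n_substeps(double len, double dt) {
  int ns = (int)std::ceil(len / dt - 1e-9);
  return ns < 1 ? 1 : ns;
}

// [[Rcpp::export(name = ".tauleapCpp")]]
NumericMatrix tauleap_cpp(List net, NumericVector c, NumericVector kappa,
                          NumericVector x0, double t0, NumericVector outTimes,
                          double dt) {
  Model m(net, c, kappa);
  int d = m.ctx.d, nout = outTimes.size();
  NumericMatrix rec(nout, d);
  std::vector<double> x(x0.begin(), x0.end()), h(m.ctx.R), buf(d);
  double t = t0;
  long upos = 0;
  for (int l = 0; l < nout; ++l) {
    double len = outTimes[l] - t;
    int ns = n_substeps(len, dt);
    double sub = len / ns;
    for (int s = 0; s < ns; ++s) {
      tauleap_step(m, x.data(), t, sub, NULL, upos, h, buf);
      t += sub;
    }
    t = outTimes[l];
    for (int i = 0; i < d; ++i) rec(l, i) = x[i];
  }
  return rec;
}

// [[Rcpp::export(name = ".langevinCpp")]]
NumericMatrix langevin_cpp(List net, NumericVector c, NumericVector kappa,
                           NumericVector x0, double t0, NumericVector outTimes,
                           double dt, bool driftOnly) {
  Model m(net, c, kappa);
  int d = m.ctx.d, nout = outTimes.size();
  NumericMatrix rec(nout, d);
  std::vector<double> x(x0.begin(), x0.end()), h(m.ctx.R), buf(d);
  double t = t0;
  long upos = 0;
  for (int l = 0; l < nout; ++l) {
    double len = outTimes[l] - t;
    int ns = n_substeps(len, dt);
    double sub = len / ns;
    for (int s = 0; s < ns; ++s) {
      langevin_step(m, x.data(), t, sub, NULL, upos, h, buf, driftOnly);
      t += sub;
    }
    t = outTimes[l];
    for (int i = 0; i < d; ++i) rec(l, i) = x[i];
  }
  return rec;
}

// ---------------------------------------------------------------------------
// Systematic resampling: one uniform v, offspring k gets position (v+k)/N.

static void systematic_indices(const double *w, int N, double v,
                               int *idx) {
  double cum = w[0];
  int j = 0;
  for (int k = 0; k < N; ++k) {
    double pos = (v + k) / N;
    while (pos > cum && j < N - 1) {
      ++j;
      cum += w[j];
    }
    idx[k] = j;
  }
}

// [[Rcpp::export(name = ".systematicResampleCpp")]]
IntegerVector systematic_resample_cpp(NumericVector weights, double u) {
  int N = weights.size();
  IntegerVector idx(N);
  std::vector<int> tmp(N);
  systematic_indices(REAL(weights), N, u, tmp.data());
  for (int k = 0; k < N; ++k) idx[k] = tmp[k] + 1;
  return idx;
}

static double logsumexp(const std::vector<double> &v) {
  double mx = R_NegInf;
  for (size_t i = 0; i < v.size(); ++i)
    if (v[i] > mx) mx = v[i];
  if (!std::isfinite(mx)) return R_NegInf;
  double s = 0.0;
  for (size_t i = 0; i < v.size(); ++i) s += std::exp(v[i] - mx);
  return mx + std::log(s);
}

// ---------------------------------------------------------------------------
// Particle filter. Bootstrap (any integrator) or guided modified-diffusion-
// bridge (scalar-state Langevin with scalar linear-Gaussian observation).
//
// Observation model: y_l = P x(t_l) + eps, eps ~ N(0, diag(sigma^2)),
// P a q x d matrix; or a nonlinear g supplied as an R function operating on
// the N x d particle matrix (bootstrap only, slow path).
//
// Auxiliary numbers (correlated pseudo-marginal): uProp is N x K with one
// standard normal per (particle, interval, substep, noise channel) in a fixed
// layout; uResamp has one standard normal per interval, Phi-transformed into
// the resampling uniform. Missing u => fresh RNG (required for SSA/Extrande).

// [[Rcpp::export(name = ".pfCpp")]]
List pf_cpp(List net, NumericVector c, NumericVector kappa,
            NumericVector sigma, NumericVector x0, double t0,
            NumericVector times, NumericMatrix y, NumericMatrix P,
            SEXP gFun, int integrator, double dt, int N, double essThr,
            bool guided, bool sortParticles, SEXP uProp, SEXP uResamp,
            double lookahead, int boundMode, int maxEvents,
            bool ouStationaryInit, double refreshRho) {
  Model m(net, c, kappa);
  const int d = m.ctx.d, R = m.ctx.R, n = times.size(), q = y.ncol();
  const bool haveU = !Rf_isNull(uProp);
  const double *U = haveU ? REAL(uProp) : NULL;
  const int uN = haveU ? Rf_nrows(uProp) : 0;
  const double *Ures = Rf_isNull(uResamp) ? NULL : REAL(uResamp);
  if (haveU && uN != N) stop("auxiliary array has %d rows, expected N = %d", uN, N);
  // optional in-place Crank-Nicolson refresh of the auxiliaries (avoids a
  // round trip through R in the Gibbs hot loop); refreshed arrays are
  // returned so the sampler can store them on acceptance
  NumericMatrix uPropNew;
  NumericVector uResampNew;
  if (refreshRho > 0.0 && haveU) {
    double sfac = std::sqrt(1.0 - refreshRho * refreshRho);
    long K = Rf_ncols(uProp);
    uPropNew = NumericMatrix(N, (int)K);
    double *dst = REAL(uPropNew);
    for (long idx = 0; idx < (long)N * K; ++idx)
      dst[idx] = refreshRho * U[idx] + sfac * norm_rand();
    U = dst;
    if (Ures) {
      uResampNew = NumericVector(n);
      for (int l = 0; l < n; ++l)
        uResampNew[l] = refreshRho * Ures[l] + sfac * norm_rand();
      Ures = REAL(uResampNew);
    }
  }
  const bool useG = !Rf_isNull(gFun);
  std::unique_ptr<Function> gfh;
  if (useG) gfh.reset(new Function(gFun));
  if (guided && (d != 1 || q != 1 || useG))
    stop("guided filter requires scalar state and scalar linear observation");
  if (guided && integrator != 3)
    stop("guided filter requires the Langevin integrator");
  if (d > 16) stop("particle filter supports at most 16 species");

  // particle storage (column-major: particle-major per species)
  std::vector<double> X(N * d), Xnew(N * d);
  for (int p = 0; p < N; ++p)
    for (int i = 0; i < d; ++i) X[p + i * N] = x0[i];
  long ucol0 = 0;
  if (ouStationaryInit) {
    // OU stationary initial law N(th2, th3^2 / (2 th1)); consumes the first
    // auxiliary column so the layout stays fixed
    if (m.ctx.id != 100) stop("stationary initialisation requires the OU model");
    double sd0 = m.c[2] / std::sqrt(2.0 * m.c[0]);
    for (int p = 0; p < N; ++p) {
      double z = haveU ? U[p] : norm_rand();
      X[p] = m.c[1] + sd0 * z;
    }
    ucol0 = 1;
  }
  std::vector<double> logW(N, -std::log((double)N));
  std::vector<double> logw(N), h(R), buf(d);
  std::vector<char> killed(N, 0);
  std::vector<int> anc(N);
  std::vector<double> ess_trace(n);
  std::vector<double> increments(n);
  int nResample = 0;

  // noise channels per substep
  const int Rn = (integrator == 3) ? (m.ctx.id == 100 ? 1 : R)
                                   : ((integrator == 2) ? R : 0);

  double tcur = t0;
  long ucol = ucol0; // column offset into U (per particle rows)
  const double sig2 = sigma[0] * sigma[0];

  for (int l = 0; l < n; ++l) {
    double tl = times[l];
    double len = tl - tcur;
    int ns = (integrator >= 2) ? n_substeps(len, dt) : 0;
    double sub = ns > 0 ? len / ns : 0.0;

    // --- propagate ------------------------------------------------------
    if (integrator == 1 && m.ctx.id == 2) {
      // fused Extrande propagation for the circadian network: thinning with
      // the analytic state-fixed bound, everything inlined
      const double c1 = m.c[0], c2 = m.c[1], c3 = m.c[2], c4 = m.c[3];
      const double amp = m.kappa[0], fa = std::fabs(amp);
      const double w = 2.0 * M_PI / 24.0;
      long events = 0;
      for (int p = 0; p < N; ++p) {
        double mr = X[p], pr = X[p + N];
        double t = tcur;
        while (t < tl) {
          double L = tl - t;
          if (L > lookahead) L = lookahead;
          double B = c1 * (1.0 + fa) + (c2 + c3) * mr + c4 * pr;
          double dtv = exp_rand() / B;
          if (dtv > L) { t += L; continue; }
          t += dtv;
          double h1 = c1 * (1.0 + amp * std::sin(w * t));
          if (h1 < 0.0) h1 = 0.0;
          double v = unif_rand() * B;
          if (v < h1) ++mr;
          else if (v < h1 + c2 * mr) --mr;
          else if (v < h1 + (c2 + c3) * mr) ++pr;
          else if (v < h1 + (c2 + c3) * mr + c4 * pr) --pr;
          // else: virtual candidate
          if (++events > (long)maxEvents * N)
            stop("Extrande event count exceeded cap");
        }
        X[p] = mr; X[p + N] = pr;
      }
    } else if (integrator == 0 || integrator == 1) { // SSA / Extrande, fresh RNG
      std::vector<double> xp(d), recbuf(d);
      double onetime[1] = {tl};
      for (int p = 0; p < N; ++p) {
        for (int i = 0; i < d; ++i) xp[i] = X[p + i * N];
        if (integrator == 0)
          ssa_path(m, xp, tcur, onetime, 1, recbuf.data(), maxEvents);
        else
          extrande_path(m, xp, tcur, onetime, 1, recbuf.data(), lookahead,
                        boundMode, NULL, maxEvents, NULL);
        for (int i = 0; i < d; ++i) X[p + i * N] = recbuf[i];
      }
    } else if (!guided && integrator == 3 && m.ctx.id == 100) {
      // OU: the linear SDE integrates in closed form, so particles take the
      // exact Gaussian transition per substep (no discretisation bias, and
      // the unbiasedness check against the Kalman oracle is exact)
      double th1 = m.c[0], th2 = m.c[1], th3 = m.c[2];
      double e = std::exp(-th1 * sub);
      double sstep = std::sqrt(th3 * th3 / (2.0 * th1) * (1.0 - e * e));
      for (int p = 0; p < N; ++p) {
        double xp = X[p];
        for (int s = 0; s < ns; ++s) {
          double z = U ? U[p + (ucol + (long)s) * N] : norm_rand();
          xp = th2 + (xp - th2) * e + sstep * z;
        }
        X[p] = xp;
      }
    } else if (!guided) { // tau-leap or Langevin bootstrap
      for (int p = 0; p < N; ++p) {
        double xp[16];
        for (int i = 0; i < d; ++i) xp[i] = X[p + i * N];
        double t = tcur;
        for (int s = 0; s < ns; ++s) {
          const double *urow = NULL;
          std::vector<double> udraw;
          if (U) {
            udraw.resize(Rn);
            for (int r = 0; r < Rn; ++r)
              udraw[r] = U[p + (ucol + (long)s * Rn + r) * N];
            urow = udraw.data();
          }
          long pos0 = 0;
          if (integrator == 2) {
            if (tauleap_step(m, xp, t, sub, urow, pos0, h, buf)) killed[p] = 1;
          } else {
            langevin_step(m, xp, t, sub, urow, pos0, h, buf, false);
          }
          t += sub;
        }
        for (int i = 0; i < d; ++i) X[p + i * N] = xp[i];
      }
    } else if (m.ctx.id == 100) {
      // guided filter, OU: exact one-substep transition N(m1, v1) combined
      // with the exact remaining-time predictive of y_l (both Gaussian), so
      // the proposal is the exact conditional p(x_{s+dt} | x_s, y_l)
      double yl = y(l, 0), pmat = P(0, 0);
      double th1 = m.c[0], th2 = m.c[1], th3 = m.c[2];
      double vstat = th3 * th3 / (2.0 * th1);
      for (int p = 0; p < N; ++p) {
        double xp = X[p];
        double t = tcur, lw = 0.0;
        for (int s = 0; s < ns; ++s) {
          double delta = tl - t;
          double eS = std::exp(-th1 * sub);
          double v1 = vstat * (1.0 - eS * eS);
          double m1 = th2 + (xp - th2) * eS;
          double eR = std::exp(-th1 * (delta - sub));
          double vR = vstat * (1.0 - eR * eR);
          // y_l | x_{s+dt} ~ N(a0 + a1 x, residvar)
          double a0 = pmat * th2 * (1.0 - eR), a1 = pmat * eR;
          double residvar = pmat * pmat * vR + sig2;
          double vpost = 1.0 / (1.0 / v1 + a1 * a1 / residvar);
          double mpost = vpost * (m1 / v1 + a1 * (yl - a0) / residvar);
          double z = U ? U[p + (ucol + (long)s) * N] : norm_rand();
          double xnew = mpost + std::sqrt(vpost) * z;
          lw += -0.5 * (std::log(v1) + (xnew - m1) * (xnew - m1) / v1) +
                0.5 * (std::log(vpost) + (xnew - mpost) * (xnew - mpost) / vpost);
          xp = xnew;
          t += sub;
        }
        X[p] = xp;
        logw[p] = lw;
      }
    } else { // guided modified diffusion bridge, scalar Langevin
      double yl = y(l, 0), pmat = P(0, 0);
      for (int p = 0; p < N; ++p) {
        double xp = X[p];
        double t = tcur, lw = 0.0;
        for (int s = 0; s < ns; ++s) {
          double delta = tl - t; // time remaining to the observation
          double a, bvar;
          {
            double xs = xp;
            m.prop_clamped(&xs, t, h.data(), buf);
            a = 0.0;
            bvar = 0.0;
            for (int j = 0; j < R; ++j) {
              a += m.stoich[j] * h[j];
              bvar += m.stoich[j] * m.stoich[j] * h[j];
            }
            if (bvar < 1e-12) bvar = 1e-12;
          }
          // one-step Gaussian proposal conditioned on y_l:
          //   denom = p^2 b delta + sigma^2
          //   mean  = x + a dt + b p (y - p (x + a delta)) / denom * dt
          //   var   = b dt (1 - p^2 b dt / denom)
          double denom = pmat * pmat * bvar * delta + sig2;
          double mprop = xp + a * sub +
                         bvar * pmat * (yl - pmat * (xp + a * delta)) / denom * sub;
          double vprop = bvar * sub * (1.0 - pmat * pmat * bvar * sub / denom);
          if (vprop < 1e-14) vprop = 1e-14;
          double z = U ? U[p + (ucol + (long)s) * N] : norm_rand();
          double xnew = mprop + std::sqrt(vprop) * z;
          // weight: latent Euler transition density / proposal density
          double mlat = xp + a * sub, vlat = bvar * sub;
          lw += -0.5 * (std::log(vlat) + (xnew - mlat) * (xnew - mlat) / vlat) +
                0.5 * (std::log(vprop) + (xnew - mprop) * (xnew - mprop) / vprop);
          xp = xnew;
          t += sub;
        }
        X[p] = xp;
        logw[p] = lw;
      }
    }
    ucol += (long)ns * (guided ? 1 : Rn);
    tcur = tl;

    // --- weight ----------------------------------------------------------
    if (useG) {
      NumericMatrix Xm(N, d);
      for (int p = 0; p < N; ++p)
        for (int i = 0; i < d; ++i) Xm(p, i) = X[p + i * N];
      NumericMatrix G = as<NumericMatrix>((*gfh)(Xm, tl));
      for (int p = 0; p < N; ++p) {
        double lg = 0.0;
        for (int r = 0; r < q; ++r) {
          double res = y(l, r) - G(p, r);
          lg += -0.5 * (LOG_2PI + 2.0 * std::log(sigma[r]) +
                        res * res / (sigma[r] * sigma[r]));
        }
        logw[p] = lg;
      }
    } else {
      for (int p = 0; p < N; ++p) {
        double lg = guided ? logw[p] : 0.0;
        for (int r = 0; r < q; ++r) {
          double mean = 0.0;
          for (int i = 0; i < d; ++i) mean += P(r, i) * X[p + i * N];
          double res = y(l, r) - mean;
          lg += -0.5 * (LOG_2PI + 2.0 * std::log(sigma[r]) +
                        res * res / (sigma[r] * sigma[r]));
        }
        logw[p] = lg;
      }
    }
    for (int p = 0; p < N; ++p)
      if (killed[p]) logw[p] = R_NegInf;
    std::fill(killed.begin(), killed.end(), 0);

    std::vector<double> tot(N);
    for (int p = 0; p < N; ++p) tot[p] = logW[p] + logw[p];
    double Z = logsumexp(tot);
    increments[l] = Z;
    if (!std::isfinite(Z)) { // all particles dead: estimate is zero
      for (int r = l; r < n; ++r) { increments[r] = R_NegInf; ess_trace[r] = 0.0; }
      return List::create(_["value"] = R_NegInf,
                          _["increments"] = NumericVector(increments.begin(), increments.end()),
                          _["ess"] = NumericVector(ess_trace.begin(), ess_trace.end()),
                          _["nResample"] = nResample,
                          _["uProp"] = (refreshRho > 0.0 && haveU) ? (SEXP)uPropNew : R_NilValue,
                          _["uResamp"] = (refreshRho > 0.0 && haveU && !Rf_isNull(uResamp)) ? (SEXP)uResampNew : R_NilValue);
    }
    // normalized weights
    double ess = 0.0;
    for (int p = 0; p < N; ++p) {
      logW[p] = tot[p] - Z;
      double w = std::exp(logW[p]);
      ess += w * w;
    }
    ess = 1.0 / ess;
    ess_trace[l] = ess;

    // --- resample (not after the last observation) -----------------------
    if (l < n - 1) {
      double v = Ures ? R::pnorm5(Ures[l], 0.0, 1.0, 1, 0) : unif_rand();
      if (ess < essThr * N) {
        std::vector<double> w(N);
        std::vector<int> ord(N);
        for (int p = 0; p < N; ++p) ord[p] = p;
        if (sortParticles) {
          const std::vector<double> &Xr = X;
          const int Nn = N, dd = d;
          std::sort(ord.begin(), ord.end(), [&Xr, Nn, dd](int a, int b) {
            for (int i = 0; i < dd; ++i) {
              double xa = Xr[a + i * Nn], xb = Xr[b + i * Nn];
              if (xa != xb) return xa < xb;
            }
            return a < b;
          });
        }
        for (int p = 0; p < N; ++p) w[p] = std::exp(logW[ord[p]]);
        systematic_indices(w.data(), N, v, anc.data());
        for (int p = 0; p < N; ++p)
          for (int i = 0; i < d; ++i)
            Xnew[p + i * N] = X[ord[anc[p]] + i * N];
        std::swap(X, Xnew);
        std::fill(logW.begin(), logW.end(), -std::log((double)N));
        ++nResample;
      }
    }
  }
  // total loglik = sum of increments (increments are incremental evidences)
  double total = 0.0;
  for (int l = 0; l < n; ++l) total += increments[l];
  return List::create(_["value"] = total,
                      _["increments"] = NumericVector(increments.begin(), increments.end()),
                      _["ess"] = NumericVector(ess_trace.begin(), ess_trace.end()),
                      _["nResample"] = nResample,
                      _["uProp"] = (refreshRho > 0.0 && haveU) ? (SEXP)uPropNew : R_NilValue,
                      _["uResamp"] = (refreshRho > 0.0 && haveU && !Rf_isNull(uResamp)) ? (SEXP)uResampNew : R_NilValue);
}

// ---------------------------------------------------------------------------
// Rank-one Cholesky update for the RAM proposal: given lower-triangular L
// with target M = L L' + eta (L z)(L z)' / |z|^2, return the lower Cholesky
// factor of M (classic dchud/dchdd sweep; eta may be negative).

// [[Rcpp::export(name = ".ramUpdateCpp")]]
NumericMatrix ram_update_cpp(NumericMatrix Lin, double eta, NumericVector z) {
  int p = Lin.nrow();
  NumericMatrix L(clone(Lin));
  double nz2 = 0.0;
  for (int i = 0; i < p; ++i) nz2 += z[i] * z[i];
  if (nz2 <= 0.0) return L;
  // v = L z * sqrt(|eta|/|z|^2); sign of eta decides update vs downdate
  std::vector<double> v(p, 0.0);
  double s = std::sqrt(std::fabs(eta) / nz2);
  for (int i = 0; i < p; ++i) {
    double acc = 0.0;
    for (int j = 0; j <= i; ++j) acc += L(i, j) * z[j];
    v[i] = acc * s;
  }
  int sign = eta >= 0.0 ? 1 : -1;
  for (int k = 0; k < p; ++k) {
    double Lkk = L(k, k);
    double r2 = Lkk * Lkk + sign * v[k] * v[k];
    if (r2 <= 0.0) r2 = 1e-12; // downdate would lose positive definiteness
    double r = std::sqrt(r2);
    double c = r / Lkk, sfac = v[k] / Lkk;
    L(k, k) = r;
    for (int i = k + 1; i < p; ++i) {
      L(i, k) = (L(i, k) + (double)sign * sfac * v[i]) / c;
      v[i] = c * v[i] - sfac * L(i, k);
    }
  }
  return L;
}
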