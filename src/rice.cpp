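// Myofilament contraction kernel (Rice et al. 2008 variant): calcium-troponin
// binding, N/P regulatory-unit transitions, four-state crossbridge cycle with
// mean-distortion dynamics, force balance with a series-elastic afterload,
// and sarcomere-length evolution. Driven by an externally supplied Cai(t)
// (one-way coupling; linear interpolation of the input trace).
// Units: ms, um, uM for calcium; rates in 1/ms; forces normalized.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct MechParams {
  // Ca binding to troponin
  double kon, koffL, koffH, Qkon, Qkoff;
  // N <-> P regulatory transitions
  double knp, kpn, Qknp, Qkpn, perm50, nperm;
  // crossbridge cycle
  double fapp, Qfapp, gapp, Qgapp, gslmod, hf, Qhf, hfmdc, hb, Qhb, hbmdc,
    gxb, Qgxb, sigmap, sigman, xbmodsp;
  // distortion / force
  double x0, xPsi;
  // geometry
  double SL0, SLrest, SLmin, SLmax, len_thick, len_hbare, len_thin;
  // passive / series element / dynamics
  double PCon_t, PExp_t, SL_c, PCon_c, PExp_c, KSE, visc, mass;
  double TmpC, Tmax;
  int    mode;              // 0 = series-elastic afterload, 1 = constant
  double afterload_const;   // used when mode == 1
  // temperature-adjusted rate products, filled by unpack()
  double konT, koffLT, koffHT, knpT0, kpnT0, fappT, gappT0, hfT0, hbT0,
    gxbT0;
};

static double pget(const List& p, const char* nm) {
  if (!p.containsElementNamed(nm)) stop("mech params: missing '%s'", nm);
  return as<double>(p[nm]);
}

static MechParams unpack(const List& p) {
  MechParams m;
  m.kon = pget(p, "kon"); m.koffL = pget(p, "koffL");
  m.koffH = pget(p, "koffH"); m.Qkon = pget(p, "Qkon");
  m.Qkoff = pget(p, "Qkoff");
  m.knp = pget(p, "knp"); m.kpn = pget(p, "kpn");
  m.Qknp = pget(p, "Qknp"); m.Qkpn = pget(p, "Qkpn");
  m.perm50 = pget(p, "perm50"); m.nperm = pget(p, "nperm");
  m.fapp = pget(p, "fapp"); m.Qfapp = pget(p, "Qfapp");
  m.gapp = pget(p, "gapp"); m.Qgapp = pget(p, "Qgapp");
  m.gslmod = pget(p, "gslmod");
  m.hf = pget(p, "hf"); m.Qhf = pget(p, "Qhf"); m.hfmdc = pget(p, "hfmdc");
  m.hb = pget(p, "hb"); m.Qhb = pget(p, "Qhb"); m.hbmdc = pget(p, "hbmdc");
  m.gxb = pget(p, "gxb"); m.Qgxb = pget(p, "Qgxb");
  m.sigmap = pget(p, "sigmap"); m.sigman = pget(p, "sigman");
  m.xbmodsp = pget(p, "xbmodsp");
  m.x0 = pget(p, "x0"); m.xPsi = pget(p, "xPsi");
  m.SL0 = pget(p, "SL0"); m.SLrest = pget(p, "SLrest");
  m.SLmin = pget(p, "SLmin"); m.SLmax = pget(p, "SLmax");
  m.len_thick = pget(p, "len_thick"); m.len_hbare = pget(p, "len_hbare");
  m.len_thin = pget(p, "len_thin");
  m.PCon_t = pget(p, "PCon_t"); m.PExp_t = pget(p, "PExp_t");
  m.SL_c = pget(p, "SL_c"); m.PCon_c = pget(p, "PCon_c");
  m.PExp_c = pget(p, "PExp_c");
  m.KSE = pget(p, "KSE"); m.visc = pget(p, "visc"); m.mass = pget(p, "mass");
  m.TmpC = pget(p, "TmpC"); m.Tmax = pget(p, "Tmax");
  m.mode = (int)pget(p, "mode");
  m.afterload_const = pget(p, "afterload_const");
  const double qt = (m.TmpC - 37.0) / 10.0;
  m.konT = m.kon * std::pow(m.Qkon, qt);
  m.koffLT = m.koffL * std::pow(m.Qkoff, qt);
  m.koffHT = m.koffH * std::pow(m.Qkoff, qt);
  m.knpT0 = m.knp * std::pow(m.Qknp, qt);          // x permtot per step
  m.kpnT0 = m.kpn * std::pow(m.Qkpn, qt);          // x inverse permtot
  m.fappT = m.fapp * m.xbmodsp * std::pow(m.Qfapp, qt);
  m.gappT0 = m.gapp * m.xbmodsp * std::pow(m.Qgapp, qt); // x SL modifier
  m.hfT0 = m.hf * m.xbmodsp * std::pow(m.Qhf, qt);       // x strain mod
  m.hbT0 = m.hb * m.xbmodsp * std::pow(m.Qhb, qt);
  m.gxbT0 = m.gxb * m.xbmodsp * std::pow(m.Qgxb, qt);
  return m;
}

static inline double heav(double x) { return x < 0.0 ? 0.0 : 1.0; }
static inline double sgn(double x) {
  return (x > 0.0) - (x < 0.0);
}

// single-overlap fractions of thick and thin filaments at sarcomere length x
static inline double sovrThick(const MechParams& m, double x) {
  double ze = std::min(m.len_thick / 2.0, x / 2.0);
  double cle = std::max(x / 2.0 - (x - m.len_thin), m.len_hbare / 2.0);
  double len_sovr = ze - cle;
  return len_sovr * 2.0 / (m.len_thick - m.len_hbare);
}
static inline double sovrThin(const MechParams& m, double x) {
  double ze = std::min(m.len_thick / 2.0, x / 2.0);
  double cle = std::max(x / 2.0 - (x - m.len_thin), m.len_hbare / 2.0);
  return (ze - cle) / m.len_thin;
}

static inline double passiveForce(const MechParams& m, double x) {
  double titin = sgn(x - m.SLrest) * m.PCon_t *
    (std::exp(m.PExp_t * std::fabs(x - m.SLrest)) - 1.0);
  double collagen = heav(x - m.SL_c) * m.PCon_c *
    (std::exp(m.PExp_c * (x - m.SL_c)) - 1.0);
  return titin + collagen;
}

// State layout
enum {
  sNNoXB = 0, sPNoXB, sNXB, sPXB, sXBprer, sXBpostr, sxXBprer, sxXBpostr,
  sTRPNCaL, sTRPNCaH, sSL, sIntf, MNSTATE
};

// normalization constant: steady post-rotation occupancy at base rates
static double ssXBpostr(const MechParams& m) {
  double d = m.gxb * m.hf + m.fapp * m.hf + m.gapp * m.hb +
    m.gapp * m.gxb + m.fapp * m.hb + m.fapp * m.gxb;
  return m.fapp * m.hf / d;
}

static double activeForce(const MechParams& m, const double* s) {
  return sovrThick(m, s[sSL]) *
    (s[sxXBprer] * s[sXBprer] + s[sxXBpostr] * s[sXBpostr]) /
    (m.x0 * ssXBpostr(m));
}

// one explicit-Euler step; cai in uM. Returns false on divergence.
static bool mechStep(double* s, double cai, const MechParams& m, double dt) {
  const double konT = m.konT, koffLT = m.koffLT, koffHT = m.koffHT;

  const double sovft = sovrThin(m, s[sSL]);
  const double tropreg = (1.0 - sovft) * s[sTRPNCaL] + sovft * s[sTRPNCaH];
  double permtot;
  if (tropreg <= 0.0) permtot = 0.0;
  else permtot = std::sqrt(1.0 / (1.0 + std::pow(m.perm50 / tropreg,
                                                 m.nperm)));
  const double inprmt = permtot > 0.0 ?
    std::min(1.0 / permtot, 100.0) : 100.0;
  const double knpT = m.knpT0 * permtot;
  const double kpnT = m.kpnT0 * inprmt;

  const double fappT = m.fappT;
  const double gapslmd = 1.0 + (1.0 - sovrThick(m, s[sSL])) * m.gslmod;
  const double gappT = m.gappT0 * gapslmd;
  const double xpre = s[sxXBprer] / m.x0;
  const double hfmd = std::exp(-sgn(s[sxXBprer]) * m.hfmdc * xpre * xpre);
  const double xpost = (s[sxXBpostr] - m.x0) / m.x0;
  const double hbmd = std::exp(sgn(xpost) * m.hbmdc * xpost * xpost);
  const double hfT = m.hfT0 * hfmd;
  const double hbT = m.hbT0 * hbmd;
  const double gxbmd = (s[sxXBpostr] <= m.x0) ?
    std::exp(m.sigmap * xpost * xpost) :
    std::exp(m.sigman * xpost * xpost);
  const double gxbT = m.gxbT0 * gxbmd;

  // duty fractions (temperature/strain-adjusted rates)
  const double dden = gxbT * hfT + fappT * hfT + gappT * hbT +
    gappT * gxbT + fappT * hbT + fappT * gxbT;
  const double dutyPrer = (fappT * hbT + fappT * gxbT) / dden;
  const double dutyPostr = fappT * hfT / dden;

  // force balance; the integral accumulates force in the shortening
  // direction: contractile (active + net passive) force drives SL down,
  // the series element KSE (SL - SL0) (or the constant isotonic load)
  // resists it. The linear SL/Intf spring pair is advanced by backward
  // Euler (the mass is small, making the pair a stiff oscillator well
  // outside the explicit stability region); everything nonlinear stays
  // explicit at the state n values.
  const double factive = activeForce(m, s);
  const double fpassive = passiveForce(m, s[sSL]);
  const double fpreload = passiveForce(m, m.SL0);
  const double A = (m.mode == 0) ?
    -(factive + fpassive - fpreload) :
    -(factive + fpassive - fpreload) + m.afterload_const;
  const double kse = (m.mode == 0) ? m.KSE : 0.0;
  const double gate = heav(s[sSL] - m.SLmin) * heav(m.SLmax - s[sSL]);
  const double d0 = s[sSL] - m.SL0;
  double dnew, intf_new, dSL;
  if (gate > 0.0) {
    dnew = (d0 + (dt / m.mass) * (s[sIntf] + dt * A)) /
      (1.0 + (dt / m.mass) * (dt * kse + m.visc));
    intf_new = s[sIntf] + dt * (A - kse * dnew);
    dSL = (dnew - d0) / dt;
  } else {
    dnew = d0;
    intf_new = s[sIntf] + dt * (A - kse * d0);
    dSL = 0.0;
  }

  // derivatives
  const double dTRPNCaL = konT * cai * (1.0 - s[sTRPNCaL]) -
    koffLT * s[sTRPNCaL];
  const double dTRPNCaH = konT * cai * (1.0 - s[sTRPNCaH]) -
    koffHT * s[sTRPNCaH];
  // flux-form occupancy update: each transition amount is added to one
  // state and subtracted from the other as the same rounded number, so
  // the pool sums are conserved to machine precision per step
  const double dNNoXB = -knpT * s[sNNoXB] + kpnT * s[sPNoXB];
  const double f_np = dt * knpT * s[sNXB];      // N -> P
  const double f_pn = dt * kpnT * s[sPXB];      // P -> N
  const double f_app = dt * fappT * s[sPXB];    // P -> PreR
  const double f_gap = dt * gappT * s[sXBprer]; // PreR -> P
  const double f_hf = dt * hfT * s[sXBprer];    // PreR -> PostR
  const double f_hb = dt * hbT * s[sXBpostr];   // PostR -> PreR
  const double f_gxb = dt * gxbT * s[sXBpostr]; // PostR -> P
  const double dxXBprer = 0.5 * dSL + (m.xPsi / dutyPrer) *
    (fappT * (-s[sxXBprer]) +
     hbT * (s[sxXBpostr] - m.x0 - s[sxXBprer]));
  const double dxXBpostr = 0.5 * dSL + (m.xPsi / dutyPostr) *
    (hfT * (s[sxXBprer] + m.x0 - s[sxXBpostr]));

  s[sTRPNCaL] += dt * dTRPNCaL;
  s[sTRPNCaH] += dt * dTRPNCaH;
  const double f_np0 = dt * dNNoXB;
  s[sNNoXB] += f_np0;
  s[sPNoXB] -= f_np0;
  s[sNXB] += f_pn - f_np;
  s[sPXB] += f_np - f_pn - f_app + f_gap + f_gxb;
  s[sXBprer] += f_app - f_gap - f_hf + f_hb;
  s[sXBpostr] += f_hf - f_hb - f_gxb;
  s[sxXBprer] += dt * dxXBprer;
  s[sxXBpostr] += dt * dxXBpostr;
  s[sSL] = m.SL0 + dnew;
  s[sIntf] = intf_new;

  if (s[sSL] < 1.2 || s[sSL] > 2.6) return false;
  for (int k = 0; k < MNSTATE; ++k)
    if (!std::isfinite(s[k])) return false;
  return true;
}

static CharacterVector mechStateNames() {
  return CharacterVector::create(
    "NNoXB", "PNoXB", "NXB", "PXB", "XBprer", "XBpostr",
    "xXBprer", "xXBpostr", "TRPNCaL", "TRPNCaH", "SL", "Intf");
}

// [[Rcpp::export(name = ".rice_initial_state")]]
NumericVector riceInitialState(List params) {
  MechParams m = unpack(params);
  NumericVector s(MNSTATE);
  s[sNNoXB] = 0.99; s[sPNoXB] = 0.01;
  s[sNXB] = 0.99; s[sPXB] = 0.01;
  s[sXBprer] = 0.0; s[sXBpostr] = 0.0;
  s[sxXBprer] = 0.0; s[sxXBpostr] = m.x0;
  s[sTRPNCaL] = 0.0; s[sTRPNCaH] = 0.0;
  s[sSL] = m.SL0; s[sIntf] = 0.0;
  s.attr("names") = mechStateNames();
  return s;
}

// [[Rcpp::export(name = ".rice_step")]]
NumericVector riceStep(NumericVector state, double cai_uM, List params,
                       double dt, int n_steps) {
  if (state.size() != MNSTATE) stop("state must have %d entries", MNSTATE);
  MechParams m = unpack(params);
  NumericVector out = clone(state);
  for (int i = 0; i < n_steps; ++i)
    if (!mechStep(REAL(out), cai_uM, m, dt))
      stop("mechanics divergence at step %d", i + 1);
  out.attr("names") = mechStateNames();
  return out;
}

// Full twitch driven by a sampled Cai(t) trace (mM, converted internally).
// Pre-equilibrates at the first Cai sample for equil_ms before the beat.
// [[Rcpp::export(name = ".rice_run_twitch")]]
List riceRunTwitch(NumericVector t_in, NumericVector cai_mM, List params,
                   double dt, double equil_ms) {
  if (t_in.size() != cai_mM.size()) stop("time and Cai lengths differ");
  if (t_in.size() < 2) stop("Cai trace needs at least 2 samples");
  MechParams m = unpack(params);

  NumericVector s0 = riceInitialState(params);
  std::vector<double> s(REAL(s0), REAL(s0) + MNSTATE);

  const double cai0 = cai_mM[0] * 1000.0; // uM
  long nequil = (long)std::lround(equil_ms / dt);
  bool ok = true;
  for (long k = 0; k < nequil && ok; ++k)
    ok = mechStep(s.data(), cai0, m, dt);

  const double SLref = s[sSL];
  const int n = t_in.size();
  const double t0 = t_in[0], tend = t_in[n - 1];
  const double in_dt = t_in[1] - t_in[0];

  NumericVector ft(n), fnorm(n), fkpa(n), lnorm(n), slout(n);
  double div_time = NA_REAL;
  bool diverged = !ok;

  long nsteps = (long)std::lround((tend - t0) / dt);
  long out_stride = (long)std::lround(in_dt / dt);
  long out_idx = 0;

  for (long k = 0; k <= nsteps; ++k) {
    double t = t0 + k * dt;
    if (!diverged && (k % out_stride == 0) && out_idx < n) {
      ft[out_idx] = t;
      double fa = activeForce(m, s.data());
      fnorm[out_idx] = fa;
      fkpa[out_idx] = fa * m.Tmax;
      lnorm[out_idx] = s[sSL] / SLref;
      slout[out_idx] = s[sSL];
      ++out_idx;
    }
    if (k == nsteps || diverged) break;
    // linear interpolation of Cai input at time t
    double frac = (t - t0) / in_dt;
    long i0 = (long)std::floor(frac);
    if (i0 >= n - 1) i0 = n - 2;
    double w = frac - i0;
    double cai = (cai_mM[i0] * (1.0 - w) + cai_mM[i0 + 1] * w) * 1000.0;
    if (!mechStep(s.data(), cai, m, dt)) {
      diverged = true;
      div_time = t;
    }
  }

  NumericVector sf(s.begin(), s.end());
  sf.attr("names") = mechStateNames();
  return List::create(
    _["time"] = ft, _["tension_norm"] = fnorm, _["tension_kPa"] = fkpa,
    _["length_norm"] = lnorm, _["SL"] = slout, _["dt"] = in_dt,
    _["final_state"] = sf, _["diverged"] = diverged,
    _["diverged_time"] = div_time);
}
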