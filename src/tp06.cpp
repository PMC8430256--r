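// Human ventricular myocyte electrophysiology kernel: ten Tusscher-Panfilov
// (2006) formulation with a reduced four-state Markov ryanodine receptor
// (tracked aggregate Rbar = R + O) and three-compartment calcium dynamics
// (cytosol / SR / diadic subspace), with per-channel maximum-conductance
// scaling. Units: mV, ms, mM, pA/pF. Operator-split stepping: Rush-Larsen
// for Hodgkin-Huxley gates, explicit Euler for V, concentrations and Rbar.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// State vector layout (names kept in R wrapper too)
enum {
  iV = 0, iM, iH, iJ, iD, iF, iF2, iFCaSS, iR, iS, iXr1, iXr2, iXs,
  iNai, iKi, iCai, iCaSR, iCaSS, iRbar, NSTATE
};

// Scaling vector layout: canonical channel ordering
enum { cNa = 0, cCaL, cto, cKr, cKs, cK1, cpK, cpCa, cbNa, cbCa, NCHAN };

// Physical constants. F is the printed 96.4867 C/mmol; volumes in um^3 so
// that products V*F match the source model's implementation exactly.
static const double Fmmol = 96.4867;       // C/mmol
static const double Fmol  = 1000.0 * Fmmol; // C/mol, used in RT/F terms
static const double Rgas  = 8314.472;       // mJ/(mol K)
static const double Temp  = 310.0;          // K
static const double RTONF = Rgas * Temp / Fmol; // mV
static const double CAPACITANCE = 0.185;    // uF

// Extracellular concentrations (mM)
static const double Ko = 5.4, Nao = 140.0, Cao = 2.0;

// Maximum conductances / permeabilities (source-model values)
static const double GNa = 14.838, GCaL = 3.980e-5, GKr = 0.153,
  GK1 = 5.405, GpK = 0.0146, GpCa = 0.1238, GbNa = 0.00029,
  GbCa = 0.000592, knaca = 1000.0, knak = 2.724;
static const double pKNa = 0.03, KmNai = 87.5, KmCa = 1.38, ksat = 0.1,
  ncagamma = 0.35, KmK = 1.0, KmNa = 40.0, KpCa = 0.0005;

// Calcium handling
static const double Vc = 16.404, Vsr = 1.094, Vss = 0.05468; // um^3
static const double Vrel = 0.102, Vxfer = 0.0038, Vleak = 0.00036,
  Vmaxup = 0.006375, Kup = 0.00025;
static const double k1prime = 0.15, k2prime = 0.045, k3ryr = 0.060,
  k4ryr = 0.005, maxsr = 2.5, minsr = 1.0, ECsr = 1.5;
static const double Bufc = 0.2, Kbufc = 0.001, Bufsr = 10.0, Kbufsr = 0.3,
  Bufss = 0.4, Kbufss = 0.00025;

struct CellType { double Gto, GKs; int s_variant; };
// 0 = epi, 1 = endo, 2 = M
static CellType cellTypeParams(int ct) {
  CellType p;
  if (ct == 1)      { p.Gto = 0.073; p.GKs = 0.392; p.s_variant = 1; }
  else if (ct == 2) { p.Gto = 0.294; p.GKs = 0.098; p.s_variant = 0; }
  else              { p.Gto = 0.294; p.GKs = 0.392; p.s_variant = 0; }
  return p;
}

struct Currents {
  double INa, ICaL, Ito, IKr, IKs, IK1, IpK, IpCa, IbNa, IbCa, INaCa, INaK;
  double Iion() const {
    return INa + ICaL + Ito + IKr + IKs + IK1 + IpK + IpCa + IbNa + IbCa +
      INaCa + INaK;
  }
};

static Currents computeCurrents(const double* s, const double* g,
                                const CellType& ct) {
  Currents c;
  const double V = s[iV];
  const double EK  = RTONF * std::log(Ko / s[iKi]);
  const double ENa = RTONF * std::log(Nao / s[iNai]);
  const double EKs = RTONF * std::log((Ko + pKNa * Nao) /
                                      (s[iKi] + pKNa * s[iNai]));
  const double ECa = 0.5 * RTONF * std::log(Cao / s[iCai]);

  c.INa = g[cNa] * GNa * s[iM] * s[iM] * s[iM] * s[iH] * s[iJ] * (V - ENa);

  // L-type Ca current (GHK-like driving term); x = 2(V-15)F/RT
  {
    const double x = 2.0 * (V - 15.0) / RTONF;
    const double gate = s[iD] * s[iF] * s[iF2] * s[iFCaSS];
    double drv;
    if (std::fabs(x) < 1e-8)
      drv = 2.0 * Fmmol * (0.25 * s[iCaSS] - Cao);
    else
      drv = 2.0 * Fmmol * x * (0.25 * s[iCaSS] * std::exp(x) - Cao) /
        std::expm1(x);
    c.ICaL = g[cCaL] * GCaL * gate * 1000.0 * drv;
  }

  c.Ito = g[cto] * ct.Gto * s[iR] * s[iS] * (V - EK);
  c.IKr = g[cKr] * GKr * std::sqrt(Ko / 5.4) * s[iXr1] * s[iXr2] * (V - EK);
  c.IKs = g[cKs] * ct.GKs * s[iXs] * s[iXs] * (V - EKs);

  {
    const double aK1 = 0.1 / (1.0 + std::exp(0.06 * (V - EK - 200.0)));
    const double bK1 = (3.0 * std::exp(0.0002 * (V - EK + 100.0)) +
                        std::exp(0.1 * (V - EK - 10.0))) /
      (1.0 + std::exp(-0.5 * (V - EK)));
    c.IK1 = g[cK1] * GK1 * std::sqrt(Ko / 5.4) * aK1 / (aK1 + bK1) * (V - EK);
  }

  c.IpK  = g[cpK] * GpK * (V - EK) / (1.0 + std::exp((25.0 - V) / 5.98));
  c.IpCa = g[cpCa] * GpCa * s[iCai] / (s[iCai] + KpCa);
  c.IbNa = g[cbNa] * GbNa * (V - ENa);
  c.IbCa = g[cbCa] * GbCa * (V - ECa);

  // exchanger and pump: never scaled
  {
    const double vf = V / RTONF;
    c.INaCa = knaca *
      (std::exp(ncagamma * vf) * s[iNai] * s[iNai] * s[iNai] * Cao -
       std::exp((ncagamma - 1.0) * vf) * Nao * Nao * Nao * s[iCai] * 2.5) /
      ((KmNai * KmNai * KmNai + Nao * Nao * Nao) * (KmCa + Cao) *
       (1.0 + ksat * std::exp((ncagamma - 1.0) * vf)));
    c.INaK = knak * (Ko / (Ko + KmK)) * (s[iNai] / (s[iNai] + KmNa)) /
      (1.0 + 0.1245 * std::exp(-0.1 * vf) + 0.0353 * std::exp(-vf));
  }
  return c;
}

// Rush-Larsen gate update helpers -------------------------------------------
static inline double rl(double g, double ginf, double tau, double dt) {
  return ginf - (ginf - g) * std::exp(-dt / tau);
}

static void updateGates(double* s, double dt, const CellType& ct) {
  const double V = s[iV];

  { // m, h, j (fast sodium)
    double minf = 1.0 / std::pow(1.0 + std::exp((-56.86 - V) / 9.03), 2.0);
    double am = 1.0 / (1.0 + std::exp((-60.0 - V) / 5.0));
    double bm = 0.1 / (1.0 + std::exp((V + 35.0) / 5.0)) +
      0.1 / (1.0 + std::exp((V - 50.0) / 200.0));
    double taum = am * bm;
    double hinf = 1.0 / std::pow(1.0 + std::exp((V + 71.55) / 7.43), 2.0);
    double ah, bh, aj, bj;
    if (V >= -40.0) {
      ah = 0.0;
      bh = 0.77 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
      aj = 0.0;
      bj = 0.6 * std::exp(0.057 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
    } else {
      ah = 0.057 * std::exp(-(V + 80.0) / 6.8);
      bh = 2.7 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.3485 * V);
      aj = (-2.5428e4 * std::exp(0.2444 * V) -
            6.948e-6 * std::exp(-0.04391 * V)) * (V + 37.78) /
        (1.0 + std::exp(0.311 * (V + 79.23)));
      bj = 0.02424 * std::exp(-0.01052 * V) /
        (1.0 + std::exp(-0.1378 * (V + 40.14)));
    }
    double tauh = 1.0 / (ah + bh), jinf = hinf, tauj = 1.0 / (aj + bj);
    s[iM] = rl(s[iM], minf, taum, dt);
    s[iH] = rl(s[iH], hinf, tauh, dt);
    s[iJ] = rl(s[iJ], jinf, tauj, dt);
  }

  { // d, f, f2, fCaSS (L-type calcium)
    double dinf = 1.0 / (1.0 + std::exp((-8.0 - V) / 7.5));
    double ad = 1.4 / (1.0 + std::exp((-35.0 - V) / 13.0)) + 0.25;
    double bd = 1.4 / (1.0 + std::exp((V + 5.0) / 5.0));
    double gd = 1.0 / (1.0 + std::exp((50.0 - V) / 20.0));
    double taud = ad * bd + gd;
    double finf = 1.0 / (1.0 + std::exp((V + 20.0) / 7.0));
    double tauf = 1102.5 * std::exp(-(V + 27.0) * (V + 27.0) / 225.0) +
      200.0 / (1.0 + std::exp((13.0 - V) / 10.0)) +
      180.0 / (1.0 + std::exp((V + 30.0) / 10.0)) + 20.0;
    double f2inf = 0.67 / (1.0 + std::exp((V + 35.0) / 7.0)) + 0.33;
    double tauf2 = 562.0 * std::exp(-(V + 27.0) * (V + 27.0) / 240.0) +
      31.0 / (1.0 + std::exp((25.0 - V) / 10.0)) +
      80.0 / (1.0 + std::exp((V + 30.0) / 10.0));
    double css = s[iCaSS] / 0.05;
    double fcassinf = 0.6 / (1.0 + css * css) + 0.4;
    double taufcass = 80.0 / (1.0 + css * css) + 2.0;
    s[iD]     = rl(s[iD], dinf, taud, dt);
    s[iF]     = rl(s[iF], finf, tauf, dt);
    s[iF2]    = rl(s[iF2], f2inf, tauf2, dt);
    s[iFCaSS] = rl(s[iFCaSS], fcassinf, taufcass, dt);
  }

  { // r, s (transient outward)
    double rinf = 1.0 / (1.0 + std::exp((20.0 - V) / 6.0));
    double taur = 9.5 * std::exp(-(V + 40.0) * (V + 40.0) / 1800.0) + 0.8;
    double sinf, taus;
    if (ct.s_variant == 1) { // endocardial variant
      sinf = 1.0 / (1.0 + std::exp((V + 28.0) / 5.0));
      taus = 1000.0 * std::exp(-(V + 67.0) * (V + 67.0) / 1000.0) + 8.0;
    } else {
      sinf = 1.0 / (1.0 + std::exp((V + 20.0) / 5.0));
      taus = 85.0 * std::exp(-(V + 45.0) * (V + 45.0) / 320.0) +
        5.0 / (1.0 + std::exp((V - 20.0) / 5.0)) + 3.0;
    }
    s[iR] = rl(s[iR], rinf, taur, dt);
    s[iS] = rl(s[iS], sinf, taus, dt);
  }

  { // xr1, xr2, xs (delayed rectifiers)
    double xr1inf = 1.0 / (1.0 + std::exp((-26.0 - V) / 7.0));
    double axr1 = 450.0 / (1.0 + std::exp((-45.0 - V) / 10.0));
    double bxr1 = 6.0 / (1.0 + std::exp((V + 30.0) / 11.5));
    double xr2inf = 1.0 / (1.0 + std::exp((V + 88.0) / 24.0));
    double axr2 = 3.0 / (1.0 + std::exp((-60.0 - V) / 20.0));
    double bxr2 = 1.12 / (1.0 + std::exp((V - 60.0) / 20.0));
    double xsinf = 1.0 / (1.0 + std::exp((-5.0 - V) / 14.0));
    double axs = 1400.0 / std::sqrt(1.0 + std::exp((5.0 - V) / 6.0));
    double bxs = 1.0 / (1.0 + std::exp((V - 35.0) / 15.0));
    s[iXr1] = rl(s[iXr1], xr1inf, axr1 * bxr1, dt);
    s[iXr2] = rl(s[iXr2], xr2inf, axr2 * bxr2, dt);
    s[iXs]  = rl(s[iXs], xsinf, axs * bxs + 80.0, dt);
  }
}

// RyR + calcium compartment update (explicit Euler) -------------------------
static void updateCalciumAndRyR(double* s, const Currents& c, double dt) {
  // SR-load-dependent RyR rates
  const double casr = s[iCaSR], cass = s[iCaSS], cai = s[iCai];
  const double kcasr = maxsr - (maxsr - minsr) /
    (1.0 + (ECsr / casr) * (ECsr / casr));
  const double k1 = k1prime / kcasr;
  const double k2 = k2prime * kcasr;
  const double O = k1 * cass * cass * s[iRbar] /
    (k3ryr + k1 * cass * cass);
  const double Irel  = Vrel * O * (casr - cass);
  const double Ileak = Vleak * (casr - cai);
  const double Iup   = Vmaxup / (1.0 + (Kup * Kup) / (cai * cai));
  const double Ixfer = Vxfer * (cass - cai);

  s[iRbar] += dt * (-k2 * cass * s[iRbar] + k4ryr * (1.0 - s[iRbar]));
  if (s[iRbar] < 0.0) s[iRbar] = 0.0;
  if (s[iRbar] > 1.0) s[iRbar] = 1.0;

  // instantaneous-buffer factors
  const double bc = 1.0 / (1.0 + Bufc * Kbufc /
                           ((cai + Kbufc) * (cai + Kbufc)));
  const double bsr = 1.0 / (1.0 + Bufsr * Kbufsr /
                            ((casr + Kbufsr) * (casr + Kbufsr)));
  const double bss = 1.0 / (1.0 + Bufss * Kbufss /
                            ((cass + Kbufss) * (cass + Kbufss)));

  const double dCai = bc *
    (-(c.IbCa + c.IpCa - 2.0 * c.INaCa) * CAPACITANCE / (2.0 * Vc * Fmmol) +
     (Vsr / Vc) * (Ileak - Iup) + Ixfer);
  const double dCasr = bsr * (Iup - Ileak - Irel);
  const double dCass = bss *
    (-c.ICaL * CAPACITANCE / (2.0 * Vss * Fmmol) +
     (Vsr / Vss) * Irel - (Vc / Vss) * Ixfer);

  s[iCai]  += dt * dCai;
  s[iCaSR] += dt * dCasr;
  s[iCaSS] += dt * dCass;
}

static void stepOnce(double* s, const double* g, const CellType& ct,
                     double dt, double istim) {
  const Currents c = computeCurrents(s, g, ct);
  updateCalciumAndRyR(s, c, dt);
  s[iNai] += dt * (-(c.INa + c.IbNa + 3.0 * c.INaK + 3.0 * c.INaCa) *
                   CAPACITANCE / (Vc * Fmmol));
  s[iKi] += dt * (-(istim + c.IK1 + c.Ito + c.IKr + c.IKs - 2.0 * c.INaK +
                    c.IpK) * CAPACITANCE / (Vc * Fmmol));
  s[iV] += dt * (-(c.Iion() + istim));
  updateGates(s, dt, ct);
}

static CharacterVector stateNames() {
  return CharacterVector::create(
    "V", "m", "h", "j", "d", "f", "f2", "fcass", "r", "s", "xr1", "xr2",
    "xs", "Nai", "Ki", "Cai", "CaSR", "CaSS", "Rbar");
}

static int firstNonFinite(const double* s) {
  for (int k = 0; k < NSTATE; ++k)
    if (!std::isfinite(s[k])) return k;
  return -1;
}

// [[Rcpp::export(name = ".tp06_initial_state")]]
NumericVector tp06InitialState() {
  NumericVector s(NSTATE);
  s[iV] = -86.2; s[iM] = 0.0; s[iH] = 0.75; s[iJ] = 0.75;
  s[iD] = 0.0; s[iF] = 1.0; s[iF2] = 1.0; s[iFCaSS] = 1.0;
  s[iR] = 0.0; s[iS] = 1.0; s[iXr1] = 0.0; s[iXr2] = 1.0; s[iXs] = 0.0;
  s[iNai] = 7.67; s[iKi] = 138.3;
  s[iCai] = 0.00007; s[iCaSR] = 1.3; s[iCaSS] = 0.00007; s[iRbar] = 1.0;
  s.attr("names") = stateNames();
  return s;
}

// [[Rcpp::export(name = ".tp06_currents")]]
NumericVector tp06Currents(NumericVector state, NumericVector scaling,
                           int cell_type) {
  if (state.size() != NSTATE) stop("state must have %d entries", NSTATE);
  if (scaling.size() != NCHAN) stop("scaling must have %d entries", NCHAN);
  CellType ct = cellTypeParams(cell_type);
  Currents c = computeCurrents(REAL(state), REAL(scaling), ct);
  NumericVector out = NumericVector::create(
    _["INa"] = c.INa, _["ICaL"] = c.ICaL, _["Ito"] = c.Ito,
    _["IKr"] = c.IKr, _["IKs"] = c.IKs, _["IK1"] = c.IK1,
    _["IpK"] = c.IpK, _["IpCa"] = c.IpCa, _["IbNa"] = c.IbNa,
    _["IbCa"] = c.IbCa, _["INaCa"] = c.INaCa, _["INaK"] = c.INaK);
  return out;
}

// [[Rcpp::export(name = ".tp06_step")]]
NumericVector tp06Step(NumericVector state, NumericVector scaling,
                       double dt, double istim, int cell_type, int n_steps) {
  if (state.size() != NSTATE) stop("state must have %d entries", NSTATE);
  if (scaling.size() != NCHAN) stop("scaling must have %d entries", NCHAN);
  CellType ct = cellTypeParams(cell_type);
  NumericVector out = clone(state);
  double* s = REAL(out);
  for (int i = 0; i < n_steps; ++i) {
    stepOnce(s, REAL(scaling), ct, dt, istim);
    int bad = firstNonFinite(s);
    if (bad >= 0)
      stop("divergence: state variable '%s' became non-finite",
           as<std::string>(stateNames()[bad]).c_str());
  }
  out.attr("names") = stateNames();
  return out;
}

// Paced run; returns the final beat's V(t) and Cai(t) sampled at out_dt.
// [[Rcpp::export(name = ".tp06_run_paced")]]
List tp06RunPaced(NumericVector scaling, double bcl, int n_beats,
                  double dt, double out_dt, double stim_amp,
                  double stim_dur, int cell_type,
                  Nullable<NumericVector> init = R_NilValue) {
  if (scaling.size() != NCHAN) stop("scaling must have %d entries", NCHAN);
  CellType ct = cellTypeParams(cell_type);
  NumericVector s0 = init.isNull() ? tp06InitialState() :
    NumericVector(init.get());
  if (s0.size() != NSTATE) stop("init state must have %d entries", NSTATE);
  std::vector<double> s(REAL(s0), REAL(s0) + NSTATE);

  const long steps_per_beat = (long)std::lround(bcl / dt);
  const long stim_steps = (long)std::lround(stim_dur / dt);
  const long stride = (long)std::lround(out_dt / dt);
  const long n_out = (long)std::lround(bcl / out_dt);

  NumericVector tout(n_out), vout(n_out), caiout(n_out);
  bool diverged = false;
  int div_beat = -1;
  std::string div_var = "";

  for (int beat = 0; beat < n_beats && !diverged; ++beat) {
    const bool last = (beat == n_beats - 1);
    for (long k = 0; k < steps_per_beat; ++k) {
      if (last && (k % stride == 0)) {
        long idx = k / stride;
        tout[idx] = k * dt;
        vout[idx] = s[iV];
        caiout[idx] = s[iCai];
      }
      double istim = (k < stim_steps) ? stim_amp : 0.0;
      stepOnce(s.data(), scaling.begin(), ct, dt, istim);
      int bad = firstNonFinite(s.data());
      if (bad >= 0) {
        diverged = true;
        div_beat = beat + 1;
        div_var = as<std::string>(stateNames()[bad]);
        break;
      }
    }
  }

  NumericVector sf(s.begin(), s.end());
  sf.attr("names") = stateNames();
  return List::create(
    _["time"] = tout, _["V"] = vout, _["Cai"] = caiout,
    _["dt"] = out_dt, _["bcl"] = bcl, _["stim_onset"] = 0.0,
    _["final_state"] = sf, _["diverged"] = diverged,
    _["diverged_beat"] = div_beat, _["diverged_var"] = div_var);
}
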