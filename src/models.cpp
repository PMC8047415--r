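// Ionic membrane kinetics: Courtemanche et al. 1998 human atrial model and a
// fast 3-variable phenomenological model used for cheap tissue-level tests.
//
// State layouts (doubles):
//   courtemanche (21): V m h j oa oi ua ui xr xs d f fca u v w Nai Ki Cai Caup Carel
//   fast_test     (3): V v w            (u = (V + 85) / 100 internally)
//
// Conductance-scale vector (order shared with R side):
//   0 gNa, 1 gK1, 2 gto, 3 gKur, 4 gKr, 5 gKs, 6 gCaL, 7 gNaCa, 8 gNaK
//
// Gates advance with Rush-Larsen; V and concentrations with forward Euler.
// Stimulus amplitude is interpreted as dV/dt in mV/ms (equivalently pA/pF for
// a 1 uF/cm^2 membrane, so 30 uA/cm^2 -> 30).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const int CRN_NSTATE = 21;
static const int FK_NSTATE = 3;

// physical constants, Courtemanche 1998
static const double CRN_R = 8.3143;
static const double CRN_T = 310.0;
static const double CRN_F = 96.4867;
static const double CRN_Cm = 100.0;        // pF
static const double CRN_Vi = 13668.0;      // um^3
static const double CRN_Vup = 1109.52;
static const double CRN_Vrel = 96.48;
static const double CRN_Ko = 5.4;          // mM
static const double CRN_Nao = 140.0;
static const double CRN_Cao = 1.8;
static const double CRN_KQ10 = 3.0;

static inline double rl(double x, double xinf, double tau, double dt) {
  return xinf + (x - xinf) * std::exp(-dt / tau);
}

void crn_rest_state(double* s) {
  s[0] = -81.18;   s[1] = 2.908e-3; s[2] = 9.649e-1; s[3] = 9.775e-1;
  s[4] = 3.043e-2; s[5] = 9.992e-1; s[6] = 4.966e-3; s[7] = 9.986e-1;
  s[8] = 3.296e-5; s[9] = 1.869e-2; s[10] = 1.367e-4; s[11] = 9.996e-1;
  s[12] = 7.755e-1; s[13] = 0.0;    s[14] = 1.0;     s[15] = 9.992e-1;
  s[16] = 11.17;   s[17] = 139.0;   s[18] = 1.013e-4; s[19] = 1.488;
  s[20] = 1.488;
}

void crn_step(double* s, double istim, double dt, const double* sc) {
  const double V = s[0];
  const double FoRT = CRN_F / (CRN_R * CRN_T);

  const double ENa = (1.0 / FoRT) * std::log(CRN_Nao / s[16]);
  const double EK  = (1.0 / FoRT) * std::log(CRN_Ko / s[17]);
  const double ECa = (0.5 / FoRT) * std::log(CRN_Cao / s[18]);

  // currents (pA/pF)
  const double INa = sc[0] * 7.8 * s[1] * s[1] * s[1] * s[2] * s[3] * (V - ENa);
  const double IK1 = sc[1] * 0.09 * (V - EK) / (1.0 + std::exp(0.07 * (V + 80.0)));
  const double Ito = sc[2] * 0.1652 * s[4] * s[4] * s[4] * s[5] * (V - EK);
  const double gKur = 0.005 + 0.05 / (1.0 + std::exp(-(V - 15.0) / 13.0));
  const double IKur = sc[3] * gKur * s[6] * s[6] * s[6] * s[7] * (V - EK);
  const double IKr = sc[4] * 0.029411765 * s[8] * (V - EK) /
    (1.0 + std::exp((V + 15.0) / 22.4));
  const double IKs = sc[5] * 0.12941176 * s[9] * s[9] * (V - EK);
  const double ICaL = sc[6] * 0.12375 * s[10] * s[11] * s[12] * (V - 65.0);

  const double sigma_nak = (std::exp(CRN_Nao / 67.3) - 1.0) / 7.0;
  const double fNaK = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * V * FoRT) +
                             0.0365 * sigma_nak * std::exp(-V * FoRT));
  const double INaK = sc[8] * 0.59933874 * fNaK /
    (1.0 + std::pow(10.0 / s[16], 1.5)) * (CRN_Ko / (CRN_Ko + 1.5));

  const double eg = std::exp(0.35 * V * FoRT);
  const double egm = std::exp((0.35 - 1.0) * V * FoRT);
  const double INaCa = sc[7] * 1600.0 *
    (eg * s[16] * s[16] * s[16] * CRN_Cao -
     egm * CRN_Nao * CRN_Nao * CRN_Nao * s[18]) /
    ((87.5 * 87.5 * 87.5 + CRN_Nao * CRN_Nao * CRN_Nao) * (1.38 + CRN_Cao) *
     (1.0 + 0.1 * egm));

  const double IbNa = 0.0006744375 * (V - ENa);
  const double IbCa = 0.001131 * (V - ECa);
  const double IpCa = 0.275 * s[18] / (0.0005 + s[18]);

  // SR fluxes (mM/ms)
  const double Irel = 30.0 * s[13] * s[13] * s[14] * s[15] * (s[20] - s[18]);
  const double Itr = (s[19] - s[20]) / 180.0;
  const double Iup = 0.005 / (1.0 + 0.00092 / s[18]);
  const double Iupleak = 0.005 * s[19] / 15.0;

  // --- gate rates ---
  double a, b, xinf, tau;

  // m
  if (std::fabs(V + 47.13) < 1e-10) a = 3.2;
  else a = 0.32 * (V + 47.13) / (1.0 - std::exp(-0.1 * (V + 47.13)));
  b = 0.08 * std::exp(-V / 11.0);
  s[1] = rl(s[1], a / (a + b), 1.0 / (a + b), dt);

  // h, j
  if (V >= -40.0) {
    a = 0.0;
    b = 1.0 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
  } else {
    a = 0.135 * std::exp(-(V + 80.0) / 6.8);
    b = 3.56 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.35 * V);
  }
  s[2] = rl(s[2], a / (a + b), 1.0 / (a + b), dt);
  if (V >= -40.0) {
    a = 0.0;
    b = 0.3 * std::exp(-2.535e-7 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
  } else {
    a = (-1.2714e5 * std::exp(0.2444 * V) - 3.474e-5 * std::exp(-0.04391 * V)) *
        (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
    b = 0.1212 * std::exp(-0.01052 * V) / (1.0 + std::exp(-0.1378 * (V + 40.14)));
  }
  s[3] = rl(s[3], a / (a + b), 1.0 / (a + b), dt);

  // oa, oi
  a = 0.65 / (std::exp(-(V + 10.0) / 8.5) + std::exp(-(V - 30.0) / 59.0));
  b = 0.65 / (2.5 + std::exp((V + 82.0) / 17.0));
  tau = 1.0 / ((a + b) * CRN_KQ10);
  xinf = 1.0 / (1.0 + std::exp(-(V + 20.47) / 17.54));
  s[4] = rl(s[4], xinf, tau, dt);
  a = 1.0 / (18.53 + std::exp((V + 113.7) / 10.95));
  b = 1.0 / (35.56 + std::exp(-(V + 1.26) / 7.44));
  tau = 1.0 / ((a + b) * CRN_KQ10);
  xinf = 1.0 / (1.0 + std::exp((V + 43.1) / 5.3));
  s[5] = rl(s[5], xinf, tau, dt);

  // ua, ui
  a = 0.65 / (std::exp(-(V + 10.0) / 8.5) + std::exp(-(V - 30.0) / 59.0));
  b = 0.65 / (2.5 + std::exp((V + 82.0) / 17.0));
  tau = 1.0 / ((a + b) * CRN_KQ10);
  xinf = 1.0 / (1.0 + std::exp(-(V + 30.3) / 9.6));
  s[6] = rl(s[6], xinf, tau, dt);
  a = 1.0 / (21.0 + std::exp(-(V - 185.0) / 28.0));
  b = std::exp((V - 158.0) / 16.0);
  tau = 1.0 / ((a + b) * CRN_KQ10);
  xinf = 1.0 / (1.0 + std::exp((V - 99.45) / 27.48));
  s[7] = rl(s[7], xinf, tau, dt);

  // xr
  if (std::fabs(V + 14.1) < 1e-10) a = 0.0015;
  else a = 0.0003 * (V + 14.1) / (1.0 - std::exp(-(V + 14.1) / 5.0));
  if (std::fabs(V - 3.3328) < 1e-10) b = 3.7862e-4;
  else b = 7.3898e-5 * (V - 3.3328) / (std::exp((V - 3.3328) / 5.1237) - 1.0);
  tau = 1.0 / (a + b);
  xinf = 1.0 / (1.0 + std::exp(-(V + 14.1) / 6.5));
  s[8] = rl(s[8], xinf, tau, dt);

  // xs
  if (std::fabs(V - 19.9) < 1e-10) a = 6.8e-4;
  else a = 4e-5 * (V - 19.9) / (1.0 - std::exp(-(V - 19.9) / 17.0));
  if (std::fabs(V - 19.9) < 1e-10) b = 3.15e-4;
  else b = 3.5e-5 * (V - 19.9) / (std::exp((V - 19.9) / 9.0) - 1.0);
  tau = 0.5 / (a + b);
  xinf = 1.0 / std::sqrt(1.0 + std::exp(-(V - 19.9) / 12.7));
  s[9] = rl(s[9], xinf, tau, dt);

  // d
  if (std::fabs(V + 10.0) < 1e-10) tau = 4.579 / (1.0 + std::exp(-(V + 10.0) / 6.24));
  else tau = (1.0 - std::exp(-(V + 10.0) / 6.24)) /
             (0.035 * (V + 10.0) * (1.0 + std::exp(-(V + 10.0) / 6.24)));
  xinf = 1.0 / (1.0 + std::exp(-(V + 10.0) / 8.0));
  s[10] = rl(s[10], xinf, tau, dt);

  // f
  tau = 9.0 / (0.0197 * std::exp(-0.0337 * 0.0337 * (V + 10.0) * (V + 10.0)) + 0.02);
  xinf = 1.0 / (1.0 + std::exp((V + 28.0) / 6.9));
  s[11] = rl(s[11], xinf, tau, dt);

  // fca
  s[12] = rl(s[12], 1.0 / (1.0 + s[18] / 0.00035), 2.0, dt);

  // SR release gates driven by Fn
  const double Fn = 1e-12 * CRN_Vrel * Irel -
    (5e-13 / CRN_F) * (0.5 * ICaL * CRN_Cm - 0.2 * INaCa * CRN_Cm);
  xinf = 1.0 / (1.0 + std::exp(-(Fn - 3.4175e-13) / 13.67e-16));
  s[13] = rl(s[13], xinf, 8.0, dt);
  tau = 1.91 + 2.09 / (1.0 + std::exp(-(Fn - 3.4175e-13) / 13.67e-16));
  xinf = 1.0 - 1.0 / (1.0 + std::exp(-(Fn - 6.835e-14) / 13.67e-16));
  s[14] = rl(s[14], xinf, tau, dt);
  if (std::fabs(V - 7.9) < 1e-10) tau = 6.0 * 0.2 / 1.3;
  else tau = 6.0 * (1.0 - std::exp(-(V - 7.9) / 5.0)) /
             ((1.0 + 0.3 * std::exp(-(V - 7.9) / 5.0)) * (V - 7.9));
  xinf = 1.0 - 1.0 / (1.0 + std::exp(-(V - 40.0) / 17.0));
  s[15] = rl(s[15], xinf, tau, dt);

  // --- concentrations (forward Euler) ---
  const double FVi = CRN_F * CRN_Vi;
  s[16] += dt * (-3.0 * INaK - 3.0 * INaCa - IbNa - INa) * CRN_Cm / FVi;
  s[17] += dt * (2.0 * INaK - IK1 - Ito - IKur - IKr - IKs) * CRN_Cm / FVi;

  const double B1 =
    (2.0 * INaCa - IpCa - ICaL - IbCa) * CRN_Cm / (2.0 * FVi) +
    (CRN_Vup * (Iupleak - Iup) + Irel * CRN_Vrel) / CRN_Vi;
  const double B2 = 1.0 +
    0.07 * 0.0005 / ((s[18] + 0.0005) * (s[18] + 0.0005)) +
    0.05 * 0.00238 / ((s[18] + 0.00238) * (s[18] + 0.00238));
  s[18] += dt * B1 / B2;
  s[19] += dt * (Iup - Iupleak - Itr * CRN_Vrel / CRN_Vup);
  s[20] += dt * (Itr - Irel) /
    (1.0 + 10.0 * 0.8 / ((s[20] + 0.8) * (s[20] + 0.8)));

  const double Iion = INa + IK1 + Ito + IKur + IKr + IKs + ICaL + IpCa +
    INaK + INaCa + IbNa + IbCa;
  s[0] += dt * (-Iion + istim);
}

// Fenton-Karma-type 3-variable model. Parameter vector fkp (13):
// 0 tau_d, 1 tau_r, 2 tau_si, 3 tau_o, 4 tau_vp, 5 tau_v1m, 6 tau_v2m,
// 7 tau_wp, 8 tau_wm, 9 u_c, 10 u_v, 11 u_csi, 12 k
// Conductance-scale mapping (documented): gNa -> 1/tau_d, gCaL -> 1/tau_si,
// gK1 -> 1/tau_o and 1/tau_r.
void fk_rest_state(double* s) { s[0] = -85.0; s[1] = 1.0; s[2] = 1.0; }

void fk_step(double* s, double istim, double dt, const double* sc,
             const double* fkp) {
  const double u = (s[0] + 85.0) / 100.0;
  const double v = s[1], w = s[2];
  const int p = (u >= fkp[9]) ? 1 : 0;
  const int q = (u >= fkp[10]) ? 1 : 0;

  const double Jfi = p ? (-v * (1.0 - u) * (u - fkp[9]) / fkp[0] * sc[0]) : 0.0;
  const double Jso = (p ? (1.0 / fkp[1]) : (u / fkp[3])) * sc[1];
  const double Jsi = -w * (1.0 + std::tanh(fkp[12] * (u - fkp[11]))) /
    (2.0 * fkp[2]) * sc[6];

  const double tau_vm = q ? fkp[5] : fkp[6];
  const double dv = p ? (-v / fkp[4]) : ((1.0 - v) / tau_vm);
  const double dw = p ? (-w / fkp[7]) : ((1.0 - w) / fkp[8]);

  s[0] += dt * (-(Jfi + Jso + Jsi) * 100.0 + istim);
  s[1] += dt * dv;
  s[2] += dt * dw;
  if (s[1] < 0.0) s[1] = 0.0; else if (s[1] > 1.0) s[1] = 1.0;
  if (s[2] < 0.0) s[2] = 0.0; else if (s[2] > 1.0) s[2] = 1.0;
}

int model_nstate(int model_id) {
  return model_id == 0 ? CRN_NSTATE : FK_NSTATE;
}

// [[Rcpp::export(name = ".rest_state_cpp")]]
NumericVector rest_state_cpp(int model_id) {
  NumericVector out(model_nstate(model_id));
  if (model_id == 0) crn_rest_state(out.begin());
  else fk_rest_state(out.begin());
  return out;
}

// Single-cell integration with a periodic-or-listed stimulus schedule.
// stim_onsets: vector of stimulus onset times (ms). Records Vm every
// record_dt; optionally records full states from time record_states_from.
// [[Rcpp::export(name = ".cell_run_cpp")]]
List cell_run_cpp(int model_id, NumericVector sc, NumericVector fkp,
                  NumericVector state0, double t_end, double dt,
                  NumericVector stim_onsets, double stim_dur,
                  double stim_amp, double record_dt,
                  double record_states_from) {
  const int ns = model_nstate(model_id);
  if (state0.size() != ns) stop("state vector has wrong length");
  std::vector<double> s(state0.begin(), state0.end());

  const long nstep = (long)std::llround(t_end / dt);
  const long rec_every = std::max(1L, (long)std::llround(record_dt / dt));
  const long nrec = nstep / rec_every + 1;
  NumericVector time(nrec), vm(nrec);

  const bool rec_states = R_finite(record_states_from) &&
    record_states_from <= t_end;
  long srec_start = rec_states ?
    (long)std::llround(record_states_from / dt) : nstep + 1;
  long nsrec = rec_states ? ((nstep - srec_start) / rec_every + 1) : 0;
  NumericMatrix states(rec_states ? ns : 0, std::max(nsrec, 0L));
  NumericVector stimes(std::max(nsrec, 0L));

  std::vector<double> onsets(stim_onsets.begin(), stim_onsets.end());
  std::sort(onsets.begin(), onsets.end());
  size_t next_on = 0;
  double stim_until = -1.0;

  long ri = 0, sri = 0;
  time[0] = 0.0; vm[0] = s[0];
  if (rec_states && srec_start == 0) {
    for (int k = 0; k < ns; ++k) states(k, 0) = s[k];
    stimes[0] = 0.0; sri = 1;
  }

  for (long i = 0; i < nstep; ++i) {
    const double t = i * dt;
    while (next_on < onsets.size() && t >= onsets[next_on] - 0.5 * dt) {
      stim_until = onsets[next_on] + stim_dur;
      ++next_on;
    }
    const double istim = (t < stim_until) ? stim_amp : 0.0;
    if (model_id == 0) crn_step(s.data(), istim, dt, sc.begin());
    else fk_step(s.data(), istim, dt, sc.begin(), fkp.begin());
    if (!R_finite(s[0]))
      stop("integration failure (NaN) at t = %f ms", t + dt);

    if ((i + 1) % rec_every == 0) {
      ++ri;
      time[ri] = (i + 1) * dt;
      vm[ri] = s[0];
      if (rec_states && (i + 1) >= srec_start && sri < nsrec) {
        for (int k = 0; k < ns; ++k) states(k, sri) = s[k];
        stimes[sri] = (i + 1) * dt;
        ++sri;
      }
    }
  }

  return List::create(_["time"] = time, _["vm"] = vm,
                      _["final"] = NumericVector(s.begin(), s.end()),
                      _["states"] = states, _["state_times"] = stimes,
                      _["n_state_rec"] = (double)sri);
}
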