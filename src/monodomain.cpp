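// Explicit operator-split monodomain stepper on a regular node grid.
// Diffusion: 5-point (3-point in 1D) stencil with per-face diffusivities
// (mm^2/ms), no-flux boundaries. Reaction: ionic step per node, with an
// integer group per node selecting control vs remodeled conductance scales.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

void crn_step(double* s, double istim, double dt, const double* sc);
void fk_step(double* s, double istim, double dt, const double* sc,
             const double* fkp);
int model_nstate(int model_id);

// [[Rcpp::export(name = ".monodomain_run_cpp")]]
List monodomain_run_cpp(int model_id, NumericVector sc_ctrl,
                        NumericVector sc_remod, NumericVector fkp,
                        IntegerVector group, NumericMatrix state0,
                        int nx, int ny, NumericVector dfx, NumericVector dfy,
                        double h, double dt, double t_end, double dt_out,
                        NumericVector stim_onset, NumericVector stim_dur,
                        NumericVector stim_amp, List stim_nodes,
                        double act_threshold, double t0) {
  const int ns = model_nstate(model_id);
  const int nn = nx * ny;
  if (state0.nrow() != ns || state0.ncol() != nn)
    stop("state matrix must be %d x %d", ns, nn);
  if ((int)dfx.size() != (nx - 1) * ny) stop("dfx has wrong length");
  if (ny > 1 && (int)dfy.size() != nx * (ny - 1)) stop("dfy has wrong length");

  NumericMatrix S = clone(state0);
  double* Sp = S.begin();

  const long nstep = (long)std::llround(t_end / dt);
  const long out_every = std::max(1L, (long)std::llround(dt_out / dt));
  const long nframes = nstep / out_every + 1;

  NumericMatrix frames(nframes, nn);
  NumericVector ftimes(nframes);
  NumericVector act(nn, NA_REAL);

  std::vector<double> lap(nn), vold(nn), istim(nn, 0.0);
  const double inv_h2 = 1.0 / (h * h);
  const int nstim = stim_onset.size();
  std::vector<std::vector<int> > snodes(nstim);
  for (int k = 0; k < nstim; ++k) {
    IntegerVector iv = stim_nodes[k];
    snodes[k].assign(iv.begin(), iv.end());  // 0-based
  }

  // frame 0
  for (int n = 0; n < nn; ++n) frames(0, n) = Sp[(size_t)n * ns];
  ftimes[0] = t0;

  long fi = 0;
  for (long step = 0; step < nstep; ++step) {
    const double t = step * dt;

    // stimulus accumulation (amplitudes are dV/dt in mV/ms)
    std::vector<int> touched;
    for (int k = 0; k < nstim; ++k) {
      if (t >= stim_onset[k] - 0.5 * dt && t < stim_onset[k] + stim_dur[k]) {
        for (size_t m = 0; m < snodes[k].size(); ++m) {
          istim[snodes[k][m]] += stim_amp[k];
          touched.push_back(snodes[k][m]);
        }
      }
    }

    // diffusion on V (state row 0)
    for (int n = 0; n < nn; ++n) vold[n] = Sp[(size_t)n * ns];
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        const int n = j * nx + i;
        double acc = 0.0;
        const double v = vold[n];
        if (i > 0)      acc += dfx[j * (nx - 1) + i - 1] * (vold[n - 1] - v);
        if (i < nx - 1) acc += dfx[j * (nx - 1) + i] * (vold[n + 1] - v);
        if (j > 0)      acc += dfy[(j - 1) * nx + i] * (vold[n - nx] - v);
        if (j < ny - 1) acc += dfy[j * nx + i] * (vold[n + nx] - v);
        lap[n] = acc * inv_h2;
      }
    }

    // reaction + explicit diffusion update
    for (int n = 0; n < nn; ++n) {
      double* s = Sp + (size_t)n * ns;
      s[0] += dt * lap[n];
      const double* sc = (group[n] == 1) ? sc_remod.begin() : sc_ctrl.begin();
      if (model_id == 0) crn_step(s, istim[n], dt, sc);
      else fk_step(s, istim[n], dt, sc, fkp.begin());
      if (!R_finite(s[0]) || std::fabs(s[0]) > 200.0)
        stop("monodomain instability at t = %.3f ms (node %d, Vm = %g); "
             "check the time-step stability bound", t0 + t + dt, n + 1, s[0]);
      if (ISNA(act[n]) && vold[n] < act_threshold && s[0] >= act_threshold)
        act[n] = t0 + t + dt;
    }

    for (size_t m = 0; m < touched.size(); ++m) istim[touched[m]] = 0.0;

    if ((step + 1) % out_every == 0) {
      ++fi;
      for (int n = 0; n < nn; ++n) frames(fi, n) = Sp[(size_t)n * ns];
      ftimes[fi] = t0 + (step + 1) * dt;
    }
  }

  return List::create(_["frames"] = frames, _["times"] = ftimes,
                      _["activation"] = act, _["final_state"] = S);
}
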