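#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Parameter-matrix column layout shared with R/neuron.R (par_matrix()).
enum ParCol {
  P_CM = 0, P_GL, P_EL, P_DT, P_VT, P_VTH, P_VR, P_TR,
  P_A, P_B, P_TAUW, P_EEXP, P_EADAPT, P_ELEAK, P_ETHR,
  P_IEXPMAX, P_PLATEAU, P_VPLAT, P_TPLAT, P_NCOL
};

// Multi-compartment AdEx integrator.
//
// Exponential Euler on the leak term, explicit exponential / adaptation /
// axial / synaptic terms.  Threshold crossings are located by linear
// interpolation inside the step; ordinary spikes reset to V_r, increment w
// by b and clamp the membrane to V_r for t_r; plateau compartments clamp to
// V_plateau for t_plateau without touching w.
//
// par:    n_comp x P_NCOL parameter matrix (hardware-domain SI units)
// g_ic:   n_comp x n_comp symmetric axial conductance matrix (S)
// stim:   n_comp x 3 step-current stimulus (I0, t_on, t_off)
// ev_*:   synaptic injection events: at ev_time, compartment ev_comp's
//         synaptic current jumps by ev_amp (A); decays with tau_syn
// [[Rcpp::export(name = ".adex_mc_run")]]
List adex_mc_run(NumericMatrix par, NumericMatrix g_ic, NumericMatrix stim,
                 NumericVector ev_time, IntegerVector ev_comp,
                 NumericVector ev_amp, double tau_syn,
                 double dt, double T, NumericVector v0, NumericVector w0,
                 bool record_traces) {
  const int nc = par.nrow();
  const int nsteps = (int)std::ceil(T / dt - 1e-9);
  const double dec_syn = std::exp(-dt / tau_syn);

  std::vector<double> V(nc), W(nc), Isyn(nc, 0.0);
  std::vector<double> ref_until(nc, -1.0), plat_until(nc, -1.0);
  for (int i = 0; i < nc; ++i) { V[i] = v0[i]; W[i] = w0[i]; }

  NumericMatrix traceV, traceW;
  NumericVector times;
  if (record_traces) {
    traceV = NumericMatrix(nsteps + 1, nc);
    traceW = NumericMatrix(nsteps + 1, nc);
    times = NumericVector(nsteps + 1);
    for (int i = 0; i < nc; ++i) { traceV(0, i) = V[i]; traceW(0, i) = W[i]; }
  }

  std::vector<double> spike_t;
  std::vector<int> spike_id;
  int ev_idx = 0;
  const int nev = ev_time.size();

  std::vector<double> Vold(nc);

  for (int n = 0; n < nsteps; ++n) {
    const double t = n * dt;
    // synaptic events scheduled inside [t, t+dt) land at the step start
    while (ev_idx < nev && ev_time[ev_idx] < t + dt) {
      Isyn[ev_comp[ev_idx]] += ev_amp[ev_idx];
      ++ev_idx;
    }
    for (int i = 0; i < nc; ++i) Vold[i] = V[i];

    for (int i = 0; i < nc; ++i) {
      const double Cm = par(i, P_CM), gl = par(i, P_GL), El = par(i, P_EL);
      const double tr = par(i, P_TR);
      const bool clamped_ref = t < ref_until[i];
      const bool clamped_plat = t < plat_until[i];

      // total explicit current: synaptic + stimulus + axial coupling;
      // the step midpoint decides window membership (robust to boundary
      // rounding, exact charge for grid-aligned windows)
      double I = Isyn[i];
      const double tm = t + 0.5 * dt;
      if (tm >= stim(i, 1) && tm < stim(i, 2)) I += stim(i, 0);
      for (int j = 0; j < nc; ++j)
        if (g_ic(i, j) > 0.0) I += g_ic(i, j) * (Vold[j] - Vold[i]);

      double Iexp = 0.0;
      if (par(i, P_EEXP) != 0.0 && !clamped_ref && !clamped_plat) {
        const double DT = par(i, P_DT);
        Iexp = gl * DT * std::exp((Vold[i] - par(i, P_VT)) / DT);
        if (Iexp > par(i, P_IEXPMAX)) Iexp = par(i, P_IEXPMAX);
      }

      // adaptation: exponential Euler toward a * (V - E_l)
      if (par(i, P_EADAPT) != 0.0) {
        const double tw = par(i, P_TAUW);
        const double winf = par(i, P_A) * (Vold[i] - El);
        W[i] = winf + (W[i] - winf) * std::exp(-dt / tw);
      }

      double Vnew;
      if (clamped_ref) {
        Vnew = par(i, P_VR);
      } else if (clamped_plat) {
        Vnew = par(i, P_VPLAT);
      } else if (par(i, P_ELEAK) != 0.0) {
        const double tau_m = Cm / gl;
        const double Veff = El + (Iexp - W[i] + I) / gl;
        Vnew = Veff + (Vold[i] - Veff) * std::exp(-dt / tau_m);
      } else {
        Vnew = Vold[i] + dt * (Iexp - W[i] + I) / Cm;
      }

      if (!std::isfinite(Vnew))
        stop("membrane potential overflowed (compartment %d, t = %g s); "
             "offending terms: I_exp = %g A, w = %g A, I = %g A",
             i + 1, t, Iexp, W[i], I);

      // threshold crossing with linear interpolation of the crossing time
      if (par(i, P_ETHR) != 0.0 && !clamped_ref && !clamped_plat &&
          Vnew >= par(i, P_VTH) && Vold[i] < par(i, P_VTH)) {
        const double frac = (par(i, P_VTH) - Vold[i]) / (Vnew - Vold[i]);
        const double tsp = t + frac * dt;
        spike_t.push_back(tsp);
        spike_id.push_back(i + 1);
        if (par(i, P_PLATEAU) != 0.0) {
          plat_until[i] = tsp + par(i, P_TPLAT);
          Vnew = par(i, P_VPLAT);
        } else {
          if (par(i, P_EADAPT) != 0.0) W[i] += par(i, P_B);
          ref_until[i] = tsp + tr;
          Vnew = par(i, P_VR);
        }
      } else if (par(i, P_ETHR) != 0.0 && Vnew >= par(i, P_VTH) &&
                 !clamped_ref && !clamped_plat && Vold[i] >= par(i, P_VTH)) {
        // started the step above threshold (e.g. released from plateau)
        spike_t.push_back(t);
        spike_id.push_back(i + 1);
        if (par(i, P_PLATEAU) != 0.0) {
          plat_until[i] = t + par(i, P_TPLAT);
          Vnew = par(i, P_VPLAT);
        } else {
          if (par(i, P_EADAPT) != 0.0) W[i] += par(i, P_B);
          ref_until[i] = t + tr;
          Vnew = par(i, P_VR);
        }
      }
      V[i] = Vnew;
    }

    for (int i = 0; i < nc; ++i) Isyn[i] *= dec_syn;

    if (record_traces) {
      times[n + 1] = (n + 1) * dt;
      for (int i = 0; i < nc; ++i) {
        traceV(n + 1, i) = V[i];
        traceW(n + 1, i) = W[i];
      }
    }
  }

  List out = List::create(
      _["spike_time"] = wrap(spike_t), _["spike_comp"] = wrap(spike_id),
      _["V_final"] = wrap(V), _["w_final"] = wrap(W));
  if (record_traces) {
    out["time"] = times;
    out["V"] = traceV;
    out["w"] = traceW;
  }
  return out;
}

// Current-based LIF network simulator for the reservoir experiments.
//
// State per neuron: membrane v (dimensionless, leak at 0, threshold vth),
// excitatory and inhibitory synaptic currents with shared tau_s.  Recurrent
// weights W (n x n, signed, column j = presynaptic); external events
// (ext_time sorted, ext_src 0-based) each deposit the corresponding column
// of Wext scaled by 1 onto their targets.
// Returns spikes, final state, and per-neuron spike counts.
// [[Rcpp::export(name = ".lif_net_run")]]
List lif_net_run(NumericMatrix W, NumericMatrix Wext,
                 NumericVector ext_time, IntegerVector ext_src,
                 double tau_m, double tau_s, double vth, double vreset,
                 double t_ref, double dt, double T,
                 NumericVector v0, NumericVector i0) {
  const int n = W.nrow();
  const int nsteps = (int)std::ceil(T / dt - 1e-9);
  const double dec_s = std::exp(-dt / tau_s);
  const double dec_m = std::exp(-dt / tau_m);

  std::vector<double> v(n), isyn(n), ref(n, -1.0);
  for (int i = 0; i < n; ++i) { v[i] = v0[i]; isyn[i] = i0[i]; }

  std::vector<double> spike_t;
  std::vector<int> spike_id;
  std::vector<int> counts(n, 0);
  int ei = 0;
  const int nev = ext_time.size();

  for (int s = 0; s < nsteps; ++s) {
    const double t = s * dt;
    while (ei < nev && ext_time[ei] < t + dt) {
      const int src = ext_src[ei];
      for (int i = 0; i < n; ++i)
        if (Wext(i, src) != 0.0) isyn[i] += Wext(i, src);
      ++ei;
    }
    // membrane update (exponential Euler, current explicit)
    for (int i = 0; i < n; ++i) {
      if (t < ref[i]) { v[i] = vreset; continue; }
      v[i] = v[i] * dec_m + isyn[i] * (1.0 - dec_m);
    }
    // threshold, reset, recurrent delivery at step resolution
    for (int i = 0; i < n; ++i) {
      if (v[i] >= vth && t >= ref[i]) {
        spike_t.push_back(t + dt);
        spike_id.push_back(i + 1);
        ++counts[i];
        v[i] = vreset;
        ref[i] = t + dt + t_ref;
        for (int k = 0; k < n; ++k)
          if (W(k, i) != 0.0) isyn[k] += W(k, i);
      }
    }
    for (int i = 0; i < n; ++i) isyn[i] *= dec_s;
  }

  return List::create(_["spike_time"] = wrap(spike_t),
                      _["spike_id"] = wrap(spike_id),
                      _["counts"] = wrap(counts),
                      _["v_final"] = wrap(v), _["i_final"] = wrap(isyn));
}
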