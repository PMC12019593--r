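#include <Rcpp.h>
using namespace Rcpp;

// one RK4 step of tau * dv/dt = I/gl - (v - E), input held constant
static inline double rk4_step(double v, double I, double gl, double E,
                              double tau) {
  const double a = I / gl + E;  // dv/dt = (a - v) / tau
  double k1 = (a - v) / tau;
  double k2 = (a - (v + 0.5 * k1)) / tau;
  double k3 = (a - (v + 0.5 * k2)) / tau;
  double k4 = (a - (v + k3)) / tau;
  return v + (k1 + 2 * k2 + 2 * k3 + k4) / 6.0;
}

// Present one sample to the MC/GC network for n_cycles gamma cycles.
// mc_drive: constant per-MC current (weight * ET activation), gamma: one
// period of the sinusoid, conn/w: MC x GC mask and plastic weights.
// MC spikes deliver additive current transients of initial magnitude w to
// connected GCs `delay` steps later, decaying with time constant tau_syn;
// STDP (on synaptic arrival times) is applied at each cycle end when
// learning is on.
// [[Rcpp::export]]
List present_sample_cpp(NumericVector mc_drive, IntegerMatrix conn,
                        NumericMatrix w, int n_cycles, bool learning,
                        List mc_par, List gc_par, NumericVector gamma,
                        int delay, double tau_syn, List stdp,
                        bool use_delay_in_stdp) {
  const int n_mc = conn.nrow(), n_gc = conn.ncol();
  const int period = gamma.size();
  const int total = n_cycles * period;

  const double mc_gl = mc_par["g_L"], mc_E = mc_par["E"],
               mc_tau = mc_par["tau_m"], mc_vth = mc_par["v_th"];
  const double gc_gl = gc_par["g_L"], gc_E = gc_par["E"],
               gc_tau = gc_par["tau_m"], gc_vth = gc_par["v_th"];
  const double a_plus = stdp["a_plus"], a_minus = stdp["a_minus"];
  const double tau_plus = stdp["tau_plus"], tau_minus = stdp["tau_minus"];
  const double w_min = stdp["w_min"], w_max = stdp["w_max"];
  const bool alpha_exp = stdp["alpha_in_exponent"];
  const double exp_plus = alpha_exp ? a_plus : tau_plus;
  const double exp_minus = alpha_exp ? a_minus : tau_minus;

  const double syn_decay = std::exp(-1.0 / tau_syn);
  NumericMatrix W = clone(w);
  IntegerMatrix mc_ph(n_cycles, n_mc), gc_ph(n_cycles, n_gc);
  std::vector<double> vm(n_mc, mc_E), vg(n_gc, gc_E);
  std::vector<char> rm(n_mc, 0), rg(n_gc, 0);
  // pulse buffer over all steps of this presentation (dropped at its end)
  std::vector<double> gc_in((size_t)(total + delay + 1) * n_gc, 0.0);
  std::vector<double> syn_I(n_gc, 0.0);  // decaying GC synaptic current

  for (int t = 0; t < total; ++t) {
    const int cyc = t / period, s = t % period;
    if (s == 0) {  // cycle reset: voltages and refractory flags
      std::fill(vm.begin(), vm.end(), mc_E);
      std::fill(vg.begin(), vg.end(), gc_E);
      std::fill(rm.begin(), rm.end(), 0);
      std::fill(rg.begin(), rg.end(), 0);
      std::fill(syn_I.begin(), syn_I.end(), 0.0);
    }
    const double g = gamma[s];
    for (int i = 0; i < n_mc; ++i) {
      vm[i] = rk4_step(vm[i], mc_drive[i] + g, mc_gl, mc_E, mc_tau);
      if (!rm[i] && vm[i] >= mc_vth) {
        rm[i] = 1;
        mc_ph(cyc, i) = s + 1;
        vm[i] = mc_E;
        const int ta = t + delay;
        if (ta < total) {
          double *buf = &gc_in[(size_t)ta * n_gc];
          for (int j = 0; j < n_gc; ++j) {
            if (conn(i, j)) buf[j] += W(i, j);
          }
        }
      }
    }
    const double *buf = &gc_in[(size_t)t * n_gc];
    for (int j = 0; j < n_gc; ++j) {
      syn_I[j] = syn_I[j] * syn_decay + buf[j];
      vg[j] = rk4_step(vg[j], syn_I[j], gc_gl, gc_E, gc_tau);
      if (!rg[j] && vg[j] >= gc_vth) {
        rg[j] = 1;
        gc_ph(cyc, j) = s + 1;
        vg[j] = gc_E;
      }
    }
    if (learning && s == period - 1) {
      for (int i = 0; i < n_mc; ++i) {
        const int pi = mc_ph(cyc, i);
        if (pi == 0) continue;
        const double t_pre = pi + (use_delay_in_stdp ? delay : 0);
        for (int j = 0; j < n_gc; ++j) {
          if (!conn(i, j)) continue;
          const int pj = gc_ph(cyc, j);
          if (pj == 0) continue;
          const double dt = pj - t_pre;  // post minus pre arrival
          double dw = (dt >= 0) ? a_plus * std::exp(-dt / exp_plus)
                                : -a_minus * std::exp(dt / exp_minus);
          double nw = W(i, j) + dw;
          if (nw < w_min) nw = w_min;
          if (nw > w_max) nw = w_max;
          W(i, j) = nw;
        }
      }
    }
  }
  return List::create(_["mc_phases"] = mc_ph, _["gc_phases"] = gc_ph,
                      _["w"] = W);
}
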