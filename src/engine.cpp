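#include <Rcpp.h>
using namespace Rcpp;

// Inner loop for one sample presentation of the spiking model.
//
// Shared-afferent population: every neuron sees the same input spike matrix,
// so the excitatory PSP traces are shared across neurons. Per step:
//   (1) decay traces, apply input PSPs
//   (2) membrane potentials and gains
//   (3) intrinsic plasticity (full three-parameter rule or mean-rate rule)
//   (4) stochastic spike draws (refractoriness-gated)
//   (5) STDP events (presynaptic-centered nearest-neighbor, all-to-all, or
//       triplet), including the lateral inhibitory connections
// Weight clipping at zero is immediate; synaptic scaling happens in R after
// the sample. Simultaneous pre/post pairs (dt = 0) contribute nothing; a
// presynaptic spike coincident with a postsynaptic one is carried over to
// pair with the next postsynaptic spike.
//
// Nearest-neighbor potentiation bookkeeping: pre_trace is a non-resetting
// exponential trace of each afferent; pre_snap(i,s) stores pre_trace[s] at
// neuron i's last spike. The discounted sum of presynaptic spikes since
// that spike is pre_trace[s] - pre_snap(i,s) * exp(-delta_i/tau_plus).
//
// State vectors are modified in place; the caller owns allocation.
// [[Rcpp::export]]
List sim_present_sample(IntegerMatrix in_spikes,
                        NumericMatrix W,
                        NumericMatrix Winh,
                        NumericMatrix gains,
                        List st,
                        List cfg,
                        bool record_steps = false) {
  const int n_steps = in_spikes.nrow();
  const int n_syn = in_spikes.ncol();
  const int n_neur = W.nrow();
  if (W.ncol() != n_syn) stop("weight matrix does not match the spike matrix");
  if (gains.nrow() != n_neur || gains.ncol() != 3) stop("bad gain matrix shape");

  const double dt = as<double>(cfg["dt"]);
  const double tau_m = as<double>(cfg["tau_m"]);
  const double tau_gaba = as<double>(cfg["tau_gaba"]);
  const double tau_abs = as<double>(cfg["tau_abs"]);
  const double tau_refr = as<double>(cfg["tau_refr"]);
  const double u_rest = as<double>(cfg["u_rest"]);
  const double amp = as<double>(cfg["psp_amplitude"]);
  const double mu_goal = as<double>(cfg["mu_goal"]);

  const int ip_mode = as<int>(cfg["ip_mode"]);        // 0 off, 1 full, 2 mean-rate
  const double eta_ip = as<double>(cfg["eta_ip"]);
  const double r0_floor = as<double>(cfg["r0_floor"]);
  const double ua_floor = as<double>(cfg["ua_floor"]);
  const double eta_mr = as<double>(cfg["eta_mr"]);
  const double tau_r = as<double>(cfg["tau_r"]);
  const double r_goal = as<double>(cfg["r_goal"]);

  const bool stdp_on = as<bool>(cfg["stdp_on"]);
  const int stdp_mode = as<int>(cfg["stdp_mode"]);    // 0 nearest, 1 all-to-all, 2 triplet
  const double A_plus = as<double>(cfg["A_plus"]);
  const double A_minus = as<double>(cfg["A_minus"]);
  const double tau_plus = as<double>(cfg["tau_plus"]);
  const double tau_minus = as<double>(cfg["tau_minus"]);
  const double A3_plus = as<double>(cfg["A3_plus"]);
  const double tau_y = as<double>(cfg["tau_y"]);
  const double inh_gain = as<double>(cfg["inh_stdp_gain"]);
  const bool inh_plastic = as<bool>(cfg["inh_plastic"]);
  const double w_max = as<double>(cfg["w_max"]);

  NumericVector x_exc = st["x_exc"];          // n_syn shared PSP traces
  NumericVector x_inh = st["x_inh"];          // n_neur lateral PSP traces (per sender)
  NumericVector delta_sp = st["delta_spike"]; // n_neur ms since last spike
  NumericVector pre_trace = st["pre_trace"];  // n_syn tau_plus trace
  NumericMatrix pre_snap = st["pre_snap"];    // n_neur x n_syn
  NumericVector inh_pre = st["inh_pre"];      // n_neur sender traces
  NumericMatrix inh_snap = st["inh_snap"];    // n_neur x n_neur
  NumericVector y_post = st["y_post"];        // n_neur tau_minus trace (all-to-all)
  NumericVector y_slow = st["y_slow"];        // n_neur tau_y trace (triplet)
  NumericVector r_bar = st["r_bar"];          // n_neur low-pass rate (Hz)

  const double dec_m = std::exp(-dt / tau_m);
  const double dec_g = std::exp(-dt / tau_gaba);
  const double dec_p = std::exp(-dt / tau_plus);
  const double dec_mn = std::exp(-dt / tau_minus);
  const double dec_y = std::exp(-dt / tau_y);

  IntegerVector spike_count(n_neur);
  NumericVector g_sum(n_neur), g_last(n_neur);
  NumericMatrix rec;
  IntegerMatrix raster;
  if (record_steps) {
    rec = NumericMatrix(n_steps, 2 * n_neur);
    raster = IntegerMatrix(n_steps, n_neur);
  }
  int clamp_count = 0;

  std::vector<int> cur; cur.reserve(n_syn);
  std::vector<int> spiked; spiked.reserve(n_neur);
  std::vector<double> u(n_neur), g(n_neur);
  const double BIG = 1e12;

  double* Wp = W.begin();
  double* snapp = pre_snap.begin();

  for (int t = 0; t < n_steps; ++t) {
    // (1) decay and input PSPs
    for (int s = 0; s < n_syn; ++s) {
      x_exc[s] *= dec_m;
      pre_trace[s] *= dec_p;
    }
    cur.clear();
    for (int s = 0; s < n_syn; ++s) {
      if (in_spikes(t, s)) { x_exc[s] += amp; cur.push_back(s); }
    }
    for (int i = 0; i < n_neur; ++i) {
      x_inh[i] *= dec_g;
      inh_pre[i] *= dec_p;
      y_post[i] *= dec_mn;
      y_slow[i] *= dec_y;
      if (delta_sp[i] < BIG) delta_sp[i] += dt;
    }

    // (2) membrane potential and gain
    for (int i = 0; i < n_neur; ++i) u[i] = u_rest;
    for (int s = 0; s < n_syn; ++s) {
      const double xe = x_exc[s];
      if (xe == 0.0) continue;
      const double* wcol = Wp + (size_t)s * n_neur;
      for (int i = 0; i < n_neur; ++i) u[i] += wcol[i] * xe;
    }
    if (n_neur > 1) {
      for (int j = 0; j < n_neur; ++j) {
        const double xi = x_inh[j];
        if (xi == 0.0) continue;
        for (int i = 0; i < n_neur; ++i) u[i] -= Winh(i, j) * xi;
      }
    }
    for (int i = 0; i < n_neur; ++i) {
      const double r0 = gains(i, 0), u0 = gains(i, 1), ua = gains(i, 2);
      const double z = (u[i] - u0) / ua;
      const double sp = z > 35.0 ? z : std::log1p(std::exp(z));
      g[i] = r0 * sp;
      g_sum[i] += g[i];

      // (3) intrinsic plasticity
      if (ip_mode == 1 && eta_ip > 0) {
        const double sg = 1.0 / (1.0 + std::exp(-z));
        const double d_r0 = -1.0 / r0 + sp / mu_goal;
        const double d_u0 = (1.0 - sg) / ua - r0 * sg / (ua * mu_goal);
        const double d_ua = (1.0 + z * (1.0 - sg)) / ua -
          r0 * sg * z / (ua * mu_goal);
        double r0n = r0 - eta_ip * d_r0;
        double uan = ua - eta_ip * d_ua;
        if (r0n < r0_floor) { r0n = r0_floor; ++clamp_count; }
        if (uan < ua_floor) { uan = ua_floor; ++clamp_count; }
        gains(i, 0) = r0n;
        gains(i, 1) = u0 - eta_ip * d_u0;
        gains(i, 2) = uan;
      } else if (ip_mode == 2) {
        gains(i, 1) = u0 + eta_mr * (r_bar[i] - r_goal);
      }
    }

    // (4) spike draws
    spiked.clear();
    for (int i = 0; i < n_neur; ++i) {
      const double d = delta_sp[i] - tau_abs;
      const double R = delta_sp[i] >= BIG ? 1.0 :
        (d < 0.0 ? 0.0 : d / (tau_refr + d));
      double p_spike = R > 0.0 ? 1.0 - std::exp(-R * g[i] * dt / 1000.0) : 0.0;
      int sp_i = 0;
      if (p_spike > 0.0 && R::unif_rand() < p_spike) sp_i = 1;
      if (sp_i) {
        spiked.push_back(i);
        ++spike_count[i];
        if (record_steps) raster(t, i) = 1;
      }
      if (ip_mode == 2)
        r_bar[i] += (dt / tau_r) * (sp_i * 1000.0 / dt - r_bar[i]);
      if (record_steps) { rec(t, 2 * i) = u[i]; rec(t, 2 * i + 1) = g[i]; }
      g_last[i] = g[i];
    }

    if (stdp_on) {
      // (5a) depression at presynaptic spikes (nearest preceding post)
      for (size_t k = 0; k < cur.size(); ++k) {
        const int s = cur[k];
        double* wcol = Wp + (size_t)s * n_neur;
        for (int i = 0; i < n_neur; ++i) {
          double dw = 0.0;
          if (stdp_mode == 1) {
            dw = A_minus * y_post[i];
          } else if (delta_sp[i] < BIG) {
            dw = A_minus * std::exp(-delta_sp[i] / tau_minus);
          }
          if (dw != 0.0) {
            wcol[i] -= dw;
            if (wcol[i] < 0.0) wcol[i] = 0.0;
          }
        }
      }
      // (5b) potentiation at postsynaptic spikes
      for (size_t k = 0; k < spiked.size(); ++k) {
        const int i = spiked[k];
        const double dfac = delta_sp[i] >= BIG ? 0.0 :
          std::exp(-delta_sp[i] / tau_plus);
        const double a_ltp = stdp_mode == 2 ? A_plus + A3_plus * y_slow[i]
                                            : A_plus;
        for (int s = 0; s < n_syn; ++s) {
          double contrib;
          if (stdp_mode == 1) {
            contrib = pre_trace[s];
          } else {
            contrib = pre_trace[s] - snapp[i + (size_t)s * n_neur] * dfac;
            if (contrib < 0.0) contrib = 0.0;
          }
          if (contrib > 0.0) {
            double& wis = Wp[i + (size_t)s * n_neur];
            wis += a_ltp * contrib;
            if (wis > w_max) wis = w_max;
          }
        }
        if (stdp_mode != 1)
          for (int s = 0; s < n_syn; ++s)
            snapp[i + (size_t)s * n_neur] = pre_trace[s];
      }
      // (5c) lateral inhibitory STDP (amplitudes scaled by inh_gain)
      if (n_neur > 1 && inh_plastic) {
        for (size_t k = 0; k < spiked.size(); ++k) {
          const int j = spiked[k];  // sender spike acts as "pre" on (i, j)
          for (int i = 0; i < n_neur; ++i) {
            if (i == j || delta_sp[i] >= BIG) continue;
            Winh(i, j) -= inh_gain * A_minus *
              std::exp(-delta_sp[i] / tau_minus);
            if (Winh(i, j) < 0.0) Winh(i, j) = 0.0;
          }
        }
        for (size_t k = 0; k < spiked.size(); ++k) {
          const int i = spiked[k];  // receiver spike: potentiation
          const double dfac = delta_sp[i] >= BIG ? 0.0 :
            std::exp(-delta_sp[i] / tau_plus);
          for (int j = 0; j < n_neur; ++j) {
            if (j == i) continue;
            double contrib = inh_pre[j] - inh_snap(i, j) * dfac;
            if (contrib > 0.0) Winh(i, j) += inh_gain * A_plus * contrib;
          }
          for (int j = 0; j < n_neur; ++j) inh_snap(i, j) = inh_pre[j];
        }
      }
    }

    // (5d) register this step's spikes in the traces
    for (size_t k = 0; k < cur.size(); ++k) pre_trace[cur[k]] += 1.0;
    for (size_t k = 0; k < spiked.size(); ++k) {
      const int i = spiked[k];
      delta_sp[i] = 0.0;
      if (n_neur > 1) { x_inh[i] += amp; inh_pre[i] += 1.0; }
      y_post[i] += 1.0;
      y_slow[i] += 1.0;
    }
  }

  List out = List::create(
    _["spike_count"] = spike_count,
    _["mean_g"] = g_sum / (double)n_steps,
    _["g_last"] = g_last,
    _["clamp_count"] = clamp_count);
  if (record_steps) {
    out["step_record"] = rec;
    out["spike_raster"] = raster;
  }
  return out;
}
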