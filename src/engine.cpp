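#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Separable 2-D convolution of field h (n x n, column-major) with the outer
// product of the 1-D Gaussian factor g (length 2*hw+1, centre g[hw] = 1),
// zero padding at the lattice edge (stencils are clipped, no wraparound).
// The self term (d = 0) is subtracted afterwards by the caller.
static void sep_conv(const std::vector<double> &h, int n,
                     const double *g, int hw, bool wrap_edges,
                     std::vector<double> &tmp, std::vector<double> &out) {
  // rows pass: tmp(i,j) = sum_di g[di] * h(i+di, j)
  for (int j = 0; j < n; ++j) {
    const double *hc = &h[(size_t)j * n];
    double *tc = &tmp[(size_t)j * n];
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      if (wrap_edges) {
        for (int d = -hw; d <= hw; ++d) {
          int ii = ((i + d) % n + n) % n;   // stencil may exceed the lattice
          acc += g[d + hw] * hc[ii];
        }
      } else {
        int lo = std::max(-hw, -i), hi = std::min(hw, n - 1 - i);
        for (int d = lo; d <= hi; ++d) acc += g[d + hw] * hc[i + d];
      }
      tc[i] = acc;
    }
  }
  // cols pass: out(i,j) = sum_dj g[dj] * tmp(i, j+dj)
  for (int j = 0; j < n; ++j) {
    double *oc = &out[(size_t)j * n];
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      if (wrap_edges) {
        for (int d = -hw; d <= hw; ++d) {
          int jj = ((j + d) % n + n) % n;
          acc += g[d + hw] * tmp[(size_t)jj * n + i];
        }
      } else {
        int lo = std::max(-hw, -j), hi = std::min(hw, n - 1 - j);
        for (int d = lo; d <= hi; ++d) acc += g[d + hw] * tmp[(size_t)(j + d) * n + i];
      }
      oc[i] = acc;
    }
  }
}

static inline double mg_block_scalar(double v, double mg) {
  return 1.0 / (1.0 + (mg / 3.57) * std::exp(-0.062 * v));
}

// Full STN-GPe-GPi circuit, forward Euler, one-to-one inter-nucleus wiring,
// Gaussian lateral kernels inside STN (AMPA+NMDA) and GPe (GABA).
// Striatal D1/D2 Poisson spikes arrive as (step, neuron) event streams.
// [[Rcpp::export]]
List cpp_run_circuit(int n, int n_steps, double dt,
                     NumericVector p_stn, NumericVector p_gpe, NumericVector p_gpi,
                     double E_ampa, double E_nmda, double E_gaba, double Mg,
                     double tau_ampa, double tau_nmda, double tau_gaba,
                     double tau_nmda_gpi,
                     double w_sg_eff, double w_gs_eff, double w_stn_gpi,
                     double w_strd1_gpi, double w_strd2_gpe,
                     double cD1, double cD2,
                     NumericVector kern_stn, int hw_stn, double A_stn,
                     NumericVector kern_gpe, int hw_gpe, double A_gpe,
                     double s_amp,
                     IntegerVector d1_step, IntegerVector d1_id,
                     IntegerVector d2_step, IntegerVector d2_id,
                     NumericVector v_stn0, NumericVector u_stn0,
                     NumericVector v_gpe0, NumericVector u_gpe0,
                     NumericVector v_gpi0, NumericVector u_gpi0,
                     LogicalVector alive_stn, bool ip_removed,
                     int delay_steps, bool wrap_edges,
                     Nullable<NumericMatrix> h_init) {
  const int N = n * n;
  const double a_stn = p_stn[0], b_stn = p_stn[1], c_stn = p_stn[2],
               d_stn = p_stn[3], vp_stn = p_stn[4], I_stn = p_stn[5];
  const double a_gpe = p_gpe[0], b_gpe = p_gpe[1], c_gpe = p_gpe[2],
               d_gpe = p_gpe[3], vp_gpe = p_gpe[4], I_gpe = p_gpe[5];
  const double a_gpi = p_gpi[0], b_gpi = p_gpi[1], c_gpi = p_gpi[2],
               d_gpi = p_gpi[3], vp_gpi = p_gpi[4], I_gpi = p_gpi[5];

  std::vector<double> v_stn(v_stn0.begin(), v_stn0.end()),
      u_stn(u_stn0.begin(), u_stn0.end()),
      v_gpe(v_gpe0.begin(), v_gpe0.end()),
      u_gpe(u_gpe0.begin(), u_gpe0.end()),
      v_gpi(v_gpi0.begin(), v_gpi0.end()),
      u_gpi(u_gpi0.begin(), u_gpi0.end());

  // gating variables, one per presynaptic neuron per receptor channel;
  // optionally resumed from a previous run (columns: d1, d2, stn_a,
  // stn_n, stn_n67, gpe_g)
  std::vector<double> h_d2(N, 0.0), h_d1(N, 0.0);       // striatal GABA
  std::vector<double> h_stn_a(N, 0.0), h_stn_n(N, 0.0), // STN glutamate
      h_stn_n67(N, 0.0),                                // NMDA onto GPi
      h_gpe_g(N, 0.0);                                  // GPe GABA
  if (h_init.isNotNull()) {
    NumericMatrix H(h_init);
    for (int i = 0; i < N; ++i) {
      h_d1[i] = H(i, 0); h_d2[i] = H(i, 1);
      h_stn_a[i] = H(i, 2); h_stn_n[i] = H(i, 3);
      h_stn_n67[i] = H(i, 4); h_gpe_g[i] = H(i, 5);
    }
  }

  // spike indicator ring buffers: gating at step t reads the spikes
  // emitted delay_steps earlier (synaptic/conduction delay)
  const int D = std::max(1, delay_steps);
  std::vector<std::vector<double>> s_stn(D, std::vector<double>(N, 0.0)),
      s_gpe(D, std::vector<double>(N, 0.0));
  std::vector<double> s_d1(N, 0.0), s_d2(N, 0.0);

  std::vector<double> tmp(N), lat_a(N), lat_n(N), lat_g(N);

  std::vector<int> sp_stn_id, sp_stn_t, sp_gpe_id, sp_gpe_t, sp_gpi_id, sp_gpi_t;
  sp_stn_id.reserve(4096); sp_gpe_id.reserve(4096); sp_gpi_id.reserve(4096);
  sp_stn_t.reserve(4096);  sp_gpe_t.reserve(4096);  sp_gpi_t.reserve(4096);

  const bool use_lat_stn = (A_stn != 0.0) && (hw_stn > 0);
  const bool use_lat_gpe = (A_gpe != 0.0) && (hw_gpe > 0);
  const double *g_stn = kern_stn.begin();
  const double *g_gpe = kern_gpe.begin();

  R_xlen_t i1 = 0, i2 = 0;
  const R_xlen_t n1 = d1_step.size(), n2 = d2_step.size();

  for (int t = 0; t < n_steps; ++t) {
    // striatal spike impulses of this step
    std::fill(s_d1.begin(), s_d1.end(), 0.0);
    std::fill(s_d2.begin(), s_d2.end(), 0.0);
    while (i1 < n1 && d1_step[i1] == t) { s_d1[d1_id[i1]] = 1.0; ++i1; }
    while (i2 < n2 && d2_step[i2] == t) { s_d2[d2_id[i2]] = 1.0; ++i2; }
    // slot t % D holds the spikes of step t - D; the gating update reads
    // it first, then the integration loops overwrite it with this step's
    // spikes
    std::vector<double> &s_stn_out = s_stn[t % D];
    std::vector<double> &s_gpe_out = s_gpe[t % D];
    const std::vector<double> &s_stn_in = s_stn_out;
    const std::vector<double> &s_gpe_in = s_gpe_out;

    // gating update: tau * dh/dt = -h + S, S scaled by the impulse amplitude
    for (int i = 0; i < N; ++i) {
      h_d1[i]      += dt * (-h_d1[i]      + s_amp * s_d1[i]) / tau_gaba;
      h_d2[i]      += dt * (-h_d2[i]      + s_amp * s_d2[i]) / tau_gaba;
      h_stn_a[i]   += dt * (-h_stn_a[i]   + s_amp * s_stn_in[i]) / tau_ampa;
      h_stn_n[i]   += dt * (-h_stn_n[i]   + s_amp * s_stn_in[i]) / tau_nmda;
      h_stn_n67[i] += dt * (-h_stn_n67[i] + s_amp * s_stn_in[i]) / tau_nmda_gpi;
      h_gpe_g[i]   += dt * (-h_gpe_g[i]   + s_amp * s_gpe_in[i]) / tau_gaba;
    }

    // lateral convolutions (self term excluded)
    if (use_lat_stn) {
      sep_conv(h_stn_a, n, g_stn, hw_stn, wrap_edges, tmp, lat_a);
      sep_conv(h_stn_n, n, g_stn, hw_stn, wrap_edges, tmp, lat_n);
      for (int i = 0; i < N; ++i) {
        lat_a[i] = A_stn * (lat_a[i] - h_stn_a[i]);
        lat_n[i] = A_stn * (lat_n[i] - h_stn_n[i]);
      }
    } else {
      std::fill(lat_a.begin(), lat_a.end(), 0.0);
      std::fill(lat_n.begin(), lat_n.end(), 0.0);
    }
    if (use_lat_gpe) {
      sep_conv(h_gpe_g, n, g_gpe, hw_gpe, wrap_edges, tmp, lat_g);
      for (int i = 0; i < N; ++i) lat_g[i] = A_gpe * (lat_g[i] - h_gpe_g[i]);
    } else {
      std::fill(lat_g.begin(), lat_g.end(), 0.0);
    }

    bool blown = false;
    // --- GPe ---
    for (int i = 0; i < N; ++i) {
      const double V = v_gpe[i];
      const double B = mg_block_scalar(V, Mg);
      double Isyn = lat_g[i] * (E_gaba - V)
        + w_sg_eff * (h_stn_a[i] * (E_ampa - V) + B * h_stn_n[i] * (E_nmda - V))
        + cD2 * w_strd2_gpe * h_d2[i] * (E_gaba - V);
      double vn = V + dt * (0.04 * V * V + 5.0 * V - u_gpe[i] + 140.0 + I_gpe + Isyn);
      double un = u_gpe[i] + dt * a_gpe * (b_gpe * V - u_gpe[i]);
      if (vn >= vp_gpe) {
        sp_gpe_id.push_back(i); sp_gpe_t.push_back(t);
        vn = c_gpe; un += d_gpe;
        s_gpe_out[i] = 1.0;
      } else s_gpe_out[i] = 0.0;
      v_gpe[i] = vn; u_gpe[i] = un;
      if (!std::isfinite(vn)) blown = true;
    }
    // --- STN ---
    for (int i = 0; i < N; ++i) {
      if (!alive_stn[i]) { s_stn_out[i] = 0.0; continue; }
      const double V = v_stn[i];
      const double B = mg_block_scalar(V, Mg);
      double Isyn = w_gs_eff * h_gpe_g[i] * (E_gaba - V)
        + lat_a[i] * (E_ampa - V) + B * lat_n[i] * (E_nmda - V);
      double vn = V + dt * (0.04 * V * V + 5.0 * V - u_stn[i] + 140.0 + I_stn + Isyn);
      double un = u_stn[i] + dt * a_stn * (b_stn * V - u_stn[i]);
      if (vn >= vp_stn) {
        sp_stn_id.push_back(i); sp_stn_t.push_back(t);
        vn = c_stn; un += d_stn;
        s_stn_out[i] = 1.0;
      } else s_stn_out[i] = 0.0;
      v_stn[i] = vn; u_stn[i] = un;
      if (!std::isfinite(vn)) blown = true;
    }
    // --- GPi ---
    for (int i = 0; i < N; ++i) {
      const double V = v_gpi[i];
      double Isyn = cD1 * w_strd1_gpi * h_d1[i] * (E_gaba - V);
      if (!ip_removed) {
        const double B = mg_block_scalar(V, Mg);
        Isyn += w_stn_gpi * (h_stn_a[i] * (E_ampa - V)
                             + B * h_stn_n67[i] * (E_nmda - V));
      }
      double vn = V + dt * (0.04 * V * V + 5.0 * V - u_gpi[i] + 140.0 + I_gpi + Isyn);
      double un = u_gpi[i] + dt * a_gpi * (b_gpi * V - u_gpi[i]);
      if (vn >= vp_gpi) {
        sp_gpi_id.push_back(i); sp_gpi_t.push_back(t);
        vn = c_gpi; un += d_gpi;
      }
      v_gpi[i] = vn; u_gpi[i] = un;
      if (!std::isfinite(vn)) blown = true;
    }
    if (blown)
      stop("numerical blow-up (non-finite membrane potential) at step %d (t = %.3f ms); reduce dt", t + 1, (t + 1) * dt);
  }

  return List::create(
    _["stn_id"] = wrap(sp_stn_id), _["stn_step"] = wrap(sp_stn_t),
    _["gpe_id"] = wrap(sp_gpe_id), _["gpe_step"] = wrap(sp_gpe_t),
    _["gpi_id"] = wrap(sp_gpi_id), _["gpi_step"] = wrap(sp_gpi_t),
    _["v_stn"] = wrap(v_stn), _["u_stn"] = wrap(u_stn),
    _["v_gpe"] = wrap(v_gpe), _["u_gpe"] = wrap(u_gpe),
    _["v_gpi"] = wrap(v_gpi), _["u_gpi"] = wrap(u_gpi),
    _["h_final"] = [&]{
      NumericMatrix H(N, 6);
      for (int i = 0; i < N; ++i) {
        H(i, 0) = h_d1[i]; H(i, 1) = h_d2[i];
        H(i, 2) = h_stn_a[i]; H(i, 3) = h_stn_n[i];
        H(i, 4) = h_stn_n67[i]; H(i, 5) = h_gpe_g[i];
      }
      return H;
    }());
}
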