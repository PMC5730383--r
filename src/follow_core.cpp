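#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Leaky integrate-and-fire population update with exact exponential voltage
// integration and sub-step refractory bookkeeping (threshold fixed at 1,
// reset 0, lower clip 0). A neuron coming out of refractoriness integrates
// only over the non-refractory fraction of the step; on threshold crossing
// the crossing time within the step is recovered by inverting the
// exponential solution and the refractory clock is started from there.
namespace {

void lif_pop_step(arma::vec& v, arma::vec& refr, const arma::vec& J,
                  double dt, double tau_m, double tau_r,
                  std::vector<arma::uword>& spk) {
  spk.clear();
  const arma::uword n = v.n_elem;
  for (arma::uword i = 0; i < n; ++i) {
    double r = refr[i] - dt;
    if (r < -dt) r = -dt;
    refr[i] = r;
    double delta = dt - r;
    if (delta < 0.0) delta = 0.0; else if (delta > dt) delta = dt;
    double vi = v[i] - (J[i] - v[i]) * std::expm1(-delta / tau_m);
    if (vi > 1.0) {
      double t_spike = dt + tau_m * std::log1p(-(vi - 1.0) / (J[i] - 1.0));
      vi = 0.0;
      refr[i] = tau_r + t_spike;
      spk.push_back(i);
    }
    if (vi < 0.0) vi = 0.0;
    v[i] = vi;
  }
}

arma::vec get_or_zeros(const List& st, const char* name, arma::uword n) {
  if (st.containsElementNamed(name)) return as<arma::vec>(st[name]);
  return arma::zeros<arma::vec>(n);
}

} // namespace

// Closed-loop simulation of the two-layer FOLLOW network.
//
// Currents from plastic connections are propagated as filtered spike input:
// on a presynaptic spike the corresponding weight column (scaled by 1/tau_s)
// is added to an exponentially decaying current vector, which for fixed
// weights is exactly w * (S * kappa). Weight increments are accumulated and
// applied every `update_every` steps as a blocked outer-product update.
//
// u:      Nc x T command input (network units)
// x_ref:  Nd x T reference signal (already filtered/delayed as desired)
// eta:    length-T learning rate schedule
// [[Rcpp::export]]
List cpp_run_network(const arma::mat& Ecmd, const arma::vec& b_cmd,
                     const arma::mat& Efb, const arma::vec& b_rec,
                     const arma::mat& D,
                     arma::mat w_ff, arma::mat w_rec,
                     const arma::mat& u, const arma::mat& x_ref,
                     List state0,
                     double dt, double tau_m, double tau_r,
                     double tau_s, double tau_eps,
                     double k, bool feedback_on, bool plasticity_on,
                     const arma::vec& eta,
                     double noise_sd,
                     const arma::mat& mask_ff, const arma::mat& mask_rec,
                     int update_every, int record_every,
                     bool readout_learning, double readout_eta,
                     arma::mat d_learn,
                     const arma::imat& spike_windows,
                     const arma::ivec& snapshot_steps,
                     int rate_bin_steps) {
  const arma::uword Ncmd = Ecmd.n_rows, Nrec = Efb.n_rows;
  const arma::uword Nc = Ecmd.n_cols, Nd = Efb.n_cols;
  const arma::uword T = u.n_cols;
  if (x_ref.n_cols != T || x_ref.n_rows != Nd)
    stop("reference series must be Nd x T");
  if (u.n_rows != Nc) stop("command series must be Nc x T");
  if (eta.n_elem != T) stop("eta schedule must have length T");

  const double decay_s = std::exp(-dt / tau_s);
  const double decay_e = std::exp(-dt / tau_eps);
  const double inv_tau_s = 1.0 / tau_s;
  const bool use_mask_ff = mask_ff.n_elem > 0;
  const bool use_mask_rec = mask_rec.n_elem > 0;

  arma::vec v_cmd = get_or_zeros(state0, "v_cmd", Ncmd);
  arma::vec refr_cmd = get_or_zeros(state0, "refr_cmd", Ncmd);
  arma::vec v_rec = get_or_zeros(state0, "v_rec", Nrec);
  arma::vec refr_rec = get_or_zeros(state0, "refr_rec", Nrec);
  arma::vec cmd_tr = get_or_zeros(state0, "cmd_traces", Ncmd);
  arma::vec rec_tr = get_or_zeros(state0, "rec_traces", Nrec);
  arma::vec ff_cur = get_or_zeros(state0, "ff_current", Nrec);
  arma::vec rec_cur = get_or_zeros(state0, "rec_current", Nrec);
  arma::vec err_tr = get_or_zeros(state0, "err_traces", Nd);
  arma::vec learn_err = get_or_zeros(state0, "learn_err_traces", Nrec);

  // recorders
  const arma::uword nrec = (T + record_every - 1) / record_every;
  arma::mat xhat_rec(Nd, nrec, arma::fill::zeros);
  arma::mat eps_full(Nd, T, arma::fill::zeros);
  std::vector<double> spike_t;
  std::vector<int> spike_n;
  const arma::uword nwin = spike_windows.n_rows;
  arma::uword nbins = 0;
  arma::imat rate_bins;
  if (rate_bin_steps > 0) {
    nbins = (T + rate_bin_steps - 1) / rate_bin_steps;
    rate_bins.zeros(Nrec, nbins);
  }
  arma::ivec count_cmd(Ncmd, arma::fill::zeros), count_rec(Nrec, arma::fill::zeros);
  List snapshots;
  arma::uword snap_idx = 0;

  // blocked weight-update buffers
  arma::mat bufE, bufC, bufR;
  int bufn = 0;
  if (plasticity_on) {
    bufE.zeros(Nrec, update_every);
    bufC.zeros(Ncmd, update_every);
    bufR.zeros(Nrec, update_every);
  }
  // reference-simulator convention: increments scaled by 1/n_presynaptic
  const double norm_ff = 1.0 / (double)Ncmd;
  const double norm_rec = 1.0 / (double)Nrec;
  auto flush = [&]() {
    if (bufn == 0) return;
    arma::mat Eb = bufE.cols(0, bufn - 1);
    arma::mat dff = (Eb * bufC.cols(0, bufn - 1).t()) * norm_ff;
    arma::mat drec = (Eb * bufR.cols(0, bufn - 1).t()) * norm_rec;
    if (use_mask_ff) dff %= mask_ff;
    if (use_mask_rec) drec %= mask_rec;
    w_ff += dff;
    w_rec += drec;
    bufn = 0;
  };

  std::vector<arma::uword> spk;
  arma::vec J_ff(Ncmd), J_rec(Nrec), xhat(Nd), eps(Nd), Ieps(Nrec);
  RNGScope rngscope;

  for (arma::uword t = 0; t < T; ++t) {
    // (i) command-layer currents and LIF step
    J_ff = Ecmd * u.col(t) + b_cmd;
    if (!J_ff.is_finite())
      stop("non-finite command-layer current at t = %f s", (t + 1) * dt);
    lif_pop_step(v_cmd, refr_cmd, J_ff, dt, tau_m, tau_r, spk);
    // (ii) command traces and feedforward synaptic current
    cmd_tr *= decay_s;
    ff_cur *= decay_s;
    for (arma::uword s : spk) {
      cmd_tr[s] += inv_tau_s;
      ff_cur += w_ff.col(s) * inv_tau_s;
      ++count_cmd[s];
    }
    // (iii) recurrent-layer currents (previous-tick recurrent/error traces)
    J_rec = ff_cur + rec_cur + b_rec;
    if (feedback_on) J_rec += k * (Efb * err_tr);
    if (!J_rec.is_finite())
      stop("non-finite recurrent-layer current at t = %f s", (t + 1) * dt);
    lif_pop_step(v_rec, refr_rec, J_rec, dt, tau_m, tau_r, spk);
    // (iv) recurrent traces and synaptic current
    rec_tr *= decay_s;
    rec_cur *= decay_s;
    for (arma::uword s : spk) {
      rec_tr[s] += inv_tau_s;
      rec_cur += w_rec.col(s) * inv_tau_s;
      ++count_rec[s];
    }
    if (nwin > 0 || rate_bin_steps > 0) {
      for (arma::uword s : spk) {
        if (rate_bin_steps > 0) ++rate_bins(s, t / rate_bin_steps);
        for (arma::uword w = 0; w < nwin; ++w) {
          if ((int)t >= spike_windows(w, 0) && (int)t < spike_windows(w, 1)) {
            spike_n.push_back((int)s + 1);
            spike_t.push_back((t + 1) * dt);
            break;
          }
        }
      }
    }
    // (v) decode
    if (readout_learning) xhat = d_learn * rec_tr;
    else xhat = D * rec_tr;
    // (vi) error
    eps = x_ref.col(t) - xhat;
    if (noise_sd > 0.0)
      for (arma::uword a = 0; a < Nd; ++a) eps[a] += R::rnorm(0.0, noise_sd);
    eps_full.col(t) = eps;
    // (vii) filtered error traces
    err_tr = err_tr * decay_s + eps * (1.0 - decay_s);
    if (plasticity_on) {
      Ieps = k * (Efb * eps);
      learn_err = learn_err * decay_e + Ieps * (1.0 - decay_e);
      // (viii) FOLLOW update (blocked)
      bufE.col(bufn) = (eta[t] * dt) * learn_err;
      bufC.col(bufn) = cmd_tr;
      bufR.col(bufn) = rec_tr;
      if (++bufn == update_every) flush();
    }
    if (readout_learning)
      d_learn -= (readout_eta * dt) * ((d_learn * rec_tr - x_ref.col(t)) * rec_tr.t());

    if (t % record_every == 0) xhat_rec.col(t / record_every) = xhat;
    if (snap_idx < snapshot_steps.n_elem && (int)t == snapshot_steps[snap_idx]) {
      flush();
      snapshots.push_back(List::create(_["step"] = (int)t + 1,
                                       _["w_ff"] = w_ff, _["w_rec"] = w_rec));
      ++snap_idx;
    }
  }
  flush();

  List state = List::create(
      _["v_cmd"] = v_cmd, _["refr_cmd"] = refr_cmd,
      _["v_rec"] = v_rec, _["refr_rec"] = refr_rec,
      _["cmd_traces"] = cmd_tr, _["rec_traces"] = rec_tr,
      _["ff_current"] = ff_cur, _["rec_current"] = rec_cur,
      _["err_traces"] = err_tr, _["learn_err_traces"] = learn_err);

  List out = List::create(
      _["xhat"] = xhat_rec, _["eps"] = eps_full,
      _["w_ff"] = w_ff, _["w_rec"] = w_rec,
      _["state"] = state,
      _["spike_neuron"] = spike_n, _["spike_time"] = spike_t,
      _["count_cmd"] = count_cmd, _["count_rec"] = count_rec,
      _["snapshots"] = snapshots,
      _["d_learn"] = d_learn);
  if (rate_bin_steps > 0) out["rate_bins"] = rate_bins;
  return out;
}

namespace {

// Two-link planar arm under gravity: pars = (m1,m2,l1,l2,s1,s2,I1,I2,
// b11,b12,b21,b22,g). State (th1,th2,om1,om2), input raw joint torques.
void arm_deriv(const double* x, const double* uu, const arma::vec& p,
               double* dx) {
  const double m1 = p[0], m2 = p[1], l1 = p[2], s1 = p[4], s2 = p[5],
               I1 = p[6], I2 = p[7], b11 = p[8], b12 = p[9], b21 = p[10],
               b22 = p[11], g = p[12];
  const double th1 = x[0], th2 = x[1], om1 = x[2], om2 = x[3];
  const double d1 = I1 + I2 + m2 * l1 * l1;
  const double d2 = m2 * l1 * s2;
  const double d3 = I2;
  const double c2 = std::cos(th2), s2t = std::sin(th2);
  const double M11 = d1 + 2.0 * d2 * c2 + m1 * s1 * s1 + m2 * s2 * s2;
  const double M12 = d3 + d2 * c2 + m2 * s2 * s2;
  const double M22 = d3 + m2 * s2 * s2;
  const double C1 = -om2 * (2.0 * om1 + om2) * d2 * s2t;
  const double C2 = om1 * om1 * d2 * s2t;
  const double D1 = (m1 * s1 + m2 * l1) * std::sin(th1) + m2 * s2 * std::sin(th1 + th2);
  const double D2 = m2 * s2 * std::sin(th1 + th2);
  // effective torque with soft clipping near +/- pi/2..3pi/4
  double tau[2];
  const double half_pi = M_PI / 2.0, quarter_pi = M_PI / 4.0;
  for (int a = 0; a < 2; ++a) {
    double ua = uu[a], th = x[a];
    double arg = (ua > 0.0) ? th : -th;
    double sig;
    if (arg <= half_pi) sig = 0.0;
    else if (arg >= 3.0 * M_PI / 4.0) sig = 1.0;
    else sig = (arg - half_pi) / quarter_pi;
    tau[a] = (ua == 0.0) ? 0.0 : ua - ua * sig;
  }
  const double r1 = tau[0] - C1 - (b11 * om1 + b12 * om2) - g * D1;
  const double r2 = tau[1] - C2 - (b21 * om1 + b22 * om2) - g * D2;
  const double det = M11 * M22 - M12 * M12;
  dx[0] = om1;
  dx[1] = om2;
  dx[2] = (M22 * r1 - M12 * r2) / det;
  dx[3] = (-M12 * r1 + M11 * r2) / det;
}

} // namespace

// Forward-Euler integration of the reference systems, with n_sub Euler
// sub-steps per network step dt (the input is held constant within a
// step). system: 1 linear, 2 van der Pol, 3 Lorenz (shifted), 4
// non-linear feedforward input to linear system, 5 two-link arm (raw
// units). Returns d x T states, x[, t] the state after step t from x0.
// [[Rcpp::export]]
arma::mat cpp_integrate_reference(int system, const arma::mat& u,
                                  const arma::vec& x0, double dt,
                                  const arma::vec& arm_pars,
                                  int n_sub = 1) {
  const arma::uword T = u.n_cols;
  const arma::uword d = x0.n_elem;
  const double h = dt / n_sub;
  arma::mat out(d, T);
  arma::vec x = x0;
  double dx[4];
  for (arma::uword t = 0; t < T; ++t) {
    const double* uc = u.colptr(t);
    for (int sub = 0; sub < n_sub; ++sub) {
    switch (system) {
    case 1:
      dx[0] = uc[0] / 0.02 + (-0.2 * x[0] - x[1]) / 0.05;
      dx[1] = uc[1] / 0.02 + (x[0] - 0.2 * x[1]) / 0.05;
      break;
    case 2:
      dx[0] = uc[0] / 0.02 + x[1] / 0.125;
      dx[1] = uc[1] / 0.02 + (2.0 * (1.0 - x[0] * x[0]) * x[1] - x[0]) / 0.125;
      break;
    case 3:
      dx[0] = uc[0] / 0.02 + 10.0 * (x[1] - x[0]);
      dx[1] = uc[1] / 0.02 - x[0] * x[2] - x[1];
      dx[2] = uc[2] / 0.02 + x[0] * x[1] - 8.0 * (x[2] + 28.0) / 3.0;
      break;
    case 4: {
      double g0 = 10.0 * (std::pow(uc[0] / 0.1, 3) - uc[0] / 0.4);
      double g1 = 10.0 * (std::pow(uc[1] / 0.1, 3) - uc[1] / 0.4);
      dx[0] = g0 + (-0.2 * x[0] - x[1]) / 0.05;
      dx[1] = g1 + (x[0] - 0.2 * x[1]) / 0.05;
      break;
    }
    case 5:
      arm_deriv(x.memptr(), uc, arm_pars, dx);
      break;
    default:
      stop("unknown system code");
    }
    for (arma::uword j = 0; j < d; ++j) x[j] += h * dx[j];
    }
    if (!x.is_finite())
      stop("reference state became non-finite at t = %f s", (t + 1) * dt);
    out.col(t) = x;
  }
  return out;
}
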