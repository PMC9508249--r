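#include <Rcpp.h>
using namespace Rcpp;

// All-to-all triplet-STDP detector loop.
//
// Presynaptic traces r1 (tau_plus) and r2 (tau_x), postsynaptic traces o1
// (tau_minus) and o2 (tau_y); every spike interacts with all previous spikes
// through the persistent traces.  Triplet contributions use the trace value
// just before the current spike's own increment.  Per-side suppression
// ("first spike dominates"): a spike following a same-side spike after a gap
// dt has efficacy 1 - exp(-dt / tau_supp); tau_supp <= 0 disables it.
//
// Returns the running weight at each event plus bookkeeping columns.
// [[Rcpp::export]]
List triplet_core(NumericVector pre, NumericVector post,
                  double A2p, double A2m, double A3p, double A3m,
                  double tau_plus, double tau_minus, double tau_x,
                  double tau_y, double tau_supp, double w_init) {
  const int np = pre.size(), nq = post.size();
  const int n = np + nq;
  NumericVector ev_t(n), ev_w(n), ev_dw(n);
  IntegerVector ev_side(n); // 0 = pre, 1 = post

  double r1 = 0, r2 = 0, o1 = 0, o2 = 0;
  double t_last = R_NegInf, last_pre = R_NegInf, last_post = R_NegInf;
  double w = w_init;
  int i = 0, j = 0;

  for (int k = 0; k < n; ++k) {
    bool take_pre;
    if (i >= np) take_pre = false;
    else if (j >= nq) take_pre = true;
    else if (pre[i] == post[j])
      stop("Simultaneous pre and post spikes at t = %f are not allowed.", pre[i]);
    else take_pre = pre[i] < post[j];

    double t = take_pre ? pre[i] : post[j];
    if (t_last != R_NegInf) {
      double dt = t - t_last;
      if (dt < 0) stop("Spike trains must be time-ordered.");
      r1 *= std::exp(-dt / tau_plus);
      r2 *= std::exp(-dt / tau_x);
      o1 *= std::exp(-dt / tau_minus);
      o2 *= std::exp(-dt / tau_y);
    }
    t_last = t;

    double dw = 0;
    if (take_pre) {
      double eff = 1.0;
      if (tau_supp > 0 && last_pre != R_NegInf)
        eff = 1.0 - std::exp(-(t - last_pre) / tau_supp);
      dw = -eff * o1 * (A2m + A3m * r2); // r2 before its own increment
      r1 += 1.0;
      r2 += 1.0;
      last_pre = t;
      ++i;
    } else {
      double eff = 1.0;
      if (tau_supp > 0 && last_post != R_NegInf)
        eff = 1.0 - std::exp(-(t - last_post) / tau_supp);
      dw = eff * r1 * (A2p + A3p * o2); // o2 before its own increment
      o1 += 1.0;
      o2 += 1.0;
      last_post = t;
      ++j;
    }
    w += dw;
    ev_t[k] = t;
    ev_dw[k] = dw;
    ev_w[k] = w;
    ev_side[k] = take_pre ? 0 : 1;
  }

  return List::create(_["time_ms"] = ev_t, _["side"] = ev_side,
                      _["dw"] = ev_dw, _["w"] = ev_w,
                      _["w_total"] = w - w_init);
}
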