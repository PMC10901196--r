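#include <Rcpp.h>
using namespace Rcpp;

// Natural-space parameters arrive fully expanded to the canonical 12-slot
// layout: eps has 4 entries ordered (WP, WN, AP, AN), rho has 2 (W, A);
// models that share a parameter across valence/PE-sign simply repeat it.
// valence: 0 = win, 1 = avoid; action: 1 = go, 0 = nogo; r in {-1, 0, +1}.
// A prediction error of exactly zero uses the positive-PE learning rate.

static inline double stable_log1pexp(double x) {
  // log(1 + exp(x)), stable for large |x|
  if (x > 35.0) return x;
  if (x < -35.0) return 0.0;
  return std::log1p(std::exp(x));
}

// [[Rcpp::export]]
double seq_loglik_cpp(IntegerVector image, IntegerVector valence,
                      IntegerVector action, IntegerVector outcome,
                      NumericVector eps, NumericVector rho,
                      double b, double pav, int n_images) {
  int n = image.size();
  std::vector<double> q_go(n_images, 0.0), q_nogo(n_images, 0.0), v(n_images, 0.0);
  double ll = 0.0;
  for (int t = 0; t < n; ++t) {
    int s = image[t];
    int val = valence[t];
    double w_go = q_go[s] + b + pav * v[s];
    double w_nogo = q_nogo[s];
    // log p(go) = -log(1 + exp(w_nogo - w_go))
    double lp_go = -stable_log1pexp(w_nogo - w_go);
    double lp_nogo = -stable_log1pexp(w_go - w_nogo);
    ll += (action[t] == 1) ? lp_go : lp_nogo;

    double target = rho[val] * outcome[t];
    double *q = (action[t] == 1) ? &q_go[s] : &q_nogo[s];
    double delta = target - *q;
    double e_q = eps[val * 2 + (delta >= 0.0 ? 0 : 1)];
    *q += e_q * delta;
    double delta_v = target - v[s];
    double e_v = eps[val * 2 + (delta_v >= 0.0 ? 0 : 1)];
    v[s] += e_v * delta_v;
  }
  return ll;
}

// Vectorized over parameter draws (rows); used by the Monte-Carlo marginal
// likelihood. eps: n_draws x 4, rho: n_draws x 2.
// [[Rcpp::export]]
NumericVector seq_loglik_many_cpp(IntegerVector image, IntegerVector valence,
                                  IntegerVector action, IntegerVector outcome,
                                  NumericMatrix eps, NumericMatrix rho,
                                  NumericVector b, NumericVector pav,
                                  int n_images) {
  int n_draws = eps.nrow();
  NumericVector out(n_draws);
  NumericVector e(4), r2(2);
  for (int k = 0; k < n_draws; ++k) {
    for (int j = 0; j < 4; ++j) e[j] = eps(k, j);
    for (int j = 0; j < 2; ++j) r2[j] = rho(k, j);
    out[k] = seq_loglik_cpp(image, valence, action, outcome, e, r2,
                            b[k], pav[k], n_images);
  }
  return out;
}

// Replay a choice/outcome sequence and return per-trial quantities:
// p(go) before the choice and the action-value difference Q(go) - Q(nogo)
// before the update. Used by value trajectories and diagnostics.
// [[Rcpp::export]]
List seq_replay_cpp(IntegerVector image, IntegerVector valence,
                    IntegerVector action, IntegerVector outcome,
                    NumericVector eps, NumericVector rho,
                    double b, double pav, int n_images) {
  int n = image.size();
  std::vector<double> q_go(n_images, 0.0), q_nogo(n_images, 0.0), v(n_images, 0.0);
  NumericVector p_go(n), qdiff(n), vval(n);
  for (int t = 0; t < n; ++t) {
    int s = image[t];
    int val = valence[t];
    double w_go = q_go[s] + b + pav * v[s];
    double w_nogo = q_nogo[s];
    p_go[t] = 1.0 / (1.0 + std::exp(w_nogo - w_go));
    qdiff[t] = q_go[s] - q_nogo[s];
    vval[t] = v[s];

    double target = rho[val] * outcome[t];
    double *q = (action[t] == 1) ? &q_go[s] : &q_nogo[s];
    double delta = target - *q;
    *q += eps[val * 2 + (delta >= 0.0 ? 0 : 1)] * delta;
    double delta_v = target - v[s];
    v[s] += eps[val * 2 + (delta_v >= 0.0 ? 0 : 1)] * delta_v;
  }
  return List::create(_["p_go"] = p_go, _["q_diff"] = qdiff, _["v"] = vval);
}

// Log-likelihood and its gradient with respect to the 12 dense natural
// parameters (eps WP,WN,AP,AN; rho W,A; b; pi), by forward-mode
// accumulation of state sensitivities through the value recursion. The
// mapping onto a model's free parameters (including the unconstrained-scale
// chain rule) happens on the R side.
// [[Rcpp::export]]
List seq_loglik_grad_cpp(IntegerVector image, IntegerVector valence,
                         IntegerVector action, IntegerVector outcome,
                         NumericVector eps, NumericVector rho,
                         double b, double pav, int n_images) {
  const int P = 12;            // 0..3 eps, 4..5 rho, 6 b, 7 pi (rest unused)
  const int I_RHO = 4, I_B = 6, I_PI = 7;
  int n = image.size();
  std::vector<double> q_go(n_images, 0.0), q_nogo(n_images, 0.0), v(n_images, 0.0);
  std::vector<double> g_qgo(n_images * P, 0.0), g_qnogo(n_images * P, 0.0),
                      g_v(n_images * P, 0.0);
  double ll = 0.0;
  std::vector<double> g_ll(P, 0.0), d_wgo(P), d_wng(P);

  for (int t = 0; t < n; ++t) {
    int s = image[t];
    int val = valence[t];
    double *gq_go = &g_qgo[s * P], *gq_ng = &g_qnogo[s * P], *gv = &g_v[s * P];

    double w_go = q_go[s] + b + pav * v[s];
    double w_ng = q_nogo[s];
    for (int k = 0; k < P; ++k) {
      d_wgo[k] = gq_go[k] + pav * gv[k];
      d_wng[k] = gq_ng[k];
    }
    d_wgo[I_B] += 1.0;
    d_wgo[I_PI] += v[s];

    double p_go = 1.0 / (1.0 + std::exp(w_ng - w_go));
    if (action[t] == 1) {
      ll += -stable_log1pexp(w_ng - w_go);
      for (int k = 0; k < P; ++k) g_ll[k] += (1.0 - p_go) * (d_wgo[k] - d_wng[k]);
    } else {
      ll += -stable_log1pexp(w_go - w_ng);
      for (int k = 0; k < P; ++k) g_ll[k] += p_go * (d_wng[k] - d_wgo[k]);
    }

    // chosen action value
    double r_t = outcome[t];
    double target = rho[val] * r_t;
    double *q = (action[t] == 1) ? &q_go[s] : &q_nogo[s];
    double *gq = (action[t] == 1) ? gq_go : gq_ng;
    double delta = target - *q;
    int slot = val * 2 + (delta >= 0.0 ? 0 : 1);
    double e_q = eps[slot];
    for (int k = 0; k < P; ++k) {
      double d_delta = -gq[k];
      if (k == I_RHO + val) d_delta += r_t;
      gq[k] += e_q * d_delta;
    }
    gq[slot] += delta;
    *q += e_q * delta;

    // stimulus value, same parameters, own PE sign
    double delta_v = target - v[s];
    int slot_v = val * 2 + (delta_v >= 0.0 ? 0 : 1);
    double e_v = eps[slot_v];
    for (int k = 0; k < P; ++k) {
      double d_delta = -gv[k];
      if (k == I_RHO + val) d_delta += r_t;
      gv[k] += e_v * d_delta;
    }
    gv[slot_v] += delta_v;
    v[s] += e_v * delta_v;
  }
  return List::create(_["loglik"] = ll, _["grad"] = NumericVector(g_ll.begin(), g_ll.end()));
}
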