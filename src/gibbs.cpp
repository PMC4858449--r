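#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for the three-stage area-level model with a fixed-variance
// Gaussian working likelihood:
//   stage 1: theta_i ~ N(eta_i, V_i) for areas with an observed summary
//   stage 2: eta_i = mu + u_i + v_i; u ICAR(tau_u) on the adjacency graph,
//            v_i iid N(0, 1/tau_v)
//   stage 3: tau_u ~ Gamma(a_u, b_u), tau_v ~ Gamma(a_v, b_v), mu flat
// All full conditionals are Gaussian or Gamma. The ICAR sum-to-zero
// constraint is enforced by re-centering u each sweep, with the removed mean
// absorbed into mu. Areas with obs == 0 carry no likelihood term and their
// effects are drawn from the prior conditionals (prediction only).
//
// structure: 0 = iid_only, 1 = icar_only, 2 = icar_plus_iid
// fix_tau_u / fix_tau_v: NA to sample, a positive value to hold fixed.
//
// Uses R's RNG, so set.seed() in R makes runs reproducible draw-for-draw.
// [[Rcpp::export]]
List gibbs_bym_cpp(NumericVector theta, NumericVector V, IntegerVector obs,
                   IntegerVector nb_flat, IntegerVector nb_start,
                   IntegerVector nb_len, int n_iter, int burn_in, int thin,
                   int structure, double a_u, double b_u, double a_v,
                   double b_v, double fix_tau_u, double fix_tau_v) {
  const int n = theta.size();
  const bool has_u = structure != 0;
  const bool has_v = structure != 1;
  const bool sample_tau_u = has_u && !R_finite(fix_tau_u);
  const bool sample_tau_v = has_v && !R_finite(fix_tau_v);

  std::vector<double> u(n, 0.0), v(n, 0.0), w(n);
  for (int i = 0; i < n; ++i) w[i] = obs[i] ? 1.0 / V[i] : 0.0;

  double mu = 0.0, wsum = 0.0;
  for (int i = 0; i < n; ++i) {
    if (obs[i]) { mu += theta[i] * w[i]; wsum += w[i]; }
  }
  mu /= wsum;
  double tau_u = has_u ? (R_finite(fix_tau_u) ? fix_tau_u : 1.0) : 0.0;
  double tau_v = has_v ? (R_finite(fix_tau_v) ? fix_tau_v : 1.0) : 0.0;

  const int n_keep = (n_iter - burn_in) / thin;
  NumericVector mu_out(n_keep), tau_u_out(n_keep), tau_v_out(n_keep);
  NumericMatrix u_out(n_keep, n), v_out(n_keep, n);

  int kept = 0;
  for (int t = 1; t <= n_iter; ++t) {
    // mu | rest (flat prior)
    double num = 0.0;
    for (int i = 0; i < n; ++i)
      if (obs[i]) num += (theta[i] - u[i] - v[i]) * w[i];
    mu = num / wsum + R::rnorm(0.0, 1.0) / std::sqrt(wsum);

    // u | rest: single-site ICAR conditionals, then re-center
    if (has_u) {
      for (int i = 0; i < n; ++i) {
        double nbsum = 0.0;
        const int s = nb_start[i];
        for (int k = 0; k < nb_len[i]; ++k) nbsum += u[nb_flat[s + k]];
        const double prec = tau_u * nb_len[i] + w[i];
        const double m =
            (tau_u * nbsum + w[i] * (theta[i] - mu - v[i])) / prec;
        u[i] = m + R::rnorm(0.0, 1.0) / std::sqrt(prec);
      }
      double ubar = 0.0;
      for (int i = 0; i < n; ++i) ubar += u[i];
      ubar /= n;
      for (int i = 0; i < n; ++i) u[i] -= ubar;
      mu += ubar;
    }

    // v | rest
    if (has_v) {
      for (int i = 0; i < n; ++i) {
        const double prec = tau_v + w[i];
        const double m = w[i] * (theta[i] - mu - u[i]) / prec;
        v[i] = m + R::rnorm(0.0, 1.0) / std::sqrt(prec);
      }
    }

    // precisions
    if (sample_tau_u) {
      double ss = 0.0;
      for (int i = 0; i < n; ++i) {
        const int s = nb_start[i];
        for (int k = 0; k < nb_len[i]; ++k) {
          const double d = u[i] - u[nb_flat[s + k]];
          ss += d * d;
        }
      }
      ss *= 0.5;  // each edge visited twice
      tau_u = R::rgamma(a_u + 0.5 * (n - 1), 1.0 / (b_u + 0.5 * ss));
    }
    if (sample_tau_v) {
      double ss = 0.0;
      for (int i = 0; i < n; ++i) ss += v[i] * v[i];
      tau_v = R::rgamma(a_v + 0.5 * n, 1.0 / (b_v + 0.5 * ss));
    }

    if (!R_finite(mu) || !R_finite(tau_u) || !R_finite(tau_v))
      stop("sampler diverged: non-finite state at iteration %d", t);

    if (t > burn_in && (t - burn_in) % thin == 0) {
      mu_out[kept] = mu;
      tau_u_out[kept] = tau_u;
      tau_v_out[kept] = tau_v;
      for (int i = 0; i < n; ++i) {
        u_out(kept, i) = u[i];
        v_out(kept, i) = v[i];
      }
      ++kept;
    }
  }

  return List::create(_["mu"] = mu_out, _["tau_u"] = tau_u_out,
                      _["tau_v"] = tau_v_out, _["u"] = u_out,
                      _["v"] = v_out);
}
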