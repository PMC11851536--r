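#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for the multi-class HBD HMM.
//
// States k = 0..S-1 with rate R_k (the last state is the non-HBD class by
// convention of the caller). Between adjacent markers at genetic distance
// d the transition matrix is
//   T(k,l) = exp(-R_k d) * 1[k == l] + (1 - exp(-R_k d)) * pi_l,
// a rank-one-plus-diagonal structure that allows O(S) updates.
//
// emis:  T x S emission probabilities (rows = markers).
// dist:  T-1 genetic distances (Morgans) between adjacent markers.
// rates: S state rates R_k.
// mix:   S mixing proportions pi (initial distribution).
//
// Returns gamma (T x S posterior), loglik, and `reset`: the expected
// number of transitions that re-draw the hidden state from pi and land
// in each state (the transition kernel is a mixture of "stay" with
// probability exp(-R_k d) and "re-draw from pi"). Together with the
// first marker's posterior these are the sufficient statistics for the
// exact EM update of pi.
// [[Rcpp::export(name = ".hbd_forward_backward_cpp")]]
List hbd_forward_backward_cpp(NumericMatrix emis, NumericVector dist,
                              NumericVector rates, NumericVector mix) {
  const int T = emis.nrow(), S = emis.ncol();
  if (dist.size() != T - 1) stop("need T-1 distances for T markers");
  if (rates.size() != S || mix.size() != S) stop("rates/mix length mismatch");

  NumericMatrix alpha(T, S), gamma(T, S);
  NumericVector scale(T);
  std::vector<double> q((T > 1 ? T - 1 : 0) * S);
  for (int t = 0; t + 1 < T; ++t)
    for (int k = 0; k < S; ++k)
      q[t * S + k] = std::exp(-rates[k] * dist[t]);

  // forward
  double c = 0.0;
  for (int k = 0; k < S; ++k) { alpha(0, k) = mix[k] * emis(0, k); c += alpha(0, k); }
  if (c <= 0.0) stop("zero forward likelihood at marker 1");
  for (int k = 0; k < S; ++k) alpha(0, k) /= c;
  scale[0] = c;
  for (int t = 1; t < T; ++t) {
    double leak = 0.0;
    for (int k = 0; k < S; ++k) leak += alpha(t - 1, k) * (1.0 - q[(t - 1) * S + k]);
    c = 0.0;
    for (int l = 0; l < S; ++l) {
      double pred = alpha(t - 1, l) * q[(t - 1) * S + l] + mix[l] * leak;
      alpha(t, l) = pred * emis(t, l);
      c += alpha(t, l);
    }
    if (c <= 0.0) stop("zero forward likelihood at marker %d", t + 1);
    for (int l = 0; l < S; ++l) alpha(t, l) /= c;
    scale[t] = c;
  }
  double loglik = 0.0;
  for (int t = 0; t < T; ++t) loglik += std::log(scale[t]);

  // backward (scaled by the forward constants); gamma = alpha * beta
  std::vector<double> beta(S, 1.0), bnew(S);
  NumericVector reset(S);
  for (int k = 0; k < S; ++k) gamma(T - 1, k) = alpha(T - 1, k);
  for (int t = T - 2; t >= 0; --t) {
    double v = 0.0;
    std::vector<double> u(S);
    for (int l = 0; l < S; ++l) {
      u[l] = emis(t + 1, l) * beta[l];
      v += mix[l] * u[l];
    }
    // xi summed over the source state, re-draw branch only:
    // sum_k alpha_t(k) (1 - q_k) * pi_l * u_l / c_{t+1}
    double leak = 0.0;
    for (int k = 0; k < S; ++k) leak += alpha(t, k) * (1.0 - q[t * S + k]);
    for (int l = 0; l < S; ++l)
      reset[l] += leak * mix[l] * u[l] / scale[t + 1];
    for (int k = 0; k < S; ++k)
      bnew[k] = (q[t * S + k] * u[k] + (1.0 - q[t * S + k]) * v) / scale[t + 1];
    beta = bnew;
    double rs = 0.0;
    for (int k = 0; k < S; ++k) { gamma(t, k) = alpha(t, k) * beta[k]; rs += gamma(t, k); }
    for (int k = 0; k < S; ++k) gamma(t, k) /= rs;  // guard rounding drift
  }
  return List::create(_["gamma"] = gamma, _["loglik"] = loglik,
                      _["reset"] = reset);
}
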