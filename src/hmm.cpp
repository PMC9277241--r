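#include <Rcpp.h>
using namespace Rcpp;

// Three-state HMM for step/turn series with covariate-dependent transition
// probabilities (multinomial logit, diagonal reference). Off-diagonal
// coefficient order (0-based rows): (0,1),(0,2),(1,0),(1,2),(2,0),(2,1).

static const int NS = 3;

static inline void trans_mat(const double* beta0, const double* betaz,
                             double z, double G[NS][NS]) {
  static const int pair_i[6] = {0, 0, 1, 1, 2, 2};
  static const int pair_j[6] = {1, 2, 0, 2, 0, 1};
  double E[NS][NS];
  for (int i = 0; i < NS; i++) E[i][i] = 1.0;
  for (int k = 0; k < 6; k++) {
    double eta = beta0[k] + betaz[k] * z;
    E[pair_i[k]][pair_j[k]] = std::exp(eta);
  }
  for (int i = 0; i < NS; i++) {
    double s = E[i][0] + E[i][1] + E[i][2];
    for (int j = 0; j < NS; j++) G[i][j] = E[i][j] / s;
  }
}

// Emission log-densities: gamma (mean/sd parametrized) for step with optional
// zero-step point mass pi0, von Mises for turn (skipped when NA).
static NumericMatrix emis_logmat(const NumericVector& step,
                                 const NumericVector& turn,
                                 const NumericVector& mu,
                                 const NumericVector& sigma,
                                 const NumericVector& pi0,
                                 const NumericVector& tmu,
                                 const NumericVector& kappa) {
  int T = step.size();
  NumericMatrix lp(T, NS);
  double shape[NS], rate[NS], cgam[NS], cvm[NS];
  for (int s = 0; s < NS; s++) {
    shape[s] = (mu[s] / sigma[s]) * (mu[s] / sigma[s]);
    rate[s] = mu[s] / (sigma[s] * sigma[s]);
    cgam[s] = shape[s] * std::log(rate[s]) - R::lgammafn(shape[s]);
    // log I0(kappa) via exponentially scaled Bessel for stability
    cvm[s] = -std::log(2.0 * M_PI) -
      (std::log(R::bessel_i(kappa[s], 0.0, 2.0)) + kappa[s]);
  }
  for (int t = 0; t < T; t++) {
    double x = step[t];
    for (int s = 0; s < NS; s++) {
      double l;
      if (x <= 0.0) {
        l = (pi0[s] > 0.0) ? std::log(pi0[s]) : R_NegInf;
      } else {
        l = cgam[s] + (shape[s] - 1.0) * std::log(x) - rate[s] * x;
        if (pi0[s] > 0.0) l += std::log1p(-pi0[s]);
      }
      if (!NumericVector::is_na(turn[t])) {
        l += kappa[s] * std::cos(turn[t] - tmu[s]) + kappa[s] * 0.0 + cvm[s];
      }
      lp(t, s) = l;
    }
  }
  return lp;
}

// [[Rcpp::export]]
double hmm_fwd_cpp(NumericVector step, NumericVector turn, NumericVector z,
                   LogicalVector seg_start, NumericVector mu,
                   NumericVector sigma, NumericVector pi0, NumericVector tmu,
                   NumericVector kappa, NumericVector beta0,
                   NumericVector betaz, NumericVector delta) {
  int T = step.size();
  NumericMatrix lp = emis_logmat(step, turn, mu, sigma, pi0, tmu, kappa);
  double ll = 0.0, a[NS], G[NS][NS];
  for (int t = 0; t < T; t++) {
    double m = std::max(lp(t, 0), std::max(lp(t, 1), lp(t, 2)));
    if (m == R_NegInf) return R_NegInf;
    double b[NS], ap[NS];
    for (int s = 0; s < NS; s++) b[s] = std::exp(lp(t, s) - m);
    if (seg_start[t]) {
      for (int s = 0; s < NS; s++) ap[s] = delta[s] * b[s];
    } else {
      trans_mat(beta0.begin(), betaz.begin(), z[t], G);
      for (int j = 0; j < NS; j++) {
        double acc = 0.0;
        for (int i = 0; i < NS; i++) acc += a[i] * G[i][j];
        ap[j] = acc * b[j];
      }
    }
    double c = ap[0] + ap[1] + ap[2];
    if (!(c > 0.0)) return R_NegInf;
    for (int s = 0; s < NS; s++) a[s] = ap[s] / c;
    ll += std::log(c) + m;
  }
  return ll;
}

// Forward-backward: returns log-likelihood and per-point posterior state
// probabilities (local decoding).
// [[Rcpp::export]]
List hmm_fb_cpp(NumericVector step, NumericVector turn, NumericVector z,
                LogicalVector seg_start, NumericVector mu, NumericVector sigma,
                NumericVector pi0, NumericVector tmu, NumericVector kappa,
                NumericVector beta0, NumericVector betaz, NumericVector delta) {
  int T = step.size();
  NumericMatrix lp = emis_logmat(step, turn, mu, sigma, pi0, tmu, kappa);
  NumericMatrix alpha(T, NS), beta(T, NS), post(T, NS);
  NumericVector cvec(T), mvec(T);
  double ll = 0.0, G[NS][NS];
  for (int t = 0; t < T; t++) {
    double m = std::max(lp(t, 0), std::max(lp(t, 1), lp(t, 2)));
    mvec[t] = m;
    double b[NS], ap[NS];
    for (int s = 0; s < NS; s++) b[s] = std::exp(lp(t, s) - m);
    if (seg_start[t]) {
      for (int s = 0; s < NS; s++) ap[s] = delta[s] * b[s];
    } else {
      trans_mat(beta0.begin(), betaz.begin(), z[t], G);
      for (int j = 0; j < NS; j++) {
        double acc = 0.0;
        for (int i = 0; i < NS; i++) acc += alpha(t - 1, i) * G[i][j];
        ap[j] = acc * b[j];
      }
    }
    double c = ap[0] + ap[1] + ap[2];
    cvec[t] = c;
    for (int s = 0; s < NS; s++) alpha(t, s) = ap[s] / c;
    ll += std::log(c) + m;
  }
  // backward, scaled with the same c
  for (int s = 0; s < NS; s++) beta(T - 1, s) = 1.0;
  for (int t = T - 2; t >= 0; t--) {
    if (seg_start[t + 1]) {
      for (int s = 0; s < NS; s++) beta(t, s) = 1.0;
      continue;
    }
    trans_mat(beta0.begin(), betaz.begin(), z[t + 1], G);
    double b[NS];
    for (int s = 0; s < NS; s++) b[s] = std::exp(lp(t + 1, s) - mvec[t + 1]);
    for (int i = 0; i < NS; i++) {
      double acc = 0.0;
      for (int j = 0; j < NS; j++) acc += G[i][j] * b[j] * beta(t + 1, j);
      beta(t, i) = acc / cvec[t + 1];
    }
  }
  for (int t = 0; t < T; t++) {
    double s3 = 0.0;
    for (int s = 0; s < NS; s++) s3 += alpha(t, s) * beta(t, s);
    for (int s = 0; s < NS; s++) post(t, s) = alpha(t, s) * beta(t, s) / s3;
  }
  return List::create(Named("loglik") = ll, Named("posterior") = post);
}

// Viterbi decoding; ties broken toward the lowest state index.
// [[Rcpp::export]]
IntegerVector hmm_viterbi_cpp(NumericVector step, NumericVector turn,
                              NumericVector z, LogicalVector seg_start,
                              NumericVector mu, NumericVector sigma,
                              NumericVector pi0, NumericVector tmu,
                              NumericVector kappa, NumericVector beta0,
                              NumericVector betaz, NumericVector delta) {
  int T = step.size();
  NumericMatrix lp = emis_logmat(step, turn, mu, sigma, pi0, tmu, kappa);
  NumericMatrix v(T, NS);
  IntegerMatrix bp(T, NS);
  double G[NS][NS];
  for (int t = 0; t < T; t++) {
    if (seg_start[t]) {
      for (int s = 0; s < NS; s++) {
        v(t, s) = std::log(delta[s]) + lp(t, s);
        bp(t, s) = -1;
      }
      continue;
    }
    trans_mat(beta0.begin(), betaz.begin(), z[t], G);
    for (int j = 0; j < NS; j++) {
      double best = R_NegInf;
      int arg = 0;
      for (int i = 0; i < NS; i++) {
        double cand = v(t - 1, i) + std::log(G[i][j]);
        if (cand > best) { best = cand; arg = i; }
      }
      v(t, j) = best + lp(t, j);
      bp(t, j) = arg;
    }
  }
  IntegerVector path(T);
  // trace back segment by segment
  int t = T - 1;
  while (t >= 0) {
    int send = t;
    while (!seg_start[send]) send--; // segment start
    double best = R_NegInf;
    int arg = 0;
    for (int s = 0; s < NS; s++) {
      if (v(t, s) > best) { best = v(t, s); arg = s; }
    }
    path[t] = arg;
    for (int u = t; u > send; u--) path[u - 1] = bp(u, path[u]);
    t = send - 1;
  }
  return path + 1; // 1-based states
}
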