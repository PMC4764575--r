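// Hidden state-path samplers for the switching autoregressive model.
// States are 0-based here: 0="++", 1="+-", 2="-+", 3="--"; sister 1's state
// is '+' for 0,1 and sister 2's is '+' for 0,2. Exactly one sister may flip
// per frame, so the transition matrix has zero entries for double flips.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

inline bool coh(int s) { return s == 1 || s == 2; }
inline int flip1(int s) { return s ^ 2; }
inline int flip2(int s) { return s ^ 1; }

void trans_matrix(double p_inc, double p_coh, double M[4][4]) {
  for (int s = 0; s < 4; ++s) {
    double p = coh(s) ? p_coh : p_inc;
    for (int t = 0; t < 4; ++t) M[s][t] = 0.0;
    M[s][s] = 1.0 - p;
    M[s][flip1(s)] += p / 2.0;
    M[s][flip2(s)] += p / 2.0;
  }
}

// Emission weights for frame t over the 4 states, scaled so max = 1.
void emission(int t, const NumericVector& dx1, const NumericVector& dx2,
              const NumericVector& x1, const NumericVector& x2,
              double a, double b, double c0, double cp, double cm,
              double inv2s2, double w[4]) {
  double m1 = -a * x1[t] + b * x2[t];
  double m2 = -a * x2[t] + b * x1[t];
  double r1p = dx1[t] - (c0 + cp + m1);
  double r1m = dx1[t] - (c0 + cm + m1);
  double r2p = dx2[t] - (-c0 - cp + m2);
  double r2m = dx2[t] - (-c0 - cm + m2);
  double ll[4];
  ll[0] = -(r1p * r1p + r2p * r2p) * inv2s2;
  ll[1] = -(r1p * r1p + r2m * r2m) * inv2s2;
  ll[2] = -(r1m * r1m + r2p * r2p) * inv2s2;
  ll[3] = -(r1m * r1m + r2m * r2m) * inv2s2;
  double mx = std::max(std::max(ll[0], ll[1]), std::max(ll[2], ll[3]));
  for (int s = 0; s < 4; ++s) w[s] = std::exp(ll[s] - mx);
}

int sample4(const double p[4]) {
  double tot = p[0] + p[1] + p[2] + p[3];
  double u = unif_rand() * tot;
  double c = 0.0;
  for (int s = 0; s < 3; ++s) {
    c += p[s];
    if (u <= c) return s;
  }
  return 3;
}

}  // namespace

// Blocked forward-filter / backward-sample draw of the full state path from
// its exact conditional given parameters and data.
// [[Rcpp::export(name = ".ks_ffbs_cpp")]]
IntegerVector ks_ffbs(NumericVector dx1, NumericVector dx2,
                      NumericVector x1, NumericVector x2,
                      double a, double b, double c0, double cp, double cm,
                      double s2, double p_inc, double p_coh) {
  const int L = dx1.size();
  double M[4][4];
  trans_matrix(p_inc, p_coh, M);
  const double inv2s2 = 1.0 / (2.0 * s2);
  NumericMatrix A(L, 4);
  double w[4];

  emission(0, dx1, dx2, x1, x2, a, b, c0, cp, cm, inv2s2, w);
  double norm = 0.0;
  for (int s = 0; s < 4; ++s) { A(0, s) = 0.25 * w[s]; norm += A(0, s); }
  for (int s = 0; s < 4; ++s) A(0, s) /= norm;

  for (int t = 1; t < L; ++t) {
    emission(t, dx1, dx2, x1, x2, a, b, c0, cp, cm, inv2s2, w);
    norm = 0.0;
    for (int s = 0; s < 4; ++s) {
      double pred = 0.0;
      for (int r = 0; r < 4; ++r) pred += A(t - 1, r) * M[r][s];
      A(t, s) = pred * w[s];
      norm += A(t, s);
    }
    if (norm <= 0.0) {  // numerically stranded; fall back to filter-free
      for (int s = 0; s < 4; ++s) A(t, s) = w[s];
      norm = w[0] + w[1] + w[2] + w[3];
    }
    for (int s = 0; s < 4; ++s) A(t, s) /= norm;
  }

  IntegerVector path(L);
  double p[4];
  for (int s = 0; s < 4; ++s) p[s] = A(L - 1, s);
  path[L - 1] = sample4(p);
  for (int t = L - 2; t >= 0; --t) {
    for (int s = 0; s < 4; ++s) p[s] = A(t, s) * M[s][path[t + 1]];
    path[t] = sample4(p);
  }
  for (int t = 0; t < L; ++t) path[t] += 1;  // back to R's 1-based codes
  return path;
}

// One single-site Gibbs sweep over the path: each frame's state is redrawn
// from its full conditional given the neighbouring frames, sequentially.
// [[Rcpp::export(name = ".ks_gibbs_sweep_cpp")]]
IntegerVector ks_gibbs_sweep(NumericVector dx1, NumericVector dx2,
                             NumericVector x1, NumericVector x2,
                             double a, double b, double c0, double cp,
                             double cm, double s2, double p_inc,
                             double p_coh, IntegerVector path0) {
  const int L = dx1.size();
  double M[4][4];
  trans_matrix(p_inc, p_coh, M);
  const double inv2s2 = 1.0 / (2.0 * s2);
  IntegerVector path = clone(path0);
  for (int t = 0; t < L; ++t) path[t] -= 1;

  double w[4], p[4];
  for (int t = 0; t < L; ++t) {
    emission(t, dx1, dx2, x1, x2, a, b, c0, cp, cm, inv2s2, w);
    double tot = 0.0;
    for (int s = 0; s < 4; ++s) {
      double pr = (t == 0) ? 0.25 : M[path[t - 1]][s];
      double nx = (t == L - 1) ? 1.0 : M[s][path[t + 1]];
      p[s] = pr * w[s] * nx;
      tot += p[s];
    }
    if (tot <= 0.0) continue;  // keep current state if stranded
    path[t] = sample4(p);
  }
  for (int t = 0; t < L; ++t) path[t] += 1;
  return path;
}
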