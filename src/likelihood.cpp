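#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// S1-model Bernoulli log-likelihood machinery. The connection probability of
// a pair is p = 1 / (1 + chi^beta) with chi = R * dtheta / (mu * kappa_i *
// kappa_j); working with t = beta * log(chi), log p = -log1p(exp(t)) and
// log(1 - p) = t - log1p(exp(t)). t is clamped so p stays inside
// [~1e-12, 1 - 1e-12].

static const double TMAX = 27.631021; // log(1e12)

static inline double ang_sep(double a, double b) {
  // angles arrive wrapped to [0, 2*pi), so |a - b| < 2*pi already
  double d = std::fabs(a - b);
  while (d >= 2.0 * M_PI) d -= 2.0 * M_PI;
  return d > M_PI ? 2.0 * M_PI - d : d;
}

// log-likelihood contribution of pair with separation dt, adjacency a
static inline double pair_ll(double dt, double lconst, double beta, bool a) {
  // lconst = log(R) - log(mu * kappa_i * kappa_j)
  double t;
  if (dt <= 0.0)
    t = -TMAX;
  else {
    t = beta * (std::log(dt) + lconst);
    if (t > TMAX) t = TMAX;
    if (t < -TMAX) t = -TMAX;
  }
  double l1p = (t > 0.0) ? t + std::log1p(std::exp(-t)) : std::log1p(std::exp(t));
  return a ? -l1p : t - l1p;
}

static std::vector<bool> adj_bits(int n, const IntegerMatrix& edges) {
  std::vector<bool> A((size_t)n * n, false);
  for (int e = 0; e < edges.nrow(); ++e) {
    int i = edges(e, 0) - 1, j = edges(e, 1) - 1;
    A[(size_t)i * n + j] = true;
    A[(size_t)j * n + i] = true;
  }
  return A;
}

// [[Rcpp::export(name = ".s1_loglik_cpp")]]
double s1_loglik_cpp(NumericVector theta, NumericVector lkap,
                     IntegerMatrix edges, double beta, double lmuR) {
  // lmuR = log(R) - log(mu); lkap = log(kappa)
  int n = theta.size();
  std::vector<bool> A = adj_bits(n, edges);
  double ll = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dt = ang_sep(theta[i], theta[j]);
      ll += pair_ll(dt, lmuR - lkap[i] - lkap[j], beta, A[(size_t)i * n + j]);
    }
  return ll;
}

// One coordinate-wise sweep: for each node (in the given order) evaluate the
// current angle plus the proposed candidate angles against all other nodes
// and keep the best. Returns the updated angles and the total log-likelihood.
// [[Rcpp::export(name = ".s1_sweep_cpp")]]
List s1_sweep_cpp(NumericVector theta, NumericVector lkap,
                  IntegerMatrix edges, double beta, double lmuR,
                  NumericMatrix proposals, IntegerVector order) {
  int n = theta.size();
  int C = proposals.ncol();
  std::vector<bool> A = adj_bits(n, edges);
  NumericVector th = clone(theta);
  for (int oi = 0; oi < order.size(); ++oi) {
    int i = order[oi] - 1;
    double best_ll = 0.0, best_th = th[i];
    // candidate 0 = current angle, then the proposals
    for (int c = -1; c < C; ++c) {
      double cand = (c < 0) ? th[i] : proposals(i, c);
      double ll = 0.0;
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        double dt = ang_sep(cand, th[j]);
        ll += pair_ll(dt, lmuR - lkap[i] - lkap[j], beta,
                      A[(size_t)i * n + j]);
      }
      if (c < 0 || ll > best_ll) { best_ll = ll; best_th = cand; }
    }
    th[i] = best_th;
  }
  double total = s1_loglik_cpp(th, lkap, edges, beta, lmuR);
  return List::create(Named("theta") = th, Named("loglik") = total);
}
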