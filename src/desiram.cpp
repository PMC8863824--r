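// Hot loops for the six-line template fit and the tethered-cell simulator.
#include <RcppArmadillo.h>
using namespace Rcpp;

// Piecewise-linear template value at time t (t >= t1 region), parameters
// levels = (r, v3, v4, v5), breakpoints derived from t1 and durations d.
// Returns the 4 basis weights so the model is linear in the levels.
static inline void post_basis(double t, double t1, const double *d,
                              double *w) {
  const double t2 = t1 + d[0], t3 = t2 + d[1], t4 = t3 + d[2], t5 = t4 + d[3];
  w[0] = w[1] = w[2] = w[3] = 0.0;
  if (t <= t2) {
    w[0] = 1.0;                      // L2 flat at r, left-closed at t1
  } else if (t <= t3) {
    double a = (t3 > t2) ? (t - t2) / (t3 - t2) : 1.0;
    w[0] = 1.0 - a; w[1] = a;        // L3: r -> v3
  } else if (t <= t4) {
    double a = (t4 > t3) ? (t - t3) / (t4 - t3) : 1.0;
    w[1] = 1.0 - a; w[2] = a;        // L4: v3 -> v4
  } else if (t <= t5) {
    double a = (t5 > t4) ? (t - t4) / (t5 - t4) : 1.0;
    w[2] = 1.0 - a; w[3] = a;        // L5: v4 -> v5
  } else {
    w[3] = 1.0;                      // L6 flat at g = v5
  }
}

// Box-constrained least squares for the 4 level parameters given fixed
// breakpoints: unconstrained normal-equation solve, clipped, then cyclic
// coordinate descent (exact for a quadratic with box constraints).
static double solve_levels(const arma::mat &X, const arma::vec &y,
                           const double *lo, const double *hi,
                           arma::vec &beta) {
  arma::mat A = X.t() * X;
  A.diag() += 1e-8;                  // keeps degenerate (empty-segment) params benign
  arma::vec b = X.t() * y;
  beta = arma::solve(A, b, arma::solve_opts::fast);
  bool inside = true;
  for (int k = 0; k < 4; ++k) {
    if (beta[k] < lo[k]) { beta[k] = lo[k]; inside = false; }
    if (beta[k] > hi[k]) { beta[k] = hi[k]; inside = false; }
  }
  if (!inside) {
    for (int sweep = 0; sweep < 60; ++sweep) {
      double delta = 0.0;
      for (int k = 0; k < 4; ++k) {
        double num = b[k];
        for (int j = 0; j < 4; ++j) if (j != k) num -= A(k, j) * beta[j];
        double cand = num / A(k, k);
        if (cand < lo[k]) cand = lo[k];
        if (cand > hi[k]) cand = hi[k];
        delta += std::fabs(cand - beta[k]);
        beta[k] = cand;
      }
      if (delta < 1e-12) break;
    }
  }
  arma::vec res = y - X * beta;
  return arma::dot(res, res);
}

// [[Rcpp::export]]
List template_rss_cpp(NumericVector t, NumericVector y, double t1,
                      NumericVector d, double b_level, double r_max) {
  const int n = t.size();
  double dd[4] = {d[0], d[1], d[2], d[3]};
  // pre-stimulus residuals against the fixed baseline level
  double rss_pre = 0.0;
  int n_post = 0;
  for (int i = 0; i < n; ++i) {
    if (t[i] < t1) { double e = y[i] - b_level; rss_pre += e * e; }
    else ++n_post;
  }
  arma::mat X(n_post, 4);
  arma::vec yy(n_post);
  double w[4];
  int j = 0;
  for (int i = 0; i < n; ++i) {
    if (t[i] < t1) continue;
    post_basis(t[i], t1, dd, w);
    for (int k = 0; k < 4; ++k) X(j, k) = w[k];
    yy[j] = y[i];
    ++j;
  }
  double lo[4] = {0.0, 0.0, 0.0, 0.0};
  double hi[4] = {std::min(r_max, b_level), 1.0, 1.0, 1.0};
  arma::vec beta(4, arma::fill::zeros);
  double rss_post = (n_post > 0) ? solve_levels(X, yy, lo, hi, beta) : 0.0;
  return List::create(_["rss"] = rss_pre + rss_post,
                      _["levels"] = NumericVector::create(beta[0], beta[1],
                                                          beta[2], beta[3]));
}

// [[Rcpp::export]]
List template_grid_cpp(NumericVector t, NumericVector y, double t1,
                       NumericVector d2_grid, NumericVector d3_grid,
                       NumericVector d4_grid, NumericVector d5_grid,
                       double b_level, double r_max, double t_max) {
  double best_rss = R_PosInf;
  NumericVector best_d(4);
  for (double d2 : d2_grid) {
    for (double d3 : d3_grid) {
      for (double d4 : d4_grid) {
        for (double d5 : d5_grid) {
          if (t1 + d2 + d3 + d4 + d5 > t_max + 1e-9) continue;
          NumericVector d = NumericVector::create(d2, d3, d4, d5);
          List fit = template_rss_cpp(t, y, t1, d, b_level, r_max);
          double rss = fit["rss"];
          if (rss < best_rss) {
            best_rss = rss;
            best_d = d;
          }
        }
      }
    }
  }
  return List::create(_["rss"] = best_rss, _["d"] = best_d);
}

// Two-state (CW/CCW) switching simulation at frame resolution with a
// time-varying target CW probability and a forced-CCW excitation window.
// Mean run length dwell_mean is split so the stationary CW fraction matches
// the target: tau_CW = 2 * dwell_mean * p, tau_CCW = 2 * dwell_mean * (1-p).
// The target schedule is the cell's own: baseline p_c before the stimulus,
// forced CCW for tau_c seconds, then a piecewise-linear recovery from 0
// through node levels rec_lvl at cumulative times rec_dur, flat thereafter.
// Labels: 0 = CW, 1 = CCW, 2 = NONE. Uses R's RNG (respects set.seed()).
// [[Rcpp::export]]
IntegerVector simulate_cell_cpp(int n, double frame_interval, double p_c,
                                double tau_c, double stim_time,
                                NumericVector rec_dur, NumericVector rec_lvl,
                                double dwell_mean, double none_prob) {
  IntegerVector out(n);
  RNGScope scope;
  const double t_r0 = stim_time + tau_c;
  const int n_nodes = rec_dur.size();
  int state = (unif_rand() < p_c) ? 0 : 1;  // 0 = CW, 1 = CCW
  for (int i = 0; i < n; ++i) {
    double t = i * frame_interval;
    bool forced = false;
    double p = p_c;
    if (tau_c > 0.0 && t >= stim_time) {
      if (t < t_r0) {
        forced = true;
      } else {
        double tr = t - t_r0;
        double prev_t = 0.0, prev_l = 0.0;
        p = rec_lvl[n_nodes - 1];  // beyond the last node
        for (int k = 0; k < n_nodes; ++k) {
          if (tr <= rec_dur[k]) {
            double span = rec_dur[k] - prev_t;
            p = (span > 0.0)
              ? prev_l + (rec_lvl[k] - prev_l) * (tr - prev_t) / span
              : rec_lvl[k];
            break;
          }
          prev_t = rec_dur[k];
          prev_l = rec_lvl[k];
        }
      }
    }
    if (forced) {
      state = 1;
    } else {
      double tau = (state == 0) ? 2.0 * dwell_mean * p
                                : 2.0 * dwell_mean * (1.0 - p);
      double p_leave = (tau <= 0.0) ? 1.0 : std::min(1.0, frame_interval / tau);
      if (unif_rand() < p_leave) state = 1 - state;
    }
    out[i] = (none_prob > 0.0 && unif_rand() < none_prob) ? 2 : state;
  }
  return out;
}
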