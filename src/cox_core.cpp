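#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Cox partial-likelihood internals. All entry points require samples sorted
// by increasing follow-up time; risk sets are suffix sets of that ordering,
// with samples censored at an event time kept in the risk set (standard
// convention). Efron's correction handles tied event times; with phi = l/d
// forced to 0 the same code gives Breslow. Linear predictors are centered
// at their maximum before exponentiation, so risk-set sums never overflow;
// all reported quantities are invariant to that shift.

// [[Rcpp::export]]
double cox_loglik_cpp(NumericVector eta, NumericVector time,
                      IntegerVector event, bool efron) {
  int n = eta.size();
  if (n == 0) return 0.0;
  double m = eta[0];
  for (int i = 1; i < n; i++) if (eta[i] > m) m = eta[i];

  double ll = 0.0, S = 0.0;
  int i = n - 1;
  while (i >= 0) {
    double t = time[i];
    double s = 0.0, sum_eta = 0.0;
    int d = 0, j = i;
    while (j >= 0 && time[j] == t) {
      double r = std::exp(eta[j] - m);
      S += r;
      if (event[j] == 1) { d++; s += r; sum_eta += eta[j] - m; }
      j--;
    }
    if (d > 0) {
      ll += sum_eta;
      for (int l = 0; l < d; l++) {
        double phi = efron ? (double)l / d : 0.0;
        ll -= std::log(S - phi * s);
      }
    }
    i = j;
  }
  return ll;
}

// Log partial likelihood, score vector and observed information matrix.
// [[Rcpp::export]]
List cox_ll_grad_info_cpp(NumericMatrix X, NumericVector eta,
                          NumericVector time, IntegerVector event,
                          bool efron) {
  int n = X.nrow(), p = X.ncol();
  double m = eta[0];
  for (int i = 1; i < n; i++) if (eta[i] > m) m = eta[i];

  double ll = 0.0, S = 0.0;
  NumericVector grad(p);
  NumericMatrix info(p, p);
  std::vector<double> Sx(p, 0.0), Sxx(p * p, 0.0);

  int i = n - 1;
  while (i >= 0) {
    double t = time[i];
    double s = 0.0, sum_eta = 0.0;
    std::vector<double> sx(p, 0.0), sxx(p * p, 0.0), sumx(p, 0.0);
    int d = 0, j = i;
    while (j >= 0 && time[j] == t) {
      double r = std::exp(eta[j] - m);
      S += r;
      for (int a = 0; a < p; a++) {
        double xa = X(j, a);
        Sx[a] += r * xa;
        for (int b = 0; b <= a; b++) Sxx[a * p + b] += r * xa * X(j, b);
      }
      if (event[j] == 1) {
        d++; s += r; sum_eta += eta[j] - m;
        for (int a = 0; a < p; a++) {
          double xa = X(j, a);
          sumx[a] += xa;
          sx[a] += r * xa;
          for (int b = 0; b <= a; b++) sxx[a * p + b] += r * xa * X(j, b);
        }
      }
      j--;
    }
    if (d > 0) {
      ll += sum_eta;
      for (int a = 0; a < p; a++) grad[a] += sumx[a];
      std::vector<double> g(p);
      for (int l = 0; l < d; l++) {
        double phi = efron ? (double)l / d : 0.0;
        double denom = S - phi * s;
        ll -= std::log(denom);
        for (int a = 0; a < p; a++) {
          g[a] = (Sx[a] - phi * sx[a]) / denom;
          grad[a] -= g[a];
        }
        for (int a = 0; a < p; a++)
          for (int b = 0; b <= a; b++)
            info(a, b) += (Sxx[a * p + b] - phi * sxx[a * p + b]) / denom -
                          g[a] * g[b];
      }
    }
    i = j;
  }
  for (int a = 0; a < p; a++)
    for (int b = 0; b < a; b++) info(b, a) = info(a, b);
  return List::create(_["loglik"] = ll, _["score"] = grad,
                      _["info"] = info);
}

// Per-sample first derivative g_i = d ll / d eta_i and diagonal curvature
// w_i = -d^2 ll / d eta_i^2, used as IRLS working quantities for the
// penalized fit. Group accumulators: q1 = sum_l 1/denom, q2 = sum_l
// 1/denom^2, and for event members of the group the phi-weighted analogues.
// [[Rcpp::export]]
List cox_grad_weight_cpp(NumericVector eta, NumericVector time,
                         IntegerVector event, bool efron) {
  int n = eta.size();
  double m = eta[0];
  for (int i = 1; i < n; i++) if (eta[i] > m) m = eta[i];

  std::vector<double> gt, gq1, gq2, ge1, ge2, ge3;
  double S = 0.0;
  int i = n - 1;
  while (i >= 0) {
    double t = time[i];
    double s = 0.0;
    int d = 0, j = i;
    while (j >= 0 && time[j] == t) {
      double r = std::exp(eta[j] - m);
      S += r;
      if (event[j] == 1) { d++; s += r; }
      j--;
    }
    if (d > 0) {
      double q1 = 0, q2 = 0, e1 = 0, e2 = 0, e3 = 0;
      for (int l = 0; l < d; l++) {
        double phi = efron ? (double)l / d : 0.0;
        double denom = S - phi * s;
        q1 += 1.0 / denom;
        q2 += 1.0 / (denom * denom);
        e1 += phi / denom;
        e2 += phi / (denom * denom);
        e3 += phi * phi / (denom * denom);
      }
      gt.push_back(t); gq1.push_back(q1); gq2.push_back(q2);
      ge1.push_back(e1); ge2.push_back(e2); ge3.push_back(e3);
    }
    i = j;
  }
  // groups were collected in decreasing time order; walk them ascending
  int ng = gt.size();
  NumericVector g(n), w(n);
  double cumA = 0.0, cumB = 0.0;
  int k = ng - 1;  // next group to absorb (smallest time first)
  double lastE1 = 0.0, lastE2 = 0.0, lastE3 = 0.0;
  double lastT = -1.0; bool haveGroup = false;
  for (int idx = 0; idx < n; idx++) {
    while (k >= 0 && gt[k] <= time[idx]) {
      cumA += gq1[k]; cumB += gq2[k];
      lastE1 = ge1[k]; lastE2 = ge2[k]; lastE3 = ge3[k];
      lastT = gt[k]; haveGroup = true;
      k--;
    }
    double A = cumA, B = cumB;
    if (event[idx] == 1 && haveGroup && time[idx] == lastT) {
      // event member of its own tie group: phi-weighted self-adjustment
      A -= lastE1;
      B -= 2.0 * lastE2 - lastE3;
    }
    double r = std::exp(eta[idx] - m);
    g[idx] = (event[idx] == 1 ? 1.0 : 0.0) - r * A;
    w[idx] = r * A - r * r * B;
  }
  return List::create(_["grad"] = g, _["weight"] = w);
}

// Cyclic coordinate descent for the L1-penalized weighted least-squares
// subproblem: minimize (1/2) sum_i v_i (z_i - x_i'b)^2 + lambda * ||b||_1.
// Full sweeps alternate with active-set sweeps until the largest single
// coefficient update falls below tol.
// [[Rcpp::export]]
List cd_wls_lasso_cpp(NumericMatrix X, NumericVector z, NumericVector v,
                      double lambda, NumericVector beta0, double tol,
                      int maxit) {
  int n = X.nrow(), p = X.ncol();
  NumericVector beta = clone(beta0);
  std::vector<double> r(n), xv(p, 0.0);
  for (int i = 0; i < n; i++) {
    double fit = 0.0;
    for (int j = 0; j < p; j++) if (beta[j] != 0.0) fit += X(i, j) * beta[j];
    r[i] = z[i] - fit;
  }
  for (int j = 0; j < p; j++) {
    double s = 0.0;
    for (int i = 0; i < n; i++) s += v[i] * X(i, j) * X(i, j);
    xv[j] = s;
  }
  std::vector<bool> active(p);
  for (int j = 0; j < p; j++) active[j] = beta[j] != 0.0;

  auto update = [&](int j) -> double {
    if (xv[j] <= 0.0) return 0.0;
    double u = xv[j] * beta[j];
    for (int i = 0; i < n; i++) u += v[i] * X(i, j) * r[i];
    double bn = 0.0;
    if (u > lambda) bn = (u - lambda) / xv[j];
    else if (u < -lambda) bn = (u + lambda) / xv[j];
    double delta = bn - beta[j];
    if (delta != 0.0) {
      for (int i = 0; i < n; i++) r[i] -= delta * X(i, j);
      beta[j] = bn;
      active[j] = bn != 0.0;
    }
    return std::fabs(delta);
  };

  int it = 0;
  bool converged = false;
  while (it < maxit) {
    double maxd = 0.0;
    for (int j = 0; j < p; j++) {
      double d = update(j);
      if (d > maxd) maxd = d;
    }
    it++;
    if (maxd < tol) { converged = true; break; }
    while (it < maxit) {
      double d2 = 0.0;
      for (int j = 0; j < p; j++) {
        if (!active[j]) continue;
        double d = update(j);
        if (d > d2) d2 = d;
      }
      it++;
      if (d2 < tol) break;
    }
  }
  return List::create(_["beta"] = beta, _["iterations"] = it,
                      _["converged"] = converged);
}

// Full warm-started lasso path on standardized covariates. Per lambda:
// sequential strong-rule screening (|u_j| >= 2*lam_k - lam_{k-1} at the
// previous solution) restricts the working set; IRLS with coordinate
// descent runs on that set; a final KKT sweep over all coordinates admits
// any violators and repeats. The working residual identity z - Xb = g/w
// at the start of each weighted subproblem and eta = z - r at its end
// avoid explicit matrix-vector products.
// [[Rcpp::export]]
List lasso_cox_path_cpp(NumericMatrix X, NumericVector time,
                        IntegerVector event, bool efron,
                        NumericVector lambda, double lambda_max,
                        double outer_tol, double inner_tol,
                        int max_outer, int max_inner) {
  int n = X.nrow(), p = X.ncol(), nlam = lambda.size();
  NumericMatrix betas(p, nlam);
  LogicalVector conv(nlam);
  std::vector<double> b(p, 0.0), r(n), z(n), v(n), xv(p), u(p);
  NumericVector eta(n);
  std::vector<bool> work(p, false);

  auto grad_at_eta = [&](std::vector<double> &out) {
    List gw = cox_grad_weight_cpp(eta, time, event, efron);
    NumericVector g = gw["grad"];
    for (int j = 0; j < p; j++) {
      double s = 0.0;
      for (int i = 0; i < n; i++) s += X(i, j) * g[i];
      out[j] = s / n;
    }
  };
  auto objective = [&](double lam) {
    double pen = 0.0;
    for (int j = 0; j < p; j++) pen += std::fabs(b[j]);
    return -cox_loglik_cpp(eta, time, event, efron) / n + lam * pen;
  };

  double prev_lam = lambda_max;
  for (int k = 0; k < nlam; k++) {
    double lam = lambda[k];
    bool allzero = true;
    for (int j = 0; j < p; j++) if (b[j] != 0.0) { allzero = false; break; }
    if (allzero && lam >= lambda_max * (1.0 - 1e-10)) {
      conv[k] = true;  // KKT: zero is exact at and above lambda_max
      prev_lam = lam;
      continue;
    }
    grad_at_eta(u);
    for (int j = 0; j < p; j++)
      work[j] = (b[j] != 0.0) || (std::fabs(u[j]) >= 2.0 * lam - prev_lam);
    bool kkt_ok = false, outer_conv = false;
    while (!kkt_ok) {
      double o_old = objective(lam);
      outer_conv = false;
      for (int it = 0; it < max_outer; it++) {
        List gw = cox_grad_weight_cpp(eta, time, event, efron);
        NumericVector g = gw["grad"], w = gw["weight"];
        for (int i = 0; i < n; i++) {
          double wi = w[i] > 1e-9 ? w[i] : 1e-9;
          v[i] = wi / n;
          r[i] = g[i] / wi;          // z - X b at the current b
          z[i] = eta[i] + r[i];
        }
        for (int j = 0; j < p; j++) {
          if (!work[j]) continue;
          double s = 0.0;
          for (int i = 0; i < n; i++) s += v[i] * X(i, j) * X(i, j);
          xv[j] = s;
        }
        for (int sweep = 0; sweep < max_inner; sweep++) {
          double maxd = 0.0;
          for (int j = 0; j < p; j++) {
            if (!work[j] || xv[j] <= 0.0) continue;
            double uj = xv[j] * b[j];
            for (int i = 0; i < n; i++) uj += v[i] * X(i, j) * r[i];
            double bn = 0.0;
            if (uj > lam) bn = (uj - lam) / xv[j];
            else if (uj < -lam) bn = (uj + lam) / xv[j];
            double delta = bn - b[j];
            if (delta != 0.0) {
              for (int i = 0; i < n; i++) r[i] -= delta * X(i, j);
              b[j] = bn;
            }
            double ad = std::fabs(delta);
            if (ad > maxd) maxd = ad;
          }
          if (maxd < inner_tol) break;
        }
        for (int i = 0; i < n; i++) eta[i] = z[i] - r[i];
        double o_new = objective(lam);
        if (std::fabs(o_old - o_new) <
            outer_tol * (std::fabs(o_old) + 1e-10)) {
          outer_conv = true;
          break;
        }
        o_old = o_new;
      }
      grad_at_eta(u);
      kkt_ok = true;
      for (int j = 0; j < p; j++) {
        if (!work[j] && std::fabs(u[j]) > lam + 1e-12) {
          work[j] = true;
          kkt_ok = false;
        }
      }
    }
    for (int j = 0; j < p; j++) betas(j, k) = b[j];
    conv[k] = outer_conv;
    prev_lam = lam;
  }
  return List::create(_["beta"] = betas, _["converged"] = conv);
}
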