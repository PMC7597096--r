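#include <Rcpp.h>
using namespace Rcpp;

// Penalty families share integer codes with the R side: 0 lasso, 1 scad, 2 mcp.

static double penalty1(double t, int family, double lam, double a, double g) {
  t = std::fabs(t);
  switch (family) {
  case 0:
    return lam * t;
  case 1:
    if (t <= lam) return lam * t;
    if (t <= a * lam)
      return -(t * t - 2.0 * a * lam * t + lam * lam) / (2.0 * (a - 1.0));
    return (a + 1.0) * lam * lam / 2.0;
  default:
    if (t <= g * lam) return lam * t - t * t / (2.0 * g);
    return g * lam * lam / 2.0;
  }
}

// Exact scalar minimizer of (kappa/2)(theta - z)^2 + rho_lambda(theta).
// Candidate enumeration over branch stationary points and knots; handles the
// nonconvex case (kappa below the penalty's concavity), ties -> smaller |theta|.
static double prox1(double z, int family, double lam, double a, double g,
                    double kappa) {
  double s = (z < 0) ? -1.0 : 1.0;
  z = std::fabs(z);
  if (lam == 0.0) return s * z;
  double cand[6];
  int nc = 0;
  if (family == 0) {
    double t = z - lam / kappa;
    return s * (t > 0 ? t : 0.0);
  } else if (family == 1) {
    double c1 = z - lam / kappa;
    if (c1 < 0) c1 = 0; else if (c1 > lam) c1 = lam;
    cand[nc++] = 0.0;
    cand[nc++] = c1;
    cand[nc++] = lam;
    cand[nc++] = a * lam;
    double k2 = kappa - 1.0 / (a - 1.0);
    if (k2 > 0) {
      double c2 = (kappa * z - a * lam / (a - 1.0)) / k2;
      if (c2 < lam) c2 = lam; else if (c2 > a * lam) c2 = a * lam;
      cand[nc++] = c2;
    }
    if (z > a * lam) cand[nc++] = z;
  } else {
    cand[nc++] = 0.0;
    cand[nc++] = g * lam;
    double k1 = kappa - 1.0 / g;
    if (k1 > 0) {
      double c1 = (kappa * z - lam) / k1;
      if (c1 < 0) c1 = 0; else if (c1 > g * lam) c1 = g * lam;
      cand[nc++] = c1;
    }
    if (z > g * lam) cand[nc++] = z;
  }
  double best_t = cand[0];
  double best_val = kappa / 2.0 * (best_t - z) * (best_t - z) +
    penalty1(best_t, family, lam, a, g);
  for (int i = 1; i < nc; ++i) {
    double t = cand[i];
    double v = kappa / 2.0 * (t - z) * (t - z) + penalty1(t, family, lam, a, g);
    double tolv = 1e-12 * (best_val > 1.0 ? best_val : 1.0);
    if (v < best_val - tolv ||
        (v <= best_val + tolv && std::fabs(t) < std::fabs(best_t))) {
      best_val = v;
      best_t = t;
    }
  }
  return s * best_t;
}

// [[Rcpp::export]]
double cd_prox(double z, int family, double lam, double a, double gamma,
               double kappa) {
  return prox1(z, family, lam, a, gamma, kappa);
}

// Cyclic coordinate descent over a decreasing lambda grid with warm starts.
// Objective per lambda: loss_scale * (1/(2n)) ||y - b0 - X b||^2 + rho_lambda(b).
// Columns of X are expected standardized (zero sum, unit norm); exact column
// norms are used so unstandardized inputs are still handled correctly.
// [[Rcpp::export]]
List cd_path(NumericMatrix X, NumericVector y, int family,
             NumericVector lambda, double a, double gamma,
             double loss_scale, double tol, int max_iter,
             NumericVector beta_init) {
  int n = X.nrow(), d = X.ncol(), nlam = lambda.size();
  NumericVector v(d); // squared column norms
  for (int j = 0; j < d; ++j) {
    double s2 = 0;
    for (int i = 0; i < n; ++i) s2 += X(i, j) * X(i, j);
    v[j] = s2;
  }
  NumericVector b(d);
  double b0 = 0.0;
  if (beta_init.size() == d + 1) {
    b0 = beta_init[0];
    for (int j = 0; j < d; ++j) b[j] = beta_init[j + 1];
  }
  NumericVector r(n); // residual y - b0 - X b
  for (int i = 0; i < n; ++i) {
    double fit = b0;
    for (int j = 0; j < d; ++j) fit += X(i, j) * b[j];
    r[i] = y[i] - fit;
  }
  NumericMatrix coefs(d + 1, nlam);
  IntegerVector iters(nlam);
  LogicalVector conv(nlam);
  NumericVector objective(nlam);

  for (int k = 0; k < nlam; ++k) {
    double lam = lambda[k];
    bool converged = false;
    int it = 0;
    for (it = 1; it <= max_iter; ++it) {
      double max_change = 0.0;
      // intercept (unpenalized)
      double rbar = 0.0;
      for (int i = 0; i < n; ++i) rbar += r[i];
      rbar /= n;
      if (rbar != 0.0) {
        b0 += rbar;
        for (int i = 0; i < n; ++i) r[i] -= rbar;
        max_change = std::fabs(rbar);
      }
      for (int j = 0; j < d; ++j) {
        double xr = 0.0;
        for (int i = 0; i < n; ++i) xr += X(i, j) * r[i];
        double z = xr / v[j] + b[j];
        double kappa = loss_scale * v[j] / n;
        double bj = prox1(z, family, lam, a, gamma, kappa);
        double diff = bj - b[j];
        if (diff != 0.0) {
          for (int i = 0; i < n; ++i) r[i] -= X(i, j) * diff;
          b[j] = bj;
          double ch = std::fabs(diff);
          if (ch > max_change) max_change = ch;
        }
      }
      if (max_change < tol) {
        converged = true;
        break;
      }
    }
    coefs(0, k) = b0;
    double pen = 0.0, rss = 0.0;
    for (int j = 0; j < d; ++j) {
      coefs(j + 1, k) = b[j];
      pen += penalty1(b[j], family, lam, a, gamma);
    }
    for (int i = 0; i < n; ++i) rss += r[i] * r[i];
    objective[k] = loss_scale * rss / (2.0 * n) + pen;
    iters[k] = it > max_iter ? max_iter : it;
    conv[k] = converged;
  }
  return List::create(_["coefs"] = coefs, _["iterations"] = iters,
                      _["converged"] = conv, _["objective"] = objective);
}
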