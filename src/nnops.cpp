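// Fused elementwise kernels for the refinement network's hot path:
// batch-norm + ReLU block forward/backward, bias + ReLU, and max-pooling
// over fixed-size point groups. Matrix products stay in R (BLAS); these
// kernels fuse everything between them to avoid R-level temporaries.
#include <Rcpp.h>
#include <cmath>
using Rcpp::NumericMatrix;
using Rcpp::NumericVector;
using Rcpp::IntegerMatrix;
using Rcpp::List;

// Batch-norm + ReLU forward in training mode. z: n x k pre-activations.
// Returns y = relu(gamma * xhat + beta) plus the per-batch statistics the
// backward pass and the running-stat update need.
// [[Rcpp::export(name = ".bnrelu_train_fwd")]]
List bnrelu_train_fwd(NumericMatrix z, NumericVector gamma,
                      NumericVector beta, double eps) {
  int n = z.nrow(), k = z.ncol();
  NumericMatrix y(n, k), xhat(n, k);
  NumericVector mean(k), var(k), istd(k);
  for (int j = 0; j < k; ++j) {
    const double* col = &z(0, j);
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += col[i];
    double mu = s / n;
    double sv = 0.0;
    for (int i = 0; i < n; ++i) { double d = col[i] - mu; sv += d * d; }
    double va = sv / n;
    double is = 1.0 / std::sqrt(va + eps);
    mean[j] = mu; var[j] = va; istd[j] = is;
    double gj = gamma[j], bj = beta[j];
    for (int i = 0; i < n; ++i) {
      double xh = (col[i] - mu) * is;
      xhat(i, j) = xh;
      double a = gj * xh + bj;
      y(i, j) = a > 0.0 ? a : 0.0;
    }
  }
  return List::create(Rcpp::Named("y") = y, Rcpp::Named("xhat") = xhat,
                      Rcpp::Named("istd") = istd, Rcpp::Named("mean") = mean,
                      Rcpp::Named("var") = var);
}

// Backward of the fused batch-norm + ReLU block. g: upstream gradient.
// Returns gz (gradient at the pre-activation z), ggamma, gbeta.
// [[Rcpp::export(name = ".bnrelu_train_bwd")]]
List bnrelu_train_bwd(NumericMatrix g, NumericMatrix y, NumericMatrix xhat,
                      NumericVector istd, NumericVector gamma) {
  int n = g.nrow(), k = g.ncol();
  NumericMatrix gz(n, k);
  NumericVector ggamma(k), gbeta(k);
  for (int j = 0; j < k; ++j) {
    double s1 = 0.0, s2 = 0.0, sg = 0.0, sb = 0.0;
    const double gj = gamma[j];
    for (int i = 0; i < n; ++i) {
      double gi = y(i, j) > 0.0 ? g(i, j) : 0.0;
      double xh = xhat(i, j);
      sg += gi * xh;
      sb += gi;
      double dxh = gi * gj;
      s1 += dxh;
      s2 += dxh * xh;
      gz(i, j) = dxh; // temporarily store dxhat
    }
    ggamma[j] = sg; gbeta[j] = sb;
    double m1 = s1 / n, m2 = s2 / n, is = istd[j];
    for (int i = 0; i < n; ++i) {
      gz(i, j) = (gz(i, j) - m1 - xhat(i, j) * m2) * is;
    }
  }
  return List::create(Rcpp::Named("gz") = gz, Rcpp::Named("ggamma") = ggamma,
                      Rcpp::Named("gbeta") = gbeta);
}

// Batch-norm + ReLU with frozen statistics (inference mode): an affine map
// per column followed by ReLU.
// [[Rcpp::export(name = ".bnrelu_eval_fwd")]]
NumericMatrix bnrelu_eval_fwd(NumericMatrix z, NumericVector gamma,
                              NumericVector beta, NumericVector mean,
                              NumericVector var, double eps) {
  int n = z.nrow(), k = z.ncol();
  NumericMatrix y(n, k);
  for (int j = 0; j < k; ++j) {
    double is = 1.0 / std::sqrt(var[j] + eps);
    double a = gamma[j] * is;
    double b = beta[j] - gamma[j] * mean[j] * is;
    for (int i = 0; i < n; ++i) {
      double v = a * z(i, j) + b;
      y(i, j) = v > 0.0 ? v : 0.0;
    }
  }
  return y;
}

// Backward of the frozen-statistics block.
// [[Rcpp::export(name = ".bnrelu_eval_bwd")]]
NumericMatrix bnrelu_eval_bwd(NumericMatrix g, NumericMatrix y,
                              NumericVector gamma, NumericVector var,
                              double eps) {
  int n = g.nrow(), k = g.ncol();
  NumericMatrix gz(n, k);
  for (int j = 0; j < k; ++j) {
    double a = gamma[j] / std::sqrt(var[j] + eps);
    for (int i = 0; i < n; ++i) {
      gz(i, j) = y(i, j) > 0.0 ? g(i, j) * a : 0.0;
    }
  }
  return gz;
}

// y = relu(z + bias), fused.
// [[Rcpp::export(name = ".bias_relu_fwd")]]
NumericMatrix bias_relu_fwd(NumericMatrix z, NumericVector bias) {
  int n = z.nrow(), k = z.ncol();
  NumericMatrix y(n, k);
  for (int j = 0; j < k; ++j) {
    double bj = bias[j];
    for (int i = 0; i < n; ++i) {
      double v = z(i, j) + bj;
      y(i, j) = v > 0.0 ? v : 0.0;
    }
  }
  return y;
}

// [[Rcpp::export(name = ".bias_relu_bwd")]]
List bias_relu_bwd(NumericMatrix g, NumericMatrix y) {
  int n = g.nrow(), k = g.ncol();
  NumericMatrix gz(n, k);
  NumericVector gb(k);
  for (int j = 0; j < k; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) {
      double gi = y(i, j) > 0.0 ? g(i, j) : 0.0;
      gz(i, j) = gi;
      s += gi;
    }
    gb[j] = s;
  }
  return List::create(Rcpp::Named("gz") = gz, Rcpp::Named("gb") = gb);
}

// Channel-wise max over consecutive groups of m rows.
// [[Rcpp::export(name = ".pool_max_fwd")]]
List pool_max_fwd(NumericMatrix x, int m) {
  int n = x.nrow(), k = x.ncol();
  int G = n / m;
  NumericMatrix val(G, k);
  IntegerMatrix arg(G, k);
  for (int j = 0; j < k; ++j) {
    for (int g = 0; g < G; ++g) {
      int base = g * m;
      double best = x(base, j);
      int bi = 0;
      for (int s = 1; s < m; ++s) {
        double v = x(base + s, j);
        if (v > best) { best = v; bi = s; }
      }
      val(g, j) = best;
      arg(g, j) = bi;
    }
  }
  return List::create(Rcpp::Named("val") = val, Rcpp::Named("arg") = arg);
}

// [[Rcpp::export(name = ".pool_max_bwd")]]
NumericMatrix pool_max_bwd(NumericMatrix g, IntegerMatrix arg, int n, int m) {
  int G = g.nrow(), k = g.ncol();
  NumericMatrix gx(n, k);
  for (int j = 0; j < k; ++j) {
    for (int gg = 0; gg < G; ++gg) {
      gx(gg * m + arg(gg, j), j) = g(gg, j);
    }
  }
  return gx;
}
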