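#include <Rcpp.h>
using namespace Rcpp;

// gather columns for convolution: idx entries are 1-based positions into x,
// 0 marks zero padding
// [[Rcpp::export]]
NumericMatrix cpp_gather(NumericVector x, IntegerMatrix idx) {
  R_xlen_t nr = idx.nrow(), nc = idx.ncol();
  NumericMatrix out(nr, nc);
  const int* ip = idx.begin();
  const double* xp = x.begin();
  double* op = out.begin();
  R_xlen_t n = nr * nc;
  for (R_xlen_t k = 0; k < n; ++k) {
    int id = ip[k];
    op[k] = (id == 0) ? 0.0 : xp[id - 1];
  }
  return out;
}

// scatter-add the column matrix back into an input-shaped vector
// [[Rcpp::export]]
NumericVector cpp_scatter_add(NumericVector cols, IntegerMatrix idx, int n_in) {
  NumericVector out(n_in);
  const int* ip = idx.begin();
  const double* cp = cols.begin();
  double* op = out.begin();
  R_xlen_t n = (R_xlen_t)idx.nrow() * idx.ncol();
  for (R_xlen_t k = 0; k < n; ++k) {
    int id = ip[k];
    if (id != 0) op[id - 1] += cp[k];
  }
  return out;
}

// fused in-place Adam update of one parameter block; lr_t carries the
// bias-correction factors
// [[Rcpp::export]]
void cpp_adam_update(NumericVector p, NumericVector g, NumericVector m,
                     NumericVector v, double lr_t, double beta1, double beta2,
                     double eps) {
  R_xlen_t n = p.size();
  double* pp = p.begin();
  const double* gp = g.begin();
  double* mp = m.begin();
  double* vp = v.begin();
  for (R_xlen_t k = 0; k < n; ++k) {
    double gk = gp[k];
    double mk = beta1 * mp[k] + (1.0 - beta1) * gk;
    double vk = beta2 * vp[k] + (1.0 - beta2) * gk * gk;
    mp[k] = mk;
    vp[k] = vk;
    pp[k] -= lr_t * mk / (std::sqrt(vk) + eps);
  }
}

// leaky rectifier forward and backward
// [[Rcpp::export]]
NumericVector cpp_lrelu(NumericVector x, double slope) {
  R_xlen_t n = x.size();
  NumericVector y(n);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (R_xlen_t k = 0; k < n; ++k) {
    double v = xp[k];
    yp[k] = v > 0 ? v : slope * v;
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_lrelu_grad(NumericVector dout, NumericVector x, double slope) {
  R_xlen_t n = x.size();
  NumericVector dx(n);
  const double* xp = x.begin();
  const double* dp = dout.begin();
  double* op = dx.begin();
  for (R_xlen_t k = 0; k < n; ++k) {
    op[k] = xp[k] > 0 ? dp[k] : slope * dp[k];
  }
  return dx;
}
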