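// ICP inner loop: alternate exact closest-point correspondence (via the
// uniform-grid mesh index) with closed-form Kabsch rigid refitting.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// defined in core.cpp; both translation units live in one shared object
List cpp_closest_point_query(SEXP index, NumericMatrix Q);

// Kabsch: proper rigid transform mapping src onto dst (matched rows).
static void kabsch(const arma::mat &src, const arma::mat &dst,
                   arma::mat33 &R, arma::vec3 &t) {
  arma::rowvec cs = arma::mean(src, 0), cd = arma::mean(dst, 0);
  arma::mat A = src.each_row() - cs;
  arma::mat B = dst.each_row() - cd;
  arma::mat H = A.t() * B;
  arma::mat U, V;
  arma::vec s;
  arma::svd(U, s, V, H);
  double d = arma::det(V * U.t());
  arma::mat33 D = arma::eye(3, 3);
  D(2, 2) = (d < 0) ? -1.0 : 1.0;
  R = V * D * U.t();
  t = cd.t() - R * cs.t();
}

// [[Rcpp::export]]
List cpp_icp_run(SEXP index, const arma::mat &P, const arma::mat &T0,
                 int max_iter, double tol) {
  arma::mat33 R = T0.submat(0, 0, 2, 2);
  arma::vec3 t = T0.col(3).subvec(0, 2);
  double rms_prev = R_PosInf;
  std::vector<double> trace;
  int niter = 0;
  NumericMatrix Q(P.n_rows, 3);
  List cp;
  double rms = R_PosInf;
  for (;;) {
    ++niter;
    arma::mat q = P * R.t();
    q.each_row() += t.t();
    for (arma::uword i = 0; i < P.n_rows; ++i)
      for (int j = 0; j < 3; ++j) Q(i, j) = q(i, j);
    cp = cpp_closest_point_query(index, Q);
    NumericVector d = cp["distance"];
    double ss = 0;
    for (int i = 0; i < d.size(); ++i) ss += d[i] * d[i];
    rms = std::sqrt(ss / d.size());
    trace.push_back(rms);
    if (std::fabs(rms_prev - rms) < tol || niter >= max_iter) break;
    rms_prev = rms;
    NumericMatrix cl = cp["closest"];
    arma::mat dst(P.n_rows, 3);
    for (arma::uword i = 0; i < P.n_rows; ++i)
      for (int j = 0; j < 3; ++j) dst(i, j) = cl(i, j);
    kabsch(P, dst, R, t);
  }
  arma::mat T(4, 4, arma::fill::eye);
  T.submat(0, 0, 2, 2) = R;
  T.col(3).subvec(0, 2) = t;
  return List::create(_["transform"] = T,
                      _["residuals"] = cp["distance"],
                      _["rms"] = rms, _["n_iterations"] = niter,
                      _["rms_trace"] = trace);
}
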