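// Compiled numerical kernels for the 1D networks: im2col convolution and
// the batched tensor contractions of multi-head attention. Activation
// tensors are [channels, length, batch] cubes, matching the R side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat weight2mat(const cube& w) {
  // w: [cout, cin, k] -> [cout, cin*k] with column c + cin*j
  const uword cout = w.n_rows, cin = w.n_cols, k = w.n_slices;
  mat w2(cout, cin * k);
  for (uword j = 0; j < k; ++j) w2.cols(j * cin, (j + 1) * cin - 1) = w.slice(j);
  return w2;
}

static mat im2col(const cube& x, uword k, uword pad, uword lout) {
  const uword cin = x.n_rows, L = x.n_cols, B = x.n_slices;
  mat xc(cin * k, lout * B, fill::zeros);
  for (uword b = 0; b < B; ++b) {
    const mat& xb = x.slice(b);
    for (uword l = 0; l < lout; ++l) {
      double* colp = xc.colptr(b * lout + l);
      for (uword j = 0; j < k; ++j) {
        const long src = (long)(l + j) - (long)pad;
        if (src >= 0 && src < (long)L) {
          std::memcpy(colp + j * cin, xb.colptr(src), cin * sizeof(double));
        }
      }
    }
  }
  return xc;
}

// [[Rcpp::export]]
arma::cube cpp_conv1d_fwd(const arma::cube& x, const arma::cube& w,
                          const arma::vec& b, int pad) {
  const uword cin = x.n_rows, L = x.n_cols, B = x.n_slices;
  const uword cout = w.n_rows, k = w.n_slices;
  if (w.n_cols != cin) Rcpp::stop("conv1d: channel mismatch");
  const long lo = (long)L + 2 * pad - (long)k + 1;
  if (lo < 1) Rcpp::stop("conv1d: input shorter than kernel");
  const uword lout = (uword)lo;
  mat y = weight2mat(w) * im2col(x, k, (uword)pad, lout);
  y.each_col() += b;
  return cube(y.memptr(), cout, lout, B);
}

// [[Rcpp::export]]
Rcpp::List cpp_conv1d_bwd(const arma::cube& x, const arma::cube& w,
                          const arma::cube& dy, int pad) {
  const uword cin = x.n_rows, L = x.n_cols, B = x.n_slices;
  const uword cout = w.n_rows, k = w.n_slices;
  const uword lout = dy.n_cols;
  const mat dym(const_cast<double*>(dy.memptr()), cout, lout * B, false);
  mat xc = im2col(x, k, (uword)pad, lout);

  mat dw2 = dym * xc.t();               // [cout, cin*k]
  cube dw(cout, cin, k);
  for (uword j = 0; j < k; ++j) dw.slice(j) = dw2.cols(j * cin, (j + 1) * cin - 1);
  vec db = sum(dym, 1);

  mat dxc = weight2mat(w).t() * dym;    // [cin*k, lout*B]
  cube dx(cin, L, B, fill::zeros);
  for (uword b = 0; b < B; ++b) {
    mat& dxb = dx.slice(b);
    for (uword l = 0; l < lout; ++l) {
      const double* colp = dxc.colptr(b * lout + l);
      for (uword j = 0; j < k; ++j) {
        const long dst = (long)(l + j) - (long)pad;
        if (dst >= 0 && dst < (long)L) {
          double* out = dxb.colptr(dst);
          const double* src = colp + j * cin;
          for (uword c = 0; c < cin; ++c) out[c] += src[c];
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}

// s[p, q, hb] = sum_d a[d, p, hb] * b[d, q, hb]
// [[Rcpp::export]]
arma::cube cpp_bmm_nt(const arma::cube& a, const arma::cube& b) {
  const uword HB = a.n_slices, L1 = a.n_cols, L2 = b.n_cols;
  cube s(L1, L2, HB);
  for (uword i = 0; i < HB; ++i) s.slice(i) = a.slice(i).t() * b.slice(i);
  return s;
}

// h[d, p, hb] = sum_q v[d, q, hb] * p[pp, q, hb]  (P applied from the right)
// [[Rcpp::export]]
arma::cube cpp_bmm_pv(const arma::cube& v, const arma::cube& p) {
  const uword HB = v.n_slices, d = v.n_rows, L1 = p.n_rows;
  cube h(d, L1, HB);
  for (uword i = 0; i < HB; ++i) h.slice(i) = v.slice(i) * p.slice(i).t();
  return h;
}

// dv[d, q, hb] = sum_p dh[d, p, hb] * p[p, q, hb]
// [[Rcpp::export]]
arma::cube cpp_bmm_ptv(const arma::cube& dh, const arma::cube& p) {
  const uword HB = dh.n_slices, d = dh.n_rows, L2 = p.n_cols;
  cube dv(d, L2, HB);
  for (uword i = 0; i < HB; ++i) dv.slice(i) = dh.slice(i) * p.slice(i);
  return dv;
}

// row-wise softmax over dim 2 (columns of each slice), in place semantics
// [[Rcpp::export]]
arma::cube cpp_softmax_dim2(const arma::cube& s) {
  cube p = s;
  for (uword i = 0; i < p.n_slices; ++i) {
    mat& m = p.slice(i);
    vec mx = max(m, 1);
    m.each_col() -= mx;
    m = exp(m);
    vec z = sum(m, 1);
    m.each_col() /= z;
  }
  return p;
}

// backward of row-softmax over dim 2: dsc = pm % (dp - rowsum(dp % pm))
// [[Rcpp::export]]
arma::cube cpp_softmax_bwd_dim2(const arma::cube& dp, const arma::cube& pm) {
  cube dsc(dp.n_rows, dp.n_cols, dp.n_slices);
  for (uword i = 0; i < dp.n_slices; ++i) {
    const mat& d = dp.slice(i);
    const mat& p = pm.slice(i);
    vec r = sum(d % p, 1);
    dsc.slice(i) = p % (d.each_col() - r);
  }
  return dsc;
}
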