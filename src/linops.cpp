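#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

#ifndef FCONE
#define FCONE
#endif

// Y = L %*% X for a dgCMatrix L and a dense X, without S4 dispatch or
// intermediate dense conversions. Used by the public Chebyshev-convolution
// helper; the training loop uses the fused kernels below.
// [[Rcpp::export(name = ".sp_dense_prod")]]
NumericMatrix sp_dense_prod(S4 L, NumericMatrix X) {
  IntegerVector p = L.slot("p"), ri = L.slot("i"), dim = L.slot("Dim");
  NumericVector xv = L.slot("x");
  const int nrow = dim[0], ncol = dim[1], m = X.ncol();
  if (X.nrow() != ncol) stop("non-conformable sparse-dense product");
  NumericMatrix Y(nrow, m);
  const int* pp = INTEGER(p);
  const int* rr = INTEGER(ri);
  const double* vv = REAL(xv);
  const double* Xp = REAL(X);
  double* Yp = REAL(Y);
  for (int col = 0; col < m; ++col) {
    const double* xc = Xp + (size_t)col * ncol;
    double* yc = Yp + (size_t)col * nrow;
    for (int j = 0; j < ncol; ++j) {
      const double xj = xc[j];
      if (xj == 0.0) continue;
      for (int idx = pp[j]; idx < pp[j + 1]; ++idx)
        yc[rr[idx]] += vv[idx] * xj;
    }
  }
  return Y;
}

// In-place Adam update: p, m, v are modified directly (they are owned by the
// training loop and never aliased).
// [[Rcpp::export(name = ".adam_update")]]
void adam_update(NumericVector p, NumericVector g, NumericVector m,
                 NumericVector v, int t, double lr, double beta1,
                 double beta2, double eps, double wd) {
  const R_xlen_t n = p.size();
  if (g.size() != n || m.size() != n || v.size() != n)
    stop("parameter/gradient size mismatch");
  const double c1 = 1.0 - std::pow(beta1, t);
  const double c2 = 1.0 - std::pow(beta2, t);
  for (R_xlen_t k = 0; k < n; ++k) {
    const double gr = g[k] + wd * p[k];
    m[k] = beta1 * m[k] + (1.0 - beta1) * gr;
    v[k] = beta2 * v[k] + (1.0 - beta2) * gr * gr;
    p[k] -= lr * (m[k] / c1) / (std::sqrt(v[k] / c2) + eps);
  }
}

namespace {
// out = (Y1 | 0) - (Y2 | 0) + alpha * L %*% X, all column-major n x m
void sp_accum(const int* pp, const int* rr, const double* vv, int n,
              const double* X, int m, double alpha, const double* Y1,
              const double* Y2, double* out) {
  const R_xlen_t total = (R_xlen_t)n * m;
  if (Y1 && Y2) for (R_xlen_t t = 0; t < total; ++t) out[t] = Y1[t] - Y2[t];
  else if (Y1) for (R_xlen_t t = 0; t < total; ++t) out[t] = Y1[t];
  else if (Y2) for (R_xlen_t t = 0; t < total; ++t) out[t] = -Y2[t];
  else for (R_xlen_t t = 0; t < total; ++t) out[t] = 0.0;
  int col = 0;
  // 4-column blocks amortize the sparse index traversal
  for (; col + 4 <= m; col += 4) {
    const double* xc = X + (size_t)col * n;
    double* yc = out + (size_t)col * n;
    for (int j = 0; j < n; ++j) {
      const double x0 = alpha * xc[j], x1 = alpha * xc[j + n],
                   x2 = alpha * xc[j + 2 * n], x3 = alpha * xc[j + 3 * n];
      if (x0 == 0.0 && x1 == 0.0 && x2 == 0.0 && x3 == 0.0) continue;
      for (int idx = pp[j]; idx < pp[j + 1]; ++idx) {
        const int r = rr[idx];
        const double v = vv[idx];
        yc[r] += v * x0;
        yc[r + n] += v * x1;
        yc[r + 2 * n] += v * x2;
        yc[r + 3 * n] += v * x3;
      }
    }
  }
  for (; col < m; ++col) {
    const double* xc = X + (size_t)col * n;
    double* yc = out + (size_t)col * n;
    for (int j = 0; j < n; ++j) {
      const double xj = alpha * xc[j];
      if (xj == 0.0) continue;
      for (int idx = pp[j]; idx < pp[j + 1]; ++idx)
        yc[rr[idx]] += vv[idx] * xj;
    }
  }
}
}  // namespace

// result = alpha * (L %*% X) + Y1 - Y2 with optional Y1/Y2; serves the
// Chebyshev recurrence and the Clenshaw reverse recurrence without
// intermediate allocations when called from R.
// [[Rcpp::export(name = ".sp_affine")]]
NumericMatrix sp_affine(S4 L, NumericMatrix X, double alpha,
                        Nullable<NumericMatrix> Y1,
                        Nullable<NumericMatrix> Y2) {
  IntegerVector p = L.slot("p"), ri = L.slot("i"), dim = L.slot("Dim");
  NumericVector xv = L.slot("x");
  const int n = dim[0], m = X.ncol();
  if (X.nrow() != dim[1]) stop("non-conformable sparse-dense product");
  NumericMatrix Y(n, m);
  const double* y1 = nullptr;
  const double* y2 = nullptr;
  NumericMatrix q1, q2;
  if (Y1.isNotNull()) {
    q1 = NumericMatrix(Y1);
    if (q1.nrow() != n || q1.ncol() != m) stop("Y1 shape mismatch");
    y1 = REAL(q1);
  }
  if (Y2.isNotNull()) {
    q2 = NumericMatrix(Y2);
    if (q2.nrow() != n || q2.ncol() != m) stop("Y2 shape mismatch");
    y2 = REAL(q2);
  }
  sp_accum(INTEGER(p), INTEGER(ri), REAL(xv), n, REAL(X), m, alpha, y1, y2,
           REAL(Y));
  return Y;
}

// Chebyshev convolution forward for a batch: Xarr is (n, B, Fin) and W is
// (K*Fin, Fout). The polynomial stack T_k(L) X is written directly into the
// column blocks of the GEMM design matrix A ((n*B) x (K*Fin)): block k seen
// as an (n, B*Fin) matrix is exactly T_k X, so the recurrence runs in place
// and a single dgemm produces all output channels.
// [[Rcpp::export(name = ".conv_fwd")]]
List conv_fwd(S4 L, NumericVector Xarr, NumericMatrix W, NumericVector b) {
  IntegerVector dm = Xarr.attr("dim");
  const int n = dm[0], B = dm[1], Fin = dm[2];
  const int KFin = W.nrow(), Fout = W.ncol();
  const int K = KFin / Fin;
  if (K * Fin != KFin) stop("weight rows not a multiple of input channels");
  IntegerVector p = L.slot("p"), ri = L.slot("i"), Ld = L.slot("Dim");
  NumericVector xv = L.slot("x");
  if (Ld[0] != n) stop("Laplacian size mismatch");
  const int* pp = INTEGER(p);
  const int* rr = INTEGER(ri);
  const double* vv = REAL(xv);
  const int nB = n * B, m = B * Fin;
  const R_xlen_t blk = (R_xlen_t)n * m;
  NumericMatrix A(nB, KFin);
  double* Ap = REAL(A);
  const double* Xp = REAL(Xarr);
  std::copy(Xp, Xp + blk, Ap);
  if (K >= 2) sp_accum(pp, rr, vv, n, Ap, m, 1.0, nullptr, nullptr, Ap + blk);
  for (int k = 2; k < K; ++k)
    sp_accum(pp, rr, vv, n, Ap + (R_xlen_t)(k - 1) * blk, m, 2.0, nullptr,
             Ap + (R_xlen_t)(k - 2) * blk, Ap + (R_xlen_t)k * blk);
  NumericVector out((R_xlen_t)nB * Fout);
  out.attr("dim") = IntegerVector::create(n, B, Fout);
  double* Yp = REAL(out);
  const double one = 1.0, zero = 0.0;
  F77_CALL(dgemm)("N", "N", &nB, &Fout, &KFin, &one, Ap, &nB, REAL(W), &KFin,
                  &zero, Yp, &nB FCONE FCONE);
  for (int f = 0; f < Fout; ++f) {
    const double bf = b[f];
    double* yc = Yp + (size_t)f * nB;
    for (int t = 0; t < nB; ++t) yc[t] += bf;
  }
  A.attr("conv_dims") = IntegerVector::create(K, Fin);
  return List::create(_["out"] = out, _["A"] = A);
}

// Backward of the batched Chebyshev convolution: dW = A^T dY, db = column
// sums of dY, and dX = sum_k T_k(L) dA_k via the Clenshaw reverse
// recurrence over the column blocks of dA = dY W^T.
// [[Rcpp::export(name = ".conv_bwd")]]
List conv_bwd(S4 L, NumericVector dYarr, NumericMatrix A, NumericMatrix W) {
  IntegerVector dm = dYarr.attr("dim");
  const int n = dm[0], B = dm[1], Fout = dm[2];
  const int KFin = W.nrow();
  if (A.ncol() != KFin) stop("cache/weight shape mismatch");
  IntegerVector meta = A.attr("conv_dims");
  const int K = meta[0], Fin = meta[1];
  const int nB = n * B, m = B * Fin;
  const R_xlen_t blk = (R_xlen_t)n * m;
  IntegerVector p = L.slot("p"), ri = L.slot("i");
  NumericVector xv = L.slot("x");
  const int* pp = INTEGER(p);
  const int* rr = INTEGER(ri);
  const double* vv = REAL(xv);
  double* dYp = REAL(dYarr);
  const double one = 1.0, zero = 0.0;
  NumericMatrix dW(KFin, Fout);
  F77_CALL(dgemm)("T", "N", &KFin, &Fout, &nB, &one, REAL(A), &nB, dYp, &nB,
                  &zero, REAL(dW), &KFin FCONE FCONE);
  NumericVector db(Fout);
  for (int f = 0; f < Fout; ++f) {
    const double* yc = dYp + (size_t)f * nB;
    double s = 0.0;
    for (int t = 0; t < nB; ++t) s += yc[t];
    db[f] = s;
  }
  NumericMatrix dA(nB, KFin);
  double* dAp = REAL(dA);
  F77_CALL(dgemm)("N", "T", &nB, &KFin, &Fout, &one, dYp, &nB, REAL(W), &KFin,
                  &zero, dAp, &nB FCONE FCONE);
  NumericVector dX((R_xlen_t)n * B * Fin);
  dX.attr("dim") = IntegerVector::create(n, B, Fin);
  if (K == 1) {
    std::copy(dAp, dAp + blk, REAL(dX));
    return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
  }
  std::vector<double> b1(blk), b2(blk), tmp(blk);
  bool have2 = false;
  std::copy(dAp + (R_xlen_t)(K - 1) * blk, dAp + (R_xlen_t)K * blk,
            b1.data());
  for (int k = K - 2; k >= 1; --k) {
    const double* Gk = dAp + (R_xlen_t)k * blk;
    sp_accum(pp, rr, vv, n, b1.data(), m, 2.0, Gk,
             have2 ? b2.data() : nullptr, tmp.data());
    b2.swap(b1);
    have2 = true;
    b1.swap(tmp);
  }
  sp_accum(pp, rr, vv, n, b1.data(), m, 1.0, dAp,
           have2 ? b2.data() : nullptr, REAL(dX));
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// Fused ReLU + size-2 max pooling over the vertex dimension of an
// (n, B, F) activation array. Returns the pooled array, the winning-slot
// flags and the positivity flag of the winning pre-activation.
// [[Rcpp::export(name = ".relu_pool_fwd")]]
List relu_pool_fwd(NumericVector Xarr) {
  IntegerVector dm = Xarr.attr("dim");
  const int n = dm[0], B = dm[1], F = dm[2], h = n / 2;
  NumericVector out((R_xlen_t)h * B * F);
  out.attr("dim") = IntegerVector::create(h, B, F);
  LogicalVector top((R_xlen_t)h * B * F), pos((R_xlen_t)h * B * F);
  const double* x = REAL(Xarr);
  double* o = REAL(out);
  int* tp = LOGICAL(top);
  int* ps = LOGICAL(pos);
  const R_xlen_t cols = (R_xlen_t)B * F;
  for (R_xlen_t c = 0; c < cols; ++c) {
    const double* xc = x + c * n;
    double* oc = o + c * h;
    int* tc = tp + c * h;
    int* pc = ps + c * h;
    for (int i = 0; i < h; ++i) {
      const double a = xc[2 * i], b = xc[2 * i + 1];
      const bool atop = a >= b;
      const double w = atop ? a : b;
      tc[i] = atop;
      pc[i] = w > 0;
      oc[i] = w > 0 ? w : 0.0;
    }
  }
  return List::create(_["out"] = out, _["top"] = top, _["pos"] = pos);
}

// Backward of the fused ReLU + pool: the gradient flows to the winning slot
// if its pre-activation was positive.
// [[Rcpp::export(name = ".relu_pool_bwd")]]
NumericVector relu_pool_bwd(NumericVector dY, LogicalVector top,
                            LogicalVector pos) {
  IntegerVector dm = dY.attr("dim");
  const int h = dm[0], B = dm[1], F = dm[2], n = 2 * h;
  NumericVector dX((R_xlen_t)n * B * F);
  dX.attr("dim") = IntegerVector::create(n, B, F);
  const double* g = REAL(dY);
  const int* tp = LOGICAL(top);
  const int* ps = LOGICAL(pos);
  double* d = REAL(dX);
  const R_xlen_t cols = (R_xlen_t)B * F;
  for (R_xlen_t c = 0; c < cols; ++c) {
    const double* gc = g + c * h;
    const int* tc = tp + c * h;
    const int* pc = ps + c * h;
    double* dc = d + c * n;
    for (int i = 0; i < h; ++i)
      if (pc[i]) dc[tc[i] ? 2 * i : 2 * i + 1] = gc[i];
  }
  return dX;
}
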