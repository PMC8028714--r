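#include <Rcpp.h>
using namespace Rcpp;

// Binary search for row `row` within Li[start, end); returns index or -1.
static inline int find_row(const int *Li, int start, int end, int row) {
  int lo = start, hi = end - 1;
  while (lo <= hi) {
    int mid = (lo + hi) / 2;
    int v = Li[mid];
    if (v == row) return mid;
    if (v < row) lo = mid + 1; else hi = mid - 1;
  }
  return -1;
}

// Takahashi selected inversion for a sparse Cholesky factor A = L L'
// (lower-triangular CSC, sorted rows, diagonal first in each column).
// Returns the entries of A^{-1} on the pattern of L. Scatter-based: for
// column j the partial sums acc_i = sum_{k in S_j} L_kj Z_(i,k) are
// accumulated by scanning the already-computed columns k > j once,
// using the symmetry of Z. All referenced entries lie inside the factor
// pattern because column structures nest along the elimination tree.
// [[Rcpp::export]]
NumericVector takahashi_selected_inverse(IntegerVector Lp_, IntegerVector Li_,
                                         NumericVector Lx_, int n) {
  const int *Lp = INTEGER(Lp_);
  const int *Li = INTEGER(Li_);
  const double *Lx = REAL(Lx_);
  NumericVector Z_(Lx_.size());
  double *Z = REAL(Z_);
  std::vector<double> acc(n, 0.0), lval(n, 0.0);
  std::vector<int> mark(n, -1), pos(n, -1);
  for (int j = n - 1; j >= 0; --j) {
    int cs = Lp[j], ce = Lp[j + 1];
    if (cs >= ce) continue;
    double djj = Lx[cs];
    // mark the column's structure; remember L values and entry positions
    for (int e = cs; e < ce; ++e) {
      int r = Li[e];
      mark[r] = j; lval[r] = Lx[e]; pos[r] = e; acc[r] = 0.0;
    }
    // accumulate acc over columns c in S_j \ {j}
    for (int e = cs + 1; e < ce; ++e) {
      int c = Li[e];
      double lcj = Lx[e];
      for (int f = Lp[c]; f < Lp[c + 1]; ++f) {
        int r = Li[f];
        if (mark[r] != j) continue;
        double z = Z[f];
        acc[r] += lcj * z;            // Z_(r,c) with multiplier L_cj
        if (r != c) acc[c] += lval[r] * z; // Z_(c,r) with multiplier L_rj
      }
    }
    // off-diagonals of column j, then the diagonal
    double dsum = 0.0;
    for (int e = cs + 1; e < ce; ++e) {
      int r = Li[e];
      double zrj = -acc[r] / djj;
      Z[e] = zrj;
      dsum += Lx[e] * zrj;
    }
    Z[cs] = (1.0 / djj - dsum) / djj;
  }
  return Z_;
}

// Accessor for C = A^{-1} entries through the selected inverse on the
// factor pattern: C[a,b] (original, 0-based) = Z[perm(a), perm(b)].
static inline double get_centry(const int *Lp, const int *Li, const double *Zx,
                                const int *iperm, int a, int b) {
  int pa = iperm[a], pb = iperm[b];
  int r = pa >= pb ? pa : pb;
  int c = pa >= pb ? pb : pa;
  int pos = find_row(Li, Lp[c], Lp[c + 1], r);
  return pos >= 0 ? Zx[pos] : 0.0;
}

// Quadratic forms w_r' C w_r for every column r of Wt (CSC; Wt = t(W),
// columns = records), with C given through the selected inverse
// (factor pattern Lp/Li, values Zx, permutation iperm: original -> factor).
// [[Rcpp::export]]
NumericVector quad_form_cols(IntegerVector Wp_, IntegerVector Wi_, NumericVector Wx_,
                             IntegerVector Lp_, IntegerVector Li_, NumericVector Zx_,
                             IntegerVector iperm_, int nrec) {
  const int *Wp = INTEGER(Wp_), *Wi = INTEGER(Wi_);
  const double *Wx = REAL(Wx_);
  const int *Lp = INTEGER(Lp_), *Li = INTEGER(Li_), *iperm = INTEGER(iperm_);
  const double *Zx = REAL(Zx_);
  NumericVector out(nrec);
  for (int r = 0; r < nrec; ++r) {
    double q = 0.0;
    int s = Wp[r], e = Wp[r + 1];
    for (int a = s; a < e; ++a) {
      double va = Wx[a];
      q += va * va * get_centry(Lp, Li, Zx, iperm, Wi[a], Wi[a]);
      for (int b = a + 1; b < e; ++b) {
        q += 2.0 * va * Wx[b] * get_centry(Lp, Li, Zx, iperm, Wi[a], Wi[b]);
      }
    }
    out[r] = q;
  }
  return out;
}

// T[k,l] = sum over nonzero K[i,j] of K_ij * C[gofs + i*nc + k, gofs + j*nc + l]
// (trace terms of the genetic-covariance REML gradient).
// [[Rcpp::export]]
NumericMatrix block_trace_sum(IntegerVector Lp_, IntegerVector Li_, NumericVector Zx_,
                              IntegerVector iperm_,
                              IntegerVector Kp_, IntegerVector Ki_, NumericVector Kx_,
                              int gofs, int nc, int n_anim) {
  const int *Lp = INTEGER(Lp_), *Li = INTEGER(Li_), *iperm = INTEGER(iperm_);
  const double *Zx = REAL(Zx_);
  const int *Kp = INTEGER(Kp_), *Ki = INTEGER(Ki_);
  const double *Kx = REAL(Kx_);
  NumericMatrix T(nc, nc);
  for (int j = 0; j < n_anim; ++j) {
    for (int e = Kp[j]; e < Kp[j + 1]; ++e) {
      int i = Ki[e];
      double kij = Kx[e];
      if (kij == 0.0) continue;
      for (int l = 0; l < nc; ++l) {
        for (int k = 0; k < nc; ++k) {
          T(k, l) += kij * get_centry(Lp, Li, Zx, iperm,
                                      gofs + i * nc + k, gofs + j * nc + l);
        }
      }
    }
  }
  return T;
}

// T[k,l] = sum over blocks g of C[off + g*bs + k, off + g*bs + l]
// (diagonal-block sum for iid random-effect priors).
// [[Rcpp::export]]
NumericMatrix diag_block_sum(IntegerVector Lp_, IntegerVector Li_, NumericVector Zx_,
                             IntegerVector iperm_, int off, int nb, int bs) {
  const int *Lp = INTEGER(Lp_), *Li = INTEGER(Li_), *iperm = INTEGER(iperm_);
  const double *Zx = REAL(Zx_);
  NumericMatrix T(bs, bs);
  for (int g = 0; g < nb; ++g) {
    for (int l = 0; l < bs; ++l) {
      for (int k = 0; k < bs; ++k) {
        T(k, l) += get_centry(Lp, Li, Zx, iperm,
                              off + g * bs + k, off + g * bs + l);
      }
    }
  }
  return T;
}
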