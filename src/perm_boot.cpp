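// Inner loops of the taxon-matching permutation null and the direction
// bootstrap. Both consume R's RNG stream (unif_rand), so set.seed() in the
// calling R code fixes them completely.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// one-way pseudo-F on a score matrix (rows = samples)
static double pseudo_f(const arma::mat& S, const arma::uvec& lab,
                       const arma::vec& sizes) {
  const int n = S.n_rows, a = sizes.n_elem;
  arma::rowvec center = arma::mean(S, 0);
  double sst = arma::accu(arma::square(S.each_row() - center));
  arma::mat gsum(a, S.n_cols, arma::fill::zeros);
  for (int i = 0; i < n; ++i) gsum.row(lab(i)) += S.row(i);
  double ssb = 0.0;
  for (int g = 0; g < a; ++g) {
    arma::rowvec mg = gsum.row(g) / sizes(g);
    ssb += sizes(g) * arma::accu(arma::square(mg - center));
  }
  double ssw = sst - ssb;
  if (ssw < 0) ssw = 0;
  double msb = ssb / (a - 1), msw = ssw / (n - a);
  if (msw == 0.0) return msb == 0.0 ? 0.0 : R_PosInf;
  return msb / msw;
}

static int unif_index(int n) {
  int k;
  do { k = (int)(unif_rand() * n); } while (k >= n);
  return k;
}

// Count taxon-matching permutations whose pseudo-F >= the observed one
// (with a tolerance guard so ties are never dropped). Each permutation
// realigns ds2's CLR columns to the union taxon order, which is equivalent
// to permuting the rows of W = basis %*% rotation.
// [[Rcpp::export(name = ".taxonPermCount")]]
int taxon_perm_count(const arma::mat& clr2, const arma::mat& W,
                     const arma::rowvec& c0, const IntegerVector& lab,
                     const NumericVector& sizes, int n_perm, double f_obs) {
  const int D = W.n_rows;
  arma::uvec lab0(lab.size());
  for (int i = 0; i < lab.size(); ++i) lab0(i) = lab[i] - 1;
  arma::vec sz(sizes.begin(), sizes.size());
  arma::uvec perm(D);
  for (int i = 0; i < D; ++i) perm(i) = i;
  double eps = R_finite(f_obs)
    ? 1e-9 * std::max(1.0, std::fabs(f_obs)) : 0.0;
  int count = 0;
  for (int t = 0; t < n_perm; ++t) {
    for (int i = D - 1; i > 0; --i) {          // Fisher-Yates on R's RNG
      int j = unif_index(i + 1);
      std::swap(perm(i), perm(j));
    }
    arma::mat S = clr2 * W.rows(perm);
    S.each_row() -= c0;
    double f = pseudo_f(S, lab0, sz);
    if (f >= f_obs - eps) ++count;
  }
  return count;
}

// Count sampled label permutations whose pseudo-F >= the observed one
// (same tolerance guard as the exhaustive path).
// [[Rcpp::export(name = ".samplePermCount")]]
int sample_perm_count(const arma::mat& S, const IntegerVector& lab,
                      const NumericVector& sizes, int n_perm, double f_obs) {
  const int n = lab.size();
  arma::uvec l(n);
  for (int i = 0; i < n; ++i) l(i) = lab[i] - 1;
  arma::vec sz(sizes.begin(), sizes.size());
  double eps = R_finite(f_obs)
    ? 1e-9 * std::max(1.0, std::fabs(f_obs)) : 0.0;
  int count = 0;
  for (int t = 0; t < n_perm; ++t) {
    for (int i = n - 1; i > 0; --i) {
      int j = unif_index(i + 1);
      std::swap(l(i), l(j));
    }
    double f = pseudo_f(S, l, sz);
    if (f >= f_obs - eps) ++count;
  }
  return count;
}

// Bootstrap distribution of the direction cosine. Samples are resampled
// with replacement within each group of each dataset; with refit = true the
// PCA is refitted on the resampled first dataset through the n x n Gram
// matrix (loadings-space projections V_r' d = S_r^-1 U_r' Xc d).
// [[Rcpp::export(name = ".bootCosine")]]
NumericVector boot_cosine(const arma::mat& X1, const arma::mat& X2,
                          const IntegerVector& i11, const IntegerVector& i12,
                          const IntegerVector& i21, const IntegerVector& i22,
                          int n_boot, bool refit, int k_axes,
                          const arma::mat& rot) {
  const int m11 = i11.size(), m12 = i12.size();
  const int m21 = i21.size(), m22 = i22.size();
  const int nb = m11 + m12, p = X1.n_cols;
  NumericVector out(n_boot);
  arma::uvec r11(m11), r12(m12), r21(m21), r22(m22);
  for (int b = 0; b < n_boot; ++b) {
    for (int i = 0; i < m11; ++i) r11(i) = i11[unif_index(m11)] - 1;
    for (int i = 0; i < m12; ++i) r12(i) = i12[unif_index(m12)] - 1;
    for (int i = 0; i < m21; ++i) r21(i) = i21[unif_index(m21)] - 1;
    for (int i = 0; i < m22; ++i) r22(i) = i22[unif_index(m22)] - 1;
    arma::rowvec d1 = arma::mean(X1.rows(r12), 0) -
                      arma::mean(X1.rows(r11), 0);
    arma::rowvec d2 = arma::mean(X2.rows(r22), 0) -
                      arma::mean(X2.rows(r21), 0);
    double cosv = NA_REAL;
    if (refit) {
      arma::mat Xb(nb, p);
      Xb.rows(0, m11 - 1) = X1.rows(r11);
      Xb.rows(m11, nb - 1) = X1.rows(r12);
      arma::rowvec cm = arma::mean(Xb, 0);
      Xb.each_row() -= cm;
      arma::mat K = Xb * Xb.t();
      arma::vec eval; arma::mat evec;
      if (arma::eig_sym(eval, evec, K)) {         // ascending order
        double mx = eval(nb - 1);
        if (mx > 0) {
          double tol = 1e-10 * mx;
          arma::vec w1 = Xb * d1.t(), w2 = Xb * d2.t();
          double s11 = 0, s22 = 0, s12 = 0;
          int used = 0;
          for (int k = nb - 1; k >= 0; --k) {     // largest first
            if (eval(k) <= tol) break;
            if (k_axes > 0 && used >= k_axes) break;
            double p1 = arma::dot(evec.col(k), w1) / std::sqrt(eval(k));
            double p2 = arma::dot(evec.col(k), w2) / std::sqrt(eval(k));
            s11 += p1 * p1; s22 += p2 * p2; s12 += p1 * p2;
            ++used;
          }
          if (used > 0 && s11 > 0 && s22 > 0) {
            cosv = s12 / std::sqrt(s11 * s22);
            if (cosv > 1) cosv = 1; else if (cosv < -1) cosv = -1;
          }
        }
      }
    } else {
      arma::vec v1 = rot.t() * d1.t(), v2 = rot.t() * d2.t();
      double n1 = arma::norm(v1), n2 = arma::norm(v2);
      if (n1 > 0 && n2 > 0) {
        cosv = arma::dot(v1, v2) / (n1 * n2);
        if (cosv > 1) cosv = 1; else if (cosv < -1) cosv = -1;
      }
    }
    out[b] = cosv;
  }
  return out;
}
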