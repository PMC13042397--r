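// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

//' Pairwise-complete Pearson correlation between matrix rows
//'
//' Computes the full rows-by-rows Pearson correlation matrix of \code{X}
//' using, for each pair of rows, only the samples observed in both rows.
//' Entries backed by fewer than \code{min_pairs} shared observations, or by
//' a zero variance on either side, are returned as \code{NaN} (flagged
//' undefined, never coerced to zero).
//'
//' @param X numeric matrix, features in rows, samples in columns; missing
//'   values encoded as \code{NaN}/\code{NA}.
//' @param min_pairs minimum number of shared observations for a defined
//'   correlation.
//' @return square numeric matrix of correlations with unit diagonal where
//'   defined.
//' @keywords internal
// [[Rcpp::export]]
arma::mat pcc_pairwise_cpp(const arma::mat& X, const int min_pairs) {
  mat M = conv_to<mat>::from(X == X);  // NaN != NaN -> 0 where missing
  mat X0 = X;
  X0.replace(datum::nan, 0.0);

  mat n   = M * M.t();
  mat S   = X0 * X0.t();
  mat Sx  = X0 * M.t();          // Sx(i,j) = sum of x_i over samples with j present
  mat Sxx = (X0 % X0) * M.t();

  mat v   = n % Sxx - Sx % Sx;   // n * centered sum of squares, pairwise
  mat num = n % S - Sx % Sx.t();
  mat den = sqrt(v % v.t());

  mat r = num / den;
  r.elem(find(den <= 0)).fill(datum::nan);
  r.elem(find(n < double(min_pairs))).fill(datum::nan);
  return r;
}
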