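#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// mirror index into [0, n): -1 -> 0, n -> n-1 (symmetric reflection)
static arma::uword reflect_idx(arma::sword i, arma::sword n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return (arma::uword)i;
}

//' 2-D convolution with symmetric (mirror) boundary padding
//'
//' Convolves \code{x} with kernel \code{k}, returning a matrix the same size
//' as \code{x}. The image is padded by reflection so that region edges do not
//' introduce artificial zero borders.
//'
//' @param x numeric matrix (image or region).
//' @param k numeric matrix, the convolution kernel (odd dimensions advised).
//' @return numeric matrix, same dimensions as \code{x}.
//' @keywords internal
// [[Rcpp::export]]
arma::mat conv2_reflect(const arma::mat& x, const arma::mat& k) {
  const arma::sword H = x.n_rows, W = x.n_cols;
  const arma::uword a = k.n_rows / 2, b = k.n_cols / 2;
  arma::mat p(H + 2 * a, W + 2 * b);
  for (arma::uword j = 0; j < p.n_cols; ++j) {
    arma::uword jj = reflect_idx((arma::sword)j - (arma::sword)b, W);
    for (arma::uword i = 0; i < p.n_rows; ++i) {
      arma::uword ii = reflect_idx((arma::sword)i - (arma::sword)a, H);
      p(i, j) = x(ii, jj);
    }
  }
  arma::mat c = arma::conv2(p, k, "same");
  return c.submat(a, b, a + H - 1, b + W - 1);
}
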