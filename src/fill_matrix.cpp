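#include <Rcpp.h>

// Overwrite the contents of an existing numeric matrix in place. Used by
// the permutation engine to push a permuted fixed-effects matrix into the
// already-built penalized-least-squares structures without reallocating
// them (their C++ side maps the original matrix memory).
// [[Rcpp::export]]
void fill_matrix_inplace(Rcpp::NumericMatrix target,
                         Rcpp::NumericMatrix source) {
  if (target.nrow() != source.nrow() || target.ncol() != source.ncol())
    Rcpp::stop("dimension mismatch");
  std::copy(source.begin(), source.end(), target.begin());
}
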