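#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Voxel-wise k-NN lesion probability: for each query row, the fraction of
// lesion-labelled reference points among its k nearest neighbours under
// squared Euclidean distance. Neighbour selection follows the total order
// (distance, reference row index): ties at the k-th distance resolve to the
// earlier reference row, so probabilities are exact multiples of 1/k and
// independent of query order.
// [[Rcpp::export]]
NumericVector knn_probability_cpp(NumericMatrix ref, IntegerVector labels,
                                  NumericMatrix query, int k) {
  const int nr = ref.nrow(), nq = query.nrow(), d = ref.ncol();
  if (labels.size() != nr) stop("labels length must match nrow(ref)");
  if (k < 1 || k > nr) stop("k must be between 1 and nrow(ref)");
  if (query.ncol() != d) stop("feature dimension mismatch");

  NumericVector out(nq);
  std::vector<double> dist(nr), buf(nr);
  const double* refp = REAL(ref);   // column-major nr x d
  const double* qp = REAL(query);   // column-major nq x d
  const int* lab = INTEGER(labels);

  for (int q = 0; q < nq; ++q) {
    std::fill(dist.begin(), dist.end(), 0.0);
    for (int j = 0; j < d; ++j) {
      const double qv = qp[(size_t)j * nq + q];
      const double* col = refp + (size_t)j * nr;
      double* dd = dist.data();
      for (int r = 0; r < nr; ++r) {
        const double diff = col[r] - qv;
        dd[r] += diff * diff;
      }
    }
    // k-th smallest distance by value
    std::copy(dist.begin(), dist.end(), buf.begin());
    std::nth_element(buf.begin(), buf.begin() + (k - 1), buf.end());
    const double kth = buf[k - 1];
    // all strictly closer points are in; ties at the k-th distance fill the
    // remaining slots in reference-row order
    int n_less = 0, les_less = 0;
    for (int r = 0; r < nr; ++r) {
      if (dist[r] < kth) {
        ++n_less;
        les_less += lab[r];
      }
    }
    int need = k - n_less, les = les_less;
    for (int r = 0; r < nr && need > 0; ++r) {
      if (dist[r] == kth) {
        les += lab[r];
        --need;
      }
    }
    out[q] = static_cast<double>(les) / k;
  }
  return out;
}
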