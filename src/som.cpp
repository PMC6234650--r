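#include <Rcpp.h>
using namespace Rcpp;

// Online Kohonen SOM with bubble neighbourhood on a rectangular lattice.
// One presentation per step; learning rate and radius decay linearly over
// the step budget. order0 holds 0-based row indices of x, one per step.
// Codebook is held node-major (contiguous per node) for cache locality.
// [[Rcpp::export]]
NumericMatrix som_train_cpp(NumericMatrix codebook, NumericMatrix x,
                            IntegerVector order0, NumericMatrix coords,
                            double lr_start, double lr_end,
                            double r_start, double r_end) {
  const int nodes = codebook.nrow(), dim = codebook.ncol();
  const int T = order0.size();
  const int n = x.nrow();
  if (x.ncol() != dim) stop("dimension mismatch between data and codebook");

  std::vector<double> w((size_t)nodes * dim);
  for (int j = 0; j < nodes; ++j)
    for (int k = 0; k < dim; ++k) w[(size_t)j * dim + k] = codebook(j, k);
  std::vector<double> xr((size_t)n * dim);           // row-major copy of x
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < dim; ++k) xr[(size_t)i * dim + k] = x(i, k);
  std::vector<double> cr(nodes), cc(nodes);
  for (int j = 0; j < nodes; ++j) { cr[j] = coords(j, 0); cc[j] = coords(j, 1); }

  for (int t = 0; t < T; ++t) {
    double frac = (T > 1) ? (double)t / (double)(T - 1) : 0.0;
    double lr = lr_start + (lr_end - lr_start) * frac;
    double rad = r_start + (r_end - r_start) * frac;
    double rad2 = rad * rad;
    const double *xi = &xr[(size_t)order0[t] * dim];

    int b = 0;
    double best = R_PosInf;
    for (int j = 0; j < nodes; ++j) {
      const double *wj = &w[(size_t)j * dim];
      double d = 0.0;
      for (int k = 0; k < dim; ++k) {
        double diff = xi[k] - wj[k];
        d += diff * diff;
      }
      if (d < best) { best = d; b = j; }   // strict <: ties keep lowest ID
    }
    double br = cr[b], bc = cc[b];
    for (int j = 0; j < nodes; ++j) {
      double dr = cr[j] - br, dc = cc[j] - bc;
      // strict <: at the final radius of 1 only the BMU itself updates
      if (dr * dr + dc * dc < rad2) {
        double *wj = &w[(size_t)j * dim];
        for (int k = 0; k < dim; ++k) wj[k] += lr * (xi[k] - wj[k]);
      }
    }
  }
  NumericMatrix out(nodes, dim);
  for (int j = 0; j < nodes; ++j)
    for (int k = 0; k < dim; ++k) out(j, k) = w[(size_t)j * dim + k];
  return out;
}

// Best-matching unit and Euclidean distance for every row of x.
// [[Rcpp::export]]
List som_map_cpp(NumericMatrix codebook, NumericMatrix x) {
  const int nodes = codebook.nrow(), dim = codebook.ncol(), n = x.nrow();
  if (x.ncol() != dim) stop("dimension mismatch between data and codebook");
  std::vector<double> w((size_t)nodes * dim);
  for (int j = 0; j < nodes; ++j)
    for (int k = 0; k < dim; ++k) w[(size_t)j * dim + k] = codebook(j, k);
  IntegerVector bmu(n);
  NumericVector dist(n);
  std::vector<double> xi(dim);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < dim; ++k) xi[k] = x(i, k);
    int b = 0;
    double best = R_PosInf;
    for (int j = 0; j < nodes; ++j) {
      const double *wj = &w[(size_t)j * dim];
      double d = 0.0;
      for (int k = 0; k < dim; ++k) {
        double diff = xi[k] - wj[k];
        d += diff * diff;
      }
      if (d < best) { best = d; b = j; }
    }
    bmu[i] = b + 1;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["bmu"] = bmu, _["dist"] = dist);
}
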