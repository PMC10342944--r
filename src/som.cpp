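#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Reads are stored as integer codes 1..nsym (A,C,G,T,N). A node profile is a
// position-weight matrix flattened to length L*nsym; the soft-Hamming distance
// of a read to a node is L - sum_pos w[pos, base(read,pos)], which reduces to
// the integer Hamming distance when the profile is one-hot.

static inline double read_node_dist(const int* code_row, int n_reads,
                                    const double* w_col0, int n_nodes,
                                    int node, int L, int nsym) {
  double s = 0.0;
  for (int p = 0; p < L; ++p) {
    int sym = code_row[(R_xlen_t)p * n_reads] - 1;     // codes is n_reads x L
    s += w_col0[(R_xlen_t)(p * nsym + sym) * n_nodes + node];
  }
  return (double)L - s;
}

// [[Rcpp::export]]
NumericMatrix C_som_train(const IntegerMatrix codes, const IntegerVector init_idx,
                          const IntegerVector present, int grid_rows, int grid_cols,
                          double alpha0, double alpha1, double sigma0, double sigma1,
                          int nsym) {
  const int N = codes.nrow(), L = codes.ncol();
  const int n_nodes = grid_rows * grid_cols;
  const R_xlen_t W_len = (R_xlen_t)L * nsym;
  NumericMatrix W(n_nodes, W_len);
  const int rounds = present.size();

  // one-hot initialisation from sampled reads (node order is row-major)
  for (int k = 0; k < n_nodes; ++k) {
    int i = init_idx[k] - 1;
    for (int p = 0; p < L; ++p)
      W(k, (R_xlen_t)p * nsym + codes(i, p) - 1) = 1.0;
  }

  double* w = REAL(W);
  const int* cd = INTEGER(codes);

  for (int t = 0; t < rounds; ++t) {
    const int i = present[t] - 1;
    const int* row = cd + i;

    // best-matching unit; strict < keeps the smallest row-major index on ties
    int bmu = 0;
    double best = R_PosInf;
    for (int k = 0; k < n_nodes; ++k) {
      double d = read_node_dist(row, N, w, n_nodes, k, L, nsym);
      if (d < best) { best = d; bmu = k; }
    }

    const double frac = (rounds > 1) ? (double)t / (rounds - 1) : 0.0;
    const double alpha = alpha0 + (alpha1 - alpha0) * frac;
    const double sigma = sigma0 + (sigma1 - sigma0) * frac;
    const double s2 = 2.0 * sigma * sigma;
    const double cut2 = 9.0 * sigma * sigma;   // skip beyond 3 sigma
    const int br = bmu / grid_cols, bc = bmu % grid_cols;

    for (int r = 0; r < grid_rows; ++r) {
      const double dr = r - br;
      for (int c = 0; c < grid_cols; ++c) {
        const double dc = c - bc;
        const double d2 = dr * dr + dc * dc;
        if (d2 > cut2) continue;
        const double ah = alpha * std::exp(-d2 / s2);
        if (ah < 1e-6) continue;
        const int k = r * grid_cols + c;
        // w <- w + ah * (onehot - w): decay everything, then add at the base
        for (R_xlen_t j = 0; j < W_len; ++j)
          w[j * n_nodes + k] *= (1.0 - ah);
        for (int p = 0; p < L; ++p) {
          const int sym = row[(R_xlen_t)p * N] - 1;
          w[((R_xlen_t)p * nsym + sym) * n_nodes + k] += ah;
        }
      }
    }
  }
  return W;
}

// [[Rcpp::export]]
List C_som_assign(const IntegerMatrix codes, const NumericMatrix W,
                  int nsym) {
  const int N = codes.nrow(), L = codes.ncol();
  const int n_nodes = W.nrow();
  IntegerVector node(N);
  NumericVector dist(N);
  const double* w = REAL(W);
  const int* cd = INTEGER(codes);
  for (int i = 0; i < N; ++i) {
    const int* row = cd + i;
    int bmu = 0;
    double best = R_PosInf;
    for (int k = 0; k < n_nodes; ++k) {
      double d = read_node_dist(row, N, w, n_nodes, k, L, nsym);
      if (d < best) { best = d; bmu = k; }
    }
    node[i] = bmu + 1;
    dist[i] = best;
  }
  return List::create(_["node"] = node, _["distance"] = dist);
}

// Hamming distances for index pairs into the code matrix (1-based indices).
// [[Rcpp::export]]
IntegerVector C_hamming_pairs(const IntegerMatrix codes, const IntegerVector a,
                              const IntegerVector b) {
  const int n = a.size(), L = codes.ncol(), N = codes.nrow();
  IntegerVector h(n);
  const int* cd = INTEGER(codes);
  for (int q = 0; q < n; ++q) {
    const int* ra = cd + (a[q] - 1);
    const int* rb = cd + (b[q] - 1);
    int s = 0;
    for (int p = 0; p < L; ++p)
      if (ra[(R_xlen_t)p * N] != rb[(R_xlen_t)p * N]) ++s;
    h[q] = s;
  }
  return h;
}
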