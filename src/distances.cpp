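#include <Rcpp.h>
using namespace Rcpp;

static void fw_inplace(double *d, int n) {
  for (int k = 0; k < n; ++k) {
    const double *ck = d + (size_t)k * n;      // column k = distances to k
    for (int j = 0; j < n; ++j) {
      double dkj = d[(size_t)j * n + k];
      if (dkj == R_PosInf) continue;
      double *cj = d + (size_t)j * n;
      for (int i = 0; i < n; ++i) {
        double v = ck[i] + dkj;
        if (v < cj[i]) cj[i] = v;
      }
    }
  }
}

// Floyd-Warshall all-pairs shortest paths on an edge-length matrix
// (R_PosInf where there is no edge, 0 on the diagonal).
// [[Rcpp::export]]
NumericMatrix fw_dist_cpp(NumericMatrix len) {
  int n = len.nrow();
  NumericMatrix d = clone(len);
  fw_inplace(REAL(d), n);
  return d;
}

// Per-node local efficiency: global efficiency of each node's neighbor
// subgraph (original weights, reciprocal-weight lengths); nodes with
// fewer than two neighbors contribute 0.
// [[Rcpp::export]]
NumericVector local_eff_nodes_cpp(NumericMatrix w) {
  int n = w.nrow();
  const double *pw = REAL(w);
  NumericVector out(n);
  std::vector<int> nb;
  std::vector<double> sub;
  for (int i = 0; i < n; ++i) {
    nb.clear();
    const double *ci = pw + (size_t)i * n;
    for (int j = 0; j < n; ++j)
      if (ci[j] > 0) nb.push_back(j);
    int k = (int)nb.size();
    if (k < 2) { out[i] = 0.0; continue; }
    sub.assign((size_t)k * k, R_PosInf);
    for (int b = 0; b < k; ++b) {
      const double *cb = pw + (size_t)nb[b] * n;
      for (int a = 0; a < k; ++a) {
        if (a == b) { sub[(size_t)b * k + a] = 0.0; continue; }
        double ww = cb[nb[a]];
        if (ww > 0) sub[(size_t)b * k + a] = 1.0 / ww;
      }
    }
    fw_inplace(sub.data(), k);
    double s = 0.0;
    for (size_t idx = 0; idx < sub.size(); ++idx)
      if (sub[idx] > 0 && sub[idx] != R_PosInf) s += 1.0 / sub[idx];
    out[i] = s / (double(k) * double(k - 1));
  }
  return out;
}
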