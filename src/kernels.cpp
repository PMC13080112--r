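#include <Rcpp.h>
using namespace Rcpp;

// Embedded-chain sampler for the semi-Markov label generator.
// States are 1-based; `cum_trans` holds row-wise cumulative transition
// probabilities (zero diagonal before accumulation). Uses R's RNG so the
// draw stream is reproducible under set.seed().
// [[Rcpp::export]]
IntegerVector sample_chain_cpp(int n, NumericMatrix cum_trans, int init) {
  if (n < 1) return IntegerVector(0);
  int k = cum_trans.nrow();
  IntegerVector out(n);
  int state = init;
  out[0] = state;
  for (int i = 1; i < n; ++i) {
    double u = unif_rand();
    int nxt = k;  // guard against rounding: fall through to last state
    for (int j = 0; j < k; ++j) {
      if (u <= cum_trans(state - 1, j)) { nxt = j + 1; break; }
    }
    state = nxt;
    out[i] = state;
  }
  return out;
}

// Zero-phase IIR filtering of a channels x samples matrix: each row is
// padded by odd reflection (3 x filter order), filtered forward and
// backward with the transposed direct-form II difference equation, and
// trimmed. Coefficients come from the caller's filter design.
// [[Rcpp::export]]
NumericMatrix filtfilt_mat_cpp(NumericVector b, NumericVector a,
                               NumericMatrix x) {
  int nb = b.size(), na = a.size();
  int order = std::max(na, nb) - 1;
  if (order < 1) stop("filter order must be at least 1");
  int n = x.ncol(), nch = x.nrow();
  int npad = 3 * order;
  if (n <= npad) stop("signal too short for the filter's edge padding");
  std::vector<double> bb(order + 1, 0.0), aa(order + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i] / a[0];
  for (int i = 0; i < na; ++i) aa[i] = a[i] / a[0];
  NumericMatrix out(nch, n);
  int m = n + 2 * npad;
  std::vector<double> buf(m), z(order);
  for (int ch = 0; ch < nch; ++ch) {
    // odd reflection about both endpoints
    for (int i = 0; i < npad; ++i)
      buf[i] = 2.0 * x(ch, 0) - x(ch, npad - i);
    for (int i = 0; i < n; ++i) buf[npad + i] = x(ch, i);
    for (int i = 0; i < npad; ++i)
      buf[npad + n + i] = 2.0 * x(ch, n - 1) - x(ch, n - 2 - i);
    for (int pass = 0; pass < 2; ++pass) {
      std::fill(z.begin(), z.end(), 0.0);
      if (pass == 0) {
        for (int i = 0; i < m; ++i) {
          double xi = buf[i];
          double yi = bb[0] * xi + z[0];
          for (int k = 0; k < order - 1; ++k)
            z[k] = bb[k + 1] * xi + z[k + 1] - aa[k + 1] * yi;
          z[order - 1] = bb[order] * xi - aa[order] * yi;
          buf[i] = yi;
        }
      } else {
        for (int i = m - 1; i >= 0; --i) {
          double xi = buf[i];
          double yi = bb[0] * xi + z[0];
          for (int k = 0; k < order - 1; ++k)
            z[k] = bb[k + 1] * xi + z[k + 1] - aa[k + 1] * yi;
          z[order - 1] = bb[order] * xi - aa[order] * yi;
          buf[i] = yi;
        }
      }
    }
    for (int i = 0; i < n; ++i) out(ch, i) = buf[npad + i];
  }
  return out;
}

// Lempel-Ziv complexity of a symbol sequence by exhaustive-history
// parsing (Kaspar & Schuster): scan left to right, counting each time the
// current word extended by the next symbol is absent from the prefix seen
// so far. Returns the raw component count.
static int lzc_core(const int *s, int n) {
  int c = 1;       // the first symbol is always a new component
  int i = 1;       // start of the current word (0-based)
  int l = 1;       // current word length
  while (i + l <= n) {
    // does s[i .. i+l-1] occur anywhere in s[0 .. i+l-2]?
    bool found = false;
    for (int start = 0; start + l <= i + l - 1; ++start) {
      bool match = true;
      for (int j = 0; j < l; ++j) {
        if (s[start + j] != s[i + j]) { match = false; break; }
      }
      if (match) { found = true; break; }
    }
    if (found) {
      ++l;                       // extend the current word
    } else {
      ++c;                       // novel component
      i += l;
      l = 1;
    }
  }
  if (i < n) ++c;                // trailing (possibly reproducible) word
  return c;
}

// [[Rcpp::export]]
int lzc_cpp(IntegerVector s) {
  if (s.size() == 0) stop("empty sequence");
  return lzc_core(INTEGER(s), s.size());
}

// batch variant over the rows of a sequence matrix (validation sweeps)
// [[Rcpp::export]]
IntegerVector lzc_batch_cpp(IntegerMatrix s) {
  int m = s.nrow(), n = s.ncol();
  IntegerVector out(m);
  std::vector<int> row(n);
  for (int r = 0; r < m; ++r) {
    for (int j = 0; j < n; ++j) row[j] = s(r, j);
    out[r] = lzc_core(row.data(), n);
  }
  return out;
}
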