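#include <Rcpp.h>
using namespace Rcpp;

// Squared Euclidean distance from each row of `a` to its nearest row of `b`.
// Brute force: clouds in this package are a few thousand points, where an
// exact O(n*m) scan is faster than building a spatial index.
// [[Rcpp::export(name = ".nn_sqdist")]]
NumericVector nn_sqdist(NumericMatrix a, NumericMatrix b) {
  const int n = a.nrow(), m = b.nrow(), d = a.ncol();
  if (b.ncol() != d) stop("point clouds must have the same dimension");
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        const double diff = a(i, k) - b(j, k);
        s += diff * diff;
      }
      if (s < best) best = s;
    }
    out[i] = best;
  }
  return out;
}

// CRC-32 (IEEE 802.3, as used by PNG chunks) of a raw vector.
// [[Rcpp::export(name = ".crc32")]]
double crc32_raw(RawVector data) {
  static uint32_t table[256];
  static bool have_table = false;
  if (!have_table) {
    for (uint32_t n = 0; n < 256; ++n) {
      uint32_t c = n;
      for (int k = 0; k < 8; ++k)
        c = (c & 1) ? (0xEDB88320u ^ (c >> 1)) : (c >> 1);
      table[n] = c;
    }
    have_table = true;
  }
  uint32_t c = 0xFFFFFFFFu;
  const int n = data.size();
  for (int i = 0; i < n; ++i)
    c = table[(c ^ data[i]) & 0xFFu] ^ (c >> 8);
  return static_cast<double>(c ^ 0xFFFFFFFFu);
}
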