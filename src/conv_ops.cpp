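#include <Rcpp.h>
using namespace Rcpp;

// Column layout of the patch matrix: j = ch*k*k + kc*k + kr, i.e. channel-major,
// then kernel column, then kernel row.  Rows are column-major over the output
// pixels of the strip: i = r + (c - c0) * H.  Weight matrices in R use the same
// layout, so convolution is a single GEMM per strip.

// Extract a strip of im2col columns [c0, c0 + nc) from a zero-padded H x W x C
// array (stride-1, 'same' convolution; pad already applied by the caller).
// [[Rcpp::export]]
NumericMatrix im2col_strip(NumericVector xpad, int Hp, int Wp, int C,
                           int k, int dil, int H, int W, int c0, int nc) {
  NumericMatrix out(H * nc, C * k * k);
  const double* x = xpad.begin();
  for (int ch = 0; ch < C; ++ch) {
    const double* base = x + (R_xlen_t)ch * Hp * Wp;
    for (int kc = 0; kc < k; ++kc) {
      for (int kr = 0; kr < k; ++kr) {
        int col = ch * k * k + kc * k + kr;
        double* o = &out(0, col);
        for (int c = 0; c < nc; ++c) {
          const double* src = base + (R_xlen_t)(c0 + c + kc * dil) * Hp + kr * dil;
          double* dst = o + (R_xlen_t)c * H;
          for (int r = 0; r < H; ++r) dst[r] = src[r];
        }
      }
    }
  }
  return out;
}

// Scatter-add a strip of column gradients back into the padded gradient
// array.  Modifies `gpad` in place (it is allocated freshly by the caller and
// never shared, so in-place accumulation is safe).
// [[Rcpp::export]]
void col2im_strip(NumericVector gpad, NumericMatrix cols, int Hp, int Wp,
                  int C, int k, int dil, int H, int W, int c0, int nc) {
  double* g = gpad.begin();
  for (int ch = 0; ch < C; ++ch) {
    double* base = g + (R_xlen_t)ch * Hp * Wp;
    for (int kc = 0; kc < k; ++kc) {
      for (int kr = 0; kr < k; ++kr) {
        int col = ch * k * k + kc * k + kr;
        const double* o = &cols(0, col);
        for (int c = 0; c < nc; ++c) {
          double* dst = base + (R_xlen_t)(c0 + c + kc * dil) * Hp + kr * dil;
          const double* src = o + (R_xlen_t)c * H;
          for (int r = 0; r < H; ++r) dst[r] += src[r];
        }
      }
    }
  }
}
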