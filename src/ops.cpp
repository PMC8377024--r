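#include <Rcpp.h>
#include <zlib.h>

using namespace Rcpp;

// Feature maps are stored as (N*H*W) x C matrices, pixel-major rows:
// row = ((n * H) + y) * W + x  (0-based), i.e. x fastest, then y, then n.

// [[Rcpp::export]]
NumericMatrix cp_im2col(const NumericMatrix& X, int N, int H, int W,
                        int K, int stride, int pad) {
  const int C = X.ncol();
  const int Ho = (H + 2 * pad - K) / stride + 1;
  const int Wo = (W + 2 * pad - K) / stride + 1;
  NumericMatrix P(N * Ho * Wo, C * K * K);
  const double* x = X.begin();
  double* p = P.begin();
  const R_xlen_t xrows = X.nrow(), prows = P.nrow();
  for (int c = 0; c < C; ++c) {
    for (int ky = 0; ky < K; ++ky) {
      for (int kx = 0; kx < K; ++kx) {
        const int col = (c * K + ky) * K + kx;
        double* pc = p + (R_xlen_t)col * prows;
        const double* xc = x + (R_xlen_t)c * xrows;
        for (int n = 0; n < N; ++n) {
          for (int yo = 0; yo < Ho; ++yo) {
            const int yi = yo * stride + ky - pad;
            const R_xlen_t prow0 = ((R_xlen_t)n * Ho + yo) * Wo;
            if (yi < 0 || yi >= H) {
              for (int xo = 0; xo < Wo; ++xo) pc[prow0 + xo] = 0.0;
              continue;
            }
            const R_xlen_t xrow0 = ((R_xlen_t)n * H + yi) * W;
            for (int xo = 0; xo < Wo; ++xo) {
              const int xi = xo * stride + kx - pad;
              pc[prow0 + xo] =
                  (xi < 0 || xi >= W) ? 0.0 : xc[xrow0 + xi];
            }
          }
        }
      }
    }
  }
  return P;
}

// Adjoint of cp_im2col: scatter-adds patch gradients back to input layout.
// [[Rcpp::export]]
NumericMatrix cp_col2im(const NumericMatrix& P, int N, int H, int W, int C,
                        int K, int stride, int pad) {
  const int Ho = (H + 2 * pad - K) / stride + 1;
  const int Wo = (W + 2 * pad - K) / stride + 1;
  NumericMatrix X(N * H * W, C);
  const double* p = P.begin();
  double* x = X.begin();
  const R_xlen_t xrows = X.nrow(), prows = P.nrow();
  for (int c = 0; c < C; ++c) {
    for (int ky = 0; ky < K; ++ky) {
      for (int kx = 0; kx < K; ++kx) {
        const int col = (c * K + ky) * K + kx;
        const double* pc = p + (R_xlen_t)col * prows;
        double* xc = x + (R_xlen_t)c * xrows;
        for (int n = 0; n < N; ++n) {
          for (int yo = 0; yo < Ho; ++yo) {
            const int yi = yo * stride + ky - pad;
            if (yi < 0 || yi >= H) continue;
            const R_xlen_t prow0 = ((R_xlen_t)n * Ho + yo) * Wo;
            const R_xlen_t xrow0 = ((R_xlen_t)n * H + yi) * W;
            for (int xo = 0; xo < Wo; ++xo) {
              const int xi = xo * stride + kx - pad;
              if (xi < 0 || xi >= W) continue;
              xc[xrow0 + xi] += pc[prow0 + xo];
            }
          }
        }
      }
    }
  }
  return X;
}

static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// Connected-component labels of a logical H x W matrix (column-major, as R
// stores it). connectivity: 4 or 8. Background = 0; labels are 1..n_comp,
// assigned in raster order of each component's first pixel.
// [[Rcpp::export]]
IntegerMatrix cp_label(const LogicalMatrix& mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> parent(H * W);
  for (int i = 0; i < H * W; ++i) parent[i] = i;
  // link each foreground pixel to prior neighbours (left, up, diagonals)
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j)) continue;
      const int id = i + j * H;
      if (i > 0 && mask(i - 1, j)) uf_union(parent, id, id - 1);
      if (j > 0 && mask(i, j - 1)) uf_union(parent, id, id - H);
      if (connectivity == 8) {
        if (i > 0 && j > 0 && mask(i - 1, j - 1))
          uf_union(parent, id, id - H - 1);
        if (i < H - 1 && j > 0 && mask(i + 1, j - 1))
          uf_union(parent, id, id - H + 1);
      }
    }
  }
  std::map<int, int> remap;
  int next = 0;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j)) continue;
      const int root = uf_find(parent, i + j * H);
      auto it = remap.find(root);
      if (it == remap.end()) {
        remap[root] = ++next;
        lab(i, j) = next;
      } else {
        lab(i, j) = it->second;
      }
    }
  }
  return lab;
}

// [[Rcpp::export]]
RawVector cp_zlib_compress(const RawVector& data, int level) {
  uLong bound = compressBound((uLong)data.size());
  std::vector<Bytef> out(bound);
  uLongf outlen = bound;
  int rc = compress2(out.data(), &outlen, (const Bytef*)data.begin(),
                     (uLong)data.size(), level);
  if (rc != Z_OK) stop("zlib compression failed (code %d)", rc);
  RawVector res(outlen);
  std::copy(out.begin(), out.begin() + outlen, res.begin());
  return res;
}

// [[Rcpp::export]]
RawVector cp_zlib_uncompress(const RawVector& data, double expected_size) {
  uLongf outlen = (uLongf)expected_size;
  RawVector res((R_xlen_t)outlen);
  int rc = uncompress((Bytef*)res.begin(), &outlen,
                      (const Bytef*)data.begin(), (uLong)data.size());
  if (rc != Z_OK) stop("zlib decompression failed (code %d)", rc);
  if ((double)outlen != expected_size) stop("unexpected decompressed size");
  return res;
}

// [[Rcpp::export]]
double cp_crc32(const RawVector& data) {
  uLong crc = crc32(0L, Z_NULL, 0);
  crc = crc32(crc, (const Bytef*)data.begin(), (uInt)data.size());
  return (double)crc;
}

// X * a[col] + b[col], fused column-wise scale-and-shift (BN / bias path)
// [[Rcpp::export]]
NumericMatrix cp_col_axpb(const NumericMatrix& X, const NumericVector& a,
                          const NumericVector& b) {
  const R_xlen_t nr = X.nrow();
  const int nc = X.ncol();
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    const double ac = a[c], bc = b[c];
    const double* xc = X.begin() + (R_xlen_t)c * nr;
    double* oc = out.begin() + (R_xlen_t)c * nr;
    for (R_xlen_t i = 0; i < nr; ++i) oc[i] = xc[i] * ac + bc;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cp_colsum_prod(const NumericMatrix& X,
                             const NumericMatrix& Y) {
  const R_xlen_t nr = X.nrow();
  const int nc = X.ncol();
  NumericVector out(nc);
  for (int c = 0; c < nc; ++c) {
    const double* xc = X.begin() + (R_xlen_t)c * nr;
    const double* yc = Y.begin() + (R_xlen_t)c * nr;
    double s = 0;
    for (R_xlen_t i = 0; i < nr; ++i) s += xc[i] * yc[i];
    out[c] = s;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cp_relu(const NumericMatrix& X) {
  NumericMatrix out(X.nrow(), X.ncol());
  const double* x = X.begin();
  double* o = out.begin();
  const R_xlen_t n = (R_xlen_t)X.nrow() * X.ncol();
  for (R_xlen_t i = 0; i < n; ++i) o[i] = x[i] > 0 ? x[i] : 0;
  return out;
}

// dY where ref > 0, else 0 (ReLU backward against the cached output)
// [[Rcpp::export]]
NumericMatrix cp_mask_pos(const NumericMatrix& dY,
                          const NumericMatrix& ref) {
  NumericMatrix out(dY.nrow(), dY.ncol());
  const double* d = dY.begin();
  const double* r = ref.begin();
  double* o = out.begin();
  const R_xlen_t n = (R_xlen_t)dY.nrow() * dY.ncol();
  for (R_xlen_t i = 0; i < n; ++i) o[i] = r[i] > 0 ? d[i] : 0;
  return out;
}
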