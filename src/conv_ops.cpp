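// Low-level numerical kernels: same-padding 2-D convolution (forward and
// backward via im2col/GEMM), 2x2 max-pooling, nearest-neighbour 2x
// up-sampling, and connected-component labelling of binary masks.
// Tensors are H x W x C cubes mapped onto R arrays (column-major).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <queue>
using namespace Rcpp;

// Unfold x (H x W x Cin) into an (H*W) x (k*k*Cin) patch matrix for a
// k x k kernel with zero padding k/2. Pixel p = col*H + row (column-major).
static arma::mat im2col(const arma::cube& x, const int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int pad = k / 2;
  arma::mat cols(static_cast<size_t>(H) * W, static_cast<size_t>(k) * k * C,
                 arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const arma::mat& xc = x.slice(c);
    for (int dc = -pad; dc <= pad; ++dc) {
      for (int dr = -pad; dr <= pad; ++dr) {
        const int j = c * k * k + (dc + pad) * k + (dr + pad);
        const int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
        const int c0 = std::max(0, -dc), c1 = std::min(W, W - dc);
        double* dst = cols.colptr(j);
        for (int cc = c0; cc < c1; ++cc) {
          const double* src = xc.colptr(cc + dc) + (r0 + dr);
          std::copy(src, src + (r1 - r0), dst + static_cast<size_t>(cc) * H + r0);
        }
      }
    }
  }
  return cols;
}

// Scatter-add patch-matrix gradients back onto the input grid.
static arma::cube col2im(const arma::mat& dcols, const int H, const int W,
                         const int C, const int k) {
  const int pad = k / 2;
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    arma::mat& dxc = dx.slice(c);
    for (int dc = -pad; dc <= pad; ++dc) {
      for (int dr = -pad; dr <= pad; ++dr) {
        const int j = c * k * k + (dc + pad) * k + (dr + pad);
        const int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
        const int c0 = std::max(0, -dc), c1 = std::min(W, W - dc);
        const double* src = dcols.colptr(j);
        for (int cc = c0; cc < c1; ++cc) {
          double* dst = dxc.colptr(cc + dc) + (r0 + dr);
          const double* s = src + static_cast<size_t>(cc) * H + r0;
          for (int i = 0; i < r1 - r0; ++i) dst[i] += s[i];
        }
      }
    }
  }
  return dx;
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
arma::cube conv2d_fwd(const arma::cube& x, const arma::mat& w,
                      const arma::vec& b, const int k) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = w.n_cols;
  if (static_cast<int>(w.n_rows) != k * k * static_cast<int>(x.n_slices))
    stop("weight shape does not match input channels/kernel");
  arma::mat y = im2col(x, k) * w;
  arma::cube out(H, W, Cout);
  for (int o = 0; o < Cout; ++o)
    out.slice(o) = arma::reshape(y.col(o), H, W) + b(o);
  return out;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(const arma::cube& x, const arma::mat& w, const arma::cube& dy,
                const int k) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = dy.n_slices;
  arma::mat dy_mat(static_cast<size_t>(H) * W, Cout);
  for (int o = 0; o < Cout; ++o)
    dy_mat.col(o) = arma::vectorise(dy.slice(o));
  arma::mat cols = im2col(x, k);
  arma::mat dw = cols.t() * dy_mat;
  arma::vec db = arma::sum(dy_mat, 0).t();
  arma::cube dx = col2im(dy_mat * w.t(), H, W, Cin, k);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export(name = ".maxpool2_fwd")]]
List maxpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  if (H % 2 || W % 2) stop("max-pooling requires even spatial dimensions");
  const int h = H / 2, w = W / 2;
  arma::cube y(h, w, C);
  arma::ucube idx(h, w, C);  // linear index within the input slice
  for (int c = 0; c < C; ++c) {
    const arma::mat& xc = x.slice(c);
    for (int j = 0; j < w; ++j) {
      for (int i = 0; i < h; ++i) {
        double best = -arma::datum::inf;
        arma::uword bi = 0;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            const int r = 2 * i + di, cc = 2 * j + dj;
            const double v = xc(r, cc);
            if (v > best) { best = v; bi = static_cast<arma::uword>(cc) * H + r; }
          }
        }
        y(i, j, c) = best;
        idx(i, j, c) = bi;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_bwd")]]
arma::cube maxpool2_bwd(const arma::ucube& idx, const arma::cube& dy,
                        const int H, const int W) {
  const int C = dy.n_slices;
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    arma::mat& dxc = dx.slice(c);
    const arma::mat& dyc = dy.slice(c);
    const arma::umat& ic = idx.slice(c);
    for (arma::uword j = 0; j < dyc.n_cols; ++j)
      for (arma::uword i = 0; i < dyc.n_rows; ++i)
        dxc(ic(i, j)) += dyc(i, j);
  }
  return dx;
}

// [[Rcpp::export(name = ".upsample2_fwd")]]
arma::cube upsample2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const double v = x(i, j, c);
        y(2 * i, 2 * j, c) = v;
        y(2 * i + 1, 2 * j, c) = v;
        y(2 * i, 2 * j + 1, c) = v;
        y(2 * i + 1, 2 * j + 1, c) = v;
      }
  return y;
}

// [[Rcpp::export(name = ".upsample2_bwd")]]
arma::cube upsample2_bwd(const arma::cube& dy) {
  const int H = dy.n_rows / 2, W = dy.n_cols / 2, C = dy.n_slices;
  arma::cube dx(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        dx(i, j, c) = dy(2 * i, 2 * j, c) + dy(2 * i + 1, 2 * j, c) +
                      dy(2 * i, 2 * j + 1, c) + dy(2 * i + 1, 2 * j + 1, c);
  return dx;
}

// Connected components of a binary mask. Labels 1..K are assigned in
// raster order (row-major scan) of each component's first pixel.
// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components(const LogicalMatrix& mask, const int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  const int n_off = connectivity;
  const int off8r[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int off8c[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int off4r[4] = {-1, 0, 0, 1};
  const int off4c[4] = {0, -1, 1, 0};
  const int* offr = connectivity == 8 ? off8r : off4r;
  const int* offc = connectivity == 8 ? off8c : off4c;
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      lab(r, c) = ++next;
      q.push(std::make_pair(r, c));
      while (!q.empty()) {
        const std::pair<int, int> p = q.front();
        q.pop();
        for (int o = 0; o < n_off; ++o) {
          const int nr = p.first + offr[o], nc = p.second + offc[o];
          if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
          if (mask(nr, nc) && lab(nr, nc) == 0) {
            lab(nr, nc) = next;
            q.push(std::make_pair(nr, nc));
          }
        }
      }
    }
  }
  return lab;
}
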