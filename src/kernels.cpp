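// Low-level numeric kernels: im2col-based 2-D convolution (forward and
// backward), 2x2 max pooling, Zhang-Suen thinning, and a brute-force
// nearest-boundary (feature) transform used by the medial-axis extractor.
//
// Array convention: images/feature maps are R arrays with dim (H, W, C),
// column-major, so the linear index of (r, c, ch) is r + H*(c + W*ch).
// Convolution weights are (k*k*Cin) x Cout matrices whose row index runs
// over (dr, dc, ci) with dr fastest, matching cpp_im2col's column order.

#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat im2col_same(const arma::cube& x, int k, int dil) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int off = (k / 2) * dil;
  arma::mat M((size_t)H * W, (size_t)k * k * C, arma::fill::zeros);
  for (int ci = 0; ci < C; ++ci) {
    for (int dc = 0; dc < k; ++dc) {
      for (int dr = 0; dr < k; ++dr) {
        const size_t col = dr + (size_t)k * (dc + (size_t)k * ci);
        const int rs = dr * dil - off, cs = dc * dil - off;
        for (int c = 0; c < W; ++c) {
          const int sc = c + cs;
          if (sc < 0 || sc >= W) continue;
          const size_t base = (size_t)H * c;
          const int r0 = std::max(0, -rs), r1 = std::min(H, H - rs);
          for (int r = r0; r < r1; ++r)
            M(r + base, col) = x(r + rs, sc, ci);
        }
      }
    }
  }
  return M;
}

// [[Rcpp::export]]
arma::mat cpp_conv2d_fwd(const arma::cube& x, const arma::mat& Wm,
                         const arma::vec& b, int k, int dil) {
  arma::mat y = im2col_same(x, k, dil) * Wm;
  y.each_row() += b.t();
  return y;  // (H*W) x Cout; caller reshapes to (H, W, Cout)
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(const arma::cube& x, const arma::mat& Wm,
                    const arma::mat& Gy, int k, int dil) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat M = im2col_same(x, k, dil);
  arma::mat gW = M.t() * Gy;
  arma::rowvec gb = arma::sum(Gy, 0);
  arma::mat Gcol = Gy * Wm.t();  // (H*W) x (k*k*Cin)
  arma::cube gx(H, W, C, arma::fill::zeros);
  const int off = (k / 2) * dil;
  for (int ci = 0; ci < C; ++ci) {
    for (int dc = 0; dc < k; ++dc) {
      for (int dr = 0; dr < k; ++dr) {
        const size_t col = dr + (size_t)k * (dc + (size_t)k * ci);
        const int rs = dr * dil - off, cs = dc * dil - off;
        for (int c = 0; c < W; ++c) {
          const int sc = c + cs;
          if (sc < 0 || sc >= W) continue;
          const size_t base = (size_t)H * c;
          const int r0 = std::max(0, -rs), r1 = std::min(H, H - rs);
          for (int r = r0; r < r1; ++r)
            gx(r + rs, sc, ci) += Gcol(r + base, col);
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gW"] = gW,
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// [[Rcpp::export]]
List cpp_maxpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int h = H / 2, w = W / 2;
  arma::cube y(h, w, C);
  IntegerVector idx((size_t)h * w * C);  // 1-based linear index into x
  size_t t = 0;
  for (int ci = 0; ci < C; ++ci)
    for (int c = 0; c < w; ++c)
      for (int r = 0; r < h; ++r) {
        double best = -std::numeric_limits<double>::infinity();
        size_t bi = 0;
        for (int dc = 0; dc < 2; ++dc)
          for (int dr = 0; dr < 2; ++dr) {
            const int rr = 2 * r + dr, cc = 2 * c + dc;
            const double v = x(rr, cc, ci);
            if (v > best) {
              best = v;
              bi = rr + (size_t)H * (cc + (size_t)W * ci);
            }
          }
        y(r, c, ci) = best;
        idx[t++] = (int)bi + 1;
      }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// Zhang-Suen two-subiteration thinning. Neighbours P2..P9 run clockwise
// from north; borders are zero-padded. Iterates until a full pass removes
// no pixel, so the output is a fixed point of the algorithm.
// [[Rcpp::export]]
IntegerMatrix cpp_zhang_suen(const IntegerMatrix& img) {
  const int H = img.nrow(), W = img.ncol();
  IntegerMatrix a = clone(img);
  auto P = [&](int r, int c) -> int {
    if (r < 0 || r >= H || c < 0 || c >= W) return 0;
    return a(r, c) != 0 ? 1 : 0;
  };
  std::vector<std::pair<int, int>> del;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int sub = 0; sub < 2; ++sub) {
      del.clear();
      for (int c = 0; c < W; ++c)
        for (int r = 0; r < H; ++r) {
          if (!a(r, c)) continue;
          const int p2 = P(r - 1, c), p3 = P(r - 1, c + 1), p4 = P(r, c + 1),
                    p5 = P(r + 1, c + 1), p6 = P(r + 1, c), p7 = P(r + 1, c - 1),
                    p8 = P(r, c - 1), p9 = P(r - 1, c - 1);
          const int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          const int seq[9] = {p2, p3, p4, p5, p6, p7, p8, p9, p2};
          int A = 0;
          for (int i = 0; i < 8; ++i)
            if (seq[i] == 0 && seq[i + 1] == 1) ++A;
          if (A != 1) continue;
          if (sub == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          del.emplace_back(r, c);
        }
      if (!del.empty()) {
        changed = true;
        for (auto& p : del) a(p.first, p.second) = 0;
      }
    }
  }
  return a;
}

// Geodesic distance within a binary region from a set of source pixels
// (n x 2 matrix of 1-based (row, col)), 8-connected with weights 1
// (orthogonal) and sqrt(2) (diagonal). Background and unreachable pixels
// get Inf.
// [[Rcpp::export]]
NumericMatrix cpp_geodesic_dist(const IntegerMatrix& mask,
                                const IntegerMatrix& sources) {
  const int H = mask.nrow(), W = mask.ncol();
  NumericMatrix D(H, W);
  std::fill(D.begin(), D.end(), R_PosInf);
  typedef std::pair<double, int> QE;  // (dist, linear index)
  std::priority_queue<QE, std::vector<QE>, std::greater<QE>> q;
  for (int s = 0; s < sources.nrow(); ++s) {
    const int r0 = sources(s, 0), c0 = sources(s, 1);
    if (r0 < 1 || r0 > H || c0 < 1 || c0 > W || !mask(r0 - 1, c0 - 1))
      continue;
    D(r0 - 1, c0 - 1) = 0.0;
    q.emplace(0.0, (r0 - 1) + H * (c0 - 1));
  }
  const double SQ2 = std::sqrt(2.0);
  while (!q.empty()) {
    const double d = q.top().first;
    const int idx = q.top().second;
    q.pop();
    const int r = idx % H, c = idx / H;
    if (d > D(r, c)) continue;
    for (int dc = -1; dc <= 1; ++dc)
      for (int dr = -1; dr <= 1; ++dr) {
        if (!dr && !dc) continue;
        const int rr = r + dr, cc = c + dc;
        if (rr < 0 || rr >= H || cc < 0 || cc >= W || !mask(rr, cc)) continue;
        const double nd = d + ((dr && dc) ? SQ2 : 1.0);
        if (nd < D(rr, cc)) {
          D(rr, cc) = nd;
          q.emplace(nd, rr + H * cc);
        }
      }
  }
  return D;
}

// For every foreground pixel, the nearest background pixel among those
// 8-adjacent to the foreground (the discrete shape boundary). Pixels outside
// the image frame count as background. Returns 1-based feature coordinates
// (0 where the pixel is background) and the distance.
// [[Rcpp::export]]
List cpp_nearest_bg(const IntegerMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  auto fg = [&](int r, int c) -> bool {
    if (r < 0 || r >= H || c < 0 || c >= W) return false;
    return mask(r, c) != 0;
  };
  // candidate background pixels: inside the frame next to foreground, or
  // virtual out-of-frame pixels next to border foreground
  std::vector<std::pair<int, int>> cand;
  for (int c = -1; c <= W; ++c)
    for (int r = -1; r <= H; ++r) {
      if (fg(r, c)) continue;
      bool adj = false;
      for (int dc = -1; dc <= 1 && !adj; ++dc)
        for (int dr = -1; dr <= 1 && !adj; ++dr)
          if ((dr || dc) && fg(r + dr, c + dc)) adj = true;
      if (adj) cand.emplace_back(r, c);
    }
  IntegerMatrix FR(H, W), FC(H, W);
  NumericMatrix D(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c)) continue;
      double best = std::numeric_limits<double>::infinity();
      int br = r, bc = c;
      for (auto& q : cand) {
        const double dr = q.first - r, dc = q.second - c;
        const double d2 = dr * dr + dc * dc;
        if (d2 < best) {
          best = d2;
          br = q.first;
          bc = q.second;
        }
      }
      FR(r, c) = br + 1;
      FC(r, c) = bc + 1;
      D(r, c) = std::sqrt(best);
    }
  return List::create(_["fr"] = FR, _["fc"] = FC, _["dist"] = D);
}
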