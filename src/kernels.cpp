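#include <Rcpp.h>
using namespace Rcpp;

// Layouts (R column-major):
//   feature maps  (C, W, H, D)
//   conv weights  (Cout, Cin, 3, 3, 3), padding 1
//   volumes       (W, H, D)
//   displacement  (3, W, H, D), voxel units, gather convention

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// [[Rcpp::export]]
NumericVector conv3d_fw(NumericVector x, NumericVector w, NumericVector b,
                        int stride) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int Cin = xd[0], W = xd[1], H = xd[2], D = xd[3];
  const int Cout = wd[0];
  const int Wo = (W - 1) / stride + 1, Ho = (H - 1) / stride + 1,
            Do = (D - 1) / stride + 1;
  NumericVector out(Cout * Wo * Ho * Do);
  out.attr("dim") = IntegerVector::create(Cout, Wo, Ho, Do);
  const double *px = x.begin(), *pw = w.begin(), *pb = b.begin();
  double *po = out.begin();
  for (int zo = 0; zo < Do; ++zo)
    for (int yo = 0; yo < Ho; ++yo)
      for (int xo = 0; xo < Wo; ++xo) {
        double *o = po + (size_t)Cout * (xo + (size_t)Wo * (yo + (size_t)Ho * zo));
        for (int co = 0; co < Cout; ++co) o[co] = pb[co];
        for (int kz = 0; kz < 3; ++kz) {
          int zi = zo * stride + kz - 1;
          if (zi < 0 || zi >= D) continue;
          for (int ky = 0; ky < 3; ++ky) {
            int yi = yo * stride + ky - 1;
            if (yi < 0 || yi >= H) continue;
            for (int kx = 0; kx < 3; ++kx) {
              int xi = xo * stride + kx - 1;
              if (xi < 0 || xi >= W) continue;
              const double *xin =
                  px + (size_t)Cin * (xi + (size_t)W * (yi + (size_t)H * zi));
              const double *wk =
                  pw + (size_t)Cout * Cin * (kx + 3 * (ky + 3 * kz));
              for (int ci = 0; ci < Cin; ++ci) {
                const double xv = xin[ci];
                if (xv == 0.0) continue;
                const double *wc = wk + (size_t)Cout * ci;
                for (int co = 0; co < Cout; ++co) o[co] += wc[co] * xv;
              }
            }
          }
        }
      }
  return out;
}

// [[Rcpp::export]]
List conv3d_bw(NumericVector x, NumericVector w, NumericVector gout,
               int stride) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int Cin = xd[0], W = xd[1], H = xd[2], D = xd[3];
  const int Cout = wd[0];
  const int Wo = (W - 1) / stride + 1, Ho = (H - 1) / stride + 1,
            Do = (D - 1) / stride + 1;
  NumericVector gx(x.size()), gw(w.size()), gb(Cout);
  gx.attr("dim") = xd;
  gw.attr("dim") = wd;
  const double *px = x.begin(), *pw = w.begin(), *pg = gout.begin();
  double *pgx = gx.begin(), *pgw = gw.begin(), *pgb = gb.begin();
  for (int zo = 0; zo < Do; ++zo)
    for (int yo = 0; yo < Ho; ++yo)
      for (int xo = 0; xo < Wo; ++xo) {
        const double *g =
            pg + (size_t)Cout * (xo + (size_t)Wo * (yo + (size_t)Ho * zo));
        for (int co = 0; co < Cout; ++co) pgb[co] += g[co];
        for (int kz = 0; kz < 3; ++kz) {
          int zi = zo * stride + kz - 1;
          if (zi < 0 || zi >= D) continue;
          for (int ky = 0; ky < 3; ++ky) {
            int yi = yo * stride + ky - 1;
            if (yi < 0 || yi >= H) continue;
            for (int kx = 0; kx < 3; ++kx) {
              int xi = xo * stride + kx - 1;
              if (xi < 0 || xi >= W) continue;
              size_t xoff = (size_t)Cin * (xi + (size_t)W * (yi + (size_t)H * zi));
              size_t woff = (size_t)Cout * Cin * (kx + 3 * (ky + 3 * kz));
              for (int ci = 0; ci < Cin; ++ci) {
                const double xv = px[xoff + ci];
                const double *wc = pw + woff + (size_t)Cout * ci;
                double *gwc = pgw + woff + (size_t)Cout * ci;
                double acc = 0.0;
                for (int co = 0; co < Cout; ++co) {
                  acc += wc[co] * g[co];
                  gwc[co] += xv * g[co];
                }
                pgx[xoff + ci] += acc;
              }
            }
          }
        }
      }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Backward warp (gather): out(x) = mov(x + T(x)), border-clamped sampling.
// mode 0 = trilinear, 1 = nearest.
// [[Rcpp::export]]
NumericVector warp_fw(NumericVector mov, NumericVector ddf, int nearest) {
  IntegerVector md = mov.attr("dim");
  const int W = md[0], H = md[1], D = md[2];
  NumericVector out(mov.size());
  out.attr("dim") = md;
  const double *pm = mov.begin(), *pd = ddf.begin();
  double *po = out.begin();
  for (int z = 0; z < D; ++z)
    for (int y = 0; y < H; ++y)
      for (int x = 0; x < W; ++x) {
        size_t vi = (size_t)x + (size_t)W * (y + (size_t)H * z);
        const double *t = pd + 3 * vi;
        double sx = x + t[0], sy = y + t[1], sz = z + t[2];
        sx = sx < 0 ? 0 : (sx > W - 1 ? W - 1 : sx);
        sy = sy < 0 ? 0 : (sy > H - 1 ? H - 1 : sy);
        sz = sz < 0 ? 0 : (sz > D - 1 ? D - 1 : sz);
        if (nearest) {
          int ix = (int)std::floor(sx + 0.5), iy = (int)std::floor(sy + 0.5),
              iz = (int)std::floor(sz + 0.5);
          ix = clampi(ix, 0, W - 1);
          iy = clampi(iy, 0, H - 1);
          iz = clampi(iz, 0, D - 1);
          po[vi] = pm[(size_t)ix + (size_t)W * (iy + (size_t)H * iz)];
        } else {
          int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy),
              z0 = (int)std::floor(sz);
          x0 = clampi(x0, 0, W - 1);
          y0 = clampi(y0, 0, H - 1);
          z0 = clampi(z0, 0, D - 1);
          int x1 = clampi(x0 + 1, 0, W - 1), y1 = clampi(y0 + 1, 0, H - 1),
              z1 = clampi(z0 + 1, 0, D - 1);
          double fx = sx - x0, fy = sy - y0, fz = sz - z0;
          double c000 = pm[(size_t)x0 + (size_t)W * (y0 + (size_t)H * z0)];
          double c100 = pm[(size_t)x1 + (size_t)W * (y0 + (size_t)H * z0)];
          double c010 = pm[(size_t)x0 + (size_t)W * (y1 + (size_t)H * z0)];
          double c110 = pm[(size_t)x1 + (size_t)W * (y1 + (size_t)H * z0)];
          double c001 = pm[(size_t)x0 + (size_t)W * (y0 + (size_t)H * z1)];
          double c101 = pm[(size_t)x1 + (size_t)W * (y0 + (size_t)H * z1)];
          double c011 = pm[(size_t)x0 + (size_t)W * (y1 + (size_t)H * z1)];
          double c111 = pm[(size_t)x1 + (size_t)W * (y1 + (size_t)H * z1)];
          double c00 = c000 * (1 - fx) + c100 * fx;
          double c10 = c010 * (1 - fx) + c110 * fx;
          double c01 = c001 * (1 - fx) + c101 * fx;
          double c11 = c011 * (1 - fx) + c111 * fx;
          double c0 = c00 * (1 - fy) + c10 * fy;
          double c1 = c01 * (1 - fy) + c11 * fy;
          po[vi] = c0 * (1 - fz) + c1 * fz;
        }
      }
  return out;
}

// Gradient of the trilinear warp with respect to the displacement field.
// Sampling coordinates clamped to the border have zero derivative.
// [[Rcpp::export]]
NumericVector warp_bw_ddf(NumericVector mov, NumericVector ddf,
                          NumericVector gout) {
  IntegerVector md = mov.attr("dim");
  const int W = md[0], H = md[1], D = md[2];
  NumericVector gd(ddf.size());
  gd.attr("dim") = ddf.attr("dim");
  const double *pm = mov.begin(), *pd = ddf.begin(), *pg = gout.begin();
  double *pgd = gd.begin();
  for (int z = 0; z < D; ++z)
    for (int y = 0; y < H; ++y)
      for (int x = 0; x < W; ++x) {
        size_t vi = (size_t)x + (size_t)W * (y + (size_t)H * z);
        const double go = pg[vi];
        if (go == 0.0) continue;
        const double *t = pd + 3 * vi;
        double sx = x + t[0], sy = y + t[1], sz = z + t[2];
        bool inx = (sx > 0 && sx < W - 1), iny = (sy > 0 && sy < H - 1),
             inz = (sz > 0 && sz < D - 1);
        sx = sx < 0 ? 0 : (sx > W - 1 ? W - 1 : sx);
        sy = sy < 0 ? 0 : (sy > H - 1 ? H - 1 : sy);
        sz = sz < 0 ? 0 : (sz > D - 1 ? D - 1 : sz);
        int x0 = clampi((int)std::floor(sx), 0, W - 1);
        int y0 = clampi((int)std::floor(sy), 0, H - 1);
        int z0 = clampi((int)std::floor(sz), 0, D - 1);
        int x1 = clampi(x0 + 1, 0, W - 1), y1 = clampi(y0 + 1, 0, H - 1),
            z1 = clampi(z0 + 1, 0, D - 1);
        double fx = sx - x0, fy = sy - y0, fz = sz - z0;
        double c000 = pm[(size_t)x0 + (size_t)W * (y0 + (size_t)H * z0)];
        double c100 = pm[(size_t)x1 + (size_t)W * (y0 + (size_t)H * z0)];
        double c010 = pm[(size_t)x0 + (size_t)W * (y1 + (size_t)H * z0)];
        double c110 = pm[(size_t)x1 + (size_t)W * (y1 + (size_t)H * z0)];
        double c001 = pm[(size_t)x0 + (size_t)W * (y0 + (size_t)H * z1)];
        double c101 = pm[(size_t)x1 + (size_t)W * (y0 + (size_t)H * z1)];
        double c011 = pm[(size_t)x0 + (size_t)W * (y1 + (size_t)H * z1)];
        double c111 = pm[(size_t)x1 + (size_t)W * (y1 + (size_t)H * z1)];
        // d/dfx
        double dx = ((c100 - c000) * (1 - fy) + (c110 - c010) * fy) * (1 - fz) +
                    ((c101 - c001) * (1 - fy) + (c111 - c011) * fy) * fz;
        double dy = ((c010 - c000) * (1 - fx) + (c110 - c100) * fx) * (1 - fz) +
                    ((c011 - c001) * (1 - fx) + (c111 - c101) * fx) * fz;
        double dz = ((c001 - c000) * (1 - fx) + (c101 - c100) * fx) * (1 - fy) +
                    ((c011 - c010) * (1 - fx) + (c111 - c110) * fx) * fy;
        double *g = pgd + 3 * vi;
        if (inx) g[0] += go * dx;
        if (iny) g[1] += go * dy;
        if (inz) g[2] += go * dz;
      }
  return gd;
}
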