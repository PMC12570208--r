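#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Gaussian gridding kernels for the 3D NUFFT (Greengard-Lee style).
//
// Nodes xi are in radians per mode-grid step, i.e. xi in [-pi, pi) covers
// the representable band.  The fine grid has nf points per dimension with
// spacing h = 2*pi/nf; each node touches (2m)^3 fine-grid points through
// the separable kernel exp(-d^2/(4*tau)).  Per-dimension weights use the
// standard three-term factorization (two exp() calls per point and
// dimension).  Spreading/interpolation work on a halo-padded cube so the
// inner loops are contiguous; a single fold/unfold pass applies grid
// periodicity.  Points are visited in bucket order (counting sort on the
// (z, y) cell) for cache locality.  Hot loops carry target_clones so an
// AVX2/FMA build is selected at run time when the CPU supports it.

#define HOT_CLONES __attribute__((target_clones("arch=x86-64-v3", "default")))

struct DimW {
  int jstart;                 // padded-coordinate start index
  double w[32];               // up to 2m = 32 weights
};

static inline void dim_weights(double xi, double h, int nf, int m, double tau,
                               const double* t2tab, DimW& dw) {
  double u = xi / h + 0.5 * nf;              // in [0, nf] for in-band nodes
  int j0 = (int)std::floor(u);
  dw.jstart = j0 + 1;                        // padded coordinate of left-most point
  double d0 = (u - (j0 - m + 1)) * h;        // distance to left-most point
  double e0 = std::exp(-d0 * d0 / (4.0 * tau));
  double rho = std::exp(d0 * h / (2.0 * tau));
  double r = 1.0;
  for (int t = 0; t < 2 * m; ++t) {
    dw.w[t] = e0 * r * t2tab[t];
    r *= rho;
  }
}

// Counting sort of points by fine-grid (z, y) cell; returns permutation.
static std::vector<R_xlen_t> bucket_order(const double* xiy, const double* xiz,
                                          R_xlen_t P, double h, int nf) {
  const R_xlen_t nb = (R_xlen_t)nf * nf;
  std::vector<R_xlen_t> count(nb + 1, 0), perm(P);
  std::vector<int> key(P);
  for (R_xlen_t p = 0; p < P; ++p) {
    int jy = (int)std::floor(xiy[p] / h) % nf; if (jy < 0) jy += nf;
    int jz = (int)std::floor(xiz[p] / h) % nf; if (jz < 0) jz += nf;
    key[p] = jz * nf + jy;
    ++count[key[p] + 1];
  }
  for (R_xlen_t b = 0; b < nb; ++b) count[b + 1] += count[b];
  for (R_xlen_t p = 0; p < P; ++p) perm[count[key[p]]++] = p;
  return perm;
}

// Padded coordinate jp (0 .. nf+2m) maps to fine index ((jp - m - nf/2) mod nf).
static inline int fold_index(int jp, int m, int nf) {
  int j = (jp - m - nf / 2) % nf;
  return j < 0 ? j + nf : j;
}

HOT_CLONES
static void spread_loop_real(const double* xix, const double* xiy, const double* xiz,
                             const double* v, R_xlen_t P,
                             double h, int nf, int np, int m, double tau,
                             const double* t2tab, double* __restrict pad) {
  DimW d1, d2, d3;
  for (R_xlen_t p = 0; p < P; ++p) {
    dim_weights(xix[p], h, nf, m, tau, t2tab, d1);
    dim_weights(xiy[p], h, nf, m, tau, t2tab, d2);
    dim_weights(xiz[p], h, nf, m, tau, t2tab, d3);
    const double vr = v[p];
    for (int c = 0; c < 2 * m; ++c) {
      const double wc = d3.w[c];
      const R_xlen_t off3 = ((R_xlen_t)(d3.jstart + c) * np + d2.jstart) * np + d1.jstart;
      for (int b = 0; b < 2 * m; ++b) {
        const double ar = vr * d2.w[b] * wc;
        double* __restrict row = pad + off3 + (R_xlen_t)b * np;
        for (int a = 0; a < 2 * m; ++a) row[a] += ar * d1.w[a];
      }
    }
  }
}

HOT_CLONES
static void spread_loop_cplx(const double* xix, const double* xiy, const double* xiz,
                             const double* vre, const double* vim, R_xlen_t P,
                             double h, int nf, int np, int m, double tau,
                             const double* t2tab, double* __restrict pad) {
  DimW d1, d2, d3;
  for (R_xlen_t p = 0; p < P; ++p) {
    dim_weights(xix[p], h, nf, m, tau, t2tab, d1);
    dim_weights(xiy[p], h, nf, m, tau, t2tab, d2);
    dim_weights(xiz[p], h, nf, m, tau, t2tab, d3);
    const double vr = vre[p], vi = vim[p];
    for (int c = 0; c < 2 * m; ++c) {
      const double wc = d3.w[c];
      const R_xlen_t off3 = ((R_xlen_t)(d3.jstart + c) * np + d2.jstart) * np + d1.jstart;
      for (int b = 0; b < 2 * m; ++b) {
        const double wbc = d2.w[b] * wc;
        const double ar = vr * wbc, ai = vi * wbc;
        double* __restrict row = pad + (off3 + (R_xlen_t)b * np) * 2;
        for (int a = 0; a < 2 * m; ++a) {
          row[2 * a] += ar * d1.w[a];
          row[2 * a + 1] += ai * d1.w[a];
        }
      }
    }
  }
}

HOT_CLONES
static void interp_loop(const double* xix, const double* xiy, const double* xiz,
                        R_xlen_t P,
                        double h, int nf, int np, int m, double tau,
                        const double* t2tab, const double* __restrict pad,
                        double* ore, double* oim) {
  DimW d1, d2, d3;
  for (R_xlen_t p = 0; p < P; ++p) {
    dim_weights(xix[p], h, nf, m, tau, t2tab, d1);
    dim_weights(xiy[p], h, nf, m, tau, t2tab, d2);
    dim_weights(xiz[p], h, nf, m, tau, t2tab, d3);
    double sr = 0.0, si = 0.0;
    for (int c = 0; c < 2 * m; ++c) {
      const double wc = d3.w[c];
      const R_xlen_t off3 = ((R_xlen_t)(d3.jstart + c) * np + d2.jstart) * np + d1.jstart;
      for (int b = 0; b < 2 * m; ++b) {
        const double wbc = d2.w[b] * wc;
        const double* __restrict row = pad + (off3 + (R_xlen_t)b * np) * 2;
        double tr = 0.0, ti = 0.0;
        for (int a = 0; a < 2 * m; ++a) {
          tr += row[2 * a] * d1.w[a];
          ti += row[2 * a + 1] * d1.w[a];
        }
        sr += tr * wbc;
        si += ti * wbc;
      }
    }
    ore[p] = sr;
    oim[p] = si;
  }
}

// [[Rcpp::export]]
NumericVector nufft_spread3_real(NumericMatrix xi, NumericVector values,
                                 int nf, int m, double tau) {
  const R_xlen_t P = xi.nrow();
  const double h = 2.0 * M_PI / nf;
  const int np = nf + 2 * m + 1;
  NumericVector out((R_xlen_t)nf * nf * nf);
  std::vector<double> pad((R_xlen_t)np * np * np, 0.0);
  std::vector<double> t2tab(2 * m);
  for (int t = 0; t < 2 * m; ++t) t2tab[t] = std::exp(-(t * h) * (t * h) / (4.0 * tau));
  const double* xix = &xi(0, 0);
  const double* xiy = &xi(0, 1);
  const double* xiz = &xi(0, 2);
  std::vector<R_xlen_t> perm = bucket_order(xiy, xiz, P, h, nf);
  std::vector<double> sx(P), sy(P), sz(P), sv(P);
  const double* v = REAL(values);
  for (R_xlen_t q = 0; q < P; ++q) {
    const R_xlen_t p = perm[q];
    sx[q] = xix[p]; sy[q] = xiy[p]; sz[q] = xiz[p]; sv[q] = v[p];
  }
  spread_loop_real(sx.data(), sy.data(), sz.data(), sv.data(), P, h, nf, np, m, tau,
                   t2tab.data(), pad.data());
  double* g = REAL(out);
  std::vector<int> fidx(np);
  for (int jp = 0; jp < np; ++jp) fidx[jp] = fold_index(jp, m, nf);
  for (int c = 0; c < np; ++c)
    for (int b = 0; b < np; ++b) {
      const R_xlen_t offo = ((R_xlen_t)fidx[c] * nf + fidx[b]) * nf;
      const double* row = pad.data() + ((R_xlen_t)c * np + b) * np;
      for (int a = 0; a < np; ++a) g[offo + fidx[a]] += row[a];
    }
  out.attr("dim") = IntegerVector::create(nf, nf, nf);
  return out;
}

// [[Rcpp::export]]
ComplexVector nufft_spread3(NumericMatrix xi, ComplexVector values,
                            int nf, int m, double tau) {
  const R_xlen_t P = xi.nrow();
  const double h = 2.0 * M_PI / nf;
  const int np = nf + 2 * m + 1;
  ComplexVector out((R_xlen_t)nf * nf * nf);
  std::vector<double> pad((R_xlen_t)np * np * np * 2, 0.0);
  std::vector<double> t2tab(2 * m);
  for (int t = 0; t < 2 * m; ++t) t2tab[t] = std::exp(-(t * h) * (t * h) / (4.0 * tau));
  const double* xix = &xi(0, 0);
  const double* xiy = &xi(0, 1);
  const double* xiz = &xi(0, 2);
  std::vector<R_xlen_t> perm = bucket_order(xiy, xiz, P, h, nf);
  std::vector<double> sx(P), sy(P), sz(P), svr(P), svi(P);
  const Rcomplex* v = COMPLEX(values);
  for (R_xlen_t q = 0; q < P; ++q) {
    const R_xlen_t p = perm[q];
    sx[q] = xix[p]; sy[q] = xiy[p]; sz[q] = xiz[p];
    svr[q] = v[p].r; svi[q] = v[p].i;
  }
  spread_loop_cplx(sx.data(), sy.data(), sz.data(), svr.data(), svi.data(), P,
                   h, nf, np, m, tau, t2tab.data(), pad.data());
  Rcomplex* g = COMPLEX(out);
  std::vector<int> fidx(np);
  for (int jp = 0; jp < np; ++jp) fidx[jp] = fold_index(jp, m, nf);
  for (int c = 0; c < np; ++c)
    for (int b = 0; b < np; ++b) {
      const R_xlen_t offo = ((R_xlen_t)fidx[c] * nf + fidx[b]) * nf;
      const double* row = pad.data() + (((R_xlen_t)c * np + b) * np) * 2;
      for (int a = 0; a < np; ++a) {
        g[offo + fidx[a]].r += row[2 * a];
        g[offo + fidx[a]].i += row[2 * a + 1];
      }
    }
  out.attr("dim") = IntegerVector::create(nf, nf, nf);
  return out;
}

// [[Rcpp::export]]
ComplexVector nufft_interp3(ComplexVector grid, NumericMatrix xi,
                            int nf, int m, double tau) {
  const R_xlen_t P = xi.nrow();
  const double h = 2.0 * M_PI / nf;
  const int np = nf + 2 * m + 1;
  ComplexVector out(P);
  const Rcomplex* g = COMPLEX(grid);
  // halo-padded interleaved copy of the cube for contiguous gathers
  std::vector<double> pad((R_xlen_t)np * np * np * 2);
  std::vector<int> fidx(np);
  for (int jp = 0; jp < np; ++jp) fidx[jp] = fold_index(jp, m, nf);
  for (int c = 0; c < np; ++c)
    for (int b = 0; b < np; ++b) {
      const R_xlen_t offi = ((R_xlen_t)fidx[c] * nf + fidx[b]) * nf;
      double* row = pad.data() + (((R_xlen_t)c * np + b) * np) * 2;
      for (int a = 0; a < np; ++a) {
        row[2 * a] = g[offi + fidx[a]].r;
        row[2 * a + 1] = g[offi + fidx[a]].i;
      }
    }
  std::vector<double> t2tab(2 * m);
  for (int t = 0; t < 2 * m; ++t) t2tab[t] = std::exp(-(t * h) * (t * h) / (4.0 * tau));
  const double* xix = &xi(0, 0);
  const double* xiy = &xi(0, 1);
  const double* xiz = &xi(0, 2);
  std::vector<R_xlen_t> perm = bucket_order(xiy, xiz, P, h, nf);
  std::vector<double> sx(P), sy(P), sz(P), ore(P), oim(P);
  for (R_xlen_t q = 0; q < P; ++q) {
    const R_xlen_t p = perm[q];
    sx[q] = xix[p]; sy[q] = xiy[p]; sz[q] = xiz[p];
  }
  interp_loop(sx.data(), sy.data(), sz.data(), P, h, nf, np, m, tau,
              t2tab.data(), pad.data(), ore.data(), oim.data());
  Rcomplex* o = COMPLEX(out);
  for (R_xlen_t q = 0; q < P; ++q) {
    o[perm[q]].r = ore[q];
    o[perm[q]].i = oim[q];
  }
  return out;
}

// Band-limit check: returns (1-based) indices of out-of-band nodes, at most 10.
// [[Rcpp::export]]
IntegerVector nufft_band_violations(NumericMatrix xi, double limit) {
  std::vector<int> bad;
  const R_xlen_t P = xi.nrow();
  for (R_xlen_t p = 0; p < P && bad.size() < 10; ++p) {
    if (std::fabs(xi(p, 0)) > limit || std::fabs(xi(p, 1)) > limit ||
        std::fabs(xi(p, 2)) > limit)
      bad.push_back((int)(p + 1));
  }
  return wrap(bad);
}
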