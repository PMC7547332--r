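#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Speckle-reducing anisotropic diffusion (Yu & Acton).
//
// Explicit (Jacobi) update I <- I + (dt/4) * div(c(q) grad I) with
// one-sided differences, mirror (replicate) boundaries, and the diffusion
// coefficient c(q) = 1 / (1 + (q^2 - q0^2) / (q0^2 (1 + q0^2))) driven by
// the instantaneous coefficient of variation q. The speckle scale q0
// decays as q0(t) = q0_init * exp(-decay * t) with t the diffusion time.
//
// [[Rcpp::export]]
NumericMatrix srad_cpp(NumericMatrix img, int n_iter, double dt,
                       double q0_init, double q0_decay) {
  const int nr = img.nrow(), nc = img.ncol();
  const size_t npx = static_cast<size_t>(nr) * nc;
  std::vector<double> A(REAL(img), REAL(img) + npx), B(npx), c(npx);
  double *cur = A.data(), *nxt = B.data();

  for (int it = 0; it < n_iter; ++it) {
    const double q0 = q0_init * std::exp(-q0_decay * it * dt);
    const double q0sq = q0 * q0;
    const double qden = q0sq * (1.0 + q0sq);

    for (int j = 0; j < nc; ++j) {
      const double *colW = cur + static_cast<size_t>(nr) * (j == 0 ? 0 : j - 1);
      const double *colE = cur + static_cast<size_t>(nr) * (j == nc - 1 ? nc - 1 : j + 1);
      const double *col = cur + static_cast<size_t>(nr) * j;
      double *ccol = c.data() + static_cast<size_t>(nr) * j;
      for (int i = 0; i < nr; ++i) {
        const double v = col[i];
        const double n = col[i == 0 ? 0 : i - 1] - v;
        const double s = col[i == nr - 1 ? nr - 1 : i + 1] - v;
        const double e = colE[i] - v;
        const double w = colW[i] - v;
        const double inv = 1.0 / v;
        const double g2 = (n * n + s * s + e * e + w * w) * inv * inv;
        const double lap = (n + s + e + w) * inv;
        const double denom = 1.0 + 0.25 * lap;
        double q2 = (0.5 * g2 - lap * lap / 16.0) / (denom * denom);
        if (q2 < 0) q2 = 0;
        double cij = 1.0 / (1.0 + (q2 - q0sq) / qden);
        if (cij < 0) cij = 0;
        else if (cij > 1) cij = 1;
        ccol[i] = cij;
      }
    }

    for (int j = 0; j < nc; ++j) {
      const size_t off = static_cast<size_t>(nr) * j;
      const double *colW = cur + static_cast<size_t>(nr) * (j == 0 ? 0 : j - 1);
      const double *colE = cur + static_cast<size_t>(nr) * (j == nc - 1 ? nc - 1 : j + 1);
      const double *ccolE = c.data() + static_cast<size_t>(nr) * (j == nc - 1 ? nc - 1 : j + 1);
      const double *ccol = c.data() + off;
      const double *col = cur + off;
      double *dst = nxt + off;
      for (int i = 0; i < nr; ++i) {
        const double v = col[i];
        const double n = col[i == 0 ? 0 : i - 1] - v;
        const double s = col[i == nr - 1 ? nr - 1 : i + 1] - v;
        const double e = colE[i] - v;
        const double w = colW[i] - v;
        const double cS = ccol[i == nr - 1 ? nr - 1 : i + 1];
        const double div = cS * s + ccol[i] * n + ccolE[i] * e + ccol[i] * w;
        dst[i] = v + 0.25 * dt * div;
      }
    }
    std::swap(cur, nxt);
  }

  NumericMatrix out(nr, nc);
  std::copy(cur, cur + npx, REAL(out));
  return out;
}
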