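#include <Rcpp.h>
#include <complex>
#include <cmath>
#include <map>
#include <vector>
using namespace Rcpp;

typedef std::complex<double> cplx;

// Complex Lorentzian of a single exponentially decaying resonance:
//   FT of a * e^{i phi} * e^{i 2 pi nu0 t} * e^{-pi w t} (t >= 0), scaled so the
//   absorptive (real, phi = 0) integral over nu equals the area a:
//   P(nu) = 2 a e^{i phi} / (pi w + i 2 pi (nu - nu0))
// w is the FWHM in Hz, nu/nu0 in Hz.
static inline cplx lorentz(double nu, double nu0, double w, double a,
                           double phi, cplx &D) {
  D = cplx(M_PI * w, 2.0 * M_PI * (nu - nu0));
  return 2.0 * a * cplx(std::cos(phi), std::sin(phi)) / D;
}

// Evaluate the full lineshape model on an axis given in Hz.
// pos (ppm), fwhm (Hz), area, phase: one entry per peak (broad included).
// bre/bim: real/imaginary polynomial baseline coefficients on xs in [-1, 1].
// [[Rcpp::export]]
ComplexVector cppModelEval(NumericVector axisHz, NumericVector xs, double sfo,
                           NumericVector pos, NumericVector fwhm,
                           NumericVector area, NumericVector phase,
                           NumericVector bre, NumericVector bim) {
  const int n = axisHz.size(), npk = pos.size(), nb = bre.size();
  ComplexVector out(n);
  for (int i = 0; i < n; ++i) {
    cplx m(0.0, 0.0), D;
    for (int k = 0; k < npk; ++k)
      m += lorentz(axisHz[i], pos[k] * sfo, fwhm[k], area[k], phase[k], D);
    double xp = 1.0;
    for (int j = 0; j < nb; ++j) {
      m += cplx(bre[j] * xp, bim[j] * xp);
      xp *= xs[i];
    }
    out[i].r = m.real();
    out[i].i = m.imag();
  }
  return out;
}

// Residuals and analytic Jacobian for weighted least squares on the
// concatenated (real, imaginary) channels.  Natural parameter layout per peak:
// (pos ppm, log fwhm, area, phase); then baseline real coeffs, imag coeffs.
// [[Rcpp::export]]
List cppResidJac(NumericVector theta, NumericVector yre, NumericVector yim,
                 NumericVector axisHz, NumericVector xs, double sfo,
                 int npk, int nbase, double sigma, bool wantJac) {
  const int n = axisHz.size();
  const int np = 4 * npk + 2 * nbase;
  NumericVector res(2 * n);
  NumericMatrix jac(wantJac ? 2 * n : 1, wantJac ? np : 1);
  std::vector<cplx> P(n * npk), Dm(n * npk);
  std::vector<double> mre(n, 0.0), mim(n, 0.0);

  for (int i = 0; i < n; ++i) {
    cplx m(0.0, 0.0);
    for (int k = 0; k < npk; ++k) {
      double p0 = theta[4 * k], w = std::exp(theta[4 * k + 1]);
      double a = theta[4 * k + 2], ph = theta[4 * k + 3];
      cplx D;
      cplx pk = lorentz(axisHz[i], p0 * sfo, w, a, ph, D);
      P[i * npk + k] = pk;
      Dm[i * npk + k] = D;
      m += pk;
    }
    double xp = 1.0;
    for (int j = 0; j < nbase; ++j) {
      m += cplx(theta[4 * npk + j] * xp, theta[4 * npk + nbase + j] * xp);
      xp *= xs[i];
    }
    mre[i] = m.real();
    mim[i] = m.imag();
    res[i] = (yre[i] - m.real()) / sigma;
    res[n + i] = (yim[i] - m.imag()) / sigma;
  }
  if (wantJac) {
    for (int i = 0; i < n; ++i) {
      for (int k = 0; k < npk; ++k) {
        cplx pk = P[i * npk + k], D = Dm[i * npk + k];
        double w = std::exp(theta[4 * k + 1]), a = theta[4 * k + 2];
        cplx dpos = pk * (cplx(0.0, 2.0 * M_PI * sfo) / D);
        cplx dlw = -pk * (M_PI * w) / D;
        cplx dar = (a != 0.0) ? pk / a : 2.0 * cplx(std::cos(theta[4 * k + 3]),
                                                    std::sin(theta[4 * k + 3])) / D;
        cplx dph = cplx(0.0, 1.0) * pk;
        jac(i, 4 * k) = -dpos.real() / sigma;
        jac(n + i, 4 * k) = -dpos.imag() / sigma;
        jac(i, 4 * k + 1) = -dlw.real() / sigma;
        jac(n + i, 4 * k + 1) = -dlw.imag() / sigma;
        jac(i, 4 * k + 2) = -dar.real() / sigma;
        jac(n + i, 4 * k + 2) = -dar.imag() / sigma;
        jac(i, 4 * k + 3) = -dph.real() / sigma;
        jac(n + i, 4 * k + 3) = -dph.imag() / sigma;
      }
      double xp = 1.0;
      for (int j = 0; j < nbase; ++j) {
        jac(i, 4 * npk + j) = -xp / sigma;
        jac(n + i, 4 * npk + nbase + j) = -xp / sigma;
        xp *= xs[i];
      }
    }
  }
  return List::create(_["residuals"] = res, _["jacobian"] = jac,
                      _["mre"] = NumericVector(mre.begin(), mre.end()),
                      _["mim"] = NumericVector(mim.begin(), mim.end()));
}

static inline double sigm(double u) { return 1.0 / (1.0 + std::exp(-u)); }

// Log posterior and gradient in the unconstrained HMC parameterisation.
// Per peak: u1 -> position (logistic to [posLo, posHi], uniform prior),
//           u2 -> log FWHM (logistic to [log lwLo, log lwHi], log-uniform),
//           u3 -> log area (half-normal prior on area, scale areaScale),
//           u4 -> phase (flat; likelihood is 2 pi periodic).
// Baseline coefficients raw with Normal(0, basePriorSd) priors.
// lwLo/lwHi are vectors (per peak) so the broad component gets its own bounds.
// [[Rcpp::export]]
List cppLogPostGrad(NumericVector u, NumericVector yre, NumericVector yim,
                    NumericVector axisHz, NumericVector xs, double sfo,
                    int npk, int nbase, double sigma,
                    double posLo, double posHi,
                    NumericVector lwLo, NumericVector lwHi,
                    double areaScale, double basePriorSd) {
  const int n = axisHz.size();
  const int np = 4 * npk + 2 * nbase;
  NumericVector grad(np);
  double lp = 0.0;

  std::vector<double> pos(npk), w(npk), a(npk), ph(npk), s1(npk), s2(npk);
  for (int k = 0; k < npk; ++k) {
    s1[k] = sigm(u[4 * k]);
    pos[k] = posLo + (posHi - posLo) * s1[k];
    s2[k] = sigm(u[4 * k + 1]);
    double llo = std::log(lwLo[k]), lhi = std::log(lwHi[k]);
    w[k] = std::exp(llo + (lhi - llo) * s2[k]);
    a[k] = std::exp(u[4 * k + 2]);
    ph[k] = u[4 * k + 3];
    lp += std::log(s1[k] * (1.0 - s1[k])) + std::log(s2[k] * (1.0 - s2[k]));
    lp += -0.5 * a[k] * a[k] / (areaScale * areaScale) + u[4 * k + 2];
  }
  for (int j = 0; j < 2 * nbase; ++j) {
    double c = u[4 * npk + j];
    lp += -0.5 * c * c / (basePriorSd * basePriorSd);
    grad[4 * npk + j] = -c / (basePriorSd * basePriorSd);
  }

  std::vector<double> gpos(npk, 0.0), glw(npk, 0.0), gar(npk, 0.0), gph(npk, 0.0);
  const double is2 = 1.0 / (sigma * sigma);
  for (int i = 0; i < n; ++i) {
    cplx m(0.0, 0.0), D;
    std::vector<cplx> Pk(npk), Dk(npk);
    for (int k = 0; k < npk; ++k) {
      Pk[k] = lorentz(axisHz[i], pos[k] * sfo, w[k], a[k], ph[k], D);
      Dk[k] = D;
      m += Pk[k];
    }
    double xp = 1.0;
    for (int j = 0; j < nbase; ++j) {
      m += cplx(u[4 * npk + j] * xp, u[4 * npk + nbase + j] * xp);
      xp *= xs[i];
    }
    const double rre = yre[i] - m.real(), rim = yim[i] - m.imag();
    lp += -0.5 * is2 * (rre * rre + rim * rim);
    const double wre = rre * is2, wim = rim * is2;
    for (int k = 0; k < npk; ++k) {
      cplx dpos = Pk[k] * (cplx(0.0, 2.0 * M_PI * sfo) / Dk[k]);
      cplx dlw = -Pk[k] * (M_PI * w[k]) / Dk[k];
      cplx dar = Pk[k] / a[k];
      cplx dph = cplx(0.0, 1.0) * Pk[k];
      gpos[k] += wre * dpos.real() + wim * dpos.imag();
      glw[k] += wre * dlw.real() + wim * dlw.imag();
      gar[k] += wre * dar.real() + wim * dar.imag();
      gph[k] += wre * dph.real() + wim * dph.imag();
    }
    xp = 1.0;
    for (int j = 0; j < nbase; ++j) {
      grad[4 * npk + j] += wre * xp;
      grad[4 * npk + nbase + j] += wim * xp;
      xp *= xs[i];
    }
  }
  for (int k = 0; k < npk; ++k) {
    double llo = std::log(lwLo[k]), lhi = std::log(lwHi[k]);
    grad[4 * k] = gpos[k] * (posHi - posLo) * s1[k] * (1.0 - s1[k]) +
                  (1.0 - 2.0 * s1[k]);
    grad[4 * k + 1] = glw[k] * (lhi - llo) * s2[k] * (1.0 - s2[k]) +
                      (1.0 - 2.0 * s2[k]);
    grad[4 * k + 2] = (gar[k] - a[k] / (areaScale * areaScale)) * a[k] + 1.0;
    grad[4 * k + 3] = gph[k];
  }
  return List::create(_["lp"] = lp, _["grad"] = grad);
}

// Per-atom contact query: for each probe atom, is any target atom closer than
// cutoff?  Cell list over the target atoms, cells of edge = cutoff.
// [[Rcpp::export]]
LogicalVector cppAnyWithin(NumericMatrix probe, NumericMatrix target,
                           double cutoff) {
  const int np = probe.nrow(), nt = target.nrow();
  LogicalVector out(np);
  if (nt == 0 || cutoff <= 0.0) return out;
  double lo[3];
  for (int d = 0; d < 3; ++d) {
    lo[d] = target(0, d);
    for (int i = 1; i < nt; ++i) lo[d] = std::min(lo[d], target(i, d));
  }
  const double cell = cutoff;
  std::map<long long, std::vector<int> > cells;
  for (int i = 0; i < nt; ++i) {
    long long cx = (long long)std::floor((target(i, 0) - lo[0]) / cell);
    long long cy = (long long)std::floor((target(i, 1) - lo[1]) / cell);
    long long cz = (long long)std::floor((target(i, 2) - lo[2]) / cell);
    cells[(cx * 73856093LL) ^ (cy * 19349663LL) ^ (cz * 83492791LL)].push_back(i);
  }
  const double c2 = cutoff * cutoff;
  for (int i = 0; i < np; ++i) {
    long long cx = (long long)std::floor((probe(i, 0) - lo[0]) / cell);
    long long cy = (long long)std::floor((probe(i, 1) - lo[1]) / cell);
    long long cz = (long long)std::floor((probe(i, 2) - lo[2]) / cell);
    bool hit = false;
    for (long long dx = -1; dx <= 1 && !hit; ++dx)
      for (long long dy = -1; dy <= 1 && !hit; ++dy)
        for (long long dz = -1; dz <= 1 && !hit; ++dz) {
          long long key = (((cx + dx) * 73856093LL) ^ ((cy + dy) * 19349663LL) ^
                           ((cz + dz) * 83492791LL));
          std::map<long long, std::vector<int> >::const_iterator it =
              cells.find(key);
          if (it == cells.end()) continue;
          for (size_t q = 0; q < it->second.size(); ++q) {
            int j = it->second[q];
            double ddx = probe(i, 0) - target(j, 0);
            double ddy = probe(i, 1) - target(j, 1);
            double ddz = probe(i, 2) - target(j, 2);
            if (ddx * ddx + ddy * ddy + ddz * ddz < c2) { hit = true; break; }
          }
        }
    out[i] = hit;
  }
  return out;
}
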