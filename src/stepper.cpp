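// Explicit forward-Euler stepper for the multi-phase-field chromatin model.
// Mirrors the pure-R reference implementation in R/solver.R (step_state)
// to floating-point round-off; exists only for speed.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double hfun(double u) {
  return u * u * u * (10.0 - 15.0 * u + 6.0 * u * u);
}

// 5-point Laplacian with mirrored (zero-flux) boundaries
static inline double lap_at(const double *f, int i, int j, int nx, int ny,
                            double idx2, double idy2) {
  const int im = (i == 0) ? 0 : i - 1;
  const int ip = (i == nx - 1) ? nx - 1 : i + 1;
  const int jm = (j == 0) ? 0 : j - 1;
  const int jp = (j == ny - 1) ? ny - 1 : j + 1;
  const double c = f[i + nx * j];
  return (f[im + nx * j] + f[ip + nx * j] - 2.0 * c) * idx2 +
         (f[i + nx * jm] + f[i + nx * jp] - 2.0 * c) * idy2;
}

// [[Rcpp::export]]
List pf_advance(NumericVector phiArr, NumericMatrix psiM, double t,
                int nsteps, List par, List sched, List geom, List cfg) {
  const int nx = as<int>(cfg["nx"]), ny = as<int>(cfg["ny"]);
  const double dt = as<double>(cfg["dt"]);
  const double dx = as<double>(cfg["dx"]), dy = as<double>(cfg["dy"]);
  const double idx2 = 1.0 / (dx * dx), idy2 = 1.0 / (dy * dy);
  const double dA = dx * dy;
  const int ncell = nx * ny;

  IntegerVector dims = phiArr.attr("dim");
  const int N = dims[2];
  if (dims[0] != nx || dims[1] != ny || psiM.nrow() != nx ||
      psiM.ncol() != ny) stop("field/grid shape mismatch");

  const double alpha0 = as<double>(par["alpha0"]);
  const double alphaV = as<double>(par["alphaV"]);
  const double alphav = as<double>(par["alphav"]);
  const double beta0 = as<double>(par["beta0"]);
  const double betaPhi = as<double>(par["betaPhi"]);
  const double betaPsi = as<double>(par["betaPsi"]);
  const double gamma = as<double>(par["gamma"]);
  const double epsPhi2 = as<double>(par["epsPhiSq"]);
  const double epsPsi2 = as<double>(par["epsPsiSq"]);
  NumericVector mob = par["mobility"];
  const double mobPhi = mob[1], mobPsi = mob[2];

  const int regime = as<int>(sched["regime"]);   // 0 conventional, 1 inverted
  const int variant = as<int>(sched["variant"]); // 0 sigmoid, 1 saturating
  NumericVector VbarM = sched["VbarM"], vbarM = sched["vbarM"];
  NumericVector rho0 = sched["rhoM0"], rhoBar = sched["rhoBarM"];
  NumericVector a1 = sched["alpha1"], a2 = sched["alpha2"],
                tSt = sched["tStar"];
  const double rContr = as<double>(sched["r"]);

  const double ax0 = as<double>(geom["ax0"]), ay0 = as<double>(geom["ay0"]);
  const double ax1 = as<double>(geom["ax1"]), ay1 = as<double>(geom["ay1"]);
  const double ts0 = as<double>(geom["ts0"]), ts1 = as<double>(geom["ts1"]);
  const double eps0 = as<double>(geom["eps0"]);
  const double cx = as<double>(geom["cx"]), cy = as<double>(geom["cy"]);
  const bool movingNucleus = (ts1 > ts0) && (ax0 != ax1 || ay0 != ay1);
  const double invW0 = 1.0 / (2.0 * std::sqrt(2.0) * std::sqrt(eps0));

  std::vector<double> phi(phiArr.begin(), phiArr.end());
  std::vector<double> psi(psiM.begin(), psiM.end());
  std::vector<double> phiNew(ncell * N), psiNew(ncell);
  std::vector<double> phi0(ncell), h0(ncell), lapH0(ncell);
  std::vector<double> hphi(ncell * N), hpsi(ncell), chi(ncell), Bacc(ncell);
  std::vector<double> xc(nx), yc(ny);
  for (int i = 0; i < nx; ++i) xc[i] = (i + 0.5) * dx;
  for (int j = 0; j < ny; ++j) yc[j] = (j + 0.5) * dy;

  double nucVol = 0.0;
  std::vector<double> V(N), v(N), rho(N), Aunif(N), cB(N), cAv(N);
  bool havePhi0 = false, finite = true;

  for (int step = 0; step < nsteps; ++step) {
    // prescribed nucleus field at the current time
    if (!havePhi0 || (movingNucleus && t <= ts1 + dt)) {
      double ax = ax0, ay = ay0;
      if (movingNucleus) {
        if (t >= ts1) { ax = ax1; ay = ay1; }
        else if (t > ts0) {
          const double w = (t - ts0) / (ts1 - ts0);
          ax = (1.0 - w) * ax0 + w * ax1;
          ay = (1.0 - w) * ay0 + w * ay1;
        }
      }
      const double mn = (ax < ay) ? ax : ay;
      for (int j = 0; j < ny; ++j) {
        const double yr = (yc[j] - cy) / ay;
        for (int i = 0; i < nx; ++i) {
          const double xr = (xc[i] - cx) / ax;
          const double q = std::sqrt(xr * xr + yr * yr);
          double s;
          if (q > 1e-9) {
            double gq = std::sqrt((xr / ax) * (xr / ax) +
                                  (yr / ay) * (yr / ay));
            if (gq < 1e-12) gq = 1e-12;
            s = (q - 1.0) * q / gq;
          } else {
            s = -mn;
          }
          const double p0 = 0.5 * (1.0 + std::tanh(s * invW0));
          phi0[i + nx * j] = p0;
          h0[i + nx * j] = hfun(p0);
        }
      }
      nucVol = 0.0;
      for (int k = 0; k < ncell; ++k) nucVol += 1.0 - h0[k];
      nucVol *= dA;
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i)
          lapH0[i + nx * j] = lap_at(h0.data(), i, j, nx, ny, idx2, idy2);
      havePhi0 = true;
    }

    // occupancies, volumes, chi
    for (int k = 0; k < ncell; ++k) hpsi[k] = hfun(psi[k]);
    std::fill(chi.begin(), chi.end(), 0.0);
    double sumV = 0.0;
    for (int m = 0; m < N; ++m) {
      const double *u = phi.data() + (size_t)ncell * m;
      double *hp = hphi.data() + (size_t)ncell * m;
      double Vm = 0.0, vm = 0.0;
      for (int k = 0; k < ncell; ++k) {
        const double h = hfun(u[k]);
        hp[k] = h;
        chi[k] += h;
        Vm += h;
        vm += h * hpsi[k];
      }
      V[m] = Vm * dA;
      v[m] = vm * dA;
      sumV += V[m];
    }
    if (!std::isfinite(sumV)) { finite = false; break; }

    // targets and spatially uniform reaction pieces
    const double occ = -60.0 * alpha0 * (nucVol - sumV);
    for (int m = 0; m < N; ++m) {
      if (regime == 0) {
        Aunif[m] = occ + 60.0 * alphaV * (V[m] - VbarM[m]);
        cAv[m] = 60.0 * alphav * (v[m] - vbarM[m]);
        cB[m] = cAv[m];
        rho[m] = 0.0;
      } else {
        double rh;
        if (variant == 0) {
          const double den = t + a1[m] * std::exp(-a2[m] * (t - tSt[m]));
          rh = rho0[m] + rhoBar[m] * t / den;
        } else {
          rh = rho0[m] + rhoBar[m] * t / (10.0 + t);
        }
        rho[m] = rh;
        Aunif[m] = occ + 60.0 * alphaV * (V[m] - rContr * VbarM[m]);
        cAv[m] = 60.0 * alphav * (v[m] - rh * V[m]);
        cB[m] = cAv[m];
      }
    }

    // B accumulation over chromosomes
    std::fill(Bacc.begin(), Bacc.end(), 0.0);
    for (int m = 0; m < N; ++m) {
      const double *hp = hphi.data() + (size_t)ncell * m;
      const double c = cB[m];
      for (int k = 0; k < ncell; ++k) Bacc[k] += c * hp[k];
    }

    // updates: interior cells with branch-free stencils, boundaries clamped
    for (int m = 0; m < N; ++m) {
      const double *u = phi.data() + (size_t)ncell * m;
      const double *hp = hphi.data() + (size_t)ncell * m;
      double *un = phiNew.data() + (size_t)ncell * m;
      const double Au = Aunif[m] - ((regime == 0) ? 0.0 : cAv[m] * rho[m]);
      const double cpsi = cAv[m] - 30.0 * betaPsi;
      for (int j = 1; j < ny - 1; ++j) {
        const int off = nx * j;
        for (int i = 1; i < nx - 1; ++i) {
          const int k = i + off;
          const double A = Au + 30.0 * beta0 * h0[k] +
                           30.0 * betaPhi * (chi[k] - hp[k]) +
                           cpsi * hpsi[k];
          const double uu = u[k];
          const double lap = (u[k - 1] + u[k + 1] - 2.0 * uu) * idx2 +
                             (u[k - nx] + u[k + nx] - 2.0 * uu) * idy2;
          const double rhs = epsPhi2 * lap +
            uu * (1.0 - uu) * (uu - 0.5 - A * uu * (1.0 - uu));
          un[k] = uu + dt * mobPhi * rhs;
        }
      }
      for (int j = 0; j < ny; ++j) {
        const int istep = (j == 0 || j == ny - 1) ? 1 : nx - 1;
        for (int i = 0; i < nx; i += istep) {
          const int k = i + nx * j;
          const double A = Au + 30.0 * beta0 * h0[k] +
                           30.0 * betaPhi * (chi[k] - hp[k]) +
                           cpsi * hpsi[k];
          const double uu = u[k];
          const double rhs = epsPhi2 * lap_at(u, i, j, nx, ny, idx2, idy2) +
            uu * (1.0 - uu) * (uu - 0.5 - A * uu * (1.0 - uu));
          un[k] = uu + dt * mobPhi * rhs;
        }
      }
    }
    {
      const double *u = psi.data();
      for (int j = 1; j < ny - 1; ++j) {
        const int off = nx * j;
        for (int i = 1; i < nx - 1; ++i) {
          const int k = i + off;
          const double B = Bacc[k] + 30.0 * betaPsi * (1.0 - chi[k]) -
                           30.0 * gamma * lapH0[k];
          const double uu = u[k];
          const double lap = (u[k - 1] + u[k + 1] - 2.0 * uu) * idx2 +
                             (u[k - nx] + u[k + nx] - 2.0 * uu) * idy2;
          const double rhs = epsPsi2 * lap +
            uu * (1.0 - uu) * (uu - 0.5 - B * uu * (1.0 - uu));
          psiNew[k] = uu + dt * mobPsi * rhs;
        }
      }
      for (int j = 0; j < ny; ++j) {
        const int istep = (j == 0 || j == ny - 1) ? 1 : nx - 1;
        for (int i = 0; i < nx; i += istep) {
          const int k = i + nx * j;
          const double B = Bacc[k] + 30.0 * betaPsi * (1.0 - chi[k]) -
                           30.0 * gamma * lapH0[k];
          const double uu = u[k];
          const double rhs = epsPsi2 * lap_at(u, i, j, nx, ny, idx2, idy2) +
            uu * (1.0 - uu) * (uu - 0.5 - B * uu * (1.0 - uu));
          psiNew[k] = uu + dt * mobPsi * rhs;
        }
      }
    }
    phi.swap(phiNew);
    psi.swap(psiNew);
    t += dt;
  }

  NumericVector phiOut((size_t)ncell * N);
  std::copy(phi.begin(), phi.end(), phiOut.begin());
  phiOut.attr("dim") = IntegerVector::create(nx, ny, N);
  NumericMatrix psiOut(nx, ny), phi0Out(nx, ny);
  std::copy(psi.begin(), psi.end(), psiOut.begin());
  std::copy(phi0.begin(), phi0.end(), phi0Out.begin());
  return List::create(_["phi"] = phiOut, _["psi"] = psiOut,
                      _["phi0"] = phi0Out, _["t"] = t,
                      _["finite"] = finite);
}
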