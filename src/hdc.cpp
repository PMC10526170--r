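// Compiled core: explicit finite-volume/FTCS stepping of the four
// reaction-diffusion fields on a polar grid, the movement-probability
// stencil of the discrete cell walk, and the coupled hybrid loop.
//
// Grid convention: cell-centred radial nodes r_j = (j + 1/2) * dr,
// j = 0..nr-1, so the r = 0 singularity never lies on a node and the
// inner face (r = 0) has zero area, giving exact discrete conservation.
// Fields are nr x ntheta matrices; ntheta == 1 means axisymmetric.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Params {
  double d_i, d_n, d_m, chi_hap, chi_chem, zeta, delta;
  double eta_max, n_half, lambda_max, p_cr, p_max, c0, cp_packing;
};

Params unpack(const NumericVector& par) {
  Params p;
  p.d_i = par["d_i"];           p.d_n = par["d_n"];
  p.d_m = par["d_m"];           p.chi_hap = par["chi_hap"];
  p.chi_chem = par["chi_chem"]; p.zeta = par["zeta"];
  p.delta = par["delta"];       p.eta_max = par["eta_max"];
  p.n_half = par["n_half"];     p.lambda_max = par["lambda_max"];
  p.p_cr = par["p_cr"];         p.p_max = par["p_max"];
  p.c0 = par["c0"];             p.cp_packing = par["cp_packing"];
  return p;
}

inline int wrapk(int k, int n) { return (k % n + n) % n; }

// One explicit step of the selected fields (synchronous update).
// cell_bc: 0 = Dirichlet c_bc at the outer face, 1 = zero flux.
void step_once(NumericMatrix& C, NumericMatrix& N, NumericMatrix& M,
               NumericMatrix& F, NumericMatrix& Cn, NumericMatrix& Nn,
               NumericMatrix& Mn, const Params& p, double c_bc, double n0,
               double m0, int cell_bc, double dr, double dth, double dt,
               bool upd_c, bool upd_n, bool upd_m, bool upd_f) {
  const int nr = C.nrow(), nt = C.ncol();
  const bool ax = (nt == 1);

  for (int k = 0; k < nt; ++k) {
    const int kp = ax ? 0 : wrapk(k + 1, nt);
    const int km = ax ? 0 : wrapk(k - 1, nt);
    for (int j = 0; j < nr; ++j) {
      const double r  = (j + 0.5) * dr;
      const double rm = j * dr;          // inner face radius (0 at j = 0)
      const double rp = (j + 1.0) * dr;  // outer face radius

      // --- nutrient: diffusion (Dirichlet n0) minus consumption ---
      if (upd_n) {
        const double um = (j > 0) ? N(j - 1, k) : N(j, k);  // reflect
        const double up = (j < nr - 1) ? N(j + 1, k) : 2.0 * n0 - N(j, k);
        double div = (rp * p.d_n * (up - N(j, k)) -
                      rm * p.d_n * (N(j, k) - um)) / (r * dr * dr);
        if (!ax)
          div += p.d_n * (N(j, kp) - 2.0 * N(j, k) + N(j, km)) /
                 (r * r * dth * dth);
        const double monod = N(j, k) / (p.n_half + N(j, k));
        const double cons = p.lambda_max * (C(j, k) / p.c0) * monod * N(j, k);
        double v = N(j, k) + dt * (div - cons);
        Nn(j, k) = v > 0.0 ? v : 0.0;
      }

      // --- collagenase: diffusion (Dirichlet m0) minus binding loss ---
      if (upd_m) {
        const double um = (j > 0) ? M(j - 1, k) : M(j, k);
        const double up = (j < nr - 1) ? M(j + 1, k) : 2.0 * m0 - M(j, k);
        double div = (rp * p.d_m * (up - M(j, k)) -
                      rm * p.d_m * (M(j, k) - um)) / (r * dr * dr);
        if (!ax)
          div += p.d_m * (M(j, kp) - 2.0 * M(j, k) + M(j, km)) /
                 (r * r * dth * dth);
        double v = M(j, k) + dt * (div - p.zeta * M(j, k) * F(j, k));
        Mn(j, k) = v > 0.0 ? v : 0.0;
      }

      // --- cells: FV divergence of diffusive + tactic fluxes, growth ---
      if (upd_c) {
        double fluxp = 0.0, fluxm = 0.0;
        if (j > 0) {
          const double cbar = 0.5 * (C(j, k) + C(j - 1, k));
          fluxm = p.d_i * (C(j, k) - C(j - 1, k)) / dr -
                  p.chi_hap * cbar * (F(j, k) - F(j - 1, k)) / dr -
                  p.chi_chem * cbar * (N(j, k) - N(j - 1, k)) / dr;
        }
        if (j < nr - 1) {
          const double cbar = 0.5 * (C(j + 1, k) + C(j, k));
          fluxp = p.d_i * (C(j + 1, k) - C(j, k)) / dr -
                  p.chi_hap * cbar * (F(j + 1, k) - F(j, k)) / dr -
                  p.chi_chem * cbar * (N(j + 1, k) - N(j, k)) / dr;
        } else if (cell_bc == 0) {
          // ghost value so the outer face sits at c_bc; taxis off at wall
          const double ug = 2.0 * c_bc - C(j, k);
          fluxp = p.d_i * (ug - C(j, k)) / dr;
        }
        double div = (rp * fluxp - rm * fluxm) / (r * dr);
        if (!ax) {
          // conservative angular fluxes at the k+-1/2 faces
          double cbp = 0.5 * (C(j, kp) + C(j, k));
          double cbm = 0.5 * (C(j, k) + C(j, km));
          double ftp = p.d_i * (C(j, kp) - C(j, k)) / dth -
                       p.chi_hap * cbp * (F(j, kp) - F(j, k)) / dth -
                       p.chi_chem * cbp * (N(j, kp) - N(j, k)) / dth;
          double ftm = p.d_i * (C(j, k) - C(j, km)) / dth -
                       p.chi_hap * cbm * (F(j, k) - F(j, km)) / dth -
                       p.chi_chem * cbm * (N(j, k) - N(j, km)) / dth;
          div += (ftp - ftm) / (r * r * dth);
        }
        const double stress = p.p_max * C(j, k) / p.cp_packing;
        double eta = 0.0;
        if (stress < p.p_cr)
          eta = p.eta_max * N(j, k) / (p.n_half + N(j, k));
        double v = C(j, k) + dt * (div + eta * C(j, k));
        Cn(j, k) = v > 0.0 ? v : 0.0;
      }
    }
  }

  if (upd_c) std::copy(Cn.begin(), Cn.end(), C.begin());
  if (upd_n) std::copy(Nn.begin(), Nn.end(), N.begin());
  if (upd_m) std::copy(Mn.begin(), Mn.end(), M.begin());
  // collagen: no spatial operator, integrate exactly per node
  if (upd_f)
    for (int i = 0; i < nr * nt; ++i)
      F[i] *= std::exp(-p.delta * M[i] * dt);
}

void check_finite(const NumericMatrix& X, const char* name) {
  for (int i = 0; i < X.size(); ++i)
    if (!R_finite(X[i]))
      stop("continuum solver diverged: non-finite value in field '%s'",
           std::string(name));
}

// Raw (un-normalised) movement weights of the five-way walk at node (j,k).
// Derived from the central-difference stencil of
//   dC/dt = D lap(C) - chi div(C grad f)
// in polar coordinates; the taxis contribution is signed so the walk's
// drift velocity equals the PDE advection velocity +chi grad f.
void raw_probs(const NumericMatrix& F, int j, int k, double dr, double dth,
               int ntheta, double D, double chi, double dt, double out[5]) {
  const int nr = F.nrow();
  const bool axf = (F.ncol() == 1);
  const int kc = axf ? 0 : wrapk(k, F.ncol());
  const int kp = axf ? 0 : wrapk(k + 1, F.ncol());
  const int km = axf ? 0 : wrapk(k - 1, F.ncol());
  const double r = (j + 0.5) * dr;

  const double fjm = (j > 0) ? F(j - 1, kc) : F(0, kc);       // reflect
  const double fjp = (j < nr - 1) ? F(j + 1, kc) : F(nr - 1, kc);
  const double fr = (fjp - fjm) / (2.0 * dr);
  const double ft = axf ? 0.0 : (F(j, kp) - F(j, km)) / (2.0 * dth);
  double lapf = (fjp - 2.0 * F(j, kc) + fjm) / (dr * dr) +
                (fjp - fjm) / (2.0 * r * dr);
  if (!axf)
    lapf += (F(j, kp) - 2.0 * F(j, kc) + F(j, km)) / (r * r * dth * dth);

  double p1 = dt * (D / (dr * dr) + D / (2.0 * r * dr) + chi * fr / (2.0 * dr));
  double p2 = dt * (D / (dr * dr) - D / (2.0 * r * dr) - chi * fr / (2.0 * dr));
  double p3 = 0.0, p4 = 0.0;
  if (ntheta > 1) {
    const double a = D / (r * r * dth * dth);
    p3 = dt * (a + chi * ft / (2.0 * dth * r * r));
    p4 = dt * (a - chi * ft / (2.0 * dth * r * r));
  }
  if (p1 < 0.0) p1 = 0.0;
  if (p2 < 0.0) p2 = 0.0;
  if (p3 < 0.0) p3 = 0.0;
  if (p4 < 0.0) p4 = 0.0;
  double p0 = 1.0 - (p1 + p2 + p3 + p4) - chi * dt * lapf;
  if (p0 < 0.0) p0 = 0.0;
  out[0] = p0; out[1] = p1; out[2] = p2; out[3] = p3; out[4] = p4;
}

// One walk step for every live agent, using R's RNG stream.
void agents_step_once(std::vector<int>& aj, std::vector<int>& ak,
                      std::vector<int>& alive, std::vector<double>& age,
                      const NumericMatrix& F, double dr, double dth,
                      int ntheta_ag, int nr, double D, double chi,
                      double dt) {
  double p[5];
  for (size_t i = 0; i < aj.size(); ++i) {
    if (!alive[i]) continue;
    raw_probs(F, aj[i], ak[i], dr, dth, ntheta_ag, D, chi, dt, p);
    double s = p[0] + p[1] + p[2] + p[3] + p[4];
    if (s <= 0.0) { age[i] += dt; continue; }
    const double u = unif_rand() * s;
    int move = 4;
    double acc = 0.0;
    for (int m = 0; m < 5; ++m) {
      acc += p[m];
      if (u < acc) { move = m; break; }
    }
    switch (move) {
      case 1: aj[i] += 1; break;
      case 2: if (aj[i] > 0) aj[i] -= 1; break;  // reflect at r = 0
      case 3: ak[i] = wrapk(ak[i] + 1, ntheta_ag); break;
      case 4: ak[i] = wrapk(ak[i] - 1, ntheta_ag); break;
      default: break;
    }
    if (aj[i] >= nr - 1) { aj[i] = nr - 1; alive[i] = 0; }  // absorbed
    age[i] += dt;
  }
}

// Ring-front index: outermost j whose angular-mean cell density reaches
// alpha * max of the angular-mean profile. Returns -1 for an empty field.
int front_index(const NumericMatrix& C, double alpha) {
  const int nr = C.nrow(), nt = C.ncol();
  double mx = 0.0;
  std::vector<double> prof(nr);
  for (int j = 0; j < nr; ++j) {
    double s = 0.0;
    for (int k = 0; k < nt; ++k) s += C(j, k);
    prof[j] = s / nt;
    if (prof[j] > mx) mx = prof[j];
  }
  if (mx <= 0.0) return -1;
  for (int j = nr - 1; j >= 0; --j)
    if (prof[j] >= alpha * mx) return j;
  return -1;
}

}  // namespace

// [[Rcpp::export]]
List cpp_continuum_steps(NumericMatrix C, NumericMatrix N, NumericMatrix M,
                         NumericMatrix F, NumericVector par, double c_bc,
                         double n0, double m0, int cell_bc, double dr,
                         double dth, double dt, int nsteps, bool upd_c,
                         bool upd_n, bool upd_m, bool upd_f) {
  NumericMatrix Cc = clone(C), Nc = clone(N), Mc = clone(M), Fc = clone(F);
  NumericMatrix Cb = clone(C), Nb = clone(N), Mb = clone(M);
  const Params p = unpack(par);
  for (int s = 0; s < nsteps; ++s) {
    step_once(Cc, Nc, Mc, Fc, Cb, Nb, Mb, p, c_bc, n0, m0, cell_bc, dr,
              dth, dt, upd_c, upd_n, upd_m, upd_f);
    if (s % 1000 == 999) {
      check_finite(Cc, "Cp"); check_finite(Nc, "n");
      check_finite(Mc, "M");  check_finite(Fc, "f");
      Rcpp::checkUserInterrupt();
    }
  }
  check_finite(Cc, "Cp"); check_finite(Nc, "n");
  check_finite(Mc, "M");  check_finite(Fc, "f");
  return List::create(_["Cp"] = Cc, _["n"] = Nc, _["M"] = Mc, _["f"] = Fc);
}

// [[Rcpp::export]]
List cpp_move_probs(NumericMatrix F, IntegerVector jj, IntegerVector kk,
                    double dr, double dth, int ntheta, double D, double chi,
                    double dt) {
  const int n = jj.size();
  NumericMatrix raw(n, 5), prob(n, 5);
  double p[5];
  for (int i = 0; i < n; ++i) {
    raw_probs(F, jj[i], kk[i], dr, dth, ntheta, D, chi, dt, p);
    double s = p[0] + p[1] + p[2] + p[3] + p[4];
    for (int m = 0; m < 5; ++m) {
      raw(i, m) = p[m];
      prob(i, m) = (s > 0.0) ? p[m] / s : (m == 0 ? 1.0 : 0.0);
    }
  }
  return List::create(_["raw"] = raw, _["prob"] = prob);
}

// [[Rcpp::export]]
List cpp_agent_walk(IntegerVector j, IntegerVector k, IntegerVector alive,
                    NumericVector age, NumericMatrix F, double dr, double dth,
                    int ntheta_ag, int nr, double D, double chi, double dt,
                    int nsteps) {
  std::vector<int> aj(j.begin(), j.end()), ak(k.begin(), k.end()),
      av(alive.begin(), alive.end());
  std::vector<double> ag(age.begin(), age.end());
  for (int s = 0; s < nsteps; ++s)
    agents_step_once(aj, ak, av, ag, F, dr, dth, ntheta_ag, nr, D, chi, dt);
  return List::create(_["j"] = wrap(aj), _["k"] = wrap(ak),
                      _["alive"] = wrap(av), _["age"] = wrap(ag));
}

// [[Rcpp::export]]
List cpp_shed_event(NumericMatrix C, NumericMatrix F, double dr, int ntheta_ag,
                    double shed_rate, double shed_base, double front_alpha,
                    double c0, double f0, double r_domain, int n_current,
                    int max_agents) {
  const int jf = front_index(C, front_alpha);
  std::vector<int> sj, sk;
  if (jf >= 1 && jf <= C.nrow() - 2) {
    const int nr = F.nrow();
    const bool axf = (F.ncol() == 1);
    int room = max_agents - n_current;
    // candidate nodes: the invasive front region, from the ring front
    // outward through the leading cell tail (boundary node excluded)
    for (int j = jf; j <= nr - 2 && room > 0; ++j) {
      for (int k = 0; k < ntheta_ag && room > 0; ++k) {
        const int kc = axf ? 0 : wrapk(k, F.ncol());
        const double grad =
            std::fabs((F(j + 1, kc) - F(j - 1, kc)) / (2.0 * dr)) / f0 *
            r_domain;
        const double cfrac =
            C(j, C.ncol() == 1 ? 0 : wrapk(k, C.ncol())) / c0;
        double pr = shed_rate * cfrac * (shed_base + grad);
        if (pr > 1.0) pr = 1.0;
        if (pr > 0.0 && unif_rand() < pr) {
          sj.push_back(j);
          sk.push_back(k);
          --room;
        }
      }
    }
  }
  return List::create(_["front_j"] = jf, _["j"] = wrap(sj), _["k"] = wrap(sk));
}

// [[Rcpp::export]]
List cpp_hybrid_block(NumericMatrix C, NumericMatrix N, NumericMatrix M,
                      NumericMatrix F, NumericVector par, double c_bc,
                      double n0, double m0, int cell_bc, double dr, double dth,
                      double dt, IntegerVector j, IntegerVector k,
                      IntegerVector alive, NumericVector age, int ntheta_ag,
                      double shed_rate, double shed_base, double front_alpha,
                      double f0, double r_domain, int max_agents, int nevents,
                      int stride) {
  NumericMatrix Cc = clone(C), Nc = clone(N), Mc = clone(M), Fc = clone(F);
  NumericMatrix Cb = clone(C), Nb = clone(N), Mb = clone(M);
  const Params p = unpack(par);
  const int nr = Cc.nrow();
  const double dth_ag = 2.0 * M_PI / ntheta_ag;
  const double dt_ag = stride * dt;
  std::vector<int> aj(j.begin(), j.end()), ak(k.begin(), k.end()),
      av(alive.begin(), alive.end());
  std::vector<double> ag(age.begin(), age.end());

  for (int e = 0; e < nevents; ++e) {
    for (int s = 0; s < stride; ++s)
      step_once(Cc, Nc, Mc, Fc, Cb, Nb, Mb, p, c_bc, n0, m0, cell_bc, dr,
                dth, dt, true, true, true, true);
    // shedding at the continuum front, then one walk step for everyone
    const int jf = front_index(Cc, front_alpha);
    if (jf >= 1 && jf <= nr - 2 && (int)aj.size() < max_agents) {
      const bool axf = (Fc.ncol() == 1);
      for (int jj2 = jf; jj2 <= nr - 2; ++jj2) {
        if ((int)aj.size() >= max_agents) break;
        for (int kk2 = 0; kk2 < ntheta_ag; ++kk2) {
          if ((int)aj.size() >= max_agents) break;
          const int kc = axf ? 0 : wrapk(kk2, Fc.ncol());
          const double grad =
              std::fabs((Fc(jj2 + 1, kc) - Fc(jj2 - 1, kc)) / (2.0 * dr)) /
              f0 * r_domain;
          const double cfrac = Cc(jj2, axf ? 0 : kc) / p.c0;
          double pr = shed_rate * cfrac * (shed_base + grad);
          if (pr > 1.0) pr = 1.0;
          if (pr > 0.0 && unif_rand() < pr) {
            aj.push_back(jj2); ak.push_back(kk2);
            av.push_back(1);  ag.push_back(0.0);
          }
        }
      }
    }
    agents_step_once(aj, ak, av, ag, Fc, dr, dth_ag, ntheta_ag, nr, p.d_i,
                     p.chi_hap, dt_ag);
    if (e % 50 == 49) Rcpp::checkUserInterrupt();
  }
  check_finite(Cc, "Cp"); check_finite(Nc, "n");
  check_finite(Mc, "M");  check_finite(Fc, "f");
  return List::create(_["Cp"] = Cc, _["n"] = Nc, _["M"] = Mc, _["f"] = Fc,
                      _["j"] = wrap(aj), _["k"] = wrap(ak),
                      _["alive"] = wrap(av), _["age"] = wrap(ag));
}
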