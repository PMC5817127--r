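// Metropolis-within-Gibbs sampler for the Poisson log-link GLMM with a
// phylogeny-structured random effect, a genus random effect and an
// observation-level residual:
//   y_i ~ Poisson(exp(beta0 + beta1 x_i + a_host(i) + g_genus(i) + e_i))
//   a ~ N(0, vP * C), g ~ N(0, vG * I), e_i ~ N(0, vR)
// Variance components have scaled inverse-chi-squared priors
// (== IG(nu/2, nu*V/2)) and are updated by their conjugate conditionals;
// the fixed and latent effects use random-walk Metropolis with step sizes
// adapted toward 0.44 acceptance during burn-in and frozen afterwards.
//
// exp(eta) is maintained incrementally: a random-walk step d shifts every
// touched linear predictor by the same amount, so the Poisson likelihood
// ratio needs only one exp(d) per proposal (per distinct covariate level
// for the slope). The cache is refreshed periodically against drift.
//
// Uses R's RNG, so seeding with set.seed() on the R side makes chains
// reproducible.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Adapt {
  std::vector<double> lsd;    // log step size
  std::vector<int> acc, tot;  // acceptance bookkeeping per site
  explicit Adapt(int n, double init = -0.5)
      : lsd(n, init), acc(n, 0), tot(n, 0) {}
  void maybeTune(bool adapting) {
    if (!adapting) return;
    for (size_t j = 0; j < lsd.size(); ++j) {
      if (tot[j] >= 50) {
        double rate = double(acc[j]) / tot[j];
        lsd[j] += (rate > 0.44 ? 0.05 : -0.05);
        if (lsd[j] < -8) lsd[j] = -8;
        if (lsd[j] > 4) lsd[j] = 4;
        acc[j] = 0; tot[j] = 0;
      }
    }
  }
};

inline double rinvgamma(double shape, double rate) {
  return 1.0 / R::rgamma(shape, 1.0 / rate);  // R::rgamma uses scale
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix pglmm_mcmc(NumericVector y, NumericVector x,
                         IntegerVector hostIdx, IntegerVector genusIdx,
                         int q, int m, NumericMatrix Cinv, double V,
                         double nu, double fixedVar, int nIter,
                         int burnin, int thin) {
  const int n = y.size();
  std::vector<std::vector<int> > byHost(q), byGenus(m);
  std::vector<double> sumYhost(q, 0.0), sumYgen(m, 0.0);
  for (int i = 0; i < n; ++i) {
    byHost[hostIdx[i]].push_back(i);
    byGenus[genusIdx[i]].push_back(i);
    sumYhost[hostIdx[i]] += y[i];
    sumYgen[genusIdx[i]] += y[i];
  }
  double sumY = 0.0, sumYX = 0.0;
  for (int i = 0; i < n; ++i) { sumY += y[i]; sumYX += y[i] * x[i]; }

  // distinct covariate levels (clade ranks are small integers)
  std::vector<double> xLevVal;
  std::vector<int> xLev(n, 0);
  for (int i = 0; i < n; ++i) {
    int found = -1;
    for (size_t l = 0; l < xLevVal.size(); ++l)
      if (xLevVal[l] == x[i]) { found = int(l); break; }
    if (found < 0) { xLevVal.push_back(x[i]); found = int(xLevVal.size()) - 1; }
    xLev[i] = found;
  }
  const int nLev = int(xLevVal.size());

  double beta0 = 0.0, beta1 = 0.0;
  if (n > 0) beta0 = std::log(sumY / n + 0.5);
  std::vector<double> a(q, 0.0), g(m, 0.0), e(n, 0.0), eta(n), expEta(n);
  double vP = V, vG = V, vR = V;
  for (int i = 0; i < n; ++i) {
    eta[i] = beta0 + beta1 * x[i];
    expEta[i] = std::exp(eta[i]);
  }

  Adapt adB(2), adA(q), adG(m), adE(n), adT(3);
  std::vector<double> expDx(nLev);
  double xbar = 0.0;
  for (int i = 0; i < n; ++i) xbar += x[i];
  if (n > 0) xbar /= n;
  double CinvSum = 0.0;
  for (int j = 0; j < q; ++j)
    for (int k = 0; k < q; ++k) CinvSum += Cinv(j, k);

  const int nKeep = (nIter - burnin + thin - 1) / thin;
  NumericMatrix out(nKeep, 5);
  int kept = 0;

  for (int iter = 0; iter < nIter; ++iter) {
    const bool adapting = iter < burnin;

    if (n > 0) {
      // ---- intercept ----
      {
        double d = R::norm_rand() * std::exp(adB.lsd[0]);
        double sumE = 0.0;
        for (int i = 0; i < n; ++i) sumE += expEta[i];
        double dll = sumY * d - (std::exp(d) - 1.0) * sumE +
                     (beta0 * beta0 - (beta0 + d) * (beta0 + d)) /
                         (2.0 * fixedVar);
        ++adB.tot[0];
        if (std::log(R::unif_rand()) < dll) {
          ++adB.acc[0];
          beta0 += d;
          double f = std::exp(d);
          for (int i = 0; i < n; ++i) { eta[i] += d; expEta[i] *= f; }
        }
      }
      // ---- slope (centered: beta0 absorbs -d*xbar, so the proposal
      //      moves along the weakly identified direction) ----
      {
        double d = R::norm_rand() * std::exp(adB.lsd[1]);
        double d0 = -d * xbar;
        for (int l = 0; l < nLev; ++l)
          expDx[l] = std::exp(d * xLevVal[l] + d0);
        double dll = sumYX * d + sumY * d0;
        for (int i = 0; i < n; ++i)
          dll -= expEta[i] * (expDx[xLev[i]] - 1.0);
        dll += (beta1 * beta1 - (beta1 + d) * (beta1 + d)) /
                   (2.0 * fixedVar) +
               (beta0 * beta0 - (beta0 + d0) * (beta0 + d0)) /
                   (2.0 * fixedVar);
        ++adB.tot[1];
        if (std::log(R::unif_rand()) < dll) {
          ++adB.acc[1];
          beta1 += d;
          beta0 += d0;
          for (int i = 0; i < n; ++i) {
            eta[i] += d * x[i] + d0;
            expEta[i] *= expDx[xLev[i]];
          }
        }
      }
      // ---- likelihood-invariant translation moves: shift beta0 by d
      //      and subtract d from every effect of one block, leaving all
      //      eta unchanged; accepted on the prior ratio alone ----
      if (q > 0) {
        double d = R::norm_rand() * std::exp(adT.lsd[0]);
        double dQ = 0.0;  // change in a' Cinv a for a -> a - d
        for (int j = 0; j < q; ++j) {
          double sj = 0.0;
          for (int k = 0; k < q; ++k) sj += Cinv(j, k) * a[k];
          dQ += -2.0 * d * sj;
        }
        dQ += d * d * CinvSum;
        double dll = -dQ / (2.0 * vP) +
                     (beta0 * beta0 - (beta0 + d) * (beta0 + d)) /
                         (2.0 * fixedVar);
        ++adT.tot[0];
        if (std::log(R::unif_rand()) < dll) {
          ++adT.acc[0];
          beta0 += d;
          for (int j = 0; j < q; ++j) a[j] -= d;
        }
      }
      if (m > 0) {
        double d = R::norm_rand() * std::exp(adT.lsd[1]);
        double ss0 = 0.0, ss1 = 0.0;
        for (int j = 0; j < m; ++j) {
          ss0 += g[j] * g[j];
          double gn = g[j] - d;
          ss1 += gn * gn;
        }
        double dll = (ss0 - ss1) / (2.0 * vG) +
                     (beta0 * beta0 - (beta0 + d) * (beta0 + d)) /
                         (2.0 * fixedVar);
        ++adT.tot[1];
        if (std::log(R::unif_rand()) < dll) {
          ++adT.acc[1];
          beta0 += d;
          for (int j = 0; j < m; ++j) g[j] -= d;
        }
      }
      {
        double d = R::norm_rand() * std::exp(adT.lsd[2]);
        double ss0 = 0.0, ss1 = 0.0;
        for (int i = 0; i < n; ++i) {
          ss0 += e[i] * e[i];
          double en = e[i] - d;
          ss1 += en * en;
        }
        double dll = (ss0 - ss1) / (2.0 * vR) +
                     (beta0 * beta0 - (beta0 + d) * (beta0 + d)) /
                         (2.0 * fixedVar);
        ++adT.tot[2];
        if (std::log(R::unif_rand()) < dll) {
          ++adT.acc[2];
          beta0 += d;
          for (int i = 0; i < n; ++i) e[i] -= d;
        }
      }
    }

    // ---- phylogenetic effects ----
    for (int j = 0; j < q; ++j) {
      double d = R::norm_rand() * std::exp(adA.lsd[j]);
      double sj = 0.0;
      for (int k = 0; k < q; ++k) sj += Cinv(j, k) * a[k];
      double dll = -(d * d * Cinv(j, j) + 2.0 * d * sj) / (2.0 * vP);
      double sumE = 0.0;
      for (size_t ii = 0; ii < byHost[j].size(); ++ii)
        sumE += expEta[byHost[j][ii]];
      double f = std::exp(d);
      dll += sumYhost[j] * d - (f - 1.0) * sumE;
      ++adA.tot[j];
      if (std::log(R::unif_rand()) < dll) {
        ++adA.acc[j];
        a[j] += d;
        for (size_t ii = 0; ii < byHost[j].size(); ++ii) {
          int i = byHost[j][ii];
          eta[i] += d; expEta[i] *= f;
        }
      }
    }

    // ---- genus effects ----
    for (int j = 0; j < m; ++j) {
      double d = R::norm_rand() * std::exp(adG.lsd[j]);
      double dll = (g[j] * g[j] - (g[j] + d) * (g[j] + d)) / (2.0 * vG);
      double sumE = 0.0;
      for (size_t ii = 0; ii < byGenus[j].size(); ++ii)
        sumE += expEta[byGenus[j][ii]];
      double f = std::exp(d);
      dll += sumYgen[j] * d - (f - 1.0) * sumE;
      ++adG.tot[j];
      if (std::log(R::unif_rand()) < dll) {
        ++adG.acc[j];
        g[j] += d;
        for (size_t ii = 0; ii < byGenus[j].size(); ++ii) {
          int i = byGenus[j][ii];
          eta[i] += d; expEta[i] *= f;
        }
      }
    }

    // ---- observation-level residuals ----
    for (int i = 0; i < n; ++i) {
      double d = R::norm_rand() * std::exp(adE.lsd[i]);
      double f = std::exp(d);
      double dll = (e[i] * e[i] - (e[i] + d) * (e[i] + d)) / (2.0 * vR) +
                   y[i] * d - expEta[i] * (f - 1.0);
      ++adE.tot[i];
      if (std::log(R::unif_rand()) < dll) {
        ++adE.acc[i];
        e[i] += d;
        eta[i] += d;
        expEta[i] *= f;
      }
    }

    // ---- conjugate variance updates ----
    double ssA = 0.0;
    for (int j = 0; j < q; ++j) {
      double sj = 0.0;
      for (int k = 0; k < q; ++k) sj += Cinv(j, k) * a[k];
      ssA += a[j] * sj;
    }
    vP = rinvgamma((nu + q) / 2.0, (nu * V + ssA) / 2.0);
    double ssG = 0.0;
    for (int j = 0; j < m; ++j) ssG += g[j] * g[j];
    vG = rinvgamma((nu + m) / 2.0, (nu * V + ssG) / 2.0);
    double ssE = 0.0;
    for (int i = 0; i < n; ++i) ssE += e[i] * e[i];
    vR = rinvgamma((nu + n) / 2.0, (nu * V + ssE) / 2.0);

    adB.maybeTune(adapting);
    adA.maybeTune(adapting);
    adG.maybeTune(adapting);
    adE.maybeTune(adapting);
    adT.maybeTune(adapting);

    if ((iter & 511) == 511)  // guard against multiplicative drift
      for (int i = 0; i < n; ++i) expEta[i] = std::exp(eta[i]);

    if (iter >= burnin && (iter - burnin) % thin == 0) {
      out(kept, 0) = beta0;
      out(kept, 1) = beta1;
      out(kept, 2) = vP;
      out(kept, 3) = vG;
      out(kept, 4) = vR;
      ++kept;
    }
  }
  return out;
}
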