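// Metropolis-within-Gibbs sampler for the spatiotemporal boundary-detection
// model: per visit t the field y_t ~ N(mu_t 1, tau2_t Q(alpha_t)^-1) with
// Q(alpha) = rho (D(alpha) - W(alpha)) + (1 - rho) I and boundary-detection
// weights W_ij = exp(-alpha z_ij) on adjacent pairs; the per-visit parameter
// blocks theta_t = (mu_t, ln tau2_t, ln alpha_t) carry a matrix-normal prior
// with cross-parameter covariance Sigma (inverse-Wishart) and exponential
// temporal correlation Psi(phi), phi uniform on (aPhi, bPhi), level delta
// Gaussian. All randomness comes from R's RNG so fits are seed-reproducible.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static mat build_q(double alpha, const ivec& ei, const ivec& ej,
                   const vec& z, int n, double rho) {
  mat W(n, n, fill::zeros);
  for (uword e = 0; e < z.n_elem; ++e) {
    double w = std::exp(-alpha * z[e]);
    W(ei[e], ej[e]) = w;
    W(ej[e], ei[e]) = w;
  }
  vec d = sum(W, 1);
  mat Q = -rho * W;
  Q.diag() += rho * d + (1.0 - rho);
  return Q;
}

// Gaussian CAR log-density; returns false (through ok) if the Cholesky
// factorisation fails (numerically indefinite Q, e.g. parameter overflow).
static double car_loglik_q(const vec& y, double mu, double tau2,
                           const mat& Q, bool& ok) {
  mat L;
  ok = chol(L, Q, "lower");
  if (!ok) return -datum::inf;
  double logdetQ = 2.0 * accu(log(L.diag()));
  vec r = y - mu;
  double quad = dot(r, Q * r);
  int n = y.n_elem;
  return -0.5 * n * std::log(2.0 * M_PI * tau2) + 0.5 * logdetQ
         - 0.5 * quad / tau2;
}

// [[Rcpp::export(name = ".cpp_car_loglik")]]
double cpp_car_loglik(const arma::vec& y, double mu, double tau2,
                      double alpha, const arma::ivec& ei,
                      const arma::ivec& ej, const arma::vec& z,
                      double rho) {
  if (tau2 <= 0 || alpha <= 0) Rcpp::stop("tau2 and alpha must be positive");
  bool ok = true;
  mat Q = build_q(alpha, ei, ej, z, y.n_elem, rho);
  double ll = car_loglik_q(y, mu, tau2, Q, ok);
  if (!ok) Rcpp::stop("Cholesky factorisation of Q failed (alpha = %g)",
                      alpha);
  return ll;
}

static vec rnorm_vec(int n) {
  vec out(n);
  for (int i = 0; i < n; ++i) out[i] = R::norm_rand();
  return out;
}

// Wishart(df, V) draw via the Bartlett decomposition; V must be SPD.
static mat rwishart(double df, const mat& V) {
  int p = V.n_rows;
  mat L = chol(V, "lower");
  mat A(p, p, fill::zeros);
  for (int i = 0; i < p; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  }
  mat LA = L * A;
  return LA * LA.t();
}

// Conjugate Gaussian update of the level delta given the matrix-normal
// prior on Theta: precision P = (1' Psi^-1 1) Sigma^-1 + I / deltaVar,
// mean P^-1 Sigma^-1 Theta Psi^-1 1.
// [[Rcpp::export(name = ".cpp_draw_delta")]]
arma::vec cpp_draw_delta(const arma::mat& Theta, const arma::mat& SigmaInv,
                         const arma::mat& PsiInv, double deltaVar) {
  int T = Theta.n_cols;
  double c = accu(PsiInv);
  mat P = c * SigmaInv + eye(3, 3) / deltaVar;
  vec b = SigmaInv * (Theta * (PsiInv * ones(T)));
  mat Lp = chol(P, "lower");
  vec m = solve(trimatu(Lp.t()), solve(trimatl(Lp), b));
  vec zdraw = rnorm_vec(3);
  return m + solve(trimatu(Lp.t()), zdraw);
}

static double prior_quad(const mat& Theta, const vec& delta,
                         const mat& SigmaInv, const mat& PsiInv) {
  mat Tc = Theta.each_col() - delta;
  return trace(SigmaInv * Tc * PsiInv * Tc.t());
}

// [[Rcpp::export(name = ".cpp_stbound_mcmc")]]
Rcpp::List cpp_stbound_mcmc(const arma::mat& Y, const arma::vec& times,
                            const arma::ivec& ei, const arma::ivec& ej,
                            const arma::vec& z, double rho,
                            double deltaVar, double sigmaDf,
                            const arma::mat& sigmaScale,
                            double aPhi, double bPhi,
                            int nBurn, int nKeep, int thin,
                            const arma::vec& baseScales, double phiScale0,
                            bool adapt, bool tobit,
                            const arma::vec& muInit,
                            const arma::vec& ltau2Init,
                            const arma::vec& lalphaInit) {
  const int n = Y.n_rows, T = Y.n_cols;
  const int nIter = nBurn + nKeep, nStore = nKeep / thin;

  mat Dt(T, T);
  for (int t = 0; t < T; ++t)
    for (int s = 0; s < T; ++s) Dt(t, s) = std::fabs(times[t] - times[s]);

  mat Theta(3, T);
  Theta.row(0) = muInit.t();
  Theta.row(1) = ltau2Init.t();
  Theta.row(2) = lalphaInit.t();
  vec delta = mean(Theta, 1);
  mat Sigma = eye(3, 3), SigmaInv = eye(3, 3);
  double phi = 0.5 * (aPhi + bPhi);

  mat Psi = exp(-phi * Dt);
  mat PsiInv = inv_sympd(symmatu(Psi));
  double ldPsi;
  {
    double sign;
    log_det(ldPsi, sign, Psi);
  }

  // censored (0 dB) entries per visit for the Tobit likelihood
  std::vector<uvec> cens(T);
  mat Ylat = Y;
  if (tobit) for (int t = 0; t < T; ++t) cens[t] = find(Y.col(t) <= 0.0);

  // cached per-visit log-likelihoods at the current state
  vec ll(T);
  for (int t = 0; t < T; ++t) {
    bool ok = true;
    mat Q = build_q(std::exp(Theta(2, t)), ei, ej, z, n, rho);
    ll[t] = car_loglik_q(Ylat.col(t), Theta(0, t),
                         std::exp(Theta(1, t)), Q, ok);
    if (!ok) Rcpp::stop("initial Q factorisation failed at visit %d", t + 1);
  }

  vec scaleVisit(T, fill::ones);
  double phiScale = phiScale0;
  vec accV(T, fill::zeros), attV(T, fill::zeros);
  double accPhi = 0, attPhi = 0;
  vec accVkeep(T, fill::zeros), attVkeep(T, fill::zeros);
  double accPhiKeep = 0, attPhiKeep = 0;

  mat keepMu(nStore, T), keepTau2(nStore, T), keepAlpha(nStore, T);
  mat keepDelta(nStore, 3);
  vec keepPhi(nStore);
  int stored = 0;

  for (int iter = 1; iter <= nIter; ++iter) {
    if (iter % 256 == 0) Rcpp::checkUserInterrupt();
    bool burn = iter <= nBurn;

    // latent-field imputation for left-censored observations (Tobit)
    if (tobit) {
      for (int t = 0; t < T; ++t) {
        if (cens[t].n_elem == 0) continue;
        double mu = Theta(0, t), tau2 = std::exp(Theta(1, t));
        mat Q = build_q(std::exp(Theta(2, t)), ei, ej, z, n, rho);
        vec yc = Ylat.col(t);
        for (uword k = 0; k < cens[t].n_elem; ++k) {
          uword i = cens[t][k];
          double qii = Q(i, i);
          double dotq = dot(Q.row(i).t(), yc - mu) - qii * (yc[i] - mu);
          double m = mu - dotq / qii;
          double s = std::sqrt(tau2 / qii);
          double cap = R::pnorm(0.0, m, s, 1, 0);
          double u = std::max(R::unif_rand() * cap, 1e-14);
          double x = m + s * R::qnorm(u, 0.0, 1.0, 1, 0);
          yc[i] = std::min(std::max(x, m - 8 * s), 0.0);
        }
        Ylat.col(t) = yc;
        bool ok = true;
        ll[t] = car_loglik_q(yc, mu, tau2, Q, ok);
        if (!ok) Rcpp::stop("Q factorisation failed during imputation");
      }
    }

    // per-visit Metropolis blocks
    for (int t = 0; t < T; ++t) {
      attV[t] += 1;
      if (!burn) attVkeep[t] += 1;
      vec prop = Theta.col(t) + scaleVisit[t] * (baseScales % rnorm_vec(3));
      if (std::fabs(prop[1]) > 30 || std::fabs(prop[2]) > 30) continue;
      bool ok = true;
      mat Qp = build_q(std::exp(prop[2]), ei, ej, z, n, rho);
      double llNew = car_loglik_q(Ylat.col(t), prop[0], std::exp(prop[1]),
                                  Qp, ok);
      if (!ok) continue;
      double qOld = prior_quad(Theta, delta, SigmaInv, PsiInv);
      mat ThetaProp = Theta;
      ThetaProp.col(t) = prop;
      double qNew = prior_quad(ThetaProp, delta, SigmaInv, PsiInv);
      double logr = llNew - ll[t] - 0.5 * (qNew - qOld);
      if (std::log(R::unif_rand()) < logr) {
        Theta.col(t) = prop;
        ll[t] = llNew;
        accV[t] += 1;
        if (!burn) accVkeep[t] += 1;
      }
    }

    // conjugate updates: level, cross-parameter covariance
    delta = cpp_draw_delta(Theta, SigmaInv, PsiInv, deltaVar);
    {
      mat Tc = Theta.each_col() - delta;
      mat M = Tc * PsiInv * Tc.t();
      mat Spost = sigmaScale + M;
      mat W = rwishart(sigmaDf + T, inv_sympd(symmatu(Spost)));
      SigmaInv = symmatu(W);
      Sigma = inv_sympd(SigmaInv);
    }

    // temporal decay phi: random walk on the logit of (phi-a)/(b-a)
    {
      attPhi += 1;
      if (!burn) attPhiKeep += 1;
      double q = (phi - aPhi) / (bPhi - aPhi);
      double u = std::log(q / (1 - q));
      double uProp = u + phiScale * R::norm_rand();
      double qProp = 1.0 / (1.0 + std::exp(-uProp));
      double phiProp = aPhi + (bPhi - aPhi) * qProp;
      mat PsiProp = exp(-phiProp * Dt);
      mat PsiPropInv;
      bool ok = inv_sympd(PsiPropInv, symmatu(PsiProp));
      if (ok) {
        double ldProp, sign;
        log_det(ldProp, sign, PsiProp);
        double tgtOld = -1.5 * ldPsi
          - 0.5 * prior_quad(Theta, delta, SigmaInv, PsiInv)
          + std::log(q * (1 - q));
        double tgtNew = -1.5 * ldProp
          - 0.5 * prior_quad(Theta, delta, SigmaInv, PsiPropInv)
          + std::log(qProp * (1 - qProp));
        if (std::log(R::unif_rand()) < tgtNew - tgtOld) {
          phi = phiProp;
          Psi = PsiProp;
          PsiInv = PsiPropInv;
          ldPsi = ldProp;
          accPhi += 1;
          if (!burn) accPhiKeep += 1;
        }
      }
    }

    // burn-in scale adaptation targeting acceptance ~0.35
    if (adapt && burn && iter % 50 == 0) {
      for (int t = 0; t < T; ++t) {
        double rate = attV[t] > 0 ? accV[t] / attV[t] : 0.0;
        scaleVisit[t] = std::min(1e3, std::max(1e-3,
          scaleVisit[t] * std::exp(0.8 * (rate - 0.35))));
      }
      double ratePhi = attPhi > 0 ? accPhi / attPhi : 0.0;
      phiScale = std::min(1e3, std::max(1e-3,
        phiScale * std::exp(0.8 * (ratePhi - 0.35))));
      accV.zeros(); attV.zeros(); accPhi = 0; attPhi = 0;
    }

    if (!burn && (iter - nBurn) % thin == 0 && stored < nStore) {
      keepMu.row(stored) = Theta.row(0);
      keepTau2.row(stored) = exp(Theta.row(1));
      keepAlpha.row(stored) = exp(Theta.row(2));
      keepDelta.row(stored) = delta.t();
      keepPhi[stored] = phi;
      ++stored;
    }
  }

  vec accRates(T + 1);
  for (int t = 0; t < T; ++t) {
    accRates[t] = attVkeep[t] > 0 ? accVkeep[t] / attVkeep[t] : NA_REAL;
  }
  accRates[T] = attPhiKeep > 0 ? accPhiKeep / attPhiKeep : NA_REAL;

  return Rcpp::List::create(
    Rcpp::Named("mu") = keepMu,
    Rcpp::Named("tau2") = keepTau2,
    Rcpp::Named("alpha") = keepAlpha,
    Rcpp::Named("delta") = keepDelta,
    Rcpp::Named("phi") = keepPhi,
    Rcpp::Named("acceptance") = accRates);
}
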