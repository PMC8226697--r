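// Gibbs sampler core for the multiple-trait random regression test-day
// animal model. Location effects are updated in blocks (one multivariate
// normal draw per effect level); covariance components have inverted-Wishart
// full conditionals. All randomness flows through R's RNG so a single
// set.seed() in R makes chains exactly reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static vec rnorm_vec(int n) {
  vec z(n);
  for (int i = 0; i < n; ++i) z(i) = norm_rand();
  return z;
}

// Wishart(nu, S) draw by Bartlett decomposition; S is the scale matrix.
static mat rwishart_c(double nu, const mat& S) {
  const int p = S.n_rows;
  mat L = chol(S, "lower");
  mat A(p, p, fill::zeros);
  for (int i = 0; i < p; ++i) {
    A(i, i) = std::sqrt(Rf_rchisq(nu - i));
    for (int j = 0; j < i; ++j) A(i, j) = norm_rand();
  }
  mat LA = L * A;
  return LA * LA.t();
}

// Inverted Wishart(Psi, nu): X^{-1} ~ Wishart(nu, Psi^{-1}).
static mat riwishart_c(double nu, const mat& Psi) {
  mat W = rwishart_c(nu, inv_sympd(Psi));
  return inv_sympd(W);
}

// [[Rcpp::export(name = ".riwishart")]]
arma::mat riwishart_cpp(double nu, const arma::mat& Psi) {
  return riwishart_c(nu, Psi);
}

// Quadratic form sum_{ij} ainv_{ij} u_i u_j' over the sparse A-inverse.
static mat ainv_quadform(const sp_mat& Ainv, const mat& U) {
  mat S(U.n_cols, U.n_cols, fill::zeros);
  for (sp_mat::const_iterator it = Ainv.begin(); it != Ainv.end(); ++it) {
    S += (*it) * (U.row(it.row()).t() * U.row(it.col()));
  }
  return symmatu(0.5 * (S + S.t()));
}

// Full-conditional draw of a covariance component given the current effect
// matrix U (levels x dim), its prior, and the A-inverse weighting (identity
// for PE and residual components). Exposed for conjugate-oracle tests.
// [[Rcpp::export(name = ".draw_cov_conditional")]]
arma::mat draw_cov_conditional(const arma::mat& U, const arma::sp_mat& Ainv,
                               const arma::mat& prior_scale, double prior_nu,
                               bool use_ainv) {
  mat S = use_ainv ? ainv_quadform(Ainv, U) : mat(U.t() * U);
  return riwishart_c(prior_nu + U.n_rows, prior_scale + S);
}

// One-dimensional slice sampler (Neal 2003, stepping out) on an
// unnormalized log density.
template <class F>
static double slice_sample_1d(const F& logf, double x0, double w, int m) {
  double f0 = logf(x0);
  double y = f0 + std::log(unif_rand());
  double L = x0 - w * unif_rand();
  double R = L + w;
  int j = (int)std::floor(m * unif_rand());
  int k = m - 1 - j;
  while (j-- > 0 && y < logf(L)) L -= w;
  while (k-- > 0 && y < logf(R)) R += w;
  for (int tries = 0; tries < 100; ++tries) {
    double x1 = L + (R - L) * unif_rand();
    if (y <= logf(x1)) return x1;
    if (x1 < x0) L = x1; else R = x1;
  }
  return x0;
}

// Draw x ~ N(C^{-1} b, C^{-1}) from precision C and rhs b; if !stochastic
// returns the conditional mean (Gauss-Seidel mode).
static vec mvn_from_precision(const mat& C, const vec& b, bool stochastic) {
  mat Uc;
  if (!chol(Uc, C)) {
    // near-singular conditional: tiny jitter, standard MME practice
    mat Cj = C + 1e-10 * trace(C) / C.n_rows * eye(C.n_rows, C.n_cols);
    Uc = chol(Cj);
  }
  vec mu = solve(trimatu(Uc), solve(trimatl(Uc.t()), b));
  if (!stochastic) return mu;
  return mu + solve(trimatu(Uc), rnorm_vec(C.n_rows));
}

// [[Rcpp::export(name = ".gibbs_rrtdm")]]
Rcpp::List gibbs_rrtdm(const arma::mat& Y,        // n x T responses
                       const arma::mat& Phi_a,    // n x q RR basis
                       const arma::mat& Phi_f,    // n x p fixed basis (p may be 0)
                       const arma::uvec& animal,  // 1-based, into 1..n_anim
                       const arma::uvec& pe,      // 1-based
                       const arma::uvec& htd,     // 1-based
                       const arma::uvec& as_cls,  // 1-based (empty if p == 0)
                       const arma::sp_mat& Ainv,  // n_anim x n_anim
                       const arma::mat& Ka0, const arma::mat& Kpe0,
                       const arma::mat& R0,
                       const arma::mat& Sa, const arma::mat& Spe,
                       const arma::mat& Sr,
                       double nua, double nupe, double nur,
                       int n_iter, int burn_in, int thin,
                       bool sample_effects, bool sample_cov,
                       int n_realloc) {
  const uword n = Y.n_rows, T = Y.n_cols;
  const uword q = Phi_a.n_cols, p = Phi_f.n_cols;
  const uword n_anim = Ainv.n_rows;
  const uword n_pe = pe.max();
  const uword n_htd = htd.max();
  const uword n_as = (p > 0 && as_cls.n_elem > 0) ? as_cls.max() : 0;
  const uword qa = q * T, pf = p * T;

  if (n_iter <= burn_in)
    Rcpp::stop("n_iter must exceed burn_in");
  if (thin < 1) Rcpp::stop("thin must be >= 1");

  // record lists per effect level
  std::vector<std::vector<uword>> recs_anim(n_anim), recs_pe(n_pe),
      recs_htd(n_htd), recs_as(n_as);
  for (uword r = 0; r < n; ++r) {
    recs_anim[animal(r) - 1].push_back(r);
    recs_pe[pe(r) - 1].push_back(r);
    recs_htd[htd(r) - 1].push_back(r);
    if (n_as > 0) recs_as[as_cls(r) - 1].push_back(r);
  }
  // each PE level belongs to exactly one animal (the phenotyped cow)
  uvec anim_of_pe(n_pe);
  for (uword c = 0; c < n_pe; ++c) {
    if (recs_pe[c].empty()) Rcpp::stop("PE level without records");
    anim_of_pe[c] = animal(recs_pe[c][0]) - 1;
    for (uword r : recs_pe[c])
      if (animal(r) - 1 != anim_of_pe[c])
        Rcpp::stop("a PE level spans multiple animals");
  }

  // per-level basis cross-products (complete trait vectors per record)
  std::vector<mat> Qp(n_pe), Qf(n_as);
  for (uword i = 0; i < n_pe; ++i) {
    mat Q(q, q, fill::zeros);
    for (uword r : recs_pe[i]) Q += Phi_a.row(r).t() * Phi_a.row(r);
    Qp[i] = Q;
  }
  for (uword i = 0; i < n_as; ++i) {
    mat Q(p, p, fill::zeros);
    for (uword r : recs_as[i]) Q += Phi_f.row(r).t() * Phi_f.row(r);
    Qf[i] = Q;
  }

  // state
  mat Ka = Ka0, Kpe = Kpe0, R = R0;
  mat U(n_anim, qa, fill::zeros), P(n_pe, qa, fill::zeros);
  mat H(n_htd, T, fill::zeros), AS(n_as, pf, fill::zeros);
  mat E = Y;  // residuals given all-zero effects

  const double tr0 = trace(Ka0) + trace(Kpe0) + trace(R0);

  const int n_keep = (n_iter - burn_in) / thin;
  mat keep_Ka(n_keep, qa * qa), keep_Kpe(n_keep, qa * qa),
      keep_R(n_keep, T * T);
  mat Um(n_anim, qa, fill::zeros), Pm(n_pe, qa, fill::zeros),
      Hm(n_htd, T, fill::zeros), ASm(n_as, pf, fill::zeros);
  int kept = 0, averaged = 0;

  // column access to the symmetric sparse A-inverse
  for (int it = 0; it < n_iter; ++it) {
    mat Rinv = inv_sympd(R);
    mat Kainv = inv_sympd(Ka);
    mat Kpeinv = inv_sympd(Kpe);

    // --- herd-test-day blocks (flat prior) ---
    for (uword h = 0; h < n_htd; ++h) {
      const std::vector<uword>& idx = recs_htd[h];
      if (idx.empty()) continue;
      rowvec s(T, fill::zeros);
      for (uword r : idx) { E.row(r) += H.row(h); s += E.row(r); }
      mat C = (double)idx.size() * Rinv;
      vec draw = mvn_from_precision(C, Rinv * s.t(), sample_effects);
      H.row(h) = draw.t();
      for (uword r : idx) E.row(r) -= H.row(h);
    }

    // --- age-season regression blocks (flat prior) ---
    for (uword c = 0; c < n_as; ++c) {
      const std::vector<uword>& idx = recs_as[c];
      if (idx.empty()) continue;
      vec b(pf, fill::zeros);
      for (uword r : idx) {
        for (uword j = 0; j < T; ++j)
          E(r, j) += dot(Phi_f.row(r), AS.row(c).subvec(j * p, j * p + p - 1));
        vec re = Rinv * E.row(r).t();
        for (uword j = 0; j < T; ++j)
          b.subvec(j * p, j * p + p - 1) += re(j) * Phi_f.row(r).t();
      }
      mat C = kron(Rinv, Qf[c]);
      vec draw = mvn_from_precision(C, b, sample_effects);
      AS.row(c) = draw.t();
      for (uword r : idx) {
        for (uword j = 0; j < T; ++j)
          E(r, j) -= dot(Phi_f.row(r), AS.row(c).subvec(j * p, j * p + p - 1));
      }
    }

    // --- additive genetic blocks for animals without records ---
    // (phenotyped animals are drawn jointly with their PE block below,
    // which removes the slow additive/PE random walk within a cow)
    for (uword i = 0; i < n_anim; ++i) {
      if (!recs_anim[i].empty()) continue;
      double aii = 0.0;
      vec nbr(qa, fill::zeros);
      for (sp_mat::const_col_iterator ci = Ainv.begin_col(i);
           ci != Ainv.end_col(i); ++ci) {
        uword j = ci.row();
        if (j == i) aii = *ci;
        else nbr += (*ci) * U.row(j).t();
      }
      mat C = aii * Kainv;
      vec b = -(Kainv * nbr);
      vec draw = mvn_from_precision(C, b, sample_effects);
      U.row(i) = draw.t();
    }

    // --- joint (additive, permanent environment) blocks per cow ---
    for (uword c = 0; c < n_pe; ++c) {
      const uword i = anim_of_pe[c];
      const std::vector<uword>& idx = recs_pe[c];
      double aii = 0.0;
      vec nbr(qa, fill::zeros);
      for (sp_mat::const_col_iterator ci = Ainv.begin_col(i);
           ci != Ainv.end_col(i); ++ci) {
        uword j = ci.row();
        if (j == i) aii = *ci;
        else nbr += (*ci) * U.row(j).t();
      }
      vec bd(qa, fill::zeros);
      for (uword r : idx) {
        for (uword j = 0; j < T; ++j)
          E(r, j) += dot(Phi_a.row(r),
                         U.row(i).subvec(j * q, j * q + q - 1) +
                         P.row(c).subvec(j * q, j * q + q - 1));
        vec re = Rinv * E.row(r).t();
        for (uword j = 0; j < T; ++j)
          bd.subvec(j * q, j * q + q - 1) += re(j) * Phi_a.row(r).t();
      }
      mat Cd = kron(Rinv, Qp[c]);
      mat C(2 * qa, 2 * qa);
      C.submat(0, 0, qa - 1, qa - 1) = Cd + aii * Kainv;
      C.submat(0, qa, qa - 1, 2 * qa - 1) = Cd;
      C.submat(qa, 0, 2 * qa - 1, qa - 1) = Cd;
      C.submat(qa, qa, 2 * qa - 1, 2 * qa - 1) = Cd + Kpeinv;
      vec b(2 * qa);
      b.subvec(0, qa - 1) = bd - Kainv * nbr;
      b.subvec(qa, 2 * qa - 1) = bd;
      vec draw = mvn_from_precision(C, b, sample_effects);
      U.row(i) = draw.subvec(0, qa - 1).t();
      P.row(c) = draw.subvec(qa, 2 * qa - 1).t();
      for (uword r : idx) {
        for (uword j = 0; j < T; ++j)
          E(r, j) -= dot(Phi_a.row(r),
                         U.row(i).subvec(j * q, j * q + q - 1) +
                         P.row(c).subvec(j * q, j * q + q - 1));
      }
    }

    // --- scaled reallocation moves between additive and PE components ---
    // The likelihood sees a cow's effects only through their sum, so the
    // additive/PE split (and with it trace(Ka) vs trace(Kpe)) mixes very
    // slowly under plain blocked Gibbs. Two generalized Gibbs steps per
    // trait block move variances and effects together along likelihood-
    // invariant group orbits:
    //   A: u[bj] -> alpha u[bj] (all animals), p[bj] -> p[bj]+(1-alpha)u[bj]
    //      (phenotyped cows), Ka -> D Ka D with D = diag(alpha on bj);
    //   B: the mirror image scaling the PE block and Kpe.
    // Every fitted value is unchanged; log(alpha) is slice-sampled from the
    // exact induced density (prior quadratic forms, inverted-Wishart terms
    // and Jacobians), so the posterior is left invariant while the scale of
    // each component can change in one step.
    if (sample_effects && sample_cov && n_realloc > 0) {
      for (int sweep = 0; sweep < n_realloc; ++sweep)
      for (uword j = 0; j < T; ++j) {
        const uword b0 = j * q, b1 = j * q + q - 1;
        const double qn = (double)q * nua;   // nu exponent term, move A

        // ---- move A: scale the additive block ----
        {
          mat KP = Kainv % Sa;  // elementwise, for tr((DKaD)^-1 Sa) terms
          double c2 = accu(KP.submat(b0, b0, b1, b1));
          double c1 = 2.0 * (accu(KP.rows(b0, b1)) - c2);
          mat Uj(n_pe, q);
          for (uword c = 0; c < n_pe; ++c)
            Uj.row(c) = U.row(anim_of_pe[c]).subvec(b0, b1);
          mat G1m = Uj.t() * P;                // q x qa
          double G1 = accu(Kpeinv.rows(b0, b1) % G1m);
          double G2 = accu(Kpeinv.submat(b0, b0, b1, b1) % (Uj.t() * Uj));
          auto logfA = [&](double th) {
            double a = std::exp(th), d = 1.0 - a;
            return -qn * th -
                   0.5 * (c2 * std::exp(-2 * th) + c1 * std::exp(-th)) -
                   d * G1 - 0.5 * d * d * G2;
          };
          double th = slice_sample_1d(logfA, 0.0, 0.5, 20);
          double a = std::exp(th), d = 1.0 - a;
          if (th != 0.0) {
            for (uword c = 0; c < n_pe; ++c)
              P.row(c).subvec(b0, b1) +=
                  d * U.row(anim_of_pe[c]).subvec(b0, b1);
            U.cols(b0, b1) *= a;
            Ka.rows(b0, b1) *= a;
            Ka.cols(b0, b1) *= a;
            Kainv = inv_sympd(Ka);
          }
        }

        // ---- move B: scale the permanent environment block ----
        {
          const double qnp = (double)q * nupe;
          mat KP = Kpeinv % Spe;
          double c2 = accu(KP.submat(b0, b0, b1, b1));
          double c1 = 2.0 * (accu(KP.rows(b0, b1)) - c2);
          mat Wj(n_anim, q, fill::zeros);
          for (uword c = 0; c < n_pe; ++c)
            Wj.row(anim_of_pe[c]) = P.row(c).subvec(b0, b1);
          mat AU = Ainv * U;                   // n_anim x qa
          double B1 = accu(Kainv.rows(b0, b1) % (Wj.t() * AU));
          double B2 = accu(Kainv.submat(b0, b0, b1, b1) %
                           (Wj.t() * (Ainv * Wj)));
          auto logfB = [&](double th) {
            double b = std::exp(th), d = 1.0 - b;
            return -qnp * th -
                   0.5 * (c2 * std::exp(-2 * th) + c1 * std::exp(-th)) -
                   d * B1 - 0.5 * d * d * B2;
          };
          double th = slice_sample_1d(logfB, 0.0, 0.5, 20);
          double b = std::exp(th), d = 1.0 - b;
          if (th != 0.0) {
            for (uword c = 0; c < n_pe; ++c)
              U.row(anim_of_pe[c]).subvec(b0, b1) +=
                  d * P.row(c).subvec(b0, b1);
            P.cols(b0, b1) *= b;
            Kpe.rows(b0, b1) *= b;
            Kpe.cols(b0, b1) *= b;
            Kpeinv = inv_sympd(Kpe);
          }
        }
      }
    }

    // --- covariance components: inverted-Wishart full conditionals ---
    if (sample_cov) {
      Ka = riwishart_c(nua + n_anim, Sa + ainv_quadform(Ainv, U));
      Kpe = riwishart_c(nupe + n_pe, Spe + P.t() * P);
      R = riwishart_c(nur + n, Sr + E.t() * E);
      if (trace(Ka) + trace(Kpe) + trace(R) > 1e6 * tr0) {
        Rcpp::stop("Gibbs chain diverged at iteration %d "
                   "(covariance trace exceeded 1e6 x initial)", it + 1);
      }
    }

    if (it >= burn_in) {
      Um += U; Pm += P; Hm += H; ASm += AS;
      ++averaged;
      if ((it - burn_in) % thin == 0 && kept < n_keep) {
        keep_Ka.row(kept) = vectorise(Ka).t();
        keep_Kpe.row(kept) = vectorise(Kpe).t();
        keep_R.row(kept) = vectorise(R).t();
        ++kept;
      }
    }
    if (it % 500 == 0) Rcpp::checkUserInterrupt();
  }
  Um /= averaged; Pm /= averaged; Hm /= averaged;
  if (n_as > 0) ASm /= averaged;

  return Rcpp::List::create(
      Rcpp::Named("Ka") = keep_Ka.rows(0, kept - 1),
      Rcpp::Named("Kpe") = keep_Kpe.rows(0, kept - 1),
      Rcpp::Named("R") = keep_R.rows(0, kept - 1),
      Rcpp::Named("U_mean") = Um, Rcpp::Named("P_mean") = Pm,
      Rcpp::Named("H_mean") = Hm, Rcpp::Named("AS_mean") = ASm,
      Rcpp::Named("n_kept") = kept);
}
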