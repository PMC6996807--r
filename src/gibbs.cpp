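// Gibbs sampler for single- and multi-trait random regression models.
//
// Model: y = X b + Z u + Q p + e with
//   Var(u) = C (x) G   (coefficient-major Kronecker layout, trait-major C),
//   Var(p) = D (x) I,
//   e ~ per-(accession, day) blocks R(t) restricted to the observed traits.
//
// Sampling scheme per iteration:
//   1. fixed coefficients b jointly from their multivariate-normal
//      conditional;
//   2. genetic coefficient blocks u_a, one accession at a time, with the
//      accession's permanent-environment block integrated out analytically
//      (collapsed update: p_a only enters that accession's records, so its
//      marginalized record covariance V_a = B_p D B_p' + R_a is small and
//      local). Collapsing is what keeps the genetic / permanent-environment
//      partition mixing when the genomic structure separating them is
//      modest;
//   3. permanent-environment blocks p_a | u from their conjugate normal;
//   4. C ~ inverse-Wishart with scale U' G^-1 U, D likewise with P'P;
//   5. each day's residual block: inverse-Wishart from complete trait
//      pairs, or per-trait scaled inverse chi-square when only one trait is
//      observed that day (cross term held at zero).
//
// Record patterns (the set of (day, trait) cells an accession carries) are
// shared by many accessions in (near-)balanced designs, so the per-pattern
// matrices B, V^-1, B'V^-1 are assembled once per iteration per pattern.
// All randomness comes from R's RNG: set.seed() in R reproduces runs.

#include <RcppArmadillo.h>
#include <map>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::cube;

static mat safe_chol_lower(mat A) {
  mat L;
  if (arma::chol(L, A, "lower")) return L;
  double bump = 1e-10 * arma::trace(A) / A.n_rows;
  for (int k = 0; k < 6; ++k) {
    if (arma::chol(L, A + bump * arma::eye(A.n_rows, A.n_cols), "lower"))
      return L;
    bump *= 100.0;
  }
  stop("Cholesky failed on a conditional precision/scale matrix");
  return L;  // not reached
}

// Wishart_d(df, S) via the Bartlett decomposition, using R's RNG.
static mat rwishart(double df, const mat& S) {
  const int d = S.n_rows;
  mat L = safe_chol_lower(S);
  mat A(d, d, arma::fill::zeros);
  for (int i = 0; i < d; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) A(i, j) = norm_rand();
  }
  mat LA = L * A;
  return LA * LA.t();
}

static mat rinvwishart(double df, const mat& S) {
  mat W = rwishart(df, arma::inv_sympd(arma::symmatu(S)));
  return arma::inv_sympd(arma::symmatu(W));
}

// Draw from N(P^-1 r, P^-1) given precision P and linear term r.
static vec sample_mvn_canonical(const mat& P, const vec& r) {
  mat L = safe_chol_lower(arma::symmatu(P));
  vec mu = arma::solve(arma::trimatl(L), r);
  mu = arma::solve(arma::trimatu(L.t()), mu);
  vec z(r.n_elem);
  for (arma::uword i = 0; i < z.n_elem; ++i) z(i) = norm_rand();
  return mu + arma::solve(arma::trimatu(L.t()), z);
}

struct Pattern {
  std::vector<int> day;    // per row of the pattern
  std::vector<int> trait;
  mat Bg, Bp;              // m x KTg, m x KTp
  // per-iteration quantities
  mat Ag, Tg;              // Bg' V^-1 Bg, Bg' V^-1   (p marginalized)
  mat Ap, Tp;              // Bp' Ra^-1 Bp, Bp' Ra^-1
};

// [[Rcpp::export(name = ".gibbs_rrm_cpp")]]
List gibbs_rrm_cpp(const arma::vec& y,
                   const arma::ivec& acc,    // 0-based accession index
                   const arma::ivec& trt,    // 0-based trait index
                   const arma::ivec& dayi,   // 0-based day index
                   const arma::mat& Phi_f,   // nday x Kf
                   const arma::mat& Phi_g,   // nday x Kg
                   const arma::mat& Phi_p,   // nday x Kp
                   const arma::mat& Ginv,    // n x n
                   int n, int ntraits, int nday,
                   bool het_residual, bool include_pe,
                   int niter, int burnin, int thin,
                   double nu_c, const arma::mat& S_c,
                   double nu_d, const arma::mat& S_d,
                   double nu_r, const arma::mat& S_r,
                   const arma::mat& C0, const arma::mat& D0,
                   const arma::cube& R0,
                   bool update_c, bool update_d, bool update_r,
                   bool store_b) {
  RNGScope scope;

  const int nrec = y.n_elem;
  const int Kf = Phi_f.n_cols, Kg = Phi_g.n_cols;
  const int Kp = include_pe ? (int)Phi_p.n_cols : 0;
  const int KTf = ntraits * Kf, KTg = ntraits * Kg, KTp = ntraits * Kp;
  const int ndayr = het_residual ? nday : 1;

  // record lookup: cell_rec[(a * nday + d) * ntraits + q] = record or -1
  std::vector<int> cell_rec((size_t)n * nday * ntraits, -1);
  for (int r = 0; r < nrec; ++r) {
    cell_rec[((size_t)acc(r) * nday + dayi(r)) * ntraits + trt(r)] = r;
  }

  // record-pattern bookkeeping: accessions sharing the same (day, trait)
  // support share all per-pattern matrices
  std::vector<int> pat_of(n, -1);
  std::vector<Pattern> pats;
  std::vector<std::vector<int>> acc_rows(n);  // record ids, pattern order
  {
    std::map<std::vector<int>, int> keymap;
    for (int a = 0; a < n; ++a) {
      std::vector<int> key;
      std::vector<int> rows;
      for (int d = 0; d < nday; ++d) {
        for (int q = 0; q < ntraits; ++q) {
          int r = cell_rec[((size_t)a * nday + d) * ntraits + q];
          if (r >= 0) {
            key.push_back(d * ntraits + q);
            rows.push_back(r);
          }
        }
      }
      acc_rows[a] = rows;
      if (key.empty()) continue;  // accession with no records
      auto it = keymap.find(key);
      if (it == keymap.end()) {
        Pattern p;
        const int m = key.size();
        p.day.resize(m);
        p.trait.resize(m);
        p.Bg.zeros(m, KTg);
        if (include_pe) p.Bp.zeros(m, KTp);
        for (int i = 0; i < m; ++i) {
          p.day[i] = key[i] / ntraits;
          p.trait[i] = key[i] % ntraits;
          p.Bg(i, arma::span(p.trait[i] * Kg, (p.trait[i] + 1) * Kg - 1)) =
            Phi_g.row(p.day[i]);
          if (include_pe)
            p.Bp(i, arma::span(p.trait[i] * Kp, (p.trait[i] + 1) * Kp - 1)) =
              Phi_p.row(p.day[i]);
        }
        keymap[key] = pats.size();
        pat_of[a] = pats.size();
        pats.push_back(std::move(p));
      } else {
        pat_of[a] = it->second;
      }
    }
  }

  // per-day outer products of the fixed-effect basis rows
  cube OPf(Kf, Kf, nday);
  for (int d = 0; d < nday; ++d) {
    OPf.slice(d) = Phi_f.row(d).t() * Phi_f.row(d);
  }

  // state
  vec b(KTf, arma::fill::zeros);
  mat U(n, KTg, arma::fill::zeros);
  mat P(n, std::max(KTp, 1), arma::fill::zeros);
  vec e = y;
  mat C = C0, Cinv = arma::inv_sympd(arma::symmatu(C0));
  mat D, Dinv;
  if (include_pe) { D = D0; Dinv = arma::inv_sympd(arma::symmatu(D0)); }
  cube R = R0;  // ntraits x ntraits x ndayr

  // storage
  const int ns = (niter - burnin) / thin;
  if (ns <= 0) stop("no retained iterations: check n_iter/burn_in/thin");
  cube C_draws(KTg, KTg, ns);
  cube D_draws(std::max(KTp, 1), std::max(KTp, 1), ns);
  mat R_draws(ntraits * ntraits * ndayr, ns);
  mat b_draws(store_b ? ns : 0, KTf);
  vec b_mean(KTf, arma::fill::zeros);
  mat U_mean(n, KTg, arma::fill::zeros);
  mat P_mean(n, std::max(KTp, 1), arma::fill::zeros);
  int stored = 0;

  cube RinvF(ntraits, ntraits, ndayr);  // inverse of the full day block
  mat Rmarg(ntraits, ndayr);            // marginal precisions 1/R(q,q)
  mat S(n, KTg);                        // Ginv * U, kept current in the sweep

  for (int iter = 1; iter <= niter; ++iter) {
    if (iter % 256 == 0) Rcpp::checkUserInterrupt();

    for (int d = 0; d < ndayr; ++d) {
      RinvF.slice(d) = arma::inv_sympd(arma::symmatu(R.slice(d)));
      for (int q = 0; q < ntraits; ++q) Rmarg(q, d) = 1.0 / R(q, q, d);
    }

    // per-pattern matrices for this iteration's D and R values
    for (auto& p : pats) {
      const int m = p.day.size();
      mat Ra(m, m, arma::fill::zeros);
      mat RaInv(m, m, arma::fill::zeros);
      for (int i = 0; i < m; ++i) {
        const int dr = het_residual ? p.day[i] : 0;
        Ra(i, i) = R(p.trait[i], p.trait[i], dr);
        bool paired = false;
        if (i + 1 < m && p.day[i + 1] == p.day[i]) {  // both traits this day
          Ra(i, i + 1) = Ra(i + 1, i) = R(0, 1, dr);
          paired = true;
        }
        if (i > 0 && p.day[i - 1] == p.day[i]) paired = true;
        if (paired) {
          if (p.trait[i] == 0) {  // fill the 2x2 inverse once, at the top row
            RaInv(i, i) = RinvF(0, 0, dr);
            RaInv(i, i + 1) = RaInv(i + 1, i) = RinvF(0, 1, dr);
            RaInv(i + 1, i + 1) = RinvF(1, 1, dr);
          }
        } else {
          RaInv(i, i) = Rmarg(p.trait[i], dr);
        }
      }
      if (include_pe) {
        mat V = Ra + p.Bp * D * p.Bp.t();
        mat Vinv = arma::inv_sympd(arma::symmatu(V));
        p.Tg = p.Bg.t() * Vinv;
        p.Ag = p.Tg * p.Bg;
        p.Tp = p.Bp.t() * RaInv;
        p.Ap = p.Tp * p.Bp;
      } else {
        p.Tg = p.Bg.t() * RaInv;
        p.Ag = p.Tg * p.Bg;
      }
    }

    // ---- fixed effects -------------------------------------------------
    {
      mat prec(KTf, KTf, arma::fill::zeros);
      vec rhs(KTf, arma::fill::zeros);
      for (int a = 0; a < n; ++a) {
        const auto& rows = acc_rows[a];
        if (rows.empty()) continue;
        const Pattern& p = pats[pat_of[a]];
        const int m = rows.size();
        for (int i = 0; i < m; ++i) {
          const int d = p.day[i], q = p.trait[i];
          const int dr = het_residual ? d : 0;
          const bool paired =
            (i + 1 < m && p.day[i + 1] == d) || (i > 0 && p.day[i - 1] == d);
          double w_i = e(rows[i]) +
            arma::dot(Phi_f.row(d), b.subvec(q * Kf, (q + 1) * Kf - 1));
          if (paired && ntraits == 2) {
            const int j = (q == 0) ? i + 1 : i - 1;  // partner row
            const int qj = p.trait[j];
            double w_j = e(rows[j]) +
              arma::dot(Phi_f.row(d), b.subvec(qj * Kf, (qj + 1) * Kf - 1));
            prec.submat(q * Kf, q * Kf, (q + 1) * Kf - 1, (q + 1) * Kf - 1) +=
              RinvF(q, q, dr) * OPf.slice(d);
            prec.submat(q * Kf, qj * Kf, (q + 1) * Kf - 1, (qj + 1) * Kf - 1) +=
              RinvF(q, qj, dr) * OPf.slice(d);
            rhs.subvec(q * Kf, (q + 1) * Kf - 1) +=
              (RinvF(q, q, dr) * w_i + RinvF(q, qj, dr) * w_j) * Phi_f.row(d).t();
          } else {
            prec.submat(q * Kf, q * Kf, (q + 1) * Kf - 1, (q + 1) * Kf - 1) +=
              Rmarg(q, dr) * OPf.slice(d);
            rhs.subvec(q * Kf, (q + 1) * Kf - 1) +=
              Rmarg(q, dr) * w_i * Phi_f.row(d).t();
          }
        }
      }
      vec b_new = sample_mvn_canonical(prec, rhs);
      for (int r = 0; r < nrec; ++r) {
        const int q = trt(r), d = dayi(r);
        e(r) -= arma::dot(Phi_f.row(d),
                          b_new.subvec(q * Kf, (q + 1) * Kf - 1) -
                          b.subvec(q * Kf, (q + 1) * Kf - 1));
      }
      b = b_new;
    }

    // ---- genetic coefficients, permanent environment marginalized ------
    S = Ginv * U;
    for (int a = 0; a < n; ++a) {
      const auto& rows = acc_rows[a];
      vec u_a = U.row(a).t();
      mat prec = Ginv(a, a) * Cinv;
      vec rhs = -(Cinv * (S.row(a).t() - Ginv(a, a) * u_a));
      if (!rows.empty()) {
        const Pattern& p = pats[pat_of[a]];
        const int m = rows.size();
        vec r(m);
        for (int i = 0; i < m; ++i) {  // record value minus fixed part only
          r(i) = e(rows[i]) + arma::dot(p.Bg.row(i), u_a);
          if (include_pe) r(i) += arma::dot(p.Bp.row(i), P.row(a));
        }
        prec += p.Ag;
        rhs += p.Tg * r;
      }
      vec u_new = sample_mvn_canonical(prec, rhs);
      vec du = u_new - u_a;
      if (!rows.empty()) {
        const Pattern& p = pats[pat_of[a]];
        for (size_t i = 0; i < rows.size(); ++i) {
          e(rows[i]) -= arma::dot(p.Bg.row(i), du);
        }
      }
      U.row(a) = u_new.t();
      S += Ginv.col(a) * du.t();
    }

    // ---- permanent environment | u -------------------------------------
    if (include_pe) {
      for (int a = 0; a < n; ++a) {
        const auto& rows = acc_rows[a];
        vec p_a = P.row(a).t();
        mat prec = Dinv;
        vec rhs(KTp, arma::fill::zeros);
        if (!rows.empty()) {
          const Pattern& p = pats[pat_of[a]];
          const int m = rows.size();
          vec r(m);
          for (int i = 0; i < m; ++i) {
            r(i) = e(rows[i]) + arma::dot(p.Bp.row(i), p_a);
          }
          prec += p.Ap;
          rhs += p.Tp * r;
        }
        vec p_new = sample_mvn_canonical(prec, rhs);
        vec dp = p_new - p_a;
        if (!rows.empty()) {
          const Pattern& p = pats[pat_of[a]];
          for (size_t i = 0; i < rows.size(); ++i) {
            e(rows[i]) -= arma::dot(p.Bp.row(i), dp);
          }
        }
        P.row(a) = p_new.t();
      }
    }

    // ---- coefficient covariance matrices -------------------------------
    if (update_c) {
      mat scale = S_c + arma::symmatu(U.t() * (Ginv * U));
      C = rinvwishart(nu_c + n, scale);
      Cinv = arma::inv_sympd(arma::symmatu(C));
    }
    if (include_pe && update_d) {
      mat scale = S_d + arma::symmatu(P.t() * P);
      D = rinvwishart(nu_d + n, scale);
      Dinv = arma::inv_sympd(arma::symmatu(D));
    }

    // ---- residual blocks ------------------------------------------------
    if (update_r) {
      for (int dr = 0; dr < ndayr; ++dr) {
        mat Spair(ntraits, ntraits, arma::fill::zeros);
        int npair = 0;
        vec sse(ntraits, arma::fill::zeros);
        arma::ivec msolo(ntraits, arma::fill::zeros);
        const int d_lo = het_residual ? dr : 0;
        const int d_hi = het_residual ? dr : nday - 1;
        for (int d = d_lo; d <= d_hi; ++d) {
          for (int a = 0; a < n; ++a) {
            int r0 = cell_rec[((size_t)a * nday + d) * ntraits + 0];
            int r1 = ntraits == 2 ?
              cell_rec[((size_t)a * nday + d) * ntraits + 1] : -1;
            if (ntraits == 2 && r0 >= 0 && r1 >= 0) {
              vec ee = {e(r0), e(r1)};
              Spair += ee * ee.t();
              ++npair;
            } else {
              if (r0 >= 0) { sse(0) += e(r0) * e(r0); ++msolo(0); }
              if (r1 >= 0) { sse(1) += e(r1) * e(r1); ++msolo(1); }
            }
          }
        }
        if (ntraits == 2 && npair > 0) {
          R.slice(dr) = rinvwishart(nu_r + npair, S_r + Spair);
        } else {
          for (int q = 0; q < ntraits; ++q) {
            if (msolo(q) > 0) {
              R(q, q, dr) = (S_r(q, q) + sse(q)) / R::rchisq(nu_r + msolo(q));
            }
          }
          if (ntraits == 2) { R(0, 1, dr) = 0.0; R(1, 0, dr) = 0.0; }
        }
      }
    }

    // ---- store ----------------------------------------------------------
    if (iter > burnin && (iter - burnin) % thin == 0 && stored < ns) {
      C_draws.slice(stored) = C;
      if (include_pe) D_draws.slice(stored) = D;
      R_draws.col(stored) = arma::vectorise(R);
      if (store_b) b_draws.row(stored) = b.t();
      b_mean += b;
      U_mean += U;
      if (include_pe) P_mean += P;
      ++stored;
    }
  }

  b_mean /= stored;
  U_mean /= stored;
  if (include_pe) P_mean /= stored;

  return List::create(
    _["C"] = C_draws, _["D"] = D_draws, _["R"] = R_draws,
    _["b_draws"] = b_draws,
    _["b_mean"] = b_mean, _["U_mean"] = U_mean, _["P_mean"] = P_mean,
    _["n_stored"] = stored);
}
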