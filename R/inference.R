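# Variance-component estimation (Gibbs) and MME solving at fixed variances.

#' Configuration for the Gibbs sampler
#'
#' Priors are the standard conjugate choices: flat for fixed effects,
#' inverse-Wishart for the coefficient covariance matrices `C` and `D`
#' (default degrees of freedom `dim + 2`, scale a small multiple of the
#' per-trait phenotypic variance on the matching diagonal blocks), and
#' inverse-Wishart / scaled inverse chi-square for the per-day residual
#' blocks. Defaults are weakly informative; with hundreds of accessions the
#' data term dominates the scale matrix by several orders of magnitude.
#'
#' @param n_iter,burn_in,thin chain controls (defaults 30000 / 10000 / 10).
#' @param seed integer seed applied with `set.seed()` before sampling; `NULL`
#'   leaves the RNG state untouched.
#' @param priors optional list with elements `nu_c`, `S_c`, `nu_d`, `S_d`,
#'   `nu_r`, `S_r`; missing pieces get the data-scaled defaults.
#' @param fixed_variances optional [cov_components()]; when supplied, variance
#'   sampling is disabled and every retained draw equals these components
#'   exactly (the "fixed variance option"): only locations are sampled.
#' @param store_b keep the retained draws of the fixed coefficients (for
#'   chain diagnostics).
#' @return object of class `gibbs_config`.
#' @export
gibbs_config <- function(n_iter = 30000, burn_in = 10000, thin = 10,
                         seed = NULL, priors = NULL, fixed_variances = NULL,
                         store_b = FALSE) {
  stopifnot(burn_in < n_iter, thin >= 1)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = seed, priors = priors,
                 fixed_variances = fixed_variances, store_b = store_b),
            class = "gibbs_config")
}

# Data-scaled default priors and starting values. The scale unit per trait
# is the within-day phenotypic variance (averaged over days), i.e. the trait
# variance with the mean trajectory removed; prior scales then partition it
# 10% genetic / 2.5% permanent environment / 30% residual, a
# weakly-informative assignment in the style of Bayesian genomic regression
# software (the PE share is kept small: in a controlled greenhouse with
# daily re-watering the persistent non-genetic component is modest).
# C and R use df = dim + 2 (vague); D uses df = dim + 10 with the scale
# matched so its prior mean stays at the 2.5% share: when kinship separates
# the genetic and permanent-environment terms only weakly, a vague D prior
# lets chains settle in a degenerate mode where one term absorbs the other,
# and the moderate concentration tips that balance without overriding
# identified data. With a few hundred accessions the likelihood dominates
# wherever the data identify a component.
.gibbs_defaults <- function(model, priors) {
  spec <- model$spec
  nt <- spec$n_traits
  vq <- vapply(seq_len(nt), function(q) {
    sel <- model$rec$trait == q
    v <- tapply(model$y[sel], model$rec$dayi[sel], var)
    v <- mean(v[is.finite(v)])
    if (!is.finite(v) || v <= 0) 1 else v
  }, numeric(1))
  rep_block <- function(K) rep(vq, each = K)
  out <- list(
    nu_c = nt * model$Kg + 2,
    S_c = diag(0.10 * rep_block(model$Kg), nt * model$Kg),
    nu_d = nt * model$Kp + 10,
    S_d = diag(0.025 * rep_block(model$Kp) * 9, nt * model$Kp),
    nu_r = nt + 2,
    S_r = diag(0.30 * vq, nt),
    vq = vq
  )
  if (!is.null(priors)) out[names(priors)] <- priors
  out
}

#' Gibbs sampling of a random regression model
#'
#' Cycles between (1) the multivariate-normal full conditionals of the
#' location effects (fixed coefficients jointly, then per-accession blocks of
#' genetic and permanent-environment coefficients), (2) an inverse-Wishart
#' draw of `C` with scale `U' G^-1 U`, (3) likewise for `D` with `P'P`, and
#' (4) each day's residual block from its conjugate conditional (full block
#' from complete trait pairs; per-trait scaled inverse chi-square when only
#' one trait is observed that day, with the cross term held at zero).
#' Convergence is not auto-detected; see [ess()] for a simple effective
#' sample size diagnostic on the returned draws.
#'
#' @param model an [rrm_model][build_design()]; its `G` must be invertible
#'   (apply [add_ridge()] before [build_design()]).
#' @param config a [gibbs_config()].
#' @return object of class `rrm_draws`: arrays `C` (`KT x KT x n_stored`),
#'   `D`, `R` (`n_traits x n_traits x n_days x n_stored`), posterior means of
#'   the locations, and the configuration used.
#' @export
gibbs_rrm <- function(model, config = gibbs_config()) {
  stopifnot(inherits(model, "rrm_model"), inherits(config, "gibbs_config"))
  spec <- model$spec
  nt <- spec$n_traits
  if (!is.null(config$seed)) set.seed(config$seed)

  if (rcond(model$G) < 1e-7) {
    warning("G is near-singular; Gibbs location updates mix poorly on such ",
            "a matrix - consider blend_grm() before build_design()")
  }

  pri <- .gibbs_defaults(model, config$priors)
  ndayr <- if (spec$het_residual) model$nday else 1L

  fixed <- config$fixed_variances
  if (!is.null(fixed)) {
    C0 <- fixed$C
    D0 <- if (spec$include_pe) fixed$D else diag(1)
    R0 <- fixed$R
    if (dim(R0)[3] == 1L && ndayr > 1L) {
      R0 <- array(R0, dim = c(nt, nt, ndayr))
    }
    if (dim(R0)[3] != ndayr) stop("fixed R has wrong number of day blocks")
    upd <- c(FALSE, FALSE, FALSE)
  } else {
    vq <- pri$vq
    if (is.null(vq)) vq <- rep(1, nt)
    C0 <- diag(0.3 * rep(vq, each = model$Kg), nt * model$Kg)
    D0 <- diag(0.1 * rep(vq, each = model$Kp), nt * model$Kp)
    R0 <- array(diag(0.5 * vq, nt), dim = c(nt, nt, ndayr))
    upd <- c(TRUE, TRUE, TRUE)
  }

  Ginv <- chol2inv(chol(model$G))
  phi <- model$basis$phi
  res <- .gibbs_rrm_cpp(
    y = model$y,
    acc = model$rec$acc - 1L, trt = model$rec$trait - 1L,
    dayi = model$rec$dayi - 1L,
    Phi_f = phi[, 1:model$Kf, drop = FALSE],
    Phi_g = phi[, 1:model$Kg, drop = FALSE],
    Phi_p = phi[, 1:model$Kp, drop = FALSE],
    Ginv = Ginv, n = model$n, ntraits = nt, nday = model$nday,
    het_residual = spec$het_residual, include_pe = spec$include_pe,
    niter = config$n_iter, burnin = config$burn_in, thin = config$thin,
    nu_c = pri$nu_c, S_c = pri$S_c, nu_d = pri$nu_d, S_d = pri$S_d,
    nu_r = pri$nu_r, S_r = pri$S_r,
    C0 = C0, D0 = D0, R0 = R0,
    update_c = upd[1], update_d = upd[2], update_r = upd[3],
    store_b = config$store_b)

  ns <- res$n_stored
  R_draws <- array(res$R, dim = c(nt, nt, ndayr, ns))
  structure(list(
    C = res$C, D = if (spec$include_pe) res$D,
    R = R_draws,
    b_draws = if (config$store_b) res$b_draws,
    b_mean = res$b_mean, U_mean = res$U_mean,
    P_mean = if (spec$include_pe) res$P_mean,
    n_stored = ns, spec = spec, days = model$basis$grid$days,
    accession_ids = model$accession_ids, config = config),
    class = "rrm_draws")
}

#' Posterior-mean variance components from Gibbs draws
#'
#' @param draws an [rrm_draws][gibbs_rrm()].
#' @return a [cov_components()] of posterior means.
#' @export
posterior_means <- function(draws) {
  stopifnot(inherits(draws, "rrm_draws"))
  Cm <- apply(draws$C, c(1, 2), mean)
  Dm <- if (!is.null(draws$D)) apply(draws$D, c(1, 2), mean)
  Rm <- apply(draws$R, c(1, 2, 3), mean)
  days <- if (dim(Rm)[3] == length(draws$days)) draws$days
  cov_components(Cm, Dm, Rm, days = days)
}

#' Posterior-mean location solutions from Gibbs draws
#'
#' @param draws an [rrm_draws][gibbs_rrm()].
#' @return an `rrm_solutions` object (see [solve_mme()]).
#' @export
posterior_solutions <- function(draws) {
  stopifnot(inherits(draws, "rrm_draws"))
  spec <- draws$spec
  nt <- spec$n_traits
  Kf <- length(draws$b_mean) / nt
  .as_solutions(draws$b_mean, draws$U_mean, draws$P_mean,
                nt, Kf, ncol(draws$U_mean) / nt,
                if (!is.null(draws$P_mean)) ncol(draws$P_mean) / nt else 0,
                draws$accession_ids, spec$traits)
}

# Shape flat location vectors/matrices into the solutions container.
.as_solutions <- function(b, U, P, nt, Kf, Kg, Kp, ids, traits) {
  bmat <- matrix(b, ncol = nt)
  colnames(bmat) <- traits
  u <- array(U, dim = c(length(ids), Kg, nt),
             dimnames = list(ids, NULL, traits))
  p <- if (!is.null(P)) {
    array(P, dim = c(length(ids), Kp, nt), dimnames = list(ids, NULL, traits))
  }
  structure(list(b = bmat, u = u, p = p), class = "rrm_solutions")
}

#' Effective sample size of a chain
#'
#' Initial positive sequence estimator from the empirical autocorrelations.
#'
#' @param x numeric vector of draws.
#' @return estimated effective sample size.
#' @export
ess <- function(x) {
  n <- length(x)
  if (n < 4 || sd(x) == 0) return(n)
  rho <- acf(x, lag.max = min(n - 2, 200), plot = FALSE)$acf[-1]
  s <- 0
  for (k in seq(1, length(rho) - 1, by = 2)) {
    g <- rho[k] + rho[k + 1]
    if (is.na(g) || g <= 0) break
    s <- s + g
  }
  n / (1 + 2 * s)
}

#' Solve Henderson's mixed model equations at fixed variances
#'
#' Builds and solves the MME for an assembled random regression model with
#' `Var(u) = C %x% G`, `Var(p) = D %x% I` and the day-specific residual
#' structure. The solution is verified against the residual identity
#' `||LHS sol - RHS|| <= tol * ||RHS||`.
#'
#' @param model an [rrm_model][build_design()].
#' @param comps a [cov_components()]; `C`, `D` and every residual block must
#'   be positive definite.
#' @param tol relative tolerance for the residual identity check.
#' @return object of class `rrm_solutions` with elements `b` (matrix,
#'   coefficients x traits), `u` and `p` (arrays accessions x coefficients x
#'   traits); the relative residual is attached as attribute `"resid"`.
#' @export
solve_mme <- function(model, comps, tol = 1e-8) {
  stopifnot(inherits(model, "rrm_model"), inherits(comps, "cov_components"))
  spec <- model$spec
  nt <- spec$n_traits
  KTg <- nt * model$Kg

  Rinv <- .residual_matrix(model, comps$R, inverse = TRUE)
  W <- if (spec$include_pe) cbind(model$X, model$Z, model$Q)
       else cbind(model$X, model$Z)
  WtRi <- crossprod(W, Rinv)
  LHS <- as.matrix(WtRi %*% W)
  RHS <- as.numeric(WtRi %*% model$y)

  Ginv <- chol2inv(chol(model$G))
  nb <- ncol(model$X)
  iu <- nb + seq_len(KTg * model$n)
  LHS[iu, iu] <- LHS[iu, iu] + chol2inv(chol(comps$C)) %x% Ginv
  if (spec$include_pe) {
    KTp <- nt * model$Kp
    ip <- nb + KTg * model$n + seq_len(KTp * model$n)
    Dinv <- chol2inv(chol(comps$D))
    LHS[ip, ip] <- LHS[ip, ip] + Dinv %x% diag(model$n)
  }

  ch <- tryCatch(chol(LHS), error = function(e) {
    stop("singular mixed-model equations: ", conditionMessage(e))
  })
  sol <- backsolve(ch, forwardsolve(t(ch), RHS))
  rel <- sqrt(sum((LHS %*% sol - RHS)^2)) / max(sqrt(sum(RHS^2)), 1e-300)
  if (rel > tol) {
    warning(sprintf("MME residual %.3e exceeds tol %.3e", rel, tol))
  }

  b <- sol[seq_len(nb)]
  u <- sol[iu]
  p <- if (spec$include_pe) sol[nb + KTg * model$n + seq_len(nt * model$Kp * model$n)]
  out <- .as_solutions(b, matrix(u, nrow = model$n),
                       if (!is.null(p)) matrix(p, nrow = model$n),
                       nt, model$Kf, model$Kg, model$Kp,
                       model$accession_ids, spec$traits)
  attr(out, "resid") <- rel
  out
}

#' Genetic-value trajectories from solved coefficients
#'
#' The genetic value of accession `j`, trait `q` at day `t` is
#' `phi(t) . u[j, , q]`.
#'
#' @param sols an `rrm_solutions` object.
#' @param basis the [legendre_basis()] used in the fit.
#' @param trait trait label or index (default first trait).
#' @param days days at which to evaluate (default: the basis grid). Days off
#'   the grid are evaluated through [eval_basis()] (extrapolation).
#' @return accessions x days matrix.
#' @export
genetic_values <- function(sols, basis, trait = 1, days = NULL) {
  U <- .trait_coef(sols$u, trait)
  if (is.null(days)) days <- basis$grid$days
  phi <- eval_basis(basis, days)[, seq_len(ncol(U)), drop = FALSE]
  out <- U %*% t(phi)
  colnames(out) <- as.character(days)
  out
}

.trait_coef <- function(u, trait) {
  if (is.character(trait)) {
    trait <- match(trait, dimnames(u)[[3]])
    if (is.na(trait)) stop("unknown trait")
  }
  u[, , trait, drop = FALSE][, , 1]
}

#' Predict genetic values of unphenotyped accessions
#'
#' Projects training genetic values through the genomic relationship matrix:
#' `a_tst(t) = G[tst, trn] G[trn, trn]^-1 a_trn(t)` with
#' `a_trn(t) = Phi u_trn`. At fixed variances this equals the joint-MME BLUP
#' of accessions carried in the model with zero phenotype rows.
#'
#' @param grm relationship matrix covering both sets (the same, already
#'   stabilized matrix used in the fit).
#' @param train_ids,test_ids disjoint accession id sets present in `grm`.
#' @param sols `rrm_solutions` from a fit on the training accessions.
#' @param basis the [legendre_basis()] of the fit.
#' @param trait trait label or index (default first).
#' @param days evaluation days (default: basis grid).
#' @return test accessions x days matrix of predicted genetic values.
#' @export
predict_unphenotyped <- function(grm, train_ids, test_ids, sols, basis,
                                 trait = 1, days = NULL) {
  train_ids <- as.character(train_ids)
  test_ids <- as.character(test_ids)
  if (length(intersect(train_ids, test_ids)) > 0) {
    stop("train and test sets overlap")
  }
  if (!all(c(train_ids, test_ids) %in% rownames(grm))) {
    stop("ids missing from the relationship matrix")
  }
  a_trn <- genetic_values(sols, basis, trait = trait, days = days)
  a_trn <- a_trn[train_ids, , drop = FALSE]
  G11 <- grm[train_ids, train_ids]
  G21 <- grm[test_ids, train_ids, drop = FALSE]
  out <- G21 %*% solve(G11, a_trn)
  rownames(out) <- test_ids
  out
}
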