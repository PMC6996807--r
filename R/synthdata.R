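# Synthetic genotypes and bivariate longitudinal phenotypes with the
# statistical structure the random regression analysis assumes.

# Default coefficient covariance construction: a shared genetic trajectory
# factor f(x) = alpha + beta x (variance growing over time) plus trait-
# specific intercept-level variance and a small isotropic jitter that keeps
# every matrix comfortably positive definite. With these shapes the implied
# genomic correlation rises over the imaging period and the first trait is
# consistently less heritable than the second, the regime of a greenhouse
# water-use / shoot-area experiment.
.default_truth <- function(n_days = 20) {
  alpha <- 0.68; beta <- 0.32          # shared factor in the phi basis
  e1 <- 0.167; e2 <- 0.167             # trait-specific intercept genetic var
  jg <- 0.015                          # genetic jitter
  d1 <- 0.03; d2 <- 0.025; jd <- 0.005 # permanent environment levels: a
  # modest share of phenotypic variance (pot-level micro-environment); with
  # unstructured synthetic kinship the genetic / permanent-environment split
  # is only weakly identified, so the emulated regime keeps the persistent
  # non-genetic term small and carries day-to-day noise in the residual
  rho_pe <- 0.3                        # PE intercept correlation
  v1 <- seq(0.93, 0.66, length.out = n_days)  # residual shapes
  v2 <- seq(0.36, 0.30, length.out = n_days)
  rho_e <- 0.3                         # residual correlation
  s1 <- 0.004                          # WU scale, kg^2
  s2 <- 0.35                           # PSA scale, (1e5 px)^2

  w <- c(alpha, beta / sqrt(3), 0)   # f expressed in the scaled basis
  A <- tcrossprod(w)
  e0 <- c(1, 0, 0)
  E0 <- tcrossprod(e0)
  I3 <- diag(3)

  C1 <- s1 * (A + e1 * E0 + jg * I3)
  C2 <- s2 * (A + e2 * E0 + jg * I3)
  C12 <- sqrt(s1 * s2) * A
  C <- rbind(cbind(C1, C12), cbind(t(C12), C2))

  D1 <- s1 * (d1 * E0 + jd * I3)
  D2 <- s2 * (d2 * E0 + jd * I3)
  D12 <- sqrt(s1 * s2) * rho_pe * sqrt(d1 * d2) * E0
  D <- rbind(cbind(D1, D12), cbind(t(D12), D2))

  R <- array(0, dim = c(2, 2, n_days))
  for (t in seq_len(n_days)) {
    ve1 <- s1 * v1[t]
    ve2 <- s2 * v2[t]
    R[, , t] <- matrix(c(ve1, rho_e * sqrt(ve1 * ve2),
                         rho_e * sqrt(ve1 * ve2), ve2), 2, 2)
  }
  list(C = C, D = D, R = R)
}

# Upper Cholesky factor tolerating positive semi-definite (even zero) input.
.chol_upper <- function(M) {
  M <- as.matrix(M)
  if (max(abs(M)) == 0) return(matrix(0, nrow(M), ncol(M)))
  tryCatch(chol(M),
           error = function(e) chol(M + diag(1e-10 * max(diag(M)), nrow(M))))
}

# Exponential mean trajectories projected on the quadratic basis.
.default_mean_coefs <- function(basis) {
  t <- basis$grid$days
  m <- cbind(WU = 0.04 * exp(0.107 * t), PSA = 0.15 * exp(0.145 * t))
  solve(crossprod(basis$phi), crossprod(basis$phi, m))
}

#' Configuration of the synthetic bivariate longitudinal dataset
#'
#' Defaults emulate a rice greenhouse experiment: 357 accessions imaged daily
#' for 20 days for water use (WU, kg/day) and projected shoot area (PSA,
#' 1e5-pixel units), with exponential-like mean trajectories, WU less
#' heritable than PSA, and a genomic correlation that rises over the imaging
#' period towards roughly 0.8.
#'
#' @param n_accessions,n_markers,n_days design sizes (defaults 357 / 2000 /
#'   20; markers are kept moderate because GRM properties stabilize beyond a
#'   few hundred markers).
#' @param maf_range allele frequencies are drawn uniformly from this range.
#' @param traits trait labels.
#' @param mean_coefs `(order+1) x n_traits` matrix of mean-curve coefficients
#'   in the Legendre basis; `NULL` projects the documented exponential curves.
#' @param mean_form `"legendre"` (true mean exactly representable by the
#'   fixed regression, default) or `"exponential"` (misspecified truth for
#'   robustness checks).
#' @param C,D true 6x6 coefficient covariance matrices (trait-major);
#'   `NULL` uses the documented defaults.
#' @param R true per-day 2x2 residual blocks; `NULL` uses the defaults.
#' @param blend identity weight used to stabilize the simulated GRM (see
#'   [blend_grm()]); the blended matrix is both the generative covariance and
#'   the matrix returned for analysis, so simulation and fitting agree.
#' @param seed master seed used by [simulate_dataset()].
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_accessions = 357, n_markers = 2000, n_days = 20,
                         maf_range = c(0.05, 0.5), traits = c("WU", "PSA"),
                         mean_coefs = NULL,
                         mean_form = c("legendre", "exponential"),
                         C = NULL, D = NULL, R = NULL,
                         blend = 0.05, seed = NULL) {
  mean_form <- match.arg(mean_form)
  stopifnot(length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2])
  truth <- .default_truth(n_days)
  if (is.null(C)) C <- truth$C
  if (is.null(D)) D <- truth$D
  if (is.null(R)) R <- truth$R
  if (is.matrix(R)) R <- array(R, dim = c(nrow(R), ncol(R), n_days))
  structure(list(n_accessions = n_accessions, n_markers = n_markers,
                 n_days = n_days, maf_range = maf_range, traits = traits,
                 mean_coefs = mean_coefs, mean_form = mean_form,
                 C = C, D = D, R = R, blend = blend, seed = seed),
            class = "synth_config")
}

#' Simulate SNP genotypes
#'
#' Per marker, an allele frequency is drawn uniformly from `maf_range` and
#' dosages are Binomial(2, p) independently per accession
#' (Hardy-Weinberg, no LD, complete calls).
#'
#' @param cfg a [synth_config()].
#' @return a [genotype_matrix()].
#' @export
simulate_genotypes <- function(cfg) {
  n <- cfg$n_accessions
  m <- cfg$n_markers
  p <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
  d <- matrix(rbinom(n * m, 2L, rep(p, each = n)), nrow = n)
  genotype_matrix(d,
                  accession_ids = sprintf("ACC%04d", seq_len(n)),
                  marker_ids = sprintf("M%05d", seq_len(m)))
}

#' Simulate bivariate longitudinal phenotypes from the generative RRM
#'
#' Draws genetic coefficients `u ~ N(0, C (x) G)` (via the Cholesky factors
#' of both matrices), permanent-environment coefficients `p ~ N(0, D (x) I)`,
#' and per-day residual pairs `e ~ N(0, R(t))`; the phenotype of accession
#' `j`, trait `q` at day `t` is `mean_q(t) + phi(t) u + phi(t) p + e`.
#'
#' @param geno a [genotype_matrix()] (complete).
#' @param cfg a [synth_config()].
#' @param basis a [legendre_basis()] over `1:n_days`; `NULL` builds the
#'   default quadratic basis.
#' @param grm optionally, a precomputed (already stabilized) GRM for `geno`.
#' @return list with elements `phenos` (long-format data.frame), `truth`
#'   (true coefficients, per-day genetic values, heritability and genomic
#'   correlation trajectories), `grm`, and `basis`.
#' @export
simulate_traits <- function(geno, cfg, basis = NULL, grm = NULL) {
  nt <- length(cfg$traits)
  if (is.null(basis)) basis <- legendre_basis(time_grid(seq_len(cfg$n_days)), 2)
  if (is.null(grm)) {
    # markers can realize with zero dosage variance in small samples; they
    # carry no relationship information and are dropped
    d <- .geno_unclass(geno)
    mono <- colMeans(d^2) - colMeans(d)^2 <= 0
    if (any(mono)) {
      geno <- genotype_matrix(.geno_unclass(geno)[, !mono, drop = FALSE])
    }
    grm <- blend_grm(compute_grm(geno), cfg$blend)
  }
  n <- nrow(grm)
  K <- ncol(basis$phi)
  days <- basis$grid$days
  nday <- length(days)
  stopifnot(nrow(cfg$C) == nt * K, dim(cfg$R)[3] == nday)

  Lg <- t(chol(grm))
  U <- Lg %*% matrix(rnorm(n * nt * K), n) %*% .chol_upper(cfg$C)
  P <- matrix(rnorm(n * nt * K), n) %*% .chol_upper(cfg$D)

  mean_coefs <- cfg$mean_coefs
  if (is.null(mean_coefs)) mean_coefs <- .default_mean_coefs(basis)
  mu <- basis$phi %*% mean_coefs  # nday x nt
  if (cfg$mean_form == "exponential") {
    mu <- cbind(0.04 * exp(0.107 * days), 0.15 * exp(0.145 * days))
  }

  gv <- array(0, dim = c(n, nday, nt),
              dimnames = list(rownames(grm), as.character(days), cfg$traits))
  pv <- array(0, dim = c(n, nday, nt))
  for (q in seq_len(nt)) {
    sel <- (q - 1) * K + 1:K
    gv[, , q] <- U[, sel] %*% t(basis$phi)
    pv[, , q] <- P[, sel] %*% t(basis$phi)
  }

  recs <- vector("list", nday)
  for (t in seq_len(nday)) {
    E <- matrix(rnorm(n * nt), n) %*% .chol_upper(cfg$R[, , t, drop = TRUE])
    vals <- lapply(seq_len(nt), function(q) {
      mu[t, q] + gv[, t, q] + pv[, t, q] + E[, q]
    })
    recs[[t]] <- data.frame(
      accession = rep(rownames(grm), nt),
      trait = rep(cfg$traits, each = n),
      day = days[t],
      value = unlist(vals))
  }
  phenos <- do.call(rbind, recs)
  rownames(phenos) <- NULL

  comps <- cov_components(cfg$C, cfg$D, cfg$R, days = days)
  h2 <- vapply(seq_len(nt), function(q) heritability(comps, basis, q),
               numeric(nday))
  truth <- list(U = U, P = P, genetic_values = gv,
                h2 = t(h2),
                rg = if (nt == 2) genomic_correlation(comps, basis),
                C = cfg$C, D = cfg$D, R = cfg$R, mean_coefs = mean_coefs)
  list(phenos = phenos, truth = truth, grm = grm, basis = basis)
}

#' Simulate a complete synthetic study
#'
#' Genotypes, GRM, basis and phenotypes in one call, seeded by
#' `cfg$seed` (when set).
#'
#' @param cfg a [synth_config()].
#' @return list with `geno`, `grm`, `basis`, `phenos`, `truth`, `config`.
#' @export
simulate_dataset <- function(cfg = synth_config()) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  geno <- simulate_genotypes(cfg)
  sim <- simulate_traits(geno, cfg)
  c(list(geno = geno, config = cfg), sim)
}
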