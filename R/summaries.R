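# Per-day genetic summaries from coefficient covariance matrices.

# Quadratic forms phi(t) A phi(t)' for every basis row.
.qform_days <- function(phi, A) {
  rowSums((phi %*% A) * phi)
}

# Trait blocks of a trait-major bivariate coefficient covariance matrix.
.trait_blocks <- function(M, K) {
  list(b1 = M[1:K, 1:K, drop = FALSE],
       b12 = M[1:K, K + 1:K, drop = FALSE],
       b2 = M[K + 1:K, K + 1:K, drop = FALSE])
}

#' Genomic correlation trajectory between two traits
#'
#' For each day `t` with basis row `t_i`, returns
#' `t_i C12 t_i' / sqrt((t_i C1 t_i') (t_i C2 t_i'))`, the correlation of the
#' two traits' additive genetic values at that day implied by the coefficient
#' covariance matrix.
#'
#' @param comps bivariate [cov_components()].
#' @param basis the [legendre_basis()] of the fit.
#' @return numeric vector of per-day correlations, named by day. Days where
#'   either trait has zero genetic variance are `NA`.
#' @export
genomic_correlation <- function(comps, basis) {
  K <- nrow(comps$C) / 2
  if (K != round(K)) stop("genomic_correlation needs a bivariate C")
  phi <- basis$phi[, 1:K, drop = FALSE]
  bl <- .trait_blocks(comps$C, K)
  g1 <- .qform_days(phi, bl$b1)
  g2 <- .qform_days(phi, bl$b2)
  g12 <- rowSums((phi %*% bl$b12) * phi)
  rg <- rep(NA_real_, length(g1))
  ok <- g1 > 0 & g2 > 0
  rg[ok] <- g12[ok] / sqrt(g1[ok] * g2[ok])
  over <- which(abs(rg) > 1)
  if (length(over)) {
    if (max(abs(rg[over])) - 1 > 1e-10) {
      stop("genomic correlation exceeds 1 beyond numerical tolerance")
    }
    rg[over] <- sign(rg[over])
  }
  names(rg) <- rownames(basis$phi)
  rg
}

#' Narrow-sense heritability trajectory
#'
#' `h2(t) = g(t) / (g(t) + pe(t) + ve(t))` with genetic variance
#' `g(t) = t_i C_q t_i'`, permanent-environment variance
#' `pe(t) = t_i D_q t_i'` and the day's residual variance `ve(t)`. Set
#' `include_pe = FALSE` to drop the permanent-environment variance from the
#' denominator (this changes levels, not shapes).
#'
#' @param comps [cov_components()] (single- or multi-trait).
#' @param basis the [legendre_basis()] of the fit.
#' @param trait trait index (1 or 2) within the components.
#' @param include_pe include `pe(t)` in the denominator (default TRUE).
#' @return numeric vector of per-day heritabilities, named by day.
#' @export
heritability <- function(comps, basis, trait = 1, include_pe = TRUE) {
  nt <- dim(comps$R)[1]
  if (trait > nt) stop("trait index exceeds number of traits")
  K <- nrow(comps$C) / nt
  phi <- basis$phi[, 1:K, drop = FALSE]
  sel <- (trait - 1) * K + 1:K
  g <- .qform_days(phi, comps$C[sel, sel, drop = FALSE])
  pe <- 0
  if (include_pe && !is.null(comps$D)) {
    Kp <- nrow(comps$D) / nt
    selp <- (trait - 1) * Kp + 1:Kp
    pe <- .qform_days(basis$phi[, 1:Kp, drop = FALSE],
                      comps$D[selp, selp, drop = FALSE])
  }
  nday <- nrow(phi)
  ve <- vapply(seq_len(nday), function(t) .r_day(comps$R, t)[trait, trait],
               numeric(1))
  denom <- g + pe + ve
  if (any(denom <= 0)) stop("non-positive phenotypic variance at some day")
  h2 <- g / denom
  names(h2) <- rownames(basis$phi)
  h2
}

#' Per-day trajectory summary table
#'
#' @param comps [cov_components()].
#' @param basis the [legendre_basis()] of the fit.
#' @param traits optional trait labels for the output columns.
#' @param include_pe passed to [heritability()].
#' @return data.frame with one row per day: heritability per trait and, for
#'   bivariate components, the genomic correlation.
#' @export
trajectory_summary <- function(comps, basis, traits = NULL, include_pe = TRUE) {
  nt <- dim(comps$R)[1]
  if (is.null(traits)) traits <- paste0("trait", seq_len(nt))
  out <- data.frame(day = basis$grid$days)
  for (q in seq_len(nt)) {
    out[[paste0("h2_", traits[q])]] <-
      as.numeric(heritability(comps, basis, trait = q, include_pe = include_pe))
  }
  if (nt == 2) out$rg <- as.numeric(genomic_correlation(comps, basis))
  out
}
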