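# Assembly of single- and multi-trait random regression designs.

#' Specification of a random regression model
#'
#' @param traits character vector of one or two trait labels, e.g.
#'   `c("WU", "PSA")`. Trait order fixes the block order of all stacked
#'   vectors and coefficient covariance matrices.
#' @param fixed_order,genetic_order,pe_order Legendre degrees of the fixed
#'   mean trajectory, the additive-genetic regression and the
#'   permanent-environment regression (all quadratic by default).
#' @param include_pe model a permanent-environment term (default TRUE; only
#'   meaningful to disable for single-record-per-accession designs).
#' @param het_residual one residual (co)variance block per day (default TRUE);
#'   if FALSE a single block is shared by all days.
#' @return object of class `rrm_spec`.
#' @export
rrm_spec <- function(traits, fixed_order = 2, genetic_order = 2, pe_order = 2,
                     include_pe = TRUE, het_residual = TRUE) {
  traits <- as.character(traits)
  if (!(length(traits) %in% 1:2)) stop("one or two traits are supported")
  if (anyDuplicated(traits)) stop("duplicate trait labels")
  stopifnot(fixed_order >= 0, genetic_order >= 0, pe_order >= 0)
  structure(list(traits = traits, n_traits = length(traits),
                 fixed_order = fixed_order, genetic_order = genetic_order,
                 pe_order = pe_order, include_pe = include_pe,
                 het_residual = het_residual),
            class = "rrm_spec")
}

#' Coefficient and residual (co)variance components
#'
#' `C` and `D` are the additive-genetic and permanent-environment coefficient
#' covariance matrices, of size `n_traits * (order + 1)`, laid out trait-major:
#' for two traits `C = rbind(cbind(C1, C12), cbind(t(C12), C2))`. `R` holds
#' one `n_traits` x `n_traits` residual block per day.
#'
#' @param C,D symmetric positive semi-definite matrices (`D = NULL` when the
#'   model has no permanent-environment term).
#' @param R a single residual block (recycled over days), a list of per-day
#'   blocks, or an `n_traits x n_traits x n_days` array.
#' @param days optional day labels for `R`.
#' @return object of class `cov_components` with `R` normalized to a 3-d array.
#' @export
cov_components <- function(C, D, R, days = NULL) {
  C <- as.matrix(C)
  .check_sym(C, "C")
  if (!is.null(D)) {
    D <- as.matrix(D)
    .check_sym(D, "D")
  }
  if (is.list(R)) R <- simplify2array(lapply(R, as.matrix))
  if (is.matrix(R) || length(R) == 1) {
    R <- as.matrix(R)
    R <- array(R, dim = c(nrow(R), ncol(R), 1L))
  }
  if (length(dim(R)) != 3) stop("R must be a matrix, list or 3-d array")
  for (t in seq_len(dim(R)[3])) .check_sym(R[, , t, drop = TRUE], "R block")
  if (!is.null(days)) {
    if (dim(R)[3] == 1 && length(days) > 1) {
      R <- array(R, dim = c(dim(R)[1], dim(R)[2], length(days)))
    }
    dimnames(R) <- list(NULL, NULL, as.character(days))
  }
  structure(list(C = C, D = D, R = R), class = "cov_components")
}

.check_sym <- function(M, label) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M) || max(abs(M - t(M))) > 1e-8 * max(1, max(abs(M)))) {
    stop(label, " must be symmetric")
  }
  invisible(TRUE)
}

# Residual block for day index t (recycles a single stored block).
.r_day <- function(R, t) {
  s <- if (dim(R)[3] == 1L) 1L else t
  matrix(R[, , s], dim(R)[1], dim(R)[2])
}

#' Assemble the mixed-model design for a random regression analysis
#'
#' Builds the stacked observation vector and the sparse design matrices of
#' `y = X b + Z u + Q p + e`. Row `r` for (accession `j`, trait `q`, day `t`)
#' carries the basis row `phi(t)` in the trait-`q` fixed block of `X`, in the
#' (trait `q`, accession `j`) genetic block of `Z`, and likewise in `Q`.
#' Random-effect columns are ordered coefficient-major: column
#' `((q-1) K + k) n + j` belongs to trait `q`, coefficient `k`, accession `j`,
#' so that `Var(u) = C %x% G` and `Var(p) = D %x% I` hold exactly for the
#' trait-major coefficient layout of [cov_components()]. Accessions in `grm`
#' without phenotype records simply contribute no rows (their genetic
#' coefficients are still in the model and are predicted through `G`).
#'
#' @param phenos data.frame with columns `accession`, `trait`, `day`, `value`
#'   (at most one record per accession-trait-day; missing records allowed).
#' @param basis a [legendre_basis()] covering all observed days.
#' @param spec an [rrm_spec()]; `basis$order` must be at least every order in
#'   the spec.
#' @param grm relationship matrix over all modelled accessions (apply
#'   [add_ridge()] beforehand if it will be inverted).
#' @return object of class `rrm_model`.
#' @export
build_design <- function(phenos, basis, spec, grm) {
  stopifnot(inherits(basis, "legendre_basis"), inherits(spec, "rrm_spec"))
  need <- c("accession", "trait", "day", "value")
  if (!all(need %in% names(phenos))) {
    stop("phenos needs columns ", paste(need, collapse = ", "))
  }
  if (max(spec$fixed_order, spec$genetic_order, spec$pe_order) > basis$order) {
    stop("basis order is lower than a model order")
  }
  ids <- rownames(grm)
  acc <- match(as.character(phenos$accession), ids)
  if (anyNA(acc)) {
    stop("phenotype accession absent from GRM: ",
         paste(unique(phenos$accession[is.na(acc)]), collapse = ", "))
  }
  trait <- match(as.character(phenos$trait), spec$traits)
  if (anyNA(trait)) {
    stop("trait not in spec: ",
         paste(unique(phenos$trait[is.na(trait)]), collapse = ", "))
  }
  dayi <- match(as.character(phenos$day), as.character(basis$grid$days))
  if (anyNA(dayi)) {
    stop("day outside basis grid: ",
         paste(unique(phenos$day[is.na(dayi)]), collapse = ", "))
  }
  if (anyDuplicated(cbind(acc, trait, dayi))) {
    stop("more than one record per (accession, trait, day)")
  }

  n <- nrow(grm)
  nrec <- nrow(phenos)
  nday <- length(basis$grid$days)
  Kf <- spec$fixed_order + 1L
  Kg <- spec$genetic_order + 1L
  Kp <- spec$pe_order + 1L
  rows <- seq_len(nrec)

  X <- sparseMatrix(
    i = rep(rows, each = Kf),
    j = as.vector(t((trait - 1L) * Kf + matrix(1:Kf, nrec, Kf, byrow = TRUE))),
    x = as.vector(t(basis$phi[dayi, 1:Kf, drop = FALSE])),
    dims = c(nrec, spec$n_traits * Kf))
  Z <- sparseMatrix(
    i = rep(rows, each = Kg),
    j = as.vector(t(((trait - 1L) * Kg + matrix(1:Kg, nrec, Kg, byrow = TRUE)) - 1L) * n +
                  rep(acc, each = Kg)),
    x = as.vector(t(basis$phi[dayi, 1:Kg, drop = FALSE])),
    dims = c(nrec, spec$n_traits * Kg * n))
  Q <- NULL
  if (spec$include_pe) {
    Q <- sparseMatrix(
      i = rep(rows, each = Kp),
      j = as.vector(t(((trait - 1L) * Kp + matrix(1:Kp, nrec, Kp, byrow = TRUE)) - 1L) * n +
                    rep(acc, each = Kp)),
      x = as.vector(t(basis$phi[dayi, 1:Kp, drop = FALSE])),
      dims = c(nrec, spec$n_traits * Kp * n))
  }

  structure(list(
    y = as.numeric(phenos$value),
    rec = data.frame(acc = acc, trait = trait, dayi = dayi),
    X = X, Z = Z, Q = Q,
    basis = basis, spec = spec, G = grm,
    accession_ids = ids, n = n, nday = nday,
    Kf = Kf, Kg = Kg, Kp = Kp
  ), class = "rrm_model")
}

# Split records into complete within-day trait pairs and singletons.
.residual_parts <- function(model) {
  rec <- model$rec
  if (model$spec$n_traits == 1L) {
    return(list(pair = NULL,
                single = data.frame(row = seq_len(nrow(rec)),
                                    trait = rec$trait, day = rec$dayi)))
  }
  key <- (rec$acc - 1L) * model$nday + rec$dayi
  i1 <- which(rec$trait == 1L)
  i2 <- which(rec$trait == 2L)
  m <- match(key[i1], key[i2])
  paired1 <- i1[!is.na(m)]
  paired2 <- i2[m[!is.na(m)]]
  solo <- c(i1[is.na(m)], setdiff(i2, paired2))
  pair <- if (length(paired1)) {
    data.frame(row1 = paired1, row2 = paired2, day = rec$dayi[paired1])
  }
  single <- if (length(solo)) {
    data.frame(row = solo, trait = rec$trait[solo], day = rec$dayi[solo])
  }
  list(pair = pair, single = single)
}

# Sparse residual covariance (or precision) matrix over the record rows.
# A record whose within-day trait partner is missing contributes its marginal
# variance R[q, q](t).
.residual_matrix <- function(model, R, inverse = FALSE) {
  parts <- .residual_parts(model)
  het <- dim(R)[3] > 1L
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  if (!is.null(parts$single)) {
    s <- parts$single
    d <- if (het) s$day else rep(1L, nrow(s))
    v <- R[cbind(s$trait, s$trait, d)]
    if (inverse) v <- 1 / v
    ii <- c(ii, s$row); jj <- c(jj, s$row); xx <- c(xx, v)
  }
  if (!is.null(parts$pair)) {
    p <- parts$pair
    d <- if (het) p$day else rep(1L, nrow(p))
    a <- R[cbind(1L, 1L, d)]
    b <- R[cbind(1L, 2L, d)]
    cc <- R[cbind(2L, 2L, d)]
    if (inverse) {
      det <- a * cc - b^2
      tmp <- a; a <- cc / det; cc <- tmp / det; b <- -b / det
    }
    ii <- c(ii, p$row1, p$row2, p$row1, p$row2)
    jj <- c(jj, p$row1, p$row2, p$row2, p$row1)
    xx <- c(xx, a, cc, b, b)
  }
  nrec <- nrow(model$rec)
  sparseMatrix(i = ii, j = jj, x = xx, dims = c(nrec, nrec))
}

#' Phenotypic covariance implied by a fitted structure
#'
#' Returns `Z (C %x% G) Z' + Q (D %x% I) Q' + R`-expansion over the record
#' rows of the model: a verification device (Monte-Carlo and algebra checks),
#' not an inference path.
#'
#' @param model an [rrm_model][build_design()].
#' @param comps a [cov_components()] whose dimensions match the model.
#' @return dense covariance matrix of `y`.
#' @export
realized_covariance <- function(model, comps) {
  spec <- model$spec
  KTg <- spec$n_traits * model$Kg
  if (!all(dim(comps$C) == KTg)) stop("C dimension mismatch")
  V <- model$Z %*% (comps$C %x% model$G) %*% t(model$Z)
  if (spec$include_pe) {
    KTp <- spec$n_traits * model$Kp
    if (!all(dim(comps$D) == KTp)) stop("D dimension mismatch")
    V <- V + model$Q %*% (comps$D %x% diag(model$n)) %*% t(model$Q)
  }
  V <- V + .residual_matrix(model, comps$R, inverse = FALSE)
  as.matrix(V)
}
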