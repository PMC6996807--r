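# Time standardization and Legendre polynomial basis (Phi = M Lambda).

#' Time grid for a longitudinal design
#'
#' @param days strictly increasing time points (days of imaging).
#' @param t_min,t_max standardization bounds; default to the range of `days`.
#'   Fixing them at the full design range lets a model trained on early days
#'   evaluate the same basis at later days (forecasting).
#' @return object of class `time_grid`.
#' @export
time_grid <- function(days, t_min = min(days), t_max = max(days)) {
  days <- as.numeric(days)
  if (any(diff(days) <= 0)) stop("days must be strictly increasing")
  if (!(t_min <= min(days) && t_max >= max(days))) {
    stop("standardization bounds must cover the days")
  }
  if (t_min >= t_max) stop("t_min must be < t_max")
  structure(list(days = days, t_min = t_min, t_max = t_max),
            class = "time_grid")
}

#' Map time onto the standardized interval [-1, 1]
#'
#' `x = -1 + 2 (t - t_min) / (t_max - t_min)`, so `t_min` maps to -1 and
#' `t_max` to +1. Values outside the bounds are allowed (extrapolation) but
#' flagged with a message.
#'
#' @param t time value(s).
#' @param t_min,t_max standardization bounds, `t_min < t_max`.
#' @param quiet suppress the extrapolation message.
#' @return standardized value(s).
#' @export
standardize_time <- function(t, t_min, t_max, quiet = FALSE) {
  if (t_min >= t_max) stop("t_min must be < t_max")
  x <- -1 + 2 * (t - t_min) / (t_max - t_min)
  if (!quiet && any(t < t_min | t > t_max)) {
    message("standardize_time: extrapolating outside [",
            t_min, ", ", t_max, "]")
  }
  x
}

# Coefficient matrix Lambda: column k holds the monomial coefficients of
# c * sqrt((2k+1)/2) * P_k(x), with the global constant c = sqrt(2) so that
# the intercept column is identically 1. P_k via the three-term recurrence
# k P_k = (2k-1) x P_{k-1} - (k-1) P_{k-2}.
legendre_lambda <- function(order, scale_intercept = TRUE) {
  K <- order + 1L
  P <- matrix(0, K, K)  # column k: monomial coefficients of P_{k-1}
  P[1, 1] <- 1
  if (order >= 1) P[2, 2] <- 1
  if (order >= 2) {
    for (k in 2:order) {
      shifted <- c(0, P[1:order, k])  # x * P_{k-1}
      P[, k + 1] <- ((2 * k - 1) * shifted - (k - 1) * P[, k - 1]) / k
    }
  }
  norm <- sqrt((2 * (0:order) + 1) / 2)
  if (scale_intercept) norm <- norm * sqrt(2)
  sweep(P, 2, norm, "*")
}

#' Legendre polynomial basis matrix
#'
#' Builds `Phi = M Lambda`, where `M` holds monomials of standardized time and
#' `Lambda` the (normalized) Legendre coefficients. Column `k` evaluates
#' `sqrt(2) * sqrt((2k+1)/2) * P_k(x) = sqrt(2k+1) * P_k(x)`; the scaling
#' makes the intercept column identically 1 (the conventional intercept
#' standardization). All coefficient (co)variance components are specific to
#' this basis convention; set `scale_intercept = FALSE` for the plain
#' orthonormal basis.
#'
#' @param grid a [time_grid()].
#' @param order polynomial degree (quadratic, `order = 2`, is the usual choice
#'   for growth-curve RRM analyses).
#' @param scale_intercept multiply all columns by `sqrt(2)` so column 0 is 1.
#' @return object of class `legendre_basis` with elements `phi`, `M`,
#'   `Lambda`, `order`, `grid`.
#' @export
legendre_basis <- function(grid, order = 2, scale_intercept = TRUE) {
  stopifnot(inherits(grid, "time_grid"), order >= 0)
  Lambda <- legendre_lambda(order, scale_intercept)
  x <- standardize_time(grid$days, grid$t_min, grid$t_max, quiet = TRUE)
  M <- outer(x, 0:order, "^")
  phi <- M %*% Lambda
  rownames(phi) <- rownames(M) <- as.character(grid$days)
  structure(list(phi = phi, M = M, Lambda = Lambda, order = order,
                 grid = grid, scale_intercept = scale_intercept),
            class = "legendre_basis")
}

#' Evaluate a basis at arbitrary times
#'
#' Uses the same standardization bounds and `Lambda` as the stored basis, so
#' evaluating at grid times reproduces the stored `phi` rows, and times beyond
#' the grid extrapolate the same polynomials (the forecasting device).
#'
#' @param basis a [legendre_basis()].
#' @param t numeric times.
#' @param quiet suppress the extrapolation message.
#' @return matrix with `length(t)` rows and `order + 1` columns.
#' @export
eval_basis <- function(basis, t, quiet = TRUE) {
  x <- standardize_time(t, basis$grid$t_min, basis$grid$t_max, quiet = quiet)
  M <- outer(x, 0:basis$order, "^")
  out <- M %*% basis$Lambda
  rownames(out) <- as.character(t)
  out
}

# Rows of phi for given days (must lie on the grid).
.phi_rows <- function(basis, days) {
  idx <- match(as.character(days), rownames(basis$phi))
  if (anyNA(idx)) stop("day outside the basis grid: ",
                       paste(days[is.na(idx)], collapse = ", "))
  basis$phi[idx, , drop = FALSE]
}
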