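# Design assembly and realized covariance structure.

test_that("build_design produces the documented dimensions", {
  G <- tiny_grm(2, 100, seed = 1)
  basis <- legendre_basis(time_grid(1:20), 2)
  spec <- rrm_spec(c("WU", "PSA"))
  ph <- expand.grid(accession = rownames(G), trait = c("WU", "PSA"),
                    day = 1:20, stringsAsFactors = FALSE)
  ph$value <- rnorm(nrow(ph))
  m <- build_design(ph, basis, spec, G)
  expect_equal(length(m$y), 80L)
  expect_equal(ncol(m$Z), 12L)       # 2 traits x 3 coefficients x 2 accessions
  expect_equal(ncol(m$Q), 12L)
  expect_equal(ncol(m$X), 6L)

  # single record: Z row is phi(day) in the right block
  ph1 <- data.frame(accession = rownames(G)[1], trait = "WU", day = 1,
                    value = 0.5)
  m1 <- build_design(ph1, basis, rrm_spec("WU"), G)
  expect_equal(dim(m1$Z), c(1L, 6L))
  z <- as.numeric(m1$Z[1, ])
  expect_equal(z[c(1, 3, 5)], unname(basis$phi[1, ]))
  expect_equal(z[c(2, 4, 6)], rep(0, 3))
})

test_that("removing one record removes one row, keeps all columns", {
  G <- tiny_grm(4, 100, seed = 2)
  basis <- legendre_basis(time_grid(1:6), 2)
  spec <- rrm_spec(c("WU", "PSA"))
  ph <- expand.grid(accession = rownames(G), trait = c("WU", "PSA"),
                    day = 1:6, stringsAsFactors = FALSE)
  ph$value <- rnorm(nrow(ph))
  m_full <- build_design(ph, basis, spec, G)
  m_drop <- build_design(ph[-17, ], basis, spec, G)
  expect_equal(nrow(m_drop$X), nrow(m_full$X) - 1L)
  expect_equal(ncol(m_drop$X), ncol(m_full$X))
  expect_equal(ncol(m_drop$Z), ncol(m_full$Z))
  expect_equal(ncol(m_drop$Q), ncol(m_full$Q))
})

test_that("build_design validates accessions, traits, days, duplicates", {
  G <- tiny_grm(3, 100, seed = 3)
  basis <- legendre_basis(time_grid(1:5), 2)
  spec <- rrm_spec("WU")
  ph <- data.frame(accession = "nope", trait = "WU", day = 1, value = 0)
  expect_error(build_design(ph, basis, spec, G), "absent from GRM")
  ph2 <- data.frame(accession = rownames(G)[1], trait = "XX", day = 1,
                    value = 0)
  expect_error(build_design(ph2, basis, spec, G), "trait not in spec")
  ph3 <- data.frame(accession = rownames(G)[1], trait = "WU", day = 9,
                    value = 0)
  expect_error(build_design(ph3, basis, spec, G), "outside basis grid")
  ph4 <- data.frame(accession = rownames(G)[1], trait = "WU",
                    day = c(1, 1), value = c(0, 1))
  expect_error(build_design(ph4, basis, spec, G), "one record per")
})

test_that("realized_covariance degenerates to its closed forms", {
  G <- tiny_grm(3, 100, seed = 4)
  basis <- legendre_basis(time_grid(1:2), 2)
  spec <- rrm_spec(c("WU", "PSA"))
  ph <- expand.grid(accession = rownames(G), trait = c("WU", "PSA"),
                    day = 1:2, stringsAsFactors = FALSE)
  ph$value <- 0
  m <- build_design(ph, basis, spec, G)
  R <- array(0, dim = c(2, 2, 2))
  R[, , 1] <- matrix(c(1, 0.3, 0.3, 2), 2)
  R[, , 2] <- matrix(c(1.5, -0.2, -0.2, 1), 2)
  comps0 <- cov_components(diag(1e-30, 6), diag(1e-30, 6), R, days = 1:2)
  V <- realized_covariance(m, comps0)
  # residual-only model: block structure over (accession, day) cells
  i1 <- which(m$rec$acc == 1 & m$rec$dayi == 1)
  expect_equal(V[i1, i1], matrix(c(1, 0.3, 0.3, 2), 2), tolerance = 1e-12)
  i2 <- which(m$rec$acc == 2 & m$rec$dayi == 2)
  expect_equal(V[i2, i2], matrix(c(1.5, -0.2, -0.2, 1), 2),
               tolerance = 1e-12)
  expect_equal(V[i1, i2], matrix(0, 2, 2), tolerance = 1e-20)

  # single day, order 0, one trait: GBLUP covariance su2 G + sp2 I + ve I
  basis0 <- legendre_basis(time_grid(1, 0, 2), 0)
  ph0 <- data.frame(accession = rownames(G), trait = "WU", day = 1, value = 0)
  m0 <- build_design(ph0, basis0, rrm_spec("WU", 0, 0, 0), G)
  V0 <- realized_covariance(
    m0, cov_components(matrix(2), matrix(0.5), matrix(1), days = 1))
  expect_equal(V0, 2 * G + 0.5 * diag(3) + diag(3),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("realized_covariance matches a Monte-Carlo covariance oracle", {
  set.seed(11)
  G <- tiny_grm(3, 100, seed = 5)
  basis <- legendre_basis(time_grid(1:2), 1)
  spec <- rrm_spec(c("WU", "PSA"), 1, 1, 1)
  ph <- expand.grid(accession = rownames(G), trait = c("WU", "PSA"),
                    day = 1:2, stringsAsFactors = FALSE)
  ph$value <- 0
  m <- build_design(ph, basis, spec, G)
  A <- matrix(rnorm(16, sd = 0.5), 4)
  C <- crossprod(A) + diag(0.1, 4)
  B <- matrix(rnorm(16, sd = 0.3), 4)
  D <- crossprod(B) + diag(0.1, 4)
  R <- array(c(1, 0.2, 0.2, 0.8, 1.2, -0.1, -0.1, 0.6), dim = c(2, 2, 2))
  comps <- cov_components(C, D, R, days = 1:2)
  V <- realized_covariance(m, comps)

  # brute-force oracle: simulate u, p, e from the generative model
  ndr <- 1e5
  Z <- as.matrix(m$Z)
  Q <- as.matrix(m$Q)
  U <- matrix(rnorm(ndr * 12), ndr) %*% chol(C %x% G)
  P <- matrix(rnorm(ndr * 12), ndr) %*% chol(D %x% diag(3))
  E <- matrix(0, ndr, nrow(Z))
  for (d in 1:2) {
    rows <- which(m$rec$dayi == d)
    for (a in 1:3) {
      rr <- rows[m$rec$acc[rows] == a]
      E[, rr] <- matrix(rnorm(ndr * 2), ndr) %*% chol(R[, , d])
    }
  }
  Y <- U %*% t(Z) + P %*% t(Q) + E
  Vmc <- cov(Y)
  # entries agree within Monte-Carlo error (relative ~ sqrt(2/ndr))
  expect_lt(max(abs(Vmc - V)), 0.05 * max(diag(V)))
})

test_that("genetic-value variance across accessions is phi C1 phi' x G", {
  set.seed(12)
  sim <- small_sim(n = 60, n_days = 6, seed = 8)
  basis <- sim$basis
  phi <- basis$phi
  C1 <- sim$config$C[1:3, 1:3]
  L <- t(chol(sim$grm))
  # empirical covariance of the day-4 genetic values over many fresh draws
  ndr <- 3000
  a_t <- array(0, dim = c(ndr, 60))
  phi4 <- phi[4, ]
  for (i in seq_len(ndr)) {
    U1 <- L %*% matrix(rnorm(60 * 3), 60) %*% chol(C1)
    a_t[i, ] <- U1 %*% phi4
  }
  emp <- cov(a_t)
  theo <- as.numeric(phi4 %*% C1 %*% phi4) * sim$grm
  expect_lt(max(abs(emp - theo)) / max(theo), 0.15)
})

test_that("exchanging trait labels conjugates the covariance consistently", {
  G <- tiny_grm(3, 100, seed = 6)
  basis <- legendre_basis(time_grid(1:3), 2)
  ph <- expand.grid(accession = rownames(G), trait = c("WU", "PSA"),
                    day = 1:3, stringsAsFactors = FALSE)
  ph$value <- 0
  m12 <- build_design(ph, basis, rrm_spec(c("WU", "PSA")), G)
  m21 <- build_design(ph, basis, rrm_spec(c("PSA", "WU")), G)
  A <- matrix(rnorm(36, sd = 0.4), 6)
  C <- crossprod(A) + diag(0.2, 6)
  D <- diag(0.3, 6)
  R <- array(rep(c(1, 0.2, 0.2, 0.9), 3), dim = c(2, 2, 3))
  sw <- c(4:6, 1:3)
  comps12 <- cov_components(C, D, R, days = 1:3)
  comps21 <- cov_components(C[sw, sw], D[sw, sw],
                            array(R[2:1, 2:1, ], dim = dim(R)), days = 1:3)
  V12 <- realized_covariance(m12, comps12)
  V21 <- realized_covariance(m21, comps21)
  # same records, same joint distribution: covariances must be identical
  expect_equal(V12, V21, tolerance = 1e-10)
})
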