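# MME solving, Gibbs sampling, and prediction of unphenotyped accessions.

test_that("solve_mme equals closed-form GBLUP on a degenerate RRM", {
  set.seed(7)
  n <- 20
  G <- tiny_grm(n, 400, seed = 7)
  basis <- legendre_basis(time_grid(1, 0, 2), 0)
  spec <- rrm_spec("WU", 0, 0, 0)
  u_true <- as.numeric(t(chol(G)) %*% rnorm(n)) * sqrt(2)
  ph <- data.frame(accession = rownames(G), trait = "WU", day = 1,
                   value = 5 + u_true + rnorm(n))
  m <- build_design(ph, basis, spec, G)
  su2 <- 2; sp2 <- 0.5; ve <- 1
  comps <- cov_components(matrix(su2), matrix(sp2), matrix(ve), days = 1)
  sols <- solve_mme(m, comps)

  # dense closed-form oracle: GLS intercept, then the shrinkage solution
  V <- su2 * G + (sp2 + ve) * diag(n)
  Vi <- solve(V)
  bhat <- sum(Vi %*% ph$value) / sum(Vi)
  lambda <- (sp2 + ve) / su2
  uhat <- solve(solve(G) * lambda + diag(n), ph$value - bhat)
  expect_equal(as.numeric(sols$b), bhat, tolerance = 1e-8)
  expect_lt(max(abs(sols$u[, 1, 1] - uhat)) / max(abs(uhat)), 1e-8)
})

test_that("solve_mme basics: zero phenotypes, exchangeability, record order", {
  basis <- legendre_basis(time_grid(1:5), 2)
  spec <- rrm_spec("WU")
  # duplicate genotype rows -> identical accessions
  set.seed(3)
  d <- poly_mat(5, 150, seed = 3)
  d[2, ] <- d[1, ]
  d <- d[, apply(d, 2, var) > 0, drop = FALSE]
  G <- blend_grm(compute_grm(genotype_matrix(d)))
  ph <- expand.grid(accession = rownames(G), day = 1:5,
                    stringsAsFactors = FALSE)
  ph$trait <- "WU"
  ph$value <- rnorm(25)
  # give the two copies identical records
  for (day in 1:5) {
    ph$value[ph$accession == rownames(G)[2] & ph$day == day] <-
      ph$value[ph$accession == rownames(G)[1] & ph$day == day]
  }
  comps <- cov_components(diag(0.5, 3), diag(0.2, 3),
                          array(1, c(1, 1, 5)), days = 1:5)
  m <- build_design(ph, basis, spec, G)
  sols <- solve_mme(m, comps)
  expect_equal(sols$u[1, , 1], sols$u[2, , 1], tolerance = 1e-8)

  # all-zero phenotypes give all-zero solutions
  ph0 <- ph
  ph0$value <- 0
  s0 <- solve_mme(build_design(ph0, basis, spec, G), comps)
  expect_equal(max(abs(c(s0$b, s0$u, s0$p))), 0, tolerance = 1e-12)

  # record order is irrelevant
  perm <- sample(nrow(ph))
  s1 <- solve_mme(build_design(ph[perm, ], basis, spec, G), comps)
  expect_equal(sols$u, s1$u, tolerance = 1e-10)
  expect_equal(sols$b, s1$b, tolerance = 1e-10)
})

test_that("predict_unphenotyped projects through the relationship matrix", {
  basis <- legendre_basis(time_grid(1:4), 2)
  # 5-accession hand-built toy: block structure with a zero-related test set
  ids <- paste0("A", 1:5)
  G <- diag(5)
  G[1, 2] <- G[2, 1] <- 0.5
  G[4, 1] <- G[1, 4] <- 0.3
  G[4, 2] <- G[2, 4] <- 0.15
  dimnames(G) <- list(ids, ids)
  U <- matrix(rnorm(15), 5, 3)
  sols <- structure(list(b = matrix(0, 3, 1),
                         u = array(U, c(5, 3, 1), list(ids, NULL, "WU")),
                         p = NULL), class = "rrm_solutions")
  trn <- ids[1:3]
  tst <- ids[4:5]
  pred <- predict_unphenotyped(G, trn, tst, sols, basis)
  # dense oracle
  a_trn <- U[1:3, ] %*% t(basis$phi)
  expect_equal(unname(pred),
               unname(G[4:5, 1:3] %*% solve(G[1:3, 1:3]) %*% a_trn),
               tolerance = 1e-10)
  # an unrelated test accession is predicted 0 at every day
  expect_equal(unname(pred[2, ]), rep(0, 4), tolerance = 1e-12)

  # a test accession genotypically identical to a training one inherits
  # that accession's trajectory exactly (its G row repeats a training row;
  # the joint matrix is the singular PSD covariance of (x1, x2, x3, x1))
  A <- matrix(rnorm(9), 3)
  G11 <- crossprod(A) + diag(0.3, 3)
  G2 <- rbind(cbind(G11, G11[, 1]), c(G11[1, ], G11[1, 1]))
  dimnames(G2) <- list(paste0("S", 1:4), paste0("S", 1:4))
  U2 <- matrix(rnorm(9), 3, 3)
  s2 <- structure(list(b = matrix(0, 3, 1),
                       u = array(U2, c(3, 3, 1),
                                 list(paste0("S", 1:3), NULL, "WU")),
                       p = NULL), class = "rrm_solutions")
  # train on 1:3; accession 4 is a copy of accession 1
  p2 <- predict_unphenotyped(G2, rownames(G2)[1:3], rownames(G2)[4],
                             s2, basis)
  a1 <- as.numeric(U2[1, ] %*% t(basis$phi))
  expect_equal(as.numeric(p2[1, ]), a1, tolerance = 1e-8)
})

test_that("zero-record accessions in the joint MME equal the G-projection", {
  # BLUP theorem: carrying unphenotyped accessions in the MME with zero
  # rows is the same as projecting the phenotyped-only fit through G
  set.seed(21)
  n <- 30
  G <- tiny_grm(n, 300, seed = 21)
  basis <- legendre_basis(time_grid(1:6), 2)
  spec <- rrm_spec("WU")
  trn <- rownames(G)[1:22]
  tst <- rownames(G)[23:30]
  ph <- expand.grid(accession = trn, day = 1:6, stringsAsFactors = FALSE)
  ph$trait <- "WU"
  ph$value <- rnorm(nrow(ph), sd = 1.5)
  comps <- cov_components(diag(c(0.8, 0.3, 0.1)), diag(0.2, 3),
                          array(0.9, c(1, 1, 6)), days = 1:6)
  # joint model: all accessions in G, phenotypes only for the training set
  m_joint <- build_design(ph, basis, spec, G)
  s_joint <- solve_mme(m_joint, comps)
  a_joint <- genetic_values(s_joint, basis)[tst, ]
  # training-only fit, then projection
  m_trn <- build_design(ph, basis, spec, G[trn, trn])
  s_trn <- solve_mme(m_trn, comps)
  a_proj <- predict_unphenotyped(G, trn, tst, s_trn, basis)
  expect_lt(max(abs(a_joint - a_proj)) / max(abs(a_joint)), 1e-6)
})

test_that("fixed-variance Gibbs returns the inputs verbatim and MME locations", {
  set.seed(31)
  n <- 25
  G <- tiny_grm(n, 300, seed = 31)
  basis <- legendre_basis(time_grid(1:4), 2)
  spec <- rrm_spec("WU")
  ph <- expand.grid(accession = rownames(G), day = 1:4,
                    stringsAsFactors = FALSE)
  ph$trait <- "WU"
  ph$value <- rnorm(nrow(ph))
  comps <- cov_components(diag(c(0.6, 0.2, 0.1)), diag(0.15, 3),
                          array(0.8, c(1, 1, 4)), days = 1:4)
  m <- build_design(ph, basis, spec, G)
  dr <- gibbs_rrm(m, gibbs_config(n_iter = 6000, burn_in = 1000, thin = 1,
                                  seed = 4, fixed_variances = comps))
  # every retained draw equals the input components exactly
  expect_equal(apply(dr$C, c(1, 2), min), comps$C, tolerance = 0)
  expect_equal(apply(dr$C, c(1, 2), max), comps$C, tolerance = 0)
  expect_equal(apply(dr$R, c(1, 2, 3), var)[1, 1, ], rep(0, 4))
  # posterior means of locations match the MME solution (MC error only)
  sols <- solve_mme(m, comps)
  gs <- posterior_solutions(dr)
  expect_lt(max(abs(sols$u - gs$u)), 0.08)
  expect_lt(max(abs(sols$b - gs$b)), 0.08)
})

test_that("Gibbs reproduces the analytic conjugate posterior of a variance", {
  # one-variance toy: y ~ N(mu, s2), flat prior on mu, inverse-Wishart
  # (nu0, Psi) prior on s2; analytic marginal posterior of s2 is scaled
  # inverse chi-square with df nu0 + n - 1 and scale Psi + sum((y - ybar)^2)
  set.seed(5)
  n <- 50
  y <- rnorm(n, mean = 3, sd = 1.4)
  nu0 <- 4
  Psi <- 3
  ids <- sprintf("T%02d", 1:n)
  G <- diag(n)
  dimnames(G) <- list(ids, ids)
  basis <- legendre_basis(time_grid(1, 0, 2), 0)
  ph <- data.frame(accession = ids, trait = "WU", day = 1, value = y)
  m <- build_design(ph, basis, rrm_spec("WU", 0, 0, 0, include_pe = FALSE), G)
  res <- rrgp:::.gibbs_rrm_cpp(
    y = m$y, acc = m$rec$acc - 1L, trt = m$rec$trait - 1L,
    dayi = m$rec$dayi - 1L,
    Phi_f = basis$phi, Phi_g = basis$phi, Phi_p = basis$phi,
    Ginv = G, n = n, ntraits = 1L, nday = 1L,
    het_residual = TRUE, include_pe = FALSE,
    niter = 24000, burnin = 4000, thin = 2,
    nu_c = 3, S_c = matrix(1e-10), nu_d = 3, S_d = matrix(1e-10),
    nu_r = nu0, S_r = matrix(Psi),
    C0 = matrix(1e-8), D0 = matrix(1), R0 = array(1, c(1, 1, 1)),
    update_c = FALSE, update_d = FALSE, update_r = TRUE, store_b = FALSE)
  draws <- res$R[1, ]
  sse <- sum((y - mean(y))^2)
  post_mean <- (Psi + sse) / (nu0 + n - 1 - 2)
  mcse <- sd(draws) / sqrt(ess(draws))
  expect_lt(abs(mean(draws) - post_mean), 3 * mcse + 1e-8)
})

test_that("the sampler recovers known components on generated data", {
  # generative-model round trip at reduced scale: posterior-mean genomic
  # correlation and heritability trajectories track the truth
  sim <- simulate_dataset(synth_config(n_accessions = 200, seed = 14))
  m <- build_design(sim$phenos, sim$basis, rrm_spec(c("WU", "PSA")), sim$grm)
  dr <- gibbs_rrm(m, gibbs_config(n_iter = 6000, burn_in = 2500, thin = 4,
                                  seed = 15))
  pm <- posterior_means(dr)
  rg_hat <- genomic_correlation(pm, sim$basis)
  expect_lt(mean(abs(rg_hat - sim$truth$rg)), 0.1)
  h1 <- heritability(pm, sim$basis, 1)
  h2 <- heritability(pm, sim$basis, 2)
  expect_lt(mean(abs(h1 - sim$truth$h2[1, ])), 0.1)
  expect_lt(mean(abs(h2 - sim$truth$h2[2, ])), 0.1)
  # estimated rg reproduces the increasing shape
  expect_gt(cor(seq_along(rg_hat), rg_hat, method = "spearman"), 0)
})

test_that("gibbs_rrm is reproducible under a seed and warns on singular G", {
  sim <- small_sim(n = 20, n_days = 4, seed = 2)
  m <- build_design(sim$phenos, sim$basis, rrm_spec(c("WU", "PSA")), sim$grm)
  cfgA <- gibbs_config(n_iter = 300, burn_in = 100, thin = 2, seed = 9)
  d1 <- gibbs_rrm(m, cfgA)
  d2 <- gibbs_rrm(m, cfgA)
  expect_identical(d1$C, d2$C)
  expect_identical(d1$U_mean, d2$U_mean)

  G_sing <- add_ridge(compute_grm(filter_snps(tiny_geno(20, 300, seed = 2), 0, 0)), 1e-9)
  m2 <- build_design(sim$phenos[sim$phenos$trait == "WU", ],
                     legendre_basis(time_grid(1:4), 2),
                     rrm_spec("WU"), G_sing)
  expect_warning(gibbs_rrm(m2, gibbs_config(n_iter = 60, burn_in = 20,
                                            thin = 1, seed = 1)),
                 "near-singular")
})
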