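# Small in-code fixtures shared across test files.

# genotype matrix with controlled dimensions
tiny_geno <- function(n = 12, m = 80, seed = 1) {
  set.seed(seed)
  simulate_genotypes(synth_config(n_accessions = n, n_markers = m))
}

# dosage matrix with zero-variance marker realizations dropped
poly_mat <- function(n = 12, m = 200, seed = 1) {
  d <- unclass(tiny_geno(n, m, seed))
  d[, apply(d, 2, var) > 0, drop = FALSE]
}

# a stabilized GRM for model-based tests
tiny_grm <- function(n = 12, m = 200, seed = 1) {
  blend_grm(compute_grm(genotype_matrix(poly_mat(n, m, seed))))
}

# complete bivariate synthetic study at reduced scale
small_sim <- function(n = 40, n_days = 8, m = 300, seed = 1) {
  simulate_dataset(synth_config(n_accessions = n, n_markers = m,
                                n_days = n_days, seed = seed))
}

# single-trait phenotypes for an explicit genetic-coefficient matrix
st_phenos <- function(ids, basis, U, b = c(0, 0, 0), sigma_e = 0,
                      days = basis$grid$days, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  phi <- eval_basis(basis, days)
  recs <- expand.grid(accession = ids, day = days,
                      stringsAsFactors = FALSE)
  idx <- match(recs$accession, ids)
  didx <- match(recs$day, days)
  g <- (U %*% t(phi))[cbind(idx, didx)]
  mu <- as.numeric(phi %*% b)[didx]
  data.frame(accession = recs$accession, trait = "WU", day = recs$day,
             value = mu + g + if (sigma_e > 0)
               rnorm(nrow(recs), 0, sigma_e) else 0)
}
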