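# Study workflow: water-use derivation, first-stage BLUEs, cross-validation.

#' Daily water use from pot weights
#'
#' `WU_t = Potwt_{t-1} - Potwt_t`: the weight of the pot after watering on
#' the previous day minus its weight on the current day prior to watering.
#' Rows are grouped by every identifier column other than `day`, `potwt`,
#' `potwt_pre`; within a group, a day without a previous-day record gets a
#' missing WU (the first imaging day always does).
#'
#' @param weights data.frame with columns `accession`, `day`, `potwt`
#'   (weight after watering, kg), `potwt_pre` (weight before watering, kg),
#'   plus any grouping identifiers (experiment, replicate, ...).
#' @return the input with an added `wu` column.
#' @export
compute_wu <- function(weights) {
  need <- c("accession", "day", "potwt", "potwt_pre")
  if (!all(need %in% names(weights))) {
    stop("weights needs columns ", paste(need, collapse = ", "))
  }
  if (any(c(weights$potwt, weights$potwt_pre) <= 0, na.rm = TRUE)) {
    stop("pot weights must be positive")
  }
  idcols <- setdiff(names(weights), c("day", "potwt", "potwt_pre", "wu"))
  key <- interaction(weights[idcols], drop = TRUE)
  out <- weights
  out$wu <- NA_real_
  for (g in split(seq_len(nrow(weights)), key)) {
    d <- weights$day[g]
    prev <- match(d - 1, d)
    out$wu[g] <- weights$potwt[g][prev] - weights$potwt_pre[g]
  }
  out
}

#' First-stage BLUEs of accession effects for one day
#'
#' Fits `y = mu + accession (fixed) + experiment:replicate +
#' experiment:replicate:smarthouse + accession:experiment + e` with all terms
#' except the accession effect random, and returns the generalized
#' least-squares accession estimates under a sum-to-zero constraint. Random-
#' term variances are estimated by REML (lme4) when not supplied; the BLUEs
#' themselves come from the package's own mixed-model-equation solve at those
#' components, so a fit at user-supplied components is exactly reproducible.
#'
#' @param raw data.frame with columns `accession`, `experiment`, `replicate`,
#'   `smarthouse`, `day`, `value` (and optionally `trait`).
#' @param day the day to fit.
#' @param trait optional trait label to filter on.
#' @param varcomp optional named list `list(E =, B =, AE =, residual =)` of
#'   variance components; terms with non-positive variance are dropped (the
#'   all-zero case reduces to ordinary least squares).
#' @return data.frame with columns `accession`, `blue`; the overall mean and
#'   the variance components used are attached as attributes `"mu"` and
#'   `"varcomp"`.
#' @export
stage1_blue <- function(raw, day, trait = NULL, varcomp = NULL) {
  sub <- raw[raw$day == day, , drop = FALSE]
  if (!is.null(trait) && "trait" %in% names(raw)) {
    sub <- sub[sub$trait == trait, , drop = FALSE]
  }
  if (nrow(sub) == 0) stop("no records for day ", day)
  acc <- factor(sub$accession)
  if (nlevels(acc) < 2) stop("need at least 2 accessions")
  E <- droplevels(interaction(sub$experiment, sub$replicate, drop = TRUE))
  B <- droplevels(interaction(E, sub$smarthouse, drop = TRUE))
  AE <- droplevels(interaction(acc, sub$experiment, drop = TRUE))
  y <- sub$value

  if (is.null(varcomp)) {
    dd <- data.frame(y = y, acc = acc, E = E, B = B, AE = AE)
    terms <- c(E = "(1 | E)", B = "(1 | B)", AE = "(1 | AE)")
    keep <- c(E = nlevels(E) > 1, B = nlevels(B) > 1, AE = nlevels(AE) > 1)
    varcomp <- list(E = 0, B = 0, AE = 0, residual = 0)
    if (any(keep)) {
      fml <- stats::as.formula(
        paste("y ~ acc +", paste(terms[keep], collapse = " + ")))
      fit <- suppressWarnings(suppressMessages(lme4::lmer(fml, data = dd)))
      vc <- as.data.frame(lme4::VarCorr(fit))
      for (nm in names(terms)[keep]) {
        varcomp[[nm]] <- vc$vcov[vc$grp == nm]
      }
      varcomp$residual <- vc$vcov[vc$grp == "Residual"]
    } else {
      ols <- stats::lm(y ~ acc)
      varcomp$residual <- summary(ols)$sigma^2
    }
  }

  X <- stats::model.matrix(~acc, contrasts.arg = list(acc = "contr.sum"))
  if (qr(X)$rank < ncol(X)) {
    stop("confounded design: accession effects are not estimable")
  }
  rand <- list(E = E, B = B, AE = AE)
  active <- names(rand)[vapply(names(rand), function(nm) {
    isTRUE(varcomp[[nm]] > 1e-12) && nlevels(rand[[nm]]) > 1
  }, logical(1))]
  se2 <- varcomp$residual
  if (!is.finite(se2) || se2 <= 0) se2 <- 1

  Zs <- lapply(rand[active], function(f) {
    sparseMatrix(i = seq_along(f), j = as.integer(f),
                 x = 1, dims = c(length(f), nlevels(f)))
  })
  W <- Reduce(cbind, Zs, init = as(X, "CsparseMatrix"))
  LHS <- as.matrix(crossprod(W)) / se2
  RHS <- as.numeric(crossprod(W, y)) / se2
  off <- ncol(X)
  for (nm in active) {
    idx <- off + seq_len(nlevels(rand[[nm]]))
    diag(LHS)[idx] <- diag(LHS)[idx] + 1 / varcomp[[nm]]
    off <- off + nlevels(rand[[nm]])
  }
  sol <- unname(solve(LHS, RHS))
  b <- sol[seq_len(ncol(X))]
  alpha <- c(b[-1], -sum(b[-1]))  # contr.sum: last level is minus the sum
  out <- data.frame(accession = levels(acc), blue = b[1] + alpha)
  attr(out, "mu") <- b[1]
  attr(out, "varcomp") <- varcomp
  out
}

#' First-stage BLUEs for every trait and day
#'
#' Convenience loop over [stage1_blue()] returning the long-format phenotype
#' table consumed by [build_design()] and the cross-validation runners.
#'
#' @param raw as in [stage1_blue()], with a `trait` column.
#' @return data.frame with columns `accession`, `trait`, `day`, `value`.
#' @export
stage1_blue_table <- function(raw) {
  combos <- unique(raw[, c("trait", "day")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    b <- stage1_blue(raw, day = combos$day[i], trait = combos$trait[i])
    data.frame(accession = b$accession, trait = combos$trait[i],
               day = combos$day[i], value = b$blue)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Prediction accuracy as a Pearson correlation
#'
#' Pairs with a missing value on either side are dropped; fewer than three
#' complete pairs, or zero variance on either side, give `NA`.
#'
#' @param pred,obs numeric vectors (predicted genetic values and observed
#'   BLUEs over the same accessions).
#' @return Pearson correlation or `NA`.
#' @export
accuracy <- function(pred, obs) {
  ok <- is.finite(pred) & is.finite(obs)
  pred <- pred[ok]
  obs <- obs[ok]
  if (length(pred) < 3 || sd(pred) == 0 || sd(obs) == 0) return(NA_real_)
  cor(pred, obs)
}

#' Cross-validation configuration
#'
#' @param n_train,n_test training and testing set sizes (defaults 245 / 112).
#' @param n_repeats number of random repeats (default 10).
#' @param seed master seed; every repeat and every Gibbs chain derives its
#'   own seed from it deterministically.
#' @param t_split for the forecasting scenario: the number of leading days
#'   whose records train the model (default 10).
#' @param traits trait labels, target trait first.
#' @param genetic_order,fixed_order,pe_order Legendre degrees (default 2).
#' @param gibbs list of chain controls for within-repeat variance estimation
#'   (shorter than the standalone default since only posterior-mean
#'   components are needed).
#' @param ridge diagonal ridge applied once to the relationship matrix.
#' @param models subset of `c("ST-RRM", "MT-RRM1", "MT-RRM2")`.
#' @param fixed_comps optional list `list(st =, mt =)` of [cov_components()];
#'   when supplied, variance estimation is skipped and all repeats use these
#'   components (prediction at fixed variances only).
#' @return object of class `cv_config`.
#' @export
cv_config <- function(n_train = 245, n_test = 112, n_repeats = 10, seed = 1,
                      t_split = 10, traits = c("WU", "PSA"),
                      genetic_order = 2, fixed_order = 2, pe_order = 2,
                      gibbs = list(n_iter = 4000, burn_in = 1500, thin = 5),
                      ridge = 1e-6,
                      models = c("ST-RRM", "MT-RRM1", "MT-RRM2"),
                      fixed_comps = NULL) {
  models <- match.arg(models, several.ok = TRUE)
  structure(list(n_train = n_train, n_test = n_test, n_repeats = n_repeats,
                 seed = seed, t_split = t_split, traits = traits,
                 genetic_order = genetic_order, fixed_order = fixed_order,
                 pe_order = pe_order, gibbs = gibbs, ridge = ridge,
                 models = models, fixed_comps = fixed_comps),
            class = "cv_config")
}

# Observed values of one trait as an ids x days matrix.
.wide_values <- function(phenos, ids, trait, days) {
  sub <- phenos[phenos$trait == trait & phenos$accession %in% ids &
                phenos$day %in% days, ]
  out <- matrix(NA_real_, length(ids), length(days),
                dimnames = list(ids, as.character(days)))
  out[cbind(match(sub$accession, ids), match(sub$day, days))] <- sub$value
  out
}

# Variance components for one model fit: fixed, or Gibbs posterior means.
.estimate_comps <- function(model, cfg, seed, which) {
  if (!is.null(cfg$fixed_comps)) {
    comps <- cfg$fixed_comps[[which]]
    if (is.null(comps)) stop("fixed_comps lacks element '", which, "'")
    return(comps)
  }
  g <- cfg$gibbs
  draws <- gibbs_rrm(model, gibbs_config(n_iter = g$n_iter,
                                         burn_in = g$burn_in,
                                         thin = g$thin, seed = seed))
  posterior_means(draws)
}

.cv_specs <- function(cfg) {
  list(st = rrm_spec(cfg$traits[1], fixed_order = cfg$fixed_order,
                     genetic_order = cfg$genetic_order,
                     pe_order = cfg$pe_order),
       mt = rrm_spec(cfg$traits, fixed_order = cfg$fixed_order,
                     genetic_order = cfg$genetic_order,
                     pe_order = cfg$pe_order))
}

.accuracy_rows <- function(scenario, mdl, rep, days, pred, obs, truth_mat) {
  acc_obs <- vapply(seq_along(days), function(i) {
    accuracy(pred[, i], obs[, i])
  }, numeric(1))
  out <- data.frame(scenario = scenario, model = mdl, rep = rep, day = days,
                    accuracy = acc_obs)
  if (!is.null(truth_mat)) {
    out$accuracy_true <- vapply(seq_along(days), function(i) {
      accuracy(pred[, i], truth_mat[rownames(pred), as.character(days[i])])
    }, numeric(1))
  }
  out
}

#' Cross-validation scenario 1: predicting unphenotyped accessions
#'
#' Per repeat, accessions are split at random into a training and a testing
#' set. Variance components are estimated on the training set (single-trait
#' for ST-RRM, bivariate shared by both MT models), and prediction runs at
#' those fixed components: ST-RRM and MT-RRM1 fit the training set and
#' project test genetic values through the relationship matrix; MT-RRM2
#' additionally carries the testing accessions' secondary-trait records in
#' the model and reads their target-trait genetic values directly from the
#' BLUP solutions. Accuracy per day is the Pearson correlation between
#' predicted genetic values and the observed target-trait values of the
#' testing set.
#'
#' @param phenos long-format phenotype table (accession, trait, day, value)
#'   of BLUEs.
#' @param grm relationship matrix over all accessions (unridged; the
#'   configured ridge is applied once here).
#' @param cfg a [cv_config()].
#' @param truth optional accessions x days matrix of true genetic values of
#'   the target trait (synthetic-data diagnostics); adds an `accuracy_true`
#'   column.
#' @return data.frame with columns `scenario`, `model`, `rep`, `day`,
#'   `accuracy` (and `accuracy_true`); repeat seeds are attached as
#'   attribute `"seeds"`.
#' @export
run_cv1 <- function(phenos, grm, cfg = cv_config(), truth = NULL) {
  G <- add_ridge(grm, cfg$ridge)
  ids <- rownames(G)
  if (cfg$n_train + cfg$n_test > length(ids)) {
    stop("split sizes exceed the number of accessions")
  }
  days <- sort(unique(phenos$day))
  basis <- legendre_basis(time_grid(days),
                          max(cfg$fixed_order, cfg$genetic_order,
                              cfg$pe_order))
  specs <- .cv_specs(cfg)
  target <- cfg$traits[1]

  set.seed(cfg$seed)
  rep_seeds <- sample.int(2147483646L, cfg$n_repeats)
  out <- list()
  for (r in seq_len(cfg$n_repeats)) {
    set.seed(rep_seeds[r])
    perm <- sample(ids)
    trn <- sort(perm[seq_len(cfg$n_train)])
    tst <- sort(perm[cfg$n_train + seq_len(cfg$n_test)])
    gseeds <- sample.int(2147483646L, 2)
    ph_trn <- phenos[phenos$accession %in% trn, ]
    ph_wu_trn <- ph_trn[ph_trn$trait == target, ]
    obs <- .wide_values(phenos, tst, target, days)
    preds <- list()

    if ("ST-RRM" %in% cfg$models) {
      m_st <- build_design(ph_wu_trn, basis, specs$st, G[trn, trn])
      comps <- .estimate_comps(m_st, cfg, gseeds[1], "st")
      sols <- solve_mme(m_st, comps)
      preds[["ST-RRM"]] <- predict_unphenotyped(G, trn, tst, sols, basis)
    }
    if (any(c("MT-RRM1", "MT-RRM2") %in% cfg$models)) {
      m_mt <- build_design(ph_trn, basis, specs$mt, G[trn, trn])
      comps_mt <- .estimate_comps(m_mt, cfg, gseeds[2], "mt")
      if ("MT-RRM1" %in% cfg$models) {
        sols1 <- solve_mme(m_mt, comps_mt)
        preds[["MT-RRM1"]] <- predict_unphenotyped(G, trn, tst, sols1, basis,
                                                   trait = 1)
      }
      if ("MT-RRM2" %in% cfg$models) {
        ph2 <- rbind(ph_trn,
                     phenos[phenos$accession %in% tst &
                            phenos$trait == cfg$traits[2], ])
        both <- c(trn, tst)
        m2 <- build_design(ph2, basis, specs$mt, G[both, both])
        sols2 <- solve_mme(m2, comps_mt)
        preds[["MT-RRM2"]] <- genetic_values(sols2, basis,
                                             trait = 1)[tst, , drop = FALSE]
      }
    }
    for (mdl in names(preds)) {
      out[[length(out) + 1]] <-
        .accuracy_rows("CV1", mdl, r, days, preds[[mdl]], obs, truth)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "seeds") <- rep_seeds
  res
}

#' Cross-validation scenario 2: forecasting future time points
#'
#' Per repeat, a panel of known accessions is sampled; models are trained on
#' their early records only (target trait up to day `t_split`; the secondary
#' trait up to `t_split` for MT-RRM1 and over all days for MT-RRM2), and the
#' genetic values of the target trait at the remaining days are forecast by
#' evaluating the fitted random regressions at those days. Accuracy per day
#' is the Pearson correlation between forecasts and the observed values of
#' the same accessions at days after `t_split`.
#'
#' @inheritParams run_cv1
#' @return data.frame as in [run_cv1()], days after `t_split` only.
#' @export
run_cv2 <- function(phenos, grm, cfg = cv_config(), truth = NULL) {
  G <- add_ridge(grm, cfg$ridge)
  ids <- rownames(G)
  if (cfg$n_train > length(ids)) {
    stop("split sizes exceed the number of accessions")
  }
  days <- sort(unique(phenos$day))
  if (cfg$t_split >= length(days)) stop("t_split leaves no days to forecast")
  early <- days[seq_len(cfg$t_split)]
  late <- days[-seq_len(cfg$t_split)]
  basis <- legendre_basis(time_grid(days),
                          max(cfg$fixed_order, cfg$genetic_order,
                              cfg$pe_order))
  specs <- .cv_specs(cfg)
  target <- cfg$traits[1]

  set.seed(cfg$seed)
  rep_seeds <- sample.int(2147483646L, cfg$n_repeats)
  out <- list()
  for (r in seq_len(cfg$n_repeats)) {
    set.seed(rep_seeds[r])
    sel <- sort(sample(ids, cfg$n_train))
    gseeds <- sample.int(2147483646L, 3)
    Gs <- G[sel, sel]
    ph_sel <- phenos[phenos$accession %in% sel, ]
    wu_early <- ph_sel[ph_sel$trait == target & ph_sel$day %in% early, ]
    psa_all <- ph_sel[ph_sel$trait == cfg$traits[2], ]
    psa_early <- psa_all[psa_all$day %in% early, ]
    obs <- .wide_values(phenos, sel, target, late)
    preds <- list()

    if ("ST-RRM" %in% cfg$models) {
      m <- build_design(wu_early, basis, specs$st, Gs)
      comps <- .estimate_comps(m, cfg, gseeds[1], "st")
      sols <- solve_mme(m, comps)
      preds[["ST-RRM"]] <- genetic_values(sols, basis, trait = 1,
                                          days = late)[sel, , drop = FALSE]
    }
    if ("MT-RRM1" %in% cfg$models) {
      m <- build_design(rbind(wu_early, psa_early), basis, specs$mt, Gs)
      comps <- .estimate_comps(m, cfg, gseeds[2], "mt")
      sols <- solve_mme(m, comps)
      preds[["MT-RRM1"]] <- genetic_values(sols, basis, trait = 1,
                                           days = late)[sel, , drop = FALSE]
    }
    if ("MT-RRM2" %in% cfg$models) {
      m <- build_design(rbind(wu_early, psa_all), basis, specs$mt, Gs)
      comps <- .estimate_comps(m, cfg, gseeds[3], "mt")
      sols <- solve_mme(m, comps)
      preds[["MT-RRM2"]] <- genetic_values(sols, basis, trait = 1,
                                           days = late)[sel, , drop = FALSE]
    }
    for (mdl in names(preds)) {
      out[[length(out) + 1]] <-
        .accuracy_rows("CV2", mdl, r, late, preds[[mdl]], obs, truth)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "seeds") <- rep_seeds
  res
}
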