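hier_design <- function(n = 150, p = 4, seed = 1, family = "lm",
                        beta = c(x1 = 0.4, x2 = 0.4),
                        interaction_beta = c("x1:x2" = 0.5)) {
  coh <- simulate_cohort(n = n, n_continuous = p, n_categorical = 0,
                         family = family, beta = beta,
                         interaction_beta = interaction_beta,
                         missing_rate = 0, unwanted_rate = 0, seed = seed)
  cc <- complete_cases(coh)
  list(cohort = cc,
       design = build_design(cc, exposure_names(cc), covariate_names(cc),
                             interactions = TRUE, intercept = TRUE))
}

test_that("every selected interaction's parents are selected mains", {
  violations <- 0
  fits <- 0
  for (seed in 1:12) {
    hd <- hier_design(n = 120, p = 4, seed = seed)
    path <- hier_lasso_path(hd$design, hd$cohort$PHENO, "lm", nlambda = 8,
                            lambda_min_ratio = 5e-3, tol = 1e-8,
                            max_iter = 500)
    for (i in seq_along(path$lambda)) {
      sel <- hier_selection(path, i)
      fits <- fits + 1
      if (nrow(sel$pairs) > 0) {
        parents <- unique(c(sel$pairs$a, sel$pairs$b))
        if (!all(parents %in% sel$mains)) violations <- violations + 1
      }
    }
  }
  expect_gt(fits, 50)
  expect_equal(violations, 0)
})

test_that("lambda above the path maximum shrinks every penalized group to zero", {
  hd <- hier_design(seed = 3)
  path <- hier_lasso_path(hd$design, hd$cohort$PHENO, "lm", nlambda = 3)
  big <- hier_lasso_path(hd$design, hd$cohort$PHENO, "lm",
                         lambda = max(path$lambda) * 2)
  pen <- hd$design$penalty_factor > 0
  expect_true(all(big$beta[pen, 1] == 0))
  sel <- hier_selection(big, 1)
  expect_length(sel$mains, 0)
  expect_equal(nrow(sel$pairs), 0)
})

test_that("FISTA solutions satisfy the group-lasso optimality conditions", {
  # KKT certificate on the latent (non-overlapping) formulation: for an
  # active group the smooth gradient must equal -lambda * s_g * theta/|theta|;
  # for an inactive group its gradient norm must not exceed lambda * s_g.
  for (seed in 1:4) {
    hd <- hier_design(n = 100, p = 3, seed = seed)
    path <- hier_lasso_path(hd$design, hd$cohort$PHENO, "lm", nlambda = 6,
                            tol = 1e-12, max_iter = 20000)
    ex <- path$expand
    Z <- ex$Z; y <- hd$cohort$PHENO; n <- nrow(Z)
    for (i in c(2, 4, 6)) {
      th <- path$theta[, i]; lam <- path$lambda[i]
      g <- crossprod(Z, drop(Z %*% th) - y)[, 1] / n
      expect_lt(max(abs(g[ex$unpen])), 1e-4)
      for (k in seq_along(ex$pen_groups)) {
        idx <- ex$pen_groups[[k]]
        nrm <- sqrt(sum(th[idx]^2))
        if (nrm > 0) {
          expect_lt(max(abs(g[idx] + lam * ex$s_g[k] * th[idx] / nrm)), 1e-4)
        } else {
          expect_lte(sqrt(sum(g[idx]^2)), lam * ex$s_g[k] + 1e-5)
        }
      }
    }
  }
})

test_that("with singleton groups and no interactions the group lasso is the lasso", {
  # strip the interaction groups: penalizing only the main-effect groups of
  # size 1 makes the group penalty an L1 penalty; compare with the
  # coordinate-descent lasso at the same lambda
  hd <- hier_design(n = 200, p = 3, seed = 6, interaction_beta = NULL)
  d <- hd$design
  d$groups$pairs <- list()
  keep <- d$term_map %in% c("(Intercept)", d$exposures, d$covariates) &
    !grepl(":", names(d$term_map))
  d$X <- d$X[, keep]; d$penalty_factor <- d$penalty_factor[keep]
  d$center <- d$center[keep]; d$scale <- d$scale[keep]
  d$term_map <- d$term_map[keep]
  d$groups$mains <- lapply(d$exposures, function(e)
    which(colnames(d$X) == e))
  names(d$groups$mains) <- d$exposures
  y <- hd$cohort$PHENO
  gp <- hier_lasso_path(d, y, "lm", lambda = c(0.2, 0.05), tol = 1e-14,
                        max_iter = 20000)
  en <- enet_path(d$X, y, "lm", alpha = 1, penalty_factor = d$penalty_factor,
                  lambda = c(0.2, 0.05))
  expect_equal(unname(gp$beta), unname(en$beta), tolerance = 1e-4)
  # objective values agree far more tightly than the iterates
  obj <- function(b, lam) {
    mean((y - drop(d$X %*% b))^2) / 2 + lam * sum(d$penalty_factor * abs(b))
  }
  for (i in 1:2) {
    expect_lt(abs(obj(gp$beta[, i], gp$lambda[i]) -
                  obj(en$beta[, i], gp$lambda[i])), 1e-8)
  }
})

test_that("the true interaction is recovered under a strong planted signal", {
  hits <- 0
  for (seed in 1:5) {
    hd <- hier_design(n = 600, p = 5, seed = 20 + seed)
    cv <- cv_hier_interaction_lasso(hd$design, hd$cohort$PHENO, "lm", k = 5,
                                    seed = seed, nlambda = 25,
                                    lambda_min_ratio = 1e-2, tol = 1e-8,
                                    max_iter = 800)
    found <- any(cv$selected_pairs$a == "x1" & cv$selected_pairs$b == "x2" |
                 cv$selected_pairs$a == "x2" & cv$selected_pairs$b == "x1")
    hits <- hits + found
  }
  expect_gte(hits, 4)
})

test_that("logistic group lasso runs and respects hierarchy", {
  hd <- hier_design(n = 300, p = 3, seed = 30, family = "logistic",
                    beta = c(x1 = 0.8, x2 = 0.8),
                    interaction_beta = c("x1:x2" = 0.8))
  cv <- cv_hier_interaction_lasso(hd$design, hd$cohort$PHENO, "logistic",
                                  k = 4, seed = 2, nlambda = 15,
                                  lambda_min_ratio = 1e-2, tol = 1e-8,
                                  max_iter = 500)
  if (nrow(cv$selected_pairs) > 0) {
    expect_true(all(c(cv$selected_pairs$a, cv$selected_pairs$b) %in%
                    cv$selected_mains))
  }
  expect_error(cv_hier_interaction_lasso(
    build_design(hd$cohort, exposure_names(hd$cohort)), hd$cohort$PHENO),
    "interaction groups")
})
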