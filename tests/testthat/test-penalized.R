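make_design <- function(n = 120, seed = 1, categorical = FALSE,
                        interactions = FALSE, family = "lm") {
  coh <- simulate_cohort(n = n, n_continuous = if (categorical) 2 else 4,
                         n_categorical = if (categorical) 1 else 0,
                         beta = c(x1 = 0.3, x2 = 0.3),
                         family = family, missing_rate = 0, unwanted_rate = 0,
                         seed = seed)
  cc <- complete_cases(coh)
  list(cohort = cc,
       design = build_design(cc, exposure_names(cc), covariate_names(cc),
                             interactions = interactions,
                             intercept = family != "cox"))
}

test_that("design expansion: dummy coding, standardization, interaction groups", {
  md <- make_design(categorical = TRUE, interactions = TRUE)
  d <- md$design
  # categorical exposure with 3 levels -> 2 dummy columns, reference dropped
  expect_equal(sum(d$term_map == "c1"), 2)
  expect_true(all(grepl("^c1=", names(d$term_map)[d$term_map == "c1"])))
  # penalized columns standardized
  pen <- d$penalty_factor > 0
  expect_true(all(abs(colMeans(d$X[, pen])) < 1e-10))
  expect_true(all(abs(apply(d$X[, pen], 2, sd) - 1) < 1e-10))
  # covariates unpenalized and unstandardized
  expect_true(all(d$penalty_factor[d$term_map %in% c("age", "sex")] == 0))
  # 3 exposures -> 3 main groups + choose(3,2) interaction groups
  expect_length(d$groups$mains, 3)
  expect_length(d$groups$pairs, 3)
  # a continuous-continuous interaction group has 2 mains + 1 product column
  g <- d$groups$pairs[["x1:x2"]]
  expect_length(g$cols, 3)
  expect_length(g$prod_cols, 1)
})

test_that("constant exposures are dropped with a warning; all-constant errors", {
  d <- data.frame(ID = 1:20, PHENO = rnorm(20), flat = rep(1, 20),
                  x = rnorm(20))
  coh <- cohort(d, "lm", c(flat = "exposure", x = "exposure"))
  expect_warning(ds <- build_design(coh, c("flat", "x")), "flat")
  expect_false("flat" %in% ds$exposures)
  coh2 <- cohort(d[, -4], "lm", c(flat = "exposure"))
  expect_error(suppressWarnings(build_design(coh2, "flat")), "constant")
})

test_that("all penalized coefficients are exactly zero at and above lambda_max", {
  md <- make_design(seed = 3)
  d <- md$design
  y <- md$cohort$PHENO
  # analytic KKT bound, written from the formula (intercept + covariates
  # unpenalized; residual from their fit)
  unpen <- d$penalty_factor == 0
  r0 <- residuals(lm.fit(d$X[, unpen, drop = FALSE], y))
  lmax <- max(abs(crossprod(d$X[, !unpen], r0))) / nrow(d$X)
  expect_equal(as.numeric(pxscan:::enet_lambda_max(d$X, y, "lm", 1, d$penalty_factor)),
               lmax, tolerance = 1e-8)
  fit <- enet_path(d$X, y, "lm", alpha = 1, penalty_factor = d$penalty_factor,
                   lambda = c(lmax * 2, lmax))
  expect_true(all(fit$beta[!unpen, ] == 0))
})

test_that("orthonormal lasso equals the soft-threshold closed form", {
  set.seed(21)
  n <- 64; p <- 6
  Q <- qr.Q(qr(matrix(rnorm(n * p), n, p))) * sqrt(n)  # crossprod(Q)/n = I
  colnames(Q) <- paste0("v", 1:p)
  y <- rnorm(n, sd = 2)
  ols <- crossprod(Q, y)[, 1] / n
  for (lam in c(0.05, 0.2, 0.5)) {
    fit <- enet_path(Q, y, "lm", alpha = 1, lambda = lam)
    expect_equal(unname(fit$beta[, 1]),
                 unname(sign(ols) * pmax(abs(ols) - lam, 0)),
                 tolerance = 1e-6)
  }
})

test_that("the unpenalized limit agrees with the GLM engines", {
  md <- make_design(seed = 5)
  d <- md$design; y <- md$cohort$PHENO
  fit <- enet_path(d$X, y, "lm", alpha = 1, penalty_factor = d$penalty_factor,
                   lambda = c(1, 0))
  ref <- fit_linear(d$X, y)
  expect_equal(unname(fit$beta[, 2]), unname(ref$beta), tolerance = 1e-4)

  mdl <- make_design(seed = 6, family = "logistic")
  dl <- mdl$design; yl <- mdl$cohort$PHENO
  fitl <- enet_path(dl$X, yl, "logistic", alpha = 1,
                    penalty_factor = dl$penalty_factor, lambda = c(1, 0))
  refl <- fit_logistic(dl$X, yl)
  expect_equal(unname(fitl$beta[, 2]), unname(refl$beta), tolerance = 1e-4)
})

test_that("coordinate-descent objective is non-increasing within every sweep sequence", {
  md <- make_design(seed = 7)
  d <- md$design; y <- md$cohort$PHENO
  fit <- enet_path(d$X, y, "lm", alpha = 1, penalty_factor = d$penalty_factor,
                   nlambda = 20, trace = TRUE)
  for (tr in attr(fit, "objective_trace")) {
    if (length(tr) > 1) expect_true(all(diff(tr) <= 1e-12))
  }
})

test_that("solutions satisfy the elastic-net KKT conditions", {
  for (seed in 1:5) {
    md <- make_design(seed = seed)
    d <- md$design; y <- md$cohort$PHENO
    alpha <- c(1, 0.5, 1, 0.5, 1)[seed]
    fit <- enet_path(d$X, y, "lm", alpha = alpha,
                     penalty_factor = d$penalty_factor, nlambda = 10)
    n <- nrow(d$X)
    for (i in c(3, 6, 10)) {
      b <- fit$beta[, i]; lam <- fit$lambda[i]
      g <- crossprod(d$X, drop(d$X %*% b) - y)[, 1] / n +
        lam * (1 - alpha) * d$penalty_factor * b
      for (j in seq_along(b)) {
        thr <- lam * alpha * d$penalty_factor[j]
        if (b[j] != 0 || thr == 0) {
          expect_lt(abs(g[j] + thr * sign(b[j])), 1e-6)
        } else {
          expect_lte(abs(g[j]), thr + 1e-6)
        }
      }
    }
  }
})

test_that("warm-started path solutions equal cold starts", {
  md <- make_design(seed = 9)
  d <- md$design; y <- md$cohort$PHENO
  path <- enet_path(d$X, y, "lm", alpha = 1,
                    penalty_factor = d$penalty_factor, nlambda = 12)
  for (i in c(4, 8, 12)) {
    cold <- enet_path(d$X, y, "lm", alpha = 1,
                      penalty_factor = d$penalty_factor,
                      lambda = path$lambda[i])
    expect_equal(unname(cold$beta[, 1]), unname(path$beta[, i]),
                 tolerance = 1e-6)
  }
})

test_that("fold assignment is deterministic and stratified", {
  f1 <- pxscan:::make_folds(100, 10, seed = 4, strata = rep(0:1, 50))
  f2 <- pxscan:::make_folds(100, 10, seed = 4, strata = rep(0:1, 50))
  expect_identical(f1, f2)
  tb <- table(f1, rep(0:1, 50))
  expect_true(all(tb == 5))  # perfectly balanced strata across folds
  expect_error(pxscan:::make_folds(5, 10, seed = 1), "exceeds")
})

test_that("cross-validated lasso agrees with glmnet on selection and weights", {
  skip_if_not_installed("glmnet")
  md <- make_design(n = 400, seed = 13)
  d <- md$design; y <- md$cohort$PHENO
  cv <- cv_elastic_net(d, y = y, family = "lm", k = 5, seed = 2)
  # glmnet as independent cross-check at the same effective penalty
  # (glmnet rescales penalty.factor to sum to the number of columns)
  pf <- d$penalty_factor[-1]
  g <- glmnet::glmnet(d$X[, -1], y, family = "gaussian", alpha = 1,
                      penalty.factor = pf,
                      lambda = cv$lambda_min * sum(pf) / length(pf),
                      standardize = FALSE, thresh = 1e-12)
  gb <- as.numeric(g$beta)
  mine <- cv$beta_std[-1]
  expect_equal(unname(mine), gb, tolerance = 1e-4)
})

test_that("Cox penalized path recovers a strong effect and respects lambda_max", {
  coh <- simulate_cohort(n = 500, n_continuous = 4, n_categorical = 0,
                         family = "cox", beta = c(x1 = 0.8),
                         missing_rate = 0, unwanted_rate = 0, seed = 17)
  cc <- complete_cases(coh)
  d <- build_design(cc, exposure_names(cc), covariate_names(cc),
                    intercept = FALSE)
  cv <- cv_elastic_net(d, time = cc$TIME, event = cc$PHENO, family = "cox",
                       k = 5, seed = 3, nlambda = 40)
  expect_true("x1" %in% cv$selected_exposures)
  # top of the path: all penalized coefficients zero
  path <- enet_path(d$X, family = "cox", alpha = 1,
                    penalty_factor = d$penalty_factor, nlambda = 5,
                    time = cc$TIME, event = cc$PHENO)
  expect_true(all(path$beta[d$penalty_factor > 0, 1] == 0))
  # unpenalized limit vs the Efron engine (no ties in simulated times)
  low <- enet_path(d$X, family = "cox", alpha = 1,
                   penalty_factor = d$penalty_factor,
                   lambda = c(1, 1e-6), time = cc$TIME, event = cc$PHENO)
  ref <- fit_cox(d$X, cc$TIME, cc$PHENO)
  expect_equal(unname(low$beta[, 2]), unname(ref$beta), tolerance = 1e-3)
})
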