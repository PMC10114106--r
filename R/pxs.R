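#' Derive a polyexposure risk score (main effects)
#'
#' The three-group PXS derivation.  Step 1, on Group A: cross-validated
#' elastic-net (lasso by default) selection over the candidate exposures,
#' keeping every exposure with a nonzero coefficient at `lambda_min`.
#' Step 2, on Group B: backward stepwise calibration of an unpenalized
#' multivariable model over the Step-1 survivors, iteratively removing the
#' least significant exposure until only independently significant
#' exposures (at `p_threshold`, default 0.05) remain; covariates are
#' forced in throughout and never removed.  The returned model's score is
#' a weighted sum of the retained exposure terms with weights from the
#' final Group-B fit; score individuals in the held-out Group C with
#' [score_pxs()] and assess with [assess_prediction()].
#'
#' Exposures are ideally pre-filtered to the significant hits of a
#' preceding [xwas()] scan, which minimizes the sample lost to
#' complete-case filtering in the selection step.
#'
#' @param x a [cohort()].
#' @param split a [split_groups()] result; Groups A and B must be
#'   non-empty.
#' @param exposures candidate exposures (default: all exposures).
#' @param covariates adjustment columns (default: all covariates), always
#'   unpenalized and exempt from removal.
#' @param alpha elastic-net mixing (1 = lasso, default).
#' @param k CV folds (default 10).
#' @param p_threshold stepwise retention threshold (default 0.05).
#' @param max_iterations stepwise iteration cap.
#' @param seed RNG seed (CV fold partition).
#' @param nlambda,lambda_min_ratio penalty-path geometry.
#' @return An object of class `pxs_model`; see [score_pxs()].
#' @export
pxs <- function(x, split, exposures = NULL, covariates = NULL, alpha = 1,
                k = 10L, p_threshold = 0.05, max_iterations = 100L,
                seed = 1L, nlambda = 100L, lambda_min_ratio = 1e-3) {
  stopifnot(inherits(x, "cohort"), inherits(split, "group_split"))
  family <- cohort_family(x)
  exposures <- exposures %||% exposure_names(x)
  covariates <- covariates %||% covariate_names(x)
  fail_if(length(split$ids_a) == 0, "Group A is empty")
  fail_if(length(split$ids_b) == 0, "Group B is empty")

  # Step 1 (Group A): penalized selection
  sub_a <- complete_cases(cohort_subset(x, x$ID %in% split$ids_a),
                          c(exposures, covariates))
  design_a <- build_design(sub_a, exposures, covariates,
                           intercept = family != "cox")
  cv <- cv_elastic_net(design_a,
                       y = if (family != "cox") sub_a$PHENO else NULL,
                       time = if (family == "cox") sub_a$TIME else NULL,
                       event = if (family == "cox") sub_a$PHENO else NULL,
                       family = family, alpha = alpha, k = k, seed = seed,
                       nlambda = nlambda,
                       lambda_min_ratio = lambda_min_ratio)
  survivors <- cv$selected_exposures
  fail_if(length(survivors) == 0,
          "the regularization step selected no exposure at lambda_min")

  # Step 2 (Group B): backward stepwise calibration
  sub_b <- cohort_subset(x, x$ID %in% split$ids_b)
  sw <- backward_stepwise(sub_b, survivors, covariates,
                          p_threshold = p_threshold,
                          max_iterations = max_iterations)

  model <- new_pxs_model(
    family = family, fit = sw$fit, cohort = sw$data,
    main_exposures = sw$retained, pairs = NULL, covariates = covariates,
    provenance = list(method = "pxs", alpha = alpha,
                      lambda_min = cv$lambda_min, k = k, seed = seed,
                      p_threshold = p_threshold,
                      n_a = nrow(sub_a), n_b = sw$fit$n_used,
                      step1_selected = survivors,
                      final_exposure_p = as.list(sw$exposure_p),
                      group_sizes = lengths(split)))
  model
}

#' Backward stepwise calibration
#'
#' Fits the multivariable model of all current candidate exposures plus
#' covariates, computes one p-value per exposure (Wald for a single term,
#' likelihood-ratio for a multi-level categorical), and while the worst
#' exposure p-value is at or above the threshold removes that single
#' exposure (ties broken by removing the later one in input order) and
#' refits.  Complete cases are taken once, on the initial candidate set,
#' so successive fits are nested on identical rows.  Covariates are never
#' removed.  A refit that fails after a removal drops the worst remaining
#' exposure with a logged diagnostic; failure of the first full fit is an
#' error.
#'
#' @param x a [cohort()] (typically the Group B subset).
#' @param candidates candidate exposure columns, non-empty.
#' @param covariates forced-in adjustment columns.
#' @param p_threshold retention threshold (default 0.05).
#' @param max_iterations iteration cap.
#' @return list with `fit` (the final `fit_result`), `retained`
#'   (exposures in the final model), `removed` (in removal order), and
#'   `data` (the complete-case cohort the fits used).
#' @export
backward_stepwise <- function(x, candidates, covariates = character(),
                              p_threshold = 0.05, max_iterations = 100L) {
  stopifnot(inherits(x, "cohort"))
  fail_if(length(candidates) == 0, "no candidate exposures")
  fail_if(p_threshold <= 0 || p_threshold > 1,
          "p_threshold must lie in (0, 1]")
  family <- cohort_family(x)
  sub <- complete_cases(x, c(candidates, covariates))
  current <- candidates
  removed <- character()
  first <- TRUE
  last_p <- NULL
  for (it in seq_len(max_iterations)) {
    fit <- tryCatch(fit_exposure_model(sub, current, covariates, family),
                    error = function(e) e)
    failed <- inherits(fit, "error") || !fit$fit$converged
    if (failed) {
      fail_if(first, "initial calibration fit failed: %s",
              if (inherits(fit, "error")) conditionMessage(fit) else "did not converge")
      worst <- if (!is.null(last_p)) {
        names(last_p)[which(names(last_p) %in% current)][
          which.max(last_p[names(last_p) %in% current])]
      } else current[length(current)]
      message(sprintf("stepwise: refit failed; removing '%s'", worst))
      removed <- c(removed, worst)
      current <- setdiff(current, worst)
      fail_if(length(current) == 0, "no exposure survives calibration")
      next
    }
    first <- FALSE
    p_vec <- fit$exposure_p
    last_p <- p_vec
    if (max(p_vec) < p_threshold) {
      return(list(fit = fit$fit, retained = current, removed = removed,
                  data = sub, exposure_p = p_vec))
    }
    worst_val <- max(p_vec)
    tied <- names(p_vec)[p_vec == worst_val]
    worst <- tied[which.max(match(tied, candidates))]  # later input order first
    removed <- c(removed, worst)
    current <- setdiff(current, worst)
    fail_if(length(current) == 0, "no exposure survives calibration")
  }
  stop("stepwise calibration did not terminate within max_iterations",
       call. = FALSE)
}

# multivariable fit of exposures + covariates with one p-value per exposure
fit_exposure_model <- function(sub, exposures, covariates, family) {
  ed <- expand_terms(sub, exposures)
  cd <- if (length(covariates) > 0) expand_terms(sub, covariates) else NULL
  Xc <- if (is.null(cd)) NULL else cd$X
  has_int <- family != "cox"
  design <- if (has_int) cbind(`(Intercept)` = 1, ed$X, Xc) else cbind(ed$X, Xc)
  fit <- fit_family(design, sub, family)
  p_vec <- stats::setNames(numeric(length(exposures)), exposures)
  for (e in exposures) {
    e_terms <- names(ed$map)[ed$map == e]
    if (length(e_terms) == 1) {
      p_vec[e] <- unname(fit$wald_p[e_terms])
    } else {
      keep <- setdiff(colnames(design), e_terms)
      red <- fit_family(design[, keep, drop = FALSE], sub, family)
      p_vec[e] <- likelihood_ratio_test(fit, red)
    }
  }
  list(fit = fit, exposure_p = p_vec, term_map = ed$map)
}

fit_family <- function(design, sub, family) {
  switch(family,
         lm = fit_linear(design, sub$PHENO),
         logistic = fit_logistic(design, sub$PHENO),
         cox = fit_cox(design, sub$TIME, sub$PHENO))
}

#' Derive a polyexposure risk score with pairwise interactions
#'
#' The interaction-aware variant.  Step 1, on Group A: hierarchical
#' group-lasso selection over all exposure pairs
#' ([cv_hier_interaction_lasso()]); for a survival cohort the selection
#' runs as a logistic model on the event indicator, since the group-lasso
#' loss is linear/logistic only.  Step 2, on Group B: the selected main
#' effects and product terms plus covariates are recalibrated in a single
#' unpenalized model of the designated family (a Cox model for survival
#' cohorts) — there is no stepwise pruning in this variant.  Product
#' terms are products of the two parents' standardized values, with
#' standardization constants taken from the Group-B calibration data and
#' stored in the model for scoring.
#'
#' @inheritParams pxs
#' @param tol,max_iter FISTA convergence controls.
#' @return An object of class `pxs_model` satisfying strong hierarchy:
#'   both parents of every interaction term are present as main effects.
#' @export
pxs_gl <- function(x, split, exposures = NULL, covariates = NULL, k = 10L,
                   seed = 1L, nlambda = 100L, lambda_min_ratio = 1e-3,
                   tol = 1e-9, max_iter = 2000L) {
  stopifnot(inherits(x, "cohort"), inherits(split, "group_split"))
  family <- cohort_family(x)
  exposures <- exposures %||% exposure_names(x)
  covariates <- covariates %||% covariate_names(x)
  fail_if(length(split$ids_a) == 0, "Group A is empty")
  fail_if(length(split$ids_b) == 0, "Group B is empty")
  family_eff <- if (family == "lm") "lm" else "logistic"

  sub_a <- complete_cases(cohort_subset(x, x$ID %in% split$ids_a),
                          c(exposures, covariates))
  design_a <- build_design(sub_a, exposures, covariates,
                           interactions = TRUE, intercept = TRUE)
  cv <- cv_hier_interaction_lasso(design_a, y = sub_a$PHENO,
                                  family = family_eff, k = k, seed = seed,
                                  nlambda = nlambda,
                                  lambda_min_ratio = lambda_min_ratio,
                                  tol = tol, max_iter = max_iter)
  mains <- cv$selected_mains
  pairs <- cv$selected_pairs
  fail_if(length(mains) == 0,
          "the group-lasso step selected no exposure at lambda_min")

  # Step 2 (Group B): recalibrate in the designated family
  sub_b <- complete_cases(cohort_subset(x, x$ID %in% split$ids_b),
                          c(mains, covariates))
  recal <- build_recalibration_design(sub_b, mains, pairs, covariates,
                                      intercept = family != "cox")
  fit <- fit_family(recal$design, sub_b, family)

  model <- new_pxs_model(
    family = family, fit = fit, cohort = sub_b, main_exposures = mains,
    pairs = pairs, covariates = covariates, product_info = recal$products,
    provenance = list(method = "pxs_gl", lambda_min = cv$lambda_min,
                      k = k, seed = seed, family_effective = family_eff,
                      n_a = nrow(sub_a), n_b = fit$n_used,
                      group_sizes = lengths(split)))
  model
}

# Raw dummy mains + standardized-product interaction terms + covariates.
# Aliased product columns are dropped with a warning (rank repair).
build_recalibration_design <- function(sub, mains, pairs, covariates,
                                       intercept = TRUE) {
  ed <- expand_terms(sub, mains)
  products <- NULL
  P <- NULL
  if (!is.null(pairs) && nrow(pairs) > 0) {
    prod_cols <- list(); prod_rows <- list()
    for (r in seq_len(nrow(pairs))) {
      ta <- names(ed$map)[ed$map == pairs$a[r]]
      tb <- names(ed$map)[ed$map == pairs$b[r]]
      for (a in ta) for (b in tb) {
        va <- ed$X[, a]; vb <- ed$X[, b]
        ca <- mean(va); sa <- stats::sd(va)
        cb <- mean(vb); sb <- stats::sd(vb)
        if (sa == 0 || sb == 0) next
        nm <- paste0(a, ":", b)
        lvl_a <- if (startsWith(a, paste0(pairs$a[r], "=")))
          substring(a, nchar(pairs$a[r]) + 2L) else NA_character_
        lvl_b <- if (startsWith(b, paste0(pairs$b[r], "=")))
          substring(b, nchar(pairs$b[r]) + 2L) else NA_character_
        prod_cols[[nm]] <- ((va - ca) / sa) * ((vb - cb) / sb)
        prod_rows[[nm]] <- data.frame(
          term = nm, a_term = a, b_term = b,
          exposure_a = pairs$a[r], exposure_b = pairs$b[r],
          level_a = lvl_a, level_b = lvl_b,
          center_a = ca, scale_a = sa, center_b = cb, scale_b = sb,
          stringsAsFactors = FALSE)
      }
    }
    if (length(prod_cols) > 0) {
      P <- do.call(cbind, prod_cols)
      colnames(P) <- names(prod_cols)
      products <- do.call(rbind, c(prod_rows, list(make.row.names = FALSE)))
    }
  }
  cd <- if (length(covariates) > 0) expand_terms(sub, covariates) else NULL
  Xc <- if (is.null(cd)) NULL else cd$X
  design <- cbind(ed$X, P, Xc)
  if (intercept) design <- cbind(`(Intercept)` = 1, design)
  # rank repair: drop aliased product columns only
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    aliased <- colnames(design)[qr_d$pivot[(qr_d$rank + 1):ncol(design)]]
    droppable <- intersect(aliased, colnames(P) %||% character())
    fail_if(length(droppable) < length(aliased),
            "rank deficiency not attributable to product terms: %s",
            paste(setdiff(aliased, droppable), collapse = ", "))
    warning("dropping aliased product term(s): ",
            paste(droppable, collapse = ", "), call. = FALSE)
    design <- design[, setdiff(colnames(design), droppable), drop = FALSE]
    products <- products[!products$term %in% droppable, , drop = FALSE]
  }
  list(design = design, products = products, term_map = ed$map)
}

# --- the fitted-model container -------------------------------------------

new_pxs_model <- function(family, fit, cohort, main_exposures, pairs,
                          covariates, product_info = NULL, provenance) {
  lev <- cohort_levels(cohort)
  main_terms <- list()
  for (e in main_exposures) {
    if (e %in% names(lev)) {
      obs <- lev[[e]]
      for (l in obs[-1]) {
        nm <- paste0(e, "=", l)
        if (nm %in% fit$terms) {
          main_terms[[nm]] <- data.frame(term = nm, type = "main_cat",
                                         exposure = e, level = l,
                                         stringsAsFactors = FALSE)
        }
      }
    } else if (e %in% fit$terms) {
      main_terms[[e]] <- data.frame(term = e, type = "main_cont",
                                    exposure = e, level = NA_character_,
                                    stringsAsFactors = FALSE)
    }
  }
  terms <- do.call(rbind, c(main_terms, list(make.row.names = FALSE)))
  weights <- fit$beta[terms$term]
  if (!is.null(product_info) && nrow(product_info) > 0) {
    keep <- product_info$term %in% fit$terms
    product_info <- product_info[keep, , drop = FALSE]
    weights <- c(weights, fit$beta[product_info$term])
  }
  structure(list(family = family, exposures = main_exposures,
                 pairs = pairs, covariates = covariates,
                 terms = terms, products = product_info,
                 weights = weights, fit = fit,
                 level_sets = lev[intersect(names(lev),
                   union(main_exposures,
                         c(product_info$exposure_a, product_info$exposure_b)))],
                 provenance = provenance),
            class = "pxs_model")
}

#' @export
print.pxs_model <- function(x, ...) {
  cat(sprintf("pxs_model (%s, %s): %d exposures%s, %d score terms\n",
              x$provenance$method %||% "pxs", x$family, length(x$exposures),
              if (!is.null(x$pairs) && nrow(x$pairs) > 0)
                sprintf(" + %d interaction pairs", nrow(x$pairs)) else "",
              length(x$weights)))
  cat("  exposures: ", paste(x$exposures, collapse = ", "), "\n", sep = "")
  print(data.frame(weight = x$weights), ...)
  invisible(x)
}

#' Score individuals with a fitted PXS model
#'
#' The polyexposure risk score of an individual is the weighted sum of
#' the model's exposure terms (interaction terms included; covariate
#' terms and the intercept are excluded — covariates adjust, they do not
#' score).  Dummy coding, and the standardization constants of product
#' terms, are the ones stored at training time.  Individuals with a
#' missing value, an unwanted response or a categorical level unseen in
#' training on any model exposure are unscoreable and returned as `NA`.
#'
#' @param model a `pxs_model` from [pxs()] or [pxs_gl()].
#' @param x the [cohort()] subset to score (Group C in the standard
#'   pipeline).
#' @return A data frame of class `pxs_scores` with columns `ID`, `PXS`
#'   and attribute `n_unscoreable`.
#' @export
score_pxs <- function(model, x) {
  stopifnot(inherits(model, "pxs_model"), inherits(x, "cohort"))
  n <- nrow(x)
  needed <- unique(c(model$terms$exposure,
                     model$products$exposure_a, model$products$exposure_b))
  usable <- rep(TRUE, n)
  vals <- list()
  unwanted <- cohort_unwanted(x)
  for (e in needed) {
    v <- x[[e]]
    fail_if(is.null(v), "scoring cohort lacks model exposure '%s'", e)
    if (e %in% names(model$level_sets)) {
      v_chr <- as.character(v)
      bad <- is.na(v_chr) | v_chr %in% (unwanted[[e]] %||% character()) |
        !(v_chr %in% model$level_sets[[e]])
      usable <- usable & !bad
      vals[[e]] <- v_chr
    } else {
      usable <- usable & !is.na(v)
      vals[[e]] <- as.numeric(v)
    }
  }
  term_value <- function(type, exposure, level) {
    if (type == "main_cont") vals[[exposure]]
    else as.numeric(vals[[exposure]] == level)
  }
  score <- numeric(n)
  if (!is.null(model$terms)) {
    for (r in seq_len(nrow(model$terms))) {
      tr <- model$terms[r, ]
      tv <- term_value(tr$type, tr$exposure, tr$level)
      score <- score + model$weights[[tr$term]] * tv
    }
  }
  if (!is.null(model$products) && nrow(model$products) > 0) {
    main_val <- function(exposure, level) {
      if (!is.na(level)) as.numeric(vals[[exposure]] == level)
      else vals[[exposure]]
    }
    for (r in seq_len(nrow(model$products))) {
      pr <- model$products[r, ]
      za <- (main_val(pr$exposure_a, pr$level_a) - pr$center_a) / pr$scale_a
      zb <- (main_val(pr$exposure_b, pr$level_b) - pr$center_b) / pr$scale_b
      score <- score + model$weights[[pr$term]] * za * zb
    }
  }
  score[!usable] <- NA_real_
  out <- data.frame(ID = x$ID, PXS = score, stringsAsFactors = FALSE)
  attr(out, "n_unscoreable") <- sum(!usable)
  class(out) <- c("pxs_scores", "data.frame")
  out
}

#' Assess PXS prediction accuracy in a held-out group
#'
#' Fits `PHENO ~ PXS + covariates` on the evaluation cohort and reports
#' the family's goodness-of-fit metric — R-squared for linear models, AUC
#' of the fitted probabilities for logistic models, Harrell's C-index of
#' the linear predictor for Cox models — with a seeded percentile
#' bootstrap confidence interval.
#'
#' @param model a `pxs_model`.
#' @param scores a [score_pxs()] result for the evaluation cohort.
#' @param x the evaluation [cohort()] (Group C).
#' @param B bootstrap replicates for the CI.
#' @param ci_level confidence level.
#' @param seed RNG seed.
#' @return list with `metric`, `value`, `ci`, `n`, `fit`.
#' @export
assess_prediction <- function(model, scores, x, B = 1000L, ci_level = 0.95,
                              seed = 1L) {
  stopifnot(inherits(model, "pxs_model"), inherits(x, "cohort"))
  fail_if(nrow(x) == 0, "evaluation group is empty")
  m <- match(x$ID, scores$ID)
  s <- scores$PXS[m]
  keep <- !is.na(s)
  covs <- model$covariates
  if (length(covs) > 0) {
    cc <- rep(TRUE, nrow(x))
    for (col in covs) cc <- cc & !is.na(x[[col]])
    keep <- keep & cc
  }
  fail_if(sum(keep) == 0, "no scoreable individuals in the evaluation group")
  sub <- cohort_subset(x, keep)
  s <- s[keep]
  cd <- if (length(covs) > 0) expand_terms(sub, covs) else NULL
  Xc <- if (is.null(cd)) NULL else cd$X
  family <- model$family
  design <- if (family == "cox") cbind(PXS = s, Xc)
            else cbind(`(Intercept)` = 1, PXS = s, Xc)
  fit <- fit_family(design, sub, family)
  pred <- if (family == "logistic") fit$fitted else fit$linear_predictor
  metric_fun <- switch(family,
    lm = function(idx) r_squared(sub$PHENO[idx], pred[idx]),
    logistic = function(idx) auc(sub$PHENO[idx], pred[idx]),
    cox = function(idx) c_index(sub$TIME[idx], sub$PHENO[idx], pred[idx]))
  value <- metric_fun(seq_len(nrow(sub)))
  boots <- numeric(B)
  with_seed(seed, {
    for (b in seq_len(B)) {
      for (attempt in seq_len(100L)) {
        idx <- sample.int(nrow(sub), nrow(sub), replace = TRUE)
        res <- tryCatch(metric_fun(idx), error = function(e) NULL)
        if (!is.null(res)) break
        fail_if(attempt == 100L, "could not draw a valid bootstrap replicate")
      }
      boots[b] <- res
    }
  })
  ci <- stats::quantile(boots, c((1 - ci_level) / 2, 1 - (1 - ci_level) / 2),
                        names = FALSE, type = 7)
  list(metric = switch(family, lm = "r_squared", logistic = "auc",
                       cox = "c_index"),
       value = value, ci = ci, ci_level = ci_level, B = B, seed = seed,
       n = nrow(sub), fit = fit)
}

# --- JSON serialization ----------------------------------------------------

#' Serialize / restore a PXS model
#'
#' Writes the model — family, score terms and weights, dummy coding,
#' product standardization constants, covariates and provenance — as a
#' JSON document at full floating-point precision, and reads it back.
#' `read_pxs_model(write_pxs_model(m, path))` reproduces scores exactly.
#'
#' @param model a `pxs_model`.
#' @param path JSON file path.
#' @return `write_pxs_model()`: `path`, invisibly.  `read_pxs_model()`:
#'   the restored `pxs_model` (without the heavy `fit` component's
#'   linear-predictor vectors).
#' @export
write_pxs_model <- function(model, path) {
  stopifnot(inherits(model, "pxs_model"))
  fit_slim <- model$fit[c("family", "terms", "beta", "se", "wald_p",
                          "loglik", "n_used", "converged")]
  doc <- list(family = model$family, exposures = model$exposures,
              pairs = model$pairs, covariates = model$covariates,
              terms = model$terms, products = model$products,
              weights = as.list(model$weights),
              level_sets = model$level_sets,
              fit = fit_slim, provenance = model$provenance)
  # 17 significant digits guarantee exact double round-trip through text
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_pxs_model
#' @export
read_pxs_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  fit <- doc$fit
  fit_res <- new_fit_result(fit$family, fit$terms, unlist(fit$beta),
                            unlist(fit$se), unlist(fit$wald_p), fit$loglik,
                            fit$n_used, fit$converged)
  pairs <- doc$pairs
  if (!is.null(pairs) && length(pairs) == 0) pairs <- NULL
  products <- doc$products
  if (!is.null(products) && length(products) == 0) products <- NULL
  structure(list(family = doc$family, exposures = doc$exposures,
                 pairs = pairs, covariates = doc$covariates %||% character(),
                 terms = doc$terms, products = products,
                 weights = unlist(doc$weights),
                 level_sets = doc$level_sets, fit = fit_res,
                 provenance = doc$provenance),
            class = "pxs_model")
}

#' Write scores as TSV
#'
#' @param scores a [score_pxs()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
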