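#' Exposure-wide association scan
#'
#' Fits one covariate-adjusted model per exposure (`PHENO ~ exposure +
#' covariates` in the designated family), each on its own complete-case
#' subset with missing and unwanted responses removed, and corrects the
#' per-exposure p-values for multiple testing (Benjamini–Yekutieli by
#' default, which is valid under arbitrary dependence between exposures).
#'
#' Continuous exposures contribute their slope's Wald p-value; multi-level
#' categorical exposures contribute a single likelihood-ratio p-value for
#' all dummy terms jointly.  Exposures whose model fails (e.g. separation
#' in a logistic fit) are reported with `converged = FALSE` and excluded
#' from the correction, which reduces the number of tests accordingly.
#'
#' @param x a [cohort()].
#' @param exposures exposure columns to scan (default: all exposures).
#' @param covariates adjustment columns (default: all covariates); must be
#'   complete after filtering and disjoint from `exposures`.
#' @param correction `"BY"` (default), `"BH"` or `"bonferroni"`.
#' @param save_covariate_effects also return every model's covariate
#'   coefficients (the intermediate table of covariate effects)?
#' @return An object of class `xwas_result` with elements `table` (one
#'   row per exposure: `exposure`, `beta`, `se` — `NA` for multi-level
#'   categoricals — `p`, `p_adjusted`, `n_used`, `converged`), `terms`
#'   (one row per expanded term) and optionally `covariate_effects`.
#' @export
xwas <- function(x, exposures = NULL, covariates = NULL,
                 correction = c("BY", "BH", "bonferroni"),
                 save_covariate_effects = FALSE) {
  stopifnot(inherits(x, "cohort"))
  correction <- match.arg(correction)
  family <- cohort_family(x)
  exposures <- exposures %||% exposure_names(x)
  covariates <- covariates %||% covariate_names(x)
  fail_if(length(exposures) == 0, "empty exposure list")
  overlap <- intersect(exposures, covariates)
  fail_if(length(overlap) > 0, "exposure(s) also listed as covariates: %s",
          paste(overlap, collapse = ", "))

  rows <- vector("list", length(exposures))
  term_rows <- list(); cov_rows <- list()
  for (i in seq_along(exposures)) {
    e <- exposures[i]
    res <- tryCatch(
      xwas_one(x, e, covariates, family),
      error = function(err) list(error = conditionMessage(err)))
    if (!is.null(res$error) || !res$fit$converged) {
      rows[[i]] <- data.frame(exposure = e, beta = NA_real_, se = NA_real_,
                              p = NA_real_, n_used = res$n_used %||% NA_integer_,
                              converged = FALSE, stringsAsFactors = FALSE)
      next
    }
    fit <- res$fit
    e_terms <- res$exposure_terms
    single <- length(e_terms) == 1
    rows[[i]] <- data.frame(
      exposure = e,
      beta = if (single) unname(fit$beta[e_terms]) else NA_real_,
      se = if (single) unname(fit$se[e_terms]) else NA_real_,
      p = res$exposure_p, n_used = fit$n_used, converged = TRUE,
      stringsAsFactors = FALSE)
    term_rows[[e]] <- data.frame(
      exposure = e, term = e_terms, beta = unname(fit$beta[e_terms]),
      se = unname(fit$se[e_terms]), p = unname(fit$wald_p[e_terms]),
      n_used = fit$n_used, stringsAsFactors = FALSE)
    if (save_covariate_effects) {
      c_terms <- setdiff(fit$terms, c(e_terms, "(Intercept)"))
      if (length(c_terms) > 0) {
        cov_rows[[e]] <- data.frame(
          exposure = e, term = c_terms, beta = unname(fit$beta[c_terms]),
          se = unname(fit$se[c_terms]), p = unname(fit$wald_p[c_terms]),
          stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  tab$p_adjusted <- NA_real_
  ok <- tab$converged
  if (any(ok)) tab$p_adjusted[ok] <- adjust_pvalues(tab$p[ok], correction)
  rownames(tab) <- NULL
  bind_rows0 <- function(lst) {
    if (length(lst) == 0) return(NULL)
    do.call(rbind, c(lst, list(make.row.names = FALSE)))
  }
  out <- structure(list(table = tab, terms = bind_rows0(term_rows),
                        correction = correction, family = family),
                   class = "xwas_result")
  if (save_covariate_effects) out$covariate_effects <- bind_rows0(cov_rows)
  out
}

# one exposure: complete-case subset, family fit, single p-value
xwas_one <- function(x, exposure, covariates, family) {
  sub <- complete_cases(x, c(exposure, covariates))
  ed <- expand_terms(sub, exposure)
  fail_if(stats::sd(ed$X[, 1]) == 0 && ncol(ed$X) == 1,
          "exposure '%s' is constant after filtering", exposure)
  cd <- if (length(covariates) > 0) expand_terms(sub, covariates) else NULL
  Xc <- if (is.null(cd)) NULL else cd$X
  if (family == "cox") {
    design <- cbind(ed$X, Xc)
    fit <- fit_cox(design, sub$TIME, sub$PHENO)
    reduced <- function() {
      fail_if(is.null(Xc), "internal: null reduced model")  # handled below
      fit_cox(Xc, sub$TIME, sub$PHENO)
    }
    null_loglik <- function() cox_loglik_eta(rep(0, nrow(sub)), sub$TIME, sub$PHENO)
  } else {
    design <- cbind(`(Intercept)` = 1, ed$X, Xc)
    engine <- if (family == "lm") fit_linear else fit_logistic
    fit <- engine(design, sub$PHENO)
    reduced <- function() engine(cbind(`(Intercept)` = rep(1, nrow(sub)), Xc), sub$PHENO)
  }
  e_terms <- colnames(ed$X)
  if (length(e_terms) == 1) {
    p <- unname(fit$wald_p[e_terms])
  } else {
    red <- if (family == "cox" && is.null(Xc)) {
      # null Cox model: partial likelihood at beta = 0
      new_fit_result("cox", character(), numeric(), numeric(), numeric(),
                     loglik = cox_loglik_eta(rep(0, nrow(sub)), sub$TIME, sub$PHENO),
                     n_used = fit$n_used, converged = TRUE)
    } else reduced()
    p <- likelihood_ratio_test(fit, red)
  }
  list(fit = fit, exposure_terms = e_terms, exposure_p = p,
       n_used = fit$n_used)
}

#' Multiple-testing adjustment of p-values
#'
#' Adjusts raw p-values by the Benjamini–Yekutieli step-up procedure
#' (default; FDR control under arbitrary dependence, inflating the BH
#' adjustment by the harmonic factor \eqn{c(m)=\sum_{j=1}^m 1/j}), by
#' Benjamini–Hochberg, or by Bonferroni.  Delegates to
#' [stats::p.adjust()]; results are returned in the input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param method `"BY"`, `"BH"` or `"bonferroni"`.
#' @return The adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("BY", "BH", "bonferroni")) {
  method <- match.arg(method)
  fail_if(any(p < 0 | p > 1, na.rm = TRUE), "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = method)
}

#' @export
print.xwas_result <- function(x, ...) {
  tab <- x$table
  cat(sprintf("xwas_result (%s, %s correction): %d exposures, %d converged\n",
              x$family, x$correction, nrow(tab), sum(tab$converged)))
  print(utils::head(tab[order(tab$p), ], 10), ...)
  invisible(x)
}

#' Write scan results as TSV
#'
#' Emits one row per expanded exposure term plus one per-exposure summary
#' row (`term = "(overall)"`, carrying the single exposure p-value and its
#' adjustment), with columns `exposure`, `term`, `beta`, `se`, `p`,
#' `p_adjusted`, `n_used`, `converged`.
#'
#' @param x an [xwas()] result.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_xwas <- function(x, path) {
  stopifnot(inherits(x, "xwas_result"))
  summ <- transform(x$table, term = "(overall)")
  summ <- summ[, c("exposure", "term", "beta", "se", "p", "p_adjusted",
                   "n_used", "converged")]
  rows <- summ
  if (!is.null(x$terms) && nrow(x$terms) > 0) {
    tr <- x$terms
    tr$p_adjusted <- NA_real_
    tr$converged <- TRUE
    rows <- rbind(summ, tr[, names(summ)])
    rows <- rows[order(match(rows$exposure, x$table$exposure)), ]
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
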