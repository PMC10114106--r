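#' Unpenalized model engines
#'
#' [fit_linear()], [fit_logistic()] and [fit_cox()] fit one unpenalized
#' model on a term-expanded numeric design matrix and return a uniform
#' `fit_result`: per-term coefficients, standard errors, two-sided Wald
#' p-values and the maximized (partial) log-likelihood.  They are the
#' engine under the exposure-wide scan, backward stepwise calibration and
#' recalibration of selected models.
#'
#' The linear engine is exact least squares with standard errors from the
#' unbiased residual variance and t-based Wald p-values (n - p df); its
#' log-likelihood is the Gaussian ML value.  The logistic engine is IRLS
#' (via [stats::glm.fit()], tolerance 1e-8, up to 100 iterations) with
#' normal-approximation Wald p-values; complete separation is flagged, not
#' repaired: fits with fitted probabilities pinned at 0/1 or a diverging
#' standardized coefficient norm return `converged = FALSE` and must be
#' treated as unusable downstream.  The survival engine maximizes the Cox
#' partial likelihood with the Efron tie correction (via
#' [survival::coxph()]) and has no intercept.
#'
#' @param design numeric design matrix with named columns.  For `lm` and
#'   `logistic` it must contain the intercept column (named
#'   `"(Intercept)"`); for `cox` it must not.
#' @param y response: real-valued for `fit_linear`, 0/1 for `fit_logistic`.
#' @param time positive times to event or censoring.
#' @param event 0/1 event indicator.
#' @return An object of class `fit_result`: a list with `family`, `terms`,
#'   `beta`, `se`, `wald_p`, `loglik`, `n_used`, `converged` (and
#'   `linear_predictor` / `fitted` for reuse by callers).
#' @export
fit_linear <- function(design, y) {
  design <- as.matrix(design)
  n <- nrow(design); p <- ncol(design)
  stopifnot(length(y) == n)
  fail_if(n < p + 1, "need at least %d rows to fit %d terms", p + 1, p)
  qr_x <- qr(design)
  if (qr_x$rank < p) {
    bad <- colnames(design)[qr_x$pivot[(qr_x$rank + 1):p]]
    fail_if(TRUE, "design is rank deficient; collinear term(s): %s",
            paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qr_x, y)
  res <- y - drop(design %*% beta)
  rss <- sum(res^2)
  sigma2 <- rss / (n - p)
  xtx_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(pmax(diag(xtx_inv) * sigma2, 0))
  tval <- ifelse(se > 0, beta / se, 0)
  wald_p <- 2 * stats::pt(abs(tval), df = n - p, lower.tail = FALSE)
  # Gaussian ML log-likelihood (variance at its ML value rss/n)
  loglik <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  new_fit_result("lm", colnames(design), beta, se, wald_p, loglik, n,
                 converged = TRUE, linear_predictor = drop(design %*% beta),
                 fitted = drop(design %*% beta), df_resid = n - p)
}

#' @rdname fit_linear
#' @export
fit_logistic <- function(design, y) {
  design <- as.matrix(design)
  n <- nrow(design); p <- ncol(design)
  stopifnot(length(y) == n, all(y %in% c(0, 1)))
  fail_if(length(unique(y)) < 2, "y contains a single class")
  fail_if(n < p, "more terms than rows")
  qr_x <- qr(design)
  if (qr_x$rank < p) {
    bad <- colnames(design)[qr_x$pivot[(qr_x$rank + 1):p]]
    fail_if(TRUE, "design is rank deficient; collinear term(s): %s",
            paste(bad, collapse = ", "))
  }
  fit <- suppressWarnings(
    stats::glm.fit(design, y, family = stats::binomial(),
                   control = list(epsilon = 1e-8, maxit = 100)))
  beta <- fit$coefficients
  mu <- fit$fitted.values
  # fitted probabilities pinned at 0/1 are the operational signature of
  # complete or quasi-complete separation
  separation <- any(mu < 1e-10 | mu > 1 - 1e-10)
  w <- mu * (1 - mu)
  xtwx <- crossprod(design * sqrt(pmax(w, 0)))
  cov_ok <- !inherits(try(covb <- chol2inv(chol(xtwx)), silent = TRUE), "try-error")
  se <- if (cov_ok) sqrt(pmax(diag(covb), 0)) else rep(NA_real_, p)
  # separation also shows as a diverging coefficient on the standardized scale
  sds <- apply(design, 2, stats::sd)
  if (any(abs(beta * sds) > 50, na.rm = TRUE)) separation <- TRUE
  converged <- isTRUE(fit$converged) && !separation
  zval <- ifelse(!is.na(se) & se > 0, beta / se, 0)
  wald_p <- 2 * stats::pnorm(abs(zval), lower.tail = FALSE)
  eps <- 1e-12
  loglik <- sum(y * log(pmax(mu, eps)) + (1 - y) * log(pmax(1 - mu, eps)))
  out <- new_fit_result("logistic", colnames(design), beta, se, wald_p,
                        loglik, n, converged = converged,
                        linear_predictor = drop(design %*% beta), fitted = mu)
  if (separation) out$diagnostic <- "complete or quasi-complete separation detected"
  out
}

#' @rdname fit_linear
#' @export
fit_cox <- function(design, time, event) {
  design <- as.matrix(design)
  n <- nrow(design)
  stopifnot(length(time) == n, length(event) == n)
  fail_if(any(time <= 0), "all times must be positive")
  fail_if(!all(event %in% c(0, 1)), "event must be 0/1")
  fail_if(sum(event) == 0, "no events: the partial likelihood is undefined")
  fail_if("(Intercept)" %in% colnames(design),
          "the Cox model has no intercept term")
  const <- apply(design, 2, function(v) stats::sd(v) == 0)
  fail_if(any(const), "constant design column(s) give a flat partial likelihood: %s",
          paste(colnames(design)[const], collapse = ", "))
  X <- design  # name used inside the formula below
  fit <- survival::coxph(survival::Surv(time, event) ~ X, ties = "efron")
  beta <- fit$coefficients
  names(beta) <- sub("^X", "", names(beta))
  fail_if(anyNA(beta), "Cox fit dropped term(s) (singular design): %s",
          paste(names(beta)[is.na(beta)], collapse = ", "))
  se <- sqrt(diag(fit$var))
  zval <- ifelse(se > 0, beta / se, 0)
  wald_p <- 2 * stats::pnorm(abs(zval), lower.tail = FALSE)
  new_fit_result("cox", colnames(design), beta, se, wald_p,
                 loglik = fit$loglik[2], n_used = n,
                 converged = fit$iter < 100 && !anyNA(se),
                 linear_predictor = drop(design %*% beta),
                 fitted = drop(design %*% beta))
}

new_fit_result <- function(family, terms, beta, se, wald_p, loglik, n_used,
                           converged, linear_predictor = NULL, fitted = NULL,
                           df_resid = NULL) {
  beta <- stats::setNames(as.numeric(beta), terms)
  structure(list(family = family, terms = terms, beta = beta,
                 se = stats::setNames(as.numeric(se), terms),
                 wald_p = stats::setNames(as.numeric(wald_p), terms),
                 loglik = as.numeric(loglik), n_used = n_used,
                 converged = converged, linear_predictor = linear_predictor,
                 fitted = fitted, df_resid = df_resid),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result (%s): %d terms, n = %d, loglik = %.4f%s\n",
              x$family, length(x$terms), x$n_used, x$loglik,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(data.frame(beta = x$beta, se = x$se, p = x$wald_p,
                   row.names = x$terms), ...)
  invisible(x)
}

#' Likelihood-ratio test between nested fits
#'
#' Compares a full and a reduced model of the same family fitted to the
#' same individuals; used to obtain one p-value per multi-level
#' categorical exposure (all of its dummy terms jointly).
#'
#' @param full,reduced `fit_result` objects; `reduced`'s terms must be a
#'   subset of `full`'s and both must be fitted on the same rows.
#' @return The upper-tail chi-square p-value of twice the log-likelihood
#'   difference, with degrees of freedom equal to the term-count
#'   difference.
#' @export
likelihood_ratio_test <- function(full, reduced) {
  stopifnot(inherits(full, "fit_result"), inherits(reduced, "fit_result"))
  fail_if(full$family != reduced$family, "families differ: %s vs %s",
          full$family, reduced$family)
  fail_if(full$n_used != reduced$n_used,
          "fits use different numbers of rows (%d vs %d): not comparable",
          full$n_used, reduced$n_used)
  fail_if(!all(reduced$terms %in% full$terms),
          "reduced model is not nested in the full model")
  df <- length(full$terms) - length(reduced$terms)
  fail_if(df <= 0, "full model has no extra terms")
  dev <- max(2 * (full$loglik - reduced$loglik), 0)
  stats::pchisq(dev, df = df, lower.tail = FALSE)
}
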