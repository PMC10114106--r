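#' Elastic-net regularization path by cyclic coordinate descent
#'
#' Solves, for each `lambda` on a decreasing path,
#' \deqn{\min_\beta \; \bar\ell(\beta) \;+\;
#'   \lambda \sum_j w_j\big(\alpha|\beta_j| + \tfrac{1-\alpha}{2}\beta_j^2\big)}
#' where \eqn{\bar\ell} is the average negative log-likelihood of the
#' family (squared error / 2 for `lm`, binomial deviance / 2n for
#' `logistic`, the Breslow-approximated Cox partial deviance for `cox`)
#' and `w_j` is the per-column penalty factor (0 = unpenalized,
#' e.g. covariates and the intercept).  `alpha = 1` is the lasso
#' (default), `alpha = 0` ridge, values between give the elastic net.
#'
#' Gaussian problems are solved by covariance-updating cyclic coordinate
#' descent; logistic and Cox problems by an outer quadratic (IRLS)
#' approximation with the same inner loop, as is standard for penalized
#' GLMs.  Solutions along the path are warm-started.
#'
#' @param X numeric design matrix (including the intercept column for
#'   `lm`/`logistic`; penalized columns are assumed standardized by
#'   [build_design()]).
#' @param y response (real for `lm`, 0/1 for `logistic`; ignored for
#'   `cox`).
#' @param family `"lm"`, `"logistic"` or `"cox"`.
#' @param alpha elastic-net mixing parameter in `[0, 1]`; 1 = lasso.
#' @param penalty_factor per-column penalty weights; 0 means unpenalized.
#' @param lambda decreasing penalty sequence; if `NULL`, a 100-value
#'   log-spaced path from the analytic `lambda_max` (the smallest value
#'   with all penalized coefficients zero, from the KKT bound) down to
#'   `lambda_max * lambda_min_ratio`.
#' @param nlambda,lambda_min_ratio path length and ratio used when
#'   `lambda` is `NULL`.
#' @param time,event survival outcome (family `"cox"` only).
#' @param tol coordinate-descent convergence tolerance on the scaled
#'   coefficient change.
#' @param trace record the penalized objective after every sweep (exposed
#'   as attribute `objective_trace`, used to verify monotone descent).
#' @param warm_start optional coefficient vector initializing the first
#'   path point.
#' @return An object of class `enet_path`: list with `lambda`, `beta`
#'   (p x nlambda matrix), `alpha`, `penalty_factor`, `family`.
#' @export
enet_path <- function(X, y = NULL, family = c("lm", "logistic", "cox"),
                      alpha = 1, penalty_factor = NULL, lambda = NULL,
                      nlambda = 100L, lambda_min_ratio = 1e-3,
                      time = NULL, event = NULL, tol = 1e-9,
                      trace = FALSE, warm_start = NULL) {
  family <- match.arg(family)
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  pf <- penalty_factor %||% rep(1, p)
  stopifnot(length(pf) == p, alpha >= 0, alpha <= 1)
  if (family == "cox") {
    stopifnot(!is.null(time), !is.null(event))
    fail_if(sum(event) == 0, "no events")
  } else {
    stopifnot(length(y) == n)
  }
  fail_if(all(pf == 0), "no penalized columns")

  if (is.null(lambda)) {
    lmax <- enet_lambda_max(X, y, family, alpha, pf, time, event)
    lambda <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                      length.out = nlambda))
    # start from the unpenalized-block solution: the top of the path is
    # then the exact all-zero KKT point, not a numerical neighbour of it
    if (is.null(warm_start)) warm_start <- attr(lmax, "b0")
  }
  lambda <- sort(as.numeric(lambda), decreasing = TRUE)

  b <- warm_start %||% numeric(p)
  B <- matrix(0, p, length(lambda),
              dimnames = list(colnames(X), signif(lambda, 6)))
  traces <- if (trace) vector("list", length(lambda)) else NULL
  for (i in seq_along(lambda)) {
    sol <- switch(family,
      lm = cd_gaussian(X, y, b, lambda[i], alpha, pf, tol, trace),
      logistic = irls_penalized(X, y, b, lambda[i], alpha, pf, tol, trace,
                                family = "logistic"),
      cox = irls_penalized(X, NULL, b, lambda[i], alpha, pf, tol, trace,
                           family = "cox", time = time, event = event))
    b <- sol$beta
    B[, i] <- b
    if (trace) traces[[i]] <- sol$objective_trace
  }
  out <- structure(list(lambda = lambda, beta = B, alpha = alpha,
                        penalty_factor = pf, family = family),
                   class = "enet_path")
  if (trace) attr(out, "objective_trace") <- traces
  out
}

# Analytic lambda_max: gradient of the smooth loss at the unpenalized-only
# solution; for alpha = 0 the all-zero KKT bound is undefined and the path
# is anchored at the alpha = 0.001 bound.
enet_lambda_max <- function(X, y, family, alpha, pf, time = NULL, event = NULL) {
  n <- nrow(X)
  b0 <- numeric(ncol(X))
  if (any(pf == 0)) {
    # fit the unpenalized block alone (huge lambda freezes penalized cols at 0)
    sol <- switch(family,
      lm = cd_gaussian(X, y, b0, 1e10, 1, pf, 1e-10, FALSE),
      logistic = irls_penalized(X, y, b0, 1e10, 1, pf, 1e-10, FALSE, "logistic"),
      cox = irls_penalized(X, NULL, b0, 1e10, 1, pf, 1e-10, FALSE, "cox",
                           time = time, event = event))
    b0 <- sol$beta
  }
  g <- smooth_gradient(X, y, b0, family, time, event)
  a_eff <- max(alpha, 1e-3)
  j <- pf > 0
  structure(max(abs(g[j]) / (a_eff * pf[j])), b0 = b0)
}

# gradient of the average negative log-likelihood at beta
smooth_gradient <- function(X, y, beta, family, time = NULL, event = NULL) {
  n <- nrow(X)
  eta <- drop(X %*% beta)
  switch(family,
    lm = crossprod(X, eta - y)[, 1] / n,
    logistic = crossprod(X, stats::plogis(eta) - y)[, 1] / n,
    cox = -crossprod(X, cox_eta_derivs(eta, time, event)$g)[, 1] / n)
}

soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

# Cyclic coordinate descent for the quadratic (Gram-form) elastic-net
# subproblem, accelerated by exact active-face solves: a few cyclic
# sweeps settle the support and sign pattern, then the penalized
# quadratic is minimized exactly on that face by a linear solve, and the
# KKT conditions are verified globally.  The face minimizer can never
# increase the objective on the current support, so the per-sweep
# objective trace stays monotone.
cd_quadratic <- function(G, q, b, lambda, alpha, pf, tol, trace,
                         const_term = 0, max_sweeps = 10000L) {
  p <- length(q)
  Gb <- drop(G %*% b)
  l1 <- lambda * alpha * pf
  l2 <- lambda * (1 - alpha) * pf
  dG <- diag(G)
  denom <- dG + l2
  sq <- sqrt(pmax(dG, 1e-12))
  obj_trace <- if (trace) numeric() else NULL
  push_obj <- function() {
    if (trace) {
      obj <- const_term / 2 - sum(b * q) + sum(b * Gb) / 2 +
        lambda * sum(pf * (alpha * abs(b) + (1 - alpha) / 2 * b^2))
      obj_trace <<- c(obj_trace, obj)
    }
  }
  sweep_once <- function() {
    delta_max <- 0
    for (j in seq_len(p)) {
      bj <- b[j]
      num <- q[j] - Gb[j] + dG[j] * bj
      g1 <- l1[j]
      bn <- if (num > g1) (num - g1) / denom[j]
            else if (num < -g1) (num + g1) / denom[j] else 0
      if (bn != bj) {
        Gb <<- Gb + G[, j] * (bn - bj)
        b[j] <<- bn
        d <- abs(bn - bj) * sq[j]
        if (d > delta_max) delta_max <- d
      }
    }
    push_obj()
    delta_max
  }
  sweeps <- 0L
  while (sweeps < max_sweeps) {
    delta_max <- Inf
    for (i in 1:3) {
      delta_max <- sweep_once()
      sweeps <- sweeps + 1L
      if (delta_max < tol) break
    }
    if (delta_max < tol) break
    # exact solve on the current face (active support with fixed signs)
    A <- which(b != 0 | l1 == 0)
    if (length(A) > 0) {
      s <- sign(b[A])
      x <- tryCatch(
        solve(G[A, A, drop = FALSE] + diag(l2[A], length(A)),
              q[A] - l1[A] * s),
        error = function(e) NULL)
      if (!is.null(x)) {
        pen_act <- l1[A] > 0
        if (all(sign(x[pen_act]) == s[pen_act])) {
          b[A] <- x
          Gb <- drop(G %*% b)
          push_obj()
          # global KKT check: any inactive violator re-enters via sweeps
          viol <- b == 0 & l1 > 0 & abs(q - Gb) > l1 + tol
          if (!any(viol)) {
            delta_max <- sweep_once()   # final polishing sweep
            sweeps <- sweeps + 1L
            if (delta_max < tol) break
          }
        }
      }
    }
  }
  b[abs(b) < 1e-10] <- 0  # snap numerical zeros (exact at the KKT boundary)
  list(beta = b, objective_trace = obj_trace)
}

cd_gaussian <- function(X, y, b, lambda, alpha, pf, tol, trace) {
  n <- nrow(X)
  G <- crossprod(X) / n
  q <- crossprod(X, y)[, 1] / n
  cd_quadratic(G, q, b, lambda, alpha, pf, tol, trace,
               const_term = mean(y^2))
}

# Outer IRLS loop for logistic / Cox penalized fits: quadratic
# approximation of the loss at the current beta, solved by cd_quadratic.
# The diagonal-Hessian approximation used for the Cox loss converges
# linearly and can be slow; a secant extrapolation of the fixed point
# (accepted only when it improves the penalized objective) restores fast
# convergence.
irls_penalized <- function(X, y, b, lambda, alpha, pf, tol, trace, family,
                           time = NULL, event = NULL, max_outer = 200L) {
  n <- nrow(X)
  neg_obj <- function(bb) {           # penalized average negative loglik
    eta <- drop(X %*% bb)
    ll <- if (family == "logistic") {
      mu <- stats::plogis(eta)
      sum(y * log(pmax(mu, 1e-12)) + (1 - y) * log(pmax(1 - mu, 1e-12)))
    } else cox_loglik_eta(eta, time, event)
    -ll / n + lambda * sum(pf * (alpha * abs(bb) + (1 - alpha) / 2 * bb^2))
  }
  ll_old <- -Inf
  b_hist <- list()
  obj_trace <- if (trace) numeric() else NULL
  for (it in seq_len(max_outer)) {
    eta <- drop(X %*% b)
    if (family == "logistic") {
      mu <- stats::plogis(eta)
      w <- pmax(mu * (1 - mu), 1e-5)
      z <- eta + (y - mu) / w
      ll <- sum(y * log(pmax(mu, 1e-12)) + (1 - y) * log(pmax(1 - mu, 1e-12)))
    } else {
      d <- cox_eta_derivs(eta, time, event)
      w <- pmax(d$w, 1e-8)
      z <- eta + d$g / w
      ll <- d$loglik
    }
    Xw <- X * w
    G <- crossprod(X, Xw) / n
    q <- crossprod(X, w * z)[, 1] / n
    b_old <- b
    sol <- cd_quadratic(G, q, b, lambda, alpha, pf, tol, trace,
                        const_term = sum(w * z^2) / n)
    b <- sol$beta
    b_hist <- c(b_hist, list(b))
    if (length(b_hist) >= 3) {
      h <- length(b_hist)
      d1 <- b_hist[[h - 1]] - b_hist[[h - 2]]
      d2 <- b_hist[[h]] - b_hist[[h - 1]]
      den <- sum(d1 * d1)
      if (den > 0) {
        rho <- sum(d2 * d1) / den
        if (is.finite(rho) && rho > 0.2 && rho < 0.9999) {
          b_ext <- b + d2 * rho / (1 - rho)
          if (neg_obj(b_ext) < neg_obj(b)) {
            b <- b_ext
            b_hist <- list()
          }
        }
      }
    }
    if (trace) obj_trace <- c(obj_trace, neg_obj(b))
    if (max(abs(b - b_old)) < 1e-7 &&
        abs(ll - ll_old) < 1e-9 * (abs(ll_old) + 1e-9)) break
    ll_old <- ll
  }
  list(beta = b, objective_trace = obj_trace)
}

# First and (diagonal) second derivatives of the Breslow partial
# log-likelihood with respect to the linear predictor, plus its value.
cox_eta_derivs <- function(eta, time, event) {
  n <- length(eta)
  ord <- order(time)
  ts <- time[ord]; ev <- event[ord]; et <- exp(eta[ord] - max(eta))
  scale_back <- max(eta)
  # risk-set sums: all subjects with time >= t (tie blocks share one value)
  revcs <- rev(cumsum(rev(et)))
  block_start <- cummax(ifelse(!duplicated(ts), seq_len(n), 0L))
  S0 <- revcs[block_start]
  # cumulative event terms, inclusive of the subject's own tie block
  ev_over_S0 <- ev / S0
  ev_over_S02 <- ev / S0^2
  block_id <- cumsum(!duplicated(ts))
  a_block <- tapply(ev_over_S0, block_id, sum)
  b_block <- tapply(ev_over_S02, block_id, sum)
  cum_a <- cumsum(a_block)[block_id]
  cum_b <- cumsum(b_block)[block_id]
  g_s <- ev - et * cum_a
  w_s <- et * cum_a - et^2 * cum_b
  ll <- sum(ev * (log(et) + scale_back - log(S0) - scale_back))
  g <- numeric(n); w <- numeric(n)
  g[ord] <- g_s; w[ord] <- w_s
  list(g = g, w = w, loglik = ll)
}

# Breslow partial log-likelihood at a given linear predictor (used for
# cross-validated deviance in the Verweij-van Houwelingen form).
cox_loglik_eta <- function(eta, time, event) {
  cox_eta_derivs(eta, time, event)$loglik
}

#' Cross-validated elastic net
#'
#' Runs [enet_path()] with k-fold cross-validation, choosing the penalty
#' `lambda_min` that minimizes the mean cross-validated deviance
#' (squared-error loss for `lm`, binomial deviance for `logistic`, the
#' Verweij–van Houwelingen partial-likelihood deviance for `cox`).  Folds
#' are a seeded partition, stratified by outcome class for `logistic` and
#' by event status for `cox`.  Coefficients at `lambda_min` are reported
#' back-transformed to the original column scale.
#'
#' @param design a [build_design()] result.
#' @param y response vector (`lm`/`logistic`).
#' @param time,event survival outcome (`cox`).
#' @param family model family.
#' @param alpha elastic-net mixing parameter (1 = lasso, default).
#' @param k number of folds (default 10).
#' @param seed RNG seed controlling the fold partition.
#' @param nlambda,lambda_min_ratio path geometry (100 values down to
#'   1e-3 of `lambda_max` by default).
#' @return An object of class `cv_enet`: `lambda`, `cvm`, `cvsd`,
#'   `lambda_min`, `beta` (original scale, at `lambda_min`), `beta_std`,
#'   `selected_exposures`, `alpha`, `k`, `seed`, `family`, `design`.
#' @export
cv_elastic_net <- function(design, y = NULL, time = NULL, event = NULL,
                           family = c("lm", "logistic", "cox"), alpha = 1,
                           k = 10L, seed = 1L, nlambda = 100L,
                           lambda_min_ratio = 1e-3) {
  family <- match.arg(family)
  stopifnot(inherits(design, "design_spec"))
  X <- design$X
  n <- nrow(X)
  fail_if(family == "cox" && design$intercept,
          "Cox designs must be built with intercept = FALSE")
  pf <- design$penalty_factor

  lmax <- enet_lambda_max(X, y, family, alpha, pf, time, event)
  b0 <- attr(lmax, "b0")
  lambda <- exp(seq(log(as.numeric(lmax)), log(as.numeric(lmax) * lambda_min_ratio),
                    length.out = nlambda))

  full <- enet_path(X, y, family, alpha, pf, lambda,
                    time = time, event = event, warm_start = b0)

  strata <- switch(family, lm = NULL, logistic = y, cox = event)
  folds <- make_folds(n, k, seed, strata)
  dev <- matrix(NA_real_, k, length(lambda))
  for (f in seq_len(k)) {
    tr <- folds != f; te <- !tr
    fit_f <- enet_path(X[tr, , drop = FALSE], y[tr], family, alpha, pf,
                       lambda, time = time[tr], event = event[tr])
    for (i in seq_along(lambda)) {
      b <- fit_f$beta[, i]
      dev[f, i] <- switch(family,
        lm = mean((y[te] - drop(X[te, , drop = FALSE] %*% b))^2),
        logistic = {
          mu <- stats::plogis(drop(X[te, , drop = FALSE] %*% b))
          -2 * mean(y[te] * log(pmax(mu, 1e-12)) +
                    (1 - y[te]) * log(pmax(1 - mu, 1e-12)))
        },
        cox = {
          eta <- drop(X %*% b)
          -2 * (cox_loglik_eta(eta, time, event) -
                cox_loglik_eta(eta[tr], time[tr], event[tr]))
        })
    }
  }
  cvm <- colMeans(dev)
  cvsd <- apply(dev, 2, stats::sd) / sqrt(k)
  i_min <- which.min(cvm)
  beta_std <- full$beta[, i_min]
  beta <- backtransform_beta(beta_std, design)
  pen <- pf > 0
  sel_terms <- names(beta_std)[pen & beta_std != 0]
  sel <- unique(design$term_map[sel_terms])
  sel_main <- sel[!grepl(":", sel)]
  structure(list(lambda = lambda, cvm = cvm, cvsd = cvsd,
                 lambda_min = lambda[i_min], index_min = i_min,
                 beta = beta, beta_std = beta_std,
                 selected_exposures = intersect(design$exposures, sel_main),
                 alpha = alpha, k = k, seed = seed, family = family,
                 design = design),
            class = "cv_enet")
}

# map standardized-scale coefficients back to the original column scale
backtransform_beta <- function(beta_std, design) {
  b <- beta_std / design$scale
  if (design$intercept) {
    shift <- sum(beta_std * design$center / design$scale)
    b["(Intercept)"] <- beta_std["(Intercept)"] - shift
  }
  b
}

#' @export
print.cv_enet <- function(x, ...) {
  cat(sprintf("cv_enet (%s, alpha = %g, %d-fold): lambda_min = %.5g\n",
              x$family, x$alpha, x$k, x$lambda_min))
  cat(sprintf("  selected exposures (%d): %s\n",
              length(x$selected_exposures),
              paste(x$selected_exposures, collapse = ", ")))
  invisible(x)
}
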