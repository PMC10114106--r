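#' Hierarchical group lasso for pairwise exposure interactions
#'
#' Selects main effects and pairwise interactions under a *strong
#' hierarchy* guarantee: an interaction can enter the model only together
#' with both of its main effects.  The guarantee is obtained by
#' construction through an overlapped group lasso: every exposure has a
#' main-effect group, and every exposure pair has an interaction group
#' whose latent coefficient block contains copies of both mains' columns
#' plus their element-wise products.  The optimized objective is
#' \deqn{\bar\ell(\theta) + \lambda \sum_g s_g \lVert\theta_g\rVert_2,
#'   \qquad s_g = \sqrt{|g|},}
#' over the latent (column-duplicated) design; a nonzero interaction group
#' therefore necessarily carries its mains into the fitted model.  The
#' problem is convex and solved by proximal gradient descent (FISTA) with
#' the group soft-thresholding proximal step and adaptive restarts.
#' Covariates and the intercept are unpenalized.
#'
#' Only linear and logistic losses are supported; survival callers run the
#' selection as a logistic model on the event indicator and recalibrate a
#' Cox model afterwards (see [pxs_gl()]).
#'
#' @param design a [build_design()] result with `interactions = TRUE`.
#' @param y response (real for `lm`, 0/1 for `logistic`).
#' @param family `"lm"` or `"logistic"`.
#' @param lambda decreasing penalty sequence, or `NULL` for a log-spaced
#'   path from the group KKT bound.
#' @param nlambda,lambda_min_ratio path geometry when `lambda` is `NULL`.
#' @param tol relative-objective convergence tolerance for FISTA.
#' @param max_iter FISTA iteration cap per path point.
#' @return An object of class `hier_path`: `lambda`, `theta` (latent
#'   coefficients per path point), `beta` (summed per original column),
#'   group bookkeeping, and per-lambda `objective` values.
#' @export
hier_lasso_path <- function(design, y, family = c("lm", "logistic"),
                            lambda = NULL, nlambda = 100L,
                            lambda_min_ratio = 1e-3, tol = 1e-9,
                            max_iter = 2000L) {
  family <- match.arg(family)
  stopifnot(inherits(design, "design_spec"))
  fail_if(is.null(design$groups), "design has no interaction groups; build with interactions = TRUE")
  ex <- hier_expand(design)
  Z <- ex$Z
  n <- nrow(Z)
  y <- as.numeric(y)

  # Lipschitz constant of the smooth part
  G <- crossprod(Z) / n
  L <- max(1e-8, power_iter_eig(G))
  if (family == "logistic") L <- L / 4
  step <- 1 / L

  grad_fn <- function(theta) {
    eta <- drop(Z %*% theta)
    r <- if (family == "lm") eta - y else stats::plogis(eta) - y
    crossprod(Z, r)[, 1] / n
  }
  loss_fn <- function(theta) {
    eta <- drop(Z %*% theta)
    if (family == "lm") mean((y - eta)^2) / 2
    else -mean(y * log(pmax(stats::plogis(eta), 1e-12)) +
               (1 - y) * log(pmax(1 - stats::plogis(eta), 1e-12)))
  }
  pen_fn <- function(theta, lam) {
    s <- 0
    for (i in seq_along(ex$pen_groups)) {
      g <- ex$pen_groups[[i]]
      s <- s + ex$s_g[i] * sqrt(sum(theta[g]^2))
    }
    lam * s
  }

  if (is.null(lambda)) {
    theta0 <- hier_null_fit(Z, y, family, ex$unpen)
    g0 <- grad_fn(theta0)
    lmax <- max(vapply(seq_along(ex$pen_groups), function(i) {
      sqrt(sum(g0[ex$pen_groups[[i]]]^2)) / ex$s_g[i]
    }, numeric(1)))
    lambda <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                      length.out = nlambda))
  }
  lambda <- sort(as.numeric(lambda), decreasing = TRUE)

  P <- ncol(Z)
  theta <- numeric(P)
  Theta <- matrix(0, P, length(lambda))
  objective <- numeric(length(lambda))
  for (li in seq_along(lambda)) {
    lam <- lambda[li]
    x_k <- theta; z_k <- theta; t_k <- 1
    obj_old <- loss_fn(x_k) + pen_fn(x_k, lam)
    for (it in seq_len(max_iter)) {
      g <- grad_fn(z_k)
      x_new <- z_k - step * g
      # group soft-threshold proximal step (unpenalized coords untouched)
      for (i in seq_along(ex$pen_groups)) {
        gidx <- ex$pen_groups[[i]]
        nrm <- sqrt(sum(x_new[gidx]^2))
        thr <- step * lam * ex$s_g[i]
        x_new[gidx] <- if (nrm <= thr) 0 else x_new[gidx] * (1 - thr / nrm)
      }
      t_new <- (1 + sqrt(1 + 4 * t_k^2)) / 2
      z_k <- x_new + (t_k - 1) / t_new * (x_new - x_k)
      obj <- loss_fn(x_new) + pen_fn(x_new, lam)
      if (obj > obj_old) {       # adaptive restart of the momentum
        z_k <- x_new; t_new <- 1
      }
      done <- abs(obj_old - obj) < tol * (abs(obj_old) + 1e-12)
      x_k <- x_new; t_k <- t_new; obj_old <- min(obj_old, obj)
      if (done && it > 5) break
    }
    theta <- x_k
    Theta[, li] <- theta
    objective[li] <- obj_old
  }
  beta <- apply(Theta, 2, function(th) hier_collapse(th, ex, ncol(design$X)))
  rownames(beta) <- colnames(design$X)
  structure(list(lambda = lambda, theta = Theta, beta = beta,
                 objective = objective, expand = ex, family = family,
                 design = design),
            class = "hier_path")
}

# Latent column-duplicated design: unpenalized block + one block per main
# group + one block per interaction group (mains' copies + products).
hier_expand <- function(design) {
  X <- design$X
  gr <- design$groups
  unpen_cols <- which(design$penalty_factor == 0)
  map <- unpen_cols
  pen_groups <- list(); s_g <- numeric()
  for (nm in names(gr$mains)) {
    cols <- gr$mains[[nm]]
    pen_groups[[length(pen_groups) + 1L]] <- length(map) + seq_along(cols)
    s_g <- c(s_g, sqrt(length(cols)))
    map <- c(map, cols)
  }
  pair_group_index <- integer()
  for (nm in names(gr$pairs)) {
    cols <- gr$pairs[[nm]]$cols
    pen_groups[[length(pen_groups) + 1L]] <- length(map) + seq_along(cols)
    s_g <- c(s_g, sqrt(length(cols)))
    pair_group_index[nm] <- length(pen_groups)
    map <- c(map, cols)
  }
  list(Z = X[, map, drop = FALSE], map = map,
       unpen = seq_along(unpen_cols), pen_groups = pen_groups, s_g = s_g,
       pair_group_index = pair_group_index)
}

# total coefficient per original column = sum over latent copies
hier_collapse <- function(theta, ex, p) {
  b <- numeric(p)
  for (i in seq_along(ex$map)) b[ex$map[i]] <- b[ex$map[i]] + theta[i]
  b
}

# unpenalized-block-only fit to anchor lambda_max
hier_null_fit <- function(Z, y, family, unpen) {
  theta <- numeric(ncol(Z))
  if (length(unpen) > 0) {
    Z0 <- Z[, unpen, drop = FALSE]
    cf <- if (family == "lm") stats::lm.fit(Z0, y)$coefficients
          else stats::glm.fit(Z0, y, family = stats::binomial())$coefficients
    theta[unpen] <- ifelse(is.na(cf), 0, cf)
  }
  theta
}

power_iter_eig <- function(G, iters = 200L, tol = 1e-10) {
  v <- rep(1, ncol(G)) / sqrt(ncol(G))
  ev <- 0
  for (i in seq_len(iters)) {
    w <- drop(G %*% v)
    ev_new <- sqrt(sum(w^2))
    if (ev_new == 0) return(0)
    v <- w / ev_new
    if (abs(ev_new - ev) < tol * ev_new) break
    ev <- ev_new
  }
  ev_new
}

#' Cross-validated hierarchical interaction lasso
#'
#' k-fold cross-validation over the [hier_lasso_path()] penalty path,
#' choosing `lambda_min` by mean CV deviance (folds seeded and stratified
#' by outcome for logistic loss, exactly as in [cv_elastic_net()]).  The
#' selection at `lambda_min` is reported as main effects plus interaction
#' pairs; by the overlapped-group construction every reported pair's two
#' parent exposures are reported mains.
#'
#' @inheritParams hier_lasso_path
#' @param k number of folds.
#' @param seed RNG seed for the fold partition.
#' @inheritParams cv_elastic_net
#' @return An object of class `cv_hier`: `lambda`, `cvm`, `cvsd`,
#'   `lambda_min`, latent and collapsed coefficients at `lambda_min`,
#'   `selected_mains`, `selected_pairs`, fold/seed provenance.
#' @export
cv_hier_interaction_lasso <- function(design, y, family = c("lm", "logistic"),
                                      k = 10L, seed = 1L, nlambda = 100L,
                                      lambda_min_ratio = 1e-3, tol = 1e-9,
                                      max_iter = 2000L) {
  family <- match.arg(family)
  full <- hier_lasso_path(design, y, family, nlambda = nlambda,
                          lambda_min_ratio = lambda_min_ratio, tol = tol,
                          max_iter = max_iter)
  lambda <- full$lambda
  X <- design$X
  n <- nrow(X)
  strata <- if (family == "logistic") y else NULL
  folds <- make_folds(n, k, seed, strata)
  dev <- matrix(NA_real_, k, length(lambda))
  for (f in seq_len(k)) {
    tr <- folds != f; te <- !tr
    d_tr <- design; d_tr$X <- X[tr, , drop = FALSE]
    fit_f <- hier_lasso_path(d_tr, y[tr], family, lambda = lambda, tol = tol,
                             max_iter = max_iter)
    for (i in seq_along(lambda)) {
      b <- fit_f$beta[, i]
      eta <- drop(X[te, , drop = FALSE] %*% b)
      dev[f, i] <- if (family == "lm") mean((y[te] - eta)^2) else {
        mu <- stats::plogis(eta)
        -2 * mean(y[te] * log(pmax(mu, 1e-12)) +
                  (1 - y[te]) * log(pmax(1 - mu, 1e-12)))
      }
    }
  }
  cvm <- colMeans(dev)
  cvsd <- apply(dev, 2, stats::sd) / sqrt(k)
  i_min <- which.min(cvm)
  sel <- hier_selection(full, i_min)
  structure(list(lambda = lambda, cvm = cvm, cvsd = cvsd,
                 lambda_min = lambda[i_min], index_min = i_min,
                 theta = full$theta[, i_min], beta = full$beta[, i_min],
                 selected_mains = sel$mains, selected_pairs = sel$pairs,
                 family = family, k = k, seed = seed, design = design),
            class = "cv_hier")
}

#' Selection read-out of a hierarchical lasso fit
#'
#' @param path a [hier_lasso_path()] result.
#' @param index path point to read.
#' @return list with `mains` (exposures in the model) and `pairs`
#'   (data frame of selected interaction pairs `a`, `b`).  Parents of
#'   every selected pair are always included among the mains.
#' @export
hier_selection <- function(path, index) {
  ex <- path$expand
  design <- path$design
  theta <- path$theta[, index]
  gr <- design$groups
  mains <- character()
  for (nm in names(gr$mains)) {
    gi <- which(names(gr$mains) == nm)
    if (any(theta[ex$pen_groups[[gi]]] != 0)) mains <- c(mains, nm)
  }
  pairs <- data.frame(a = character(), b = character(),
                      stringsAsFactors = FALSE)
  for (nm in names(gr$pairs)) {
    gi <- ex$pair_group_index[[nm]]
    gcols <- ex$pen_groups[[gi]]
    # product columns are the tail of the group block
    npr <- length(gr$pairs[[nm]]$prod_cols)
    prod_part <- theta[gcols[(length(gcols) - npr + 1):length(gcols)]]
    if (any(prod_part != 0)) {
      pairs <- rbind(pairs, data.frame(a = gr$pairs[[nm]]$a,
                                       b = gr$pairs[[nm]]$b,
                                       stringsAsFactors = FALSE))
      mains <- union(mains, c(gr$pairs[[nm]]$a, gr$pairs[[nm]]$b))
    } else if (any(theta[gcols] != 0)) {
      # interaction group active only through its main-effect copies:
      # contributes to the mains, no interaction term
      mains <- union(mains, c(gr$pairs[[nm]]$a, gr$pairs[[nm]]$b))
    }
  }
  list(mains = intersect(design$exposures, mains), pairs = pairs)
}

#' @export
print.cv_hier <- function(x, ...) {
  cat(sprintf("cv_hier (%s, %d-fold): lambda_min = %.5g\n",
              x$family, x$k, x$lambda_min))
  cat(sprintf("  mains (%d): %s\n", length(x$selected_mains),
              paste(x$selected_mains, collapse = ", ")))
  cat(sprintf("  interaction pairs (%d): %s\n", nrow(x$selected_pairs),
              paste(paste(x$selected_pairs$a, x$selected_pairs$b, sep = ":"),
                    collapse = ", ")))
  invisible(x)
}
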