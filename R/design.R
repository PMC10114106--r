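#' Build a penalized design from a cohort
#'
#' Expands exposures and covariates into a numeric term matrix for the
#' penalized selection stage.  Categorical columns are dummy-coded against
#' their first (reference) level; exposure columns are standardized to
#' mean 0 / unit variance (centers and scales are stored for
#' back-transformation); covariate columns are neither standardized nor
#' penalized — they are forced into every model.  With `interactions =
#' TRUE` every exposure pair additionally receives an interaction group
#' containing both exposures' main-effect columns plus their element-wise
#' products, the overlapped-group structure that yields strong hierarchy.
#'
#' Exposure columns that are constant in the (already complete-case
#' filtered) subset are dropped with a warning; an error is raised if no
#' exposure column survives.
#'
#' @param x a complete-case filtered [cohort()].
#' @param exposures,covariates column names.
#' @param interactions build pairwise interaction groups?
#' @param intercept include an (unpenalized, unstandardized) intercept
#'   column?  Use `FALSE` for Cox designs.
#' @return An object of class `design_spec`: list with the term matrix
#'   `X`, `penalty_factor`, `center`/`scale` per column, `term_map`
#'   (column name to source exposure/covariate), and for interactions a
#'   `groups` list (`mains`, `pairs`).
#' @export
build_design <- function(x, exposures, covariates = character(),
                         interactions = FALSE, intercept = TRUE) {
  stopifnot(inherits(x, "cohort"))
  fail_if(length(exposures) == 0, "no exposures given")
  fail_if(length(intersect(exposures, covariates)) > 0,
          "exposures and covariates overlap: %s",
          paste(intersect(exposures, covariates), collapse = ", "))

  exp_exp <- expand_terms(x, exposures)
  keep <- apply(exp_exp$X, 2, function(v) stats::sd(v) > 0)
  if (any(!keep)) {
    warning("dropping constant exposure column(s): ",
            paste(colnames(exp_exp$X)[!keep], collapse = ", "), call. = FALSE)
  }
  fail_if(!any(keep), "all exposure columns are constant in this subset")
  Xe <- exp_exp$X[, keep, drop = FALSE]
  map_e <- exp_exp$map[keep]
  exposures <- unique(map_e)

  center <- colMeans(Xe)
  scale <- apply(Xe, 2, stats::sd)
  Xe <- sweep(sweep(Xe, 2, center), 2, scale, "/")

  blocks <- list(Xe)
  maps <- map_e
  centers <- center
  scales <- scale
  pf <- rep(1, ncol(Xe))

  groups <- NULL
  if (interactions) {
    mains <- split(seq_len(ncol(Xe)), factor(map_e, levels = exposures))
    pair_cols <- list(); pair_names <- character()
    prod_block <- NULL
    next_col <- ncol(Xe)
    pairs <- list()
    if (length(exposures) >= 2) {
      combs <- utils::combn(exposures, 2, simplify = FALSE)
      for (pr in combs) {
        cj <- mains[[pr[1]]]; ck <- mains[[pr[2]]]
        prods <- list(); pn <- character()
        for (a in cj) for (b in ck) {
          v <- Xe[, a] * Xe[, b]
          if (stats::sd(v) == 0) next
          prods[[length(prods) + 1L]] <- v
          pn <- c(pn, paste0(colnames(Xe)[a], ":", colnames(Xe)[b]))
        }
        if (length(prods) == 0) next
        P <- do.call(cbind, prods)
        colnames(P) <- pn
        pc <- colMeans(P); ps <- apply(P, 2, stats::sd)
        P <- sweep(sweep(P, 2, pc), 2, ps, "/")
        idx <- next_col + seq_len(ncol(P))
        next_col <- next_col + ncol(P)
        prod_block <- cbind(prod_block, P)
        centers <- c(centers, pc); scales <- c(scales, ps)
        maps <- c(maps, rep(paste(pr, collapse = ":"), ncol(P)))
        pf <- c(pf, rep(1, ncol(P)))
        pairs[[paste(pr, collapse = ":")]] <-
          list(a = pr[1], b = pr[2], cols = c(cj, ck, idx), prod_cols = idx)
      }
    }
    if (!is.null(prod_block)) blocks <- c(blocks, list(prod_block))
    groups <- list(mains = mains, pairs = pairs)
  }

  if (length(covariates) > 0) {
    cov_exp <- expand_terms(x, covariates)
    blocks <- c(blocks, list(cov_exp$X))
    maps <- c(maps, cov_exp$map)
    centers <- c(centers, rep(0, ncol(cov_exp$X)))
    scales <- c(scales, rep(1, ncol(cov_exp$X)))
    pf <- c(pf, rep(0, ncol(cov_exp$X)))
  }
  X <- do.call(cbind, blocks)
  if (intercept) {
    X <- cbind(`(Intercept)` = 1, X)
    maps <- c("(Intercept)" = "(Intercept)", maps)
    centers <- c(0, centers); scales <- c(1, scales)
    pf <- c(0, pf)
    if (!is.null(groups)) {
      groups$mains <- lapply(groups$mains, `+`, 1L)
      groups$pairs <- lapply(groups$pairs, function(g) {
        g$cols <- g$cols + 1L; g$prod_cols <- g$prod_cols + 1L; g
      })
    }
  }
  names(maps) <- colnames(X)
  structure(list(X = X, penalty_factor = pf, center = centers, scale = scales,
                 term_map = maps, exposures = exposures,
                 covariates = covariates, groups = groups,
                 intercept = intercept),
            class = "design_spec")
}

# Dummy-expand a set of cohort columns into a numeric matrix.
# Factors contribute one column per non-reference level, named
# "column=level"; numerics contribute themselves.  `map` gives the source
# column of each term.
expand_terms <- function(x, columns) {
  cols <- list(); map <- character()
  for (col in columns) {
    v <- x[[col]]
    fail_if(is.null(v), "unknown column '%s'", col)
    if (is.factor(v)) {
      lev <- base::levels(v)
      lev <- lev[lev %in% as.character(unique(v))]  # only observed levels
      for (l in lev[-1]) {
        nm <- paste0(col, "=", l)
        cols[[nm]] <- as.numeric(v == l)
        map <- c(map, stats::setNames(col, nm))
      }
      if (length(lev) == 1) {  # single observed level: constant, flagged later
        nm <- paste0(col, "=", lev[1])
        cols[[nm]] <- as.numeric(v == lev[1])
        map <- c(map, stats::setNames(col, nm))
      }
    } else {
      cols[[col]] <- as.numeric(v)
      map <- c(map, stats::setNames(col, col))
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  list(X = X, map = map)
}
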