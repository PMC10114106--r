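#' Simulate a cohort with known ground truth
#'
#' Generates a UK-Biobank-like synthetic cohort for testing every
#' pipeline stage against a known sparse true model: a latent Gaussian
#' exposure vector with exchangeable correlation `rho` (single common
#' factor), from which continuous exposures are taken directly and
#' categorical exposures by quantile-slicing the latent variable into
#' equal-probability levels; forced-in covariates `age` (N(55, 8), the
#' linear predictor uses its standardized value) and `sex` (Bernoulli(0.5),
#' 0/1); a sparse true coefficient map over latent exposure values (so
#' effects are on the standardized scale), optional pairwise interaction
#' effects respecting hierarchy; and an outcome per family:
#' \itemize{
#'   \item `lm`: \eqn{y = \eta + N(0, 1)};
#'   \item `logistic`: \eqn{y \sim Bernoulli(expit(\eta))};
#'   \item `cox`: event times \eqn{\sim Exp(rate \cdot e^\eta)}
#'     (proportional hazards by construction), independent
#'     \eqn{Uniform(0, horizon)} censoring; `TIME` is the minimum and
#'     `PHENO` the event indicator.
#' }
#' Missing values are then injected completely at random into exposure
#' columns only (never ID/PHENO/TIME or covariates), and the unwanted
#' response code is injected into categorical exposures at its own rate.
#' Everything is reproducible from `seed`.
#'
#' @param n cohort size.
#' @param n_continuous,n_categorical exposure counts by type.
#' @param n_levels levels per categorical exposure.
#' @param rho exchangeable latent correlation in `[0, 1)`.
#' @param beta named vector of true main effects; names must be exposure
#'   names (`x1 ... xk` continuous, `c1 ...` categorical, which act
#'   through their latent liability).
#' @param interaction_beta named vector of true pairwise interaction
#'   effects, names like `"x1:x2"`; both parents must have (possibly
#'   zero) declared main entries.
#' @param covariate_beta length-2 vector: effects of standardized age and
#'   of sex.
#' @param intercept link-scale intercept (e.g. `qlogis(0.2)` for a 20%
#'   baseline event rate).
#' @param family outcome family.
#' @param baseline_hazard,censor_horizon survival parameters.
#' @param missing_rate per-exposure missingness rate in `[0, 1)`.
#' @param unwanted_rate per-categorical-exposure rate of the unwanted
#'   code.
#' @param unwanted_code the injected invalid response value.
#' @param seed RNG seed.
#' @return A [cohort()] with attribute `truth` (the generating
#'   parameters, retrievable with [cohort_truth()]).
#' @export
simulate_cohort <- function(n = 500L, n_continuous = 10L, n_categorical = 5L,
                            n_levels = 3L, rho = 0.2,
                            beta = c(x1 = 0.3, x2 = 0.3, x3 = 0.3, x4 = 0.3),
                            interaction_beta = NULL,
                            covariate_beta = c(age = 0.2, sex = 0.2),
                            intercept = 0,
                            family = c("lm", "logistic", "cox"),
                            baseline_hazard = 0.1, censor_horizon = 10,
                            missing_rate = 0.02, unwanted_rate = 0.02,
                            unwanted_code = "prefer_not_to_answer",
                            seed = 1L) {
  family <- match.arg(family)
  fail_if(rho < 0 || rho >= 1, "rho must lie in [0, 1)")
  fail_if(missing_rate < 0 || missing_rate >= 1, "missing_rate must lie in [0, 1)")
  fail_if(unwanted_rate < 0 || unwanted_rate >= 1, "unwanted_rate must lie in [0, 1)")
  exp_names <- c(if (n_continuous > 0) paste0("x", seq_len(n_continuous)),
                 if (n_categorical > 0) paste0("c", seq_len(n_categorical)))
  bad <- setdiff(names(beta), exp_names)
  fail_if(length(bad) > 0, "true effects name unknown exposures: %s",
          paste(bad, collapse = ", "))
  if (!is.null(interaction_beta)) {
    parents <- strsplit(names(interaction_beta), ":", fixed = TRUE)
    for (pr in parents) {
      fail_if(length(pr) != 2 || !all(pr %in% exp_names),
              "bad interaction name '%s'", paste(pr, collapse = ":"))
      fail_if(!all(pr %in% names(beta)),
              "interaction parents must have declared (possibly zero) main effects")
    }
  }
  p <- n_continuous + n_categorical

  out <- with_seed(seed, {
    # exchangeable latent Gaussian: single common factor
    common <- stats::rnorm(n)
    Z <- sqrt(rho) * common + sqrt(1 - rho) *
      matrix(stats::rnorm(n * p), n, p)
    colnames(Z) <- exp_names
    age <- stats::rnorm(n, 55, 8)
    sex <- stats::rbinom(n, 1, 0.5)
    eta <- intercept + covariate_beta[1] * (age - 55) / 8 +
      covariate_beta[2] * sex
    for (e in names(beta)) eta <- eta + beta[[e]] * Z[, e]
    if (!is.null(interaction_beta)) {
      for (nm in names(interaction_beta)) {
        pr <- strsplit(nm, ":", fixed = TRUE)[[1]]
        eta <- eta + interaction_beta[[nm]] * Z[, pr[1]] * Z[, pr[2]]
      }
    }
    dat <- data.frame(ID = sprintf("S%06d", seq_len(n)),
                      stringsAsFactors = FALSE)
    if (family == "lm") {
      dat$PHENO <- eta + stats::rnorm(n)
    } else if (family == "logistic") {
      dat$PHENO <- stats::rbinom(n, 1, stats::plogis(eta))
    } else {
      t_event <- stats::rexp(n, rate = baseline_hazard * exp(eta))
      t_cens <- stats::runif(n, 0, censor_horizon)
      dat$PHENO <- as.numeric(t_event <= t_cens)
      dat$TIME <- pmax(pmin(t_event, t_cens), .Machine$double.eps)
    }
    if (n_continuous > 0) {
      for (j in seq_len(n_continuous)) dat[[paste0("x", j)]] <- Z[, j]
    }
    lev <- paste0("L", seq_len(n_levels))
    cuts <- stats::qnorm(seq(0, 1, length.out = n_levels + 1))
    if (n_categorical > 0) {
      for (j in seq_len(n_categorical)) {
        nm <- paste0("c", j)
        dat[[nm]] <- as.character(cut(Z[, nm], breaks = cuts, labels = lev,
                                      include.lowest = TRUE))
      }
    }
    dat$age <- age
    dat$sex <- sex
    # inject missingness (exposures only), then unwanted codes (categoricals)
    for (e in exp_names) {
      if (missing_rate > 0) {
        miss <- stats::runif(n) < missing_rate
        dat[[e]][miss] <- NA
      }
      if (unwanted_rate > 0 && startsWith(e, "c")) {
        unw <- stats::runif(n) < unwanted_rate & !is.na(dat[[e]])
        dat[[e]][unw] <- unwanted_code
      }
    }
    dat
  })

  roles <- stats::setNames(c(rep("exposure", p), "covariate", "covariate"),
                           c(exp_names, "age", "sex"))
  level_spec <- NULL
  unwanted <- NULL
  if (n_categorical > 0) {
    lev_all <- c(paste0("L", seq_len(n_levels)),
                 if (unwanted_rate > 0) unwanted_code)
    level_spec <- stats::setNames(
      rep(list(lev_all), n_categorical), paste0("c", seq_len(n_categorical)))
    if (unwanted_rate > 0) {
      unwanted <- stats::setNames(rep(list(unwanted_code), n_categorical),
                                  paste0("c", seq_len(n_categorical)))
    }
  }
  coh <- cohort(out, family = family, roles = roles, levels = level_spec,
                unwanted = unwanted)
  attr(coh, "truth") <- list(
    n = n, n_continuous = n_continuous, n_categorical = n_categorical,
    n_levels = n_levels, rho = rho, beta = as.list(beta),
    interaction_beta = as.list(interaction_beta %||% stats::setNames(numeric(), character())),
    covariate_beta = as.list(covariate_beta), intercept = intercept,
    family = family, baseline_hazard = baseline_hazard,
    censor_horizon = censor_horizon, missing_rate = missing_rate,
    unwanted_rate = unwanted_rate, unwanted_code = unwanted_code,
    seed = as.integer(seed))
  coh
}

#' Retrieve the generating truth of a simulated cohort
#'
#' @param x a [simulate_cohort()] result.
#' @return The list of generating parameters.
#' @export
cohort_truth <- function(x) attr(x, "truth")

#' Write deterministic fixture cohorts
#'
#' Writes small CSV cohorts (n = 500 by default; one per family, plus an
#' interaction variant) with a YAML manifest of their generating
#' parameters; regenerating from the manifest seeds reproduces the files
#' byte-identically.
#'
#' @param dir output directory (created if needed).
#' @param n fixture size.
#' @return Invisibly, the manifest list.
#' @export
write_fixtures <- function(dir, n = 500L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  specs <- list(
    lm = list(family = "lm", seed = 101L),
    logistic = list(family = "logistic", seed = 102L,
                    intercept = stats::qlogis(0.3)),
    cox = list(family = "cox", seed = 103L),
    lm_interactions = list(family = "lm", seed = 104L,
                           interaction_beta = c("x1:x2" = 0.3)))
  manifest <- list()
  for (nm in names(specs)) {
    args <- c(specs[[nm]], list(n = n))
    coh <- do.call(simulate_cohort, args)
    path <- file.path(dir, paste0("cohort_", nm, ".csv"))
    write_cohort(coh, path)
    manifest[[nm]] <- c(list(file = basename(path)), cohort_truth(coh))
  }
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(manifest)
}

#' Serialize the generating truth as JSON
#'
#' @param truth a [cohort_truth()] list.
#' @param path JSON path.
#' @return `path` (writer) or the restored list (reader).
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
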