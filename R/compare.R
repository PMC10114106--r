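#' Goodness-of-fit metrics
#'
#' The three prediction-accuracy metrics used across the package, one per
#' model family: coefficient of determination for linear models, area
#' under the ROC curve for logistic models, Harrell's concordance index
#' for Cox models.
#'
#' `auc()` is the Mann–Whitney form: the probability that a random
#' positive outscores a random negative, ties counted 1/2.  `c_index()`
#' follows Harrell's definition for censored data: over comparable pairs
#' (the earlier time is an observed event), a pair is concordant when the
#' earlier-failing individual has the higher risk; risk ties count 1/2;
#' pairs of two events with tied times, and pairs where the earlier time
#' is censored, are not comparable.  Pair counting delegates to
#' [survival::concordance()].
#'
#' @param y,yhat observed and predicted real-valued outcomes.
#' @param labels 0/1 class labels.
#' @param scores real-valued risk scores (higher = predicted positive /
#'   higher risk).
#' @param time,event survival outcome; `risk` the predicted risk score.
#' @param risk numeric risk scores for `c_index`.
#' @return A single number: R-squared in `(-Inf, 1]`, AUC or C-index in
#'   `[0, 1]`.
#' @export
r_squared <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 2)
  ss_tot <- sum((y - mean(y))^2)
  fail_if(ss_tot == 0, "constant outcome: R-squared is undefined")
  1 - sum((y - yhat)^2) / ss_tot
}

#' @rdname r_squared
#' @export
auc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  fail_if(n1 == 0 || n0 == 0, "both classes must be present")
  r <- rank(scores)  # midranks handle ties as 1/2
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @rdname r_squared
#' @export
c_index <- function(time, event, risk) {
  stopifnot(length(time) == length(event), length(time) == length(risk))
  fail_if(sum(event) == 0, "no events: no comparable pairs")
  cc <- survival::concordance(survival::Surv(time, event) ~ risk,
                              reverse = TRUE)
  cnt <- cc$count
  denom <- cnt["concordant"] + cnt["discordant"] + cnt["tied.x"]
  fail_if(denom == 0, "no comparable pairs")
  unname((cnt["concordant"] + cnt["tied.x"] / 2) / denom)
}

#' Paired-bootstrap comparison of two models' goodness of fit
#'
#' Evaluates the family metric ([r_squared()], [auc()] or [c_index()]) for
#' two prediction vectors on the same individuals, then bootstraps the
#' *difference*: each replicate resamples individuals with replacement
#' once and evaluates both models on the same replicate, so the
#' between-model pairing (and its variance reduction) is preserved.  The
#' delta distribution is summarized by its mean and a percentile
#' confidence interval.  Replicates on which the metric is undefined (a
#' single outcome class, no comparable pairs) are redrawn, up to 100
#' attempts each.
#'
#' @param y outcome: real (`lm`), 0/1 (`logistic`), or for `cox` a list /
#'   data frame with `time` and `event`.
#' @param pred1,pred2 predictions of models 1 and 2 for the same
#'   individuals (linear predictors, probabilities or risk scores).
#' @param family model family.
#' @param B bootstrap replicates (default 1000; must be >= 1).
#' @param ci_level confidence level of the percentile interval.
#' @param seed RNG seed.
#' @return An object of class `gof_comparison`: `metric`, `value1`,
#'   `value2`, `delta` (value2 - value1), `delta_boot` mean, `ci`, `B`,
#'   `seed`, and the replicate deltas.
#' @export
delta_pred <- function(y, pred1, pred2, family = c("lm", "logistic", "cox"),
                       B = 1000L, ci_level = 0.95, seed = 1L) {
  family <- match.arg(family)
  fail_if(B < 1, "B must be at least 1")
  if (family == "cox") {
    time <- y$time; event <- y$event
    n <- length(time)
    metric <- function(idx, pred) c_index(time[idx], event[idx], pred[idx])
    ok <- function(idx) sum(event[idx]) > 0 &&
      length(unique(time[idx][event[idx] == 1])) > 0
    metric_name <- "c_index"
  } else if (family == "logistic") {
    n <- length(y)
    metric <- function(idx, pred) auc(y[idx], pred[idx])
    ok <- function(idx) length(unique(y[idx])) == 2
    metric_name <- "auc"
  } else {
    n <- length(y)
    metric <- function(idx, pred) r_squared(y[idx], pred[idx])
    ok <- function(idx) stats::sd(y[idx]) > 0
    metric_name <- "r_squared"
  }
  stopifnot(length(pred1) == n, length(pred2) == n)
  full <- seq_len(n)
  v1 <- metric(full, pred1)
  v2 <- metric(full, pred2)
  deltas <- numeric(B)
  with_seed(seed, {
    for (b in seq_len(B)) {
      for (attempt in seq_len(100L)) {
        idx <- sample.int(n, n, replace = TRUE)
        if (ok(idx)) break
        fail_if(attempt == 100L,
                "could not draw a valid bootstrap replicate in 100 attempts")
      }
      deltas[b] <- metric(idx, pred2) - metric(idx, pred1)
    }
  })
  qs <- stats::quantile(deltas, c((1 - ci_level) / 2, 1 - (1 - ci_level) / 2),
                        names = FALSE, type = 7)
  structure(list(metric = metric_name, value1 = v1, value2 = v2,
                 delta = v2 - v1, delta_boot_mean = mean(deltas),
                 ci_level = ci_level, ci = qs, B = B, seed = seed,
                 deltas = deltas),
            class = "gof_comparison")
}

#' @export
print.gof_comparison <- function(x, ...) {
  cat(sprintf("gof_comparison (%s): model1 = %.4f, model2 = %.4f\n",
              x$metric, x$value1, x$value2))
  cat(sprintf("  delta = %.4f, %g%% percentile CI [%.4f, %.4f], B = %d\n",
              x$delta, 100 * x$ci_level, x$ci[1], x$ci[2], x$B))
  invisible(x)
}

#' Top-fraction risk stratification
#'
#' Compares individuals in the top fraction (top decile by default) of the
#' risk-score distribution against the remaining individuals: a Cox model
#' of the membership indicator gives the hazard ratio (for
#' `family = "logistic"`, a logistic fit gives the odds ratio instead),
#' with a 95% Wald interval.  Also returns the percentile-incidence table:
#' individuals are binned into 100 groups by score percentile and the
#' event rate (mean outcome) of each bin is reported.
#'
#' @param scores data frame with columns `ID` and `PXS` (as produced by
#'   [score_pxs()]), or a numeric vector aligned with `x`.
#' @param x the evaluation [cohort()].
#' @param top_fraction fraction defining the high-risk group (default
#'   0.10).
#' @return An object of class `risk_strata`: `estimate` (HR or OR), `ci`,
#'   `p`, `n_top`, `n_rest`, `measure`, and `percentile_table`
#'   (`percentile`, `n`, `events`, `incidence`).
#' @export
risk_stratify <- function(scores, x, top_fraction = 0.10) {
  stopifnot(inherits(x, "cohort"))
  family <- cohort_family(x)
  fail_if(!family %in% c("cox", "logistic"),
          "risk stratification needs a cox or logistic cohort")
  if (is.data.frame(scores)) {
    m <- match(x$ID, scores$ID)
    s <- scores$PXS[m]
  } else {
    stopifnot(length(scores) == nrow(x))
    s <- as.numeric(scores)
  }
  keep <- !is.na(s)
  s <- s[keep]
  dat <- cohort_subset(x, keep)
  n <- length(s)
  fail_if(n < 10, "need at least 10 scored individuals (have %d)", n)
  cutoff <- stats::quantile(s, 1 - top_fraction, names = FALSE, type = 7)
  top <- as.numeric(s > cutoff)
  if (sum(top) == 0) top <- as.numeric(s >= cutoff)  # heavy score ties
  fail_if(sum(top) == 0 || sum(top) == n,
          "top-fraction indicator is degenerate")
  design <- cbind(top = top)
  if (family == "cox") {
    fit <- fit_cox(design, dat$TIME, dat$PHENO)
    measure <- "hazard_ratio"
  } else {
    fit <- fit_logistic(cbind(`(Intercept)` = 1, design), dat$PHENO)
    measure <- "odds_ratio"
  }
  b <- fit$beta["top"]; se <- fit$se["top"]
  pct <- ceiling(100 * rank(s, ties.method = "first") / n)
  tab <- data.frame(percentile = sort(unique(pct)))
  tab$n <- as.integer(table(pct)[as.character(tab$percentile)])
  ev <- tapply(dat$PHENO, pct, sum)
  tab$events <- as.numeric(ev[as.character(tab$percentile)])
  tab$incidence <- tab$events / tab$n
  structure(list(estimate = exp(unname(b)),
                 ci = exp(unname(b) + c(-1, 1) * 1.96 * unname(se)),
                 p = unname(fit$wald_p["top"]), measure = measure,
                 n_top = sum(top), n_rest = n - sum(top),
                 top_fraction = top_fraction, percentile_table = tab),
            class = "risk_strata")
}

#' @export
print.risk_strata <- function(x, ...) {
  cat(sprintf("risk_strata: top %.0f%% vs rest, %s = %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              100 * x$top_fraction, x$measure, x$estimate,
              x$ci[1], x$ci[2], x$p))
  invisible(x)
}
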