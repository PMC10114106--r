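# Independent oracles and small fixture builders used across the suite.
# Everything here is deliberately written from the definitions, not by
# calling the package's own code paths.

# --- step-up FDR adjustments, brute force from the formulas ---------------
adjust_brute <- function(p, method) {
  m <- length(p)
  if (m == 0) return(p)
  if (method == "bonferroni") return(pmin(1, m * p))
  cm <- if (method == "BY") sum(1 / seq_len(m)) else 1
  o <- order(p)
  adj <- pmin(1, p[o] * m * cm / seq_len(m))
  # enforce monotone non-decreasing from the largest down
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[o] <- adj
  out
}

# --- Harrell's C, O(n^2) pair enumeration ---------------------------------
cindex_brute <- function(time, event, risk) {
  n <- length(time)
  num <- 0; den <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (time[i] == time[j]) {
      if (event[i] + event[j] != 1) next  # two events or two censorings: not comparable
      # death precedes censoring at a tied time
      early <- if (event[i] == 1) i else j
      late <- if (event[i] == 1) j else i
      den <- den + 1
      if (risk[early] > risk[late]) num <- num + 1
      else if (risk[early] == risk[late]) num <- num + 0.5
      next
    }
    early <- if (time[i] < time[j]) i else j
    late <- if (time[i] < time[j]) j else i
    if (event[early] != 1) next  # earlier time censored: not comparable
    den <- den + 1
    if (risk[early] > risk[late]) num <- num + 1
    else if (risk[early] == risk[late]) num <- num + 0.5
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}

# --- AUC by direct pair enumeration ---------------------------------------
auc_brute <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  num <- 0
  for (a in pos) for (b in neg) num <- num + (a > b) + 0.5 * (a == b)
  num / (length(pos) * length(neg))
}

# --- Cox partial log-likelihood (no ties assumed) and 1-D maximizer -------
cox_pll_1d <- function(beta, x, time, event) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

golden_max_1d <- function(f, lower = -5, upper = 5, tol = 1e-9) {
  stats::optimize(f, c(lower, upper), maximum = TRUE, tol = tol)$maximum
}

# --- binomial log-likelihood for the grid-search oracle -------------------
binom_ll <- function(b0, b1, x, y) {
  eta <- b0 + b1 * x
  sum(y * eta - log1p(exp(eta)))
}

# --- tiny cohort builders --------------------------------------------------
tiny_cohort <- function(family = "lm", n = 8, seed = 1) {
  set.seed(seed)
  d <- data.frame(ID = paste0("I", seq_len(n)),
                  PHENO = if (family == "lm") rnorm(n) else rbinom(n, 1, 0.5),
                  e1 = rnorm(n),
                  smoke = sample(c("never", "ex", "current"), n, replace = TRUE),
                  age = rnorm(n, 50, 5),
                  stringsAsFactors = FALSE)
  if (family == "cox") d$TIME <- rexp(n) + 0.1
  cohort(d, family = family,
         roles = c(e1 = "exposure", smoke = "exposure", age = "covariate"))
}

# seeded noise that does not disturb the surrounding RNG stream
with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed + 5000)
  force(code)
}

# standard simulation conditions used by several recovery tests
recovery_cohort <- function(seed, n = 4000, n_exposures = 20, n_true = 4,
                            effect = 0.3, rho = 0.2, family = "lm") {
  simulate_cohort(
    n = n, n_continuous = n_exposures, n_categorical = 0, rho = rho,
    beta = stats::setNames(rep(effect, n_true), paste0("x", seq_len(n_true))),
    family = family, missing_rate = 0, unwanted_rate = 0, seed = seed)
}
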