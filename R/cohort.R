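#' Cohort tables
#'
#' A `cohort` is a validated data frame holding one row per individual with
#' the reserved columns `ID` (unique identifier), `PHENO` (the outcome:
#' real-valued for linear models, 0/1 for logistic and survival models) and,
#' for survival analysis, `TIME` (positive time to event or censoring; the
#' event indicator is `PHENO`).  Every remaining column that enters an
#' analysis carries a *role* (`"exposure"` or `"covariate"`) and a *type*
#' (continuous, or categorical with an explicit ordered level set whose
#' first level is the dummy-coding reference).  Categorical columns may also
#' declare *unwanted codes*: response values, such as "prefer not to
#' answer", that are treated as invalid in addition to missing values.
#'
#' @param data a data frame containing `ID`, `PHENO`, optionally `TIME`,
#'   and the analysis columns.
#' @param family model family: `"lm"`, `"logistic"` or `"cox"`.
#' @param roles named character vector mapping column names to
#'   `"exposure"` or `"covariate"`.  Columns of `data` absent from `roles`
#'   are dropped with a warning.
#' @param levels optional named list giving the ordered level set of each
#'   categorical column; the first level is the reference.  Columns not
#'   listed are treated as continuous if numeric, otherwise their levels
#'   are taken in first-seen order.
#' @param unwanted optional named list of character vectors: per-column
#'   categorical codes to treat as invalid responses.
#'
#' @return An object of class `cohort` (a data frame with metadata
#'   attributes; see [cohort_roles()], [cohort_family()]).
#' @seealso [read_cohort()], [complete_cases()], [split_groups()]
#' @export
cohort <- function(data, family = c("lm", "logistic", "cox"),
                   roles, levels = NULL, unwanted = NULL) {
  family <- match.arg(family)
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data, stringsAsFactors = FALSE)

  for (col in c("ID", "PHENO")) {
    fail_if(!col %in% names(data), "required column '%s' is missing", col)
  }
  ids <- as.character(data$ID)
  dup <- unique(ids[duplicated(ids)])
  fail_if(length(dup) > 0, "duplicated IDs: %s",
          paste(utils::head(dup, 5L), collapse = ", "))
  data$ID <- ids

  pheno <- data$PHENO
  fail_if(!is.numeric(pheno) && !all(pheno %in% c("0", "1", NA)),
          "PHENO must be numeric")
  pheno <- as.numeric(pheno)
  fail_if(anyNA(pheno), "PHENO contains missing values")
  if (family %in% c("logistic", "cox")) {
    fail_if(!all(pheno %in% c(0, 1)),
            "family '%s' requires a 0/1 PHENO", family)
  }
  data$PHENO <- pheno

  if (family == "cox") {
    fail_if(!"TIME" %in% names(data),
            "family 'cox' requires a TIME column (time to event or censoring)")
    tm <- as.numeric(data$TIME)
    fail_if(anyNA(tm), "TIME contains missing values")
    fail_if(any(tm <= 0), "TIME must be strictly positive")
    data$TIME <- tm
  }

  fail_if(is.null(names(roles)) || !all(roles %in% c("exposure", "covariate")),
          "'roles' must be a named vector of \"exposure\"/\"covariate\"")
  missing_cols <- setdiff(names(roles), names(data))
  fail_if(length(missing_cols) > 0, "role given for absent column(s): %s",
          paste(missing_cols, collapse = ", "))
  reserved <- intersect(names(roles), c("ID", "PHENO", "TIME"))
  fail_if(length(reserved) > 0, "reserved columns cannot carry roles: %s",
          paste(reserved, collapse = ", "))

  extra <- setdiff(names(data), c("ID", "PHENO", "TIME", names(roles)))
  if (length(extra) > 0) {
    warning("ignoring column(s) without a role: ",
            paste(extra, collapse = ", "), call. = FALSE)
    data <- data[, setdiff(names(data), extra), drop = FALSE]
  }

  # materialize categorical level sets (first-seen order unless declared)
  level_sets <- list()
  for (col in names(roles)) {
    v <- data[[col]]
    declared <- levels[[col]]
    if (!is.null(declared)) {
      lev <- as.character(declared)
      bad <- setdiff(unique(as.character(v[!is.na(v)])), lev)
      fail_if(length(bad) > 0, "column '%s' has values outside its declared levels: %s",
              col, paste(utils::head(bad, 5L), collapse = ", "))
      data[[col]] <- factor(as.character(v), levels = lev)
      level_sets[[col]] <- lev
    } else if (is.factor(v)) {
      level_sets[[col]] <- base::levels(v)
    } else if (!is.numeric(v) && !is.logical(v)) {
      seen <- unique(as.character(v[!is.na(v) & v != ""]))
      data[[col]][!is.na(v) & v == ""] <- NA
      data[[col]] <- factor(as.character(data[[col]]), levels = seen)
      level_sets[[col]] <- seen
    } else {
      data[[col]] <- as.numeric(v)
    }
  }

  if (!is.null(unwanted)) {
    bad <- setdiff(names(unwanted), names(level_sets))
    fail_if(length(bad) > 0,
            "unwanted codes declared for non-categorical column(s): %s",
            paste(bad, collapse = ", "))
  }

  structure(data,
            class = c("cohort", "data.frame"),
            family = family,
            roles = roles[order(match(names(roles), names(data)))],
            level_sets = level_sets,
            unwanted = unwanted %||% list())
}

#' @export
print.cohort <- function(x, ...) {
  roles <- cohort_roles(x)
  cat(sprintf("cohort: %d individuals, family '%s'\n", nrow(x), cohort_family(x)))
  cat(sprintf("  exposures:  %d (%d categorical)\n",
              sum(roles == "exposure"),
              sum(names(roles)[roles == "exposure"] %in% names(attr(x, "level_sets")))))
  cat(sprintf("  covariates: %d\n", sum(roles == "covariate")))
  if (cohort_family(x) == "cox") {
    cat(sprintf("  events: %d / %d\n", sum(x$PHENO), nrow(x)))
  }
  invisible(x)
}

#' Cohort accessors
#'
#' @param x a [cohort()].
#' @return `cohort_roles()`: named character vector of column roles;
#'   `cohort_family()`: the model family string; `cohort_levels()`: named
#'   list of categorical level sets; `cohort_unwanted()`: named list of
#'   unwanted response codes; `exposure_names()` / `covariate_names()`:
#'   character vectors of column names.
#' @export
cohort_roles <- function(x) attr(x, "roles")

#' @rdname cohort_roles
#' @export
cohort_family <- function(x) attr(x, "family")

#' @rdname cohort_roles
#' @export
cohort_levels <- function(x) attr(x, "level_sets")

#' @rdname cohort_roles
#' @export
cohort_unwanted <- function(x) attr(x, "unwanted")

#' @rdname cohort_roles
#' @export
exposure_names <- function(x) names(cohort_roles(x))[cohort_roles(x) == "exposure"]

#' @rdname cohort_roles
#' @export
covariate_names <- function(x) names(cohort_roles(x))[cohort_roles(x) == "covariate"]

#' Row-subset a cohort preserving its metadata
#'
#' @param x a [cohort()].
#' @param i logical or integer row index (e.g. `x$ID %in% ids_c`).
#' @return The subset, still a [cohort()] with the same family, roles,
#'   level sets and unwanted codes.
#' @export
cohort_subset <- function(x, i) {
  out <- as.data.frame(x)[i, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            class = c("cohort", "data.frame"),
            family = cohort_family(x),
            roles = cohort_roles(x),
            level_sets = cohort_levels(x),
            unwanted = cohort_unwanted(x))
}

#' Read a cohort table from a delimited file
#'
#' Reads a CSV or TSV file with a header row (delimiter auto-detected from
#' the header line unless given), validates it and returns a [cohort()].
#' Missing values may be encoded as empty strings or `NA`.
#'
#' @inheritParams cohort
#' @param path path to the delimited file.
#' @param sep field delimiter; `NULL` (default) auto-detects `,` vs tab by
#'   sniffing the header line.
#' @return A [cohort()].
#' @export
read_cohort <- function(path, family = c("lm", "logistic", "cox"),
                        roles, levels = NULL, unwanted = NULL, sep = NULL) {
  fail_if(!file.exists(path), "file not found: %s", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >
               lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  }
  data <- utils::read.table(path, header = TRUE, sep = sep,
                            na.strings = c("", "NA"), stringsAsFactors = FALSE,
                            check.names = FALSE, quote = "\"", comment.char = "")
  cohort(data, family = family, roles = roles, levels = levels,
         unwanted = unwanted)
}

#' Write a cohort table to CSV
#'
#' Values round-trip exactly through [read_cohort()] when re-read with the
#' same roles and the cohort's own level sets.
#'
#' @param x a [cohort()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  out <- as.data.frame(x)
  for (col in names(out)) if (is.factor(out[[col]])) out[[col]] <- as.character(out[[col]])
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Complete-case filtering with unwanted-code removal
#'
#' Returns the subset of individuals with no missing value and no unwanted
#' response code in any of the named columns, preserving the original row
#' order.  This is the per-model filtering step used by the scan and the
#' score pipelines: each model keeps every individual that is complete on
#' the variables *it* uses, so retained counts differ between models.
#'
#' @param x a [cohort()].
#' @param columns columns to require completeness on.
#' @param unwanted optional named list of per-column unwanted codes,
#'   overriding the codes stored in the cohort.
#' @return The filtered [cohort()], with attribute `n_retained`.  Unwanted
#'   codes are removed from the level sets of the filtered columns.
#' @export
complete_cases <- function(x, columns = NULL, unwanted = NULL) {
  stopifnot(inherits(x, "cohort"))
  columns <- columns %||% names(cohort_roles(x))
  missing_cols <- setdiff(columns, names(x))
  fail_if(length(missing_cols) > 0, "unknown column(s): %s",
          paste(missing_cols, collapse = ", "))
  unwanted <- unwanted %||% cohort_unwanted(x)

  keep <- rep(TRUE, nrow(x))
  for (col in columns) {
    v <- x[[col]]
    bad <- is.na(v)
    codes <- unwanted[[col]]
    if (!is.null(codes) && is.factor(v)) bad <- bad | (as.character(v) %in% codes)
    keep <- keep & !bad
  }
  fail_if(sum(keep) == 0,
          "no individuals remain after complete-case filtering on {%s}",
          paste(columns, collapse = ", "))
  out <- cohort_subset(x, keep)
  # unwanted codes can no longer occur in the filtered columns
  lev <- cohort_levels(out)
  for (col in intersect(columns, names(lev))) {
    codes <- unwanted[[col]]
    if (!is.null(codes)) {
      lev[[col]] <- setdiff(lev[[col]], codes)
      out[[col]] <- factor(as.character(out[[col]]), levels = lev[[col]])
    }
  }
  attr(out, "level_sets") <- lev
  attr(out, "n_retained") <- sum(keep)
  out
}

#' Split a cohort into selection / calibration / validation groups
#'
#' Partitions individuals into three non-overlapping groups: Group A for
#' penalized variable selection, Group B for model calibration, Group C for
#' held-out scoring and validation.  Either explicit ID lists or fractions
#' may be given; fractional splitting is a seeded uniform permutation
#' partition and is deterministic for a fixed seed.
#'
#' @param x a [cohort()].
#' @param ids_a,ids_b,ids_c explicit ID vectors (all three required if any
#'   is given).
#' @param fractions numeric vector of length 3 with the A/B/C fractions
#'   (each in `[0, 1]`, sum at most 1).
#' @param seed RNG seed for fractional splitting.
#' @return An object of class `group_split`: a list with `ids_a`, `ids_b`,
#'   `ids_c`.
#' @export
split_groups <- function(x, ids_a = NULL, ids_b = NULL, ids_c = NULL,
                         fractions = NULL, seed = NULL) {
  stopifnot(inherits(x, "cohort"))
  all_ids <- x$ID
  if (!is.null(ids_a) || !is.null(ids_b) || !is.null(ids_c)) {
    ids_a <- as.character(ids_a %||% character())
    ids_b <- as.character(ids_b %||% character())
    ids_c <- as.character(ids_c %||% character())
    unknown <- setdiff(c(ids_a, ids_b, ids_c), all_ids)
    fail_if(length(unknown) > 0, "IDs not in the cohort: %s",
            paste(utils::head(unknown, 5L), collapse = ", "))
    ov <- c(intersect(ids_a, ids_b), intersect(ids_a, ids_c),
            intersect(ids_b, ids_c))
    fail_if(length(ov) > 0, "groups overlap on IDs: %s",
            paste(utils::head(unique(ov), 5L), collapse = ", "))
  } else {
    fail_if(is.null(fractions), "give either explicit ID lists or 'fractions'")
    fail_if(length(fractions) != 3 || any(fractions < 0) || any(fractions > 1),
            "'fractions' must be three values in [0, 1]")
    fail_if(sum(fractions) > 1 + 1e-12, "'fractions' sum to more than 1")
    fail_if(is.null(seed), "'seed' is required for fractional splitting")
    n <- length(all_ids)
    perm <- with_seed(seed, sample(n))
    n_a <- floor(fractions[1] * n)
    n_b <- floor(fractions[2] * n)
    n_c <- min(n - n_a - n_b, ceiling(fractions[3] * n))
    ids_a <- all_ids[perm[seq_len(n_a)]]
    ids_b <- all_ids[perm[n_a + seq_len(n_b)]]
    ids_c <- if (n_c > 0) all_ids[perm[n_a + n_b + seq_len(n_c)]] else character()
  }
  structure(list(ids_a = ids_a, ids_b = ids_b, ids_c = ids_c),
            class = "group_split")
}

#' @export
print.group_split <- function(x, ...) {
  cat(sprintf("group_split: A = %d, B = %d, C = %d individuals\n",
              length(x$ids_a), length(x$ids_b), length(x$ids_c)))
  invisible(x)
}
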