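#' Manhattan-style plot of scan p-values
#'
#' Plots `-log10(p)` per exposure from an [xwas()] result, with a
#' horizontal reference line at the significance threshold.  Either the
#' raw or the FDR-adjusted p-values can be plotted; exposures may be
#' grouped on the x-axis by a user-supplied category.  Zero p-values are
#' floored at the smallest representable double (with a warning) so the
#' figure never contains infinities.
#'
#' @param x an [xwas()] result.
#' @param threshold p-value cutoff drawn as a horizontal line (default
#'   0.05).
#' @param value plot `"adjusted"` (default) or `"raw"` p-values.
#' @param category optional named vector mapping exposures to display
#'   groups.
#' @param file optional output path (PNG/SVG by extension); the plot is
#'   written with `ggplot2::ggsave`.
#' @param width,height device size in inches.
#' @return Invisibly, a list with `plot` (the ggplot object) and `data`
#'   (the plotted coordinates).
#' @export
manhattan_xwas <- function(x, threshold = 0.05,
                           value = c("adjusted", "raw"), category = NULL,
                           file = NULL, width = 7, height = 4) {
  stopifnot(inherits(x, "xwas_result"))
  value <- match.arg(value)
  tab <- x$table[x$table$converged, , drop = FALSE]
  fail_if(nrow(tab) == 0, "no converged exposures to plot")
  p <- if (value == "adjusted") tab$p_adjusted else tab$p
  if (any(p == 0, na.rm = TRUE)) {
    warning("p-values of 0 floored at the smallest representable double",
            call. = FALSE)
    p[p == 0] <- .Machine$double.xmin
  }
  df <- data.frame(exposure = tab$exposure, neg_log10_p = -log10(p),
                   stringsAsFactors = FALSE)
  df$category <- if (is.null(category)) "all" else
    as.character(category[df$exposure])
  df <- df[order(df$category, df$exposure), ]
  df$position <- seq_len(nrow(df))
  gg <- ggplot2::ggplot(df, ggplot2::aes(
          x = position, y = neg_log10_p,
          colour = category)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(threshold), linetype = "dashed") +
    ggplot2::scale_x_continuous(breaks = df$position, labels = df$exposure) +
    ggplot2::labs(x = NULL,
                  y = sprintf("-log10(%s p)", value),
                  colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1),
                   legend.position = if (is.null(category)) "none" else "bottom")
  if (!is.null(file)) ggplot2::ggsave(file, gg, width = width, height = height)
  invisible(list(plot = gg, data = df))
}

#' Coefficient (effect-size) plot of scan or model estimates
#'
#' Point estimates with 95% Wald intervals (`beta +/- 1.96 se`), sorted
#' by estimate.  For logistic and Cox scans the estimates can be drawn as
#' `exp(beta)` (odds/hazard ratios) on a log-scaled axis.
#'
#' @param x an [xwas()] result or a `pxs_model`.
#' @param exp_scale plot `exp(beta)` on a log axis?
#' @param file optional output path.
#' @param width,height device size in inches.
#' @return Invisibly, a list with `plot` and `data` (term, estimate,
#'   lower, upper).
#' @export
plot_coeff_xwas <- function(x, exp_scale = FALSE, file = NULL,
                            width = 6, height = 5) {
  if (inherits(x, "xwas_result")) {
    est <- if (!is.null(x$terms) && nrow(x$terms) > 0) {
      data.frame(term = x$terms$term, beta = x$terms$beta, se = x$terms$se,
                 stringsAsFactors = FALSE)
    } else {
      tab <- x$table[x$table$converged & !is.na(x$table$beta), , drop = FALSE]
      data.frame(term = tab$exposure, beta = tab$beta, se = tab$se,
                 stringsAsFactors = FALSE)
    }
  } else if (inherits(x, "pxs_model")) {
    nm <- names(x$weights)
    est <- data.frame(term = nm, beta = unname(x$fit$beta[nm]),
                      se = unname(x$fit$se[nm]), stringsAsFactors = FALSE)
  } else stop("x must be an xwas_result or a pxs_model", call. = FALSE)
  fail_if(nrow(est) == 0, "no estimates to plot")
  fail_if(anyNA(est$se), "missing standard errors")
  est$lower <- est$beta - 1.96 * est$se
  est$upper <- est$beta + 1.96 * est$se
  if (exp_scale) {
    est$estimate <- exp(est$beta)
    est$lower <- exp(est$lower); est$upper <- exp(est$upper)
    ref <- 1
  } else {
    est$estimate <- est$beta
    ref <- 0
  }
  est <- est[order(est$estimate), ]
  est$term <- factor(est$term, levels = est$term)
  gg <- ggplot2::ggplot(est, ggplot2::aes(x = estimate, y = term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = lower,
                                         xmax = upper), height = 0.2) +
    ggplot2::geom_vline(xintercept = ref, linetype = "dashed") +
    ggplot2::labs(x = if (exp_scale) "ratio (95% CI)" else "beta (95% CI)",
                  y = NULL) +
    ggplot2::theme_minimal()
  if (exp_scale) gg <- gg + ggplot2::scale_x_log10()
  if (!is.null(file)) ggplot2::ggsave(file, gg, width = width, height = height)
  invisible(list(plot = gg, data = est))
}
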