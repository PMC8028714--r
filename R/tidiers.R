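# broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' @rdname penfeed_tidiers
#' @name penfeed_tidiers
#' @title Tidy and glance methods for penfeed fits
#' @description `tidy()` returns one row per variance parameter (with
#'   asymptotic standard errors from the inverse average-information matrix
#'   when available); `glance()` returns a one-row model summary with
#'   `logLik`, `AIC`, `BIC`, parameter and record counts, and convergence.
#' @param x A `penfeed_reml` or `penfeed_cv` object.
#' @param ... Unused.
NULL

theta_labels <- function(fit) {
  map <- fit$param_map
  coef_names <- colnames(fit$vc$G) %||% paste0("c", seq_len(map$nc))
  lab <- character(map$n_theta)
  pairs <- ltri_pairs(map$nc)
  lab[map$iG] <- sprintf("G[%s,%s]", coef_names[pairs[, 2]], coef_names[pairs[, 1]])
  if (map$has_p1) {
    pp <- ltri_pairs(map$np1)
    lab[map$iP1] <- sprintf("P1[%d,%d]", pp[, 2] - 1, pp[, 1] - 1)
  }
  if (map$has_p2) {
    pp <- ltri_pairs(map$np2)
    lab[map$iP2] <- sprintf("P2[%d,%d]", pp[, 2] - 1, pp[, 1] - 1)
  }
  lab[map$iR] <- paste0("sigma2_e_", map$labels)
  lab
}

#' @rdname penfeed_tidiers
#' @export
tidy.penfeed_reml <- function(x, ...) {
  se <- if (!is.null(x$ai_inverse)) sqrt(pmax(diag(x$ai_inverse), 0)) else NA_real_
  tibble(term = theta_labels(x), estimate = x$theta, std_error = se)
}

#' @rdname penfeed_tidiers
#' @export
glance.penfeed_reml <- function(x, ...) {
  tibble(logLik = x$logLik, AIC = -2 * x$logLik + 2 * x$n_params,
         BIC = -2 * x$logLik + x$n_params * log(x$n_records),
         n_params = x$n_params, n_records = x$n_records,
         iterations = x$iterations, converged = x$converged)
}

#' @rdname penfeed_tidiers
#' @export
tidy.penfeed_cv <- function(x, ...) {
  tidyr::pivot_longer(x$stats, -"stratum", names_to = "statistic",
                      values_to = "value")
}

#' @rdname penfeed_tidiers
#' @export
glance.penfeed_cv <- function(x, ...) {
  tibble(n_folds = x$n_folds, n_animals = nrow(x$animal),
         n_groups = nrow(x$group),
         rho_fr_all = x$stats$rho_fr[x$stats$stratum == "all"],
         rho_yc_r = x$stats$rho_yc_r[x$stats$stratum == "group"])
}

#' Plot a heritability / variance trajectory
#'
#' @param object A `penfeed_trajectory` from [heritability_trajectory()].
#' @param what `"h2"` or `"variances"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.penfeed_trajectory <- function(object, what = c("h2", "variances"), ...) {
  what <- match.arg(what)
  if (what == "h2") {
    ggplot2::ggplot(object, ggplot2::aes(x = .data$day, y = .data$h2,
                                         colour = .data$trait)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "Days on test", y = expression(h^2),
                    colour = NULL) +
      ggplot2::theme_minimal()
  } else {
    long <- tidyr::pivot_longer(object,
                                c("sigma_a2", "sigma_pe2", "sigma_e2", "sigma_p2"),
                                names_to = "component", values_to = "variance")
    ggplot2::ggplot(long, ggplot2::aes(x = .data$day, y = .data$variance,
                                       colour = .data$component,
                                       linetype = .data$trait)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "Days on test", y = "Variance",
                    colour = NULL, linetype = NULL) +
      ggplot2::theme_minimal()
  }
}

#' Plot full- versus reduced-data predictions from a cross-validation
#'
#' @param object A `penfeed_cv` from [run_logo_cv()].
#' @param level `"animal"` or `"group"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.penfeed_cv <- function(object, level = c("animal", "group"), ...) {
  level <- match.arg(level)
  d <- if (level == "animal") object$animal else object$group
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$ebv_reduced, y = .data$ebv_full)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(x = "(G)EBV, reduced data", y = "(G)EBV, full data") +
    ggplot2::theme_minimal()
  if (level == "animal") p <- p + ggplot2::facet_wrap(~stratum)
  p
}

#' Plot the daily genetic-correlation trajectory
#'
#' @param r_daily Tibble from [daily_genetic_correlation()].
#' @param se Optional tibble from [trajectory_se()] with matching days.
#' @return A ggplot object.
#' @export
plot_genetic_correlation <- function(r_daily, se = NULL) {
  p <- ggplot2::ggplot(r_daily, ggplot2::aes(x = .data$day, y = .data$r)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Days on test", y = "Genetic correlation") +
    ggplot2::ylim(-1, 1) +
    ggplot2::theme_minimal()
  if (!is.null(se)) {
    d <- dplyr::left_join(r_daily, se, by = "day")
    p <- p +
      ggplot2::geom_line(data = d, ggplot2::aes(y = .data$r + .data$se), linetype = 3) +
      ggplot2::geom_line(data = d, ggplot2::aes(y = .data$r - .data$se), linetype = 3)
  }
  p
}
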