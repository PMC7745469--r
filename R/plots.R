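# ggplot2 displays for the standard MR data products. These mirror the
# field's conventional panels: the per-SNP scatter with one fitted line
# per method, the leave-one-SNP-out forest, and analytic power curves.

#' @rdname plot_mr_scatter
#' @param object An [mr_fit()] or `mr_scatter` object.
#' @param ... Unused.
#' @method autoplot mr_fit
#' @export
autoplot.mr_fit <- function(object, ...) {
  plot_mr_scatter(mr_scatter_data(object$data, object$estimates),
                  title = sprintf("%s → %s", object$exposure,
                                  object$outcome))
}

#' @method autoplot mr_scatter
#' @export
autoplot.mr_scatter <- function(object, ...) plot_mr_scatter(object)

#' Scatter plot of per-SNP effects with fitted method lines
#'
#' @param scatter An `mr_scatter` object from [mr_scatter_data()].
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_mr_scatter <- function(scatter, title = NULL) {
  p <- scatter$points
  ggplot2::ggplot(p, ggplot2::aes(x = .data$beta_exposure,
                                  y = .data$beta_outcome)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$beta_outcome - .data$se_outcome,
                   ymax = .data$beta_outcome + .data$se_outcome),
      colour = "grey70", width = 0) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$beta_exposure - .data$se_exposure,
                   xmax = .data$beta_exposure + .data$se_exposure),
      colour = "grey70", height = 0) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::geom_abline(
      data = scatter$lines,
      ggplot2::aes(slope = .data$slope, intercept = .data$intercept,
                   colour = .data$method)) +
    ggplot2::labs(x = "SNP effect on exposure (SD)",
                  y = "SNP effect on outcome",
                  colour = "Method", title = title) +
    ggplot2::theme_minimal()
}

#' Forest plot of a leave-one-SNP-out series
#'
#' @param loo Result of [mr_leave_one_out()].
#' @return A ggplot object.
#' @export
plot_leave_one_out <- function(loo) {
  loo$variant_id <- factor(loo$variant_id,
                           levels = rev(unique(loo$variant_id)))
  ggplot2::ggplot(loo, ggplot2::aes(x = .data$b, y = .data$variant_id)) +
    ggplot2::geom_vline(xintercept = loo$b[loo$variant_id == "all"],
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_lower, xmax = .data$ci_upper),
      height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "IVW estimate omitting variant", y = NULL) +
    ggplot2::theme_minimal()
}

#' Analytic IVW power curves for a binary outcome
#'
#' Power as a function of the true odds ratio per SD, one curve per
#' instrument variance explained — the conventional way of judging
#' whether a null MR estimate is informative.
#'
#' @param n_cases,n_controls Outcome GWAS case/control counts.
#' @param r2 Vector of instrument variance-explained values (one curve
#'   each).
#' @param or_range Range of odds ratios per SD to span.
#' @param alpha Two-sided significance level.
#' @return A ggplot object.
#' @export
plot_power_curves <- function(n_cases, n_controls, r2 = c(0.003, 0.05),
                              or_range = c(1, 2), alpha = 0.05) {
  grid <- tidyr::expand_grid(
    or = seq(or_range[1], or_range[2], length.out = 200),
    r2 = r2
  )
  grid$power <- mr_power(n_cases, n_controls, grid$r2, grid$or, alpha)
  grid$r2 <- factor(grid$r2)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$or, y = .data$power,
                                     colour = .data$r2)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.8, linetype = "dotted") +
    ggplot2::labs(x = "True odds ratio per SD of exposure", y = "Power",
                  colour = expression(r^2)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
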