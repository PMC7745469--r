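#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an MR fit into one row per estimate
#'
#' @param x An [mr_fit()] object.
#' @param ... Unused.
#' @return Tibble with `method`, `nsnp`, `b`, `se`, `ci_lower`,
#'   `ci_upper`, `pval`, `re_scale` (plus `exposure`/`outcome` labels).
#' @method tidy mr_fit
#' @export
tidy.mr_fit <- function(x, ...) {
  dplyr::mutate(x$estimates, exposure = x$exposure, outcome = x$outcome,
                .before = 1)
}

#' One-row summary of an MR fit
#'
#' @param x An [mr_fit()] object.
#' @param ... Unused.
#' @return One-row tibble: `exposure`, `outcome`, `nsnp`, `n_methods`,
#'   and IVW heterogeneity (`Q`, `Q_df`, `Q_pval`, `I2`) when available.
#' @method glance mr_fit
#' @export
glance.mr_fit <- function(x, ...) {
  het <- dplyr::filter(x$heterogeneity, .data$method == "ivw")
  tibble::tibble(
    exposure = x$exposure, outcome = x$outcome,
    nsnp = nrow(x$data), n_methods = length(unique(x$estimates$method)),
    Q = if (nrow(het)) het$Q else NA_real_,
    Q_df = if (nrow(het)) het$df else NA_integer_,
    Q_pval = if (nrow(het)) het$pval else NA_real_,
    I2 = if (nrow(het)) het$I2 else NA_real_
  )
}

#' Tidy a multivariable MR fit
#'
#' @param x An [mvmr_fit()] object.
#' @param ... Unused.
#' @return Tibble with one row per exposure (direct effects).
#' @method tidy mvmr_fit
#' @export
tidy.mvmr_fit <- function(x, ...) x$estimates

#' One-row summary of a multivariable MR fit
#'
#' @param x An [mvmr_fit()] object.
#' @param ... Unused.
#' @return One-row tibble with `nsnp`, `n_exposures` and residual
#'   heterogeneity `Q_mv`, `Q_df`, `Q_pval`.
#' @method glance mvmr_fit
#' @export
glance.mvmr_fit <- function(x, ...) {
  tibble::tibble(
    outcome = x$outcome, nsnp = x$estimates$nsnp[1],
    n_exposures = nrow(x$estimates),
    Q_mv = x$heterogeneity$Q, Q_df = x$heterogeneity$df,
    Q_pval = x$heterogeneity$pval
  )
}
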