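# Two-sample MR estimators. All take a harmonized set (or any data frame
# with beta_exposure/se_exposure/beta_outcome/se_outcome columns); only
# kept pairs enter the fit. Estimates are returned as one-row tibbles in
# the canonical MREstimate shape, with Cochran's Q attached where defined.

kept_or_abort <- function(hset, min_n, method) {
  k <- kept_pairs(hset)
  stopifnot_cols(k, c("beta_exposure", "se_exposure", "beta_outcome",
                      "se_outcome"), "harmonized set")
  if (nrow(k) < min_n) {
    abort_mr(sprintf("%s requires at least %d kept pairs (have %d)",
                     method, min_n, nrow(k)), "mr_insufficient_instruments")
  }
  k
}

#' Wald ratio estimate from a single variant
#'
#' The single-SNP causal estimate `beta_outcome / beta_exposure`. The
#' default standard error is the first-order delta method,
#' `se_outcome / |beta_exposure|`, which ignores exposure uncertainty; the
#' second-order form adds the `beta_outcome^2 * se_exposure^2 /
#' beta_exposure^4` term.
#'
#' @param pair A one-row harmonized pair (extra rows beyond the first are
#'   an error).
#' @param second_order Use the second-order delta-method SE?
#' @return A one-row estimate tibble (`method = "wald_ratio"`).
#' @export
wald_ratio <- function(pair, second_order = FALSE) {
  k <- kept_or_abort(pair, 1, "wald_ratio")
  if (nrow(k) != 1) {
    abort_mr("wald_ratio expects exactly one kept pair", "mr_bad_input")
  }
  bx <- k$beta_exposure
  by <- k$beta_outcome
  if (bx == 0) {
    abort_mr("wald_ratio undefined: beta_exposure is 0", "mr_undefined_ratio")
  }
  se <- if (second_order) {
    sqrt(k$se_outcome^2 / bx^2 + by^2 * k$se_exposure^2 / bx^4)
  } else {
    k$se_outcome / abs(bx)
  }
  estimate_row("wald_ratio", by / bx, se, nsnp = 1)
}

#' Inverse-variance-weighted (IVW) estimate
#'
#' Weighted regression of outcome betas on exposure betas through the
#' origin with weights `1/se_outcome^2` — the inverse-variance-weighted
#' meta-analysis of per-SNP Wald ratios. The reported SE is the
#' fixed-effect SE `(sum w beta_x^2)^(-1/2)` inflated by the
#' multiplicative random-effects scale `max(1, sqrt(Q/(J-1)))`, so it is
#' never deflated below the fixed-effect SE. Cochran's Q (df = J-1) is
#' attached; retrieve it with [heterogeneity()].
#'
#' @param hset Harmonized set with at least two kept pairs.
#' @return One-row estimate tibble (`method = "ivw"`) with the extra
#'   column `se_fixed`; heterogeneity attached as attribute.
#' @export
mr_ivw <- function(hset) {
  k <- kept_or_abort(hset, 2, "mr_ivw")
  w <- 1 / k$se_outcome^2
  sxx <- sum(w * k$beta_exposure^2)
  theta <- sum(w * k$beta_exposure * k$beta_outcome) / sxx
  se_fixed <- sqrt(1 / sxx)
  Q <- sum(w * (k$beta_outcome - theta * k$beta_exposure)^2)
  J <- nrow(k)
  phi <- max(1, sqrt(Q / (J - 1)))
  out <- estimate_row("ivw", theta, phi * se_fixed, nsnp = J, re_scale = phi)
  out$se_fixed <- se_fixed
  attr(out, "heterogeneity") <- heterogeneity_row(Q, J - 1)
  out
}

#' MR-Egger regression
#'
#' Weighted simple linear regression of outcome betas on exposure betas
#' (weights `1/se_outcome^2`), fitted from the explicit normal equations.
#' The intercept estimates average directional pleiotropy; the slope is
#' the causal estimate under the InSIDE assumption. Both SEs carry the
#' multiplicative random-effects scale `max(1, sqrt(Q'/(J-2)))`, with `Q'`
#' the weighted residual sum of squares (attached as heterogeneity,
#' df = J-2). Inference is normal-based throughout (no t-correction).
#'
#' Orient the input with [orient_positive_exposure()] first: the intercept
#' is only meaningful relative to a fixed exposure-effect direction.
#'
#' @param hset Harmonized set with at least three kept pairs and
#'   non-degenerate spread in `beta_exposure`.
#' @return Two-row estimate tibble (`egger_slope`, `egger_intercept`);
#'   heterogeneity attached as attribute.
#' @export
mr_egger <- function(hset) {
  k <- kept_or_abort(hset, 3, "mr_egger")
  bx <- k$beta_exposure
  by <- k$beta_outcome
  w <- 1 / k$se_outcome^2
  J <- nrow(k)
  sw <- sum(w)
  sx <- sum(w * bx)
  sy <- sum(w * by)
  sxx <- sum(w * bx^2)
  sxy <- sum(w * bx * by)
  det <- sw * sxx - sx^2
  if (det <= .Machine$double.eps * sw * sxx || sd(bx) == 0) {
    abort_mr("mr_egger: exposure betas are collinear with the intercept (no spread)",
             "mr_collinear")
  }
  slope <- (sw * sxy - sx * sy) / det
  intercept <- (sy - slope * sx) / sw
  Q <- sum(w * (by - intercept - slope * bx)^2)
  phi <- max(1, sqrt(Q / (J - 2)))
  se_slope <- sqrt(sw / det)
  se_intercept <- sqrt(sxx / det)
  out <- dplyr::bind_rows(
    estimate_row("egger_slope", slope, phi * se_slope, J, re_scale = phi),
    estimate_row("egger_intercept", intercept, phi * se_intercept, J,
                 re_scale = phi)
  )
  attr(out, "heterogeneity") <- heterogeneity_row(Q, J - 2)
  out
}

# Per-SNP Wald ratios and normalized weights shared by median and mode.
ratio_weights <- function(k) {
  theta <- k$beta_outcome / k$beta_exposure
  w <- k$beta_exposure^2 / k$se_outcome^2
  list(theta = theta, w = w / sum(w))
}

weighted_median_point <- function(theta, w) {
  ord <- order(theta)
  th <- theta[ord]
  ww <- w[ord] / sum(w)
  s <- cumsum(ww) - ww / 2
  if (0.5 <= s[1]) return(th[1])
  if (0.5 >= s[length(s)]) return(th[length(th)])
  stats::approx(s, th, xout = 0.5, ties = "ordered")$y
}

mode_bandwidth <- function(theta, bandwidth_factor) {
  J <- length(theta)
  spread <- min(sd(theta), stats::mad(theta))  # mad has consistency constant 1.4826
  bandwidth_factor * 0.9 * spread * J^(-1 / 5)
}

weighted_mode_point <- function(theta, w, bandwidth_factor, n_grid = 10000) {
  w <- w / sum(w)
  h <- mode_bandwidth(theta, bandwidth_factor)
  if (!is.finite(h) || h <= 0) {
    # degenerate spread: return the value carrying the most weight
    u <- sort(unique(theta))
    tot <- vapply(u, function(v) sum(w[theta == v]), numeric(1))
    return(u[which.max(tot)])
  }
  grid <- seq(min(theta) - 3 * h, max(theta) + 3 * h, length.out = n_grid)
  dens <- outer(grid, theta, function(g, t) stats::dnorm(g, t, h)) %*% w
  grid[which.max(dens)]
}

# Parametric bootstrap SE shared by the median and mode estimators:
# redraw both beta vectors from their reported normal sampling
# distributions and recompute the point estimate (weights included).
ratio_bootstrap_se <- function(k, point_fun, n_reps, seed) {
  if (n_reps < 100) {
    abort_mr("bootstrap requires n_reps >= 100", "mr_config_error")
  }
  J <- nrow(k)
  with_seed_if(seed, {
    est <- vapply(seq_len(n_reps), function(r) {
      bx <- stats::rnorm(J, k$beta_exposure, k$se_exposure)
      by <- stats::rnorm(J, k$beta_outcome, k$se_outcome)
      theta <- by / bx
      w <- bx^2 / k$se_outcome^2
      point_fun(theta, w / sum(w))
    }, numeric(1))
    sd(est)
  })
}

#' Weighted-median MR estimate
#'
#' The median of the per-SNP Wald ratios under inverse-variance weights
#' `w_j` proportional to `beta_exposure^2 / se_outcome^2`: ratios are
#' sorted, the standardized cumulative weight `s_j = sum(w_(1..j)) - w_j/2`
#' computed, and the estimate read off by linear interpolation at
#' `s = 0.5`. Consistent when valid instruments carry more than half the
#' weight. The SE is a seeded parametric bootstrap (both beta vectors
#' redrawn from their reported sampling distributions).
#'
#' @param hset Harmonized set with at least two kept pairs.
#' @param n_reps Bootstrap replicates (minimum 100).
#' @param seed Optional integer seed making the SE bit-reproducible.
#' @return One-row estimate tibble (`method = "weighted_median"`).
#' @export
mr_weighted_median <- function(hset, n_reps = 1000, seed = NULL) {
  k <- kept_or_abort(hset, 2, "mr_weighted_median")
  rw <- ratio_weights(k)
  b <- weighted_median_point(rw$theta, rw$w)
  se <- ratio_bootstrap_se(k, weighted_median_point, n_reps, seed)
  estimate_row("weighted_median", b, se, nsnp = nrow(k))
}

#' Weighted-mode MR estimate
#'
#' Assumes the largest cluster of per-SNP ratios is driven by valid
#' instruments: the estimate is the argmax of a weighted Gaussian kernel
#' density of the Wald ratios, evaluated on a 10,000-point grid spanning
#' `[min - 3h, max + 3h]`. Bandwidth
#' `h = bandwidth_factor * 0.9 * min(sd, 1.4826 * mad) * J^(-1/5)`. When
#' every ratio is identical the common value is returned. SE by the same
#' parametric bootstrap as [mr_weighted_median()].
#'
#' @param hset Harmonized set with at least three kept pairs.
#' @param bandwidth_factor Multiplier on the default bandwidth.
#' @param n_reps Bootstrap replicates (minimum 100).
#' @param seed Optional integer seed.
#' @param n_grid Grid resolution for the density argmax.
#' @return One-row estimate tibble (`method = "weighted_mode"`).
#' @export
mr_weighted_mode <- function(hset, bandwidth_factor = 1, n_reps = 1000,
                             seed = NULL, n_grid = 10000) {
  k <- kept_or_abort(hset, 3, "mr_weighted_mode")
  rw <- ratio_weights(k)
  b <- weighted_mode_point(rw$theta, rw$w, bandwidth_factor, n_grid)
  se <- ratio_bootstrap_se(
    k, function(th, w) weighted_mode_point(th, w, bandwidth_factor, n_grid),
    n_reps, seed
  )
  estimate_row("weighted_mode", b, se, nsnp = nrow(k))
}

#' Leave-one-SNP-out IVW series
#'
#' Recomputes the IVW estimate omitting each kept variant in turn, plus
#' the all-SNP estimate, to flag variants whose omission materially moves
#' the estimate.
#'
#' @param hset Harmonized set with at least three kept pairs.
#' @return Tibble with one row per omitted variant (in input order) and a
#'   final row `variant_id = "all"`.
#' @export
mr_leave_one_out <- function(hset) {
  k <- kept_or_abort(hset, 3, "mr_leave_one_out")
  rows <- purrr::map(seq_len(nrow(k)), function(i) {
    est <- mr_ivw(k[-i, ])
    dplyr::mutate(est, variant_id = k$variant_id[i], .before = 1)
  })
  all_est <- dplyr::mutate(mr_ivw(k), variant_id = "all", .before = 1)
  dplyr::bind_rows(rows, all_est)
}

#' Per-SNP scatter data with fitted method lines
#'
#' The data behind the conventional MR scatter plot: per-variant exposure
#' and outcome betas with SEs, plus one `(slope, intercept)` line per
#' fitted method (intercept 0 for all slope-through-origin methods; the
#' MR-Egger line uses its fitted intercept).
#'
#' @param hset Harmonized set.
#' @param estimates Estimate tibble as produced by the `mr_*` functions or
#'   [mr_fit()].
#' @return A list of class `mr_scatter` with tibbles `points` and `lines`.
#' @export
mr_scatter_data <- function(hset, estimates) {
  k <- kept_pairs(hset)
  points <- dplyr::select(k, dplyr::any_of(c(
    "variant_id", "beta_exposure", "se_exposure", "beta_outcome", "se_outcome"
  )))
  est <- tibble::as_tibble(estimates)
  egger_int <- est$b[est$method == "egger_intercept"]
  lines <- est |>
    dplyr::filter(.data$method != "egger_intercept") |>
    dplyr::transmute(
      method = .data$method,
      slope = .data$b,
      intercept = ifelse(.data$method == "egger_slope",
                         ifelse(length(egger_int) == 1, egger_int, NA_real_),
                         0)
    )
  structure(list(points = points, lines = lines), class = "mr_scatter")
}

#' Approximate power of the IVW test for a binary outcome
#'
#' Standard analytic approximation: the non-centrality of the IVW z-test
#' is `log(OR) * sqrt(n * cf * (1 - cf) * r2)` with `cf` the case
#' fraction and `r2` the variance in the exposure explained by the
#' instrument set; power is the two-sided normal tail beyond the
#' `alpha`-critical value. Monotone in `n`, `r2` and `|log OR|`; equals
#' `alpha` at OR = 1.
#'
#' @param n_cases,n_controls Outcome GWAS case and control counts.
#' @param r2 Variance explained in the exposure by the instruments, in
#'   (0, 1).
#' @param or_per_sd True odds ratio per SD of exposure (> 0).
#' @param alpha Two-sided significance level.
#' @return Power in (0, 1); vectorized over its arguments.
#' @export
mr_power <- function(n_cases, n_controls, r2, or_per_sd, alpha = 0.05) {
  if (any(n_cases <= 0) || any(n_controls <= 0) || any(r2 <= 0) ||
      any(r2 >= 1) || any(or_per_sd <= 0) || any(alpha <= 0) ||
      any(alpha >= 1)) {
    abort_mr("mr_power: invalid query", "mr_config_error")
  }
  n <- n_cases + n_controls
  cf <- n_cases / n
  ncp <- log(or_per_sd) * sqrt(n * cf * (1 - cf) * r2)
  crit <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(-crit + ncp) + stats::pnorm(-crit - ncp)
}

#' Heterogeneity statistics attached to an estimate
#'
#' @param x An estimate from [mr_ivw()], [mr_egger()], [mvmr_fit()] or an
#'   [mr_fit()] object.
#' @return Tibble with `Q`, `df`, `pval`, `I2` (and a `method` column for
#'   [mr_fit()] objects).
#' @export
heterogeneity <- function(x) {
  if (inherits(x, "mr_fit") || inherits(x, "mvmr_fit")) return(x$heterogeneity)
  attr(x, "heterogeneity") %||%
    abort_mr("heterogeneity: no heterogeneity statistics attached",
             "mr_bad_input")
}

#' Fit the full set of two-sample MR estimators
#'
#' Applies every estimator the kept-pair count supports: the Wald ratio
#' for a single variant; IVW and the weighted median for two or more;
#' MR-Egger (after [orient_positive_exposure()]) and the weighted mode
#' for three or more. Heterogeneity (IVW's Q, Egger's residual Q') is
#' collected alongside.
#'
#' @param hset Harmonized set.
#' @param n_reps,seed Bootstrap control for the median/mode SEs.
#' @param bandwidth_factor Passed to [mr_weighted_mode()].
#' @return An object of class `mr_fit`: list with `estimates`,
#'   `heterogeneity`, `data`, `exposure`, `outcome`. Methods: [tidy()],
#'   [glance()], [ggplot2::autoplot()].
#' @export
mr_fit <- function(hset, n_reps = 1000, seed = NULL, bandwidth_factor = 1) {
  k <- kept_or_abort(hset, 1, "mr_fit")
  J <- nrow(k)
  ests <- list()
  het <- list()
  if (J == 1) {
    ests$wald <- wald_ratio(k)
  } else {
    ivw <- mr_ivw(k)
    ests$ivw <- ivw
    het$ivw <- dplyr::mutate(heterogeneity(ivw), method = "ivw", .before = 1)
    ests$wm <- mr_weighted_median(k, n_reps = n_reps, seed = seed)
    if (J >= 3) {
      oriented <- orient_positive_exposure(k)
      egger <- tryCatch(mr_egger(oriented), mr_collinear = function(e) NULL)
      if (!is.null(egger)) {
        ests$egger <- egger
        het$egger <- dplyr::mutate(heterogeneity(egger), method = "egger",
                                   .before = 1)
      }
      ests$mode <- mr_weighted_mode(k, bandwidth_factor = bandwidth_factor,
                                    n_reps = n_reps, seed = seed)
    }
  }
  structure(
    list(
      estimates = dplyr::bind_rows(ests),
      heterogeneity = dplyr::bind_rows(het),
      data = k,
      exposure = attr(hset, "exposure") %||% NA_character_,
      outcome = attr(hset, "outcome") %||% NA_character_
    ),
    class = "mr_fit"
  )
}

#' @export
print.mr_fit <- function(x, ...) {
  cat(sprintf("<mr_fit> %s -> %s (%d SNPs)\n",
              x$exposure, x$outcome, nrow(x$data)))
  print(x$estimates)
  invisible(x)
}
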