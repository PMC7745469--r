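#' Harmonize several exposures and one outcome onto a shared allele frame
#'
#' Builds the wide per-variant table multivariable MR consumes: the first
#' exposure's alleles define the reference frame, every other exposure and
#' the outcome are aligned to it with [harmonize()], and only variants
#' kept for every trait are retained.
#'
#' @param exposures Named list of summary-statistics tibbles (canonical
#'   columns), one per exposure; names are the exposure trait ids.
#' @param outcome Outcome summary-statistics tibble.
#' @param variants Optional variant ids to restrict to (e.g. a clumped
#'   union of instrument sets).
#' @param eaf_window Palindrome ambiguity window, as in [harmonize()].
#' @return A tibble of class `mr_multi_harmonized` with columns
#'   `variant_id`, `effect_allele`, `other_allele`, then `beta_<id>` and
#'   `se_<id>` per exposure, and `beta_outcome`, `se_outcome`. Attributes
#'   `exposures` and `outcome` hold the trait ids.
#' @export
harmonize_multi <- function(exposures, outcome, variants = NULL,
                            eaf_window = c(0.42, 0.58)) {
  if (!is.list(exposures) || is.null(names(exposures)) ||
      any(names(exposures) == "")) {
    abort_mr("harmonize_multi: exposures must be a named list", "mr_bad_input")
  }
  ref <- tibble::as_tibble(exposures[[1]])
  if (!is.null(variants)) {
    ref <- dplyr::filter(ref, .data$variant_id %in% variants)
  }
  if (nrow(ref) == 0) {
    abort_mr("harmonize_multi: no reference variants", "mr_data_error")
  }
  out <- tibble::tibble(
    variant_id = ref$variant_id,
    effect_allele = toupper(ref$effect_allele),
    other_allele = toupper(ref$other_allele)
  )
  out[[paste0("beta_", names(exposures)[1])]] <- ref$beta
  out[[paste0("se_", names(exposures)[1])]] <- ref$se
  keep <- rep(TRUE, nrow(ref))

  align_to_ref <- function(tbl) {
    h <- harmonize(ref, tbl, eaf_window = eaf_window)
    list(keep = h$status %in% KEPT_STATUSES,
         beta = h$beta_outcome, se = h$se_outcome)
  }
  for (id in names(exposures)[-1]) {
    a <- align_to_ref(exposures[[id]])
    keep <- keep & a$keep
    out[[paste0("beta_", id)]] <- a$beta
    out[[paste0("se_", id)]] <- a$se
  }
  a <- align_to_ref(outcome)
  keep <- keep & a$keep
  out$beta_outcome <- a$beta
  out$se_outcome <- a$se
  out <- out[keep, ]
  structure(out,
            exposures = names(exposures),
            outcome = outcome[["trait_id"]][1] %||% "outcome",
            class = c("mr_multi_harmonized", class(tibble::tibble())))
}

mvmr_matrices <- function(mset, exposures = NULL) {
  exposures <- exposures %||% attr(mset, "exposures")
  if (is.null(exposures)) {
    bcols <- grep("^beta_", names(mset), value = TRUE)
    exposures <- sub("^beta_", "", setdiff(bcols, "beta_outcome"))
  }
  stopifnot_cols(mset, c(paste0("beta_", exposures), "beta_outcome",
                         "se_outcome"), "multi-harmonized set")
  X <- as.matrix(mset[paste0("beta_", exposures)])
  colnames(X) <- exposures
  secols <- paste0("se_", exposures)
  SE <- if (all(secols %in% names(mset))) {
    as.matrix(mset[secols])
  } else {
    NULL
  }
  list(X = X, SE = SE, y = mset$beta_outcome, w = 1 / mset$se_outcome^2,
       exposures = exposures)
}

#' Multivariable MR: joint direct effects of several exposures
#'
#' Weighted multiple regression of outcome betas on the exposure beta
#' columns, no intercept, weights `1/se_outcome^2`, solved from the
#' explicit normal equations. SEs carry the multiplicative random-effects
#' scale `max(1, sqrt(Q_mv/(J-K)))`, where `Q_mv` is the weighted residual
#' sum of squares (residual heterogeneity, df = J-K). Conditional
#' F-statistics (see [conditional_f()]) are appended per exposure when
#' exposure SEs are available.
#'
#' An exposure column with zero weighted norm is dropped from the fit
#' (its estimate reported `NA`) with a warning; genuinely collinear
#' non-degenerate columns raise an identifiability error naming the pair.
#'
#' @param mset A [harmonize_multi()] result, or any data frame with
#'   `beta_<id>`/`se_<id>` exposure columns and `beta_outcome`,
#'   `se_outcome`.
#' @param exposures Exposure ids (defaults to those recorded on `mset`).
#' @param conditional_f Compute conditional F-statistics?
#' @return An object of class `mvmr_fit`: list with `estimates` (one row
#'   per exposure, `method = "mvmr"`), `heterogeneity` (Q_mv), `data`.
#' @export
mvmr_fit <- function(mset, exposures = NULL, conditional_f = TRUE) {
  mat <- mvmr_matrices(mset, exposures)
  X <- mat$X
  y <- mat$y
  w <- mat$w
  J <- nrow(X)
  K <- ncol(X)
  if (J < K + 2) {
    abort_mr(sprintf("mvmr_fit needs J >= K + 2 variants (J = %d, K = %d)",
                     J, K), "mr_insufficient_instruments")
  }
  norms <- colSums(w * X^2)
  active <- norms > 0
  if (any(!active)) {
    rlang::warn(sprintf(
      "mvmr_fit: dropping exposure(s) with all-zero instrument effects: %s",
      paste(colnames(X)[!active], collapse = ", ")))
  }
  Xa <- X[, active, drop = FALSE]
  Ka <- ncol(Xa)
  XtWX <- crossprod(Xa, w * Xa)
  qr_x <- qr(sqrt(w) * Xa)
  if (qr_x$rank < Ka) {
    cc <- stats::cor(Xa)
    pair <- which(abs(cc) == max(abs(cc[upper.tri(cc)])), arr.ind = TRUE)
    pair <- pair[pair[, 1] < pair[, 2], , drop = FALSE][1, ]
    abort_mr(sprintf(
      "mvmr_fit: design is rank deficient; exposures '%s' and '%s' are collinear",
      colnames(Xa)[pair[1]], colnames(Xa)[pair[2]]), "mr_collinear")
  }
  XtWy <- crossprod(Xa, w * y)
  beta <- drop(solve(XtWX, XtWy))
  resid <- y - drop(Xa %*% beta)
  Q <- sum(w * resid^2)
  df <- J - Ka
  phi <- max(1, sqrt(Q / df))
  se_fixed <- sqrt(diag(solve(XtWX)))

  b_full <- se_full <- rep(NA_real_, K)
  b_full[active] <- beta
  se_full[active] <- phi * se_fixed
  est <- tibble::tibble(
    exposure = colnames(X),
    method = "mvmr",
    nsnp = as.integer(J),
    b = b_full,
    se = se_full,
    ci_lower = b_full - Z95 * se_full,
    ci_upper = b_full + Z95 * se_full,
    pval = ifelse(is.na(b_full), NA_real_, two_sided_p(b_full / se_full)),
    re_scale = phi
  )
  if (conditional_f && !is.null(mat$SE) && K >= 1) {
    est$conditional_f <- vapply(
      seq_len(K),
      function(k) {
        if (!active[k]) return(NA_real_)
        tryCatch(conditional_f(mset, exposure = colnames(X)[k],
                               exposures = colnames(X)),
                 error = function(e) NA_real_)
      },
      numeric(1))
  }
  structure(
    list(estimates = est, heterogeneity = heterogeneity_row(Q, df),
         data = tibble::as_tibble(mset),
         outcome = attr(mset, "outcome") %||% "outcome"),
    class = "mvmr_fit"
  )
}

#' @export
print.mvmr_fit <- function(x, ...) {
  cat(sprintf("<mvmr_fit> %d exposures -> %s (%d SNPs)\n",
              nrow(x$estimates), x$outcome, x$estimates$nsnp[1]))
  print(x$estimates)
  invisible(x)
}

#' Conditional F-statistic for one exposure in a multivariable model
#'
#' Instrument strength of exposure `k` net of the other exposures, from
#' summary data with zero assumed cross-study covariance: nuisance
#' coefficients `delta` minimize
#' `Q_xk = sum_j (beta_kj - sum_l delta_l beta_lj)^2 /
#' (se_kj^2 + sum_l delta_l^2 se_lj^2)`
#' (Nelder-Mead from `delta = 0` with 5 jittered restarts, relative
#' tolerance 1e-8), and the conditional F is `Q_xk / (J - K + 1)`. With a
#' single exposure this reduces to the mean per-SNP F-statistic scaling,
#' `sum((beta/se)^2) / J`. Nuisance exposures whose instrument effects are
#' identically zero are excluded from the minimization (their `delta`
#' fixed at 0), since they carry no explanatory signal and would only
#' inflate the variance term.
#'
#' @param mset A [harmonize_multi()] result (exposure SE columns
#'   required).
#' @param exposure Name (or index) of the exposure whose conditional
#'   strength is wanted.
#' @param exposures Exposure ids (defaults to those recorded on `mset`).
#' @param n_restarts Jittered restarts around `delta = 0`.
#' @return The conditional F-statistic (non-negative scalar).
#' @export
conditional_f <- function(mset, exposure, exposures = NULL, n_restarts = 5) {
  mat <- mvmr_matrices(mset, exposures)
  if (is.null(mat$SE)) {
    abort_mr("conditional_f: exposure se columns are required", "mr_bad_input")
  }
  K <- ncol(mat$X)
  J <- nrow(mat$X)
  if (is.numeric(exposure)) exposure <- mat$exposures[exposure]
  k <- match(exposure, mat$exposures)
  if (is.na(k)) {
    abort_mr(sprintf("conditional_f: unknown exposure '%s'", exposure),
             "mr_bad_input")
  }
  if (J < K + 1) {
    abort_mr("conditional_f needs J >= K + 1", "mr_insufficient_instruments")
  }
  bk <- mat$X[, k]
  sk2 <- mat$SE[, k]^2
  others <- setdiff(seq_len(K), k)
  # exclude degenerate nuisance exposures (all-zero effects): delta = 0
  others <- others[colSums(mat$X[, others, drop = FALSE]^2) > 0]
  qfun <- function(delta) {
    if (length(delta) == 0) return(sum(bk^2 / sk2))
    Bl <- mat$X[, others, drop = FALSE]
    Sl2 <- mat$SE[, others, drop = FALSE]^2
    num <- (bk - drop(Bl %*% delta))^2
    den <- sk2 + drop(Sl2 %*% delta^2)
    sum(num / den)
  }
  if (length(others) == 0) {
    qmin <- qfun(numeric(0))
  } else {
    starts <- c(list(rep(0, length(others))),
                lapply(seq_len(n_restarts - 1), function(i) {
                  withr::with_seed(i, stats::rnorm(length(others), 0, 0.1))
                }))
    fits <- lapply(starts, function(s) {
      # NM also drives the 1-d case: the jittered restarts cover its
      # known sensitivity to the initial simplex there
      suppressWarnings(
        stats::optim(s, qfun, method = "Nelder-Mead",
                     control = list(reltol = 1e-8, maxit = 2000))
      )
    })
    qmin <- min(vapply(fits, function(f) f$value, numeric(1)))
  }
  qmin / (J - K + 1)
}
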