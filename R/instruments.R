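#' Construct and validate a pairwise LD matrix
#'
#' @param r2 Square numeric matrix of pairwise r-squared values.
#' @param variant_ids Variant identifiers for the rows/columns; defaults to
#'   existing dimnames.
#' @return The validated matrix (symmetric, unit diagonal, values in
#'   \[0, 1\]) with dimnames set, classed `mr_ld_matrix`.
#' @export
ld_matrix <- function(r2, variant_ids = NULL) {
  r2 <- as.matrix(r2)
  variant_ids <- variant_ids %||% rownames(r2)
  if (is.null(variant_ids) || length(variant_ids) != nrow(r2)) {
    abort_mr("ld_matrix: variant_ids must label every row", "mr_bad_input")
  }
  if (nrow(r2) != ncol(r2)) abort_mr("ld_matrix: must be square", "mr_bad_input")
  if (any(is.na(r2)) || any(r2 < 0) || any(r2 > 1)) {
    abort_mr("ld_matrix: r2 values must lie in [0, 1]", "mr_bad_input")
  }
  if (max(abs(r2 - t(r2))) > 1e-12) {
    abort_mr("ld_matrix: must be symmetric", "mr_bad_input")
  }
  if (any(abs(diag(r2) - 1) > 1e-12)) {
    abort_mr("ld_matrix: diagonal must be exactly 1", "mr_bad_input")
  }
  diag(r2) <- 1
  dimnames(r2) <- list(variant_ids, variant_ids)
  class(r2) <- c("mr_ld_matrix", class(r2))
  r2
}

#' Select genome-wide-significant, LD-independent instruments
#'
#' Greedy LD clumping: variants with `pval < p_threshold` are ranked by
#' p-value (ties broken by `variant_id`, lexicographically); the best
#' remaining variant is kept and every other candidate with
#' `r2 >= r2_threshold` to it is removed, until no candidates remain. The
#' defaults are the conventional genome-wide thresholds (P < 5e-8,
#' r-squared < 0.001).
#'
#' @param assocs Summary-statistics tibble (see [read_summary_stats()]).
#' @param ld An [ld_matrix()] covering every candidate variant.
#' @param p_threshold Inclusion threshold on `pval` (strict `<`).
#' @param r2_threshold Variants with `r2 >=` this to a kept variant are
#'   removed.
#' @return The selected rows of `assocs`, in kept order.
#' @export
select_instruments <- function(assocs, ld, p_threshold = 5e-8,
                               r2_threshold = 0.001) {
  stopifnot_cols(assocs, c("variant_id", "pval"), "assocs")
  cand <- dplyr::filter(assocs, .data$pval < p_threshold)
  if (nrow(cand) == 0) {
    rlang::warn("select_instruments: no variant passes the p-value threshold")
    return(cand)
  }
  absent <- setdiff(cand$variant_id, rownames(ld))
  if (length(absent) > 0) {
    abort_mr(sprintf("select_instruments: variant(s) absent from LD matrix: %s",
                     paste(utils::head(absent, 5), collapse = ", ")),
             "mr_data_error")
  }
  cand <- dplyr::arrange(cand, .data$pval, .data$variant_id)
  remaining <- cand$variant_id
  kept <- character(0)
  while (length(remaining) > 0) {
    best <- remaining[1]
    kept <- c(kept, best)
    r2_to_best <- ld[best, remaining]
    remaining <- remaining[r2_to_best < r2_threshold]
  }
  out <- cand[match(kept, cand$variant_id), ]
  if (nrow(out) == 0) rlang::warn("select_instruments: empty selection")
  out
}

#' Instrument-strength diagnostics (variance explained and F-statistics)
#'
#' Per-SNP variance explained uses the large-sample approximation for a
#' standardized trait, `R2_j = beta_j^2 / (beta_j^2 + n * se_j^2)`; the
#' per-SNP F-statistic is the squared z-score `(beta_j / se_j)^2`. The
#' aggregate F over K independent SNPs is
#' `F = (R2 / (1 - R2)) * ((N - K - 1) / K)` with `R2` the summed per-SNP
#' variance explained.
#'
#' @param x A summary-statistics tibble (columns `beta`, `se`) or a
#'   harmonized set (columns `beta_exposure`, `se_exposure`; only kept
#'   pairs are used).
#' @param n Exposure GWAS sample size; taken from an `n` column when
#'   present and not supplied.
#' @return A one-row tibble with `k`, `n`, `r2_total`, `f_aggregate`,
#'   `f_mean`, `f_min`; per-SNP values are attached as attribute
#'   `"per_snp"` (see [per_snp_strength()]).
#' @export
instrument_strength <- function(x, n = NULL) {
  if (inherits(x, "mr_harmonized") || "beta_exposure" %in% names(x)) {
    k <- kept_pairs(x)
    beta <- k$beta_exposure
    se <- k$se_exposure
    ids <- k$variant_id
    if (is.null(n) && "n_exposure" %in% names(k)) n <- k$n_exposure[1]
  } else {
    stopifnot_cols(x, c("beta", "se"), "assocs")
    beta <- x$beta
    se <- x$se
    ids <- x$variant_id
    if (is.null(n) && "n" %in% names(x)) n <- x$n[1]
  }
  if (is.null(n) || is.na(n)) {
    abort_mr("instrument_strength: exposure sample size n is required",
             "mr_config_error")
  }
  K <- length(beta)
  r2_snp <- beta^2 / (beta^2 + n * se^2)
  f_snp <- (beta / se)^2
  r2 <- sum(r2_snp)
  out <- tibble::tibble(
    k = as.integer(K), n = as.integer(n), r2_total = r2,
    f_aggregate = (r2 / (1 - r2)) * ((n - K - 1) / K),
    f_mean = mean(f_snp), f_min = min(f_snp)
  )
  attr(out, "per_snp") <- tibble::tibble(variant_id = ids, r2 = r2_snp,
                                         f = f_snp)
  out
}

#' Per-SNP strength table behind [instrument_strength()]
#'
#' @param x The result of [instrument_strength()].
#' @return Tibble with columns `variant_id`, `r2`, `f`.
#' @export
per_snp_strength <- function(x) {
  attr(x, "per_snp") %||%
    abort_mr("per_snp_strength: no per-SNP table attached", "mr_bad_input")
}
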