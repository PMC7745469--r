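#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Standard step-up adjustment: with p-values sorted ascending,
#' `p_adj(i) = min over k >= i of (m * p(k) / k)`, clipped at 1, returned
#' in the input order.
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(is.na(pvals)) || any(pvals <= 0) || any(pvals > 1)) {
    abort_mr("bh_fdr: p-values must lie in (0, 1]", "mr_bad_input")
  }
  m <- length(pvals)
  ord <- order(pvals)
  sorted <- pvals[ord]
  adj_sorted <- pmin(1, rev(cummin(rev(m * sorted / seq_len(m)))))
  adj <- numeric(m)
  adj[ord] <- adj_sorted
  adj
}

#' Screen a mediator panel under FDR control
#'
#' Applies [bh_fdr()] to the step-1 (exposure to mediator) p-values —
#' by default separately within each exposure across the full panel —
#' and selects the union over exposures of mediators with adjusted
#' p-value at or below `fdr_alpha`. The joint family (one correction over
#' all exposure-mediator pairs) is available as an option.
#'
#' @param step1 Tibble of step-1 results with columns `exposure`,
#'   `mediator`, `pval`.
#' @param fdr_alpha Selection threshold on the adjusted p-value.
#' @param family `"per_exposure"` (default) or `"joint"`.
#' @return `step1` with columns `pval_fdr` and `selected` appended; the
#'   selected mediator ids are available via [selected_mediators()].
#' @export
screen_mediators <- function(step1, fdr_alpha = 0.05,
                             family = c("per_exposure", "joint")) {
  family <- match.arg(family)
  stopifnot_cols(step1, c("exposure", "mediator", "pval"), "step1 results")
  out <- tibble::as_tibble(step1)
  if (family == "per_exposure") {
    out <- out |>
      dplyr::group_by(.data$exposure) |>
      dplyr::mutate(pval_fdr = bh_fdr(.data$pval)) |>
      dplyr::ungroup()
  } else {
    out$pval_fdr <- bh_fdr(out$pval)
  }
  hits <- unique(out$mediator[out$pval_fdr <= fdr_alpha])
  out$selected <- out$mediator %in% hits
  attr(out, "selected") <- sort(hits)
  attr(out, "fdr_alpha") <- fdr_alpha
  attr(out, "family") <- family
  out
}

#' Mediators selected by [screen_mediators()]
#'
#' @param screened The annotated tibble returned by [screen_mediators()].
#' @return Character vector of selected mediator ids (union over
#'   exposures), sorted.
#' @export
selected_mediators <- function(screened) {
  attr(screened, "selected") %||%
    sort(unique(screened$mediator[screened$selected]))
}

#' Classify mediation records by direction consistency
#'
#' A mediator is direction-consistent with mediation of the total
#' exposure-outcome effect when the sign of (step-1 effect) times
#' (step-2 effect) equals the sign of the total effect. Records whose
#' step-2 confidence interval spans zero are additionally flagged
#' `weak_step2`.
#'
#' @param records Tibble with columns `step1_b`, `step2_b`,
#'   `step2_ci_lower`, `step2_ci_upper` (one row per exposure-mediator
#'   pair).
#' @param total One-row estimate for the total exposure-outcome effect
#'   (column `b`), or a plain number.
#' @return `records` with `direction` (`"consistent"`/`"inconsistent"`,
#'   `NA` when any estimate is missing) and `weak_step2` appended.
#' @export
classify_mediation <- function(records, total) {
  stopifnot_cols(records, c("step1_b", "step2_b", "step2_ci_lower",
                            "step2_ci_upper"), "mediation records")
  total_b <- if (is.numeric(total)) total[1] else total$b[1]
  out <- tibble::as_tibble(records)
  prod_sign <- sign(out$step1_b) * sign(out$step2_b)
  out$direction <- dplyr::case_when(
    is.na(out$step1_b) | is.na(out$step2_b) ~ NA_character_,
    prod_sign == sign(total_b) ~ "consistent",
    TRUE ~ "inconsistent"
  )
  out$weak_step2 <- !is.na(out$step2_ci_lower) &
    out$step2_ci_lower < 0 & out$step2_ci_upper > 0
  out
}

#' Pick one representative mediator per class by instrument strength
#'
#' Within each mediator class the member with the highest aggregate
#' F-statistic is chosen (ties broken lexicographically by mediator id),
#' mirroring the convention of adjusting for the strongest-instrumented
#' member of each correlated metabolite class.
#'
#' @param diagnostics Tibble with columns `mediator` and `f_aggregate`.
#' @param classes Named character vector mapping mediator id to class, or
#'   a tibble with columns `mediator`, `class`.
#' @return Tibble with one row per class: `class`, `mediator`,
#'   `f_aggregate`.
#' @export
select_representatives <- function(diagnostics, classes) {
  stopifnot_cols(diagnostics, c("mediator", "f_aggregate"), "diagnostics")
  if (!is.data.frame(classes)) {
    classes <- tibble::tibble(mediator = names(classes),
                              class = unname(classes))
  }
  stopifnot_cols(classes, c("mediator", "class"), "classes")
  empty <- setdiff(classes$class, classes$class[
    classes$mediator %in% diagnostics$mediator])
  if (length(empty) > 0) {
    abort_mr(sprintf("select_representatives: class(es) with no diagnosed member: %s",
                     paste(empty, collapse = ", ")), "mr_bad_input")
  }
  dplyr::inner_join(diagnostics, classes, by = "mediator") |>
    dplyr::arrange(dplyr::desc(.data$f_aggregate), .data$mediator) |>
    dplyr::distinct(.data$class, .keep_all = TRUE) |>
    dplyr::arrange(.data$class) |>
    dplyr::select("class", "mediator", "f_aggregate")
}
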