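COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Harmonize exposure and outcome summary statistics to one effect allele
#'
#' Aligns each shared variant's outcome association onto the exposure's
#' effect-allele frame, assuming both GWAS report the forward strand but
#' tolerating recorded strand flips:
#'
#' * identical alleles in the same order: kept unchanged;
#' * identical alleles swapped: outcome beta negated, eaf reflected
#'   (`sign_flipped`);
#' * alleles that are strand complements of either case: complemented,
#'   then treated as above (`strand_flipped`);
#' * palindromic variants (A/T or C/G), where letters cannot resolve the
#'   strand: aligned by effect-allele-frequency agreement, but only when
#'   both studies' frequencies lie outside the ambiguity window
#'   (`dropped_palindromic` otherwise, including when either eaf is
#'   missing);
#' * irreconcilable allele pairs: `dropped_incompatible`;
#' * variants absent from the outcome: `dropped_missing_outcome`.
#'
#' For palindromic variants the status records the net operation: letter
#' alignment alone gives `kept`/`sign_flipped`; a flip forced by the
#' frequency comparison gives `strand_flipped`.
#'
#' @param exposure,outcome Summary-statistics tibbles (canonical columns;
#'   see [read_summary_stats()]).
#' @param eaf_window Open eaf interval inside which a palindromic variant
#'   is considered unresolvable (default `c(0.42, 0.58)`).
#' @return A tibble of class `mr_harmonized` with one row per exposure
#'   variant: `variant_id`, exposure-frame `effect_allele`/`other_allele`,
#'   `beta_exposure`, `se_exposure`, `pval_exposure`, `eaf_exposure`,
#'   `n_exposure`, aligned `beta_outcome`, `se_outcome`, `eaf_outcome`,
#'   and `status`. Use [kept_pairs()] for the rows entering estimation and
#'   [harmonization_report()] for the per-status counts.
#' @export
harmonize <- function(exposure, outcome, eaf_window = c(0.42, 0.58)) {
  stopifnot_cols(exposure, c("variant_id", "effect_allele", "other_allele",
                             "beta", "se"), "exposure")
  stopifnot_cols(outcome, c("variant_id", "effect_allele", "other_allele",
                            "beta", "se"), "outcome")
  if (length(intersect(exposure$variant_id, outcome$variant_id)) == 0) {
    abort_mr("harmonize: no shared variants between exposure and outcome",
             "mr_data_error")
  }
  exp <- tibble::as_tibble(exposure)
  if (!"eaf" %in% names(exp)) exp$eaf <- NA_real_
  if (!"pval" %in% names(exp)) exp$pval <- NA_real_
  if (!"n" %in% names(exp)) exp$n <- NA_real_
  out <- tibble::as_tibble(outcome)
  if (!"eaf" %in% names(out)) out$eaf <- NA_real_

  m <- match(exp$variant_id, out$variant_id)
  ea_e <- toupper(exp$effect_allele)
  oa_e <- toupper(exp$other_allele)
  ea_o <- toupper(out$effect_allele[m])
  oa_o <- toupper(out$other_allele[m])
  b_o <- out$beta[m]
  se_o <- out$se[m]
  eaf_o <- out$eaf[m]

  n <- nrow(exp)
  status <- rep("dropped_missing_outcome", n)
  beta_out <- rep(NA_real_, n)
  se_out <- rep(NA_real_, n)
  eaf_out <- rep(NA_real_, n)

  present <- !is.na(m)
  pal <- present & ea_e == unname(COMPLEMENT[oa_e])
  same <- present & ea_o == ea_e & oa_o == oa_e
  swap <- present & ea_o == oa_e & oa_o == ea_e
  comp_same <- present & !pal & ea_o == unname(COMPLEMENT[ea_e]) &
    oa_o == unname(COMPLEMENT[oa_e])
  comp_swap <- present & !pal & ea_o == unname(COMPLEMENT[oa_e]) &
    oa_o == unname(COMPLEMENT[ea_e])
  for (v in c("pal", "same", "swap", "comp_same", "comp_swap")) {
    x <- get(v)
    x[is.na(x)] <- FALSE
    assign(v, x)
  }

  set <- function(idx, st, flip) {
    status[idx] <<- st
    beta_out[idx] <<- ifelse(flip[idx], -b_o[idx], b_o[idx])
    se_out[idx] <<- se_o[idx]
    eaf_out[idx] <<- ifelse(flip[idx], 1 - eaf_o[idx], eaf_o[idx])
  }
  no_flip <- rep(FALSE, n)
  all_flip <- rep(TRUE, n)

  # non-palindromic letter logic
  set(which(!pal & same), "kept", no_flip)
  set(which(!pal & swap), "sign_flipped", all_flip)
  set(which(comp_same), "strand_flipped", no_flip)
  set(which(comp_swap), "strand_flipped", all_flip)
  status[present & !pal & !same & !swap & !comp_same & !comp_swap] <-
    "dropped_incompatible"

  # palindromic variants: letters can only be same-order or swapped
  # (their complements coincide); anything else is incompatible
  pal_same <- pal & same
  pal_swap <- pal & swap
  status[pal & !same & !swap] <- "dropped_incompatible"
  if (any(pal_same | pal_swap)) {
    idx <- which(pal_same | pal_swap)
    eaf_e_i <- exp$eaf[idx]
    # letter alignment first: swapped letters flip beta and reflect eaf
    eaf_o_i <- ifelse(pal_swap[idx], 1 - eaf_o[idx], eaf_o[idx])
    b_o_i <- ifelse(pal_swap[idx], -b_o[idx], b_o[idx])
    outside <- function(p) !is.na(p) & (p <= eaf_window[1] | p >= eaf_window[2])
    resolvable <- outside(eaf_e_i) & outside(eaf_o_i)
    agree <- (eaf_e_i < 0.5) == (eaf_o_i < 0.5)
    for (j in seq_along(idx)) {
      i <- idx[j]
      if (!resolvable[j]) {
        status[i] <- "dropped_palindromic"
      } else if (agree[j]) {
        status[i] <- if (pal_swap[i]) "sign_flipped" else "kept"
        beta_out[i] <- b_o_i[j]
        se_out[i] <- se_o[i]
        eaf_out[i] <- eaf_o_i[j]
      } else {
        # frequencies disagree: outcome coded on the opposite strand
        status[i] <- "strand_flipped"
        beta_out[i] <- -b_o_i[j]
        se_out[i] <- se_o[i]
        eaf_out[i] <- 1 - eaf_o_i[j]
      }
    }
  }

  res <- tibble::tibble(
    variant_id = exp$variant_id,
    effect_allele = ea_e, other_allele = oa_e,
    beta_exposure = exp$beta, se_exposure = exp$se,
    pval_exposure = exp$pval, eaf_exposure = exp$eaf,
    n_exposure = exp$n,
    beta_outcome = beta_out, se_outcome = se_out, eaf_outcome = eaf_out,
    status = status
  )
  new_harmonized(res,
                 exposure = exp[["trait_id"]][1] %||% NA_character_,
                 outcome = out[["trait_id"]][1] %||% NA_character_)
}

KEPT_STATUSES <- c("kept", "sign_flipped", "strand_flipped")

new_harmonized <- function(df, exposure = NA_character_,
                           outcome = NA_character_) {
  kept <- df$status %in% KEPT_STATUSES
  if (anyDuplicated(df$variant_id[kept]) > 0) {
    abort_mr("harmonized set has duplicate kept variant_id", "mr_data_error")
  }
  structure(df,
            exposure = exposure, outcome = outcome,
            class = c("mr_harmonized", class(tibble::tibble())))
}

#' Rows of a harmonized set that enter estimation
#'
#' @param hset A [harmonize()] result (any data frame with a `status`
#'   column).
#' @return The rows whose status is `kept`, `sign_flipped` or
#'   `strand_flipped`.
#' @export
kept_pairs <- function(hset) {
  if (!"status" %in% names(hset)) return(tibble::as_tibble(hset))
  dplyr::filter(tibble::as_tibble(hset), .data$status %in% KEPT_STATUSES)
}

#' Per-status counts for a harmonized set
#'
#' @param hset A [harmonize()] result.
#' @return Tibble with columns `status` and `n`.
#' @export
harmonization_report <- function(hset) {
  dplyr::count(tibble::as_tibble(hset), .data$status, name = "n")
}

#' Orient a harmonized set so every exposure effect is positive
#'
#' MR-Egger's intercept is defined relative to the exposure effect
#' direction, so pairs are conventionally oriented to positive
#' SNP-exposure associations before fitting. Kept pairs with
#' `beta_exposure < 0` have both betas negated (and alleles/eafs
#' reflected, keeping the record internally consistent). Slope-type
#' estimates (Wald, IVW, median, mode) are invariant to this
#' transformation.
#'
#' @param hset A [harmonize()] result with at least one kept pair.
#' @return The reoriented `mr_harmonized` tibble.
#' @export
orient_positive_exposure <- function(hset) {
  df <- tibble::as_tibble(hset)
  if (!"status" %in% names(df)) df$status <- "kept"
  if (sum(df$status %in% KEPT_STATUSES) == 0) {
    abort_mr("orient_positive_exposure: no kept pairs", "mr_bad_input")
  }
  flip <- df$status %in% KEPT_STATUSES & !is.na(df$beta_exposure) &
    df$beta_exposure < 0
  if (any(flip)) {
    if (all(c("effect_allele", "other_allele") %in% names(df))) {
      ea <- df$effect_allele[flip]
      df$effect_allele[flip] <- df$other_allele[flip]
      df$other_allele[flip] <- ea
    }
    df$beta_exposure[flip] <- -df$beta_exposure[flip]
    df$beta_outcome[flip] <- -df$beta_outcome[flip]
    if ("eaf_exposure" %in% names(df)) {
      df$eaf_exposure[flip] <- 1 - df$eaf_exposure[flip]
    }
    if ("eaf_outcome" %in% names(df)) {
      df$eaf_outcome[flip] <- 1 - df$eaf_outcome[flip]
    }
  }
  new_harmonized(df, exposure = attr(hset, "exposure"),
                 outcome = attr(hset, "outcome"))
}
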