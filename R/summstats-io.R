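#' Describe how source columns map onto the canonical summary-statistics fields
#'
#' GWAS summary-statistics files from different consortia name the same
#' quantities differently (`rsid`/`SNP`/`MarkerName`, `b`/`beta`/`Effect`,
#' ...). A column map translates one source dialect into the canonical
#' fields used throughout the package: `variant_id`, `effect_allele`,
#' `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#'
#' Every canonical field except `eaf` and `n` must be mapped; those two may
#' be `NA` when the source file does not carry them (`n` can then be
#' supplied through [study_meta()]).
#'
#' @param variant_id,effect_allele,other_allele,beta,se,pval Source column
#'   names for the required canonical fields.
#' @param eaf,n Source column names for the optional fields, or `NA` when
#'   absent from the file.
#' @param na_strings Strings treated as missing values when reading.
#' @return A `mr_column_map` list.
#' @seealso [read_column_map()] to load a map from a YAML file.
#' @export
#' @examples
#' column_map(variant_id = "SNP", beta = "Effect", se = "StdErr",
#'            pval = "P", effect_allele = "A1", other_allele = "A2")
column_map <- function(variant_id = "variant_id",
                       effect_allele = "effect_allele",
                       other_allele = "other_allele",
                       beta = "beta",
                       se = "se",
                       pval = "pval",
                       eaf = "eaf",
                       n = "n",
                       na_strings = c("NA", "", ".")) {
  map <- list(
    variant_id = variant_id, effect_allele = effect_allele,
    other_allele = other_allele, beta = beta, se = se, pval = pval,
    eaf = eaf, n = n
  )
  required <- c("variant_id", "effect_allele", "other_allele", "beta", "se",
                "pval")
  for (field in required) {
    if (!is.character(map[[field]]) || is.na(map[[field]])) {
      abort_mr(sprintf("column_map: field '%s' must be mapped", field),
               "mr_config_error")
    }
  }
  structure(c(map, list(na_strings = na_strings)), class = "mr_column_map")
}

#' Read a column map from a YAML file
#'
#' The file holds one key per canonical field (see [column_map()]) plus an
#' optional `na_strings` list.
#'
#' @param path Path to a YAML file.
#' @return A `mr_column_map` list.
#' @export
read_column_map <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("variant_id", "effect_allele", "other_allele", "beta", "se",
             "pval", "eaf", "n", "na_strings")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort_mr(sprintf("read_column_map: unknown field(s): %s",
                     paste(unknown, collapse = ", ")), "mr_config_error")
  }
  do.call(column_map, raw)
}

#' Study-level metadata for one GWAS
#'
#' Carries the sample-size and trait-scale context that individual
#' summary-statistics rows do not: continuous traits are analysed in SD
#' units, binary traits on the log-odds scale with `n_cases` of `n_total`
#' subjects being cases.
#'
#' @param trait_id Trait identifier, matching the `trait_id` of the
#'   associated summary statistics.
#' @param trait_type `"continuous"` or `"binary"`.
#' @param n_total Total GWAS sample size (cases + controls when binary).
#' @param n_cases Number of cases; required for binary traits.
#' @param unit Free-text unit label (default `"SD"` for continuous,
#'   `"logOR"` for binary).
#' @param ancestry_note Optional free-text ancestry description.
#' @return A one-row tibble of class `mr_study_meta`.
#' @export
study_meta <- function(trait_id, trait_type = c("continuous", "binary"),
                       n_total, n_cases = NA_integer_, unit = NULL,
                       ancestry_note = NA_character_) {
  trait_type <- match.arg(trait_type)
  if (!is_scalar_number(n_total) || n_total <= 0) {
    abort_mr("study_meta: n_total must be a positive number", "mr_config_error")
  }
  if (trait_type == "binary") {
    if (!is_scalar_number(n_cases) || n_cases <= 0 || n_cases >= n_total) {
      abort_mr("study_meta: binary traits need 0 < n_cases < n_total",
               "mr_config_error")
    }
  }
  unit <- unit %||% if (trait_type == "binary") "logOR" else "SD"
  structure(
    tibble::tibble(trait_id = trait_id, trait_type = trait_type, unit = unit,
                   n_total = as.integer(n_total),
                   n_cases = as.integer(n_cases),
                   ancestry_note = ancestry_note),
    class = c("mr_study_meta", class(tibble::tibble()))
  )
}

#' Read and validate a GWAS summary-statistics table
#'
#' Reads a tab-delimited file, renames columns through a [column_map()],
#' upper-cases alleles, recomputes missing p-values from `beta`/`se`
#' (two-sided normal), and enforces the record invariants. Rows violating
#' an invariant are dropped and counted per reason in the rejection report
#' (see [rejection_report()]); a duplicated `variant_id` is a fatal data
#' error.
#'
#' Invariants enforced per row: alleles in \{A, C, G, T\} and distinct;
#' `se > 0`; `beta` finite; `eaf` in \[0, 1\] when present; `pval` in
#' (0, 1\]; `n` positive when present.
#'
#' @param path Path to a tab-delimited file with a single header row.
#' @param trait_id Trait identifier stamped onto every record.
#' @param colmap A [column_map()]; defaults to canonical headers.
#' @param meta Optional [study_meta()]; its `n_total` fills a missing `n`
#'   column.
#' @return A tibble of validated records with columns `variant_id`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`,
#'   `trait_id`, carrying the rejection counts as an attribute.
#' @export
read_summary_stats <- function(path, trait_id, colmap = column_map(),
                               meta = NULL) {
  if (!file.exists(path)) {
    abort_mr(sprintf("read_summary_stats: no such file: %s", path),
             "mr_io_error")
  }
  if (!inherits(colmap, "mr_column_map")) colmap <- do.call(column_map, colmap)
  raw <- readr::read_tsv(path, na = colmap$na_strings, col_types = readr::cols(),
                         progress = FALSE, show_col_types = FALSE)
  required <- c("variant_id", "effect_allele", "other_allele", "beta", "se",
                "pval")
  optional <- c("eaf", "n")
  for (field in required) {
    if (!colmap[[field]] %in% names(raw)) {
      abort_mr(sprintf(
        "read_summary_stats: mapped column '%s' (field %s) not in header of %s",
        colmap[[field]], field, path), "mr_config_error")
    }
  }
  out <- tibble::tibble(
    variant_id = as.character(raw[[colmap$variant_id]]),
    effect_allele = toupper(as.character(raw[[colmap$effect_allele]])),
    other_allele = toupper(as.character(raw[[colmap$other_allele]])),
    eaf = NA_real_, beta = as.numeric(raw[[colmap$beta]]),
    se = as.numeric(raw[[colmap$se]]),
    pval = as.numeric(raw[[colmap$pval]]),
    n = NA_real_
  )
  for (field in optional) {
    src <- colmap[[field]]
    if (is.character(src) && !is.na(src) && src %in% names(raw)) {
      out[[field]] <- as.numeric(raw[[src]])
    }
  }
  if (all(is.na(out$n)) && !is.null(meta)) out$n <- as.numeric(meta$n_total)
  validate_summary_stats(out, trait_id = trait_id)
}

#' Validate an in-memory summary-statistics table
#'
#' The validation core behind [read_summary_stats()], usable directly on a
#' data frame (e.g. simulator output). Alleles are upper-cased, missing
#' p-values recomputed from `beta`/`se`, invalid rows dropped and counted.
#'
#' @param df Data frame with canonical summary-statistics columns
#'   (`eaf` and `n` optional).
#' @param trait_id Trait identifier stamped onto every record.
#' @return A validated tibble; rejection counts in
#'   `attr(, "rejections")`.
#' @export
validate_summary_stats <- function(df, trait_id) {
  stopifnot_cols(df, c("variant_id", "effect_allele", "other_allele",
                       "beta", "se", "pval"), "summary statistics")
  df <- tibble::as_tibble(df)
  if (!"eaf" %in% names(df)) df$eaf <- NA_real_
  if (!"n" %in% names(df)) df$n <- NA_real_
  df$effect_allele <- toupper(df$effect_allele)
  df$other_allele <- toupper(df$other_allele)

  ok_se <- !is.na(df$se) & df$se > 0
  # recompute p from beta/se (two-sided normal) where absent and se usable
  need_p <- is.na(df$pval) & ok_se & !is.na(df$beta)
  df$pval[need_p] <- two_sided_p(df$beta[need_p] / df$se[need_p])

  bases <- c("A", "C", "G", "T")
  reason <- rep(NA_character_, nrow(df))
  flag <- function(bad, why) ifelse(is.na(reason) & bad, why, reason)
  reason <- flag(is.na(df$variant_id) | df$variant_id == "", "missing_id")
  reason <- flag(!(df$effect_allele %in% bases) |
                   !(df$other_allele %in% bases) |
                   df$effect_allele == df$other_allele, "bad_alleles")
  reason <- flag(!ok_se, "nonpositive_se")
  reason <- flag(is.na(df$beta) | !is.finite(df$beta), "bad_beta")
  reason <- flag(is.na(df$pval) | df$pval <= 0 | df$pval > 1, "bad_pval")
  reason <- flag(!is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1), "bad_eaf")
  reason <- flag(!is.na(df$n) & df$n <= 0, "bad_n")

  kept <- df[is.na(reason), c("variant_id", "effect_allele", "other_allele",
                              "eaf", "beta", "se", "pval", "n")]
  kept$trait_id <- trait_id
  if (anyDuplicated(kept$variant_id) > 0) {
    dup <- kept$variant_id[duplicated(kept$variant_id)][1]
    abort_mr(sprintf(
      "summary statistics for trait '%s' contain duplicate variant_id '%s'",
      trait_id, dup), "mr_data_error")
  }
  rej <- table(reason[!is.na(reason)])
  attr(kept, "rejections") <- stats::setNames(as.integer(rej), names(rej))
  attr(kept, "n_input") <- nrow(df)
  kept
}

#' Rejection report for a validated summary-statistics table
#'
#' @param x A table returned by [read_summary_stats()] or
#'   [validate_summary_stats()].
#' @return A tibble with columns `reason` and `n`, plus one row
#'   `"rows_kept"`; rows in = rows kept + rows rejected.
#' @export
rejection_report <- function(x) {
  rej <- attr(x, "rejections") %||% integer(0)
  tibble::tibble(
    reason = c(names(rej), "rows_kept"),
    n = c(as.integer(rej), nrow(x))
  )
}

#' Write MR estimates to the canonical tab-delimited results table
#'
#' Columns: `exposure`, `outcome`, `method`, `nsnp`, `b`, `se`,
#' `ci_lower`, `ci_upper`, `pval`, `or`. The `or` column holds `exp(b)`
#' (odds ratio per SD of exposure) when the outcome is binary and is blank
#' otherwise. Numbers are written in the shortest representation that
#' round-trips, so reading the file back reproduces every value exactly.
#'
#' @param estimates Non-empty data frame with at least `method`, `nsnp`,
#'   `b`, `se`, `ci_lower`, `ci_upper`, `pval`; `exposure`/`outcome`
#'   columns are carried through (blank when absent).
#' @param path Output file path.
#' @param binary_outcome Is the outcome on the log-odds scale? Used for
#'   the `or` column; ignored when `estimates` has an `outcome_type`
#'   column.
#' @return The written tibble, invisibly.
#' @export
write_results_table <- function(estimates, path, binary_outcome = TRUE) {
  if (is.null(estimates) || nrow(estimates) == 0) {
    abort_mr("write_results_table: estimates must be non-empty", "mr_bad_input")
  }
  est <- tibble::as_tibble(estimates)
  if (!"exposure" %in% names(est)) est$exposure <- NA_character_
  if (!"outcome" %in% names(est)) est$outcome <- NA_character_
  binary <- if ("outcome_type" %in% names(est)) {
    est$outcome_type == "binary"
  } else {
    rep(binary_outcome, nrow(est))
  }
  out <- tibble::tibble(
    exposure = est$exposure, outcome = est$outcome, method = est$method,
    nsnp = as.integer(est$nsnp), b = est$b, se = est$se,
    ci_lower = est$ci_lower, ci_upper = est$ci_upper, pval = est$pval,
    or = ifelse(binary, exp(est$b), NA_real_)
  )
  # 17 significant digits guarantee a bit-exact double round-trip
  printed <- dplyr::mutate(out, dplyr::across(
    dplyr::where(is.double),
    function(x) ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
  ))
  readr::write_tsv(printed, path, na = "", progress = FALSE)
  invisible(out)
}

#' Read a results table written by [write_results_table()]
#'
#' @param path Path to the tab-delimited results file.
#' @return A tibble with the canonical results columns.
#' @export
read_results_table <- function(path) {
  # base strtod parsing is correctly rounded, preserving the bit-exact
  # round-trip that write_results_table's 17-digit output guarantees
  df <- utils::read.delim(path, sep = "\t", na.strings = "",
                          colClasses = c(
                            exposure = "character", outcome = "character",
                            method = "character", nsnp = "integer",
                            b = "numeric", se = "numeric",
                            ci_lower = "numeric", ci_upper = "numeric",
                            pval = "numeric", or = "numeric"
                          ))
  tibble::as_tibble(df)
}
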