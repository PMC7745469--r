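#' Configuration for a two-step MR mediation study
#'
#' @param exposures Character vector of exposure trait ids (order matters:
#'   each exposure is also used as the positive-control covariate for the
#'   others in multivariable models).
#' @param outcome Outcome trait id.
#' @param mediator_classes Named character vector mapping mediator id to
#'   class label (every mediator must have exactly one class).
#' @param fdr_alpha FDR threshold for the step-1 screen.
#' @param fdr_family `"per_exposure"` (default) or `"joint"`; see
#'   [screen_mediators()].
#' @param p_instrument,r2_clump Instrument-selection thresholds (see
#'   [select_instruments()]).
#' @param eaf_window Palindrome ambiguity window for [harmonize()].
#' @param n_boot Bootstrap replicates for median/mode SEs.
#' @param mvmr_snp_subset Optional named list (by exposure id) of variant
#'   ids restricting the exposure instruments used in multivariable
#'   models (e.g. an earlier, smaller GWAS instrument list to balance
#'   instrument strength against the mediators).
#' @param seed Integer seed governing every stochastic step.
#' @return A `mr_pipeline_config` list.
#' @export
pipeline_config <- function(exposures, outcome, mediator_classes = character(0),
                            fdr_alpha = 0.05,
                            fdr_family = c("per_exposure", "joint"),
                            p_instrument = 5e-8, r2_clump = 0.001,
                            eaf_window = c(0.42, 0.58),
                            n_boot = 1000, mvmr_snp_subset = NULL,
                            seed = 1) {
  fdr_family <- match.arg(fdr_family)
  stopifnot(fdr_alpha > 0, fdr_alpha < 1, length(exposures) >= 1)
  if (length(mediator_classes) > 0 &&
      (is.null(names(mediator_classes)) ||
         anyDuplicated(names(mediator_classes)) > 0)) {
    abort_mr("pipeline_config: mediator_classes must map each mediator to one class",
             "mr_config_error")
  }
  structure(
    list(exposures = exposures, outcome = outcome,
         mediator_classes = mediator_classes, fdr_alpha = fdr_alpha,
         fdr_family = fdr_family, p_instrument = p_instrument,
         r2_clump = r2_clump, eaf_window = eaf_window, n_boot = n_boot,
         mvmr_snp_subset = mvmr_snp_subset, seed = as.integer(seed)),
    class = "mr_pipeline_config"
  )
}

# Greedy clump over an id/p-value list restricted to the supplied LD matrix.
clump_ids <- function(ids, pvals, ld, r2_threshold) {
  ord <- order(pvals, ids)
  remaining <- ids[ord]
  kept <- character(0)
  while (length(remaining) > 0) {
    best <- remaining[1]
    kept <- c(kept, best)
    remaining <- remaining[ld[best, remaining] < r2_threshold]
  }
  kept
}

stage_runner <- function(manifest) {
  # stages are thunks so an early return inside one exits only the stage
  run <- function(name, deps, fn) {
    failed_dep <- deps[vapply(deps, function(d) {
      !identical(manifest$stages[[d]]$status, "ok")
    }, logical(1))]
    if (length(failed_dep) > 0) {
      manifest$stages[[name]] <<- list(status = "skipped",
                                       reason = paste("upstream failure:",
                                                      failed_dep[1]))
      return(NULL)
    }
    tryCatch({
      value <- fn()
      manifest$stages[[name]] <<- list(status = "ok")
      value
    }, error = function(e) {
      manifest$stages[[name]] <<- list(status = "error",
                                       reason = conditionMessage(e))
      NULL
    })
  }
  list(run = run, manifest = function() manifest)
}

#' Run the full two-step MR mediation study
#'
#' Executes, in order: instrument selection per exposure; total-effect MR
#' (all applicable estimators, heterogeneity, leave-one-SNP-out and
#' scatter data) per exposure; step-1 IVW of each exposure on every
#' mediator; the FDR screen; step-2 MR of each selected mediator on the
#' outcome (IVW when two or more instruments, otherwise the Wald ratio);
#' direction-consistency classification; and multivariable MR adjusting
#' each exposure one-at-a-time for each representative mediator (the
#' strongest-instrumented member of each selected class) and for the
#' other exposures as positive controls. A failed stage is recorded in
#' the manifest and its dependents skipped; independent stages proceed.
#'
#' @param data A `mr_sim` object from [simulate_summary_stats()], or a
#'   list with elements `exposures` (named list of summary-statistics
#'   tibbles), `mediators` (named list), `outcome` (tibble) and `ld`
#'   (an [ld_matrix()]).
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory; when given, the stage tables
#'   (`total_effects.tsv`, `step1_metabolites.tsv`,
#'   `step2_metabolites.tsv`, `mvmr_adjusted.tsv`, `leave_one_out.tsv`,
#'   `scatter_points.tsv`, `scatter_lines.tsv`) and the JSON run manifest
#'   are written there.
#' @return An `mr_study_report` list with the stage tibbles
#'   (`total_effects`, `heterogeneity`, `leave_one_out`, `scatter`,
#'   `step1`, `screen`, `step2`, `mediation`, `representatives`, `mvmr`),
#'   the `manifest`, and `instruments` (selected per exposure).
#' @export
run_mediation_study <- function(data, config, out_dir = NULL) {
  stopifnot(inherits(config, "mr_pipeline_config"))
  if (inherits(data, "mr_sim")) {
    exps <- stats::setNames(list(data$exposure), data$exposure$trait_id[1])
    if (!is.null(data$exposure2)) {
      exps[[data$exposure2$trait_id[1]]] <- data$exposure2
    }
    data <- list(exposures = exps, mediators = data$mediators,
                 outcome = data$outcome, ld = data$ld)
  }
  exposures <- intersect(config$exposures, names(data$exposures))
  if (length(exposures) == 0) {
    abort_mr("run_mediation_study: none of the configured exposures found in data",
             "mr_config_error")
  }
  mediators <- data$mediators %||% list()
  ld <- data$ld
  outcome <- data$outcome
  sr <- stage_runner(list(stages = list()))
  res <- list()

  instruments <- sr$run("instruments", character(0), function() {
    out <- lapply(exposures, function(e) {
      select_instruments(data$exposures[[e]], ld,
                         p_threshold = config$p_instrument,
                         r2_threshold = config$r2_clump)
    })
    names(out) <- exposures
    if (any(vapply(out, nrow, integer(1)) == 0)) {
      stop("no instruments selectable for exposure(s): ",
           paste(exposures[vapply(out, nrow, integer(1)) == 0],
                 collapse = ", "))
    }
    out
  })
  res$instruments <- instruments

  total <- sr$run("total_effects", "instruments", function() {
    fits <- lapply(exposures, function(e) {
      h <- orient_positive_exposure(
        harmonize(instruments[[e]], outcome, eaf_window = config$eaf_window))
      mr_fit(h, n_reps = config$n_boot, seed = config$seed)
    })
    names(fits) <- exposures
    fits
  })
  res$total_effects <- if (!is.null(total)) {
    purrr::imap_dfr(total, function(f, e) {
      dplyr::mutate(f$estimates, exposure = e, outcome = config$outcome,
                    .before = 1)
    })
  }
  res$heterogeneity <- if (!is.null(total)) {
    purrr::imap_dfr(total, function(f, e) {
      dplyr::mutate(f$heterogeneity, exposure = e, .before = 1)
    })
  }
  res$leave_one_out <- sr$run("leave_one_out", "total_effects", function() {
    purrr::imap_dfr(total, function(f, e) {
      if (nrow(f$data) < 3) return(NULL)
      dplyr::mutate(mr_leave_one_out(f$data), exposure = e, .before = 1)
    })
  })
  scatter <- sr$run("scatter_data", "total_effects", function() {
    lapply(total, function(f) mr_scatter_data(f$data, f$estimates))
  })
  res$scatter <- scatter

  step1 <- sr$run("step1", "instruments", function() {
    if (length(mediators) == 0) return(tibble::tibble())
    purrr::map_dfr(exposures, function(e) {
      purrr::map_dfr(names(mediators), function(m) {
        h <- harmonize(instruments[[e]], mediators[[m]],
                       eaf_window = config$eaf_window)
        k <- kept_pairs(h)
        est <- if (nrow(k) >= 2) mr_ivw(k) else if (nrow(k) == 1) {
          wald_ratio(k)
        } else {
          return(NULL)
        }
        dplyr::mutate(est, exposure = e, mediator = m, .before = 1)
      })
    })
  })
  res$step1 <- step1

  screen <- sr$run("screen", "step1", function() {
    if (is.null(step1) || nrow(step1) == 0) return(NULL)
    screen_mediators(step1, fdr_alpha = config$fdr_alpha,
                     family = config$fdr_family)
  })
  res$screen <- screen
  selected <- if (is.null(screen)) character(0) else selected_mediators(screen)

  med_instruments <- sr$run("mediator_instruments", "screen", function() {
    out <- lapply(selected, function(m) {
      select_instruments(mediators[[m]], ld,
                         p_threshold = config$p_instrument,
                         r2_threshold = config$r2_clump)
    })
    names(out) <- selected
    out
  })

  step2 <- sr$run("step2", "mediator_instruments", function() {
    purrr::map_dfr(selected, function(m) {
      instr <- med_instruments[[m]]
      if (nrow(instr) == 0) return(NULL)
      h <- harmonize(instr, outcome, eaf_window = config$eaf_window)
      k <- kept_pairs(h)
      est <- if (nrow(k) >= 2) mr_ivw(k) else if (nrow(k) == 1) {
        wald_ratio(k)
      } else {
        return(NULL)
      }
      dplyr::mutate(est, mediator = m, outcome = config$outcome, .before = 1)
    })
  })
  res$step2 <- step2

  res$mediation <- sr$run("classification", c("step2", "total_effects"), function() {
    if (is.null(step2) || nrow(step2) == 0) return(tibble::tibble())
    purrr::map_dfr(exposures, function(e) {
      s1 <- dplyr::filter(step1, .data$exposure == e,
                          .data$mediator %in% selected)
      rec <- dplyr::inner_join(
        dplyr::transmute(s1, mediator = .data$mediator, step1_b = .data$b,
                         step1_pval = .data$pval),
        dplyr::transmute(step2, mediator = .data$mediator,
                         step2_b = .data$b, step2_ci_lower = .data$ci_lower,
                         step2_ci_upper = .data$ci_upper),
        by = "mediator")
      tot <- dplyr::filter(res$total_effects, .data$exposure == e,
                           .data$method %in% c("ivw", "wald_ratio"))
      dplyr::mutate(classify_mediation(rec, tot$b[1]),
                    exposure = e, total_b = tot$b[1], .before = 1)
    })
  })

  representatives <- sr$run("representatives", "mediator_instruments", function() {
    usable <- selected[vapply(selected, function(m) {
      nrow(med_instruments[[m]]) > 0 &&
        m %in% names(config$mediator_classes)
    }, logical(1))]
    if (length(usable) == 0) return(tibble::tibble())
    diag <- purrr::map_dfr(usable, function(m) {
      s <- instrument_strength(med_instruments[[m]])
      tibble::tibble(mediator = m, f_aggregate = s$f_aggregate,
                     r2_total = s$r2_total, nsnp = s$k)
    })
    cls <- tibble::tibble(mediator = usable,
                          class = unname(config$mediator_classes[usable]))
    dplyr::left_join(select_representatives(diag, cls),
                     dplyr::select(diag, "mediator", "r2_total", "nsnp"),
                     by = "mediator")
  })
  res$representatives <- representatives

  res$mvmr <- sr$run("mvmr", c("representatives", "total_effects"), function() {
    covariates <- list()
    if (!is.null(representatives) && nrow(representatives) > 0) {
      for (m in representatives$mediator) covariates[[m]] <- mediators[[m]]
    }
    rows <- purrr::map_dfr(exposures, function(e) {
      covs <- covariates
      for (alt in setdiff(exposures, e)) {
        covs[[alt]] <- data$exposures[[alt]]  # positive control
      }
      if (length(covs) == 0) return(NULL)
      exp_ids <- instruments[[e]]$variant_id
      subset <- config$mvmr_snp_subset[[e]]
      if (!is.null(subset)) exp_ids <- intersect(exp_ids, subset)
      purrr::map_dfr(names(covs), function(cv) {
        cov_ids <- if (cv %in% names(med_instruments %||% list())) {
          med_instruments[[cv]]$variant_id
        } else if (cv %in% exposures) {
          instruments[[cv]]$variant_id
        } else {
          character(0)
        }
        ids <- union(exp_ids, cov_ids)
        pv <- pmin(
          data$exposures[[e]]$pval[match(ids, data$exposures[[e]]$variant_id)],
          covs[[cv]]$pval[match(ids, covs[[cv]]$variant_id)],
          na.rm = TRUE)
        ids <- clump_ids(ids, pv, ld, config$r2_clump)
        mh <- harmonize_multi(
          stats::setNames(list(data$exposures[[e]], covs[[cv]]), c(e, cv)),
          outcome, variants = ids, eaf_window = config$eaf_window)
        fit <- mvmr_fit(mh)
        est <- fit$estimates
        tibble::tibble(
          exposure = e, covariate = cv, outcome = config$outcome,
          nsnp = est$nsnp[1],
          b = est$b[est$exposure == e],
          se = est$se[est$exposure == e],
          ci_lower = est$ci_lower[est$exposure == e],
          ci_upper = est$ci_upper[est$exposure == e],
          pval = est$pval[est$exposure == e],
          b_covariate = est$b[est$exposure == cv],
          conditional_f = if ("conditional_f" %in% names(est))
            est$conditional_f[est$exposure == e] else NA_real_,
          q_mv = fit$heterogeneity$Q
        )
      })
    })
    if (nrow(rows) > 0) {
      uni <- dplyr::filter(res$total_effects,
                           .data$method %in% c("ivw", "wald_ratio"))
      rows <- dplyr::left_join(
        rows, dplyr::select(uni, "exposure", b_univariable = "b"),
        by = "exposure")
      rows$method <- "mvmr"
    }
    rows
  })

  manifest <- sr$manifest()
  manifest$config <- list(
    exposures = exposures, outcome = config$outcome,
    fdr_alpha = config$fdr_alpha, fdr_family = config$fdr_family,
    p_instrument = config$p_instrument, r2_clump = config$r2_clump,
    eaf_window = config$eaf_window, n_boot = config$n_boot,
    seed = config$seed
  )
  manifest$config_hash <- rlang::hash(manifest$config)
  manifest$package_version <- as.character(utils::packageVersion("mrmediate"))
  manifest$counts <- list(
    exposures = length(exposures), mediators = length(mediators),
    selected_mediators = length(selected),
    step2_analyses = if (is.null(res$step2)) 0L else nrow(res$step2),
    representatives = if (is.null(representatives)) 0L else
      nrow(representatives)
  )
  res$manifest <- manifest

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(tbl, name) {
      if (!is.null(tbl) && nrow(tbl) > 0) {
        readr::write_tsv(tbl, file.path(out_dir, name), na = "",
                         progress = FALSE)
      }
    }
    wr(res$total_effects, "total_effects.tsv")
    wr(res$step1, "step1_metabolites.tsv")
    wr(res$step2, "step2_metabolites.tsv")
    wr(res$mvmr, "mvmr_adjusted.tsv")
    wr(res$leave_one_out, "leave_one_out.tsv")
    if (!is.null(scatter)) {
      wr(purrr::imap_dfr(scatter, function(s, e) {
        dplyr::mutate(s$points, exposure = e, .before = 1)
      }), "scatter_points.tsv")
      wr(purrr::imap_dfr(scatter, function(s, e) {
        dplyr::mutate(s$lines, exposure = e, .before = 1)
      }), "scatter_lines.tsv")
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  structure(res, class = "mr_study_report")
}
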