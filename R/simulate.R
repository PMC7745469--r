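#' Generative specification for synthetic two-sample GWAS summary statistics
#'
#' Defines a full scenario with known ground truth: exposure instrument
#' effects, an optional mediator panel with class structure, directional
#' or balanced pleiotropy, block LD with redundant proxies, and the
#' sample sizes that determine every standard error. Defaults emulate the
#' sex-combined adiposity-metabolite-colorectal-cancer setting: 312
#' exposure instruments from a GWAS of N = 806,810 (SD units), a
#' metabolite GWAS of N = 24,925, and a binary outcome with 58,221 cases
#' and 67,694 controls on the log-odds scale, with instrument variance
#' explained near 4% and a true exposure odds ratio of 1.12 per SD.
#'
#' @param J Number of causal exposure instruments.
#' @param maf_range Uniform bounds for minor-allele frequencies.
#' @param tau2 Variance of true per-allele SNP-exposure effects.
#' @param n_exposure,n_mediator GWAS sample sizes for the exposure and
#'   mediator traits (continuous, SD units).
#' @param n_cases,n_controls Outcome GWAS case/control counts.
#' @param theta_direct Direct exposure-outcome effect (log-OR per SD),
#'   i.e. the effect not passing through the mediator panel.
#' @param mediators `NULL`, or a tibble with columns `id`, `class`,
#'   `kappa` (exposure-mediator effect, SD per SD) and `theta`
#'   (mediator-outcome effect, log-OR per SD); see [nmr_panel()].
#' @param snps_per_class Instruments specific to each mediator class.
#' @param class_rho Correlation of SNP effects among mediators of one
#'   class (one latent factor per class, emulating the redundancy of
#'   lipoprotein subclass panels).
#' @param med_tau2 Variance of class-SNP effects on their mediators.
#' @param pleiotropy List `(prop, mu, sd, cor_gamma)`: fraction of
#'   exposure instruments with a direct outcome effect, its mean and SD,
#'   and an optional correlation with instrument strength (an InSIDE
#'   violation when non-zero).
#' @param ld List `(block_size, r2)`: each causal exposure SNP is
#'   accompanied by `block_size - 1` redundant proxies at the given
#'   within-block r-squared (block-diagonal LD).
#' @param palindromic_rate Fraction of variants given A/T or C/G alleles.
#' @param strand_flip_rate Fraction of non-palindromic variants whose
#'   outcome/mediator records are coded on the opposite strand.
#' @param allele_swap_rate Fraction of variants whose outcome/mediator
#'   records list the alleles in swapped order (sign-flipped beta).
#' @param exposure2 `NULL`, or list `(rho, theta_direct)`: adds a second
#'   adiposity-like exposure measured in the same GWAS sample whose SNP
#'   effects have genetic correlation `rho` with the first and which has
#'   its own direct outcome effect (used for positive-control
#'   multivariable adjustment).
#' @param exact_r2 When non-`NULL`, rescale the drawn SNP-exposure
#'   effects so the realized variance explained by the exposure SNPs
#'   equals this value exactly (used when a scenario must sit at a
#'   prescribed instrument strength, e.g. power validation — the
#'   analytic power curve is conditional on r^2).
#' @param positive_gamma Code every causal exposure SNP with the
#'   exposure-increasing allele as effect allele (true gamma >= 0), the
#'   common convention of published instrument lists and the frame in
#'   which directional pleiotropy is defined.
#' @param exposure_id,outcome_id Trait identifiers stamped on the tables.
#' @param seed Integer seed; a fixed seed makes the output byte-identical.
#' @return A `mr_scenario` list of validated settings.
#' @export
scenario_config <- function(J = 312,
                            maf_range = c(0.05, 0.5),
                            tau2 = 3.5e-4,
                            n_exposure = 806810,
                            n_mediator = 24925,
                            n_cases = 58221,
                            n_controls = 67694,
                            theta_direct = log(1.12),
                            mediators = NULL,
                            snps_per_class = 8,
                            class_rho = 0.7,
                            med_tau2 = 0.02,
                            pleiotropy = list(prop = 0, mu = 0, sd = 0,
                                              cor_gamma = 0),
                            ld = list(block_size = 1, r2 = 0),
                            palindromic_rate = 0,
                            strand_flip_rate = 0,
                            allele_swap_rate = 0,
                            exposure2 = NULL,
                            exact_r2 = NULL,
                            positive_gamma = FALSE,
                            exposure_id = "exposure",
                            outcome_id = "outcome",
                            seed = 1) {
  pleiotropy <- utils::modifyList(
    list(prop = 0, mu = 0, sd = 0, cor_gamma = 0), pleiotropy)
  ld <- utils::modifyList(list(block_size = 1, r2 = 0), ld)
  stopifnot(
    J >= 1, tau2 >= 0, med_tau2 >= 0,
    maf_range[1] > 0, maf_range[2] <= 0.5, maf_range[1] <= maf_range[2],
    n_exposure > 0, n_mediator > 0, n_cases > 0, n_controls > 0,
    pleiotropy$prop >= 0, pleiotropy$prop <= 1, pleiotropy$sd >= 0,
    abs(pleiotropy$cor_gamma) <= 1,
    ld$block_size >= 1, ld$r2 >= 0, ld$r2 <= 1,
    palindromic_rate >= 0, palindromic_rate <= 1,
    strand_flip_rate >= 0, strand_flip_rate <= 1,
    allele_swap_rate >= 0, allele_swap_rate <= 1,
    class_rho >= 0, class_rho <= 1
  )
  if (!is.null(mediators)) {
    stopifnot_cols(mediators, c("id", "class", "kappa", "theta"), "mediators")
    if (anyDuplicated(mediators$id) > 0) {
      abort_mr("scenario_config: duplicate mediator ids", "mr_config_error")
    }
  }
  if (!is.null(exposure2)) {
    exposure2 <- utils::modifyList(list(rho = 0.3, theta_direct = 0), exposure2)
    stopifnot(abs(exposure2$rho) <= 1)
  }
  structure(
    list(J = as.integer(J), maf_range = maf_range, tau2 = tau2,
         n_exposure = n_exposure, n_mediator = n_mediator,
         n_cases = n_cases, n_controls = n_controls,
         theta_direct = theta_direct, mediators = mediators,
         snps_per_class = as.integer(snps_per_class), class_rho = class_rho,
         med_tau2 = med_tau2, pleiotropy = pleiotropy, ld = ld,
         palindromic_rate = palindromic_rate,
         strand_flip_rate = strand_flip_rate,
         allele_swap_rate = allele_swap_rate,
         exposure2 = exposure2, exact_r2 = exact_r2,
         positive_gamma = positive_gamma,
         exposure_id = exposure_id,
         outcome_id = outcome_id, seed = as.integer(seed)),
    class = "mr_scenario"
  )
}

#' A 123-trait NMR-style mediator panel
#'
#' Builds a mediator panel shaped like targeted NMR metabolomics: 123
#' traits grouped into lipoprotein subclass lipids, apolipoproteins,
#' cholesterol and glyceride measures, fatty acids, amino acids,
#' glycolysis-related metabolites, ketone bodies, fluid balance and an
#' inflammation marker. `n_true` traits (spread evenly across the panel)
#' are given non-zero mediation paths.
#'
#' @param n_true Number of true mediators.
#' @param kappa Exposure-mediator effect (SD per SD) for true mediators.
#' @param theta Mediator-outcome effect (log-OR per SD) for true
#'   mediators.
#' @return Tibble with columns `id`, `class`, `kappa`, `theta`
#'   (123 rows).
#' @export
nmr_panel <- function(n_true = 0, kappa = 0.25, theta = 0.15) {
  counts <- c(
    vldl_lipids = 28, ldl_lipids = 15, idl_lipids = 5, hdl_lipids = 20,
    apolipoproteins = 3, cholesterol = 9, glycerides_phospholipids = 9,
    fatty_acids = 14, amino_acids = 9, glycolysis = 4, ketone_bodies = 2,
    fluid_balance = 2, inflammation = 1, other = 2
  )
  cls <- rep(names(counts), counts)
  ids <- unlist(lapply(names(counts), function(cl) {
    sprintf("%s_%02d", cl, seq_len(counts[[cl]]))
  }))
  panel <- tibble::tibble(id = ids, class = cls, kappa = 0, theta = 0)
  if (n_true > 0) {
    idx <- unique(round(seq(1, nrow(panel), length.out = n_true)))
    panel$kappa[idx] <- kappa
    panel$theta[idx] <- theta
  }
  panel
}

sample_alleles <- function(n, palindromic_rate) {
  bases <- c("A", "C", "G", "T")
  pal <- stats::runif(n) < palindromic_rate
  ea <- sample(bases, n, replace = TRUE)
  oa <- character(n)
  oa[pal] <- unname(COMPLEMENT[ea[pal]])
  for (i in which(!pal)) {
    oa[i] <- sample(setdiff(bases, c(ea[i], COMPLEMENT[ea[i]])), 1)
  }
  list(ea = ea, oa = oa, pal = pal)
}

# Recode a trait table for a second study sample: swap allele order
# and/or complement the strand for flagged variants.
recode_table <- function(tbl, swap, flip) {
  tbl$beta[swap] <- -tbl$beta[swap]
  tbl$eaf[swap] <- 1 - tbl$eaf[swap]
  ea <- tbl$effect_allele
  tbl$effect_allele[swap] <- tbl$other_allele[swap]
  tbl$other_allele[swap] <- ea[swap]
  tbl$effect_allele[flip] <- unname(COMPLEMENT[tbl$effect_allele[flip]])
  tbl$other_allele[flip] <- unname(COMPLEMENT[tbl$other_allele[flip]])
  tbl
}

assoc_table <- function(ids, ea, oa, eaf, true_beta, se, n, trait_id) {
  beta <- true_beta + stats::rnorm(length(ids), 0, se)
  tibble::tibble(
    variant_id = ids, effect_allele = ea, other_allele = oa, eaf = eaf,
    beta = beta, se = se, pval = two_sided_p(beta / se), n = n,
    trait_id = trait_id
  )
}

#' Simulate two-sample GWAS summary statistics with known ground truth
#'
#' Draws minor-allele frequencies and true per-allele effects under a
#' [scenario_config()], then emits independent summary-statistics tables
#' for the exposure (and optional second exposure), each mediator, and
#' the binary outcome, together with the block-diagonal LD matrix and a
#' ground-truth manifest.
#'
#' Standard errors follow the large-sample approximations for
#' standardized traits: `1/sqrt(2 p (1-p) N)` for continuous traits and
#' `1/sqrt(2 p (1-p) N cf (1-cf))` (case fraction `cf`) for the log-OR
#' scale. Observed betas are drawn `Normal(truth, se^2)` independently
#' across study samples. The true SNP-outcome effect is
#' `theta_direct * gamma_j + sum_m theta_m * delta_mj + alpha_j`, where
#' `delta_mj` is SNP `j`'s total effect on mediator `m` (the
#' exposure-mediated part `kappa_m * gamma_j` plus mediator-specific
#' class-SNP effects) and `alpha_j` is the pleiotropic direct effect.
#'
#' @param cfg A [scenario_config()].
#' @return A `mr_sim` list: `exposure` (tibble), optional `exposure2`,
#'   `mediators` (named list of tibbles), `outcome`, `ld`
#'   ([ld_matrix()]), `truth` (per-SNP tibble plus scenario-level values,
#'   including `theta_total = theta_direct + sum(kappa * theta)`), and
#'   the `config`.
#' @export
simulate_summary_stats <- function(cfg) {
  stopifnot(inherits(cfg, "mr_scenario"))
  withr::with_seed(cfg$seed, simulate_summary_stats_impl(cfg))
}

simulate_summary_stats_impl <- function(cfg) {
  bs <- cfg$ld$block_size
  n_exp_snp <- cfg$J * bs
  classes <- if (is.null(cfg$mediators)) character(0) else
    unique(cfg$mediators$class)
  n_class_snp <- length(classes) * cfg$snps_per_class
  n_snp <- n_exp_snp + n_class_snp
  ids <- sprintf("rs%06d", seq_len(n_snp))
  is_exp_snp <- seq_len(n_snp) <= n_exp_snp
  block <- rep(NA_integer_, n_snp)
  block[is_exp_snp] <- rep(seq_len(cfg$J), each = bs)
  lead <- is_exp_snp & (seq_len(n_snp) - 1) %% bs == 0
  lead[!is_exp_snp] <- FALSE
  class_of_snp <- rep(NA_character_, n_snp)
  if (n_class_snp > 0) {
    class_of_snp[!is_exp_snp] <- rep(classes, each = cfg$snps_per_class)
  }

  maf <- stats::runif(n_snp, cfg$maf_range[1], cfg$maf_range[2])
  al <- sample_alleles(n_snp, cfg$palindromic_rate)
  r_prox <- sqrt(cfg$ld$r2)

  # true per-allele exposure effects; proxies carry the attenuated
  # marginal effect r * gamma of their block lead
  gamma_lead <- stats::rnorm(cfg$J, 0, sqrt(cfg$tau2))
  if (isTRUE(cfg$positive_gamma)) gamma_lead <- abs(gamma_lead)
  gamma <- numeric(n_snp)
  gamma[is_exp_snp] <- ifelse(lead[is_exp_snp], gamma_lead[block[is_exp_snp]],
                              r_prox * gamma_lead[block[is_exp_snp]])

  if (!is.null(cfg$exact_r2)) {
    realized <- sum(2 * maf * (1 - maf) * gamma^2)
    gamma <- gamma * sqrt(cfg$exact_r2 / realized)
  }

  gamma2 <- NULL
  if (!is.null(cfg$exposure2)) {
    rho <- cfg$exposure2$rho
    g2_lead <- rho * gamma_lead +
      sqrt(1 - rho^2) * stats::rnorm(cfg$J, 0, sqrt(cfg$tau2))
    gamma2 <- numeric(n_snp)
    gamma2[is_exp_snp] <- ifelse(lead[is_exp_snp], g2_lead[block[is_exp_snp]],
                                 r_prox * g2_lead[block[is_exp_snp]])
  }

  # mediator effects: exposure-mediated part + class-specific instruments
  delta <- NULL
  loadings <- NULL
  if (!is.null(cfg$mediators)) {
    med <- cfg$mediators
    loadings <- stats::runif(nrow(med), 0.6, 1.4)
    class_factor <- matrix(0, n_snp, length(classes),
                           dimnames = list(NULL, classes))
    for (cl in classes) {
      snps <- which(class_of_snp == cl)
      class_factor[snps, cl] <- stats::rnorm(length(snps), 0,
                                             sqrt(cfg$med_tau2))
    }
    delta <- matrix(0, n_snp, nrow(med), dimnames = list(NULL, med$id))
    for (m in seq_len(nrow(med))) {
      cl <- med$class[m]
      snps <- which(class_of_snp == cl)
      own <- numeric(n_snp)
      own[snps] <- loadings[m] *
        (sqrt(cfg$class_rho) * class_factor[snps, cl] +
           sqrt(1 - cfg$class_rho) *
           stats::rnorm(length(snps), 0, sqrt(cfg$med_tau2)))
      delta[, m] <- med$kappa[m] * gamma + own
    }
  }

  # pleiotropic direct SNP-outcome effects on exposure instruments
  alpha <- numeric(n_snp)
  pl <- cfg$pleiotropy
  if (pl$prop > 0) {
    hit <- is_exp_snp & stats::rbinom(n_snp, 1, pl$prop) == 1
    z <- stats::rnorm(n_snp)
    if (pl$cor_gamma != 0 && sd(gamma[is_exp_snp]) > 0) {
      gs <- gamma / sd(gamma[is_exp_snp])
      z <- pl$cor_gamma * gs + sqrt(1 - pl$cor_gamma^2) * z
    }
    alpha[hit] <- pl$mu + pl$sd * z[hit]
  }

  b_outcome <- cfg$theta_direct * gamma + alpha
  if (!is.null(delta)) {
    b_outcome <- b_outcome + drop(delta %*% cfg$mediators$theta)
  }
  if (!is.null(gamma2)) {
    b_outcome <- b_outcome + cfg$exposure2$theta_direct * gamma2
  }

  v <- 2 * maf * (1 - maf)
  se_x <- 1 / sqrt(v * cfg$n_exposure)
  se_m <- 1 / sqrt(v * cfg$n_mediator)
  n_out <- cfg$n_cases + cfg$n_controls
  cf <- cfg$n_cases / n_out
  se_y <- 1 / sqrt(v * n_out * cf * (1 - cf))

  exposure <- assoc_table(ids, al$ea, al$oa, maf, gamma, se_x,
                          cfg$n_exposure, cfg$exposure_id)
  exposure2 <- if (!is.null(gamma2)) {
    assoc_table(ids, al$ea, al$oa, maf, gamma2, se_x, cfg$n_exposure,
                paste0(cfg$exposure_id, "2"))
  }

  # second-sample recoding flags shared by outcome and mediator tables
  swap <- stats::runif(n_snp) < cfg$allele_swap_rate
  flip <- !al$pal & stats::runif(n_snp) < cfg$strand_flip_rate

  outcome <- recode_table(
    assoc_table(ids, al$ea, al$oa, maf, b_outcome, se_y, n_out,
                cfg$outcome_id),
    swap, flip)

  mediators <- list()
  if (!is.null(delta)) {
    for (m in seq_len(ncol(delta))) {
      id <- colnames(delta)[m]
      mediators[[id]] <- recode_table(
        assoc_table(ids, al$ea, al$oa, maf, delta[, m], se_m,
                    cfg$n_mediator, id),
        swap, flip)
    }
  }

  ld <- diag(1, n_snp)
  if (bs > 1) {
    for (b in seq_len(cfg$J)) {
      snps <- which(block == b)
      ld[snps, snps] <- cfg$ld$r2
      ld[cbind(snps, snps)] <- 1
    }
  }
  ld <- ld_matrix(ld, ids)

  kappa <- if (is.null(cfg$mediators)) numeric(0) else cfg$mediators$kappa
  theta_m <- if (is.null(cfg$mediators)) numeric(0) else cfg$mediators$theta
  truth <- list(
    per_snp = tibble::tibble(
      variant_id = ids, maf = maf, gamma = gamma,
      gamma2 = if (is.null(gamma2)) NA_real_ else gamma2,
      alpha = alpha, b_outcome = b_outcome,
      exposure_region = is_exp_snp, block_lead = lead,
      class_snp = class_of_snp, palindromic = al$pal,
      swapped = swap, strand_flipped = flip,
      valid_instrument = is_exp_snp & alpha == 0,
      se_exposure = se_x, se_outcome = se_y
    ),
    delta = delta, loadings = loadings,
    kappa = kappa, theta_m = theta_m,
    theta_direct = cfg$theta_direct,
    theta_total = cfg$theta_direct + sum(kappa * theta_m)
  )
  structure(
    list(exposure = exposure, exposure2 = exposure2, mediators = mediators,
         outcome = outcome, ld = ld, truth = truth, config = cfg),
    class = "mr_sim"
  )
}

#' Write a full synthetic fixture set to disk
#'
#' Emits the tables, LD matrix, ground-truth manifest (JSON) and a
#' matching pipeline configuration (YAML) for a scenario — by default the
#' 123-mediator NMR-style panel — so the whole pipeline can be exercised
#' from files.
#'
#' @param cfg A [scenario_config()]; defaults to the standard scenario
#'   with the [nmr_panel()] mediator panel.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the named list of written paths.
#' @export
emit_panel_fixture <- function(cfg = scenario_config(mediators = nmr_panel()),
                               out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "mediators"), showWarnings = FALSE)
  sim <- simulate_summary_stats(cfg)
  paths <- list()
  wr <- function(tbl, name) {
    p <- file.path(out_dir, name)
    readr::write_tsv(tbl, p, progress = FALSE)
    p
  }
  paths$exposure <- wr(sim$exposure, "exposure.tsv")
  if (!is.null(sim$exposure2)) paths$exposure2 <- wr(sim$exposure2,
                                                     "exposure2.tsv")
  paths$outcome <- wr(sim$outcome, "outcome.tsv")
  paths$mediators <- vapply(names(sim$mediators), function(id) {
    wr(sim$mediators[[id]], file.path("mediators", paste0(id, ".tsv")))
  }, character(1))
  ld_tbl <- tibble::as_tibble(as.data.frame(unclass(sim$ld)))
  ld_tbl <- dplyr::bind_cols(tibble::tibble(variant_id = rownames(sim$ld)),
                             ld_tbl)
  paths$ld <- wr(ld_tbl, "ld.tsv")
  paths$truth <- file.path(out_dir, "truth.json")
  jsonlite::write_json(
    list(per_snp = sim$truth$per_snp,
         kappa = sim$truth$kappa, theta_m = sim$truth$theta_m,
         theta_direct = sim$truth$theta_direct,
         theta_total = sim$truth$theta_total),
    paths$truth, digits = NA, na = "null")
  paths$config <- file.path(out_dir, "pipeline_config.yaml")
  med <- cfg$mediators
  yaml::write_yaml(list(
    exposures = c(cfg$exposure_id,
                  if (!is.null(cfg$exposure2)) paste0(cfg$exposure_id, "2")),
    outcome = cfg$outcome_id,
    mediator_classes = if (is.null(med)) list() else
      as.list(stats::setNames(med$class, med$id)),
    fdr_alpha = 0.05, p_instrument = 5e-8, r2_clump = 0.001,
    seed = cfg$seed
  ), paths$config)
  invisible(paths)
}
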