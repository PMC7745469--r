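test_that("the same seed reproduces every table byte-identically", {
  cfg <- scenario_config(J = 30, mediators = nmr_panel(2)[1:10, ], seed = 77,
                         palindromic_rate = 0.1, strand_flip_rate = 0.2,
                         allele_swap_rate = 0.3,
                         ld = list(block_size = 2, r2 = 0.5))
  s1 <- simulate_summary_stats(cfg)
  s2 <- simulate_summary_stats(cfg)
  expect_identical(s1$exposure, s2$exposure)
  expect_identical(s1$outcome, s2$outcome)
  expect_identical(s1$mediators, s2$mediators)
  expect_identical(s1$truth$per_snp, s2$truth$per_snp)
  s3 <- simulate_summary_stats(scenario_config(J = 30, seed = 78))
  expect_false(identical(s1$exposure$beta[1], s3$exposure$beta[1]))
})

test_that("emitted standard errors are calibrated against the observed noise", {
  # one draw across many SNPs: sd of (observed - true)/se should be 1
  cfg <- scenario_config(J = 4000, seed = 3)
  sim <- simulate_summary_stats(cfg)
  z_x <- (sim$exposure$beta - sim$truth$per_snp$gamma) /
    sim$truth$per_snp$se_exposure
  expect_equal(sd(z_x), 1, tolerance = 0.03)
  z_y <- (sim$outcome$beta - sim$truth$per_snp$b_outcome) /
    sim$truth$per_snp$se_outcome
  expect_equal(sd(z_y), 1, tolerance = 0.03)
})

test_that("in the noiseless limit per-SNP Wald ratios converge to the total effect", {
  panel <- nmr_panel(2)[c(1, 62), ]  # two true mediators
  cfg <- scenario_config(J = 12, mediators = panel, n_exposure = 1e12,
                         n_cases = 1e12, n_controls = 1e12,
                         n_mediator = 1e12, seed = 5)
  sim <- simulate_summary_stats(cfg)
  expect_equal(sim$truth$theta_total,
               cfg$theta_direct + sum(panel$kappa * panel$theta))
  h <- kept_pairs(harmonize(sim$exposure, sim$outcome))
  # only the exposure's own instruments are valid: mediator-class SNPs
  # have no exposure effect and their ratios diverge by construction
  valid <- sim$truth$per_snp$variant_id[sim$truth$per_snp$exposure_region]
  h <- h[h$variant_id %in% valid, ]
  ratios <- h$beta_outcome / h$beta_exposure
  expect_lt(max(abs(ratios - sim$truth$theta_total)), 0.01)
})

test_that("mean per-SNP F increases with sample size and effect variance", {
  mean_f <- function(n, tau2) {
    sim <- simulate_summary_stats(scenario_config(J = 150, n_exposure = n,
                                                  tau2 = tau2, seed = 9))
    mean((sim$exposure$beta / sim$exposure$se)^2)
  }
  expect_gt(mean_f(4e5, 3.5e-4), mean_f(1e5, 3.5e-4))
  expect_gt(mean_f(1e5, 1.4e-3), mean_f(1e5, 3.5e-4))
})

test_that("injected recodings are exactly recovered or dropped by harmonization", {
  cfg <- scenario_config(J = 400, seed = 31, palindromic_rate = 0.25,
                         strand_flip_rate = 0.3, allele_swap_rate = 0.4)
  sim <- simulate_summary_stats(cfg)
  h <- harmonize(sim$exposure, sim$outcome)
  t <- sim$truth$per_snp
  # the aligned outcome beta must equal the generated (pre-recoding)
  # value for every kept variant: harmonization inverts the recoding
  kept <- h$status %in% c("kept", "sign_flipped", "strand_flipped")
  pre <- sim$outcome$beta
  pre[t$swapped] <- -pre[t$swapped]
  expect_equal(h$beta_outcome[kept], pre[kept], tolerance = 1e-12)
  # non-palindromic variants are never dropped; palindromic drops are
  # exactly those with a frequency inside the ambiguity window
  expect_true(all(kept[!t$palindromic]))
  amb <- t$palindromic & (t$maf > 0.42 & t$maf < 0.58)
  expect_equal(h$status[amb], rep("dropped_palindromic", sum(amb)))
  expect_true(all(kept[t$palindromic & !amb]))
  # swap flags map onto sign-flip statuses for plain non-palindromic SNPs
  plain <- !t$palindromic & !t$strand_flipped
  expect_equal(h$status[plain & t$swapped] == "sign_flipped",
               rep(TRUE, sum(plain & t$swapped)))
  expect_equal(h$status[plain & !t$swapped] == "kept",
               rep(TRUE, sum(plain & !t$swapped)))
})

test_that("block LD yields proxies that clumping removes", {
  cfg <- scenario_config(J = 25, seed = 13, tau2 = 8e-4, n_exposure = 5e5,
                         ld = list(block_size = 3, r2 = 0.6))
  sim <- simulate_summary_stats(cfg)
  expect_equal(nrow(sim$exposure), 75)
  expect_equal(unname(sim$ld["rs000001", "rs000002"]), 0.6)
  expect_equal(unname(sim$ld["rs000003", "rs000004"]), 0)
  sel <- select_instruments(sim$exposure, sim$ld, r2_threshold = 0.1)
  # at most one SNP survives per block
  blocks <- ceiling(match(sel$variant_id, sim$exposure$variant_id) / 3)
  expect_false(any(duplicated(blocks)))
})

test_that("the emitted fixture set loads back through the readers cleanly", {
  out_dir <- withr::local_tempdir()
  cfg <- scenario_config(J = 20, mediators = nmr_panel(1)[1:6, ], seed = 2)
  paths <- emit_panel_fixture(cfg, out_dir)
  expect_length(paths$mediators, 6)
  x <- read_summary_stats(paths$exposure, trait_id = "exposure")
  # 20 exposure instruments plus one class block of 8 mediator SNPs
  expect_equal(nrow(x), 28)
  rep <- rejection_report(x)
  expect_equal(sum(rep$n[rep$reason != "rows_kept"]), 0)
  truth <- jsonlite::read_json(paths$truth, simplifyVector = TRUE)
  expect_equal(truth$theta_direct + sum(truth$kappa * truth$theta_m),
               truth$theta_total)
  cfg_back <- yaml::read_yaml(paths$config)
  expect_equal(cfg_back$fdr_alpha, 0.05)

  # the default panel is the 123-trait NMR-style layout
  expect_equal(nrow(nmr_panel()), 123)
  expect_equal(sum(nmr_panel(20)$kappa > 0), 20)
  expect_gt(length(unique(nmr_panel()$class)), 5)
})
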