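pair_row <- function(bx, by, sex = 0.01, sey = 0.1) {
  tibble::tibble(variant_id = "rs1", beta_exposure = bx, se_exposure = sex,
                 beta_outcome = by, se_outcome = sey, status = "kept")
}

test_that("Wald ratio arithmetic, identity instrument, and delta-method options", {
  est <- wald_ratio(pair_row(0.1, 0.3, sey = 0.1))
  expect_equal(est$b, 3)
  expect_equal(est$se, 1)
  expect_equal(est$nsnp, 1L)

  expect_equal(wald_ratio(pair_row(1, -0.42))$b, -0.42)
  expect_error(wald_ratio(pair_row(0, 0.3)), class = "mr_undefined_ratio")

  # second-order SE equals the explicit Taylor expansion and exceeds
  # the first-order SE
  p <- pair_row(0.08, 0.12, sex = 0.02, sey = 0.05)
  s1 <- wald_ratio(p)$se
  s2 <- wald_ratio(p, second_order = TRUE)$se
  expect_equal(s2, sqrt(0.05^2 / 0.08^2 + 0.12^2 * 0.02^2 / 0.08^4))
  expect_gt(s2, s1)
})

test_that("IVW on exact proportional data recovers the slope with zero heterogeneity", {
  k <- rand_hset(8, seed = 1)
  k$beta_outcome <- 0.37 * k$beta_exposure  # exactly on the line
  est <- mr_ivw(k)
  expect_equal(est$b, 0.37, tolerance = 1e-12)
  het <- heterogeneity(est)
  expect_equal(het$Q, 0, tolerance = 1e-20)
  expect_equal(est$re_scale, 1)
  expect_equal(est$se, est$se_fixed)
})

test_that("IVW matches the weighted-least-squares oracle and is weight-proportional", {
  k <- rand_hset(3, seed = 7)
  est <- mr_ivw(k)
  o <- oracle_wls_origin(k$beta_exposure, k$beta_outcome, 1 / k$se_outcome^2)
  expect_equal(est$b, o$b, tolerance = 1e-12)
  expect_equal(est$se_fixed, o$se_fixed, tolerance = 1e-12)
  expect_equal(heterogeneity(est)$Q, o$Q, tolerance = 1e-12)

  # duplicating every SNP leaves the estimate unchanged
  expect_equal(mr_ivw(dplyr::bind_rows(k, dplyr::mutate(
    k, variant_id = paste0(variant_id, "b"))))$b, est$b, tolerance = 1e-14)
  expect_error(mr_ivw(k[1, ]), class = "mr_insufficient_instruments")
})

test_that("with equal outcome SEs two-SNP IVW is the beta_x^2-weighted mean of Wald ratios", {
  k <- rand_hset(2, seed = 3)
  k$se_outcome <- c(0.02, 0.02)
  ratios <- k$beta_outcome / k$beta_exposure
  expect_equal(mr_ivw(k)$b,
               weighted.mean(ratios, k$beta_exposure^2), tolerance = 1e-12)
})

test_that("scaling outcome SEs rescales the fixed SE but not the estimate", {
  k <- rand_hset(12, seed = 11)
  est1 <- mr_ivw(k)
  k2 <- dplyr::mutate(k, se_outcome = 3 * se_outcome)
  est2 <- mr_ivw(k2)
  expect_equal(est2$b, est1$b, tolerance = 1e-14)
  expect_equal(est2$se_fixed, 3 * est1$se_fixed, tolerance = 1e-12)
})

test_that("MR-Egger recovers exact affine data and reduces to IVW without pleiotropy", {
  k <- rand_hset(10, seed = 5)
  k$beta_exposure <- abs(k$beta_exposure)
  k$se_outcome <- rep(0.02, 10)
  k$beta_outcome <- 0.1 + 0.5 * k$beta_exposure
  est <- mr_egger(k)
  expect_equal(est$b[est$method == "egger_slope"], 0.5, tolerance = 1e-10)
  expect_equal(est$b[est$method == "egger_intercept"], 0.1, tolerance = 1e-10)
  expect_equal(heterogeneity(est)$Q, 0, tolerance = 1e-18)

  k$beta_outcome <- 0.5 * k$beta_exposure  # no directional pleiotropy
  est0 <- mr_egger(k)
  expect_equal(est0$b[est0$method == "egger_intercept"], 0, tolerance = 1e-12)
  expect_equal(est0$b[est0$method == "egger_slope"], mr_ivw(k)$b,
               tolerance = 1e-10)
})

test_that("MR-Egger matches the weighted-regression oracle on random sets", {
  for (seed in c(2, 9, 31)) {
    k <- rand_hset(10, seed = seed)
    est <- mr_egger(k)
    o <- oracle_wls_intercept(k$beta_exposure, k$beta_outcome,
                              1 / k$se_outcome^2)
    phi <- max(1, sqrt(o$Q / (10 - 2)))
    expect_equal(est$b[est$method == "egger_slope"], o$slope,
                 tolerance = 1e-10)
    expect_equal(est$b[est$method == "egger_intercept"], o$intercept,
                 tolerance = 1e-10)
    expect_equal(est$se[est$method == "egger_slope"],
                 phi * o$se_slope_fixed, tolerance = 1e-10)
    expect_equal(est$se[est$method == "egger_intercept"],
                 phi * o$se_intercept_fixed, tolerance = 1e-10)
  }
  # degenerate exposure spread is an identifiability error
  k <- rand_hset(5, seed = 1)
  k$beta_exposure <- rep(0.05, 5)
  expect_error(mr_egger(k), class = "mr_collinear")
  expect_error(mr_egger(rand_hset(2, seed = 1)),
               class = "mr_insufficient_instruments")
})

test_that("weighted median: order statistics, degeneracy, and the brute-force oracle", {
  # equal weights, ratios (1, 2, 9): the middle order statistic
  k <- pair_row(1, 1)[c(1, 1, 1), ]
  k$variant_id <- c("a", "b", "c")
  k$beta_outcome <- c(1, 2, 9)
  est <- mr_weighted_median(k, n_reps = 150, seed = 1)
  expect_equal(est$b, 2)

  # all ratios equal c: estimate c, bootstrap SE small
  k$beta_outcome <- c(0.8, 0.8, 0.8)
  est <- mr_weighted_median(k, n_reps = 150, seed = 1)
  expect_equal(est$b, 0.8)
  expect_lt(est$se, 0.25)

  for (seed in c(4, 17, 23)) {
    k <- rand_hset(7, seed = seed)
    est <- mr_weighted_median(k, n_reps = 150, seed = 1)
    rw <- list(theta = k$beta_outcome / k$beta_exposure,
               w = k$beta_exposure^2 / k$se_outcome^2)
    expect_equal(est$b, oracle_weighted_median(rw$theta, rw$w),
                 tolerance = 1e-12)
  }
})

test_that("bootstrap SEs are bit-reproducible under a fixed seed", {
  k <- rand_hset(9, seed = 6)
  a <- mr_weighted_median(k, n_reps = 200, seed = 99)
  b <- mr_weighted_median(k, n_reps = 200, seed = 99)
  expect_identical(a$se, b$se)
  c <- mr_weighted_median(k, n_reps = 200, seed = 100)
  expect_false(identical(a$se, c$se))
  m1 <- mr_weighted_mode(k, n_reps = 150, seed = 7)
  m2 <- mr_weighted_mode(k, n_reps = 150, seed = 7)
  expect_identical(m1$se, m2$se)
})

test_that("weighted mode finds the majority cluster and matches the grid oracle", {
  k <- pair_row(1, 1)[c(1, 1, 1, 1), ]
  k$variant_id <- letters[1:4]
  k$beta_outcome <- c(0.5, 0.5, 0.5, 3.0)
  est <- mr_weighted_mode(k, n_reps = 150, seed = 2)
  expect_equal(est$b, 0.5, tolerance = 0.02)

  k$beta_outcome <- rep(1.3, 4)  # degenerate: all ratios identical
  est <- mr_weighted_mode(k, n_reps = 150, seed = 2)
  expect_equal(est$b, 1.3)

  for (seed in c(3, 12)) {
    k <- rand_hset(10, seed = seed)
    est <- mr_weighted_mode(k, n_reps = 150, seed = 1)
    theta <- k$beta_outcome / k$beta_exposure
    w <- k$beta_exposure^2 / k$se_outcome^2
    h <- 0.9 * min(sd(theta), mad(theta)) * 10^(-1 / 5)
    spacing <- (max(theta) - min(theta) + 6 * h) / 9999
    expect_lt(abs(est$b - oracle_weighted_mode(theta, w, h)),
              spacing + 1e-4)
  }
  expect_error(mr_weighted_mode(rand_hset(2, seed = 1)),
               class = "mr_insufficient_instruments")
})

test_that("leave-one-out recomputes IVW on each subset and flags gross outliers", {
  k <- rand_hset(4, seed = 14)
  loo <- mr_leave_one_out(k)
  expect_equal(nrow(loo), 5)
  expect_equal(loo$variant_id, c(k$variant_id, "all"))
  for (i in 1:4) {
    expect_equal(loo$b[i], mr_ivw(k[-i, ])$b, tolerance = 1e-14)
  }

  # homogeneous data: every omission gives the full-set estimate
  k$beta_outcome <- 0.25 * k$beta_exposure
  loo <- mr_leave_one_out(k)
  expect_true(all(abs(loo$b - 0.25) < 1e-12))

  # a gross outlier moves the estimate most when omitted
  k <- rand_hset(8, seed = 15)
  k$beta_outcome[3] <- k$beta_outcome[3] + 1
  loo <- mr_leave_one_out(k)
  full <- loo$b[loo$variant_id == "all"]
  shifts <- abs(loo$b[loo$variant_id != "all"] - full)
  expect_equal(which.max(shifts), 3)
})

test_that("scatter data carries every kept pair and consistent fitted lines", {
  k <- rand_hset(9, seed = 18)
  fit <- mr_fit(k, n_reps = 120, seed = 1)
  sc <- mr_scatter_data(k, fit$estimates)
  expect_equal(nrow(sc$points), 9)
  expect_equal(sc$lines$intercept[sc$lines$method == "ivw"], 0)
  expect_equal(sc$lines$intercept[sc$lines$method == "egger_slope"],
               fit$estimates$b[fit$estimates$method == "egger_intercept"])
  expect_false("egger_intercept" %in% sc$lines$method)
})

test_that("under exact homogeneity all estimators agree", {
  k <- rand_hset(11, seed = 20)
  k$beta_exposure <- abs(k$beta_exposure)
  k$beta_outcome <- 0.42 * k$beta_exposure
  fit <- mr_fit(k, n_reps = 120, seed = 5)
  b <- fit$estimates$b[fit$estimates$method != "egger_intercept"]
  expect_true(all(abs(b - 0.42) < 1e-10))
})

test_that("analytic power: null effect gives alpha, and power is monotone", {
  expect_equal(mr_power(58221, 67694, 0.003, 1), 0.05)
  expect_equal(mr_power(1000, 1000, 0.05, 1, alpha = 0.2), 0.2)
  p1 <- mr_power(58221, 67694, 0.003, 1.1)
  p2 <- mr_power(58221, 67694, 0.006, 1.1)
  p3 <- mr_power(58221, 67694, 0.006, 1.2)
  expect_true(p1 < p2 && p2 < p3)
  expect_gt(mr_power(2 * 58221, 2 * 67694, 0.003, 1.1), p1)
  expect_error(mr_power(1000, 1000, 0, 1.2), class = "mr_config_error")
})

test_that("mr_fit dispatches by instrument count and supports tidy/glance", {
  k1 <- rand_hset(1, seed = 2)
  f1 <- mr_fit(k1)
  expect_equal(f1$estimates$method, "wald_ratio")

  k <- rand_hset(6, seed = 2)
  f <- mr_fit(k, n_reps = 120, seed = 3)
  expect_setequal(f$estimates$method,
                  c("ivw", "weighted_median", "egger_slope",
                    "egger_intercept", "weighted_mode"))
  td <- tidy(f)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("method", "b", "se", "pval") %in% names(td)))
  gl <- glance(f)
  expect_equal(gl$nsnp, 6)
  expect_equal(gl$Q_df, 5L)
})
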