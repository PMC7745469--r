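rand_mset <- function(J, seed, b1 = 0.2, b2 = 0.3) {
  withr::with_seed(seed, {
    bx1 <- rnorm(J, 0.05, 0.02)
    bx2 <- rnorm(J, 0.04, 0.03)
    sey <- runif(J, 0.01, 0.04)
    tibble::tibble(
      variant_id = sprintf("rs%03d", seq_len(J)),
      beta_x1 = bx1, se_x1 = runif(J, 0.002, 0.006),
      beta_x2 = bx2, se_x2 = runif(J, 0.002, 0.006),
      beta_outcome = b1 * bx1 + b2 * bx2 + rnorm(J, 0, sey),
      se_outcome = sey
    )
  })
}

test_that("exact noiseless data is recovered with zero residual heterogeneity", {
  m <- rand_mset(12, seed = 1)
  m$beta_outcome <- 0.2 * m$beta_x1 + 0.3 * m$beta_x2
  fit <- mvmr_fit(m, exposures = c("x1", "x2"))
  expect_equal(fit$estimates$b, c(0.2, 0.3), tolerance = 1e-10)
  expect_equal(fit$heterogeneity$Q, 0, tolerance = 1e-16)
  expect_equal(fit$heterogeneity$df, 10L)
})

test_that("random instances match the weighted normal-equations oracle", {
  for (seed in c(2, 8, 21)) {
    m <- rand_mset(20, seed = seed)
    fit <- mvmr_fit(m, exposures = c("x1", "x2"), conditional_f = FALSE)
    o <- oracle_wls_multi(cbind(m$beta_x1, m$beta_x2), m$beta_outcome,
                          1 / m$se_outcome^2)
    phi <- max(1, sqrt(o$Q / (20 - 2)))
    expect_equal(fit$estimates$b, o$b, tolerance = 1e-10)
    expect_equal(fit$estimates$se, phi * o$se_fixed, tolerance = 1e-10)
    expect_equal(fit$heterogeneity$Q, o$Q, tolerance = 1e-10)
  }
})

test_that("a zero second exposure column reduces to univariable IVW", {
  m <- rand_mset(15, seed = 3)
  m$beta_x2 <- 0
  expect_warning(fit <- mvmr_fit(m, exposures = c("x1", "x2"),
                                 conditional_f = FALSE),
                 "all-zero")
  uni <- mr_ivw(tibble::tibble(
    variant_id = m$variant_id, beta_exposure = m$beta_x1,
    se_exposure = m$se_x1, beta_outcome = m$beta_outcome,
    se_outcome = m$se_outcome, status = "kept"))
  expect_equal(fit$estimates$b[1], uni$b, tolerance = 1e-12)
  expect_true(is.na(fit$estimates$b[2]))
})

test_that("K = 1 multivariable fit equals univariable IVW exactly", {
  m <- rand_mset(10, seed = 5)
  fit <- mvmr_fit(dplyr::select(m, -beta_x2, -se_x2), exposures = "x1",
                  conditional_f = FALSE)
  uni <- mr_ivw(tibble::tibble(
    variant_id = m$variant_id, beta_exposure = m$beta_x1,
    se_exposure = m$se_x1, beta_outcome = m$beta_outcome,
    se_outcome = m$se_outcome, status = "kept"))
  expect_equal(fit$estimates$b, uni$b)
  expect_equal(fit$estimates$se, uni$se)
})

test_that("row order does not affect the fit, and collinearity is named", {
  m <- rand_mset(18, seed = 9)
  f1 <- mvmr_fit(m, exposures = c("x1", "x2"), conditional_f = FALSE)
  perm <- withr::with_seed(1, sample(nrow(m)))
  f2 <- mvmr_fit(m[perm, ], exposures = c("x1", "x2"),
                 conditional_f = FALSE)
  expect_equal(f2$estimates$b, f1$estimates$b, tolerance = 1e-12)
  expect_equal(f2$heterogeneity$Q, f1$heterogeneity$Q, tolerance = 1e-10)

  m$beta_x2 <- 2 * m$beta_x1
  err <- tryCatch(mvmr_fit(m, exposures = c("x1", "x2")),
                  error = function(e) conditionMessage(e))
  expect_match(err, "x1.*x2")
  expect_error(mvmr_fit(rand_mset(3, seed = 1), exposures = c("x1", "x2")),
               class = "mr_insufficient_instruments")
})

test_that("tidy and glance expose the multivariable fit", {
  fit <- mvmr_fit(rand_mset(20, seed = 12), exposures = c("x1", "x2"))
  td <- tidy(fit)
  expect_equal(nrow(td), 2)
  expect_true("conditional_f" %in% names(td))
  gl <- glance(fit)
  expect_equal(gl$n_exposures, 2)
  expect_equal(gl$Q_df, 18L)
})

test_that("conditional F reduces to the scaled mean per-SNP F with a null co-exposure", {
  m <- rand_mset(15, seed = 4)
  m$beta_x2 <- 0
  J <- nrow(m)
  f <- conditional_f(m, exposure = "x1", exposures = c("x1", "x2"))
  expect_equal(f, sum((m$beta_x1 / m$se_x1)^2) / (J - 2 + 1),
               tolerance = 1e-12)
})

test_that("perfect collinearity between exposures gives near-zero conditional F", {
  m <- rand_mset(15, seed = 6)
  m$beta_x2 <- m$beta_x1
  m$se_x1 <- m$se_x2 <- rep(1e-4, 15)
  f <- conditional_f(m, exposure = "x1", exposures = c("x1", "x2"))
  expect_lt(f, 1)
})

test_that("conditional F of independent strong exposures grows with precision", {
  f_at <- function(se_scale, seed) {
    withr::with_seed(seed, {
      J <- 25
      bx1 <- rnorm(J, 0, 0.05)
      bx2 <- rnorm(J, 0, 0.05)
      se <- rep(0.01 * se_scale, J)
      m <- tibble::tibble(
        variant_id = sprintf("rs%03d", 1:J),
        beta_x1 = bx1 + rnorm(J, 0, se), se_x1 = se,
        beta_x2 = bx2 + rnorm(J, 0, se), se_x2 = se,
        beta_outcome = rnorm(J, 0, 0.02), se_outcome = rep(0.02, J)
      )
      conditional_f(m, exposure = "x1", exposures = c("x1", "x2"))
    })
  }
  # halving the exposure SEs (a larger exposure GWAS) raises conditional F
  expect_gt(mean(vapply(1:5, function(s) f_at(0.5, s), numeric(1))),
            mean(vapply(1:5, function(s) f_at(1, s), numeric(1))))
})
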