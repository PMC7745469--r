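# Independent oracles used to cross-check the analytic implementations.
# These deliberately use different machinery (stats::lm, explicit loops,
# fine grids) from the package's own normal-equations code.

# weighted least squares through the origin via lm(); fixed-effect SE
# recovered by dividing out lm's estimated residual scale
oracle_wls_origin <- function(bx, by, w) {
  fit <- stats::lm(by ~ 0 + bx, weights = w)
  s <- summary(fit)
  list(b = unname(stats::coef(fit)),
       se_fixed = unname(s$coefficients[1, 2] / s$sigma),
       Q = sum(w * stats::resid(fit)^2))
}

oracle_wls_intercept <- function(bx, by, w) {
  fit <- stats::lm(by ~ bx, weights = w)
  s <- summary(fit)
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       se_intercept_fixed = unname(s$coefficients[1, 2] / s$sigma),
       se_slope_fixed = unname(s$coefficients[2, 2] / s$sigma),
       Q = sum(w * stats::resid(fit)^2))
}

oracle_wls_multi <- function(X, y, w) {
  fit <- stats::lm(y ~ 0 + X, weights = w)
  s <- summary(fit)
  list(b = unname(stats::coef(fit)),
       se_fixed = unname(s$coefficients[, 2] / s$sigma),
       Q = sum(w * stats::resid(fit)^2))
}

# brute-force cumulative-weight interpolation for the weighted median
oracle_weighted_median <- function(theta, w) {
  ord <- order(theta)
  theta <- theta[ord]
  w <- w[ord] / sum(w)
  s <- numeric(length(w))
  for (j in seq_along(w)) s[j] <- sum(w[seq_len(j)]) - w[j] / 2
  if (0.5 <= s[1]) return(theta[1])
  if (0.5 >= s[length(s)]) return(theta[length(theta)])
  j <- max(which(s < 0.5))
  theta[j] + (theta[j + 1] - theta[j]) * (0.5 - s[j]) / (s[j + 1] - s[j])
}

# fine-grid weighted KDE argmax for the mode (1e-4 spacing)
oracle_weighted_mode <- function(theta, w, h, spacing = 1e-4) {
  w <- w / sum(w)
  grid <- seq(min(theta) - 3 * h, max(theta) + 3 * h, by = spacing)
  dens <- vapply(grid, function(g) sum(w * stats::dnorm(g, theta, h)),
                 numeric(1))
  grid[which.max(dens)]
}

# exhaustive greedy clumping oracle over all pairs
oracle_greedy_clump <- function(ids, pvals, r2, p_threshold, r2_threshold) {
  keep <- ids[pvals < p_threshold]
  pv <- pvals[pvals < p_threshold]
  ord <- order(pv, keep)
  keep <- keep[ord]
  selected <- character(0)
  while (length(keep) > 0) {
    best <- keep[1]
    selected <- c(selected, best)
    drop <- vapply(keep, function(v) r2[best, v] >= r2_threshold, logical(1))
    keep <- keep[!drop]
  }
  selected
}

# literal step-up Benjamini-Hochberg: p_adj(i) = min_{k >= i} m p_(k) / k
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    adj_sorted[i] <- min(1, min(m * sorted[i:m] / (i:m)))
  }
  adj <- numeric(m)
  adj[ord] <- adj_sorted
  adj
}

# random harmonized set of kept pairs
rand_hset <- function(J, seed, theta = 0.3) {
  withr::with_seed(seed, {
    bx <- stats::rnorm(J, 0.05, 0.02)
    sex <- stats::runif(J, 0.002, 0.01)
    sey <- stats::runif(J, 0.01, 0.05)
    by <- theta * bx + stats::rnorm(J, 0, sey)
    tibble::tibble(
      variant_id = sprintf("rs%04d", seq_len(J)),
      beta_exposure = bx, se_exposure = sex,
      beta_outcome = by, se_outcome = sey,
      status = "kept"
    )
  })
}

# random block-diagonal LD with matching p-values, for clumping tests
rand_block_ld <- function(n, seed) {
  withr::with_seed(seed, {
    ids <- sprintf("rs%04d", seq_len(n))
    r2 <- diag(1, n)
    i <- 1
    while (i < n) {
      size <- min(sample(1:4, 1), n - i + 1)
      if (size > 1) {
        idx <- i:(i + size - 1)
        val <- stats::runif(1, 0, 1)
        r2[idx, idx] <- val
        r2[cbind(idx, idx)] <- 1
      }
      i <- i + size
    }
    list(ld = ld_matrix(r2, ids), ids = ids,
         pvals = stats::runif(n, 0, 2e-7))
  })
}
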