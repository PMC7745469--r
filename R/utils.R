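# Internal helpers shared across modules.

# Two-sided normal p-value from a z-score, clamped into (0, 1] so the
# MREstimate invariant pval > 0 survives |z| large enough to underflow.
two_sided_p <- function(z) {
  pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
}

# One estimate row in the canonical MREstimate shape.
estimate_row <- function(method, b, se, nsnp, re_scale = 1) {
  tibble::tibble(
    method = method,
    nsnp = as.integer(nsnp),
    b = b,
    se = se,
    ci_lower = b - Z95 * se,
    ci_upper = b + Z95 * se,
    pval = two_sided_p(b / se),
    re_scale = re_scale
  )
}

heterogeneity_row <- function(Q, df) {
  tibble::tibble(
    Q = Q,
    df = as.integer(df),
    pval = stats::pchisq(Q, df = df, lower.tail = FALSE),
    I2 = max(0, (Q - df) / Q)
  )
}

abort_mr <- function(message, class) {
  rlang::abort(message, class = c(class, "mrmediate_error"))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

stopifnot_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort_mr(
      sprintf("%s is missing required column(s): %s", what,
              paste(missing, collapse = ", ")),
      "mr_bad_input"
    )
  }
  invisible(df)
}

# Run `expr` under a fixed RNG state when `seed` is given, untouched otherwise.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}
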