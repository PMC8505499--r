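#' Covariate-adjusted ordinary least squares with standardized coefficients
#'
#' Fits an OLS regression with intercept and reports, per predictor, the raw
#' coefficient, its standard error and two-sided t-test p-value, plus the
#' standardized coefficient `beta = b * sd(x) / sd(y)` computed on the
#' complete cases actually used. Rows with missing values are dropped
#' (complete-case analysis) and the number removed is recorded.
#'
#' @param formula a model formula.
#' @param data a data frame.
#' @return an object of class `"ols_fit"`: list with `outcome`,
#'   `coefficients` (data frame with columns `term`, `estimate`, `beta`,
#'   `se`, `p_value`), `n`, `n_dropped`, `r_squared` and the underlying
#'   `lm` fit.
#' @examples
#' d <- data.frame(y = rnorm(50), x = rnorm(50))
#' fit_ols(y ~ x, d)$coefficients
#' @export
fit_ols <- function(formula, data) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  n_dropped <- nrow(data) - nrow(mf)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  preds <- setdiff(colnames(X), "(Intercept)")
  if (nrow(X) <= ncol(X)) {
    stop("too few complete cases (", nrow(X), ") for ", ncol(X),
         " coefficients", call. = FALSE)
  }
  const <- preds[apply(X[, preds, drop = FALSE], 2, function(v)
    stats::var(v) == 0)]
  if (length(const)) {
    stop("constant predictor column(s): ", paste(const, collapse = ", "),
         call. = FALSE)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm(formula, data = mf)
  sm <- summary(fit)
  ct <- sm$coefficients
  terms_out <- rownames(ct)
  sdy <- stats::sd(y)
  beta <- vapply(terms_out, function(tm) {
    if (tm == "(Intercept)") return(NA_real_)
    ct[tm, 1L] * stats::sd(X[, tm]) / sdy
  }, numeric(1))
  structure(list(
    outcome = deparse(formula[[2L]]),
    coefficients = data.frame(
      term = terms_out,
      estimate = ct[, 1L],
      beta = beta,
      se = ct[, 2L],
      p_value = ct[, 4L],
      row.names = NULL
    ),
    n = nrow(X),
    n_dropped = n_dropped,
    r_squared = sm$r.squared,
    lm = fit
  ), class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, digits = 4, ...) {
  cat(sprintf("OLS: %s  (n = %d, dropped %d, R-squared %.4f)\n",
              x$outcome, x$n, x$n_dropped, x$r_squared))
  cf <- x$coefficients
  cf[-1] <- lapply(cf[-1], signif, digits = digits)
  print(cf, row.names = FALSE)
  invisible(x)
}

ols_coef <- function(fit, term, col = "estimate") {
  cf <- fit$coefficients
  cf[[col]][match(term, cf$term)]
}

#' Holm-Bonferroni stepdown familywise error control
#'
#' Sorts the p-values ascending and rejects the k-th smallest iff every
#' smaller p-value `p_(j)` satisfies `p_(j) <= alpha / (m - j + 1)`,
#' stopping at the first failure (boundary ties rejected). Decisions are
#' delegated to [stats::p.adjust()] with `method = "holm"`, which
#' implements the identical stepdown rule.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param alpha familywise error level (default 0.05).
#' @return a data frame, in input order, with columns `p`, `rank`,
#'   `threshold` (`alpha / (m - rank + 1)`), `p_adjusted` and `reject`.
#'   Empty input yields an empty data frame.
#' @examples
#' holm_bonferroni(c(0.01, 0.04), alpha = 0.05)
#' @export
holm_bonferroni <- function(p, alpha = 0.05) {
  if (length(p) == 0L) {
    return(data.frame(p = numeric(0), rank = integer(0),
                      threshold = numeric(0), p_adjusted = numeric(0),
                      reject = logical(0)))
  }
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p)
  rk <- rank(p, ties.method = "first")
  data.frame(
    p = p,
    rank = rk,
    threshold = alpha / (m - rk + 1),
    p_adjusted = stats::p.adjust(p, method = "holm"),
    reject = stats::p.adjust(p, method = "holm") <= alpha
  )
}
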