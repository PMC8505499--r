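# Independent oracles used across tests. Kept deliberately separate from
# the package implementation: normal equations for OLS, an explicit
# stepdown loop for Holm, quadrature for component mass.

# closed-form OLS via normal equations (X includes no intercept column;
# one is prepended here)
ols_oracle <- function(X, y) {
  X1 <- cbind(1, X)
  XtX <- crossprod(X1)
  beta <- drop(solve(XtX, crossprod(X1, y)))
  res <- y - X1 %*% beta
  n <- nrow(X1); p <- ncol(X1)
  sigma2 <- sum(res^2) / (n - p)
  se <- sqrt(diag(solve(XtX)) * sigma2)
  tval <- beta / se
  list(coef = drop(beta), se = se,
       p = 2 * pt(-abs(tval), df = n - p))
}

# literal stepdown: sort ascending, reject p_(k) iff p_(j) <= a/(m-j+1)
# for all j <= k, stopping at the first failure
holm_oracle <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  reject_sorted <- logical(m)
  for (k in seq_len(m)) {
    ok <- TRUE
    for (j in seq_len(k)) {
      if (p[ord[j]] > alpha / (m - j + 1)) { ok <- FALSE; break }
    }
    if (!ok) break
    reject_sorted[k] <- TRUE
  }
  out <- logical(m)
  out[ord] <- reject_sorted
  out
}

ref_params <- function() ntra_reference_params("baseline")

ref_total_mass <- function() {
  p <- ref_params()
  sum(p[c("fat_N", "conn_N", "muscle_N")])
}

# minimal schema-complete cohort for hand-built mediation fixtures
blank_cohort <- function(n, seed = 1) {
  withr::with_seed(seed, {
    df <- data.frame(
      id = sprintf("S%04d", seq_len(n)),
      age = rnorm(n, 75, 5),
      sex = rbinom(n, 1, 0.42),
      bmi = rnorm(n, 27, 4),
      pa = sample(1:5, n, replace = TRUE)
    )
    for (t in c("gsf", "gsn", "str", "tug")) {
      df[[paste0(t, "_base")]] <- rnorm(n)
      df[[paste0(t, "_fu")]] <- rnorm(n)
    }
    for (j in names(coef_names <- ntra_reference_params("baseline"))) {
      df[[j]] <- rnorm(n)
    }
    df
  })
}

# config with no covariate structure: pure exposure -> mediator -> outcome
bare_config <- function(n, a_val, b_val, mediator = "muscle_N",
                        task = "gsf", seed = 1) {
  nm <- names(ntra_reference_params("baseline"))
  a <- setNames(numeric(11), nm)
  a[mediator] <- a_val
  b <- matrix(0, 11, 4, dimnames = list(nm, c("gsf", "gsn", "str", "tug")))
  b[mediator, task] <- b_val
  zero11 <- setNames(numeric(11), nm)
  zero4 <- setNames(numeric(4), c("gsf", "gsn", "str", "tug"))
  cohort_config(
    n_subjects = n, a = a, b = b,
    c_direct = zero4,
    cov_mediator = list(age = zero11, sex = zero11, bmi = zero11),
    cov_outcome = list(age = zero4, sex = zero4, bmi = zero4),
    gamma_base = zero4,
    seed = seed
  )
}
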