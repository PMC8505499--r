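# bound windows for the fit; mu windows widened relative to the canonical
# tissue domains so peaks near a domain boundary are not clipped
ntra_lower <- function() {
  c(fat_N = 0, fat_mu = -200, fat_sigma = 0.5, fat_alpha = -10,
    conn_N = 0, conn_mu = -60, conn_sigma = 0.5,
    muscle_N = 0, muscle_mu = 30, muscle_sigma = 0.5, muscle_alpha = -10)
}

ntra_upper <- function() {
  c(fat_N = Inf, fat_mu = 0, fat_sigma = 60, fat_alpha = 10,
    conn_N = Inf, conn_mu = 50, conn_sigma = 60,
    muscle_N = Inf, muscle_mu = 120, muscle_sigma = 60, muscle_alpha = 10)
}

#' Moment-based starting values for the trimodal fit
#'
#' Partitions the histogram into the canonical tissue HU domains
#' (fat -200..-10, connective -9..40, muscle 41..200) and computes, per
#' domain, the count-weighted mean (location start), count-weighted SD
#' floored at 1 HU (width start) and peak height times `sigma * sqrt(2*pi)`
#' (amplitude start). Skewness starts at -2 for fat, 0 for connective and
#' +2 for muscle, matching the inward slope of the peripheral peaks. A
#' domain with no counts yields an empty component: `N = 0`, `mu` at the
#' domain midpoint, `sigma` = domain width / 6.
#'
#' @param hist an [hu_histogram].
#' @param scale histogram mass scale passed to the fit (see [ntra_fit]).
#' @return a [trimodal_params] starting value.
#' @export
ntra_init <- function(hist, scale = NULL) {
  h <- histogram_heights(hist, scale)
  mids <- hist$mids
  alpha0 <- c(fat = -2, conn = 0, muscle = 2)
  out <- numeric(0)
  for (tis in NTRA_TISSUES) {
    dom <- NTRA_DOMAINS[[tis]]
    # widen by half a bin so integer-edge bins fall in their natural domain
    in_dom <- mids >= dom[1L] - hist$width / 2 & mids <= dom[2L] + hist$width / 2
    cts <- hist$counts[in_dom]
    if (sum(cts) > 0) {
      xs <- mids[in_dom]
      mu <- sum(cts * xs) / sum(cts)
      sigma <- max(1, sqrt(sum(cts * (xs - mu)^2) / sum(cts)))
      N <- max(h[in_dom]) * sigma * sqrt(2 * pi)
    } else {
      mu <- mean(dom)
      sigma <- diff(dom) / 6
      N <- 0
    }
    comp <- c(N, mu, sigma)
    if (tis != "conn") comp <- c(comp, alpha0[[tis]])
    out <- c(out, comp)
  }
  names(out) <- NTRA_PARAM_NAMES
  # clamp mu/sigma/alpha inside the fit windows; amplitudes stay as-is
  lo <- ntra_lower(); up <- ntra_upper()
  amp <- c("fat_N", "conn_N", "muscle_N")
  keep_N <- out[amp]
  out <- pmin(pmax(out, lo + 1e-6), pmin(up - 1e-6, .Machine$double.xmax))
  out[amp] <- keep_N
  structure(out, class = "trimodal_params")
}

#' Fit the trimodal skew-Gaussian radiodensity model
#'
#' Estimates the eleven subject-specific parameters by bounded nonlinear
#' least squares on bin heights: the objective is
#' `sum_k (h_k - model(x_k))^2`, where `h_k` are the histogram counts
#' rescaled so that the histogram area equals `scale` (the model's total
#' mass units) and `x_k` are bin centers. A Levenberg-Marquardt optimizer
#' with box constraints is run from a moment-based start plus jittered
#' multistarts, keeping the best objective. The connective component's
#' skewness is structurally zero and is not a free parameter.
#'
#' Amplitudes are identifiable only up to the histogram's total mass, so
#' `scale` fixes their units: the default (`sum(counts) * bin_width`) fits
#' raw counts, while passing a known total tissue mass expresses amplitudes
#' in that unit.
#'
#' @param hist an [hu_histogram] with positive total count.
#' @param init optional [trimodal_params] starting values; default
#'   [ntra_init].
#' @param scale histogram mass scale (see Details); default raw counts.
#' @param n_starts number of optimizer starts (1 unjittered + jittered);
#'   default 5.
#' @param seed integer seed for the multistart jitter; default 1.
#' @param maxit maximum optimizer iterations per start.
#' @return an object of class `"ntra_fit"`: list with elements `params`
#'   (the fitted [trimodal_params]), `objective` (final sum of squared
#'   errors), `converged`, `n_iterations`, `r_squared`, `rmse`,
#'   `residuals` (per-bin observed minus fitted), `fitted`, `hist`,
#'   `scale`, `at_bounds` (names of parameters on a box constraint) and
#'   `degenerate` (TRUE when a width collapsed to its lower bound).
#' @examples
#' p <- ntra_reference_params()
#' h <- bin_voxels(sample_voxels(p, 2e4, seed = 1))
#' fit <- ntra_fit(h, scale = sum(p[c("fat_N", "conn_N", "muscle_N")]))
#' coef(fit)
#' @export
ntra_fit <- function(hist, init = NULL, scale = NULL, n_starts = 5,
                     seed = 1, maxit = 200) {
  stopifnot(inherits(hist, "hu_histogram"))
  h <- histogram_heights(hist, scale)  # errors on zero total
  mids <- hist$mids
  if (is.null(init)) init <- ntra_init(hist, scale)
  init <- as.numeric(as_trimodal_params(init))
  lo <- ntra_lower(); up <- ntra_upper()

  resid_fun <- function(theta) {
    names(theta) <- NTRA_PARAM_NAMES
    h - trimodal_density(mids, structure(theta, class = "trimodal_params"))
  }

  starts <- list(init)
  if (n_starts > 1) {
    starts <- c(starts, with_seed(seed, {
      lapply(seq_len(n_starts - 1L), function(j) {
        jit <- init
        idx_N <- c(1, 5, 8); idx_mu <- c(2, 6, 9)
        idx_sig <- c(3, 7, 10); idx_a <- c(4, 11)
        jit[idx_N] <- jit[idx_N] * stats::runif(3, 0.7, 1.4)
        jit[idx_mu] <- jit[idx_mu] + stats::runif(3, -5, 5)
        jit[idx_sig] <- jit[idx_sig] * stats::runif(3, 0.7, 1.4)
        jit[idx_a] <- jit[idx_a] + stats::runif(2, -1, 1)
        pmin(pmax(jit, lo + 1e-8), ifelse(is.finite(up), up - 1e-8, jit))
      })
    }))
  }

  best <- NULL
  for (s in starts) {
    res <- try(minpack.lm::nls.lm(
      par = s, lower = lo, upper = up, fn = resid_fun,
      control = minpack.lm::nls.lm.control(maxiter = maxit)
    ), silent = TRUE)
    if (inherits(res, "try-error")) next
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }
  if (is.null(best)) stop("all optimizer starts failed", call. = FALSE)

  theta <- best$par
  names(theta) <- NTRA_PARAM_NAMES
  # enforce the location ordering invariant post-fit
  mus <- theta[c("fat_mu", "conn_mu", "muscle_mu")]
  if (is.unsorted(mus, strictly = TRUE)) {
    warning("fitted component locations are not ordered fat < conn < muscle",
            call. = FALSE)
  }
  params <- structure(theta, class = "trimodal_params")
  fitted_vals <- trimodal_density(mids, params)
  resid_vals <- h - fitted_vals
  gof <- gof_from_heights(h, fitted_vals)
  tol <- 1e-6
  at_bounds <- NTRA_PARAM_NAMES[
    (theta - lo <= tol & is.finite(lo)) |
      (is.finite(up) & up - theta <= tol)]
  converged <- best$info %in% 1:4

  structure(list(
    params = params,
    objective = best$deviance,
    converged = converged,
    n_iterations = best$niter,
    r_squared = gof$r_squared,
    rmse = gof$rmse,
    residuals = resid_vals,
    fitted = fitted_vals,
    hist = hist,
    heights = h,
    scale = if (is.null(scale)) sum(hist$counts) * hist$width else scale,
    n_starts = length(starts),
    at_bounds = at_bounds,
    degenerate = any(c("fat_sigma", "conn_sigma", "muscle_sigma") %in%
                       at_bounds)
  ), class = "ntra_fit")
}

gof_from_heights <- function(h, model) {
  sse <- sum((h - model)^2)
  sst <- sum((h - mean(h))^2)
  list(
    r_squared = if (sst > 0) 1 - sse / sst else NA_real_,
    rmse = sqrt(sse / length(h))
  )
}

#' Goodness of fit of trimodal parameters to a histogram
#'
#' @param hist an [hu_histogram].
#' @param params a [trimodal_params] object.
#' @param scale histogram mass scale, as in [ntra_fit].
#' @return list with `r_squared` (`1 - SSE/SST` on bin heights; `NA` for a
#'   zero-variance histogram) and `rmse`.
#' @export
ntra_gof <- function(hist, params, scale = NULL) {
  h <- histogram_heights(hist, scale)
  gof_from_heights(h, trimodal_density(hist$mids, params))
}

#' @export
print.ntra_fit <- function(x, digits = 4, ...) {
  cat("Trimodal radiodensity fit\n")
  cat(sprintf("  bins: %d   scale: %s   converged: %s%s\n",
              length(x$hist$counts), format(x$scale, digits = 6),
              x$converged, if (x$degenerate) "  [degenerate width]" else ""))
  cat(sprintf("  SSE: %.6g   R-squared: %.4f\n", x$objective, x$r_squared))
  print(x$params, digits = digits)
  invisible(x)
}

#' @export
summary.ntra_fit <- function(object, ...) {
  masses <- object$params[c("fat_N", "conn_N", "muscle_N")]
  out <- list(
    params = object$params,
    tissue_fractions = masses / sum(masses),
    objective = object$objective,
    r_squared = object$r_squared,
    rmse = object$rmse,
    converged = object$converged,
    n_iterations = object$n_iterations,
    at_bounds = object$at_bounds
  )
  class(out) <- "summary.ntra_fit"
  out
}

#' @export
print.summary.ntra_fit <- function(x, ...) {
  print(x$params)
  cat("\nTissue mass fractions:\n")
  print(round(x$tissue_fractions, 4))
  cat(sprintf("\nSSE %.6g, RMSE %.6g, R-squared %.4f, %s after %d iterations\n",
              x$objective, x$rmse, x$r_squared,
              if (x$converged) "converged" else "did not converge",
              x$n_iterations))
  if (length(x$at_bounds)) {
    cat("Parameters at bounds:", paste(x$at_bounds, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.ntra_fit <- function(object, ...) {
  stats::setNames(as.numeric(object$params), NTRA_PARAM_NAMES)
}

#' @export
residuals.ntra_fit <- function(object, ...) object$residuals

#' @export
fitted.ntra_fit <- function(object, ...) object$fitted

#' Predicted model density on a new HU grid
#'
#' @param object an `"ntra_fit"`.
#' @param newdata numeric vector of HU values (default: the fitted bin
#'   centers).
#' @param ... unused.
#' @export
predict.ntra_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$hist$mids else newdata
  trimodal_density(x, object$params)
}

#' Draw synthetic voxels from a fitted trimodal model
#'
#' @param object an `"ntra_fit"`.
#' @param nsim number of voxel values to draw.
#' @param seed integer seed.
#' @param ... unused.
#' @return numeric vector of HU values (see [sample_voxels]).
#' @export
simulate.ntra_fit <- function(object, nsim = 1, seed = NULL, ...) {
  sample_voxels(object$params, n = nsim, seed = seed)
}

#' Plot a radiodensity histogram with fitted tissue components
#'
#' @param x an `"ntra_fit"`.
#' @param ... passed to [plot()].
#' @export
plot.ntra_fit <- function(x, ...) {
  mids <- x$hist$mids
  plot(mids, x$heights, type = "h", col = "grey70",
       xlab = "Radiodensity (HU)", ylab = "Scaled bin height", ...)
  m <- param_matrix(x$params)
  cols <- c(fat = "goldenrod3", conn = "steelblue3", muscle = "firebrick3")
  for (tis in rownames(m)) {
    graphics::lines(mids, component_density(mids, m[tis, 1], m[tis, 2],
                                            m[tis, 3], m[tis, 4]),
                    col = cols[[tis]], lwd = 2)
  }
  graphics::lines(mids, x$fitted, lwd = 2)
  graphics::legend("topleft", bty = "n", lwd = 2,
                   col = c(cols, "black"),
                   legend = c("fat", "connective", "muscle", "total"))
  invisible(x)
}
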