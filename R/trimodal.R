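NTRA_PARAM_NAMES <- c(
  "fat_N", "fat_mu", "fat_sigma", "fat_alpha",
  "conn_N", "conn_mu", "conn_sigma",
  "muscle_N", "muscle_mu", "muscle_sigma", "muscle_alpha"
)

NTRA_TISSUES <- c("fat", "conn", "muscle")

# canonical tissue HU domains used for initialization
NTRA_DOMAINS <- list(
  fat    = c(-200, -10),
  conn   = c(-9, 40),
  muscle = c(41, 200)
)

#' Skew-Gaussian tissue component density
#'
#' Evaluates one tissue component of the trimodal radiodensity model,
#' \deqn{\varphi(x) = \frac{N}{\sigma\sqrt{2\pi}}
#'   e^{-(x-\mu)^2 / 2\sigma^2}\,
#'   \mathrm{erfc}\!\left(\frac{\alpha(x-\mu)}{\sigma\sqrt{2}}\right),}
#' a skew-normal density scaled to total mass `N`. At `x = mu` the value is
#' `N / (sigma * sqrt(2*pi))` for any skewness, and `alpha > 0` produces a
#' longer tail toward lower HU (negative third moment).
#'
#' @param x numeric vector of Hounsfield-unit values.
#' @param N amplitude (total integrated mass), `>= 0`.
#' @param mu location (HU).
#' @param sigma width (HU), `> 0`.
#' @param alpha skewness; `0` gives a symmetric Gaussian.
#' @return numeric vector of non-negative density values.
#' @examples
#' component_density(0, N = 1, mu = 0, sigma = 1, alpha = 0)  # 1/sqrt(2*pi)
#' @export
component_density <- function(x, N, mu, sigma, alpha = 0) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0) {
    stop("'sigma' must be a single positive number", call. = FALSE)
  }
  if (N < 0) stop("'N' must be non-negative", call. = FALSE)
  z <- (x - mu) / sigma
  # erfc(t) == 2 * pnorm(-t * sqrt(2))
  N / (sigma * sqrt(2 * pi)) * exp(-z^2 / 2) * 2 * stats::pnorm(-alpha * z)
}

#' Construct a full set of trimodal radiodensity parameters
#'
#' Bundles the eleven free parameters of the trimodal model: amplitude,
#' location, width and skewness for fat and lean muscle, and amplitude,
#' location and width for loose connective tissue, whose skewness is
#' structurally zero (a symmetric central peak).
#'
#' @param fat numeric `c(N, mu, sigma, alpha)` for the fat component.
#' @param conn numeric `c(N, mu, sigma)` for the connective component.
#' @param muscle numeric `c(N, mu, sigma, alpha)` for the muscle component.
#' @return a named numeric vector of length 11 with class
#'   `"trimodal_params"`; names are `fat_N, fat_mu, ..., muscle_alpha`.
#' @examples
#' trimodal_params(fat = c(62, -117.8, 8.2, -2.5),
#'                 conn = c(41.6, -24.1, 25.1),
#'                 muscle = c(78, 61.5, 8.6, 2.8))
#' @export
trimodal_params <- function(fat, conn, muscle) {
  stopifnot(length(fat) == 4L, length(conn) == 3L, length(muscle) == 4L)
  p <- c(fat, conn, muscle)
  names(p) <- NTRA_PARAM_NAMES
  validate_trimodal_params(p)
  structure(p, class = "trimodal_params")
}

#' @rdname trimodal_params
#' @param x a named numeric vector carrying all eleven parameter names.
#' @export
as_trimodal_params <- function(x) {
  if (inherits(x, "trimodal_params")) return(x)
  x <- unlist(x)
  if (!all(NTRA_PARAM_NAMES %in% names(x))) {
    stop("missing parameter names: ",
         paste(setdiff(NTRA_PARAM_NAMES, names(x)), collapse = ", "),
         call. = FALSE)
  }
  p <- x[NTRA_PARAM_NAMES]
  validate_trimodal_params(p)
  structure(p, class = "trimodal_params")
}

validate_trimodal_params <- function(p) {
  sig <- p[c("fat_sigma", "conn_sigma", "muscle_sigma")]
  if (any(!is.finite(p))) stop("parameters must be finite", call. = FALSE)
  if (any(sig <= 0)) stop("all sigma must be positive", call. = FALSE)
  if (any(p[c("fat_N", "conn_N", "muscle_N")] < 0)) {
    stop("amplitudes must be non-negative", call. = FALSE)
  }
  mus <- p[c("fat_mu", "conn_mu", "muscle_mu")]
  if (any(mus < -200 | mus > 200)) {
    stop("locations must lie in [-200, 200] HU", call. = FALSE)
  }
  if (!(p[["fat_mu"]] < p[["conn_mu"]] && p[["conn_mu"]] < p[["muscle_mu"]])) {
    stop("component locations must satisfy fat < connective < muscle",
         call. = FALSE)
  }
  invisible(p)
}

# 4-column (N, mu, sigma, alpha) matrix view, one row per tissue
param_matrix <- function(params) {
  p <- as_trimodal_params(params)
  rbind(
    fat    = p[c("fat_N", "fat_mu", "fat_sigma", "fat_alpha")],
    conn   = c(p[c("conn_N", "conn_mu", "conn_sigma")], 0),
    muscle = p[c("muscle_N", "muscle_mu", "muscle_sigma", "muscle_alpha")]
  )
}

#' Trimodal radiodensity model density
#'
#' Pointwise sum of the three skew-Gaussian tissue components (fat,
#' connective, muscle) over a grid of HU values.
#'
#' @param x numeric vector of HU values.
#' @param params a [trimodal_params] object (or coercible named vector).
#' @return numeric vector, non-negative.
#' @export
trimodal_density <- function(x, params) {
  m <- param_matrix(params)
  out <- numeric(length(x))
  for (i in seq_len(3L)) {
    if (m[i, 1L] > 0) {
      out <- out + component_density(x, m[i, 1L], m[i, 2L], m[i, 3L], m[i, 4L])
    }
  }
  out
}

#' Total integrated mass of a tissue component
#'
#' The component density integrates to its amplitude `N` exactly: the erfc
#' form equals `2 N` times a normal density times a normal CDF with shape
#' `-alpha`, i.e. a skew-normal density scaled by `N`, and skew-normal
#' normalization does not depend on the shape.
#'
#' @inheritParams component_density
#' @return the analytic integral over the real line, equal to `N`.
#' @export
component_mass <- function(N, mu, sigma, alpha = 0) {
  if (sigma <= 0) stop("'sigma' must be positive", call. = FALSE)
  if (N < 0) stop("'N' must be non-negative", call. = FALSE)
  N
}

#' Reference trimodal parameters for an elderly mid-thigh cross-section
#'
#' Published cohort-mean parameters from a large longitudinal study of
#' healthy elderly volunteers (AGES-Reykjavik), used as defaults by the
#' synthetic-data generator and as a realistic fixture in examples.
#'
#' @param timepoint `"baseline"` (first study visit) or `"followup"`
#'   (approximately five years later).
#' @return a [trimodal_params] object.
#' @export
ntra_reference_params <- function(timepoint = c("baseline", "followup")) {
  timepoint <- match.arg(timepoint)
  if (timepoint == "baseline") {
    trimodal_params(fat = c(62.0, -117.8, 8.2, -2.5),
                    conn = c(41.6, -24.1, 25.1),
                    muscle = c(78.0, 61.5, 8.6, 2.8))
  } else {
    trimodal_params(fat = c(62.3, -117.2, 8.1, -2.5),
                    conn = c(41.8, -25.9, 24.6),
                    muscle = c(72.6, 60.9, 9.2, 3.0))
  }
}

#' @export
print.trimodal_params <- function(x, digits = 4, ...) {
  m <- param_matrix(x)
  colnames(m) <- c("N", "mu", "sigma", "alpha")
  cat("Trimodal radiodensity parameters (HU):\n")
  print(round(m, digits))
  invisible(x)
}
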