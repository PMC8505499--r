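#' Radiodensity histogram over the soft-tissue HU range
#'
#' A binned representation of a subject's soft-tissue radiodensity
#' distribution: half-open bins `[e_k, e_{k+1})` spanning -200 to 200 HU
#' with non-negative voxel counts.
#'
#' @param counts non-negative integer-like vector of voxel counts per bin.
#' @param edges strictly increasing bin edges; first must be -200, last 200.
#' @return an object of class `"hu_histogram"`: a list with `edges`,
#'   `counts`, `mids` (bin centers) and `width` (common bin width, HU).
#' @seealso [bin_voxels()] to build one from raw HU values.
#' @export
hu_histogram <- function(counts, edges = seq(-200, 200, by = 1)) {
  edges <- as.numeric(edges)
  counts <- as.numeric(counts)
  if (length(edges) < 2L || any(diff(edges) <= 0)) {
    stop("bin edges must be strictly increasing", call. = FALSE)
  }
  if (edges[1L] != -200 || edges[length(edges)] != 200) {
    stop("histogram must span the soft-tissue range [-200, 200] HU",
         call. = FALSE)
  }
  if (length(counts) != length(edges) - 1L) {
    stop("length(counts) must equal length(edges) - 1", call. = FALSE)
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and non-negative", call. = FALSE)
  }
  w <- diff(edges)
  width <- if (all(abs(w - w[1L]) < 1e-9)) w[1L] else NA_real_
  structure(
    list(edges = edges, counts = counts,
         mids = (edges[-1L] + edges[-length(edges)]) / 2,
         width = width),
    class = "hu_histogram"
  )
}

#' Bin raw HU voxel values into a radiodensity histogram
#'
#' Values are assigned to half-open bins `[e, e + width)` covering
#' `[-200, 200)`; values outside that range (including exactly 200) are
#' discarded and their count reported in the `n_discarded` attribute.
#'
#' @param hu_values numeric vector of HU measurements.
#' @param bin_width bin width in HU (must divide 400 evenly); default 1.
#' @return an `"hu_histogram"` with attribute `n_discarded`.
#' @export
bin_voxels <- function(hu_values, bin_width = 1) {
  if (bin_width <= 0 || abs(400 / bin_width - round(400 / bin_width)) > 1e-9) {
    stop("'bin_width' must be positive and divide the 400 HU range",
         call. = FALSE)
  }
  hu_values <- hu_values[is.finite(hu_values)]
  keep <- hu_values >= -200 & hu_values < 200
  n_discarded <- sum(!keep)
  x <- hu_values[keep]
  if (length(x) == 0L) {
    stop("no HU values inside [-200, 200)", call. = FALSE)
  }
  edges <- seq(-200, 200, by = bin_width)
  idx <- floor((x + 200) / bin_width) + 1L
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  h <- hu_histogram(counts, edges)
  attr(h, "n_discarded") <- n_discarded
  h
}

# heights on the model's mass scale: counts / (total * width) * scale
histogram_heights <- function(hist, scale = NULL) {
  total <- sum(hist$counts)
  if (total <= 0) stop("histogram has zero total count", call. = FALSE)
  if (is.null(scale)) scale <- total * hist$width
  hist$counts / (total * hist$width) * scale
}

#' @export
print.hu_histogram <- function(x, ...) {
  cat(sprintf(
    "Radiodensity histogram: %d bins of %s HU, %s voxels in [-200, 200)\n",
    length(x$counts), format(x$width), format(sum(x$counts))))
  invisible(x)
}
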