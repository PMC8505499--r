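# header comment written at the top of every output file
file_header <- function(seed = NULL, extra = NULL) {
  ver <- as.character(utils::packageVersion("ntramed"))
  parts <- c(sprintf("ntramed %s", ver),
             if (!is.null(seed)) sprintf("seed=%s", format(seed)),
             extra)
  paste0("# ", paste(parts, collapse = "; "))
}

# small deterministic checksum for config provenance (31-bit rolling hash,
# kept in doubles to stay exact)
config_hash <- function(x) {
  s <- paste(utils::capture.output(utils::str(x, digits.d = 12)),
             collapse = "\n")
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

write_csv_with_header <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(format(df, digits = 6, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
}

#' Read and write radiodensity histogram files
#'
#' Histogram files are two-column comma-separated text
#' (`bin_center_HU,count`) with a required header line; lines starting
#' with `#` are provenance comments. One file per subject, the file name
#' (minus extension) being the subject identifier.
#'
#' @param path file path.
#' @return [read_histogram()] returns an [hu_histogram].
#' @export
read_histogram <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  if (ncol(df) < 2L) {
    stop("histogram file must have columns bin_center_HU,count: ", path,
         call. = FALSE)
  }
  centers <- as.numeric(df[[1L]])
  counts <- as.numeric(df[[2L]])
  if (any(is.na(centers)) || any(is.na(counts))) {
    stop("non-numeric values in histogram file: ", path, call. = FALSE)
  }
  w <- diff(centers)
  if (length(w) == 0L || any(abs(w - w[1L]) > 1e-9)) {
    stop("bin centers must be evenly spaced: ", path, call. = FALSE)
  }
  edges <- c(centers - w[1L] / 2, centers[length(centers)] + w[1L] / 2)
  hu_histogram(counts, edges)
}

#' @rdname read_histogram
#' @param hist an [hu_histogram].
#' @param seed optional seed recorded in the provenance header.
#' @export
write_histogram <- function(hist, path, seed = NULL) {
  df <- data.frame(bin_center_HU = hist$mids, count = hist$counts)
  write_csv_with_header(df, path, file_header(seed))
  invisible(path)
}

#' Read a voxel file (one HU value per line)
#' @param path file path; `#` lines are ignored.
#' @return numeric vector of HU values.
#' @export
read_voxels <- function(path) {
  x <- scan(path, what = numeric(), comment.char = "#", quiet = TRUE)
  if (!length(x)) stop("empty voxel file: ", path, call. = FALSE)
  x
}

#' Read and write longitudinal cohort tables
#'
#' Comma-separated, one row per subject, with the exact column schema of
#' [cohort_columns()]; extra columns are preserved. `#` lines are
#' provenance comments.
#'
#' @param path file path.
#' @return [read_cohort()] returns a validated data frame.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  validate_cohort(df)
  df
}

#' @rdname read_cohort
#' @param cohort a cohort data frame.
#' @param seed optional seed recorded in the provenance header.
#' @export
write_cohort <- function(cohort, path, seed = NULL) {
  validate_cohort(cohort)
  write_csv_with_header(cohort, path, file_header(seed))
  invisible(path)
}

#' Fit the trimodal model to a batch of histogram files
#'
#' Each readable file contributes one row of the result; malformed files
#' are skipped with a warning naming the file, and non-convergent fits are
#' flagged in the `converged` column rather than dropped.
#'
#' @param paths character vector of histogram file paths.
#' @param ... passed on to [ntra_fit()].
#' @return data frame with columns `subject`, the 11 parameter names,
#'   `objective`, `r_squared`, `converged`; failed files are recorded in
#'   the `"errors"` attribute (named character vector).
#' @export
ntra_fit_batch <- function(paths, ...) {
  rows <- list()
  errors <- character(0)
  for (p in paths) {
    res <- tryCatch({
      h <- read_histogram(p)
      fit <- ntra_fit(h, ...)
      row <- data.frame(subject = sub("\\.[^.]*$", "", basename(p)),
                        t(coef(fit)))
      row$objective <- fit$objective
      row$r_squared <- fit$r_squared
      row$converged <- fit$converged
      row
    }, error = function(e) {
      warning(sprintf("skipping '%s': %s", p, conditionMessage(e)),
              call. = FALSE)
      errors[[p]] <<- conditionMessage(e)
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject = character(0))
  attr(out, "errors") <- errors
  out
}

#' @rdname ntra_fit_batch
#' @param fits the data frame returned by `ntra_fit_batch`.
#' @param path output file path.
#' @param seed optional seed for the provenance header.
#' @export
write_fit_table <- function(fits, path, seed = NULL) {
  write_csv_with_header(fits, path, file_header(seed))
  invisible(path)
}

#' Simulate a study to disk: cohort table, voxel histograms, manifest
#'
#' Generates a synthetic cohort from `config`, writes the cohort table, a
#' JSON manifest recording the seed, configuration hash and planted
#' ground-truth effects, and (optionally) per-subject radiodensity
#' histogram files sampled from the reference trimodal parameters, in the
#' formats consumed by [read_cohort()] and [ntra_fit_batch()].
#'
#' @param dir output directory (created if needed).
#' @param config a [cohort_config]; default the planted muscle-mediation
#'   scenario.
#' @param n_hist_subjects number of per-subject histogram files to write
#'   (0 to skip).
#' @param n_voxels voxels sampled per histogram subject.
#' @return invisibly, a list with the file paths written and the truth.
#' @export
simulate_study_files <- function(dir, config = muscle_mediation_scenario(),
                                 n_hist_subjects = 0, n_voxels = 1e5) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(dir, mode = 2) != 0) {
    stop("output directory is not writable: ", dir, call. = FALSE)
  }
  gen <- generate_cohort(config)
  cohort_path <- file.path(dir, "cohort.csv")
  write_cohort(gen$cohort, cohort_path, seed = config$seed)

  hist_paths <- character(0)
  if (n_hist_subjects > 0) {
    hdir <- file.path(dir, "histograms")
    dir.create(hdir, showWarnings = FALSE)
    p <- ntra_reference_params("baseline")
    for (k in seq_len(n_hist_subjects)) {
      v <- sample_voxels(p, n_voxels, seed = config$seed + k)
      hp <- file.path(hdir, sprintf("%s.csv", gen$cohort$id[k]))
      write_histogram(bin_voxels(v), hp, seed = config$seed + k)
      hist_paths <- c(hist_paths, hp)
    }
  }

  planted <- NTRA_PARAM_NAMES[config$a != 0]
  manifest <- list(
    package = "ntramed",
    version = as.character(utils::packageVersion("ntramed")),
    seed = config$seed,
    config_hash = config_hash(config),
    n_subjects = config$n_subjects,
    planted_mediators = planted,
    truth = gen$truth
  )
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(cohort = cohort_path, histograms = hist_paths,
                 manifest = manifest_path, truth = gen$truth))
}

#' Run the mediation pipeline on a cohort file and write report tables
#'
#' Reads and validates the cohort, runs [ntra_mediation()], and writes
#' `table2_total_effect.csv` ... `table6_bootstrap.csv` plus a structured
#' `summary.json` to `out_dir`.
#'
#' @param cohort_path path to a cohort CSV (schema of [cohort_columns()]).
#' @param out_dir output directory.
#' @param ... passed to [ntra_mediation()] (`alpha`, `B`, `ci_level`,
#'   `seed`, ...).
#' @return invisibly, the `"ntra_mediation"` object.
#' @export
mediate_files <- function(cohort_path, out_dir, ...) {
  cohort <- read_cohort(cohort_path)
  report <- ntra_mediation(cohort, ...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- mediation_tables(report)
  hdr <- file_header(report$settings$seed,
                     extra = sprintf("config=%s", config_hash(
                       report$settings)))
  for (nm in names(tabs)) {
    write_csv_with_header(tabs[[nm]], file.path(out_dir,
                                                paste0(nm, ".csv")), hdr)
  }
  summary_obj <- list(
    settings = report$settings,
    selected_mediators = report$selected,
    step1_significant = report$step1$significant,
    attenuation = report$attenuation,
    bootstrap_significant = if (!is.null(report$bootstrap)) {
      lapply(report$bootstrap, function(b)
        stats::setNames(as.list(b$effects$significant), b$effects$effect))
    }
  )
  jsonlite::write_json(summary_obj, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
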