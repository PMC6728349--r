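# Readers/writers, covariate preparation and bioclim derivation.
# All tables are comma-delimited UTF-8 with header rows; missing values are
# empty fields.

#' Convert stop-group counts to presence/absence replicates
#'
#' Each replicate is scored 1 when its summed count is positive, matching
#' the reduction of raw BBS 10-stop count summaries to binary replicate
#' detections.
#'
#' @param counts Non-negative numeric vector (or matrix) of counts.
#' @return Integer vector (or matrix) of 0/1 presence indicators.
#' @export
counts_to_presence <- function(counts) {
  if (any(is.na(counts)) || any(counts < 0)) {
    abort("counts must be non-negative and non-missing")
  }
  out <- ifelse(counts > 0, 1L, 0L)
  if (!is.null(dim(counts))) dim(out) <- dim(counts)
  out
}

#' Derive the five bioclim covariates from a monthly climate series
#'
#' For each site-year, summarizes the 12-month June-to-May window preceding
#' the survey into: mean temperature (mean over months of `(tmin + tmax)/2`),
#' mean diurnal temperature range (mean of `tmax - tmin`), mean temperature
#' of the wettest quarter, annual precipitation (sum of monthly totals), and
#' precipitation of the warmest quarter. Quarters are the 12 consecutive
#' (wrapping) 3-month windows within the June-May year; the wettest quarter
#' maximizes total precipitation and the warmest quarter maximizes mean
#' temperature.
#'
#' @param mc Data frame with columns `month` (1-12, position within the
#'   June-May window), `prec` (mm, non-negative), `tmin`, `tmax` (deg C), and
#'   optionally `site_id` and `year` grouping columns.
#' @return A tibble with one row per group and columns `mean_temp`,
#'   `diurnal_range`, `wet_quarter_temp`, `annual_prec`, `warm_quarter_prec`.
#' @export
monthly_to_bioclim <- function(mc) {
  mc <- as_tibble(mc)
  need <- c("month", "prec", "tmin", "tmax")
  miss <- setdiff(need, names(mc))
  if (length(miss)) abort(paste("missing climate columns:",
                                paste(miss, collapse = ", ")))
  if (any(mc$prec < 0)) abort("precipitation must be non-negative")
  grp <- intersect(c("site_id", "year"), names(mc))
  one <- function(d) {
    if (nrow(d) != 12 || !setequal(d$month, 1:12)) {
      abort("each site-year needs exactly months 1..12")
    }
    d <- d[order(d$month), ]
    tmean <- (d$tmin + d$tmax) / 2
    # wrapping 3-month windows
    widx <- lapply(1:12, function(s) ((s - 1):(s + 1)) %% 12 + 1)
    wprec <- vapply(widx, function(ii) sum(d$prec[ii]), 0)
    wtemp <- vapply(widx, function(ii) mean(tmean[ii]), 0)
    wet <- which.max(wprec)
    warm <- which.max(wtemp)
    tibble(
      mean_temp = mean(tmean),
      diurnal_range = mean(d$tmax - d$tmin),
      wet_quarter_temp = wtemp[wet],
      annual_prec = sum(d$prec),
      warm_quarter_prec = wprec[warm]
    )
  }
  if (length(grp) == 0) return(one(mc))
  mc %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) %>%
    dplyr::group_modify(~ one(.x)) %>%
    dplyr::ungroup()
}

#' Standardize covariate columns, storing the transform
#'
#' Scales each covariate column to mean 0 and standard deviation 1 over the
#' observed rows. The returned transform can be re-applied (e.g. to a
#' prediction grid) so new data are standardized with the training
#' constants, never re-estimated.
#'
#' @param x Data frame of covariates.
#' @param vars Character vector of columns to standardize (default: all
#'   numeric columns except `site_id`/`year`/`cell_id`).
#' @param transform Optional stored transform (tibble with `var`, `center`,
#'   `scale`) to apply instead of estimating new constants.
#' @return A list with `data` (tibble with standardized columns) and
#'   `transform` (tibble of the constants used).
#' @export
standardize_covariates <- function(x, vars = NULL, transform = NULL) {
  x <- as_tibble(x)
  if (is.null(vars)) {
    vars <- setdiff(names(x)[vapply(x, is.numeric, TRUE)],
                    c("site_id", "year", "cell_id"))
  }
  if (is.null(transform)) {
    ctr <- vapply(vars, function(v) mean(x[[v]], na.rm = TRUE), 0)
    scl <- vapply(vars, function(v) sd(x[[v]], na.rm = TRUE), 0)
    zero <- vars[scl == 0 | !is.finite(scl)]
    if (length(zero)) {
      abort(paste("zero-variance covariate column:", zero[1]))
    }
    transform <- tibble(var = vars, center = unname(ctr),
                        scale = unname(scl))
  }
  for (i in seq_len(nrow(transform))) {
    v <- transform$var[i]
    if (!v %in% names(x)) abort(paste("missing covariate column:", v))
    x[[v]] <- (x[[v]] - transform$center[i]) / transform$scale[i]
  }
  list(data = x, transform = transform)
}

# invert a stored standardization (internal, used in tests via :::)
unstandardize_covariates <- function(x, transform) {
  x <- as_tibble(x)
  for (i in seq_len(nrow(transform))) {
    v <- transform$var[i]
    x[[v]] <- x[[v]] * transform$scale[i] + transform$center[i]
  }
  x
}

# ---------------------------------------------------------------------------
# delimited-text readers with row-numbered validation, and paired writers
# ---------------------------------------------------------------------------

read_checked <- function(path, required, validator = NULL) {
  if (!file.exists(path)) abort(paste("file not found:", path))
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(required, names(x))
  if (length(miss)) {
    abort(sprintf("%s: missing columns: %s", path,
                  paste(miss, collapse = ", ")))
  }
  if (!is.null(validator)) validator(x, path)
  x
}

#' Read site coordinates from CSV
#'
#' Columns: `site_id`, `latitude`, `longitude` (decimal degrees).
#' @param path CSV file path.
#' @return A validated tibble.
#' @export
read_sites <- function(path) {
  x <- read_checked(path, c("site_id", "latitude", "longitude"))
  bad <- which(!is.finite(x$latitude) | abs(x$latitude) > 90)
  if (length(bad)) abort(sprintf("%s row %d: invalid latitude", path, bad[1]))
  bad <- which(!is.finite(x$longitude) | abs(x$longitude) > 180)
  if (length(bad)) abort(sprintf("%s row %d: invalid longitude", path, bad[1]))
  bad <- which(duplicated(x$site_id))
  if (length(bad)) abort(sprintf("%s row %d: duplicate site_id", path, bad[1]))
  x
}

#' Read long-format detection records from CSV
#'
#' Columns: `site_id`, `year`, `replicate`, `detected`, `wind`,
#' `first_year`, `protocol`, `observer_id`.
#' @param path CSV file path.
#' @return A validated tibble.
#' @export
read_detections <- function(path) {
  x <- read_checked(path, c("site_id", "year", "replicate", "detected",
                            "wind", "first_year", "protocol", "observer_id"))
  bad <- which(!x$detected %in% c(0, 1))
  if (length(bad)) {
    abort(sprintf("%s row %d: `detected` must be 0/1", path, bad[1]))
  }
  bad <- which(!x$first_year %in% c(0, 1) | !x$protocol %in% c(0, 1))
  if (length(bad)) {
    abort(sprintf("%s row %d: flags must be 0/1", path, bad[1]))
  }
  bad <- which(x$wind < 0 | !is.finite(x$wind))
  if (length(bad)) {
    abort(sprintf("%s row %d: invalid wind score", path, bad[1]))
  }
  x
}

#' Read site-year covariates from CSV
#'
#' Columns: `site_id`, `year` plus the five climate variables.
#' @param path CSV file path.
#' @return A validated tibble.
#' @export
read_covariates <- function(path) {
  x <- read_checked(path, c("site_id", "year"))
  vars <- setdiff(names(x), c("site_id", "year"))
  if (length(vars) != 5) {
    abort(sprintf("%s: expected 5 covariate columns, found %d", path,
                  length(vars)))
  }
  for (v in vars) {
    bad <- which(!is.finite(x[[v]]))
    if (length(bad)) {
      abort(sprintf("%s row %d: non-finite value in %s", path, bad[1], v))
    }
  }
  x
}

#' Write a table atomically as CSV
#'
#' Writes to a temporary file in the destination directory and renames it
#' into place, so a failed run never leaves a partial output.
#'
#' @param x Data frame.
#' @param path Destination path.
#' @return The path, invisibly.
#' @export
write_table_atomic <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".csv.tmp")
  readr::write_csv(as_tibble(x), tmp, progress = FALSE)
  file.rename(tmp, path)
  invisible(path)
}
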