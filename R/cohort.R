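# Cohort table: one row per measurement, metadata columns followed by the
# 41 zone columns in canonical order. Tomographic indices are optional.

.etd_meta_cols <- c("subject_id", "eye", "group", "measurement_index")
.etd_tomo_cols <- c("bad_d", "abcd_a", "abcd_b", "abcd_c")

#' Assemble a cohort table of zonal ET measurements
#'
#' A cohort is a plain data frame (class `etd_cohort`) with one row per
#' measurement: columns `subject_id`, `eye` (OD/OS), `group`,
#' `measurement_index`, optional tomographic indices (`bad_d`, `abcd_a`,
#' `abcd_b`, `abcd_c`) and one numeric column per zone alias. An attribute
#' `canonical` records whether all rows are expressed in the right-eye
#' convention.
#'
#' @param df data frame with the columns above.
#' @param grid an [etd_grid()].
#' @param canonical logical; whether the zonal values are already
#'   laterality-normalized.
#' @return An `etd_cohort` data frame.
#' @export
etd_cohort <- function(df, grid = etd_grid(), canonical = FALSE) {
  aliases <- zone_aliases(grid)
  miss_meta <- setdiff(.etd_meta_cols, names(df))
  if (length(miss_meta))
    stop("missing required columns: ", paste(miss_meta, collapse = ", "))
  miss_zone <- setdiff(aliases, names(df))
  if (length(miss_zone))
    stop("missing zone columns: ", paste(miss_zone, collapse = ", "))
  extra <- setdiff(names(df), c(.etd_meta_cols, .etd_tomo_cols, aliases))
  if (length(extra))
    stop("unknown columns (not metadata, tomography or zone aliases): ",
         paste(extra, collapse = ", "))
  if (!all(df$eye %in% c("OD", "OS")))
    stop("malformed laterality: `eye` must be 'OD' or 'OS'")
  for (a in aliases)
    if (!is.numeric(df[[a]]))
      stop("non-numeric zone value in column ", a)
  key <- paste(df$subject_id, df$eye, df$measurement_index)
  if (anyDuplicated(key))
    stop("duplicate (subject_id, eye, measurement_index) rows: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  vals <- as.matrix(df[aliases])
  if (anyNA(vals) || any(!is.finite(vals)) || any(vals <= 0))
    stop("zonal ET values must be finite and strictly positive")
  if (any(vals < 20 | vals > 120))
    warning("zonal ET values outside the plausible 20-120 um range")
  present_tomo <- intersect(.etd_tomo_cols, names(df))
  df <- df[c(.etd_meta_cols, present_tomo, aliases)]
  df$measurement_index <- as.integer(df$measurement_index)
  structure(df, class = c("etd_cohort", "data.frame"),
            canonical = isTRUE(canonical))
}

#' Canonicalize every measurement in a cohort
#'
#' Mirrors all OS rows onto the right-eye convention (see
#' [canonicalize_map()]); OD rows are unchanged.
#'
#' @param cohort an [etd_cohort()].
#' @param grid an [etd_grid()].
#' @return The cohort with `canonical` attribute `TRUE`.
#' @export
canonicalize_cohort <- function(cohort, grid = etd_grid()) {
  stopifnot(inherits(cohort, "etd_cohort"))
  if (isTRUE(attr(cohort, "canonical"))) {
    warning("cohort is already canonical; returning it unchanged")
    return(cohort)
  }
  aliases <- zone_aliases(grid)
  os <- which(cohort$eye == "OS")
  for (i in os) {
    v <- unlist(cohort[i, aliases])
    cohort[i, aliases] <- as.list(mirror_values(v, grid))
  }
  attr(cohort, "canonical") <- TRUE
  cohort
}

#' Matrix of zonal values from a cohort
#'
#' @param cohort an [etd_cohort()].
#' @param grid an [etd_grid()].
#' @return Numeric matrix, one row per measurement, 41 zone columns in
#'   canonical order.
#' @export
cohort_values <- function(cohort, grid = etd_grid()) {
  as.matrix(cohort[zone_aliases(grid)])
}

# one id per eye (subject x laterality)
eye_key <- function(cohort) paste(cohort$subject_id, cohort$eye, sep = ":")

#' Read / write a cohort CSV
#'
#' The CSV dialect is UTF-8, comma-separated, "." decimal separator, with a
#' mandatory header: `subject_id, eye, group, measurement_index`, optional
#' `bad_d`, `abcd_a`, `abcd_b`, `abcd_c`, and one column per zone alias.
#' Zonal values are written with full double precision so that a
#' write-then-read round trip is exact.
#'
#' @param path CSV file path.
#' @param grid an [etd_grid()].
#' @param canonicalize mirror OS rows onto the right-eye convention after
#'   reading (default `TRUE`).
#' @return `read_cohort_csv()` returns an [etd_cohort()];
#'   `write_cohort_csv()` returns `path` invisibly.
#' @export
read_cohort_csv <- function(path, grid = etd_grid(), canonicalize = TRUE) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  cohort <- etd_cohort(df, grid, canonical = FALSE)
  if (canonicalize) cohort <- canonicalize_cohort(cohort, grid)
  cohort
}

#' @param cohort an [etd_cohort()].
#' @rdname read_cohort_csv
#' @export
write_cohort_csv <- function(cohort, path, grid = etd_grid()) {
  stopifnot(inherits(cohort, "etd_cohort"))
  out <- as.data.frame(cohort)
  num <- vapply(out, is.double, logical(1L))
  for (j in which(num))
    out[[j]] <- formatC(out[[j]], digits = 17, format = "g")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.etd_cohort <- function(x, ...) {
  ne <- length(unique(eye_key(x)))
  cat(sprintf(
    "ET cohort: %d measurements, %d eyes, groups: %s%s\n", nrow(x), ne,
    paste(names(table(x$group[!duplicated(eye_key(x))])), collapse = ", "),
    if (isTRUE(attr(x, "canonical"))) " (canonical)" else ""))
  invisible(x)
}
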