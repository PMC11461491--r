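# Nonparametric group comparisons, rank correlation and repeatability.

#' Mann-Whitney group comparisons with Bonferroni correction
#'
#' Runs a two-sided Mann-Whitney U test for each requested pair of groups
#' and flags significance at the Bonferroni-adjusted per-comparison level
#' `0.05 / family_size`. The exact null distribution is enumerated when both
#' samples have at most eight observations and there are no ties; otherwise
#' the tie-corrected normal approximation with continuity correction is
#' used (the behaviour of [stats::wilcox.test()]).
#'
#' @param values_by_group named list of numeric vectors, one per group.
#' @param comparisons list of length-2 character vectors naming the group
#'   pairs to compare; default: every pair.
#' @param family_size number of comparisons in the Bonferroni family
#'   (default: `length(comparisons)`).
#' @param alpha family-wise error rate (default 0.05).
#' @param exact_max largest per-group size for which the exact tie-free
#'   enumeration is used (default 8).
#' @return An object of class `etd_group_tests`: data frame of comparisons
#'   with `W`, `p`, `significant` and `method`, plus `alpha_adjusted`.
#' @export
compare_groups <- function(values_by_group, comparisons = NULL,
                           family_size = NULL, alpha = 0.05,
                           exact_max = 8L) {
  stopifnot(is.list(values_by_group), !is.null(names(values_by_group)))
  if (any(lengths(values_by_group) == 0L))
    stop("every group must contain at least one value")
  if (is.null(comparisons)) {
    comparisons <- utils::combn(names(values_by_group), 2L, simplify = FALSE)
  }
  if (is.null(family_size)) family_size <- length(comparisons)
  alpha_adj <- alpha / family_size

  rows <- lapply(comparisons, function(pair) {
    x <- values_by_group[[pair[1L]]]
    y <- values_by_group[[pair[2L]]]
    exact <- length(x) <= exact_max && length(y) <= exact_max &&
      !anyDuplicated(c(x, y))
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = "two.sided",
                         exact = exact, correct = TRUE))
    data.frame(group1 = pair[1L], group2 = pair[2L],
               n1 = length(x), n2 = length(y),
               W = unname(wt$statistic), p = wt$p.value,
               significant = wt$p.value < alpha_adj,
               method = if (exact) "exact" else "normal-approx",
               stringsAsFactors = FALSE)
  })
  structure(list(table = do.call(rbind, rows),
                 alpha = alpha, family_size = family_size,
                 alpha_adjusted = alpha_adj),
            class = "etd_group_tests")
}

#' @export
print.etd_group_tests <- function(x, ...) {
  cat(sprintf(
    "Mann-Whitney U comparisons (two-sided), alpha %.4g / %d = %.4g:\n",
    x$alpha, x$family_size, x$alpha_adjusted))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Spearman rank correlation
#'
#' Rank correlation with midrank handling of ties, as used to relate the
#' screening parameters to tomographic severity indices. The p-value uses
#' the asymptotic t approximation (appropriate with ties).
#'
#' @param x,y paired numeric vectors, `n >= 3`, finite.
#' @return Named list: `rho`, `p`, `n`.
#' @export
spearman_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("at least 3 complete pairs are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y: rank correlation undefined")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Intra-subject repeatability of a per-measurement quantity
#'
#' Computes, for each eye, the sample standard deviation of a quantity
#' across its repeated measurements, and summarizes the per-eye SDs by
#' their cohort median and interquartile range. Eyes with fewer than two
#' repeats are excluded with a warning.
#'
#' @param values numeric vector, one value per measurement.
#' @param eyes eye identifier per measurement (same length as `values`).
#' @param quantile_type quantile convention for the IQR: 7 (default,
#'   linear interpolation) or 6 (SPSS-like).
#' @return An object of class `etd_repeatability`: per-eye `sd` (named),
#'   `median_sd`, `iqr_sd`, `n_eyes`, `n_excluded`.
#' @export
repeatability <- function(values, eyes, quantile_type = 7L) {
  stopifnot(length(values) == length(eyes), quantile_type %in% c(6L, 7L))
  by_eye <- split(values, eyes)
  n_rep <- lengths(by_eye)
  if (any(n_rep < 2L)) {
    warning(sum(n_rep < 2L),
            " eye(s) with fewer than 2 measurements excluded")
    by_eye <- by_eye[n_rep >= 2L]
  }
  if (!length(by_eye)) stop("no eye has 2 or more measurements")
  sds <- vapply(by_eye, stats::sd, numeric(1L))
  qs <- stats::quantile(sds, c(0.25, 0.75), type = quantile_type,
                        names = FALSE)
  structure(list(sd = sds, median_sd = stats::median(sds),
                 iqr_sd = qs[2L] - qs[1L], n_eyes = length(sds),
                 n_excluded = sum(n_rep < 2L)),
            class = "etd_repeatability")
}

#' @export
print.etd_repeatability <- function(x, ...) {
  cat(sprintf(
    "Intra-subject SD over repeats: median %.3f um (IQR %.3f), %d eyes\n",
    x$median_sd, x$iqr_sd, x$n_eyes))
  invisible(x)
}
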