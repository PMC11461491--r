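# Empirical ROC analysis with DeLong confidence intervals, screening
# cut-off derivation, and per-zone zone selection.

# fast trapezoid AUC on raw scores (higher = disease); equals the
# Mann-Whitney concordance probability with ties counted 1/2
auc_trapezoid <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels)
  n0 <- length(labels) - n1
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong variance of the AUC via placement values
delong_ci <- function(scores, labels, conf = 0.95) {
  x <- scores[labels == 1L]  # diseased
  y <- scores[labels == 0L]  # healthy
  m <- length(x); n <- length(y)
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  v10 <- vapply(x, function(xi) mean(psi(xi, y)), numeric(1L))
  v01 <- vapply(y, function(yj) mean(psi(x, yj)), numeric(1L))
  auc <- mean(v10)
  va <- if (m > 1L) stats::var(v10) else 0
  vb <- if (n > 1L) stats::var(v01) else 0
  se <- sqrt(va / m + vb / n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- c(auc - z * se, auc + z * se)
  list(auc = auc, se = se, ci = pmin(pmax(ci, 0), 1))
}

#' Empirical ROC analysis of a screening score
#'
#' Builds the empirical ROC curve of a per-eye score against binary disease
#' labels, under the classification rule "score at or above the threshold is
#' positive" (after negating the score when `direction = "lower_is_disease"`).
#' The AUC is the trapezoid area, identical to the Mann-Whitney concordance
#' probability with ties counted one half; its 95% confidence interval uses
#' the DeLong variance estimate (clipped to \[0, 1\]).
#'
#' @param scores numeric per-eye score values.
#' @param labels disease indicator: logical, 0/1, or a factor/character with
#'   `positive` naming the disease level.
#' @param direction `"higher_is_disease"` (default) or `"lower_is_disease"`.
#' @param positive the label value counted as diseased when `labels` is not
#'   logical/0-1.
#' @param conf confidence level for the AUC interval.
#' @return An object of class `etd_roc`: thresholds (one per distinct score,
#'   plus `-Inf`), sensitivity and specificity at each, `auc`, `ci95`, `se`,
#'   `direction`, class counts, and the (direction-adjusted) scores/labels.
#' @export
roc_analysis <- function(scores, labels,
                         direction = c("higher_is_disease",
                                       "lower_is_disease"),
                         positive = NULL, conf = 0.95) {
  direction <- match.arg(direction)
  if (is.logical(labels)) {
    lab <- as.integer(labels)
  } else if (is.numeric(labels) && all(labels %in% c(0, 1))) {
    lab <- as.integer(labels)
  } else {
    if (is.null(positive))
      stop("`positive` must name the disease label for non-binary `labels`")
    lab <- as.integer(labels == positive)
  }
  stopifnot(length(scores) == length(lab), all(is.finite(scores)))
  if (length(unique(lab)) < 2L)
    stop("both classes (diseased and healthy) must be present")
  s <- if (direction == "lower_is_disease") -scores else scores
  if (length(unique(s)) == 1L)
    warning("all scores identical: degenerate ROC curve, AUC = 0.5")

  u <- sort(unique(s))
  thr <- c(-Inf, u)
  sens <- vapply(thr, function(t) mean(s[lab == 1L] >= t), numeric(1L))
  spec <- vapply(thr, function(t) mean(s[lab == 0L] < t), numeric(1L))
  dl <- delong_ci(s, lab, conf)
  structure(
    list(thresholds = thr, sensitivity = sens, specificity = spec,
         auc = dl$auc, ci95 = dl$ci, se = dl$se, direction = direction,
         n_disease = sum(lab), n_healthy = sum(lab == 0L),
         scores = s, labels = lab),
    class = "etd_roc"
  )
}

#' @export
print.etd_roc <- function(x, ...) {
  cat(sprintf(
    "ROC: AUC %.3f (95%% CI %.3f-%.3f), %d diseased vs %d healthy (%s)\n",
    x$auc, x$ci95[1L], x$ci95[2L], x$n_disease, x$n_healthy, x$direction))
  invisible(x)
}

#' @export
plot.etd_roc <- function(x, add = FALSE, col = "black", ...) {
  fpr <- 1 - x$specificity
  o <- order(fpr, x$sensitivity)
  if (!add) {
    graphics::plot(fpr[o], x$sensitivity[o], type = "s", col = col,
                   xlab = "1 - specificity", ylab = "sensitivity",
                   xlim = c(0, 1), ylim = c(0, 1), ...)
    graphics::abline(0, 1, lty = 3, col = "grey50")
  } else {
    graphics::lines(fpr[o], x$sensitivity[o], type = "s", col = col, ...)
  }
  invisible(x)
}

#' Derive screening and confirmation cut-offs from an ROC curve
#'
#' Two operating points are selected on the ROC curve of a
#' higher-is-disease score: a lower (screening) cut-off, the largest
#' candidate threshold whose sensitivity still reaches `sens_target` (thus
#' maximizing specificity subject to the sensitivity floor), and an upper
#' (confirmation) cut-off, the smallest candidate whose specificity reaches
#' `spec_target`. Candidate thresholds are midpoints between adjacent
#' distinct observed scores, extended half a median score-gap beyond the
#' extremes; classification is "score >= cut-off is positive". An
#' unattainable target yields an `NA` cut-off with `attained = FALSE`.
#'
#' @param roc an [roc_analysis()] result (any direction; cut-offs apply to
#'   the direction-adjusted score).
#' @param sens_target sensitivity floor for the lower cut-off (default 0.95).
#' @param spec_target specificity floor for the upper cut-off (default 0.95).
#' @return An object of class `etd_cutoffs`: `lower`, `upper`, achieved
#'   `sens`/`spec` at each, attainment flags and the targets.
#' @export
derive_cutoffs <- function(roc, sens_target = 0.95, spec_target = 0.95) {
  stopifnot(inherits(roc, "etd_roc"),
            sens_target >= 0, sens_target <= 1,
            spec_target >= 0, spec_target <= 1)
  s <- roc$scores
  lab <- roc$labels
  u <- sort(unique(s))
  gap <- if (length(u) > 1L) stats::median(diff(u)) else 1
  cand <- c(u[1L] - gap / 2,
            if (length(u) > 1L) (u[-length(u)] + u[-1L]) / 2,
            u[length(u)] + gap / 2)
  sens <- vapply(cand, function(t) mean(s[lab == 1L] >= t), numeric(1L))
  spec <- vapply(cand, function(t) mean(s[lab == 0L] < t), numeric(1L))

  pick <- function(idx, which_end) {
    if (!length(idx)) return(NA_integer_)
    if (which_end == "max") max(idx) else min(idx)
  }
  i_lo <- pick(which(sens >= sens_target), "max")
  i_hi <- pick(which(spec >= spec_target), "min")
  structure(
    list(lower = if (is.na(i_lo)) NA_real_ else cand[i_lo],
         upper = if (is.na(i_hi)) NA_real_ else cand[i_hi],
         sens_at_lower = if (is.na(i_lo)) NA_real_ else sens[i_lo],
         spec_at_lower = if (is.na(i_lo)) NA_real_ else spec[i_lo],
         sens_at_upper = if (is.na(i_hi)) NA_real_ else sens[i_hi],
         spec_at_upper = if (is.na(i_hi)) NA_real_ else spec[i_hi],
         attained = c(lower = !is.na(i_lo), upper = !is.na(i_hi)),
         sens_target = sens_target, spec_target = spec_target),
    class = "etd_cutoffs"
  )
}

#' @export
print.etd_cutoffs <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "unattainable" else sprintf("%.3f", v)
  cat(sprintf(
    "Cut-offs (score >= cut-off is positive):\n  lower %s (sens %s, spec %s; sens target %.2f)\n  upper %s (sens %s, spec %s; spec target %.2f)\n",
    fmt(x$lower), fmt(x$sens_at_lower), fmt(x$spec_at_lower), x$sens_target,
    fmt(x$upper), fmt(x$sens_at_upper), fmt(x$spec_at_upper), x$spec_target))
  invisible(x)
}

#' Sensitivity and specificity of a fixed cut-off
#'
#' Applies the rule "score >= cutoff is positive" to new scores.
#'
#' @param scores numeric scores (higher-is-disease orientation).
#' @param labels binary disease labels (1/TRUE = diseased).
#' @param cutoff threshold value.
#' @return Named vector `sens`, `spec` (either may be `NaN` when the
#'   corresponding class is absent).
#' @export
apply_cutoff <- function(scores, labels, cutoff) {
  lab <- as.integer(labels)
  c(sens = mean(scores[lab == 1L] >= cutoff),
    spec = mean(scores[lab == 0L] < cutoff))
}

#' Select the most discriminative zones by per-zone ROC
#'
#' Runs a per-zone ROC (higher inter-zonal difference = disease) over the
#' 41 zones of the supplied difference maps and returns the `k` zones with
#' the largest AUC. Exact AUC ties (routine on well-separated cohorts,
#' where every cone-affected zone discriminates perfectly) are broken by
#' the larger between-group median difference, then by canonical zone
#' order; a tie at the selection boundary is recorded in the result.
#'
#' @param diffmaps matrix of per-eye difference maps (rows = eyes, 41 zone
#'   columns), e.g. from [cohort_diffmaps()].
#' @param labels binary disease labels, one per row.
#' @param k number of zones to select (default 2).
#' @return An object of class `etd_zone_selection`: `zones` (the selected
#'   aliases in decreasing-AUC order), `auc` (named vector of all 41 zone
#'   AUCs), `k`, and `ties` (whether the selection boundary was tied).
#' @export
select_top_zones <- function(diffmaps, labels, k = 2L) {
  stopifnot(is.matrix(diffmaps), ncol(diffmaps) == 41L,
            nrow(diffmaps) == length(labels))
  if (k > ncol(diffmaps)) stop("k cannot exceed the number of zones (41)")
  lab <- as.integer(labels)
  auc <- apply(diffmaps, 2L, auc_trapezoid, labels = lab)
  effect <- apply(diffmaps, 2L, function(v)
    stats::median(v[lab == 1L]) - stats::median(v[lab == 0L]))
  ord <- order(-auc, -effect)   # stable: full ties keep canonical order
  sel <- colnames(diffmaps)[ord[seq_len(k)]]
  boundary_tied <- k < length(auc) &&
    isTRUE(all.equal(auc[ord[k]], auc[ord[k + 1L]]))
  structure(list(zones = sel, auc = auc, effect = effect,
                 k = as.integer(k), ties = boundary_tied),
            class = "etd_zone_selection")
}

#' @export
print.etd_zone_selection <- function(x, ...) {
  cat(sprintf("Top-%d zones by per-zone AUC: %s\n", x$k,
              paste(sprintf("%s (%.3f)", x$zones, x$auc[x$zones]),
                    collapse = ", ")))
  if (x$ties) cat("  note: AUC tie at the selection boundary,",
                  "broken by canonical zone order\n")
  invisible(x)
}
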