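# Two-stage screening analysis: parameter development (zone selection,
# ROC, cut-off derivation, tomography correlation) and parameter
# validation (group comparisons, fixed-cut-off performance, repeatability).

.etd_baselines <- c("mean_et", "sd_et", "min_et", "max_et",
                    "inferior_superior")
.etd_baseline_direction <- c(
  inferior_temporal = "higher_is_disease", global_mean = "higher_is_disease",
  mean_et = "lower_is_disease", sd_et = "higher_is_disease",
  min_et = "lower_is_disease", max_et = "higher_is_disease",
  inferior_superior = "lower_is_disease")

# per-eye aggregation: mean over repeats of each numeric column
aggregate_by_eye <- function(params) {
  key <- paste(params$subject_id, params$eye, sep = ":")
  num <- names(params)[vapply(params, is.numeric, logical(1L))]
  num <- setdiff(num, "measurement_index")
  agg <- stats::aggregate(params[num], by = list(eye_id = key), FUN = mean)
  first <- !duplicated(key)
  meta <- data.frame(eye_id = key[first],
                     subject_id = params$subject_id[first],
                     eye = params$eye[first], group = params$group[first],
                     stringsAsFactors = FALSE)
  merge(meta, agg, by = "eye_id")
}

#' Develop the inter-zonal ET screening parameter on a two-group cohort
#'
#' Runs the parameter-development stage: per-measurement difference maps
#' are averaged per eye; a per-zone ROC (higher inter-zonal difference =
#' disease) identifies the two most discriminative zones; the localized
#' parameter (mean difference of those zones) and the global parameter
#' (mean over all 41 zones) are evaluated by ROC with DeLong confidence
#' intervals; screening (sensitivity floor) and confirmation (specificity
#' floor) cut-offs are derived for each; and the parameters are correlated
#' (Spearman) with any tomographic indices present. Per-zone ROC of the raw
#' zonal ET (lower = disease) is computed alongside as a comparator.
#'
#' @param cohort a canonical [etd_cohort()] with exactly two groups.
#' @param disease_group,control_group group labels; defaults `"keratoconus"`
#'   and `"healthy"`.
#' @param k number of zones selected for the localized parameter.
#' @param sens_target,spec_target cut-off floors (default 0.95 each).
#' @param grid an [etd_grid()].
#' @return An object of class `etd_development` with components
#'   `selection` (per-zone AUCs and selected zones), `zonal_et_auc`,
#'   `roc` / `cutoffs` (per parameter), `spearman`, `params` (per-eye
#'   parameter table) and the settings used.
#' @export
run_development <- function(cohort, disease_group = "keratoconus",
                            control_group = "healthy", k = 2L,
                            sens_target = 0.95, spec_target = 0.95,
                            grid = etd_grid()) {
  stopifnot(inherits(cohort, "etd_cohort"))
  if (!isTRUE(attr(cohort, "canonical")))
    stop("cohort must be canonicalized first (see canonicalize_cohort)")
  present <- unique(cohort$group)
  if (!all(c(disease_group, control_group) %in% present))
    stop("cohort must contain groups '", disease_group, "' and '",
         control_group, "'")

  dm <- cohort_diffmaps(cohort, grid)
  key <- paste(cohort$subject_id, cohort$eye, sep = ":")
  dm_eye <- rowsum(dm, key) / as.vector(rowsum(rep(1, nrow(dm)), key))
  first <- !duplicated(key)
  eye_group <- cohort$group[first][match(rownames(dm_eye), key[first])]
  labels <- as.integer(eye_group == disease_group)

  selection <- select_top_zones(dm_eye, labels, k = k)

  vals <- cohort_values(cohort, grid)
  vals_eye <- rowsum(vals, key) / as.vector(rowsum(rep(1, nrow(vals)), key))
  zonal_et_auc <- apply(-vals_eye, 2L, auc_trapezoid, labels = labels)

  params_all <- screening_parameters(cohort, grid, zones = selection$zones)
  params <- aggregate_by_eye(params_all)
  params <- params[match(rownames(dm_eye), params$eye_id), ]

  roc <- list(
    localized = roc_analysis(params$inferior_temporal, labels),
    global = roc_analysis(params$global_mean, labels))
  cutoffs <- lapply(roc, derive_cutoffs, sens_target = sens_target,
                    spec_target = spec_target)

  baseline_roc <- lapply(.etd_baselines, function(b)
    roc_analysis(params[[b]], labels,
                 direction = .etd_baseline_direction[[b]]))
  names(baseline_roc) <- .etd_baselines

  tomo <- intersect(.etd_tomo_cols, names(params))
  spearman <- NULL
  if (length(tomo)) {
    spearman <- do.call(rbind, lapply(
      c(localized = "inferior_temporal", global = "global_mean"),
      function(p) do.call(rbind, lapply(tomo, function(ti) {
        sc <- spearman_cor(params[[p]], params[[ti]])
        data.frame(parameter = p, index = ti, rho = sc$rho, p = sc$p,
                   n = sc$n, stringsAsFactors = FALSE)
      }))))
    rownames(spearman) <- NULL
  } else {
    warning("no tomographic indices present: correlation section skipped")
  }

  structure(
    list(selection = selection, zonal_et_auc = zonal_et_auc,
         roc = roc, baseline_roc = baseline_roc, cutoffs = cutoffs,
         spearman = spearman, params = params,
         settings = list(disease_group = disease_group,
                         control_group = control_group, k = k,
                         sens_target = sens_target,
                         spec_target = spec_target,
                         n_disease = sum(labels),
                         n_control = sum(labels == 0L))),
    class = "etd_development")
}

#' @export
print.etd_development <- function(x, ...) {
  cat("Parameter development (", x$settings$n_disease, " ",
      x$settings$disease_group, " vs ", x$settings$n_control, " ",
      x$settings$control_group, " eyes)\n", sep = "")
  print(x$selection)
  cat(sprintf("  localized parameter (zones %s): AUC %.3f (%.3f-%.3f)\n",
              paste(x$selection$zones, collapse = "+"),
              x$roc$localized$auc, x$roc$localized$ci95[1L],
              x$roc$localized$ci95[2L]))
  cat(sprintf("  global parameter: AUC %.3f (%.3f-%.3f)\n",
              x$roc$global$auc, x$roc$global$ci95[1L],
              x$roc$global$ci95[2L]))
  for (p in names(x$cutoffs)) {
    co <- x$cutoffs[[p]]
    cat(sprintf(
      "  %s cut-offs: lower %.2f um (sens %.1f%%, spec %.1f%%), upper %.2f um (sens %.1f%%, spec %.1f%%)\n",
      p, co$lower, 100 * co$sens_at_lower, 100 * co$spec_at_lower,
      co$upper, 100 * co$sens_at_upper, 100 * co$spec_at_upper))
  }
  invisible(x)
}

#' @export
summary.etd_development <- function(object, ...) {
  print(object)
  auc <- sort(object$selection$auc, decreasing = TRUE)
  cat("  top per-zone difference AUCs:\n")
  print(round(utils::head(auc, 5L), 3))
  cat(sprintf("  best zonal-ET AUC (comparator): %.3f\n",
              max(object$zonal_et_auc)))
  if (!is.null(object$spearman)) {
    cat("  Spearman correlation with tomographic indices:\n")
    print(object$spearman, row.names = FALSE, digits = 3)
  }
  invisible(object)
}

#' Apply a developed screening rule to new eyes
#'
#' Computes the developed parameter for each eye of a new cohort and
#' classifies it against one of the derived cut-offs (score >= cut-off is
#' positive).
#'
#' @param object an [run_development()] fit.
#' @param cohort a canonical [etd_cohort()] of eyes to score.
#' @param parameter `"localized"` or `"global"`.
#' @param cutoff `"lower"` (screening) or `"upper"` (confirmation).
#' @param grid an [etd_grid()].
#' @param ... unused.
#' @return Data frame with one row per eye: `subject_id`, `eye`, `group`,
#'   `score` (um, mean over repeats) and `positive`.
#' @export
predict.etd_development <- function(object, cohort,
                                    parameter = c("localized", "global"),
                                    cutoff = c("lower", "upper"),
                                    grid = etd_grid(), ...) {
  parameter <- match.arg(parameter)
  cutoff <- match.arg(cutoff)
  params <- aggregate_by_eye(
    screening_parameters(cohort, grid, zones = object$selection$zones))
  score <- if (parameter == "localized") params$inferior_temporal else
    params$global_mean
  thr <- object$cutoffs[[parameter]][[cutoff]]
  if (is.na(thr)) stop("requested cut-off was unattainable in development")
  data.frame(params[c("subject_id", "eye", "group")], score = score,
             positive = score >= thr, row.names = NULL)
}

#' Validate screening parameters on a three-group cohort
#'
#' Runs the parameter-validation stage on a cohort of tomographically
#' significant keratoconus eyes, tomographically normal fellow eyes, and
#' healthy controls with repeated measurements: parameters are averaged
#' over each eye's repeats; the four prespecified Mann-Whitney comparisons
#' (each keratoconus group vs healthy, for both parameters) are tested at
#' the Bonferroni-adjusted level 0.05/4 = 0.0125; sensitivity and
#' specificity of the fixed development cut-offs are evaluated; ROC AUCs
#' with confidence intervals are computed for both parameters and the five
#' baseline comparators against healthy controls; and intra-subject
#' repeatability of the zonal ET and of the parameters is summarized.
#'
#' @param cohort a canonical [etd_cohort()] with the three `groups`.
#' @param cutoffs cut-offs to hold fixed: an [run_development()] fit, or a
#'   list like `list(localized = c(lower, upper), global = c(lower,
#'   upper))`.
#' @param groups named character vector mapping roles `significant`,
#'   `fellow`, `healthy` to the cohort's group labels.
#' @param zones zone pair defining the localized parameter (default
#'   cI/cTI; when `cutoffs` is a development fit, its selected zones are
#'   used).
#' @param quantile_type IQR convention (7 default, 6 for SPSS-like).
#' @param grid an [etd_grid()].
#' @return An object of class `etd_validation`: `medians` (per group, with
#'   IQR), `tests` (Mann-Whitney with adjusted alpha), `fixed_cutoff`
#'   performance table, `roc` (AUC+CI per parameter and comparison),
#'   `repeatability`, `params` (per-eye table) and settings.
#' @export
run_validation <- function(cohort, cutoffs = NULL,
                           groups = c(significant = "KC_significant",
                                      fellow = "KC_fellow_normal",
                                      healthy = "healthy"),
                           zones = c("cI", "cTI"), quantile_type = 7L,
                           grid = etd_grid()) {
  stopifnot(inherits(cohort, "etd_cohort"))
  if (!isTRUE(attr(cohort, "canonical")))
    stop("cohort must be canonicalized first (see canonicalize_cohort)")
  if (!all(groups %in% unique(cohort$group)))
    stop("cohort must contain the three groups: ",
         paste(groups, collapse = ", "))
  if (inherits(cutoffs, "etd_development")) {
    zones <- cutoffs$selection$zones
    cutoffs <- list(
      localized = c(lower = cutoffs$cutoffs$localized$lower,
                    upper = cutoffs$cutoffs$localized$upper),
      global = c(lower = cutoffs$cutoffs$global$lower,
                 upper = cutoffs$cutoffs$global$upper))
  }

  params_all <- screening_parameters(cohort, grid, zones = zones)
  params <- aggregate_by_eye(params_all)

  # parameters of the per-eye mean map, for comparison with the
  # mean-of-parameters convention actually used
  key <- paste(cohort$subject_id, cohort$eye, sep = ":")
  vals <- cohort_values(cohort, grid)
  mean_maps <- rowsum(vals, key) / as.vector(rowsum(rep(1, nrow(vals)), key))
  dm_mean <- t(apply(mean_maps, 1L, interzonal_differences, grid = grid))
  alt_localized <- inferior_temporal_parameter(dm_mean, zones)
  order_gap <- max(abs(
    alt_localized[match(params$eye_id, rownames(mean_maps))] -
      params$inferior_temporal))

  pargs <- c(localized = "inferior_temporal", global = "global_mean")
  by_group <- function(col) split(params[[col]], params$group)

  qfun <- function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = quantile_type,
                         names = FALSE)
    c(median = q[2L], iqr = q[3L] - q[1L])
  }
  medians <- do.call(rbind, lapply(names(pargs), function(p) {
    vg <- by_group(pargs[[p]])
    do.call(rbind, lapply(names(vg), function(g) {
      s <- qfun(vg[[g]])
      data.frame(parameter = p, group = g, n = length(vg[[g]]),
                 median = s[["median"]], iqr = s[["iqr"]],
                 stringsAsFactors = FALSE)
    }))
  }))

  comparisons <- list(c(groups[["significant"]], groups[["healthy"]]),
                      c(groups[["fellow"]], groups[["healthy"]]))
  tests <- lapply(pargs, function(col)
    compare_groups(by_group(col), comparisons, family_size = 4L))

  fixed <- NULL
  if (!is.null(cutoffs)) {
    fixed <- do.call(rbind, lapply(names(pargs), function(p) {
      do.call(rbind, lapply(c("lower", "upper"), function(co) {
        thr <- cutoffs[[p]][[co]]
        if (is.na(thr)) return(NULL)
        sc <- params[[pargs[[p]]]]
        do.call(rbind, lapply(c("significant", "fellow"), function(role) {
          sel <- params$group %in% c(groups[[role]], groups[["healthy"]])
          perf <- apply_cutoff(sc[sel],
                               params$group[sel] == groups[[role]], thr)
          data.frame(parameter = p, cutoff = co, value = thr,
                     versus = role, sens = perf[["sens"]],
                     spec = perf[["spec"]], stringsAsFactors = FALSE)
        }))
      }))
    }))
    rownames(fixed) <- NULL
  }

  roc_tab <- list()
  for (role in c("significant", "fellow")) {
    sel <- params$group %in% c(groups[[role]], groups[["healthy"]])
    lab <- as.integer(params$group[sel] == groups[[role]])
    for (p in c(pargs, stats::setNames(.etd_baselines, .etd_baselines))) {
      nm <- names(pargs)[match(p, pargs)]
      if (is.na(nm)) nm <- p
      dir <- if (p %in% names(.etd_baseline_direction))
        .etd_baseline_direction[[p]] else "higher_is_disease"
      roc_tab[[paste(nm, role, sep = "_vs_")]] <-
        roc_analysis(params[[p]][sel], lab, direction = dir)
    }
  }

  rep_res <- NULL
  n_rep <- table(key)
  if (all(n_rep >= 2L)) {
    zonal_vals <- as.vector(vals)
    zonal_eyes <- paste(rep(key, times = 41L),
                        rep(colnames(vals), each = nrow(vals)))
    rep_zonal <- repeatability(zonal_vals, zonal_eyes,
                               quantile_type = quantile_type)
    rep_param <- lapply(pargs, function(col) {
      lapply(split(seq_len(nrow(params_all)), params_all$group), function(i)
        repeatability(params_all[[col]][i],
                      paste(params_all$subject_id, params_all$eye)[i],
                      quantile_type = quantile_type))
    })
    rep_res <- list(zonal = rep_zonal, parameters = rep_param)
  } else {
    warning("eyes with a single measurement present: ",
            "repeatability section omitted")
  }

  structure(
    list(medians = medians, tests = tests, fixed_cutoff = fixed,
         roc = roc_tab, repeatability = rep_res, params = params,
         settings = list(groups = groups, zones = zones,
                         quantile_type = quantile_type,
                         aggregation_gap = order_gap)),
    class = "etd_validation")
}

#' @export
print.etd_validation <- function(x, ...) {
  cat("Parameter validation\n")
  cat("  group medians (IQR), um:\n")
  print(x$medians, row.names = FALSE, digits = 3)
  for (p in names(x$tests)) {
    cat("  ", p, ": ", sep = "")
    tt <- x$tests[[p]]$table
    cat(paste(sprintf("%s vs %s p=%.4g%s", tt$group1, tt$group2, tt$p,
                      ifelse(tt$significant, "*", "")), collapse = "; "),
        sprintf(" (alpha %.4f)\n", x$tests[[p]]$alpha_adjusted))
  }
  if (!is.null(x$fixed_cutoff)) {
    cat("  fixed cut-off performance:\n")
    print(x$fixed_cutoff, row.names = FALSE, digits = 3)
  }
  cat("  AUCs (95% CI):\n")
  for (nm in names(x$roc)) {
    r <- x$roc[[nm]]
    cat(sprintf("    %-28s %.3f (%.3f-%.3f)\n", nm, r$auc,
                r$ci95[1L], r$ci95[2L]))
  }
  if (!is.null(x$repeatability)) {
    cat(sprintf("  repeatability: median zonal-ET intra-subject SD %.2f um\n",
                x$repeatability$zonal$median_sd))
  }
  invisible(x)
}

#' @export
summary.etd_validation <- function(object, ...) {
  print(object)
  if (!is.null(object$repeatability)) {
    cat("  parameter repeatability (median intra-subject SD, um):\n")
    for (p in names(object$repeatability$parameters))
      for (g in names(object$repeatability$parameters[[p]]))
        cat(sprintf("    %-10s %-18s %.3f\n", p, g,
                    object$repeatability$parameters[[p]][[g]]$median_sd))
  }
  cat(sprintf(
    "  max |mean-of-parameters - parameter-of-mean-map| = %.3g um\n",
    object$settings$aggregation_gap))
  invisible(object)
}
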