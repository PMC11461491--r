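# The inter-zonal ET difference statistic and the screening parameters
# derived from it, plus the conventional baseline ET parameters.

# neighbour indices per zone, in canonical zone order
neighbour_index <- function(grid) {
  aliases <- zone_aliases(grid)
  lapply(grid$adjacency[aliases], match, table = aliases)
}

#' Inter-zonal ET differences of a map
#'
#' For every zone `a` with neighbours `x_1, ..., x_n`, computes the mean
#' absolute difference between the zone's ET and its neighbours' ET:
#' `sum(|ET(a) - ET(x_i)|) / n`. A keratoconic cone — localized thinning
#' with annular thickening around it — produces large values in the zones at
#' the cone, while the smooth profile of a healthy cornea produces uniformly
#' small ones.
#'
#' @param map an [etd_map()] (must be canonical), or a named numeric vector
#'   of 41 zonal values already in the right-eye convention.
#' @param grid the [etd_grid()] defining adjacency.
#' @return Named numeric vector of 41 non-negative differences (um), in
#'   canonical zone order, with class `etd_diffmap`.
#' @export
interzonal_differences <- function(map, grid = etd_grid()) {
  if (inherits(map, "etd_map")) {
    if (!map$canonical)
      stop("map must be canonicalized first (see canonicalize_map)")
    v <- map$values
  } else {
    v <- map
  }
  aliases <- zone_aliases(grid)
  stopifnot(is.numeric(v), setequal(names(v), aliases))
  v <- v[aliases]
  nb <- neighbour_index(grid)
  d <- vapply(seq_along(v),
              function(i) mean(abs(v[i] - v[nb[[i]]])), numeric(1L))
  names(d) <- aliases
  class(d) <- "etd_diffmap"
  d
}

#' @export
print.etd_diffmap <- function(x, ...) {
  cat("Inter-zonal ET difference map (um):\n")
  print(round(unclass(x), 3))
  invisible(x)
}

#' Per-measurement difference maps of a cohort
#'
#' @param cohort a canonical [etd_cohort()].
#' @param grid an [etd_grid()].
#' @return Numeric matrix (measurements x 41 zones) of inter-zonal ET
#'   differences.
#' @export
cohort_diffmaps <- function(cohort, grid = etd_grid()) {
  stopifnot(inherits(cohort, "etd_cohort"))
  if (!isTRUE(attr(cohort, "canonical")))
    stop("cohort must be canonicalized first (see canonicalize_cohort)")
  vals <- cohort_values(cohort, grid)
  nb <- neighbour_index(grid)
  out <- matrix(0, nrow(vals), 41L, dimnames = list(NULL, colnames(vals)))
  for (j in seq_len(41L)) {
    nbj <- vals[, nb[[j]], drop = FALSE]
    out[, j] <- rowMeans(abs(nbj - vals[, j]))
  }
  out
}

#' Inferior-temporal screening parameter
#'
#' The average of the inter-zonal ET differences of the paracentral inferior
#' (`cI`) and paracentral inferior-temporal (`cTI`) zones — the two zones
#' where keratoconic thinning concentrates. `zones` allows the same
#' construction over a different zone pair, e.g. the pair returned by
#' [select_top_zones()].
#'
#' @param d an `etd_diffmap` (or any named vector covering `zones`), or a
#'   matrix of difference maps with zone columns.
#' @param zones zone aliases to average (default `c("cI", "cTI")`).
#' @return Parameter value in um (vector of values for matrix input).
#' @export
inferior_temporal_parameter <- function(d, zones = c("cI", "cTI")) {
  if (is.matrix(d)) {
    stopifnot(all(zones %in% colnames(d)))
    return(rowMeans(d[, zones, drop = FALSE]))
  }
  stopifnot(all(zones %in% names(d)))
  mean(unclass(d)[zones])
}

#' Global screening parameter
#'
#' The mean inter-zonal ET difference over all 41 zones.
#'
#' @param d an `etd_diffmap`, or a matrix of difference maps (zone columns).
#' @return Parameter value in um (vector for matrix input).
#' @export
global_parameter <- function(d) {
  if (is.matrix(d)) return(rowMeans(d))
  stopifnot(length(d) == 41L)
  mean(unclass(d))
}

#' Baseline ET comparator parameters
#'
#' The conventional whole-map ET summaries against which the inter-zonal
#' difference parameters are compared: mean, standard deviation, minimum and
#' maximum of the 41 zonal values, and the inferior-superior asymmetry
#' (mean of all I-octant zones minus mean of all S-octant zones; the rings
#' entering the asymmetry are configurable).
#'
#' @param map an [etd_map()] (canonical) or named numeric vector of 41
#'   zonal values.
#' @param grid an [etd_grid()].
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @param is_rings rings whose I/S sectors enter the inferior-superior
#'   asymmetry (default all annuli, 1:5).
#' @return Named numeric vector: `mean_et`, `sd_et`, `min_et`, `max_et`,
#'   `inferior_superior` (all um).
#' @export
baseline_parameters <- function(map, grid = etd_grid(),
                                sd_type = c("sample", "population"),
                                is_rings = 1:5) {
  sd_type <- match.arg(sd_type)
  if (inherits(map, "etd_map")) {
    if (!map$canonical)
      stop("map must be canonicalized first (see canonicalize_map)")
    v <- map$values
  } else {
    v <- map
  }
  aliases <- zone_aliases(grid)
  stopifnot(setequal(names(v), aliases))
  v <- v[aliases]
  s <- stats::sd(v)
  if (sd_type == "population") s <- s * sqrt(40 / 41)
  z <- grid$zones
  i_zones <- z$alias[!is.na(z$sector) & z$sector == "I" & z$ring %in% is_rings]
  s_zones <- z$alias[!is.na(z$sector) & z$sector == "S" & z$ring %in% is_rings]
  c(mean_et = mean(v), sd_et = s, min_et = min(v), max_et = max(v),
    inferior_superior = mean(v[i_zones]) - mean(v[s_zones]))
}

#' Screening and baseline parameters for every measurement of a cohort
#'
#' @param cohort a canonical [etd_cohort()].
#' @param grid an [etd_grid()].
#' @param zones zone pair for the localized parameter (default cI/cTI).
#' @inheritParams baseline_parameters
#' @return Data frame: metadata columns of the cohort plus
#'   `inferior_temporal`, `global_mean`, `mean_et`, `sd_et`, `min_et`,
#'   `max_et`, `inferior_superior`.
#' @export
screening_parameters <- function(cohort, grid = etd_grid(),
                                 zones = c("cI", "cTI"),
                                 sd_type = c("sample", "population"),
                                 is_rings = 1:5) {
  sd_type <- match.arg(sd_type)
  dm <- cohort_diffmaps(cohort, grid)
  vals <- cohort_values(cohort, grid)
  base <- t(apply(vals, 1L, baseline_parameters, grid = grid,
                  sd_type = sd_type, is_rings = is_rings))
  meta <- as.data.frame(cohort)[intersect(
    c(.etd_meta_cols, .etd_tomo_cols), names(cohort))]
  cbind(meta,
        data.frame(inferior_temporal = inferior_temporal_parameter(dm, zones),
                   global_mean = global_parameter(dm)),
        as.data.frame(base))
}
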