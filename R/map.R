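#' Construct a single-eye zonal ET map
#'
#' Bundles one epithelial thickness measurement of one eye: 41 zonal mean ET
#' values in micrometres, the eye's laterality, and measurement metadata.
#' Values are validated to be finite and strictly positive; values outside
#' the plausible 20--120 um range raise a warning but are kept.
#'
#' @param values named numeric vector of length 41; names must be the zone
#'   aliases of `grid` (any order).
#' @param eye `"OD"` (right) or `"OS"` (left).
#' @param subject_id opaque subject identifier.
#' @param measurement_index positive integer, identifies repeats.
#' @param canonical logical; `TRUE` only for maps already expressed in the
#'   right-eye convention (see [canonicalize_map()]). New measurements should
#'   be created with the default `FALSE`.
#' @param grid an [etd_grid()].
#' @return An object of class `etd_map`.
#' @export
etd_map <- function(values, eye = c("OD", "OS"), subject_id = "s1",
                    measurement_index = 1L, canonical = FALSE,
                    grid = etd_grid()) {
  eye <- match.arg(eye)
  aliases <- zone_aliases(grid)
  if (is.null(names(values)) || !setequal(names(values), aliases))
    stop("`values` must be named with the 41 zone aliases of the grid")
  values <- values[aliases]
  if (length(values) != 41L || anyNA(values) || any(!is.finite(values)))
    stop("exactly 41 finite zonal ET values are required")
  if (any(values <= 0))
    stop("zonal ET values must be strictly positive (um)")
  if (any(values < 20 | values > 120))
    warning("zonal ET values outside the plausible 20-120 um range")
  stopifnot(measurement_index >= 1L)
  structure(
    list(subject_id = as.character(subject_id), eye = eye,
         measurement_index = as.integer(measurement_index),
         values = values, canonical = isTRUE(canonical)),
    class = "etd_map"
  )
}

#' @export
print.etd_map <- function(x, ...) {
  cat(sprintf("Zonal ET map: subject %s, %s, measurement %d%s\n",
              x$subject_id, x$eye, x$measurement_index,
              if (x$canonical) " (canonical)" else ""))
  cat(sprintf("  ET range %.1f-%.1f um, mean %.1f um\n",
              min(x$values), max(x$values), mean(x$values)))
  invisible(x)
}

# Mirror a named zonal-value vector across the vertical meridian
# (N <-> T, SN <-> TS, NI <-> IT); an involution on the 41 aliases.
mirror_values <- function(values, grid = etd_grid()) {
  z <- grid$zones
  mirrored_alias <- ifelse(z$ring == 0L, "C",
                           .etd_zone_alias(z$ring, .etd_sector_mirror[z$sector]))
  out <- values[z$alias]
  names(out) <- mirrored_alias
  out[z$alias]
}

#' Canonicalize a map to the right-eye convention
#'
#' Sector labels name anatomical directions (nasal, temporal, ...), which
#' mirror between right and left eyes. Canonicalization expresses every map
#' in the right-eye (OD) convention so that "temporal" means the same
#' direction cohort-wide: OD maps are returned unchanged, OS maps are
#' mirrored across the vertical meridian (N and T octants swap, SN with TS,
#' NI with IT; S and I are fixed).
#'
#' @param map an [etd_map()].
#' @param grid the [etd_grid()] the map lives on.
#' @return The canonical `etd_map` (with `canonical = TRUE`). Canonicalizing
#'   an already-canonical map is a no-op with a warning.
#' @export
canonicalize_map <- function(map, grid = etd_grid()) {
  stopifnot(inherits(map, "etd_map"))
  if (map$canonical) {
    warning("map is already canonical; returning it unchanged")
    return(map)
  }
  if (map$eye == "OS") map$values <- mirror_values(map$values, grid)
  map$canonical <- TRUE
  map
}
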