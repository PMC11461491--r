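# 41-zone polar grid of the 7-mm epithelial thickness map:
# 1 central disc (ring 0) + 5 annuli (rings 1..5) x 8 octant sectors.

# Octant sector codes clockwise from superior (right-eye anatomical
# convention: N at 0 deg, S at 90, T at 180, I at 270).
.etd_sectors <- c("S", "SN", "N", "NI", "I", "IT", "T", "TS")
.etd_sector_angle <- c(N = 0, SN = 45, S = 90, TS = 135, T = 180,
                       IT = 225, I = 270, NI = 315)

# Display alias for each sector; the inferior-temporal octant is written
# "TI" so the paracentral zone gets its clinical label "cTI".
.etd_sector_alias <- c(N = "N", SN = "SN", S = "S", TS = "TS", T = "T",
                       IT = "TI", I = "I", NI = "NI")

# Mirror across the vertical meridian (nasal <-> temporal), used to map a
# left eye (OS) onto the right-eye convention.
.etd_sector_mirror <- c(N = "T", SN = "TS", S = "S", TS = "SN", T = "N",
                        IT = "NI", I = "I", NI = "IT")

.etd_ring_prefix <- c("C", "c", "r2", "r3", "r4", "r5")

.etd_zone_alias <- function(ring, sector) {
  ifelse(ring == 0L, "C",
         paste0(.etd_ring_prefix[ring + 1L], .etd_sector_alias[sector]))
}

#' Build the 41-zone epithelial thickness map grid
#'
#' Constructs the canonical topology of the 7-mm zonal epithelial thickness
#' (ET) map: one central disc plus five concentric annuli, each split into
#' eight octant sectors (superior S, superior-nasal SN, nasal N,
#' nasal-inferior NI, inferior I, inferior-temporal IT, temporal T,
#' temporal-superior TS), for 41 zones in total. Sector directions follow the
#' right-eye (OD) anatomical convention; left-eye maps are mirrored onto it
#' by [canonicalize_map()].
#'
#' Two zones are adjacent when they share a boundary arc or radial segment:
#' same ring and neighbouring sectors, neighbouring rings and the same
#' sector, and the central disc with all eight ring-1 sectors. With
#' `adjacency = "edge+corner"` zones that only touch at a corner
#' (neighbouring ring and neighbouring sector) are also counted.
#'
#' @param adjacency neighbourhood rule, `"edge"` (default) or
#'   `"edge+corner"`.
#' @param ring_radii outer radii (mm) of the six radial bins, strictly
#'   increasing and ending at the map radius. Radii affect only rendering and
#'   the synthetic generator's radial gradients, never the inter-zonal
#'   statistics.
#' @return An object of class `etd_grid`: a list with `zones` (data frame of
#'   `alias`, `ring`, `sector`, `angle`, `radius`), `adjacency` (named list
#'   of neighbour aliases), `outer_diameter` (mm) and `adjacency_rule`.
#' @examples
#' g <- etd_grid()
#' nrow(g$zones)          # 41
#' g$adjacency[["cI"]]    # neighbours of the paracentral inferior zone
#' @export
etd_grid <- function(adjacency = c("edge", "edge+corner"),
                     ring_radii = 3.5 * (1:6) / 6) {
  adjacency <- match.arg(adjacency)
  stopifnot(length(ring_radii) == 6L, all(diff(ring_radii) > 0),
            all(ring_radii > 0))

  ring <- c(0L, rep(1:5, each = 8L))
  sector <- c(NA_character_, rep(.etd_sectors, 5L))
  alias <- .etd_zone_alias(ring, sector)
  inner <- c(0, ring_radii[-6L])[ring + 1L]
  outer <- ring_radii[ring + 1L]
  zones <- data.frame(
    alias = alias, ring = ring, sector = sector,
    angle = ifelse(ring == 0L, NA_real_, .etd_sector_angle[sector]),
    radius = (inner + outer) / 2,
    stringsAsFactors = FALSE
  )
  zones$radius[1L] <- 0

  nb <- vector("list", 41L)
  names(nb) <- alias
  sec_idx <- match(sector, .etd_sectors)
  for (i in seq_len(41L)) {
    r <- ring[i]
    if (r == 0L) {
      nb[[i]] <- alias[ring == 1L]
      next
    }
    s <- sec_idx[i]
    s_prev <- .etd_sectors[(s - 2L) %% 8L + 1L]
    s_next <- .etd_sectors[s %% 8L + 1L]
    keep <- (ring == r & sector %in% c(s_prev, s_next)) |
      (abs(ring - r) == 1L & ring > 0L & sector == sector[i]) |
      (r == 1L & ring == 0L)
    if (adjacency == "edge+corner")
      keep <- keep | (abs(ring - r) == 1L & ring > 0L &
                        sector %in% c(s_prev, s_next))
    nb[[i]] <- alias[keep]
  }

  structure(
    list(zones = zones, adjacency = nb,
         outer_diameter = 2 * ring_radii[6L], adjacency_rule = adjacency),
    class = "etd_grid"
  )
}

#' @export
print.etd_grid <- function(x, ...) {
  deg <- lengths(x$adjacency)
  cat(sprintf(
    "Zonal ET map grid: %d zones (%0.1f mm map), adjacency '%s'\n",
    nrow(x$zones), x$outer_diameter, x$adjacency_rule))
  cat(sprintf("  neighbour counts: min %d, max %d (central %d)\n",
              min(deg), max(deg), deg[["C"]]))
  invisible(x)
}

#' Zone aliases in canonical order
#'
#' Canonical zone order is ring-major (central first), sectors clockwise
#' from S within each ring. This is the column order of cohort tables.
#'
#' @param grid an [etd_grid()].
#' @return Character vector of 41 aliases.
#' @export
zone_aliases <- function(grid = etd_grid()) grid$zones$alias

#' Export a grid as JSON
#'
#' Serialises zones and adjacency lists, e.g. for documentation or external
#' rendering.
#'
#' @param grid an [etd_grid()].
#' @param path file to write; `NULL` returns the JSON string.
#' @return The JSON string, invisibly when written to file.
#' @export
grid_to_json <- function(grid, path = NULL) {
  obj <- list(outer_diameter = grid$outer_diameter,
              adjacency_rule = grid$adjacency_rule,
              zones = grid$zones,
              adjacency = grid$adjacency)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
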