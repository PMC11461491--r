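# Colour-coded polar rendering of zonal maps (ET or inter-zonal
# differences) with optional highlighting of the parameter zones.

#' Render a zonal map
#'
#' Draws the 41-zone polar layout with zones colour-coded by value, e.g. a
#' zonal ET map or an inter-zonal difference map, optionally highlighting
#' the zones entering the localized parameter with a white border.
#'
#' @param values named numeric vector over the 41 zone aliases (an
#'   `etd_diffmap` works directly).
#' @param grid an [etd_grid()].
#' @param highlight zone aliases to outline in white (default none).
#' @param palette colour ramp function, as from
#'   [grDevices::colorRampPalette()].
#' @param labels print each zone's value (default TRUE).
#' @param main plot title.
#' @return Invisibly, `values`.
#' @export
plot_zone_map <- function(values, grid = etd_grid(), highlight = NULL,
                          palette = grDevices::colorRampPalette(
                            c("#2166AC", "#F7F7F7", "#B2182B")),
                          labels = TRUE, main = "") {
  values <- unclass(values)
  z <- grid$zones
  stopifnot(setequal(names(values), z$alias))
  values <- values[z$alias]
  rng <- range(values)
  cols <- if (diff(rng) == 0) rep(palette(3L)[2L], 41L) else
    palette(64L)[pmax(1L, ceiling(64 * (values - rng[1L]) / diff(rng)))]

  radii <- c(0, grid$outer_diameter / 2 * (1:6) / 6)
  r_scale <- grid$outer_diameter / 2
  op <- graphics::par(mar = c(1, 1, 2, 1), pty = "s")
  on.exit(graphics::par(op))
  graphics::plot(NA, xlim = c(-r_scale, r_scale), ylim = c(-r_scale, r_scale),
                 axes = FALSE, xlab = "", ylab = "", asp = 1, main = main)
  wedge <- function(r0, r1, a0, a1, col, border) {
    aa <- seq(a0, a1, length.out = 24L) * pi / 180
    graphics::polygon(c(r0 * cos(aa), r1 * cos(rev(aa))),
                      c(r0 * sin(aa), r1 * sin(rev(aa))),
                      col = col, border = border, lwd = 1.5)
  }
  for (i in seq_len(41L)) {
    hl <- !is.null(highlight) && z$alias[i] %in% highlight
    border <- if (hl) "white" else "grey30"
    if (z$ring[i] == 0L) {
      aa <- seq(0, 2 * pi, length.out = 90L)
      graphics::polygon(radii[2L] * cos(aa), radii[2L] * sin(aa),
                        col = cols[i], border = border, lwd = 1.5)
    } else {
      wedge(radii[z$ring[i] + 1L], radii[z$ring[i] + 2L],
            z$angle[i] - 22.5, z$angle[i] + 22.5, cols[i], border)
    }
    if (labels) {
      r_mid <- if (z$ring[i] == 0L) 0 else
        (radii[z$ring[i] + 1L] + radii[z$ring[i] + 2L]) / 2
      a_mid <- if (z$ring[i] == 0L) 0 else z$angle[i] * pi / 180
      graphics::text(r_mid * cos(a_mid), r_mid * sin(a_mid),
                     sprintf("%.1f", values[i]), cex = 0.55)
    }
  }
  invisible(values)
}
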