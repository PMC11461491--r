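# Synthetic zonal ET cohort generator: smooth healthy surfaces with the
# physiological superior/temporal thinning gradient, keratoconic cones
# (localized paracentral inferior-temporal depression with an annular
# thickening around it), per-eye biological offsets, measurement noise and
# coupled tomographic indices.

#' Generator configuration for synthetic zonal ET cohorts
#'
#' Defaults encode the morphology and noise level of real epithelial maps:
#' a 53-um baseline; the healthy cornea's superior and temporal thinning
#' gradients (5.9 and 1.3 um between opposite sectors at the 3-mm radius);
#' zonal measurement noise of SD 0.6 um; a raised-cosine cone between the
#' paracentral inferior and inferior-temporal zones whose depth (um) is the
#' severity scale, with a surrounding annular thickening; and group severity
#' distributions (uniform ranges, um of cone depth) with healthy fixed at
#' zero so tomographically normal controls reduce exactly to the healthy
#' model.
#'
#' @param baseline_et mean central ET (um).
#' @param superior_amplitude,temporal_amplitude ET deficit (um) of the
#'   superior vs inferior and temporal vs nasal sectors at
#'   `gradient_ref_mm` radius.
#' @param gradient_ref_mm radius (mm) at which the gradient amplitudes are
#'   quoted.
#' @param gradient_onset_mm radius (mm) at which the gradient starts: the
#'   centre and paracentral ring of healthy maps are flat (the
#'   superior/temporal thinning is eyelid-related and peripheral), so the
#'   gradient rises quadratically from this onset to the reference radius.
#' @param noise_sd SD (um) of independent zonal measurement noise.
#' @param eye_offset_sd SD (um) of the per-eye baseline offset (biological
#'   between-eye variation).
#' @param cone_angle angular position (deg) of the cone centre; the default
#'   247.5 lies on the boundary between the I (270) and IT (225) octants,
#'   so the cone loads the cI and cTI zones equally.
#' @param cone_ring radial position of the cone centre, in ring units
#'   (default 1, the paracentral ring).
#' @param cone_angular_hw,cone_radial_hw half-widths of the raised-cosine
#'   depression (deg, ring units).
#' @param annulus_gain thickening amplitude as a fraction of cone depth.
#' @param annulus_offset,annulus_radial_hw radial distance (rings) from the
#'   cone centre at which the annular thickening peaks, and its half-width.
#' @param annulus_angular_hw angular half-width (deg) of the thickening.
#' @param severity named list of `c(min, max)` uniform cone-depth ranges
#'   (um) per group.
#' @param n named integer vector of eyes per group.
#' @param repeats measurements per eye.
#' @return A list of class `etd_generator_config`.
#' @export
etd_generator_config <- function(baseline_et = 53,
                                 superior_amplitude = 5.9,
                                 temporal_amplitude = 1.3,
                                 gradient_ref_mm = 3,
                                 gradient_onset_mm = 1.2,
                                 noise_sd = 0.6,
                                 eye_offset_sd = 1.5,
                                 cone_angle = 247.5,
                                 cone_ring = 1,
                                 cone_angular_hw = 55,
                                 cone_radial_hw = 1.3,
                                 annulus_gain = 0.35,
                                 annulus_offset = 2,
                                 annulus_radial_hw = 1.2,
                                 annulus_angular_hw = 110,
                                 severity = list(
                                   KC_significant = c(4, 16),
                                   KC_fellow_normal = c(0.5, 3),
                                   healthy = c(0, 0)),
                                 n = c(KC_significant = 21,
                                       KC_fellow_normal = 21,
                                       healthy = 21),
                                 repeats = 3L) {
  stopifnot(noise_sd >= 0, eye_offset_sd >= 0, repeats >= 1,
            all(unlist(severity) >= 0),
            all(vapply(severity, length, 1L) == 2L))
  structure(as.list(environment()), class = "etd_generator_config")
}

# radial profile of the physiological gradient: flat across the centre
# and paracentral ring (healthy central ET is uniform), rising smoothly
# toward the periphery, equal to 1 at the reference radius
gradient_profile <- function(r, onset, ref) {
  pmin(1, (pmax(r - onset, 0) / (ref - onset))^2)
}

# deterministic smooth healthy surface (no noise, no offset)
healthy_surface <- function(cfg, grid = etd_grid()) {
  z <- grid$zones
  theta <- ifelse(is.na(z$angle), 0, z$angle) * pi / 180
  scale_r <- gradient_profile(z$radius, cfg$gradient_onset_mm,
                              cfg$gradient_ref_mm)
  scale_r[z$ring == 0L] <- 0
  v <- cfg$baseline_et -
    (cfg$superior_amplitude / 2) * scale_r * sin(theta) -
    (cfg$temporal_amplitude / 2) * scale_r * (-cos(theta))
  names(v) <- z$alias
  v
}

# raised cosine bump: 0.5*(1+cos(pi*d/hw)) for d < hw, else 0
raised_cos <- function(d, hw) ifelse(abs(d) < hw,
                                     0.5 * (1 + cos(pi * d / hw)), 0)

# shortest angular distance in degrees
ang_dist <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

# per-unit-severity cone contribution (negative = thinning) per zone:
# central depression plus annular elevation. The central disc has no
# angular coordinate; it receives the angular average of each kernel.
cone_profile <- function(cfg, grid = etd_grid(),
                         cone_angle = cfg$cone_angle) {
  z <- grid$zones
  dth <- ang_dist(ifelse(is.na(z$angle), 0, z$angle), cone_angle)
  ang_dep <- raised_cos(dth, cfg$cone_angular_hw)
  ang_ann <- raised_cos(dth, cfg$annulus_angular_hw)
  ang_dep[z$ring == 0L] <- cfg$cone_angular_hw / 360
  ang_ann[z$ring == 0L] <- cfg$annulus_angular_hw / 360
  dr <- abs(z$ring - cfg$cone_ring)
  dep <- raised_cos(dr, cfg$cone_radial_hw) * ang_dep
  ann <- raised_cos(dr - cfg$annulus_offset, cfg$annulus_radial_hw) * ang_ann
  v <- -dep + cfg$annulus_gain * ann
  names(v) <- z$alias
  v
}

# one measurement's zonal values given eye offset and severity
synth_values <- function(cfg, grid, severity = 0, eye_offset = 0,
                         cone_angle = cfg$cone_angle) {
  v <- healthy_surface(cfg, grid) + eye_offset +
    severity * cone_profile(cfg, grid, cone_angle) +
    stats::rnorm(41L, 0, cfg$noise_sd)
  pmax(v, 20)
}

#' Simulate a healthy zonal ET map
#'
#' Draws one measurement of a healthy eye: the smooth gradient surface plus
#' a per-eye baseline offset and independent zonal noise, in canonical OD
#' orientation.
#'
#' @param cfg an [etd_generator_config()].
#' @param seed optional integer seed (uses the global RNG stream when
#'   `NULL`).
#' @param subject_id,measurement_index map metadata.
#' @param grid an [etd_grid()].
#' @return A canonical [etd_map()].
#' @export
synth_healthy_map <- function(cfg = etd_generator_config(), seed = NULL,
                              subject_id = "sim", measurement_index = 1L,
                              grid = etd_grid()) {
  synth_keratoconus_map(cfg, severity = 0, seed = seed,
                        subject_id = subject_id,
                        measurement_index = measurement_index, grid = grid)
}

#' Simulate a keratoconic zonal ET map
#'
#' A healthy map plus a severity-scaled cone: a raised-cosine depression
#' centred (by default) on the cI/cTI boundary and a surrounding annular
#' elevation. `severity` is the cone depth in um; severity 0 reproduces
#' [synth_healthy_map()] exactly under the same seed.
#'
#' @inheritParams synth_healthy_map
#' @param severity cone depth (um), `>= 0`.
#' @param cone_angle angular cone position (deg), defaulting to the
#'   config's.
#' @return A canonical [etd_map()].
#' @export
synth_keratoconus_map <- function(cfg = etd_generator_config(), severity,
                                  seed = NULL, subject_id = "sim",
                                  measurement_index = 1L,
                                  cone_angle = cfg$cone_angle,
                                  grid = etd_grid()) {
  stopifnot(severity >= 0)
  if (!is.null(seed)) set.seed(seed)
  eye_offset <- stats::rnorm(1L, 0, cfg$eye_offset_sd)
  v <- synth_values(cfg, grid, severity, eye_offset, cone_angle)
  etd_map(v, eye = "OD", subject_id = subject_id,
          measurement_index = measurement_index, canonical = TRUE,
          grid = grid)
}

# severity-coupled tomographic indices honouring the group definitions:
# BAD-D >= 2.69 for tomographically significant eyes, < 1.65 (with Belin
# ABCD stage 0) for fellow and healthy eyes.
tomography_indices <- function(group, severity) {
  if (group == "KC_significant" || group == "keratoconus") {
    bad_d <- 2.69 + 0.5 * severity + abs(stats::rnorm(1L, 0, 0.8))
    abcd <- pmin(4, pmax(0.5, 0.3 * severity + stats::rnorm(3L, 0, 0.4)))
  } else {
    bad_d <- min(stats::runif(1L, 0.2, 1.6), 1.64)
    abcd <- c(0, 0, 0)
  }
  c(bad_d = bad_d, abcd_a = abcd[1L], abcd_b = abcd[2L], abcd_c = abcd[3L])
}

#' Simulate a zonal ET cohort
#'
#' Assembles a full cohort: for each group in `cfg$n`, eyes with severities
#' drawn from the group's uniform range, a per-eye biological offset,
#' `cfg$repeats` measurements with independent zonal noise, alternating
#' OD/OS laterality, and tomographic indices consistent with the group
#' definitions (BAD-D at least 2.69 for significant keratoconus, below 1.65
#' with ABCD stage 0 otherwise). Each eye has its own deterministic RNG
#' substream derived from `seed`, so cohorts are reproducible eye-by-eye.
#'
#' @param cfg an [etd_generator_config()].
#' @param seed optional integer root seed.
#' @param grid an [etd_grid()].
#' @param canonical return the cohort already laterality-normalized
#'   (default `TRUE`); with `FALSE`, OS rows are stored mirrored, as a
#'   device would report them, for exercising [canonicalize_cohort()].
#' @return An [etd_cohort()].
#' @export
simulate_cohort <- function(cfg = etd_generator_config(), seed = NULL,
                            grid = etd_grid(), canonical = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  groups <- rep(names(cfg$n), cfg$n)
  n_eyes <- length(groups)
  eye_seeds <- sample.int(.Machine$integer.max, n_eyes)
  aliases <- zone_aliases(grid)

  rows <- vector("list", n_eyes)
  for (i in seq_len(n_eyes)) {
    set.seed(eye_seeds[i])
    g <- groups[i]
    sev_rng <- cfg$severity[[g]]
    sev <- stats::runif(1L, sev_rng[1L], sev_rng[2L])
    offset <- stats::rnorm(1L, 0, cfg$eye_offset_sd)
    tomo <- tomography_indices(g, sev)
    eye <- if (i %% 2L == 0L) "OS" else "OD"
    meas <- lapply(seq_len(cfg$repeats), function(k) {
      v <- synth_values(cfg, grid, sev, offset)
      if (!canonical && eye == "OS") v <- mirror_values(v, grid)
      v
    })
    vals <- do.call(rbind, meas)
    colnames(vals) <- aliases
    rows[[i]] <- cbind(
      data.frame(subject_id = sprintf("%s_%03d", g, i), eye = eye,
                 group = g, measurement_index = seq_len(cfg$repeats),
                 bad_d = tomo[["bad_d"]], abcd_a = tomo[["abcd_a"]],
                 abcd_b = tomo[["abcd_b"]], abcd_c = tomo[["abcd_c"]],
                 stringsAsFactors = FALSE),
      as.data.frame(vals))
  }
  etd_cohort(do.call(rbind, rows), grid, canonical = canonical)
}

#' Convenience cohorts for the two study stages
#'
#' `simulate_development_cohort()` emulates the development setting:
#' bilateral-ectasia keratoconus eyes (group `keratoconus`, severities
#' spanning moderate to advanced cones) against healthy controls, one
#' measurement per eye. `simulate_validation_cohort()` emulates the
#' validation setting: tomographically significant keratoconus eyes, their
#' tomographically normal fellow eyes (low but non-zero severity), and
#' healthy controls, three measurements per eye.
#'
#' @param n_kc,n_healthy development-stage group sizes.
#' @param seed integer root seed.
#' @param cfg base [etd_generator_config()]; group sizes, severities and
#'   repeats are overridden per stage.
#' @param grid an [etd_grid()].
#' @return An [etd_cohort()].
#' @export
simulate_development_cohort <- function(seed = NULL, n_kc = 86L,
                                        n_healthy = 40L,
                                        cfg = etd_generator_config(),
                                        grid = etd_grid()) {
  cfg$n <- c(keratoconus = n_kc, healthy = n_healthy)
  cfg$severity <- list(keratoconus = c(3, 16), healthy = c(0, 0))
  cfg$repeats <- 1L
  simulate_cohort(cfg, seed, grid)
}

#' @param n_significant,n_fellow,n_controls validation-stage group sizes.
#' @param repeats measurements per eye in the validation stage.
#' @rdname simulate_development_cohort
#' @export
simulate_validation_cohort <- function(seed = NULL, n_significant = 21L,
                                       n_fellow = 21L, n_controls = 21L,
                                       repeats = 3L,
                                       cfg = etd_generator_config(),
                                       grid = etd_grid()) {
  cfg$n <- c(KC_significant = n_significant,
             KC_fellow_normal = n_fellow, healthy = n_controls)
  cfg$repeats <- as.integer(repeats)
  simulate_cohort(cfg, seed, grid)
}
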