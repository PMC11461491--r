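# The synthetic cohort generator: reproducibility, morphology, calibration.

test_that("maps are reproducible and severity 0 is exactly healthy", {
  cfg <- etd_generator_config()
  m1 <- synth_healthy_map(cfg, seed = 7)
  m2 <- synth_healthy_map(cfg, seed = 7)
  m3 <- synth_healthy_map(cfg, seed = 8)
  expect_identical(m1$values, m2$values)
  expect_false(identical(m1$values, m3$values))
  expect_identical(synth_keratoconus_map(cfg, severity = 0, seed = 7)$values,
                   m1$values)
  expect_error(synth_keratoconus_map(cfg, severity = -1), "severity")
})

test_that("flat configuration yields a uniform map with zero parameter", {
  cfg <- etd_generator_config(noise_sd = 0, eye_offset_sd = 0,
                              superior_amplitude = 0, temporal_amplitude = 0)
  m <- synth_healthy_map(cfg, seed = 1)
  expect_equal(unname(m$values), rep(cfg$baseline_et, 41))
  expect_equal(global_parameter(interzonal_differences(m, GRID)), 0)
})

test_that("healthy gradient reproduces the physiological asymmetries", {
  cfg <- etd_generator_config(noise_sd = 0, eye_offset_sd = 0)
  v <- synth_healthy_map(cfg, seed = 1)$values
  # ring 5 spans the 3-mm reference radius where the amplitudes are quoted
  expect_equal(v[["r5I"]] - v[["r5S"]], 5.9)
  expect_equal(v[["r5N"]] - v[["r5T"]], 1.3)
  # superior thinner than inferior in every annulus where the gradient acts
  for (ring in c("r3", "r4", "r5"))
    expect_lt(v[[paste0(ring, "S")]], v[[paste0(ring, "I")]])
  # centre and paracentral ring are flat
  expect_equal(stats::sd(v[c("C", paste0("c", c("S", "SN", "N", "NI", "I",
                                                "TI", "T", "TS")))]), 0)
})

test_that("cones are recovered at every paracentral placement", {
  cfg <- etd_generator_config(noise_sd = 0, eye_offset_sd = 0)
  sectors <- c("S", "SN", "N", "NI", "I", "IT", "T", "TS")
  angles <- c(S = 90, SN = 45, N = 0, NI = 315, I = 270, IT = 225,
              T = 180, TS = 135)
  alias <- c(S = "S", SN = "SN", N = "N", NI = "NI", I = "I", IT = "TI",
             T = "T", TS = "TS")
  for (i in seq_along(sectors)) {
    s1 <- sectors[i]; s2 <- sectors[i %% 8 + 1]
    mid <- (angles[s1] + angles[s2]) / 2
    if (abs(angles[s1] - angles[s2]) > 90) mid <- (mid + 180) %% 360
    m <- synth_keratoconus_map(cfg, severity = 8, seed = 1, cone_angle = mid)
    d <- unclass(interzonal_differences(m, GRID))
    top2 <- names(sort(d, decreasing = TRUE))[1:2]
    expect_setequal(top2, paste0("c", alias[c(s1, s2)]))
  }
})

test_that("the parameter rises strictly with cone depth (noise-free)", {
  cfg <- etd_generator_config(noise_sd = 0, eye_offset_sd = 0)
  sev <- seq(0, 16, by = 0.25)
  p <- vapply(sev, function(s)
    inferior_temporal_parameter(interzonal_differences(
      synth_keratoconus_map(cfg, s, seed = 1), GRID)), numeric(1))
  expect_true(all(diff(p) > 0))
})

test_that("cohorts have the requested bookkeeping and tomography", {
  cohort <- simulate_validation_cohort(seed = 21)
  expect_equal(nrow(cohort), 189L)
  key <- paste(cohort$subject_id, cohort$eye)
  expect_equal(length(unique(key)), 63L)
  expect_true(all(table(key) == 3L))
  expect_true(isTRUE(attr(cohort, "canonical")))

  first <- !duplicated(key)
  expect_true(all(cohort$bad_d[first & cohort$group == "KC_significant"]
                  >= 2.69))
  expect_true(all(cohort$bad_d[first & cohort$group != "KC_significant"]
                  < 1.65))
  expect_true(all(cohort$abcd_a[cohort$group != "KC_significant"] == 0))

  expect_identical(as.data.frame(simulate_validation_cohort(seed = 21)),
                   as.data.frame(cohort))
})

test_that("non-canonical cohorts mirror back to the canonical one", {
  cfg <- etd_generator_config(n = c(healthy = 6), repeats = 1L)
  raw <- simulate_cohort(cfg, seed = 5, canonical = FALSE)
  canon <- simulate_cohort(cfg, seed = 5, canonical = TRUE)
  expect_identical(cohort_values(canonicalize_cohort(raw), GRID),
                   cohort_values(canon, GRID))
})

test_that("group severities order the parameter medians in expectation", {
  wins <- 0L
  for (s in 1:10) {
    cfg <- etd_generator_config(repeats = 1L)
    cohort <- simulate_cohort(cfg, seed = 400 + s)
    p <- screening_parameters(cohort, GRID)
    med <- tapply(p$inferior_temporal, p$group, stats::median)
    if (med[["healthy"]] < med[["KC_fellow_normal"]] &&
        med[["KC_fellow_normal"]] < med[["KC_significant"]])
      wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})
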