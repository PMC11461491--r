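# The inter-zonal difference statistic and derived parameters.

test_that("a constant map has zero differences everywhere", {
  v <- stats::setNames(rep(53, 41), ALIASES)
  d <- interzonal_differences(v, GRID)
  expect_equal(unname(unclass(d)), rep(0, 41))
  expect_equal(global_parameter(d), 0)
  expect_equal(inferior_temporal_parameter(d), 0)
})

test_that("a central step spreads by neighbour count", {
  v <- stats::setNames(rep(52, 41), ALIASES)
  v["C"] <- 50
  d <- unclass(interzonal_differences(v, GRID))
  expect_equal(d[["C"]], 2)
  for (a in GRID$adjacency[["C"]]) {
    deg <- length(GRID$adjacency[[a]])
    expect_equal(d[[a]], 2 / deg)
  }
  expect_equal(unname(d[GRID$zones$ring >= 2]), rep(0, 32))
})

test_that("difference maps match the brute-force oracle on random maps", {
  for (s in 1:200) {
    v <- random_map(s + 300)
    expect_equal(unclass(interzonal_differences(v, GRID)),
                 oracle_diffmap(v), tolerance = 1e-12)
  }
})

test_that("global parameter equals the explicit sum over 41 zones", {
  for (s in 1:50) {
    d <- interzonal_differences(random_map(s + 600), GRID)
    expect_equal(global_parameter(d), sum(unclass(d)) / 41,
                 tolerance = 1e-12)
  }
  expect_equal(global_parameter(structure(rep(1, 41), names = ALIASES)), 1)
})

test_that("inferior-temporal parameter averages cI and cTI", {
  d <- stats::setNames(rep(0, 41), ALIASES)
  d["cI"] <- 4.2; d["cTI"] <- 4.2
  expect_equal(inferior_temporal_parameter(d), 4.2)
  d["cI"] <- 1; d["cTI"] <- 2
  expect_equal(inferior_temporal_parameter(d), 1.5)
  expect_equal(inferior_temporal_parameter(stats::setNames(rep(0, 41),
                                                           ALIASES)), 0)
})

test_that("shift invariance and scale equivariance hold", {
  for (s in 1:30) {
    v <- random_map(s + 900)
    d <- unclass(interzonal_differences(v, GRID))
    shifted <- unclass(interzonal_differences(v + 7.3, GRID))
    scaled <- unclass(interzonal_differences(v * 1.7, GRID))
    expect_equal(shifted, d, tolerance = 1e-12)
    expect_equal(scaled, d * 1.7, tolerance = 1e-12)

    b <- baseline_parameters(v, GRID)
    b_sh <- baseline_parameters(v + 7.3, GRID)
    expect_equal(b_sh[["mean_et"]], b[["mean_et"]] + 7.3)
    expect_equal(b_sh[["sd_et"]], b[["sd_et"]])
    expect_equal(b_sh[["inferior_superior"]], b[["inferior_superior"]])
  }
})

test_that("baseline parameters match a hand-rolled oracle", {
  v <- stats::setNames(rep(53, 41), ALIASES)
  expect_equal(baseline_parameters(v, GRID),
               c(mean_et = 53, sd_et = 0, min_et = 53, max_et = 53,
                 inferior_superior = 0))

  v2 <- stats::setNames(rep(52, 41), ALIASES)
  i_zones <- paste0(c("c", "r2", "r3", "r4", "r5"), "I")
  s_zones <- paste0(c("c", "r2", "r3", "r4", "r5"), "S")
  v2[i_zones] <- 55; v2[s_zones] <- 50
  expect_equal(baseline_parameters(v2, GRID)[["inferior_superior"]], 5)

  for (s in 1:100) {
    v <- random_map(s + 1200)
    b <- baseline_parameters(v, GRID)
    expect_equal(b[["mean_et"]], mean(v))
    expect_equal(b[["sd_et"]], sqrt(sum((v - mean(v))^2) / 40))
    expect_equal(b[["min_et"]], min(v))
    expect_equal(b[["max_et"]], max(v))
    expect_equal(b[["inferior_superior"]],
                 mean(v[i_zones]) - mean(v[s_zones]))
    expect_true(b[["min_et"]] <= b[["mean_et"]] &&
                  b[["mean_et"]] <= b[["max_et"]])
  }
})

test_that("population SD option rescales by sqrt(40/41)", {
  v <- random_map(7)
  expect_equal(baseline_parameters(v, GRID, sd_type = "population")[["sd_et"]],
               baseline_parameters(v, GRID)[["sd_et"]] * sqrt(40 / 41))
})

test_that("deepening a depression at cI never lowers the parameter", {
  cfg <- etd_generator_config(noise_sd = 0, eye_offset_sd = 0)
  v0 <- etdiff:::healthy_surface(cfg, GRID)
  prev <- -Inf
  for (depth in seq(0, 10, by = 0.25)) {
    v <- v0; v["cI"] <- v["cI"] - depth
    p <- inferior_temporal_parameter(interzonal_differences(v, GRID))
    expect_gte(p, prev - 1e-12)
    prev <- p
  }
})

test_that("non-canonical inputs are rejected by the statistic", {
  m <- as_map(random_map(3))
  expect_error(interzonal_differences(m, GRID), "canonical")
  expect_error(baseline_parameters(m, GRID), "canonical")
})

test_that("cohort-level difference maps agree with per-map computation", {
  cohort <- canonicalize_cohort(etd_cohort(toy_cohort_df(), GRID))
  dm <- cohort_diffmaps(cohort, GRID)
  for (i in seq_len(nrow(cohort))) {
    v <- cohort_values(cohort, GRID)[i, ]
    expect_equal(dm[i, ], unclass(interzonal_differences(v, GRID)))
  }
  p <- screening_parameters(cohort, GRID)
  expect_equal(p$global_mean, unname(rowMeans(dm)))
  expect_equal(p$inferior_temporal,
               unname((dm[, "cI"] + dm[, "cTI"]) / 2))
})
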