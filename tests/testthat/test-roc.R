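# ROC analysis, AUC/CI, cut-off derivation, zone selection.

test_that("AUC is 1 for separated scores, 0.5 for uninformative ones", {
  r <- roc_analysis(c(1, 2, 3, 11, 12, 13), c(0, 0, 0, 1, 1, 1))
  expect_equal(r$auc, 1)
  expect_warning(
    r0 <- roc_analysis(rep(5, 8), rep(c(0, 1), 4)), "identical")
  expect_equal(r0$auc, 0.5)
  expect_error(roc_analysis(1:4, rep(1, 4)), "both classes")
})

test_that("trapezoid AUC equals exhaustive concordance enumeration", {
  # the quoted 6+6 toy case with one tie
  sc <- c(1, 2, 3, 4, 5, 6, 4, 7, 8, 9, 10, 11)
  lb <- rep(c(0, 1), each = 6)
  expect_equal(roc_analysis(sc, lb)$auc, oracle_auc(sc, lb))

  for (s in 1:200) {
    set.seed(s)
    n1 <- sample(3:10, 1); n0 <- sample(3:10, 1)
    sc <- c(rnorm(n0), rnorm(n1, 0.8))
    if (s %% 3 == 0) sc <- round(sc)   # force ties regularly
    lb <- rep(c(0, 1), c(n0, n1))
    expect_equal(roc_analysis(sc, lb)$auc, oracle_auc(sc, lb),
                 tolerance = 1e-12)
  }
})

test_that("curve is monotone and direction negation is an identity", {
  for (s in 1:30) {
    set.seed(s)
    sc <- c(rnorm(12), rnorm(10, 1))
    lb <- rep(c(0, 1), c(12, 10))
    r <- roc_analysis(sc, lb)
    expect_true(all(diff(r$sensitivity) <= 1e-12))
    expect_true(all(diff(r$specificity) >= -1e-12))
    r_neg <- roc_analysis(-sc, lb, direction = "lower_is_disease")
    expect_equal(r_neg$auc, r$auc)
    expect_equal(r_neg$ci95, r$ci95)
  }
})

test_that("DeLong intervals agree with the pROC reference", {
  skip_if_not_installed("pROC")
  for (s in 1:20) {
    set.seed(s)
    sc <- c(rnorm(15), rnorm(12, 1.2))
    lb <- rep(c(0, 1), c(15, 12))
    r <- roc_analysis(sc, lb)
    ref <- pROC::ci.auc(pROC::roc(lb, sc, quiet = TRUE, direction = "<"),
                        method = "delong")
    expect_equal(r$auc, as.numeric(ref[2]), tolerance = 1e-10)
    expect_equal(unname(r$ci95),
                 pmin(pmax(as.numeric(ref[c(1, 3)]), 0), 1),
                 tolerance = 1e-8)
  }
})

test_that("perfect separation puts both cut-offs at the gap midpoint", {
  r <- roc_analysis(c(1, 2, 3, 4, 10, 11, 12, 13),
                    c(0, 0, 0, 0, 1, 1, 1, 1))
  co <- derive_cutoffs(r)
  expect_equal(co$lower, 7)
  expect_equal(co$upper, 7)
  expect_equal(co$sens_at_lower, 1)
  expect_equal(co$spec_at_upper, 1)
})

test_that("cut-offs match an exhaustive threshold scan", {
  scan_oracle <- function(s, lab, st, ct) {
    u <- sort(unique(s))
    gap <- if (length(u) > 1) stats::median(diff(u)) else 1
    cand <- c(u[1] - gap / 2, (u[-length(u)] + u[-1]) / 2,
              u[length(u)] + gap / 2)
    sens <- sapply(cand, function(t) mean(s[lab == 1] >= t))
    spec <- sapply(cand, function(t) mean(s[lab == 0] < t))
    list(lower = if (any(sens >= st)) max(cand[sens >= st]) else NA_real_,
         upper = if (any(spec >= ct)) min(cand[spec >= ct]) else NA_real_)
  }
  for (s in 1:50) {
    set.seed(s)
    sc <- c(rnorm(10), rnorm(10, 1))
    lb <- rep(c(0, 1), each = 10)
    r <- roc_analysis(sc, lb)
    co <- derive_cutoffs(r, 0.9, 0.9)
    ref <- scan_oracle(sc, lb, 0.9, 0.9)
    expect_equal(co$lower, ref$lower)
    expect_equal(co$upper, ref$upper)
    # floors are honoured whenever the cut-off exists
    if (!is.na(co$lower)) expect_gte(co$sens_at_lower, 0.9)
    if (!is.na(co$upper)) expect_gte(co$spec_at_upper, 0.9)
  }
})

test_that("degenerate and unattainable targets behave as documented", {
  sc <- c(1, 2, 3, 4, 10, 11, 12, 13)
  lb <- c(0, 0, 0, 0, 1, 1, 1, 1)
  r <- roc_analysis(sc, lb)
  co0 <- derive_cutoffs(r, sens_target = 0)
  expect_equal(co0$lower, 13 + stats::median(diff(sort(unique(sc)))) / 2)
  expect_equal(co0$sens_at_lower, 0)

  # overlapping screening scores keep lower <= upper
  set.seed(99)
  sc2 <- c(rnorm(30), rnorm(30, 0.5))
  r2 <- roc_analysis(sc2, rep(c(0, 1), each = 30))
  co2 <- derive_cutoffs(r2)
  expect_true(co2$lower <= co2$upper)

  # with full overlap, perfect floors are only met at the degenerate
  # operating points beyond the observed scores
  r3 <- roc_analysis(c(1, 2, 1, 2), c(0, 0, 1, 1))
  co3 <- derive_cutoffs(r3, sens_target = 1, spec_target = 1)
  expect_equal(co3$upper, 2.5)
  expect_equal(co3$sens_at_upper, 0)
  expect_equal(co3$lower, 0.5)
  expect_equal(co3$spec_at_lower, 0)
  expect_true(all(co3$attained))
})

test_that("fixed cut-offs reproduce their sensitivity and specificity", {
  set.seed(5)
  sc <- c(rnorm(20), rnorm(20, 2))
  lb <- rep(c(0, 1), each = 20)
  co <- derive_cutoffs(roc_analysis(sc, lb))
  perf <- apply_cutoff(sc, lb, co$lower)
  expect_equal(perf[["sens"]], co$sens_at_lower)
  expect_equal(perf[["spec"]], co$spec_at_lower)
})

test_that("zone selection recovers noise-free cones at every placement", {
  cfg <- etd_generator_config(noise_sd = 0)
  angles <- c(67.5, 22.5, 337.5, 292.5, 247.5, 202.5, 157.5, 112.5)
  expected <- list(c("cS", "cSN"), c("cSN", "cN"), c("cN", "cNI"),
                   c("cNI", "cI"), c("cI", "cTI"), c("cTI", "cT"),
                   c("cT", "cTS"), c("cTS", "cS"))
  set.seed(31)
  for (j in seq_along(angles)) {
    dm <- matrix(0, 16, 41, dimnames = list(NULL, ALIASES))
    for (i in 1:8) {
      dm[i, ] <- unclass(interzonal_differences(
        synth_healthy_map(cfg)$values, GRID))
      dm[8 + i, ] <- unclass(interzonal_differences(
        synth_keratoconus_map(cfg, severity = runif(1, 3, 12),
                              cone_angle = angles[j])$values, GRID))
    }
    sel <- select_top_zones(dm, rep(c(0, 1), each = 8), k = 2)
    expect_setequal(sel$zones, expected[[j]])
  }
})

test_that("zone selection ranks by the brute-force per-zone AUC", {
  cfg <- etd_generator_config()
  set.seed(17)
  n <- 20
  dm <- matrix(0, 2 * n, 41, dimnames = list(NULL, ALIASES))
  for (i in 1:n) {
    dm[i, ] <- unclass(interzonal_differences(
      synth_healthy_map(cfg)$values, GRID))
    dm[n + i, ] <- unclass(interzonal_differences(
      synth_keratoconus_map(cfg, severity = 5)$values, GRID))
  }
  lab <- rep(c(0, 1), each = n)
  sel <- select_top_zones(dm, lab, k = 2)
  # the selected pair attains the two largest oracle AUCs
  ref <- vapply(ALIASES, function(z) oracle_auc(dm[, z], lab), numeric(1))
  expect_equal(unname(sel$auc), unname(ref))
  expect_setequal(sel$zones, names(sort(ref, decreasing = TRUE))[1:2])
  # and the winners sit on the cone
  expect_true(all(sel$zones %in% c("cI", "cTI", "cNI", "cT", "C",
                                   "r2I", "r2TI")))

  all41 <- select_top_zones(dm, lab, k = 41)
  expect_equal(length(all41$zones), 41L)
  expect_true(all(diff(all41$auc[all41$zones]) <= 1e-12))
  expect_error(select_top_zones(dm, lab, k = 42), "41")

  # permuted labels carry no signal: AUCs hover around 0.5
  set.seed(1)
  null_auc <- replicate(20, {
    max(abs(select_top_zones(dm, sample(lab), k = 1)$auc - 0.5))
  })
  expect_lt(stats::median(null_auc), 0.35)
})
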