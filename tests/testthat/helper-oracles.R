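# Brute-force oracles and fixture builders shared across tests.

GRID <- etd_grid()
ALIASES <- zone_aliases(GRID)

# a random plausible zonal map (named vector)
random_map <- function(seed, lo = 40, hi = 70) {
  set.seed(seed)
  stats::setNames(runif(41, lo, hi), ALIASES)
}

# an etd_map from a named value vector
as_map <- function(values, eye = "OD", canonical = FALSE, ...) {
  etd_map(values, eye = eye, canonical = canonical, grid = GRID, ...)
}

# Eq.-style brute force: plain double loop over the adjacency lists
oracle_diffmap <- function(values, grid = GRID) {
  out <- numeric(41)
  names(out) <- zone_aliases(grid)
  for (a in names(out)) {
    nbs <- grid$adjacency[[a]]
    acc <- 0
    for (x in nbs) acc <- acc + abs(values[[a]] - values[[x]])
    out[a] <- acc / length(nbs)
  }
  out
}

# concordance-probability AUC by exhaustive pair enumeration
oracle_auc <- function(scores, labels) {
  xs <- scores[labels == 1]
  ys <- scores[labels == 0]
  tot <- 0
  for (x in xs) for (y in ys)
    tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(xs) * length(ys))
}

# exact two-sided Mann-Whitney p by enumerating all label assignments
oracle_mw_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  n1 <- length(x)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(length(pooled), n1)
  u_all <- apply(idx, 2, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(y) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# tiny two-eye cohort data frame (2 eyes x n_meas) built in code
toy_cohort_df <- function(n_meas = 3, seed = 42) {
  set.seed(seed)
  rows <- list()
  for (e in 1:2) {
    v <- runif(41, 45, 60)
    for (k in seq_len(n_meas)) {
      z <- as.list(v + rnorm(41, 0, 0.5))
      names(z) <- ALIASES
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = paste0("s", e), eye = c("OD", "OS")[e],
        group = c("keratoconus", "healthy")[e], measurement_index = k,
        bad_d = c(4.2, 0.9)[e], z, check.names = FALSE)
    }
  }
  do.call(rbind, rows)
}
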