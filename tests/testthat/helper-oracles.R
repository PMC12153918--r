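# Independent oracles and small fixtures shared across test files.

# Brute-force Ward linkage: at every step recompute the Ward.D2 merge cost
# between all cluster pairs from scratch, using the closed form
#   D(A, B)^2 = 2 |A| |B| / (|A| + |B|) * ||centroid(A) - centroid(B)||^2 ,
# and merge the cheapest pair. Returns the merge heights in order.
ward_oracle_heights <- function(x) {
  x <- as.matrix(x)
  clusters <- lapply(seq_len(nrow(x)), identity)
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      a <- clusters[[i]]; b <- clusters[[j]]
      ca <- colMeans(x[a, , drop = FALSE])
      cb <- colMeans(x[b, , drop = FALSE])
      d2 <- 2 * length(a) * length(b) / (length(a) + length(b)) *
        sum((ca - cb)^2)
      if (d2 < best[1]) best <- c(d2, i, j)
    }
    heights <- c(heights, sqrt(best[1]))
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- c(clusters[-c(best[2], best[3])], list(merged))
  }
  heights
}

# Adjusted Rand index between two labelings (closed-form pair counting).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(v) sum(choose(v, 2))
  sij <- sum_comb(as.vector(tab))
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  (sij - expected) / (maxi - expected)
}

# Default-condition state models (the published Walloon profiles with the
# default within-state dispersion fraction).
default_states <- function(fraction = 0.5) {
  make_state_models(walloon_state_means(), walloon_trait_sds(), fraction)
}

# Balanced iid draws from the default state models: n_per_state records per
# state in the fat-basis trait space, with truth labels. Used for
# classifier and summary tests where balanced classes are needed.
balanced_state_draws <- function(n_per_state, fraction = 0.5, seed = 1L) {
  states <- default_states(fraction)
  set.seed(seed)
  draws <- lapply(states, function(s)
    MASS::mvrnorm(n_per_state, s$mean, s$covariance))
  x <- do.call(rbind, draws)
  fa <- intersect(colnames(x), fa_trait_names())
  x[, fa] <- pmax(x[, fa], 0)
  list(features = x[, fa_trait_names()],
       all_traits = x,
       labels = rep(seq_along(states), each = n_per_state))
}

# Small cleaned fat-basis population plus generator truth.
small_population <- function(n_herds = 6, horizon_days = 60, seed = 11L,
                             artifact_rates = c(missing = 0, range = 0,
                                                negative_fa = 0)) {
  cfg <- sim_config(n_herds = n_herds, horizon_days = horizon_days,
                    artifact_rates = artifact_rates, seed = seed)
  pop <- simulate_population(default_states(), cfg)
  cl <- clean_records(pop$records)
  list(records = convert_to_fat_basis(cl$kept), truth = pop$truth,
       raw = pop$records, log = cl$log, artifact_log = pop$artifact_log)
}
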