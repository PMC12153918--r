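test_that("state models carry the published means and scaled dispersions", {
  states <- default_states()
  expect_length(states, 7)
  expect_equal(states[[1]]$mean[["C4"]], 2.78)
  expect_equal(vapply(states, `[[`, integer(1), "state_id"), 1:7)
  # covariance = (fraction * sd)^2 on the diagonal under identity correlation
  expect_equal(diag(states[[3]]$covariance)[["C16"]], (0.5 * 3.25)^2)
  expect_true(all(vapply(states, function(s)
    min(eigen(s$covariance, symmetric = TRUE,
              only.values = TRUE)$values) > 0, logical(1))))
})

test_that("covariance construction squares the scaled SDs", {
  m <- matrix(c(1, 2), nrow = 1, dimnames = list(NULL, c("a", "b")))
  s <- make_state_models(m, c(a = 0.19, b = 0.34),
                         within_state_sd_fraction = 1)
  expect_equal(unname(diag(s[[1]]$covariance)), c(0.0361, 0.1156))
})

test_that("degenerate and mismatched state inputs are rejected", {
  m <- matrix(c(1, 2), nrow = 1, dimnames = list(NULL, c("a", "b")))
  expect_error(make_state_models(m, c(a = 0, b = 0)), "degenerate")
  expect_error(make_state_models(m, c(a = 1, wrong = 1)), "mismatch")
  expect_error(make_state_models(m, c(a = 1, b = 1),
                                 within_state_sd_fraction = 0))
})

test_that("a non-positive-definite correlation is repaired", {
  m <- matrix(c(1, 2, 3), nrow = 1, dimnames = list(NULL, c("a", "b", "c")))
  corr <- matrix(0.99, 3, 3, dimnames = list(c("a", "b", "c"),
                                             c("a", "b", "c")))
  diag(corr) <- 1
  corr[1, 2] <- corr[2, 1] <- -0.99  # inconsistent triple -> not PD
  s <- make_state_models(m, c(a = 1, b = 1, c = 1), correlation = corr)
  expect_gt(min(eigen(s[[1]]$covariance, only.values = TRUE)$values), 0)
})

test_that("an absorbing chain pins the latent state", {
  states <- default_states()
  cfg <- sim_config(n_herds = 1, horizon_days = 40,
                    transition = diag(7),
                    initial_distribution = c(0, 0, 1, 0, 0, 0, 0),
                    seed = 3)
  out <- simulate_herd_series(states, cfg, "h1", seed = 3)
  expect_true(all(out$truth$state_id == 3))
  expect_true(all(diff(as.numeric(out$records$date)) %in% 1:3))
  expect_true(all(diff(as.numeric(out$records$date)) > 0))
})

test_that("empirical transition frequencies recover a two-state chain", {
  states <- make_state_models(cbind(a = c(0, 5), b = c(0, 5)),
                              c(a = 1, b = 1))
  tr <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE)
  cfg <- sim_config(n_herds = 1, horizon_days = 20000, transition = tr,
                    sampling_probs = c(1, 0, 0), seed = 42)
  out <- simulate_herd_series(states, cfg, "h1", seed = 42)
  s <- out$truth$state_id
  from1 <- s[-length(s)] == 1
  est <- mean(s[-1][from1] == 1)
  expect_lt(abs(est - 0.9), 0.02)
})

test_that("population simulation is reproducible and herd-structured", {
  states <- default_states()
  cfg <- sim_config(n_herds = 2, horizon_days = 30, seed = 5)
  p1 <- simulate_population(states, cfg)
  p2 <- simulate_population(states, cfg)
  expect_identical(p1, p2)
  expect_setequal(unique(p1$records$herd_id), c("herd0001", "herd0002"))
  for (h in split(p1$records, p1$records$herd_id))
    expect_false(is.unsorted(h$date))
  expect_identical(p1$records$record_id, p1$truth$record_id)
})

test_that("pooled state frequencies approach the stationary distribution", {
  states <- default_states()
  cfg <- sim_config(n_herds = 200, horizon_days = 365, seed = 8)
  pop <- simulate_population(states, cfg)
  freq <- as.vector(cluster_proportions(pop$truth$state_id, k = 7))
  pi <- stationary_distribution(walloon_transition_matrix())
  expect_lt(sum(abs(freq - pi)) / 2, 0.03)  # total-variation distance
})

test_that("noiseless spectra are an exact shared linear image of traits", {
  pop <- small_population(n_herds = 3, horizon_days = 40)
  sp <- simulate_spectra(pop$records, noise_sd = 0, seed = 2)
  expect_equal(ncol(sp), 213)  # record_id + 212 points
  # two records with identical traits get identical spectra
  rec2 <- pop$records[c(1, 1), ]
  sp2 <- simulate_spectra(rec2, noise_sd = 0, seed = 2)
  expect_equal(unname(unlist(sp2[1, -1])), unname(unlist(sp2[2, -1])))
  # any trait is exactly linear in the spectra
  fit <- stats::lm.fit(cbind(1, as.matrix(sp[, -1])),
                       pop$records$C18_1cis9)
  expect_lt(max(abs(fit$residuals)), 1e-8)
  expect_error(simulate_spectra(pop$records, noise_sd = -1), "non-negative")
})

test_that("artifact injection respects its rates and logs every change", {
  pop <- small_population(n_herds = 10, horizon_days = 200)$records
  pop <- pop[seq_len(min(1000, nrow(pop))), ]
  none <- inject_artifacts(pop, c(missing = 0, range = 0, negative_fa = 0),
                           seed = 9)
  expect_identical(none$records, pop)
  expect_equal(nrow(none$log), 0)

  all_neg <- inject_artifacts(pop, c(negative_fa = 1), seed = 9)
  famat <- as.matrix(all_neg$records[, fa_trait_names()])
  expect_true(all(rowSums(famat < 0, na.rm = TRUE) >= 1))

  some <- inject_artifacts(pop, c(missing = 0.1), seed = 10)
  n_hit <- nrow(some$log)
  expect_lt(abs(n_hit - 0.1 * nrow(pop)),
            4 * sqrt(nrow(pop) * 0.1 * 0.9))
  touched <- unique(some$log$record_id)
  miss_rows <- rowSums(is.na(some$records[, c(fa_trait_names(), "fat",
                                              "protein",
                                              aux_trait_names())])) > 0
  expect_setequal(some$records$record_id[miss_rows], touched)
})
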