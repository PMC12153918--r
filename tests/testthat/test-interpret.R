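test_that("cluster summaries rank under the supplied orientation", {
  recs <- data.frame(record_id = paste0("r", 1:4), unit_basis = "fat_basis")
  recs[fa_trait_names()] <- 1
  recs$C4 <- c(1, 1, 3, 3)
  labels <- c(1, 1, 2, 2)
  s <- summarize_clusters(recs, labels,
                          trait_orientation = c(C4 = TRUE))
  expect_equal(unname(s$means["C4", ]), c(1, 3))
  expect_equal(s$best_two$C4[1], 2)
  flipped <- summarize_clusters(recs, labels,
                                trait_orientation = c(C4 = FALSE))
  expect_equal(flipped$best_two$C4[1], 1)
  # ranks are a permutation of 1..k per trait
  expect_setequal(s$ranks["C4", ], 1:2)
  # single-record cluster: SD is missing
  s1 <- summarize_clusters(recs, c(1, 1, 1, 2))
  expect_true(is.na(s1$sds["C4", 2]))
})

test_that("recovered cluster means stay within sampling error of the truth", {
  n <- 200
  draws <- balanced_state_draws(n, seed = 43)
  recs <- data.frame(record_id = seq_len(nrow(draws$all_traits)),
                     unit_basis = "fat_basis")
  recs[colnames(draws$all_traits)] <- as.data.frame(draws$all_traits)
  s <- summarize_clusters(recs, draws$labels)
  truth <- walloon_state_means()
  sds <- walloon_trait_sds()
  # non-truncated traits: z-scores of the mean at known n (3 SE bound)
  traits <- setdiff(colnames(truth), fa_trait_names())
  for (cl in 1:7) {
    se <- 0.5 * sds[traits] / sqrt(n)
    z <- abs(s$means[traits, cl] - truth[cl, traits]) / se
    expect_true(all(z < 3.5), label = paste("cluster", cl))
  }
})

test_that("best-two and worst-two sets are disjoint for k >= 4", {
  draws <- balanced_state_draws(30, seed = 47)
  recs <- data.frame(record_id = seq_len(nrow(draws$features)),
                     unit_basis = "fat_basis")
  recs[fa_trait_names()] <- as.data.frame(draws$features)
  s <- summarize_clusters(recs, draws$labels)
  for (t in rownames(s$means))
    expect_length(intersect(s$best_two[[t]], s$worst_two[[t]]), 0)
})

test_that("flags follow the cluster map with threshold escalation", {
  expect_equal(flag_records(c(4, 3, 2, 7)),
               c("green", "red", "orange", "green"))
  expect_error(flag_records(9), "unmapped")
  prob <- matrix(c(0.5, 0, 0.45, 0.05, 0, 0, 0), 1,
                 dimnames = list(NULL, 1:7))
  expect_equal(flag_records(prob), "green")
  expect_equal(flag_records(prob, probability_threshold = 0.4), "red")
  # threshold 1.0 reduces to default mode
  expect_equal(flag_records(prob, probability_threshold = 1.0), "green")
  expect_error(flag_records(3, probability_threshold = 0.4), "requires")
  # determinism: same inputs, same flags
  expect_identical(flag_records(c(1, 5, 3)), flag_records(c(1, 5, 3)))
})

test_that("probability series order, label switches and alerts behave", {
  onehot <- function(cl) { p <- rep(0, 7); p[cl] <- 1; p }
  states <- c(1, 5, 3, 5, 1)
  pred <- data.frame(herd_id = "h1", date = as.Date("2021-01-01") + 0:4)
  pm <- t(vapply(states, onehot, numeric(7)))
  pred[paste0("p", 1:7)] <- as.data.frame(pm)
  # shuffle rows; the series must come back chronological
  pred <- pred[c(3, 1, 5, 2, 4), ]
  s <- probability_series(pred, "h1")
  expect_equal(s$label, states)
  expect_equal(s$flag, c("green", "orange", "red", "orange", "green"))
  # argmax switches exactly where the hard-label series switches
  expect_equal(which(diff(s$label) != 0), which(diff(max.col(pm)) != 0))
  # single red record is flagged red but below the 2-run alert
  one <- pred[pred$date == as.Date("2021-01-03"), ]  # the state-3 record
  s1 <- probability_series(one, "h1")
  expect_equal(s1$flag, "red")
  expect_false(s1$alert)
  # runs of >= 2 non-green records raise the alert
  expect_equal(s$alert, c(FALSE, FALSE, TRUE, TRUE, FALSE))
  dup <- rbind(pred, pred[1, ])
  expect_error(probability_series(dup, "h1"), "duplicate")
})

test_that("probability-trait correlations behave at both extremes", {
  set.seed(51)
  tr <- rnorm(300)
  prob <- cbind(a = tr, b = 1 - tr)  # column identical to the trait
  r <- probability_trait_correlations(prob, cbind(t1 = tr))
  expect_equal(unname(r["a", "t1"]), 1)
  expect_equal(unname(r["b", "t1"]), -1)
  # independent columns: null correlation bound at n = 10000
  big <- matrix(rnorm(20000), ncol = 2)
  r0 <- probability_trait_correlations(cbind(p = big[, 1]),
                                       cbind(t = big[, 2]))
  expect_lt(abs(r0[1, 1]), 0.05)
  # zero-variance columns are flagged, not fatal
  rz <- probability_trait_correlations(cbind(p = rep(0.5, 10)),
                                       cbind(t = rnorm(10)))
  expect_true(is.na(rz[1, 1]))
  expect_equal(attr(rz, "flagged"), "p")
  expect_error(probability_trait_correlations(prob[1:2, ], cbind(t1 = tr[1:2])),
               "at least 3")
})

test_that("membership probability of a state tracks its signature trait", {
  draws <- balanced_state_draws(50, seed = 53)
  fit <- fit_random_forest(draws$features, draws$labels, n_trees = 100,
                           mtry_grid = 5, cv_folds = 3, seed = 7)
  prob <- fit$cv$oof_probabilities
  # state 3 has the highest C18:1 cis-9 profile of the seven states
  r <- probability_trait_correlations(prob,
                                      draws$features[, "C18_1cis9", drop = FALSE])
  expect_gt(r["3", "C18_1cis9"], 0.3)
})
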