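two_gaussians <- function(n_per, sep, p = 10, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * p, 0), n_per, p),
             matrix(rnorm(n_per * p, sep), n_per, p))
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, y = rep(1:2, each = n_per))
}

test_that("the first derivative is the adjacent difference", {
  sp <- matrix(5, 3, 10)
  expect_true(all(first_derivative(sp) == 0))
  ramp <- matrix(rep(seq(0, 9) * 0.7, each = 2), 2, 10)
  expect_true(all(abs(first_derivative(ramp) - 0.7) < 1e-12))
  # baseline-offset invariance
  set.seed(2)
  sp <- matrix(rnorm(50), 5, 10)
  shifted <- sp + runif(5)
  expect_equal(first_derivative(shifted), first_derivative(sp),
               tolerance = 1e-12)
  expect_error(first_derivative(matrix(1, 2, 1)), "at least 2")
  withid <- data.frame(record_id = c("a", "b"), s1 = c(1, 2), s2 = c(3, 5))
  out <- first_derivative(withid)
  expect_equal(out$d001, c(2, 3))
})

test_that("confusion metrics match their closed forms", {
  d <- diag(c(5L, 8L, 2L))
  expect_equal(confusion_accuracy(d), 1)
  expect_equal(confusion_kappa(d), 1)
  expect_equal(confusion_accuracy(matrix(c(3, 1, 1, 3), 2)), 0.75)
  expect_equal(confusion_kappa(matrix(25, 2, 2)), 0)
  # invariance under a simultaneous row/column permutation
  set.seed(3)
  cm <- matrix(rpois(49, 20), 7, 7)
  p <- sample(7)
  expect_equal(confusion_accuracy(cm[p, p]), confusion_accuracy(cm))
  expect_equal(confusion_kappa(cm[p, p]), confusion_kappa(cm))
  expect_error(confusion_kappa(matrix(c(9, 0, 0, 0), 2)), "undefined")
})

test_that("stratified folds balance classes and reject infeasible splits", {
  y <- rep(1:3, c(23, 31, 17))
  res <- cross_validate(matrix(rnorm(71 * 4), 71, 4), y,
                        list(kind = "random_forest", n_trees = 50, mtry = 2),
                        folds = 5, seed = 7)
  for (cl in 1:3) {
    per_fold <- table(res$fold_assign[y == cl])
    expect_lte(max(per_fold) - min(per_fold), 1)
  }
  expect_equal(sum(res$confusion), 71)
  expect_gte(res$accuracy, min(res$per_fold$accuracy))
  expect_lte(res$accuracy, max(res$per_fold$accuracy))
  expect_error(
    cross_validate(matrix(rnorm(40), 10, 4), c(rep(1, 8), 2, 2),
                   list(kind = "random_forest", n_trees = 10, mtry = 1),
                   folds = 5, seed = 1),
    "stratification")
})

test_that("PLS-DA separates well-separated classes and not shuffled ones", {
  d <- two_gaussians(60, sep = 3, seed = 13)
  fit <- fit_plsda(d$x, d$y, max_components = 5, cv_folds = 5, seed = 1)
  expect_gte(fit$cv$accuracy, 0.95)
  expect_true(all(abs(rowSums(fit$cv$oof_probabilities) - 1) < 1e-9))

  set.seed(29)
  y_shuf <- sample(rep(1:4, each = 40))
  x <- matrix(rnorm(160 * 8), 160, 8)
  fit0 <- fit_plsda(x, y_shuf, max_components = 5, cv_folds = 5, seed = 2)
  expect_lt(abs(fit0$cv$accuracy - 0.25), 0.1)
  expect_lt(abs(fit0$cv$kappa), 0.1)
})

test_that("the random forest nails near-separable states and rejects one class", {
  draws <- balanced_state_draws(40, fraction = 0.1, seed = 17)
  fit <- fit_random_forest(draws$features, draws$labels, n_trees = 200,
                           cv_folds = 5, seed = 3)
  expect_gte(fit$cv$accuracy, 0.99)
  expect_equal(sum(fit$cv$confusion), length(draws$labels))
  expect_error(fit_random_forest(draws$features[1:20, ], rep(1, 20)),
               "2 classes")
})

test_that("membership probabilities are row-stochastic and argmax-consistent", {
  draws <- balanced_state_draws(30, fraction = 0.5, seed = 19)
  fit <- fit_random_forest(draws$features, draws$labels, n_trees = 100,
                           mtry_grid = 5, cv_folds = 3, seed = 4)
  pred <- predict_membership(fit, draws$features)
  expect_true(all(abs(rowSums(pred$probabilities) - 1) < 1e-9))
  expect_true(all(pred$probabilities >= 0 & pred$probabilities <= 1))
  expect_equal(pred$labels,
               as.integer(colnames(pred$probabilities)[
                 max.col(pred$probabilities, ties.method = "first")]))
  expect_error(predict_membership(fit, draws$features[, 1:10]), "mismatch")

  plsfit <- fit_plsda(draws$features, draws$labels, max_components = 10,
                      cv_folds = 3, seed = 5)
  pp <- predict_membership(plsfit, draws$features)
  expect_true(all(abs(rowSums(pp$probabilities) - 1) < 1e-9))
  expect_equal(pp$labels,
               as.integer(colnames(pp$probabilities)[
                 max.col(pp$probabilities, ties.method = "first")]))
})

test_that("PLS-DA trails the random forest on the default state profiles", {
  draws <- balanced_state_draws(80, seed = 23)
  pls <- fit_plsda(draws$features, draws$labels, cv_folds = 5, seed = 6)
  rf <- fit_random_forest(draws$features, draws$labels, n_trees = 300,
                          cv_folds = 5, seed = 6)
  expect_lt(pls$cv$accuracy, rf$cv$accuracy)
})

test_that("spectra-based prediction trails trait-based prediction", {
  draws <- balanced_state_draws(70, seed = 27)
  recs <- data.frame(record_id = paste0("r", seq_len(nrow(draws$features))))
  recs[fa_trait_names()] <- as.data.frame(draws$features)
  sp <- simulate_spectra(recs, noise_sd = 0.5, seed = 5)
  dsp <- as.matrix(first_derivative(sp)[, -1])
  spec <- function(p) list(kind = "random_forest", n_trees = 150,
                           mtry = max(1, floor(sqrt(p))))
  on_traits <- cross_validate(draws$features, draws$labels,
                              spec(31), folds = 5, seed = 8)
  on_spectra <- cross_validate(dsp, draws$labels,
                               spec(ncol(dsp)), folds = 5, seed = 8)
  expect_lt(on_spectra$accuracy, on_traits$accuracy)
})

test_that("random-forest CV accuracy is stable across seeds", {
  draws <- balanced_state_draws(50, seed = 31)
  accs <- vapply(1:5, function(s)
    fit_random_forest(draws$features, draws$labels, n_trees = 200,
                      mtry_grid = 5, cv_folds = 5, seed = s)$cv$accuracy,
    numeric(1))
  expect_lt(max(accs) - min(accs), 0.04)
})
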