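fake_record <- function(fa_value = 0.4, fat = 4, protein = 3.4) {
  rec <- data.frame(record_id = "r1", herd_id = "h1",
                    date = as.Date("2021-06-01"),
                    unit_basis = "milk_basis", stringsAsFactors = FALSE)
  rec[fa_trait_names()] <- fa_value
  rec$fat <- fat
  rec$protein <- protein
  rec[aux_trait_names()] <- 1
  rec
}

test_that("fat-basis conversion is the stated ratio and guarded", {
  rec <- fake_record(fa_value = 0.40, fat = 4.0)
  out <- convert_to_fat_basis(rec)
  expect_equal(out$C4, 10.0)
  expect_equal(out$unit_basis, "fat_basis")
  expect_equal(out$fat, 4.0)
  expect_error(convert_to_fat_basis(out), "milk basis")

  zero <- fake_record(fa_value = 0, fat = 5)
  expect_equal(convert_to_fat_basis(zero)$C16, 0)

  bad <- fake_record(fat = 0)
  expect_error(convert_to_fat_basis(bad), "r1")
})

test_that("cleaning applies bounds, negativity and missingness in order", {
  recs <- do.call(rbind, list(
    fake_record(),                    # clean
    fake_record(fat = 1.4),           # fat bound
    fake_record(fat = 9.5),           # fat bound
    fake_record(protein = 0.5),       # protein bound
    fake_record(),                    # negative FA (below)
    fake_record()))                   # missing (below)
  recs$record_id <- paste0("r", 1:6)
  recs$C14[5] <- -0.01
  recs$C18[6] <- NA
  out <- clean_records(recs)
  expect_equal(out$kept$record_id, "r1")
  expect_equal(out$log$reason,
               c("fat_bound", "fat_bound", "protein_bound",
                 "negative_fa", "missing"))
  # precedence: a row failing fat bound AND carrying an NA logs fat_bound
  both <- fake_record(fat = 1.2)
  both$C6 <- NA
  expect_equal(clean_records(both)$log$reason, "fat_bound")
  # all-clean input passes through with an empty log
  ok <- clean_records(fake_record())
  expect_identical(ok$kept, fake_record())
  expect_equal(nrow(ok$log), 0)
})

test_that("cleaning removes exactly the generator-perturbed rows", {
  pop <- small_population(n_herds = 10, horizon_days = 200,
                          artifact_rates = c(missing = 0.04, range = 0.04,
                                             negative_fa = 0.04))
  cleaned_ids <- pop$records$record_id
  untouched <- setdiff(pop$raw$record_id, pop$artifact_log$record_id)
  expect_setequal(cleaned_ids, untouched)
  # ledger conservation: kept + rejected = input, columns unchanged
  expect_equal(nrow(pop$records) + nrow(pop$log), nrow(pop$raw))
  expect_true(all(pop$log$record_id %in% pop$artifact_log$record_id))
})

test_that("the reference projection retains components by explained variance", {
  set.seed(21)
  n <- 300
  f1 <- rnorm(n); f2 <- rnorm(n)
  x <- cbind(sapply(1:16, function(i) f1 + rnorm(n, sd = 0.01)),
             sapply(1:15, function(i) f2 + rnorm(n, sd = 0.01)))
  colnames(x) <- fa_trait_names()
  recs <- data.frame(record_id = paste0("r", 1:n), unit_basis = "fat_basis")
  recs[fa_trait_names()] <- as.data.frame(x)
  proj <- fit_reference_projection(recs, 0.95)
  expect_equal(proj$n_pc, 2)
  expect_lt(max(abs(proj$score_mean)), 1e-8)
  # loadings orthonormal
  g <- crossprod(proj$loadings)
  expect_lt(max(abs(g - diag(proj$n_pc))), 1e-8)
  # self-consistency: projecting the fitting data reproduces stored scores
  expect_lt(max(abs(project_records(recs, proj) - proj$scores)), 1e-10)
  # constant trait rejected
  recs2 <- recs; recs2$C4 <- 1
  expect_error(fit_reference_projection(recs2), "zero SD")
})

test_that("projection maps the reference center to the origin and freezes", {
  pop <- small_population()
  proj <- fit_reference_projection(pop$records)
  center <- pop$records[1, ]
  center[fa_trait_names()] <- as.list(proj$center)
  expect_lt(max(abs(project_records(center, proj))), 1e-10)
  expect_error(project_records(center[, setdiff(colnames(center), "C4")],
                               proj), "C4")
})

test_that("GH is the scaled Mahalanobis distance with its closed-form cases", {
  fakeproj <- structure(list(n_pc = 6, score_mean = rep(0, 6),
                             score_cov = diag(6),
                             score_cov_inv = diag(6)),
                        class = "reference_projection")
  expect_equal(compute_gh(matrix(0, 1, 6), fakeproj)$gh, 0)
  expect_equal(compute_gh(matrix(1, 1, 6), fakeproj)$gh, 1)
  expect_error(compute_gh(matrix(1, 1, 5), fakeproj), "dimension")
})

test_that("GH is invariant under a consistent orthonormal rotation", {
  set.seed(33)
  s <- matrix(rnorm(200 * 4), 200, 4)
  q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  mk <- function(scores) {
    cv <- stats::cov(scores)
    structure(list(n_pc = 4, score_mean = colMeans(scores),
                   score_cov = cv, score_cov_inv = solve(cv)),
              class = "reference_projection")
  }
  gh1 <- compute_gh(s, mk(s))$gh
  gh2 <- compute_gh(s %*% q, mk(s %*% q))$gh
  expect_equal(gh1, gh2, tolerance = 1e-10)
})

test_that("mean GH is about 1 on a large Gaussian reference", {
  set.seed(77)
  n <- 50000
  x <- matrix(rnorm(n * 31), n, 31) %*%
    diag(seq(1, 3, length.out = 31))
  colnames(x) <- fa_trait_names()
  recs <- data.frame(record_id = paste0("r", seq_len(n)),
                     unit_basis = "fat_basis")
  recs[fa_trait_names()] <- as.data.frame(x)
  proj <- fit_reference_projection(recs)
  gh <- compute_gh(proj$scores, proj)$gh
  expect_lt(abs(mean(gh) - 1), 0.02)
  expect_true(all(gh >= 0))
  # extreme compositions are rare in a well-behaved Gaussian reference
  expect_lt(mean(gh > 5), 0.001)
})

test_that("a projection round-trips exactly through JSON", {
  pop <- small_population()
  proj <- fit_reference_projection(pop$records)
  path <- tempfile(fileext = ".json")
  write_projection(proj, path)
  back <- read_projection(path)
  expect_identical(back$loadings, proj$loadings)
  expect_identical(back$center, proj$center)
  expect_identical(back$n_pc, proj$n_pc)
  expect_equal(project_records(pop$records, back),
               project_records(pop$records, proj), tolerance = 0)
})
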