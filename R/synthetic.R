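#' Construct a latent herd-state model
#'
#' A herd state is a multivariate-Gaussian profile over the 39 modeled
#' traits: mean vector plus positive-definite covariance. States are the
#' generator-side truth that the clustering stage is later asked to recover.
#'
#' @param state_id Integer label, unique and contiguous from 1 within a set.
#' @param mean Named numeric vector over the modeled traits. Fatty-acid
#'   components must be non-negative (g/100 g fat).
#' @param covariance Symmetric positive-definite matrix over the same traits.
#' @return An object of class `state_model`.
#' @export
state_model <- function(state_id, mean, covariance) {
  stopifnot(length(state_id) == 1L, is.numeric(mean), is.matrix(covariance))
  if (is.null(names(mean))) stop("state mean must be a named vector")
  if (!identical(dim(covariance), c(length(mean), length(mean))))
    stop("covariance dimension does not match mean length")
  fa <- intersect(names(mean), fa_trait_names())
  if (any(mean[fa] < 0)) stop("fatty-acid state means must be non-negative")
  if (max(abs(covariance - t(covariance))) > 1e-8)
    stop("covariance must be symmetric")
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("covariance must be positive-definite (degenerate covariance)")
  structure(list(state_id = as.integer(state_id), mean = mean,
                 covariance = covariance),
            class = "state_model")
}

#' Build Gaussian state models from per-state means and population SDs
#'
#' Within-state covariance is `D %*% C %*% D` where `D` is diagonal with
#' entries `within_state_sd_fraction * sd_table[trait]` and `C` is the
#' supplied trait correlation (identity when absent). A non-positive-definite
#' correlation is repaired to the nearest positive-definite matrix.
#'
#' @param mean_table Matrix or data frame, one row per state, columns named
#'   by trait (e.g. [walloon_state_means()]).
#' @param sd_table Named numeric vector of per-trait population SDs
#'   (e.g. [walloon_trait_sds()]).
#' @param within_state_sd_fraction Scalar in (0, 1]: within-state SD as a
#'   fraction of the population SD. Default 0.5, so that between-state
#'   spread dominates within-state spread.
#' @param correlation Optional trait correlation matrix shared by all states.
#' @return List of [state_model()] objects, one per row of `mean_table`.
#' @export
make_state_models <- function(mean_table, sd_table,
                              within_state_sd_fraction = 0.5,
                              correlation = NULL) {
  mean_table <- as.matrix(mean_table)
  if (!(within_state_sd_fraction > 0 && within_state_sd_fraction <= 1))
    stop("within_state_sd_fraction must lie in (0, 1]")
  traits <- colnames(mean_table)
  if (is.null(traits) || is.null(names(sd_table)))
    stop("mean_table columns and sd_table must be named by trait")
  if (!all(traits %in% names(sd_table)))
    stop("trait-name mismatch: SDs missing for ",
         paste(setdiff(traits, names(sd_table)), collapse = ", "))
  sds <- within_state_sd_fraction * sd_table[traits]
  if (any(sds <= 0)) stop("degenerate covariance: zero or negative trait SD")
  if (is.null(correlation)) {
    correlation <- diag(length(traits))
    dimnames(correlation) <- list(traits, traits)
  } else {
    correlation <- as.matrix(correlation)[traits, traits]
    ev <- eigen((correlation + t(correlation)) / 2, symmetric = TRUE,
                only.values = TRUE)$values
    if (min(ev) <= 1e-10) {
      rep <- Matrix::nearPD(correlation, corr = TRUE)
      if (!rep$converged)
        stop("correlation matrix is not positive-definite and could not be repaired")
      correlation <- as.matrix(rep$mat)
    }
  }
  covariance <- diag(sds) %*% correlation %*% diag(sds)
  dimnames(covariance) <- list(traits, traits)
  covariance <- (covariance + t(covariance)) / 2
  lapply(seq_len(nrow(mean_table)), function(i) {
    m <- mean_table[i, ]
    names(m) <- traits
    state_model(i, m, covariance)
  })
}

#' Simulation configuration for the synthetic bulk-tank generator
#'
#' @param n_herds Number of herds to simulate.
#' @param horizon_days Length of the simulated period in days (>= 1).
#' @param transition Row-stochastic state-transition matrix used as
#'   generator truth (rows must sum to 1 within 1e-9). Default:
#'   [walloon_transition_matrix()].
#' @param sampling_probs Probabilities of an inter-sample gap of 1, 2 or 3
#'   days (bulk tanks are collected every 1-3 days). Default uniform.
#' @param initial_distribution Distribution of the state of the first
#'   record; default uniform over states.
#' @param artifact_rates Named per-row probabilities for the three artifact
#'   types `missing`, `range` (fat/protein out of bounds) and `negative_fa`.
#' @param start_date First sampling date.
#' @param seed Integer seed governing every random draw.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_herds = 50, horizon_days = 365,
                       transition = walloon_transition_matrix(),
                       sampling_probs = c(1, 1, 1) / 3,
                       initial_distribution = NULL,
                       artifact_rates = c(missing = 0, range = 0,
                                          negative_fa = 0),
                       start_date = as.Date("2021-01-01"),
                       seed = 1L) {
  stopifnot(n_herds >= 1, horizon_days >= 1, length(sampling_probs) == 3,
            all(sampling_probs >= 0), sum(sampling_probs) > 0)
  transition <- as.matrix(transition)
  if (any(abs(rowSums(transition) - 1) > 1e-9))
    stop("transition rows must sum to 1 within 1e-9")
  rates <- c(missing = 0, range = 0, negative_fa = 0)
  rates[names(artifact_rates)] <- artifact_rates
  if (any(rates < 0 | rates > 1)) stop("artifact rates must lie in [0, 1]")
  if (!is.null(initial_distribution)) {
    stopifnot(length(initial_distribution) == nrow(transition),
              all(initial_distribution >= 0),
              abs(sum(initial_distribution) - 1) < 1e-9)
  }
  structure(list(n_herds = as.integer(n_herds),
                 horizon_days = as.integer(horizon_days),
                 transition = transition,
                 sampling_probs = sampling_probs / sum(sampling_probs),
                 initial_distribution = initial_distribution,
                 artifact_rates = rates,
                 start_date = as.Date(start_date),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Draw a latent Markov state path of length n.
markov_path <- function(n, transition, initial) {
  k <- nrow(transition)
  s <- integer(n)
  s[1] <- sample.int(k, 1, prob = initial)
  if (n > 1) for (i in 2:n) s[i] <- sample.int(k, 1, prob = transition[s[i - 1], ])
  s
}

#' Simulate one herd's bulk-tank record series
#'
#' Sampling dates advance by gaps of 1-3 days; the latent state follows the
#' configured Markov chain; each record is drawn from the current state's
#' Gaussian in the fat-basis trait space (fatty acids truncated at 0) and
#' emitted on the milk basis (`fa_milk = fa_fat * fat / 100`, the inverse of
#' the downstream unit conversion).
#'
#' @param states List of [state_model()] objects.
#' @param config A [sim_config()]; its `transition` dimension must equal
#'   `length(states)`.
#' @param herd_id Identifier for the herd.
#' @param seed Optional integer; when supplied the RNG is seeded on entry
#'   (population-level simulation seeds once and leaves this `NULL`).
#' @return List with `records` (milk-basis record data frame) and `truth`
#'   (data frame of `record_id`, `herd_id`, `date`, `state_id`).
#' @export
simulate_herd_series <- function(states, config, herd_id, seed = NULL) {
  if (length(states) == 0) stop("empty state list")
  k <- length(states)
  if (nrow(config$transition) != k)
    stop("transition dimension does not match number of states")
  if (config$horizon_days < 1) stop("horizon too short for one record")
  if (!is.null(seed)) set.seed(seed)
  gaps <- sample(1:3, config$horizon_days, replace = TRUE,
                 prob = config$sampling_probs)
  offsets <- c(0, cumsum(gaps))
  offsets <- offsets[offsets < config$horizon_days]
  n <- length(offsets)
  dates <- config$start_date + offsets
  init <- config$initial_distribution
  if (is.null(init)) init <- rep(1 / k, k)
  path <- markov_path(n, config$transition, init)

  traits <- names(states[[1]]$mean)
  draws <- matrix(NA_real_, n, length(traits), dimnames = list(NULL, traits))
  for (s in seq_len(k)) {
    idx <- which(path == s)
    if (length(idx))
      draws[idx, ] <- MASS::mvrnorm(length(idx), states[[s]]$mean,
                                    states[[s]]$covariance)
  }
  fa <- intersect(traits, fa_trait_names())
  draws[, fa] <- pmax(draws[, fa, drop = FALSE], 0)
  has_fat <- "fat" %in% traits

  rec <- data.frame(record_id = sprintf("%s_%05d", herd_id, seq_len(n)),
                    herd_id = herd_id, date = dates,
                    unit_basis = "milk_basis",
                    stringsAsFactors = FALSE)
  if (has_fat) {
    # states are specified in the fat basis; emit milk-basis concentrations
    fat <- pmax(draws[, "fat"], 1e-3)
    rec[fa] <- draws[, fa, drop = FALSE] * fat / 100
    rec$fat <- fat
  } else {
    rec[fa] <- draws[, fa, drop = FALSE]
  }
  other <- setdiff(traits, c(fa, "fat"))
  rec[other] <- draws[, other, drop = FALSE]
  truth <- data.frame(record_id = rec$record_id, herd_id = herd_id,
                      date = dates, state_id = path,
                      stringsAsFactors = FALSE)
  list(records = rec, truth = truth)
}

#' Simulate a multi-herd bulk-tank population
#'
#' Batched [simulate_herd_series()] over `config$n_herds` herds, fully
#' reproducible from `config$seed`. Artifacts are injected afterwards at the
#' configured rates via [inject_artifacts()].
#'
#' @param states List of [state_model()] objects.
#' @param config A [sim_config()].
#' @param herd_prefix Prefix for generated herd identifiers.
#' @return List with `records`, `truth`, and `artifact_log` (empty when all
#'   artifact rates are zero).
#' @export
simulate_population <- function(states, config, herd_prefix = "herd") {
  set.seed(config$seed)
  out <- vector("list", config$n_herds)
  for (i in seq_len(config$n_herds)) {
    hid <- sprintf("%s%04d", herd_prefix, i)
    out[[i]] <- simulate_herd_series(states, config, hid)
  }
  records <- do.call(rbind, lapply(out, `[[`, "records"))
  truth <- do.call(rbind, lapply(out, `[[`, "truth"))
  rownames(records) <- rownames(truth) <- NULL
  art <- inject_artifacts(records, config$artifact_rates,
                          seed = config$seed + 104729L)
  list(records = art$records, truth = truth, artifact_log = art$log)
}

#' Inject data artifacts into a record table
#'
#' Reproduces the defects the cleaning stage must remove: fat or protein
#' outside the plausible bulk-tank range, a negative fatty-acid value, or a
#' missing studied trait. Each artifact type is applied independently to a
#' Bernoulli-selected fraction of rows.
#'
#' @param records Milk-basis record data frame.
#' @param artifact_rates Named probabilities for `missing`, `range` and
#'   `negative_fa`, each in \[0, 1\].
#' @param seed Integer seed.
#' @return List with the perturbed `records` and a `log` data frame
#'   (`record_id`, `type`, `column`).
#' @export
inject_artifacts <- function(records, artifact_rates, seed = 1L) {
  rates <- c(missing = 0, range = 0, negative_fa = 0)
  rates[names(artifact_rates)] <- artifact_rates
  if (any(rates < 0 | rates > 1)) stop("artifact rates must lie in [0, 1]")
  set.seed(seed)
  n <- nrow(records)
  fa <- intersect(colnames(records), fa_trait_names())
  studied <- c(fa, "fat", "protein",
               intersect(colnames(records), aux_trait_names()))
  log <- list()

  pick <- function(rate) which(stats::runif(n) < rate)

  idx <- pick(rates["range"])
  if (length(idx)) {
    low <- stats::runif(length(idx)) < 0.5
    col <- ifelse(stats::runif(length(idx)) < 0.5, "fat", "protein")
    for (j in seq_along(idx)) {
      if (col[j] == "fat")
        records$fat[idx[j]] <- if (low[j]) stats::runif(1, 0.2, 1.4)
                               else stats::runif(1, 9.1, 12)
      else
        records$protein[idx[j]] <- if (low[j]) stats::runif(1, 0.1, 0.9)
                                   else stats::runif(1, 7.1, 9)
    }
    log[["range"]] <- data.frame(record_id = records$record_id[idx],
                                 type = "range", column = col,
                                 stringsAsFactors = FALSE)
  }
  idx <- pick(rates["negative_fa"])
  if (length(idx)) {
    col <- sample(fa, length(idx), replace = TRUE)
    for (j in seq_along(idx))
      records[idx[j], col[j]] <- -abs(records[idx[j], col[j]]) -
        stats::runif(1, 0.001, 0.05)
    log[["negative_fa"]] <- data.frame(record_id = records$record_id[idx],
                                       type = "negative_fa", column = col,
                                       stringsAsFactors = FALSE)
  }
  idx <- pick(rates["missing"])
  if (length(idx)) {
    col <- sample(studied, length(idx), replace = TRUE)
    for (j in seq_along(idx)) records[idx[j], col[j]] <- NA_real_
    log[["missing"]] <- data.frame(record_id = records$record_id[idx],
                                   type = "missing", column = col,
                                   stringsAsFactors = FALSE)
  }
  log <- if (length(log)) do.call(rbind, unname(log))
         else data.frame(record_id = character(), type = character(),
                         column = character(), stringsAsFactors = FALSE)
  rownames(log) <- NULL
  list(records = records, log = log)
}

#' Simulate mid-infrared-like spectral features for records
#'
#' Emulates first-derivative spectral points as a fixed random linear image
#' of the fatty-acid trait vector plus iid Gaussian noise:
#' `spectrum = traits %*% W + eps`. The loading matrix `W` is drawn once
#' from the seed and shared by all records, so the trait-to-spectrum map is
#' invertible in expectation. These are statistical stand-ins, not physical
#' spectra.
#'
#' @param records Record data frame containing the 31 fatty-acid columns.
#' @param n_points Number of spectral points (>= number of FA traits).
#' @param noise_sd Non-negative SD of the additive noise.
#' @param seed Integer seed (governs both `W` and the noise).
#' @return Data frame with `record_id` and columns `sp001..sp<n_points>`.
#' @export
simulate_spectra <- function(records, n_points = 212, noise_sd = 0.1,
                             seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  fa <- fa_trait_names()
  if (!all(fa %in% colnames(records))) stop("records lack fatty-acid columns")
  if (n_points < length(fa))
    stop("n_points must be at least the number of fatty-acid traits")
  x <- as.matrix(records[, fa])
  set.seed(seed)
  w <- matrix(stats::rnorm(length(fa) * n_points, sd = 0.3),
              nrow = length(fa))
  sp <- x %*% w
  if (noise_sd > 0)
    sp <- sp + matrix(stats::rnorm(length(sp), sd = noise_sd), nrow = nrow(sp))
  colnames(sp) <- sprintf("sp%03d", seq_len(n_points))
  cbind(data.frame(record_id = records$record_id, stringsAsFactors = FALSE),
        as.data.frame(sp))
}
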