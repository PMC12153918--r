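#' Default end-to-end run configuration
#'
#' Bundles every stage parameter (seeds, thresholds, strata plan, k window,
#' classifier settings, flag map) into one serializable list. The default
#' sizes are chosen so a complete synthetic run finishes in well under a
#' minute; scale `sim` up for study-sized runs.
#'
#' @param seed Master seed; every stochastic stage derives its seed from it.
#' @param outdir Output directory for stage artifacts (created if needed).
#' @param n_herds,horizon_days Synthetic population size.
#' @param per_stratum_n Draw size per bounded GH stratum.
#' @param artifact_rates Generator artifact rates (see [sim_config()]).
#' @param n_projected_herds Herds in the optional second (projected)
#'   population scored with the frozen reference models; 0 disables it.
#' @param cv_folds Cross-validation folds for the classifier.
#' @param n_trees Random-forest size.
#' @return Nested configuration list.
#' @export
default_run_config <- function(seed = 1L, outdir = tempfile("milkstate_run"),
                               n_herds = 40, horizon_days = 150,
                               per_stratum_n = 800,
                               artifact_rates = c(missing = 0.01,
                                                  range = 0.01,
                                                  negative_fa = 0.01),
                               n_projected_herds = 0,
                               cv_folds = 5, n_trees = 300) {
  list(mode = "synthetic",
       seed = as.integer(seed),
       outdir = outdir,
       sim = list(n_herds = n_herds, horizon_days = horizon_days,
                  artifact_rates = artifact_rates),
       within_state_sd_fraction = 0.5,
       variance_threshold = 0.95,
       strata = list(boundaries = c(0, 1, 2, 3),
                     per_stratum_n = per_stratum_n),
       k_min = 2, k_max = 15,
       classifier = list(kind = "random_forest", n_trees = n_trees,
                         cv_folds = cv_folds),
       flag_map = default_flag_map(),
       n_projected_herds = n_projected_herds)
}

write_stage_csv <- function(df, outdir, name) {
  path <- file.path(outdir, name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full monitoring pipeline from one configuration
#'
#' Executes, in order: simulate (or ingest) -> clean -> unit conversion ->
#' reference PCA + GH scoring -> GH-stratified subsampling -> Ward.D2
#' clustering with gap-rule k selection -> supervised re-prediction of
#' cluster labels -> membership prediction for all records -> transition
#' dynamics -> cluster summary and alert flags. Every intermediate table is
#' written to `config$outdir` and hashed into the run manifest; identical
#' configurations yield identical hashes.
#'
#' @param config A [default_run_config()]-style list. For `mode = "csv"`,
#'   `config$input_csv` must point to a milk-basis record table.
#' @return Invisible list with the main in-memory artifacts (`records`,
#'   `projection`, `gh`, `subset`, `tree`, `k`, `labels`, `model`,
#'   `predictions`, `transitions`, `summary`, `flags`, `manifest`) plus
#'   `projected` when a second population was requested.
#' @export
run_pipeline <- function(config = default_run_config()) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = config, stages = list())
  files <- character(0)
  note <- function(stage, rows, params = list()) {
    manifest$stages[[stage]] <<- list(rows = rows, params = params)
  }

  # --- stage 1: input -------------------------------------------------
  states <- make_state_models(walloon_state_means(), walloon_trait_sds(),
                              config$within_state_sd_fraction)
  if (identical(config$mode, "synthetic")) {
    sim <- sim_config(n_herds = config$sim$n_herds,
                      horizon_days = config$sim$horizon_days,
                      artifact_rates = config$sim$artifact_rates,
                      seed = config$seed)
    pop <- simulate_population(states, sim)
    records <- pop$records
    files["records"] <- write_stage_csv(records, config$outdir, "records.csv")
    files["truth"] <- write_stage_csv(pop$truth, config$outdir, "truth.csv")
  } else if (identical(config$mode, "csv")) {
    records <- utils::read.csv(config$input_csv, stringsAsFactors = FALSE)
    records$date <- as.Date(records$date)
    needed <- c("record_id", "herd_id", "date", "unit_basis",
                fa_trait_names(), "fat", "protein")
    missing <- setdiff(needed, colnames(records))
    if (length(missing))
      stop("input table lacks column(s): ", paste(missing, collapse = ", "))
    pop <- list(truth = NULL)
  } else stop("unknown input mode: ", config$mode)
  note("input", nrow(records))

  # --- stage 2: clean + convert --------------------------------------
  cleaned <- clean_records(records)
  if (nrow(cleaned$kept) + nrow(cleaned$log) != nrow(records))
    stop("cleaning ledger not conserved")
  fat_basis <- convert_to_fat_basis(cleaned$kept)
  files["cleaning_log"] <- write_stage_csv(cleaned$log, config$outdir,
                                           "cleaning_log.csv")
  note("clean", nrow(cleaned$kept),
       list(rejected = nrow(cleaned$log)))

  # --- stage 3: reference projection + GH ----------------------------
  projection <- fit_reference_projection(fat_basis,
                                         config$variance_threshold)
  gh <- compute_gh(projection$scores, projection)
  gh$record_id <- fat_basis$record_id
  files["gh"] <- write_stage_csv(gh, config$outdir, "gh.csv")
  note("gh", nrow(gh), list(n_pc = projection$n_pc,
                            explained = projection$explained_fraction))

  # --- stage 4: stratified subsample ---------------------------------
  plan <- strata_plan(boundaries = config$strata$boundaries,
                      per_stratum_n = config$strata$per_stratum_n,
                      seed = config$seed + 1L)
  sub <- stratified_subsample(gh[, c("record_id", "gh")], plan)
  if (!all(sub$keys %in% fat_basis$record_id))
    stop("subset is not contained in the cleaned records")
  files["subset"] <- write_stage_csv(data.frame(record_id = sub$keys),
                                     config$outdir, "subset_keys.csv")
  note("subsample", length(sub$keys),
       list(report = sub$report$drawn))

  # --- stage 5: cluster ----------------------------------------------
  subset_rows <- fat_basis[match(sub$keys, fat_basis$record_id), ]
  feats <- as.matrix(subset_rows[, fa_trait_names()])
  rownames(feats) <- subset_rows$record_id
  tree <- ward_linkage(feats)
  sel <- select_k(tree, config$k_min, config$k_max)
  raw_labels <- cut_tree(tree, sel$k)
  rel <- relabel_by_size(raw_labels)
  labels <- rel$labels
  files["linkage"] <- write_stage_csv(
    as.data.frame(tree$merges), config$outdir, "linkage.csv")
  files["labels"] <- write_stage_csv(
    data.frame(record_id = names(labels), cluster = as.integer(labels)),
    config$outdir, "cluster_labels.csv")
  note("cluster", length(labels), list(k = sel$k))

  # --- stage 6: classify ---------------------------------------------
  model <- if (identical(config$classifier$kind, "plsda")) {
    fit_plsda(feats, labels, cv_folds = config$classifier$cv_folds,
              seed = config$seed + 2L)
  } else {
    fit_random_forest(feats, labels,
                      n_trees = config$classifier$n_trees,
                      cv_folds = config$classifier$cv_folds,
                      seed = config$seed + 2L)
  }
  jsonlite::write_json(
    list(kind = model$kind, accuracy = model$cv$accuracy,
         kappa = model$cv$kappa),
    file.path(config$outdir, "classifier_metrics.json"),
    auto_unbox = TRUE, digits = NA)
  files["classifier_metrics"] <- file.path(config$outdir,
                                           "classifier_metrics.json")
  note("classify", nrow(feats),
       list(kind = model$kind, accuracy = model$cv$accuracy,
            kappa = model$cv$kappa))

  # --- stage 7: predict all records ----------------------------------
  all_feats <- as.matrix(fat_basis[, fa_trait_names()])
  pred <- predict_membership(model, all_feats)
  predictions <- data.frame(record_id = fat_basis$record_id,
                            herd_id = fat_basis$herd_id,
                            date = fat_basis$date,
                            stringsAsFactors = FALSE)
  k <- length(model$classes)
  predictions[paste0("p", 1:k)] <- as.data.frame(pred$probabilities)
  predictions$label <- pred$labels
  files["predictions"] <- write_stage_csv(predictions, config$outdir,
                                          "predictions.csv")
  note("predict", nrow(predictions))

  # --- stage 8: dynamics ---------------------------------------------
  tm <- transition_matrix(data.frame(herd_id = predictions$herd_id,
                                     date = predictions$date,
                                     label = predictions$label), k = k)
  files["transitions"] <- write_stage_csv(
    as.data.frame(round(100 * tm$probabilities, 2)), config$outdir,
    "transitions_percent.csv")
  note("dynamics", tm$n_transitions)

  # --- stage 9: interpret --------------------------------------------
  summ <- summarize_clusters(fat_basis, predictions$label)
  flags <- flag_records(predictions$label, config$flag_map)
  flag_table <- cbind(predictions[, c("record_id", "herd_id", "date",
                                      paste0("p", 1:k), "label")],
                      flag = flags)
  files["summary_means"] <- write_stage_csv(
    as.data.frame(summ$means), config$outdir, "cluster_summary_means.csv")
  files["flags"] <- write_stage_csv(flag_table, config$outdir, "alerts.csv")
  note("interpret", nrow(flag_table),
       list(flag_counts = as.list(table(flags))))

  # --- optional projected population ---------------------------------
  projected <- NULL
  if (config$n_projected_herds > 0) {
    sim2 <- sim_config(n_herds = config$n_projected_herds,
                       horizon_days = config$sim$horizon_days,
                       artifact_rates = config$sim$artifact_rates,
                       seed = config$seed + 10L)
    pop2 <- simulate_population(states, sim2, herd_prefix = "proj")
    cl2 <- clean_records(pop2$records)
    fb2 <- convert_to_fat_basis(cl2$kept)
    sc2 <- project_records(fb2, projection)
    gh2 <- compute_gh(sc2, projection)
    pr2 <- predict_membership(model, as.matrix(fb2[, fa_trait_names()]))
    proj_pred <- data.frame(record_id = fb2$record_id,
                            herd_id = fb2$herd_id, date = fb2$date,
                            label = pr2$labels)
    tm2 <- transition_matrix(proj_pred, k = k)
    projected <- list(records = fb2, gh = gh2, predictions = proj_pred,
                      transitions = tm2, truth = pop2$truth)
    files["projected_predictions"] <- write_stage_csv(
      proj_pred, config$outdir, "projected_predictions.csv")
    note("project_population", nrow(fb2))
  }

  manifest$files <- as.list(stats::setNames(
    unname(tools::md5sum(files)), names(files)))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  invisible(list(records = fat_basis, truth = pop$truth,
                 cleaning_log = cleaned$log,
                 projection = projection, gh = gh, subset = sub,
                 tree = tree, k = sel$k, labels = labels, model = model,
                 predictions = predictions, transitions = tm,
                 summary = summ, flags = flag_table,
                 projected = projected, manifest = manifest))
}
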