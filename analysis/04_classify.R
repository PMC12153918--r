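#!/usr/bin/env Rscript
# Stage 4 — supervised re-prediction of cluster labels.
#
# PLS-DA (CV-selected components, max 30) and a 500-tree Gini random
# forest (CV-tuned feature count) are cross-validated on the labeled
# subset, on the fatty-acid traits and on first-derivative spectra. The
# best model then scores every record with membership probabilities.

suppressMessages(library(milkstate))
outdir <- "results/analysis"
records <- read.csv(file.path(outdir, "records_fat_basis.csv"))
labels_df <- read.csv(file.path(outdir, "cluster_labels.csv"))
spectra <- read.csv(file.path(outdir, "spectra.csv"))

subset_rows <- records[match(labels_df$record_id, records$record_id), ]
feats <- as.matrix(subset_rows[, fa_trait_names()])
labels <- labels_df$cluster

pls <- fit_plsda(feats, labels, max_components = 30, cv_folds = 10,
                 seed = 20260903L)
cat(sprintf("PLS-DA (traits): %d components, CV accuracy %.2f %%, kappa %.2f %%\n",
            pls$n_components, 100 * pls$cv$accuracy, 100 * pls$cv$kappa))

rf <- fit_random_forest(feats, labels, n_trees = 500, cv_folds = 10,
                        seed = 20260903L)
cat(sprintf("random forest (traits): mtry %d, CV accuracy %.2f %%, kappa %.2f %%\n",
            rf$mtry, 100 * rf$cv$accuracy, 100 * rf$cv$kappa))

dsp <- first_derivative(spectra)
dmat <- as.matrix(dsp[match(labels_df$record_id, dsp$record_id), -1])
rf_sp <- fit_random_forest(dmat, labels, n_trees = 500,
                           mtry_grid = floor(sqrt(ncol(dmat))),
                           cv_folds = 10, seed = 20260903L,
                           feature_space = "spectra_first_derivative")
cat(sprintf("random forest (spectra): CV accuracy %.2f %%\n",
            100 * rf_sp$cv$accuracy))
cat(sprintf("ordering: PLS-DA %.1f %% < RF-spectra %.1f %% <= RF-traits %.1f %%\n",
            100 * pls$cv$accuracy, 100 * rf_sp$cv$accuracy,
            100 * rf$cv$accuracy))

write.csv(as.data.frame(rf$cv$confusion),
          file.path(outdir, "rf_confusion.csv"))
jsonlite::write_json(
  list(plsda = list(n_components = pls$n_components,
                    accuracy = pls$cv$accuracy, kappa = pls$cv$kappa),
       random_forest = list(mtry = rf$mtry, accuracy = rf$cv$accuracy,
                            kappa = rf$cv$kappa),
       random_forest_spectra = list(accuracy = rf_sp$cv$accuracy,
                                    kappa = rf_sp$cv$kappa)),
  file.path(outdir, "classifier_metrics.json"), auto_unbox = TRUE,
  digits = NA)

# score every record with the strongest model (tree-vote probabilities)
pred <- predict_membership(rf, as.matrix(records[, fa_trait_names()]))
predictions <- records[, c("record_id", "herd_id", "date")]
k <- length(rf$classes)
predictions[paste0("p", 1:k)] <- as.data.frame(pred$probabilities)
predictions$label <- pred$labels
write.csv(predictions, file.path(outdir, "predictions.csv"),
          row.names = FALSE)
cat(sprintf("scored %d records with the %d-state forest\n",
            nrow(predictions), k))
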