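#!/usr/bin/env Rscript
# Stage 6 — cluster interpretation and the traffic-light alert layer.
#
# Summarizes traits by predicted cluster (favorability ranks under the
# shipped orientation config), correlates membership probabilities with
# traits, and assembles per-herd probability time series with
# green/orange/red flags and the consecutive-run alert.

suppressMessages(library(milkstate))
outdir <- "results/analysis"
records <- read.csv(file.path(outdir, "records_fat_basis.csv"))
records$date <- as.Date(records$date)
predictions <- read.csv(file.path(outdir, "predictions.csv"))
predictions$date <- as.Date(predictions$date)

summ <- summarize_clusters(records, predictions$label)
cat("per-cluster C18:1 cis-9 means (fat-mobilization marker):\n")
print(round(summ$means["C18_1cis9", ], 2))
write.csv(as.data.frame(summ$means),
          file.path(outdir, "cluster_summary_means.csv"))
write.csv(as.data.frame(summ$sds),
          file.path(outdir, "cluster_summary_sds.csv"))

pcols <- grep("^p[0-9]+$", colnames(predictions), value = TRUE)
prob <- as.matrix(predictions[, pcols])
colnames(prob) <- sub("^p", "", pcols)
traits <- as.matrix(records[, c(fa_trait_names(), "thi")])
corr <- probability_trait_correlations(prob, traits)
write.csv(round(corr, 3), file.path(outdir, "probability_correlations.csv"))

flags <- flag_records(predictions$label)
cat("flag distribution over all records:\n"); print(table(flags))

# one herd's monitoring series with the 2-run alert
herd <- predictions$herd_id[1]
series <- probability_series(predictions, herd)
cat(sprintf("herd %s: %d records, %d alert days\n",
            herd, nrow(series), sum(series$alert)))
alerts <- cbind(predictions[, c("record_id", "herd_id", "date")],
                label = predictions$label, flag = flags)
write.csv(alerts, file.path(outdir, "alerts.csv"), row.names = FALSE)
write.csv(as.data.frame(series), file.path(outdir, "example_series.csv"),
          row.names = FALSE)
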