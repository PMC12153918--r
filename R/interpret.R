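#' Default trait orientation (is a high value favorable?)
#'
#' Expert-judgment defaults for ranking cluster means: `TRUE` means high
#' values are favorable. De novo fatty acids, fat, protein, yield, energy
#' balance, nitrogen efficiency and intake are treated as
#' higher-is-better; mobilization and stress markers (long-chain and trans
#' fatty acids, blood BHB, blood free fatty acids) as lower-is-better.
#' These are editable conventions, not formulas — pass your own named
#' logical vector to override any entry.
#'
#' @return Named logical vector over the 39 modeled traits.
#' @export
default_trait_orientation <- function() {
  high_good <- c("C4", "C6", "C8", "C10", "C12", "C14", "C14_1cis9",
                 "C16", "SFA", "SCFA", "MCFA", "fat", "protein",
                 "milk_yield", "energy_balance", "nitrogen_efficiency",
                 "DMI", "omega3")
  traits <- c(fa_trait_names(), "fat", "protein", aux_trait_names())
  stats::setNames(traits %in% high_good, traits)
}

#' Default cluster-to-flag alert map
#'
#' Traffic-light mapping of the seven herd states: the consistently
#' abnormal state 3 is red; the stress-related states 2, 5 and 6 are
#' orange; states 1, 4 and 7 (the population standards) are green. The map
#' is remappable because cluster numbering depends on the fitted model.
#'
#' @return Named character vector (`"1"`..`"7"` -> flag).
#' @export
default_flag_map <- function() {
  c(`1` = "green", `2` = "orange", `3` = "red", `4` = "green",
    `5` = "orange", `6` = "orange", `7` = "green")
}

#' Summarize traits by cluster with favorability ranking
#'
#' Per-cluster means and SDs for every trait, ranks under the supplied
#' orientation (rank 1 = most favorable) and the best-two / worst-two
#' cluster sets per trait.
#'
#' @param records Record data frame carrying the traits.
#' @param labels Integer cluster labels aligned with `records`.
#' @param trait_orientation Named logical vector (TRUE = high is good);
#'   default [default_trait_orientation()] restricted to available traits.
#' @return Object of class `cluster_summary`: `means`, `sds` (trait x
#'   cluster matrices), `ranks`, `best_two`, `worst_two`, `empty_clusters`.
#' @export
summarize_clusters <- function(records, labels, trait_orientation = NULL) {
  stopifnot(nrow(records) == length(labels))
  traits <- intersect(c(fa_trait_names(), "fat", "protein",
                        aux_trait_names(), "thi"), colnames(records))
  ori <- default_trait_orientation()
  if ("thi" %in% traits) ori <- c(ori, thi = FALSE)
  if (!is.null(trait_orientation))  # partial overrides merge over defaults
    ori[names(trait_orientation)] <- trait_orientation
  trait_orientation <- ori
  k <- max(labels)
  clusters <- 1:k
  means <- sds <- matrix(NA_real_, length(traits), k,
                         dimnames = list(traits, paste0("cluster", clusters)))
  for (cl in clusters) {
    sel <- labels == cl
    if (!any(sel)) next
    x <- records[sel, traits, drop = FALSE]
    means[, cl] <- vapply(x, mean, numeric(1), na.rm = TRUE)
    sds[, cl] <- vapply(x, function(v) if (sum(!is.na(v)) < 2) NA_real_
                        else stats::sd(v, na.rm = TRUE), numeric(1))
  }
  empty <- clusters[!clusters %in% unique(labels)]
  ranks <- matrix(NA_integer_, length(traits), k, dimnames = dimnames(means))
  best_two <- worst_two <- vector("list", length(traits))
  names(best_two) <- names(worst_two) <- traits
  for (t in traits) {
    good_high <- isTRUE(trait_orientation[[t]])
    v <- means[t, ]
    r <- rank(if (good_high) -v else v, ties.method = "first",
              na.last = "keep")
    ranks[t, ] <- as.integer(r)
    ok <- which(!is.na(r))
    best_two[[t]] <- unname(ok[order(r[ok])][seq_len(min(2, length(ok)))])
    worst_two[[t]] <- unname(ok[order(-r[ok])][seq_len(min(2, length(ok)))])
  }
  structure(list(means = means, sds = sds, ranks = ranks,
                 best_two = best_two, worst_two = worst_two,
                 orientation = trait_orientation[traits],
                 empty_clusters = empty),
            class = "cluster_summary")
}

#' Flag records by cluster label or membership probability
#'
#' Default mode maps the hard label through `flag_map`. Threshold mode
#' additionally escalates: whenever the probability mass on any
#' red-mapped cluster exceeds `probability_threshold` the flag is red, and
#' likewise for orange, even if that cluster is not the argmax.
#'
#' @param labels_or_probabilities Integer label vector, or a row-stochastic
#'   probability matrix with one column per cluster (in cluster order).
#' @param flag_map Named character vector mapping cluster -> flag; default
#'   [default_flag_map()].
#' @param probability_threshold Optional scalar in (0, 1\]; enables
#'   threshold mode (requires probabilities).
#' @return Character vector of flags (`"green"`, `"orange"`, `"red"`).
#' @export
flag_records <- function(labels_or_probabilities,
                         flag_map = default_flag_map(),
                         probability_threshold = NULL) {
  prob <- NULL
  if (is.matrix(labels_or_probabilities)) {
    prob <- labels_or_probabilities
    labels <- max.col(prob, ties.method = "first")
  } else {
    labels <- as.integer(labels_or_probabilities)
  }
  unmapped <- setdiff(unique(labels), as.integer(names(flag_map)))
  if (length(unmapped))
    stop("unmapped cluster label(s): ", paste(unmapped, collapse = ", "))
  flags <- unname(flag_map[as.character(labels)])
  if (!is.null(probability_threshold)) {
    if (is.null(prob))
      stop("threshold mode requires a probability matrix")
    cl_of_col <- as.integer(colnames(prob) %||% seq_len(ncol(prob)))
    for (level in c("orange", "red")) {
      cols <- which(cl_of_col %in%
                      as.integer(names(flag_map)[flag_map == level]))
      if (!length(cols)) next
      hit <- apply(prob[, cols, drop = FALSE], 1,
                   function(p) any(p > probability_threshold))
      flags[hit] <- level
    }
  }
  flags
}

#' Assemble a herd's probability time series with alert flags
#'
#' Chronologically ordered membership-probability series for one herd,
#' with the hard label (argmax), the traffic-light flag, and a
#' consecutive-run alert: by default an alert is raised from the second
#' consecutive non-green record onward, since a single abnormal tank
#' sample is rarely conclusive.
#'
#' @param predictions Data frame with `herd_id`, `date` and probability
#'   columns `p1..pk` (row-stochastic).
#' @param herd_id Herd to extract.
#' @param flag_map Cluster-to-flag map; default [default_flag_map()].
#' @param probability_threshold Optional threshold-mode escalation, see
#'   [flag_records()].
#' @param alert_min_run Minimum run of consecutive non-green records that
#'   raises the alert (default 2).
#' @return Object of class `alert_series`: data frame with probabilities,
#'   `label`, `flag`, `alert`.
#' @export
probability_series <- function(predictions, herd_id,
                               flag_map = default_flag_map(),
                               probability_threshold = NULL,
                               alert_min_run = 2) {
  h <- predictions[predictions$herd_id == herd_id, , drop = FALSE]
  if (nrow(h) == 0) stop("no predictions for herd ", herd_id)
  if (anyDuplicated(h$date)) stop("duplicate herd-date keys for ", herd_id)
  h <- h[order(h$date), , drop = FALSE]
  pcols <- grep("^p[0-9]+$", colnames(h), value = TRUE)
  pcols <- pcols[order(as.integer(sub("^p", "", pcols)))]
  prob <- as.matrix(h[, pcols])
  colnames(prob) <- sub("^p", "", pcols)
  if (any(abs(rowSums(prob) - 1) > 1e-6))
    stop("probability rows must sum to 1")
  h$label <- max.col(prob, ties.method = "first")
  h$flag <- flag_records(prob, flag_map, probability_threshold)
  nongreen <- h$flag != "green"
  run <- Reduce(function(acc, x) if (x) acc + 1L else 0L,
                nongreen, accumulate = TRUE)
  h$alert <- run >= alert_min_run
  rownames(h) <- NULL
  structure(h, class = c("alert_series", "data.frame"))
}

#' Correlations between membership probabilities and traits
#'
#' Product-moment correlation of each cluster-probability column with each
#' trait column over aligned records. Zero-variance columns yield `NA`
#' entries and are listed in the `flagged` attribute.
#'
#' @param probabilities Row-stochastic matrix, one column per cluster.
#' @param traits Data frame or matrix of trait values, same rows.
#' @return Correlation matrix (clusters x traits) with attribute
#'   `flagged` naming zero-variance columns.
#' @export
probability_trait_correlations <- function(probabilities, traits) {
  prob <- as.matrix(probabilities)
  tr <- as.matrix(traits)
  if (nrow(prob) != nrow(tr)) stop("rows must be aligned")
  if (nrow(prob) < 3) stop("need at least 3 records")
  flagged <- c(colnames(prob)[apply(prob, 2, stats::sd, na.rm = TRUE) == 0],
               colnames(tr)[apply(tr, 2, stats::sd, na.rm = TRUE) == 0])
  r <- suppressWarnings(stats::cor(prob, tr, use = "pairwise.complete.obs"))
  structure(r, flagged = flagged)
}
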