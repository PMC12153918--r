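#' Estimate the state-transition matrix from per-herd label series
#'
#' Counts transitions over consecutive record pairs within each herd (never
#' across herds) and row-normalizes into probabilities. A pair whose dates
#' are more than `max_gap_days` apart can optionally be excluded. States
#' that never occur at time t yield a row of `NA` probabilities, flagged in
#' `empty_rows`, rather than being silently normalized.
#'
#' @param label_series Data frame with `herd_id`, `date` and `label`
#'   (integers 1..k), date-sorted within herd.
#' @param k Number of states; default `max(label)`.
#' @param max_gap_days Optional maximum day gap between paired records.
#' @return Object of class `transition_matrix`: `counts`, `probabilities`,
#'   `n_transitions`, `empty_rows`.
#' @export
transition_matrix <- function(label_series, k = NULL,
                              max_gap_days = NULL) {
  if (is.null(k)) k <- max(label_series$label)
  counts <- matrix(0L, k, k, dimnames = list(
    from = paste0("state", 1:k), to = paste0("state", 1:k)))
  for (h in split(label_series, label_series$herd_id)) {
    if (nrow(h) < 2) next
    if (is.unsorted(h$date)) stop("series for herd ", h$herd_id[1],
                                  " is not date-sorted")
    from <- h$label[-nrow(h)]
    to <- h$label[-1]
    if (!is.null(max_gap_days)) {
      keep <- diff(as.numeric(h$date)) <= max_gap_days
      from <- from[keep]; to <- to[keep]
    }
    if (length(from))
      counts <- counts + table(factor(from, 1:k), factor(to, 1:k))
  }
  counts <- matrix(as.integer(counts), k, k, dimnames = dimnames(counts))
  rs <- rowSums(counts)
  prob <- counts / ifelse(rs == 0, NA_real_, rs)
  structure(list(counts = counts, probabilities = prob,
                 n_transitions = sum(counts),
                 empty_rows = which(rs == 0)),
            class = "transition_matrix")
}

#' Per-population cluster occupancy proportions
#'
#' @param labels Integer state labels (1..k).
#' @param by Optional population tag vector aligned with `labels`.
#' @param k Number of states; default `max(labels)`.
#' @return Matrix of proportions (one row per population, rows sum to 1).
#' @export
cluster_proportions <- function(labels, by = NULL, k = NULL) {
  if (is.null(k)) k <- max(labels)
  if (is.null(by)) by <- rep("all", length(labels))
  tab <- table(by, factor(labels, levels = 1:k))
  out <- unclass(tab / rowSums(tab))
  colnames(out) <- paste0("state", 1:k)
  out
}

#' Stationary distribution of an estimated transition matrix
#'
#' Left eigenvector of the row-stochastic matrix for eigenvalue 1,
#' normalized to sum to one. The chain must be irreducible (every state
#' reachable from every other); a reducible chain — e.g. the identity
#' matrix — is signaled as an error.
#'
#' @param tm A `transition_matrix` or a row-stochastic numeric matrix.
#' @return Numeric probability vector.
#' @export
stationary_distribution <- function(tm) {
  p <- if (inherits(tm, "transition_matrix")) tm$probabilities else as.matrix(tm)
  if (any(is.na(p))) stop("transition matrix has unobserved (NA) rows")
  if (any(abs(rowSums(p) - 1) > 1e-8)) stop("rows must sum to 1")
  k <- nrow(p)
  # reachability closure: irreducible iff all states intercommunicate
  reach <- (p > 0) | diag(k) > 0
  for (i in seq_len(k)) reach <- reach | (reach %*% reach) > 0
  if (!all(reach)) stop("reducible chain: not all states communicate")
  e <- eigen(t(p))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  if (any(v < -1e-10)) stop("periodic or ill-conditioned chain")
  stats::setNames(pmax(v, 0) / sum(pmax(v, 0)), rownames(p))
}
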