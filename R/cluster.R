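#' Ward.D2 agglomerative linkage on standardized traits
#'
#' Hierarchical clustering under the Ward minimum-variance criterion
#' applied to squared Euclidean distances, with merge heights reported on
#' the distance (square-root) scale — the `ward.D2` convention. Features
#' are centered and scaled to unit variance first (trait units differ by
#' orders of magnitude), unless already standardized.
#'
#' @param features Numeric matrix or data frame of traits (rows = records).
#' @param standardize Center/scale columns before clustering (default TRUE).
#' @param max_rows Guard against the O(n^2) distance matrix; default 30000.
#' @return An object of class `linkage_tree`: the `hclust` fit plus the
#'   `merges` matrix (left, right, height, size) and `leaf_keys`.
#' @export
ward_linkage <- function(features, standardize = TRUE, max_rows = 30000) {
  x <- as.matrix(features)
  if (!all(is.finite(x))) stop("non-finite feature values")
  if (nrow(x) < 2) stop("need at least 2 rows")
  if (nrow(x) > max_rows)
    stop("more than ", max_rows,
         " rows: the dense distance matrix would be too large; subsample first")
  if (standardize) x <- scale(x)
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  sizes <- integer(nrow(x) - 1)
  for (i in seq_len(nrow(hc$merge))) {
    l <- hc$merge[i, 1]; r <- hc$merge[i, 2]
    sizes[i] <- (if (l < 0) 1L else sizes[l]) + (if (r < 0) 1L else sizes[r])
  }
  merges <- cbind(left = hc$merge[, 1], right = hc$merge[, 2],
                  height = hc$height, size = sizes)
  structure(list(hclust = hc, merges = merges,
                 leaf_keys = rownames(x) %||% as.character(seq_len(nrow(x)))),
            class = "linkage_tree")
}

#' Select the number of clusters from dendrogram height gaps
#'
#' Codifies the visual dendrogram judgment: for each candidate `k`, the
#' relative gap between the merge that destroys the k-cluster partition and
#' the one below it, `(h[n-k+1] - h[n-k]) / h[n-k]`; the selected `k`
#' maximizes this gap over `[k_min, k_max]`. The full diagnostics table is
#' returned for human review.
#'
#' @param tree A [ward_linkage()] result.
#' @param k_min,k_max Candidate window (defaults 2 and 15).
#' @return List with `k` and `diagnostics` (data frame of `k`,
#'   `height_upper`, `height_lower`, `relative_gap`).
#' @export
select_k <- function(tree, k_min = 2, k_max = 15) {
  h <- tree$hclust$height
  n <- length(h) + 1
  if (k_max >= n) k_max <- n - 1
  stopifnot(k_min >= 2, k_min <= k_max)
  ks <- k_min:k_max
  upper <- h[n - ks + 1]
  lower <- h[n - ks]
  gap <- (upper - lower) / lower
  diagnostics <- data.frame(k = ks, height_upper = upper,
                            height_lower = lower, relative_gap = gap)
  if (all(!is.finite(gap)) || max(gap, na.rm = TRUE) <= 0 ||
      length(unique(h)) == 1) {
    warning("degenerate tree: no usable height gap; returning k_min")
    return(list(k = k_min, diagnostics = diagnostics))
  }
  list(k = ks[which.max(gap)], diagnostics = diagnostics)
}

#' Cut a linkage tree into k groups
#'
#' Removes the k-1 highest merges, yielding exactly k non-empty groups.
#'
#' @param tree A [ward_linkage()] result.
#' @param k Number of groups, 1 <= k <= number of leaves.
#' @return Integer label vector named by leaf key.
#' @export
cut_tree <- function(tree, k) {
  n <- length(tree$leaf_keys)
  stopifnot(k >= 1, k <= n)
  labels <- stats::cutree(tree$hclust, k = k)
  names(labels) <- tree$leaf_keys
  labels
}

#' Renumber cluster labels by decreasing size
#'
#' Cluster numbering out of a dendrogram cut is arbitrary; reports need a
#' stable convention. Clusters are renumbered 1..k from largest to
#' smallest; equal sizes keep their original relative order.
#'
#' @param labels Integer label vector.
#' @return List with `labels` (renumbered, names preserved) and `mapping`
#'   (named vector: old label -> new label).
#' @export
relabel_by_size <- function(labels) {
  tab <- table(labels)
  old <- as.integer(names(tab))
  ord <- order(-as.integer(tab), old)
  mapping <- integer(length(old))
  mapping[ord] <- seq_along(old)
  names(mapping) <- old
  new_labels <- mapping[as.character(labels)]
  names(new_labels) <- names(labels)
  list(labels = new_labels, mapping = mapping)
}
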