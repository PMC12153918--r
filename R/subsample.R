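#' Plan for GH-stratified subsampling
#'
#' The clustering subset keeps every record in the extreme GH tail and
#' draws fixed-size uniform samples from the lower GH strata, so rare
#' extreme compositions are fully represented while the bulk is thinned.
#' Bounded strata are half-open intervals `[a, b)`; the tail is
#' `gh >= last boundary`.
#'
#' @param boundaries Strictly increasing GH cut points; default
#'   `c(0, 1, 2, 3)` giving strata \[0,1), \[1,2), \[2,3) and tail >= 3.
#' @param per_stratum_n Draw size per bounded stratum (recycled); default
#'   5000.
#' @param keep_tail Keep all tail records (default TRUE).
#' @param seed Integer seed for the uniform draws.
#' @return An object of class `strata_plan`.
#' @export
strata_plan <- function(boundaries = c(0, 1, 2, 3), per_stratum_n = 5000,
                        keep_tail = TRUE, seed = 1L) {
  if (any(diff(boundaries) <= 0)) stop("boundaries must be strictly increasing")
  if (any(per_stratum_n < 0)) stop("per_stratum_n must be non-negative")
  n_strata <- length(boundaries) - 1
  structure(list(boundaries = boundaries,
                 per_stratum_n = rep_len(per_stratum_n, n_strata),
                 keep_tail = isTRUE(keep_tail), seed = as.integer(seed)),
            class = "strata_plan")
}

#' Draw the GH-stratified clustering subset
#'
#' @param gh_table Data frame with `record_id` and `gh` for every record.
#' @param plan A [strata_plan()].
#' @return List with `keys` (selected record ids) and `report`, a data
#'   frame per stratum of `stratum`, `lower`, `upper`, `size`, `drawn`,
#'   `shortfall`.
#' @export
stratified_subsample <- function(gh_table, plan = strata_plan()) {
  if (any(is.na(gh_table$gh))) stop("gh must be present for all records")
  b <- plan$boundaries
  n_strata <- length(b) - 1
  set.seed(plan$seed)
  keys <- character(0)
  rep_rows <- vector("list", n_strata + 1)
  for (i in seq_len(n_strata)) {
    in_stratum <- gh_table$record_id[gh_table$gh >= b[i] & gh_table$gh < b[i + 1]]
    take <- min(plan$per_stratum_n[i], length(in_stratum))
    drawn <- if (take == length(in_stratum)) in_stratum
             else sample(in_stratum, take)
    keys <- c(keys, drawn)
    rep_rows[[i]] <- data.frame(stratum = sprintf("[%g,%g)", b[i], b[i + 1]),
                                lower = b[i], upper = b[i + 1],
                                size = length(in_stratum), drawn = take,
                                shortfall = take < plan$per_stratum_n[i])
  }
  tail_ids <- gh_table$record_id[gh_table$gh >= b[length(b)]]
  if (plan$keep_tail) keys <- c(keys, tail_ids)
  rep_rows[[n_strata + 1]] <- data.frame(
    stratum = sprintf("[%g,Inf)", b[length(b)]),
    lower = b[length(b)], upper = Inf,
    size = length(tail_ids),
    drawn = if (plan$keep_tail) length(tail_ids) else 0L,
    shortfall = FALSE)
  report <- do.call(rbind, rep_rows)
  rownames(report) <- NULL
  list(keys = keys, report = report)
}
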