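#' Convert fatty acids from milk basis to fat basis
#'
#' Fatty acids predicted in g/dL milk are re-expressed as g/100 g fat using
#' the predicted fat content: `fa_fat = 100 * fa_milk / fat`. The fat basis
#' reduces correlation with yield and fat content and better reflects the
#' underlying metabolic pathways. Fat, protein and the auxiliary phenotypes
#' are unchanged.
#'
#' @param records Record data frame with `unit_basis == "milk_basis"`.
#' @return The same table with converted FA columns and
#'   `unit_basis == "fat_basis"`.
#' @export
convert_to_fat_basis <- function(records) {
  if (!all(records$unit_basis == "milk_basis"))
    stop("records are not on the milk basis (conversion already applied?)")
  bad <- which(!(records$fat > 0))
  if (length(bad))
    stop("non-positive fat content for records: ",
         paste(utils::head(records$record_id[bad], 5), collapse = ", "))
  fa <- intersect(colnames(records), fa_trait_names())
  records[fa] <- 100 * records[fa] / records$fat
  records$unit_basis <- "fat_basis"
  records
}

#' Clean bulk-tank records under ICAR-style plausibility rules
#'
#' Applied on the milk basis, before unit conversion. A row is rejected if
#' (in fixed precedence order) fat lies outside \[1.5, 9\] g/dL, protein
#' outside \[1, 7\] g/dL, any fatty acid is negative, or any studied trait
#' is missing. Only the first failing rule is logged per row, which makes
#' rejection counts deterministic.
#'
#' @param records Milk-basis record data frame.
#' @param fat_bounds,protein_bounds Inclusive plausibility bounds.
#' @return List with `kept` (rows passing all rules, columns unchanged) and
#'   `log` (data frame of `record_id`, `reason`).
#' @export
clean_records <- function(records, fat_bounds = c(1.5, 9),
                          protein_bounds = c(1, 7)) {
  if (!all(records$unit_basis == "milk_basis"))
    stop("cleaning is defined on milk-basis records")
  fa <- intersect(colnames(records), fa_trait_names())
  studied <- c(fa, "fat", "protein",
               intersect(colnames(records), aux_trait_names()))
  fat_bad <- !is.na(records$fat) &
    (records$fat < fat_bounds[1] | records$fat > fat_bounds[2])
  prot_bad <- !is.na(records$protein) &
    (records$protein < protein_bounds[1] | records$protein > protein_bounds[2])
  famat <- as.matrix(records[, fa])
  neg_bad <- rowSums(!is.na(famat) & famat < 0) > 0
  miss_bad <- rowSums(is.na(records[, studied])) > 0

  reason <- rep(NA_character_, nrow(records))
  reason[miss_bad] <- "missing"
  reason[neg_bad] <- "negative_fa"
  reason[prot_bad] <- "protein_bound"
  reason[fat_bad] <- "fat_bound"
  rejected <- !is.na(reason)
  list(kept = records[!rejected, , drop = FALSE],
       log = data.frame(record_id = records$record_id[rejected],
                        reason = reason[rejected],
                        stringsAsFactors = FALSE))
}

#' Fit the reference principal-component projection
#'
#' Standardizes the 31 fat-basis fatty acids (center, unit variance) and
#' decomposes their correlation structure. The number of retained
#' components is the smallest count whose cumulative explained variance
#' reaches `variance_threshold`. The retained-score mean and covariance
#' (and its inverse) are stored for GH scoring; external populations are
#' projected through this frozen reference.
#'
#' @param records Fat-basis record data frame.
#' @param variance_threshold Fraction of variance to retain, in (0, 1).
#'   Default 0.95.
#' @return An object of class `reference_projection` with fields
#'   `trait_order`, `center`, `scale`, `loadings`, `n_pc`, `score_mean`,
#'   `score_cov`, `score_cov_inv`, `explained_fraction`, `scores`.
#' @export
fit_reference_projection <- function(records, variance_threshold = 0.95) {
  stopifnot(variance_threshold > 0, variance_threshold < 1)
  if (!all(records$unit_basis == "fat_basis"))
    stop("reference projection is fitted on fat-basis records")
  traits <- fa_trait_names()
  if (!all(traits %in% colnames(records))) stop("missing fatty-acid columns")
  x <- as.matrix(records[, traits])
  if (nrow(x) < 2) stop("need at least 2 records")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("constant trait (zero SD): ",
         paste(traits[sds == 0], collapse = ", "))
  if (nrow(x) < length(traits))
    warning("fewer records than traits; projection will be rank-deficient")
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  expl <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  n_pc <- which(expl >= variance_threshold)[1]
  scores <- pc$x[, seq_len(n_pc), drop = FALSE]
  score_cov <- stats::cov(scores)
  structure(list(trait_order = traits,
                 center = pc$center, scale = pc$scale,
                 loadings = pc$rotation[, seq_len(n_pc), drop = FALSE],
                 n_pc = n_pc,
                 score_mean = colMeans(scores),
                 score_cov = score_cov,
                 score_cov_inv = solve(score_cov),
                 explained_fraction = expl[n_pc],
                 explained_by_component = pc$sdev^2 / sum(pc$sdev^2),
                 scores = scores),
            class = "reference_projection")
}

#' Project records onto a fitted reference projection
#'
#' Applies the frozen center, scale and loadings of the reference
#' population; no refitting occurs, so a second population is scored in the
#' reference coordinate system.
#'
#' @param records Fat-basis record data frame sharing the reference traits.
#' @param projection A [fit_reference_projection()] result.
#' @return Numeric score matrix (`n_pc` columns), rownames = record ids.
#' @export
project_records <- function(records, projection) {
  missing <- setdiff(projection$trait_order, colnames(records))
  if (length(missing))
    stop("missing trait column(s): ", paste(missing, collapse = ", "))
  if (!all(records$unit_basis == "fat_basis"))
    stop("projection expects fat-basis records")
  x <- as.matrix(records[, projection$trait_order])
  s <- scale(x, center = projection$center, scale = projection$scale) %*%
    projection$loadings
  rownames(s) <- records$record_id
  s
}

#' Standardized Mahalanobis (GH) novelty score
#'
#' For each record with retained-score vector `x`,
#' `GH = (x - mu)' S^{-1} (x - mu) / nPC`, where `mu` and `S` are the
#' retained-score mean and covariance of the reference population. Under a
#' Gaussian reference, GH is approximately chi-squared(nPC)/nPC with mean 1;
#' values above ~5 mark extreme milk compositions.
#'
#' @param scores Score matrix from [project_records()] (or the stored
#'   reference scores).
#' @param projection The [fit_reference_projection()] supplying `mu`, `S`.
#' @return Data frame of `record_id` and `gh`, plus the scores as an
#'   attribute-free copy in columns `PC1..PCn`.
#' @export
compute_gh <- function(scores, projection) {
  scores <- as.matrix(scores)
  if (ncol(scores) != projection$n_pc)
    stop("score dimension does not match the retained component count")
  d2 <- stats::mahalanobis(scores, projection$score_mean,
                           projection$score_cov_inv, inverted = TRUE)
  gh <- d2 / projection$n_pc
  out <- data.frame(record_id = rownames(scores) %||% seq_len(nrow(scores)),
                    gh = as.numeric(gh), stringsAsFactors = FALSE)
  cbind(out, as.data.frame(scores))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize / restore a reference projection as JSON
#'
#' Full-precision round trip of the frozen reference coordinate system, so
#' a projection fitted on one population can be reapplied elsewhere.
#'
#' @param projection A `reference_projection`.
#' @param path File path for the JSON document.
#' @return `write_projection` returns `path` invisibly; `read_projection`
#'   returns the restored `reference_projection` (without stored scores).
#' @export
write_projection <- function(projection, path) {
  obj <- projection[c("trait_order", "center", "scale", "n_pc",
                      "score_mean", "explained_fraction")]
  obj$loadings <- as.vector(projection$loadings)
  obj$score_cov <- as.vector(projection$score_cov)
  # I(17) = 17 significant digits, enough for an exact double round trip
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_projection
#' @export
read_projection <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- length(obj$trait_order)
  loadings <- matrix(obj$loadings, nrow = p,
                     dimnames = list(obj$trait_order,
                                     paste0("PC", seq_len(obj$n_pc))))
  score_cov <- matrix(obj$score_cov, nrow = obj$n_pc)
  center <- obj$center; scale <- obj$scale; mu <- obj$score_mean
  names(center) <- names(scale) <- obj$trait_order
  names(mu) <- paste0("PC", seq_len(obj$n_pc))
  structure(list(trait_order = obj$trait_order, center = center,
                 scale = scale, loadings = loadings, n_pc = obj$n_pc,
                 score_mean = mu, score_cov = score_cov,
                 score_cov_inv = solve(score_cov),
                 explained_fraction = obj$explained_fraction),
            class = "reference_projection")
}
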