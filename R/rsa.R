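#' Hypothesis model RDM: categorical (linearly separable) geometry
#'
#' Between-condition entries are 1 and within-condition entries 0: the model
#' of two linearly separable clusters, one per memorability condition. The
#' mask includes all off-diagonal entries.
#'
#' @param condition_of Character vector (`"high"`/`"low"`), one entry per
#'   image, in matrix order.
#' @return An object of class `model_rdm`: list with `values` (`K x K`),
#'   `mask` (`K x K` logical), `name`.
#' @export
categorical_model <- function(condition_of) {
  check_two_conditions(condition_of)
  K <- length(condition_of)
  values <- outer(condition_of, condition_of, FUN = `!=`) * 1
  diag(values) <- 0
  model_rdm(values, name = "categorical")
}

#' Hypothesis model RDM: dispersion (entropy-based) geometry
#'
#' High-memorability exemplars are spread far apart while low-memorability
#' exemplars cluster tightly, with no separation between the condition
#' centroids: within-high entries are 1, within-low entries 0, and
#' between-condition entries 0.5 (intermediate, as expected under a shared
#' centroid). Rank correlation makes downstream results invariant to the
#' specific coding so long as this ordering is preserved.
#'
#' @inheritParams categorical_model
#' @param mask_between If `TRUE`, between-condition pairs are excluded from
#'   the comparison mask instead of being coded 0.5.
#' @return A `model_rdm` object.
#' @export
dispersion_model <- function(condition_of, mask_between = FALSE) {
  check_two_conditions(condition_of)
  K <- length(condition_of)
  hi <- condition_of == "high"
  values <- matrix(0.5, K, K)
  values[hi, hi] <- 1
  values[!hi, !hi] <- 0
  diag(values) <- 0
  mask <- !diag(TRUE, K)
  if (mask_between) mask[outer(condition_of, condition_of, FUN = `!=`)] <- FALSE
  model_rdm(values, mask = mask, name = "dispersion")
}

check_two_conditions <- function(condition_of) {
  if (sum(condition_of == "high") < 2L || sum(condition_of == "low") < 2L)
    stop("each condition needs at least 2 images")
  invisible(NULL)
}

#' Construct a model RDM
#'
#' @param values Symmetric `K x K` numeric matrix with zero diagonal.
#' @param mask Logical `K x K` matrix of entries included in the comparison;
#'   defaults to all off-diagonal entries. The diagonal is always excluded.
#' @param name Model name string.
#' @return An object of class `model_rdm`.
#' @export
model_rdm <- function(values, mask = NULL, name = "model") {
  values <- as.matrix(values)
  K <- nrow(values)
  if (ncol(values) != K || max(abs(values - t(values))) > 1e-12)
    stop("model RDM must be a symmetric square matrix")
  if (is.null(mask)) mask <- !diag(TRUE, K)
  mask <- mask & !diag(TRUE, K)
  structure(list(values = values, mask = mask, name = name), class = "model_rdm")
}

#' Spearman correlation of an RDM series with a hypothesis model
#'
#' At each time point, the masked lower-triangle entries of the measured RDM
#' are rank-correlated (Spearman, average ranks for ties) with the matching
#' model entries. Time points where either vector has zero variance get
#' `rho = 0` and are counted in the `n_flagged` attribute.
#'
#' @param rdm An [rdm_series()] object.
#' @param model A [model_rdm()] with matching `K`.
#' @return A [decoding_timecourse()] with tag `"model_correlation"`; the
#'   number of zero-variance time points is attached as attribute
#'   `"n_flagged"`.
#' @export
rsa_correlate <- function(rdm, model) {
  validate_rdm_series(rdm)
  K <- length(rdm$image_ids)
  if (nrow(model$values) != K)
    stop("model RDM size does not match the measured RDM")
  sel <- lower.tri(model$values) & model$mask
  m <- model$values[sel]
  n_flagged <- 0L
  rho <- vapply(seq_along(rdm$times), function(t) {
    x <- rdm$values[t, , ][sel]
    if (stats::sd(x) == 0 || stats::sd(m) == 0) {
      n_flagged <<- n_flagged + 1L
      return(0)
    }
    stats::cor(x, m, method = "spearman")
  }, numeric(1))
  out <- decoding_timecourse(rho, rdm$times, "model_correlation", rdm$subject_id)
  attr(out, "n_flagged") <- n_flagged
  out
}

#' Classical (Torgerson) MDS embedding of one RDM slice
#'
#' Double-centers the squared dissimilarities and takes the top-2 spectral
#' coordinates; the embedding is centered at the origin and unique up to
#' rotation/reflection. Visualization only — it feeds no statistic.
#'
#' @param d Symmetric `K x K` dissimilarity matrix with zero diagonal,
#'   `K >= 3`.
#' @return `K x 2` matrix of coordinates.
#' @export
mds_embed <- function(d) {
  d <- as.matrix(d)
  K <- nrow(d)
  if (K < 3L) stop("MDS needs at least 3 items")
  if (max(abs(d - t(d))) > 1e-8 || max(abs(diag(d))) > 1e-8)
    stop("dissimilarity matrix must be symmetric with zero diagonal")
  xy <- stats::cmdscale(d, k = 2L)
  sweep(xy, 2L, colMeans(xy))
}
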