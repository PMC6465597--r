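#' Time-resolved representational dissimilarity matrix series
#'
#' Holds one `K x K` symmetric, zero-diagonal dissimilarity matrix per time
#' point, where dissimilarity is cross-validated pairwise decoding accuracy in
#' percent (chance 50, perfect 100).
#'
#' @param values Numeric array `[n_times x K x K]`.
#' @param times Time axis in ms.
#' @param image_ids Integer vector of length `K`, the stimulus exemplar ids
#'   indexing the matrix rows/columns.
#' @param condition_of Character vector of length `K`, `"high"`/`"low"` per
#'   image (same order as `image_ids`).
#' @param subject_id Subject identifier.
#' @param params Optional list of decoding parameters recorded for provenance.
#' @return An object of class `rdm_series`.
#' @export
rdm_series <- function(values, times, image_ids, condition_of,
                       subject_id = "unknown", params = NULL) {
  x <- structure(
    list(
      values = values, times = as.numeric(times),
      image_ids = as.integer(image_ids),
      condition_of = as.character(condition_of),
      subject_id = as.character(subject_id),
      params = params
    ),
    class = "rdm_series"
  )
  validate_rdm_series(x)
  x
}

#' Validate an RDM series
#' @param x An `rdm_series` object.
#' @return `x`, invisibly.
#' @export
validate_rdm_series <- function(x) {
  if (!inherits(x, "rdm_series")) stop("not an `rdm_series` object")
  d <- dim(x$values)
  if (length(d) != 3L || d[2L] != d[3L])
    stop("invariant violated: values must be [n_times x K x K]")
  if (d[1L] != length(x$times))
    stop("invariant violated: times length must match values")
  if (d[2L] != length(x$image_ids) || d[2L] != length(x$condition_of))
    stop("invariant violated: image_ids/condition_of must have K entries")
  if (!all(is.finite(x$values)))
    stop("invariant violated: RDM entries must be finite")
  if (min(x$values) < 0 || max(x$values) > 100)
    stop("invariant violated: RDM entries must lie in [0, 100]")
  for (t in seq_len(d[1L])) {
    m <- x$values[t, , ]
    if (max(abs(m - t(m))) > 1e-8)
      stop("invariant violated: each RDM slice must be symmetric")
    if (max(abs(diag(m))) > 1e-8)
      stop("invariant violated: each RDM slice must have zero diagonal")
  }
  invisible(x)
}

#' @export
print.rdm_series <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<rdm_series> subject %s: K = %d images, %d time points (%g..%g ms)\n",
              x$subject_id, d[2L], d[1L], min(x$times), max(x$times)))
  invisible(x)
}

#' Average pairwise decoding within conditions
#'
#' Averages the RDM entries over within-high pairs and within-low pairs
#' separately at each time point (between-condition pairs are excluded from
#' both), and forms their difference. With a 15/15 image split this averages
#' `choose(15, 2) = 105` pairs per condition and discards the 225 between
#' pairs.
#'
#' @param rdm An [rdm_series()] object.
#' @return A list of three [decoding_timecourse()] objects: `high`, `low` and
#'   `difference` (high minus low).
#' @export
condition_mean_timecourses <- function(rdm) {
  validate_rdm_series(rdm)
  for (cond in c("high", "low"))
    if (sum(rdm$condition_of == cond) < 2L)
      stop(sprintf("condition '%s' has fewer than 2 images", cond))
  K <- length(rdm$image_ids)
  lt <- which(lower.tri(matrix(0, K, K)), arr.ind = TRUE)
  ci <- rdm$condition_of[lt[, 1L]]
  cj <- rdm$condition_of[lt[, 2L]]
  sel <- function(cond) lt[ci == cond & cj == cond, , drop = FALSE]
  mean_over <- function(pairs) {
    vapply(seq_along(rdm$times),
           function(t) mean(rdm$values[t, , ][pairs]), numeric(1))
  }
  hi <- mean_over(sel("high"))
  lo <- mean_over(sel("low"))
  list(
    high = decoding_timecourse(hi, rdm$times, "high", rdm$subject_id),
    low = decoding_timecourse(lo, rdm$times, "low", rdm$subject_id),
    difference = decoding_timecourse(hi - lo, rdm$times, "difference", rdm$subject_id)
  )
}

#' A single decoding (or model-correlation) time course
#'
#' @param accuracy Numeric vector over time; percent for decoding curves,
#'   dimensionless for `"model_correlation"` tags.
#' @param times Time axis in ms.
#' @param tag One of `"high"`, `"low"`, `"difference"`, `"model_correlation"`.
#' @param subject_id Subject identifier.
#' @return An object of class `decoding_timecourse`.
#' @export
decoding_timecourse <- function(accuracy, times, tag, subject_id = "unknown") {
  stopifnot(length(accuracy) == length(times))
  tag <- match.arg(tag, c("high", "low", "difference", "model_correlation"))
  structure(list(accuracy = as.numeric(accuracy), times = as.numeric(times),
                 tag = tag, subject_id = as.character(subject_id)),
            class = "decoding_timecourse")
}

#' @export
print.decoding_timecourse <- function(x, ...) {
  cat(sprintf("<decoding_timecourse> %s (subject %s), %d time points, peak %.2f at %g ms\n",
              x$tag, x$subject_id, length(x$times),
              max(x$accuracy), x$times[which.max(x$accuracy)]))
  invisible(x)
}
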