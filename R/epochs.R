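#' Construct an epoched MEG data set
#'
#' Bundles a `trials x channels x times` array with per-trial stimulus labels
#' and per-channel metadata into a validated S3 object, the common currency of
#' the whole pipeline. Time is always expressed in milliseconds relative to
#' stimulus onset (onset at `t = 0`), on a strictly increasing uniform grid.
#'
#' @param data Numeric array `[n_trials x n_channels x n_times]`. Units are
#'   arbitrary (fT for sensor data, dimensionless for synthetic or source
#'   time series).
#' @param times Numeric vector of sample times in ms, strictly increasing with
#'   constant step `1000 / sampling_rate`.
#' @param image_id Integer vector, one entry per trial, coding the stimulus
#'   exemplar (`1..K`).
#' @param condition Character or factor per trial, one of `"high"` / `"low"`
#'   (memorability condition). Must be a function of `image_id`: the same
#'   image never appears in both conditions.
#' @param channel_names Character vector, one name per channel.
#' @param channel_group Character vector, one group label per channel (e.g.
#'   `"sensor"`, `"frontal"`, `"ROI:parietal_L"`); used for group-wise
#'   rejection thresholds, blink detection and ROI decoding.
#' @param sampling_rate Sampling rate in Hz.
#' @param subject_id Subject identifier string.
#'
#' @return An object of class `meg_epochs`.
#' @seealso [validate_epochs()], [read_epochs()], [write_epochs()]
#' @export
meg_epochs <- function(data, times, image_id, condition,
                       channel_names = NULL, channel_group = NULL,
                       sampling_rate, subject_id = "unknown") {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3-d array [trials x channels x times]")
  n_ch <- dim(data)[2L]
  if (is.null(channel_names)) channel_names <- sprintf("CH%03d", seq_len(n_ch))
  if (is.null(channel_group)) channel_group <- rep("sensor", n_ch)
  x <- structure(
    list(
      data = data,
      times = as.numeric(times),
      image_id = as.integer(image_id),
      condition = as.character(condition),
      channel_names = as.character(channel_names),
      channel_group = as.character(channel_group),
      sampling_rate = as.numeric(sampling_rate),
      subject_id = as.character(subject_id)
    ),
    class = "meg_epochs"
  )
  validate_epochs(x)
  x
}

#' Validate an epoched data set
#'
#' Checks every structural invariant of [meg_epochs()] and stops with a
#' message naming the violated invariant. Returns the object invisibly so the
#' call can be chained.
#'
#' @param x A `meg_epochs` object.
#' @return `x`, invisibly.
#' @export
validate_epochs <- function(x) {
  if (!inherits(x, "meg_epochs")) stop("not a `meg_epochs` object")
  d <- dim(x$data)
  if (length(d) != 3L) stop("invariant violated: data must be 3-d [trials x channels x times]")
  if (d[1L] < 1L) stop("invariant violated: at least one trial required (zero-trial epochs invalid)")
  if (d[2L] != length(x$channel_names))
    stop("invariant violated: channel_names length must equal n_channels")
  if (d[2L] != length(x$channel_group))
    stop("invariant violated: channel_group length must equal n_channels")
  if (d[3L] != length(x$times))
    stop("invariant violated: times length must equal n_times")
  if (length(x$image_id) != d[1L])
    stop("invariant violated: image_id must have one entry per trial")
  if (length(x$condition) != d[1L])
    stop("invariant violated: condition must have one entry per trial")
  if (!all(is.finite(x$data)))
    stop("invariant violated: all data values must be finite")
  if (!all(is.finite(x$times)))
    stop("invariant violated: times must be finite")
  dt <- diff(x$times)
  if (length(dt) && (any(dt <= 0) || max(abs(dt - dt[1L])) > 1e-6 * abs(dt[1L])))
    stop("invariant violated: times must be strictly increasing with uniform step")
  if (length(dt)) {
    step <- 1000 / x$sampling_rate
    if (abs(dt[1L] - step) > 1e-6 * step)
      stop("invariant violated: time step must equal 1000/sampling_rate ms")
  }
  if (!all(x$condition %in% c("high", "low")))
    stop("invariant violated: condition labels must be 'high' or 'low'")
  # condition must be a function of image_id
  tab <- unique(data.frame(image_id = x$image_id, condition = x$condition))
  if (anyDuplicated(tab$image_id))
    stop("invariant violated: condition must be a function of image_id (an image appears in both conditions)")
  invisible(x)
}

#' @export
print.meg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<meg_epochs> subject %s: %d trials x %d channels x %d samples (%g..%g ms @ %g Hz)\n",
    x$subject_id, d[1L], d[2L], d[3L], min(x$times), max(x$times), x$sampling_rate
  ))
  cat(sprintf("  images: %d (%d high / %d low); channel groups: %s\n",
              length(unique(x$image_id)),
              length(unique(x$image_id[x$condition == "high"])),
              length(unique(x$image_id[x$condition == "low"])),
              paste(unique(x$channel_group), collapse = ", ")))
  invisible(x)
}

#' Number of trials, channels and samples of an epoch set
#' @param x A `meg_epochs` object.
#' @return Named integer vector `(n_trials, n_channels, n_times)`.
#' @export
epochs_dim <- function(x) {
  d <- dim(x$data)
  c(n_trials = d[1L], n_channels = d[2L], n_times = d[3L])
}

#' Subset an epoch set by trials and/or channels
#'
#' Label metadata follows the retained trials/channels; the time axis is never
#' subset here (decoding and statistics own the time dimension).
#'
#' @param x A `meg_epochs` object.
#' @param trials Integer or logical index of trials to keep (default all).
#' @param channels Integer or logical index of channels to keep (default all).
#' @return A `meg_epochs` object.
#' @export
subset_epochs <- function(x, trials = NULL, channels = NULL) {
  if (is.null(trials)) trials <- seq_len(dim(x$data)[1L])
  if (is.null(channels)) channels <- seq_len(dim(x$data)[2L])
  meg_epochs(
    data = x$data[trials, channels, , drop = FALSE],
    times = x$times,
    image_id = x$image_id[trials],
    condition = x$condition[trials],
    channel_names = x$channel_names[channels],
    channel_group = x$channel_group[channels],
    sampling_rate = x$sampling_rate,
    subject_id = x$subject_id
  )
}

#' Restrict an epoch set to one channel group
#'
#' ROI decoding is plain decoding on a channel subset; this helper selects the
#' channels whose `channel_group` matches `group`.
#'
#' @param x A `meg_epochs` object.
#' @param group Character; a channel group label present in `x$channel_group`.
#' @return A `meg_epochs` object containing only the matching channels.
#' @export
select_channel_group <- function(x, group) {
  keep <- x$channel_group %in% group
  if (!any(keep)) stop(sprintf("no channels in group '%s'", paste(group, collapse = ",")))
  subset_epochs(x, channels = keep)
}
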