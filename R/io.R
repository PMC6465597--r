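#' @importFrom Rcpp evalCpp
#' @useDynLib memdecode, .registration = TRUE
NULL

EPOCHS_LAYOUT_VERSION <- "1.0"

#' Write epochs to an HDF5 container
#'
#' Layout: datasets `/data` (trials x channels x times), `/times`,
#' `/image_id`, `/condition`, `/channel_names`, `/channel_group`, plus root
#' attributes `sampling_rate`, `subject_id` and `layout_version`.
#'
#' @param epochs A validated [meg_epochs()] object.
#' @param path Output file path.
#' @param overwrite Overwrite an existing file? Default `FALSE`.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(epochs, path, overwrite = FALSE) {
  validate_epochs(epochs)
  if (file.exists(path)) {
    if (!overwrite) stop(sprintf("file '%s' exists and overwrite = FALSE", path))
    unlink(path)
  }
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5write(epochs$data, path, "data")
  rhdf5::h5write(epochs$times, path, "times")
  rhdf5::h5write(epochs$image_id, path, "image_id")
  rhdf5::h5write(epochs$condition, path, "condition")
  rhdf5::h5write(epochs$channel_names, path, "channel_names")
  rhdf5::h5write(epochs$channel_group, path, "channel_group")
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(epochs$sampling_rate, fid, "sampling_rate")
  rhdf5::h5writeAttribute(epochs$subject_id, fid, "subject_id")
  rhdf5::h5writeAttribute(EPOCHS_LAYOUT_VERSION, fid, "layout_version")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' Read epochs from an HDF5 container
#'
#' Inverse of [write_epochs()]; the returned object is validated, so a file
#' with a malformed time axis or inconsistent labels is rejected.
#'
#' @param path Path to an epochs container written by [write_epochs()].
#' @return A [meg_epochs()] object.
#' @export
read_epochs <- function(path) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path))
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  present <- rhdf5::h5ls(path, recursive = FALSE)$name
  needed <- c("data", "times", "image_id", "condition", "channel_names", "channel_group")
  missing <- setdiff(needed, present)
  if (length(missing))
    stop(sprintf("format error: container is missing dataset(s): %s",
                 paste(missing, collapse = ", ")))
  att <- rhdf5::h5readAttributes(path, "/")
  for (a in c("sampling_rate", "subject_id", "layout_version"))
    if (is.null(att[[a]]))
      stop(sprintf("format error: container is missing root attribute '%s'", a))
  if (!identical(as.character(att$layout_version), EPOCHS_LAYOUT_VERSION))
    stop(sprintf("format error: unsupported layout_version '%s'", att$layout_version))
  meg_epochs(
    data = rhdf5::h5read(path, "data"),
    times = as.numeric(rhdf5::h5read(path, "times")),
    image_id = as.integer(rhdf5::h5read(path, "image_id")),
    condition = as.character(rhdf5::h5read(path, "condition")),
    channel_names = as.character(rhdf5::h5read(path, "channel_names")),
    channel_group = as.character(rhdf5::h5read(path, "channel_group")),
    sampling_rate = as.numeric(att$sampling_rate),
    subject_id = as.character(att$subject_id)
  )
}

#' Write an RDM series as delimited text plus a JSON sidecar
#'
#' The table holds the lower triangle only, in long format with columns
#' `time_ms, image_i, image_j, accuracy` (`image_i > image_j`). The sidecar
#' (`<path>.json`) carries the image ids, condition map, subject id and any
#' parameters recorded on the object, so the artifact is reproducible from
#' its metadata.
#'
#' @param rdm An [rdm_series()] object.
#' @param path Output CSV path; the sidecar is written to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_rdm_series <- function(rdm, path) {
  validate_rdm_series(rdm)
  K <- dim(rdm$values)[2L]
  lt <- which(lower.tri(matrix(0, K, K)), arr.ind = TRUE)  # i > j
  tab <- do.call(rbind, lapply(seq_along(rdm$times), function(t) {
    data.frame(
      time_ms = rdm$times[t],
      image_i = rdm$image_ids[lt[, 1L]],
      image_j = rdm$image_ids[lt[, 2L]],
      accuracy = rdm$values[t, , ][lt]
    )
  }))
  utils::write.csv(format(tab, digits = 12, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  meta <- list(
    image_ids = rdm$image_ids,
    condition_of = as.list(stats::setNames(rdm$condition_of, rdm$image_ids)),
    subject_id = rdm$subject_id,
    times_ms = rdm$times,
    params = rdm$params
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an RDM series written by [write_rdm_series()]
#'
#' @param path CSV path (the `<path>.json` sidecar must sit next to it).
#' @return An [rdm_series()] object.
#' @export
read_rdm_series <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tab <- utils::read.csv(path)
  ids <- as.integer(meta$image_ids)
  K <- length(ids)
  times <- as.numeric(meta$times_ms)
  vals <- array(0, c(length(times), K, K))
  ti <- match(tab$time_ms, times)
  ii <- match(tab$image_i, ids)
  jj <- match(tab$image_j, ids)
  vals[cbind(ti, ii, jj)] <- tab$accuracy
  vals[cbind(ti, jj, ii)] <- tab$accuracy
  rdm_series(
    values = vals, times = times, image_ids = ids,
    condition_of = unlist(meta$condition_of)[as.character(ids)],
    subject_id = meta$subject_id,
    params = meta$params
  )
}
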