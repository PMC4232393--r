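#' Multichannel EEG recording
#'
#' Container for a continuous multichannel EEG time series with event
#' markers. Markers tag stimulation onsets with the attended flicker
#' frequency and the stimulus condition, which is all the downstream
#' epoching needs.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param sampling_rate sampling rate in Hz.
#' @param channel_labels character vector of unique channel names
#'   (10-20 system names such as `"O1"`, `"Pz"`, `"M1"`), one per row of
#'   `data`.
#' @param markers data frame with columns `onset` (0-based sample index of
#'   stimulation onset), `frequency` (flicker frequency, Hz) and
#'   `condition` (stimulus condition label).
#'
#' @return An object of class `ssvep_recording`.
#' @export
raw_recording <- function(data, sampling_rate, channel_labels, markers = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("`data` must be a numeric matrix")
  if (length(channel_labels) != nrow(data))
    stop("need one channel label per row of `data`")
  if (anyDuplicated(channel_labels))
    stop("channel labels must be unique")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("`sampling_rate` must be a positive number")
  if (is.null(markers)) {
    markers <- data.frame(onset = integer(0), frequency = numeric(0),
                          condition = character(0))
  }
  markers <- as.data.frame(markers)
  stopifnot(all(c("onset", "frequency", "condition") %in% names(markers)))
  markers$onset <- as.integer(round(markers$onset))
  markers$condition <- as.character(markers$condition)
  if (nrow(markers) && (any(markers$onset < 0) ||
                        any(markers$onset >= ncol(data))))
    stop("marker onsets must lie within the recording")
  rownames(data) <- channel_labels
  structure(
    list(data = data, sampling_rate = sampling_rate,
         channel_labels = as.character(channel_labels), markers = markers),
    class = "ssvep_recording"
  )
}

#' @export
print.ssvep_recording <- function(x, ...) {
  cat(sprintf("<ssvep_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$sampling_rate,
              ncol(x$data) / x$sampling_rate))
  cat(" channels:", paste(x$channel_labels, collapse = " "), "\n")
  if (nrow(x$markers)) {
    tab <- table(x$markers$condition, x$markers$frequency)
    cat(sprintf(" markers: %d (%d condition(s) x %d frequencies)\n",
                nrow(x$markers), nrow(tab), ncol(tab)))
  } else {
    cat(" markers: none\n")
  }
  invisible(x)
}

#' Write / read a recording in the plain-text fixture format
#'
#' The fixture format is a pair of files sharing a stem: `<stem>.tsv`
#' holding the sample matrix (one row per sample, one named column per
#' channel) and `<stem>.json` holding the metadata sidecar with fields
#' `sampling_rate`, `channel_labels` and `markers` (array of objects with
#' `onset`, `frequency`, `condition`). Onsets are 0-based sample indices.
#'
#' @param recording an [raw_recording()] object.
#' @param stem path stem; `.tsv` and `.json` are appended.
#' @return `write_recording` returns `stem` invisibly; `read_recording`
#'   returns an `ssvep_recording`.
#' @export
write_recording <- function(recording, stem) {
  stopifnot(inherits(recording, "ssvep_recording"))
  mat <- t(recording$data)
  colnames(mat) <- recording$channel_labels
  utils::write.table(format(mat, digits = 10, trim = TRUE, scientific = FALSE),
                     paste0(stem, ".tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(
    sampling_rate = recording$sampling_rate,
    channel_labels = recording$channel_labels,
    markers = recording$markers
  )
  jsonlite::write_json(meta, paste0(stem, ".json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(stem)
}

#' @rdname write_recording
#' @param stem path stem of an existing fixture pair.
#' @export
read_recording <- function(stem) {
  tsv <- paste0(stem, ".tsv")
  js <- paste0(stem, ".json")
  if (!file.exists(tsv) || !file.exists(js))
    stop("fixture files not found at stem: ", stem)
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  mat <- as.matrix(utils::read.table(tsv, header = TRUE, sep = "\t",
                                     check.names = FALSE))
  markers <- meta$markers
  if (is.null(markers) || length(markers) == 0) markers <- NULL
  raw_recording(t(mat), meta$sampling_rate, meta$channel_labels, markers)
}
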