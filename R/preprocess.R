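#' Occipito-parietal analysis montage
#'
#' The seven channels over primary and secondary visual areas used for
#' SSVEP quantification: O1, O2, Pz, P3, P4, P7 and P8.
#'
#' @return Character vector of channel labels.
#' @export
analysis_montage <- function() c("O1", "O2", "Pz", "P3", "P4", "P7", "P8")

#' Select a subset of channels
#'
#' Returns the recording restricted to the requested channels, in the
#' requested order. Matching is case-insensitive; data are untouched.
#'
#' @param recording an [raw_recording()].
#' @param labels channels to keep, in output order.
#' @return An `ssvep_recording` with exactly the requested channels.
#' @export
select_channels <- function(recording, labels = c(analysis_montage(), "M1", "M2")) {
  stopifnot(inherits(recording, "ssvep_recording"))
  idx <- match(tolower(labels), tolower(recording$channel_labels))
  if (anyNA(idx))
    stop("channel ", paste(labels[is.na(idx)], collapse = ", "), " not found")
  raw_recording(recording$data[idx, , drop = FALSE], recording$sampling_rate,
                recording$channel_labels[idx], recording$markers)
}

#' Re-reference to linked mastoids
#'
#' Subtracts the average of the two mastoid channels (M1, M2) from every
#' other channel and drops the mastoids from the output.
#'
#' @param recording an [raw_recording()] containing channels M1 and M2.
#' @return An `ssvep_recording` without mastoid channels.
#' @export
rereference_mastoids <- function(recording) {
  stopifnot(inherits(recording, "ssvep_recording"))
  im <- match(c("m1", "m2"), tolower(recording$channel_labels))
  if (anyNA(im))
    stop("mastoid channel ", paste(c("M1", "M2")[is.na(im)], collapse = ", "),
         " not found")
  ref <- colMeans(recording$data[im, , drop = FALSE])
  keep <- setdiff(seq_len(nrow(recording$data)), im)
  data <- sweep(recording$data[keep, , drop = FALSE], 2, ref)
  raw_recording(data, recording$sampling_rate,
                recording$channel_labels[keep], recording$markers)
}

# Anti-alias low-pass for decimation by `factor`: order-8 Chebyshev type I,
# 0.02 dB passband ripple, cutoff at 0.8 x target Nyquist, normalized to
# unit DC gain (even-order Chebyshev otherwise dips by the ripple at DC).
# The small ripple keeps the worst-case passband gain error of the
# zero-phase double pass below 0.5%.
antialias_filter <- function(factor) {
  flt <- signal::cheby1(8, 0.02, 0.8 / factor)
  dc <- abs(transfer_function(flt$b, flt$a, 0, 2))
  list(b = flt$b / dc, a = flt$a)
}

#' Downsample a recording
#'
#' Anti-aliased decimation: each channel is low-pass filtered with an
#' order-8 Chebyshev type I filter (0.02 dB ripple, cutoff at 0.8 times
#' the target Nyquist frequency, unit DC gain) applied zero-phase, then
#' every `factor`-th sample is kept. Marker onsets are rescaled to the new
#' rate. The original rate must be an integer multiple of `target_rate`;
#' a factor of 1 returns the recording unchanged.
#'
#' @param recording an [raw_recording()].
#' @param target_rate output sampling rate, Hz.
#' @return An `ssvep_recording` at `target_rate`.
#' @export
downsample <- function(recording, target_rate = 128) {
  stopifnot(inherits(recording, "ssvep_recording"))
  factor <- recording$sampling_rate / target_rate
  if (abs(factor - round(factor)) > 1e-9)
    stop(sprintf("sampling rate %g is not an integer multiple of %g",
                 recording$sampling_rate, target_rate))
  factor <- as.integer(round(factor))
  if (factor == 1L) return(recording)
  flt <- antialias_filter(factor)
  keep <- seq(1, ncol(recording$data), by = factor)
  data <- t(apply(recording$data, 1, function(x)
    filtfilt_refl(flt$b, flt$a, x)[keep]))
  markers <- recording$markers
  if (nrow(markers)) markers$onset <- as.integer(round(markers$onset / factor))
  raw_recording(data, target_rate, recording$channel_labels, markers)
}

#' Epoch set
#'
#' A trials x channels x samples array of fixed-length epochs belonging to
#' one (condition, stimulation frequency) cell and one epoch class:
#' `"stimulation"` (signal during flicker) or `"baseline"` (signal
#' immediately preceding onset).
#'
#' @param epochs numeric array, trials x channels x samples.
#' @param sampling_rate sampling rate, Hz.
#' @param frequency stimulation frequency, Hz.
#' @param condition condition label.
#' @param klass `"stimulation"` or `"baseline"`.
#' @param channel_labels channel names, one per array column.
#' @param filtered whether a narrow-band filter has been applied.
#' @return An object of class `ssvep_epochs`.
#' @export
epoch_set <- function(epochs, sampling_rate, frequency, condition, klass,
                      channel_labels, filtered = FALSE) {
  stopifnot(length(dim(epochs)) == 3,
            klass %in% c("stimulation", "baseline"),
            dim(epochs)[2] == length(channel_labels),
            dim(epochs)[1] >= 1)
  structure(list(epochs = epochs, sampling_rate = sampling_rate,
                 frequency = frequency, condition = condition, klass = klass,
                 channel_labels = channel_labels, filtered = filtered),
            class = "ssvep_epochs")
}

#' @export
print.ssvep_epochs <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf(
    "<ssvep_epochs> %s | %g Hz | '%s': %d trials x %d channels x %d samples%s\n",
    x$klass, x$frequency, x$condition, d[1], d[2], d[3],
    if (x$filtered) " (narrow-band filtered)" else ""))
  invisible(x)
}

n_trials <- function(x) dim(x$epochs)[1]

#' Extract stimulation and baseline epoch classes
#'
#' For every marker, cuts a stimulation epoch covering
#' `[onset, onset + duration)` and a baseline epoch covering
#' `[onset - duration, onset)` (the final part of the preceding rest
#' period). Markers without a full margin on either side are dropped with
#' a warning. Epochs are pure slices: sample values are preserved exactly.
#'
#' @param recording an [raw_recording()] with markers.
#' @param duration epoch length, s.
#' @return An object of class `ssvep_epoch_map`: a list keyed
#'   `"<condition>|<frequency>"`, each element holding `$stimulation` and
#'   `$baseline` [epoch_set()]s with equal trial counts.
#' @export
extract_epochs <- function(recording, duration = 4) {
  stopifnot(inherits(recording, "ssvep_recording"))
  fs <- recording$sampling_rate
  len <- round(duration * fs)
  mk <- recording$markers
  if (!nrow(mk)) stop("recording has no markers")
  total <- ncol(recording$data)
  ok <- mk$onset >= len & mk$onset + len <= total
  if (any(!ok))
    warning(sprintf("dropped %d marker(s) without a full %g s margin",
                    sum(!ok), duration))
  mk <- mk[ok, , drop = FALSE]
  if (!nrow(mk)) stop("no usable markers after margin check")

  cells <- split(seq_len(nrow(mk)),
                 list(condition = mk$condition, frequency = mk$frequency),
                 drop = TRUE, sep = "|")
  out <- lapply(names(cells), function(key) {
    rows <- cells[[key]]
    cond <- mk$condition[rows[1]]
    freq <- mk$frequency[rows[1]]
    slice <- function(starts) {
      arr <- array(0, c(length(starts), nrow(recording$data), len))
      for (i in seq_along(starts))
        arr[i, , ] <- recording$data[, starts[i] + seq_len(len), drop = FALSE]
      arr
    }
    list(
      stimulation = epoch_set(slice(mk$onset[rows]), fs, freq, cond,
                              "stimulation", recording$channel_labels),
      baseline = epoch_set(slice(mk$onset[rows] - len), fs, freq, cond,
                           "baseline", recording$channel_labels)
    )
  })
  names(out) <- names(cells)
  structure(out, class = "ssvep_epoch_map",
            conditions = unique(mk$condition),
            frequencies = sort(unique(mk$frequency)))
}

#' @export
print.ssvep_epoch_map <- function(x, ...) {
  cat(sprintf("<ssvep_epoch_map> %d cell(s): %s x %s Hz\n", length(x),
              paste(attr(x, "conditions"), collapse = "/"),
              paste(attr(x, "frequencies"), collapse = "/")))
  invisible(x)
}
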