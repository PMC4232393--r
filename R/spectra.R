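#' Welch power spectral density
#'
#' Averages modified periodograms of Hann-windowed overlapping segments
#' (1 s windows, 0.25 s hop by default, i.e. 3/4 s overlap). Each segment
#' is mean-detrended before windowing. The density normalization is such
#' that the integral of the PSD over the frequency grid approximates the
#' signal variance.
#'
#' @param x numeric vector, a single-channel signal.
#' @param sampling_rate sampling rate, Hz.
#' @param window_sec segment length, s.
#' @param overlap_sec overlap between consecutive segments, s.
#' @return An object of class `power_spectrum`: `frequencies` (Hz grid
#'   from 0 to Nyquist), `power` (one-sided density, microvolts^2/Hz),
#'   `resolution` (grid spacing, Hz) and `n_segments`.
#' @export
welch_psd <- function(x, sampling_rate, window_sec = 1, overlap_sec = 0.75) {
  wl <- round(window_sec * sampling_rate)
  hop <- wl - round(overlap_sec * sampling_rate)
  if (length(x) < wl)
    stop(sprintf("signal (%d samples) shorter than one %g s window",
                 length(x), window_sec))
  if (hop < 1) stop("overlap must be shorter than the window")
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(wl) - 1) / wl)
  u <- sum(w^2)
  starts <- seq(1, length(x) - wl + 1, by = hop)
  segs <- vapply(starts, function(s) {
    seg <- x[s:(s + wl - 1)]
    (seg - mean(seg)) * w
  }, numeric(wl))
  spec <- stats::mvfft(segs)
  nfreq <- wl %/% 2 + 1
  pxx <- rowMeans(Mod(spec[seq_len(nfreq), , drop = FALSE])^2) /
    (sampling_rate * u)
  if (nfreq > 2) pxx[2:(nfreq - 1)] <- 2 * pxx[2:(nfreq - 1)]
  structure(list(frequencies = seq(0, sampling_rate / 2,
                                   by = sampling_rate / wl),
                 power = pxx,
                 resolution = sampling_rate / wl,
                 n_segments = length(starts)),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d bins, resolution %g Hz, %d segment(s)\n",
              length(x$frequencies), x$resolution, x$n_segments))
  invisible(x)
}

# Mean Welch PSD over the trials of a single-channel epoch set.
mean_psd <- function(epochs, ...) {
  stopifnot(inherits(epochs, "ssvep_epochs"), dim(epochs$epochs)[2] == 1)
  d <- dim(epochs$epochs)
  first <- welch_psd(epochs$epochs[1, 1, ], epochs$sampling_rate, ...)
  acc <- first$power
  if (d[1] > 1) {
    for (tr in 2:d[1])
      acc <- acc + welch_psd(epochs$epochs[tr, 1, ],
                             epochs$sampling_rate, ...)$power
  }
  first$power <- acc / d[1]
  first
}

#' Event-related spectral perturbation at the stimulation frequency
#'
#' The relative change of spectral power at the stimulation frequency
#' during flicker with respect to its pre-stimulus baseline value:
#' `(P_stim - P_base) / P_base`, where each `P` is the Welch PSD value in
#' the bin nearest `frequency`, averaged over that class's trials
#' (average-then-ratio). The relative measure compensates the decreasing
#' 1/f background so responses at different stimulation frequencies are
#' comparable. A value of 4 means a five-fold power increase.
#'
#' @param stim_epochs single-channel stimulation [epoch_set()].
#' @param base_epochs single-channel baseline [epoch_set()].
#' @param frequency readout frequency, Hz.
#' @param variant `"relative"` for `(P_stim - P_base)/P_base` (default) or
#'   `"logratio"` for `10 log10(P_stim / P_base)` in dB.
#' @param ... further arguments passed to [welch_psd()].
#' @return A single ERSP value.
#' @export
ersp <- function(stim_epochs, base_epochs, frequency,
                 variant = c("relative", "logratio"), ...) {
  variant <- match.arg(variant)
  ps <- mean_psd(stim_epochs, ...)
  pb <- mean_psd(base_epochs, ...)
  bin <- which.min(abs(ps$frequencies - frequency))
  if (abs(ps$frequencies[bin] - frequency) > ps$resolution / 2 + 1e-9)
    stop("requested frequency is outside the spectral grid")
  p_stim <- ps$power[bin]
  p_base <- pb$power[bin]
  if (p_base <= 0) stop("baseline power is zero at the readout frequency")
  switch(variant,
         relative = (p_stim - p_base) / p_base,
         logratio = 10 * log10(p_stim / p_base))
}

# Concatenate the trials of several epoch sets (same geometry).
bind_epochs <- function(sets) {
  if (length(sets) == 1) return(sets[[1]])
  d <- dim(sets[[1]]$epochs)
  nt <- sum(vapply(sets, n_trials, 0L))
  arr <- array(0, c(nt, d[2], d[3]))
  at <- 0
  for (s in sets) {
    arr[at + seq_len(n_trials(s)), , ] <- s$epochs
    at <- at + n_trials(s)
  }
  epoch_set(arr, sets[[1]]$sampling_rate, sets[[1]]$frequency, "pooled",
            sets[[1]]$klass, sets[[1]]$channel_labels, sets[[1]]$filtered)
}

#' Compute the ERSP table for a full epoch map
#'
#' Runs the per-frequency narrow-band filter, the CSP projection and the
#' ERSP readout for every (condition, frequency) cell of an epoch map,
#' producing the unit of statistical analysis: one ERSP value per
#' (subject, frequency, condition).
#'
#' The CSP filter is fitted once per stimulation frequency, pooling the
#' (filtered) epochs of all conditions (`csp_scope = "pooled"`), or
#' separately per condition (`"per_condition"`).
#'
#' @param epoch_map an [extract_epochs()] result covering every
#'   (condition, frequency) cell.
#' @param subject subject identifier for the output rows.
#' @param filters optional named list of [design_bandpass()] objects keyed
#'   by frequency; designed automatically when `NULL`.
#' @param apply_filter narrow-band filter the epochs before CSP/ERSP.
#' @param use_csp project through CSP; when `FALSE` the epochs must
#'   already be single-channel.
#' @param csp_scope `"pooled"` or `"per_condition"`.
#' @param variant ERSP variant, see [ersp()].
#' @param zero_phase filtering mode, see [apply_bandpass()].
#' @param ridge CSP regularization, see [fit_csp()].
#' @return A data frame with columns `subject`, `frequency`, `condition`,
#'   `ersp`, `n_trials`, with the fitted band-pass and CSP filters
#'   attached as attributes `bandpass_specs` and `csp_filters`.
#' @export
compute_ersp_table <- function(epoch_map, subject = "S1", filters = NULL,
                               apply_filter = TRUE, use_csp = TRUE,
                               csp_scope = c("pooled", "per_condition"),
                               variant = "relative", zero_phase = TRUE,
                               ridge = 1e-9) {
  stopifnot(inherits(epoch_map, "ssvep_epoch_map"))
  csp_scope <- match.arg(csp_scope)
  conditions <- attr(epoch_map, "conditions")
  frequencies <- attr(epoch_map, "frequencies")
  wanted <- as.vector(outer(conditions, frequencies, paste, sep = "|"))
  missing <- setdiff(wanted, names(epoch_map))
  if (length(missing))
    stop("missing (condition, frequency) cell(s): ",
         paste(missing, collapse = ", "))

  rows <- list()
  specs <- list()
  csps <- list()
  for (f in frequencies) {
    fkey <- as.character(f)
    fs <- epoch_map[[paste(conditions[1], f, sep = "|")]]$stimulation$sampling_rate
    spec <- if (!is.null(filters)) filters[[fkey]] else design_bandpass(f, fs)
    specs[[fkey]] <- spec
    cells <- lapply(conditions, function(cond) {
      cell <- epoch_map[[paste(cond, f, sep = "|")]]
      if (apply_filter) {
        cell$stimulation <- apply_bandpass(cell$stimulation, spec, zero_phase)
        cell$baseline <- apply_bandpass(cell$baseline, spec, zero_phase)
      }
      cell
    })
    names(cells) <- conditions
    if (use_csp && csp_scope == "pooled") {
      flt <- fit_csp(bind_epochs(lapply(cells, `[[`, "stimulation")),
                     bind_epochs(lapply(cells, `[[`, "baseline")),
                     ridge = ridge)
      csps[[fkey]] <- flt
    }
    for (cond in conditions) {
      cell <- cells[[cond]]
      if (use_csp) {
        if (csp_scope == "per_condition") {
          flt <- fit_csp(cell$stimulation, cell$baseline, ridge = ridge)
          csps[[paste(fkey, cond, sep = "|")]] <- flt
        }
        stim <- apply_csp(cell$stimulation, flt)
        base <- apply_csp(cell$baseline, flt)
      } else {
        stim <- cell$stimulation
        base <- cell$baseline
      }
      rows[[length(rows) + 1]] <- data.frame(
        subject = subject, frequency = f, condition = cond,
        ersp = ersp(stim, base, f, variant = variant),
        n_trials = n_trials(stim))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "bandpass_specs") <- specs
  attr(out, "csp_filters") <- csps
  out
}

#' Write an ERSP table to CSV
#'
#' @param table a [compute_ersp_table()] data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ersp_csv <- function(table, path) {
  out <- data.frame(subject = table$subject, frequency_hz = table$frequency,
                    condition = table$condition, ersp = table$ersp,
                    n_trials = table$n_trials)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
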