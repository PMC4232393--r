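#' Default simulated 10-20 montage
#'
#' Twenty channels: eighteen scalp electrodes of the 10-20 system plus the
#' two mastoids (`M1`, `M2`) used for re-referencing.
#'
#' @return Character vector of channel labels.
#' @export
default_montage <- function() {
  c("F3", "Fz", "F4", "F7", "F8", "C3", "Cz", "C4", "T7", "T8",
    "P7", "P3", "Pz", "P4", "P8", "O1", "Oz", "O2", "M1", "M2")
}

#' Default occipito-parietal response topography
#'
#' Gains describing how strongly the SSVEP source projects onto each
#' channel: 1.0 on the occipital pair (O1, O2), 0.6 on the midline and
#' near parietals (Pz, P3, P4), 0.4 on the lateral parietals (P7, P8) and
#' 0 elsewhere - in particular 0 on the mastoids, so re-referencing never
#' subtracts signal.
#'
#' @param channel_labels channels the gain vector should cover.
#' @return Named numeric vector of per-channel gains.
#' @export
default_topography <- function(channel_labels = default_montage()) {
  gains <- c(O1 = 1, O2 = 1, Pz = 0.6, P3 = 0.6, P4 = 0.6,
             P7 = 0.4, P8 = 0.4)
  out <- stats::setNames(numeric(length(channel_labels)), channel_labels)
  hit <- intersect(names(gains), channel_labels)
  out[hit] <- gains[hit]
  out
}

#' Stimulus condition for the simulator
#'
#' Describes one stimulus condition (e.g. a colour or a size) by the SSVEP
#' response strength it evokes: amplitude of the fundamental, relative
#' amplitude of the second harmonic, and the scalp topography through
#' which the source mixes onto channels.
#'
#' @param label condition label.
#' @param ssvep_amplitude amplitude of the fundamental response, microvolts.
#' @param harmonic_ratio amplitude at twice the stimulation frequency as a
#'   fraction of the fundamental amplitude.
#' @param topography optional named numeric vector of per-channel gains;
#'   defaults to [default_topography()] for the session's montage.
#' @return An object of class `ssvep_condition`.
#' @export
condition_spec <- function(label, ssvep_amplitude, harmonic_ratio = 0.25,
                           topography = NULL) {
  if (ssvep_amplitude < 0) stop("`ssvep_amplitude` must be >= 0")
  if (harmonic_ratio < 0) stop("`harmonic_ratio` must be >= 0")
  structure(list(label = as.character(label),
                 ssvep_amplitude = ssvep_amplitude,
                 harmonic_ratio = harmonic_ratio,
                 topography = topography),
            class = "ssvep_condition")
}

#' Configuration of a simulated SSVEP session
#'
#' Defines the experimental design the generator emulates: a multichannel
#' 10-20 recording in which four squares flicker simultaneously at
#' different frequencies, trials of 4 s stimulation followed by 6 s rest,
#' and 30 repetitions per (condition, attended frequency) cell. The
#' background is 1/f^beta-shaped Gaussian noise plus an alpha-band
#' sinusoid per channel.
#'
#' @param sampling_rate recording rate, Hz.
#' @param channel_labels montage; must contain `M1` and `M2`.
#' @param stim_frequencies flicker frequencies presented simultaneously, Hz.
#' @param stim_duration stimulation length per trial, s.
#' @param rest_duration rest length preceding each stimulation, s; must be
#'   at least `stim_duration` so that a full-length baseline epoch fits.
#' @param repetitions_per_condition trials per (condition, frequency) cell.
#' @param conditions list of [condition_spec()] objects.
#' @param noise_exponent spectral exponent beta of the 1/f^beta background.
#' @param noise_psd_10hz one-sided background power spectral density at
#'   10 Hz, microvolts^2/Hz; fixes the overall background scale.
#' @param alpha_amplitude amplitude of the alpha sinusoid, microvolts.
#' @param alpha_frequency alpha frequency, Hz.
#' @param distractor_ratio amplitude of each non-attended flicker frequency
#'   as a fraction of the attended one.
#' @param max_duration optional cap on total session length, s; the
#'   configuration is rejected if the scheduled trials exceed it.
#' @param seed integer seed; identical configurations (including the seed)
#'   generate bit-identical sessions.
#' @return An object of class `ssvep_sim_config`.
#' @export
sim_config <- function(sampling_rate = 1024,
                       channel_labels = default_montage(),
                       stim_frequencies = c(14, 17, 25, 30),
                       stim_duration = 4,
                       rest_duration = 6,
                       repetitions_per_condition = 30,
                       conditions = list(condition_spec("default", 3)),
                       noise_exponent = 1,
                       noise_psd_10hz = 2,
                       alpha_amplitude = 4,
                       alpha_frequency = 10,
                       distractor_ratio = 0.25,
                       max_duration = NULL,
                       seed = 1L) {
  if (stim_duration <= 0) stop("`stim_duration` must be > 0")
  if (rest_duration < stim_duration)
    stop("`rest_duration` must be >= `stim_duration` (baseline epoch must fit)")
  if (any(stim_frequencies >= sampling_rate / 2))
    stop("all stimulation frequencies must be below the Nyquist frequency")
  if (repetitions_per_condition < 1) stop("`repetitions_per_condition` must be >= 1")
  if (!all(c("M1", "M2") %in% channel_labels))
    stop("montage must include mastoid channels M1 and M2")
  if (!length(conditions) || !all(vapply(conditions, inherits, TRUE, "ssvep_condition")))
    stop("`conditions` must be a non-empty list of condition_spec() objects")

  conditions <- lapply(conditions, function(cond) {
    topo <- cond$topography %||% default_topography(channel_labels)
    if (is.null(names(topo)))
      stop("condition topography must be a named vector")
    unknown <- setdiff(names(topo), channel_labels)
    if (length(unknown))
      stop("unknown channel in topography: ", paste(unknown, collapse = ", "))
    full <- stats::setNames(numeric(length(channel_labels)), channel_labels)
    full[names(topo)] <- topo
    if (any(full[c("M1", "M2")] != 0))
      stop("mastoid topography gains must be 0")
    cond$topography <- full
    cond
  })
  labels <- vapply(conditions, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("condition labels must be unique")

  cfg <- structure(
    list(sampling_rate = sampling_rate, channel_labels = channel_labels,
         stim_frequencies = stim_frequencies, stim_duration = stim_duration,
         rest_duration = rest_duration,
         repetitions_per_condition = repetitions_per_condition,
         conditions = conditions, noise_exponent = noise_exponent,
         noise_psd_10hz = noise_psd_10hz, alpha_amplitude = alpha_amplitude,
         alpha_frequency = alpha_frequency, distractor_ratio = distractor_ratio,
         max_duration = max_duration, seed = as.integer(seed)),
    class = "ssvep_sim_config")
  total <- session_duration(cfg)
  if (!is.null(max_duration) && total > max_duration)
    stop(sprintf("session too long: %.0f s scheduled, %.0f s allowed",
                 total, max_duration))
  cfg
}

session_duration <- function(config) {
  n_trials <- length(config$conditions) * length(config$stim_frequencies) *
    config$repetitions_per_condition
  n_trials * (config$stim_duration + config$rest_duration)
}

#' Steady-state response waveform
#'
#' A sinusoid at the stimulation frequency plus a second-harmonic
#' component, the minimal model of an SSVEP entrained at the flicker
#' frequency and its harmonic.
#'
#' @param frequency fundamental frequency, Hz.
#' @param amplitude fundamental amplitude, microvolts.
#' @param harmonic_ratio second-harmonic amplitude as a fraction of
#'   `amplitude`.
#' @param duration length, s.
#' @param sampling_rate sampling rate, Hz.
#' @param phase phase offset, radians.
#' @return Numeric vector of `round(duration * sampling_rate)` samples.
#' @export
ssvep_waveform <- function(frequency, amplitude, harmonic_ratio = 0,
                           duration = 4, sampling_rate = 1024, phase = 0) {
  if (duration <= 0) stop("`duration` must be > 0")
  if (2 * frequency >= sampling_rate / 2)
    stop(sprintf("aliasing: harmonic 2f = %g Hz is at or above Nyquist (%g Hz)",
                 2 * frequency, sampling_rate / 2))
  n <- round(duration * sampling_rate)
  t <- (seq_len(n) - 1) / sampling_rate
  amplitude * sin(2 * pi * frequency * t + phase) +
    harmonic_ratio * amplitude * sin(4 * pi * frequency * t + phase)
}

#' Theoretical background power spectral density
#'
#' One-sided PSD of the simulated background noise (excluding the alpha
#' line) at a given frequency: `noise_psd_10hz * (10 / max(f, 1))^beta`.
#' Frequencies below 1 Hz are clipped to keep the low end finite.
#'
#' @param config a [sim_config()].
#' @param frequency frequency, Hz.
#' @return PSD in microvolts^2/Hz.
#' @export
background_psd <- function(config, frequency) {
  config$noise_psd_10hz *
    (10 / pmax(frequency, 1))^config$noise_exponent
}

#' Fundamental amplitude achieving a target stimulation/baseline power ratio
#'
#' Computes the SSVEP fundamental amplitude for which the Welch spectrum
#' (1 s Hann windows) of a single analysis channel has an expected
#' stimulation-to-baseline power ratio `power_ratio` in the bin at
#' `frequency`. A bin-centred sinusoid of amplitude `a` contributes
#' `a^2/3` to the peak bin of the Hann-windowed density estimate, and
#' linked-mastoid re-referencing inflates independent per-channel
#' background power by the factor 3/2; both constants enter the
#' calibration.
#'
#' @param config a [sim_config()].
#' @param frequency stimulation frequency, Hz (must be an integer bin).
#' @param power_ratio target ratio of stimulation to baseline bin power
#'   (> 1).
#' @param channel analysis channel whose topography gain applies.
#' @param rereferenced whether the analysis channel will be linked-mastoid
#'   re-referenced before spectra are taken.
#' @param condition index of the condition whose topography applies.
#' @return Amplitude in microvolts.
#' @export
calibrate_amplitude <- function(config, frequency, power_ratio,
                                channel = "O1", rereferenced = TRUE,
                                condition = 1L) {
  if (power_ratio <= 1) stop("`power_ratio` must be > 1")
  gain <- config$conditions[[condition]]$topography[channel]
  if (is.na(gain) || gain == 0)
    stop("channel ", channel, " has no topography gain")
  noise_factor <- if (rereferenced) 1.5 else 1
  s_f <- background_psd(config, frequency)
  as.numeric(sqrt(3 * (power_ratio - 1) * noise_factor * s_f) / gain)
}

# Gaussian noise with one-sided target PSD psd_fun(f), via frequency-domain
# shaping. Exact expected spectrum; DC removed.
shaped_noise <- function(n, fs, psd_fun) {
  nf <- floor(n / 2)
  fk <- (1:nf) * fs / n
  sig2 <- n * fs * psd_fun(fk) / 2
  spec <- complex(length.out = n)
  even <- n %% 2 == 0
  ncplx <- if (even) nf - 1 else nf
  spec[2:(ncplx + 1)] <- sqrt(sig2[1:ncplx] / 2) *
    complex(real = stats::rnorm(ncplx), imaginary = stats::rnorm(ncplx))
  if (even) spec[nf + 1] <- stats::rnorm(1) * sqrt(sig2[nf])
  spec[n:(n - ncplx + 1)] <- Conj(spec[2:(ncplx + 1)])
  Re(stats::fft(spec, inverse = TRUE)) / n
}

#' Simulate an SSVEP session
#'
#' Generates a continuous multichannel recording following the configured
#' design: trials of `rest_duration` seconds of rest followed by
#' `stim_duration` seconds in which all flicker frequencies are active
#' simultaneously. The attended frequency is injected at the condition's
#' full amplitude, the remaining frequencies at `distractor_ratio` times
#' it; all are mixed onto channels through the condition topography and
#' added to a continuously running 1/f + alpha background. Trial order is
#' randomized. The SSVEP phase is drawn independently per trial and
#' frequency. Markers record the onset sample, attended frequency and
#' condition of every trial.
#'
#' @param config a [sim_config()].
#' @return An [raw_recording()] with one marker per trial.
#' @export
simulate_session <- function(config) {
  stopifnot(inherits(config, "ssvep_sim_config"))
  fs <- config$sampling_rate
  freqs <- config$stim_frequencies
  conds <- config$conditions
  reps <- config$repetitions_per_condition
  stim_len <- round(config$stim_duration * fs)
  trial_len <- round((config$stim_duration + config$rest_duration) * fs)
  schedule <- expand.grid(rep = seq_len(reps),
                          frequency = freqs,
                          condition = seq_along(conds))
  n_trials <- nrow(schedule)
  total <- n_trials * trial_len
  n_ch <- length(config$channel_labels)

  with_seed(config$seed, {
    schedule <- schedule[sample.int(n_trials), , drop = FALSE]
    data <- matrix(0, n_ch, total)
    for (ch in seq_len(n_ch)) {
      bg <- shaped_noise(total, fs, function(f) background_psd(config, f))
      phi <- stats::runif(1, 0, 2 * pi)
      t <- (seq_len(total) - 1) / fs
      data[ch, ] <- bg + config$alpha_amplitude *
        sin(2 * pi * config$alpha_frequency * t + phi)
    }
    onsets <- (seq_len(n_trials) - 1) * trial_len +
      round(config$rest_duration * fs)
    for (i in seq_len(n_trials)) {
      cond <- conds[[schedule$condition[i]]]
      attended <- schedule$frequency[i]
      idx <- onsets[i] + seq_len(stim_len)
      for (f in freqs) {
        amp <- if (f == attended) cond$ssvep_amplitude else
          config$distractor_ratio * cond$ssvep_amplitude
        if (amp == 0) next
        wave <- ssvep_waveform(f, amp, cond$harmonic_ratio,
                               config$stim_duration, fs,
                               phase = stats::runif(1, 0, 2 * pi))
        active <- which(cond$topography != 0)
        data[active, idx] <- data[active, idx, drop = FALSE] +
          outer(cond$topography[active], wave)
      }
    }
    markers <- data.frame(
      onset = onsets,
      frequency = schedule$frequency,
      condition = vapply(conds[schedule$condition], `[[`, "", "label")
    )
    raw_recording(data, fs, config$channel_labels, markers)
  })
}
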