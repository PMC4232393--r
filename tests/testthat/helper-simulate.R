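# Small simulated sessions used across tests. The reduced montage keeps
# the seven analysis channels plus mastoids; low sampling rate and few
# repetitions keep the suite fast while preserving the session structure.

compact_montage <- function() c(ssvepr::analysis_montage(), "Cz", "M1", "M2")

small_config <- function(reps = 5,
                         freqs = c(14, 17),
                         conditions = list(condition_spec("default", 3)),
                         fs = 128,
                         seed = 1,
                         ...) {
  sim_config(sampling_rate = fs,
             channel_labels = compact_montage(),
             stim_frequencies = freqs,
             repetitions_per_condition = reps,
             conditions = conditions,
             seed = seed,
             ...)
}

# Epoch set of white-noise epochs, for statistical null checks.
noise_epochs <- function(n, samples = 512, channels = 1, fs = 128,
                         klass = "baseline", sd = 1, frequency = 17) {
  arr <- array(stats::rnorm(n * channels * samples, sd = sd),
               c(n, channels, samples))
  epoch_set(arr, fs, frequency, "test", klass,
            paste0("ch", seq_len(channels)))
}

# Band power of a single-channel signal in [f - width, f + width], via
# the raw periodogram (independent of the package's Welch estimator).
band_power <- function(x, fs, f, width = 1) {
  n <- length(x)
  spec <- Mod(stats::fft(x - mean(x)))^2 / n^2
  freqs <- (seq_len(n) - 1) * fs / n
  sel <- freqs >= f - width & freqs <= f + width
  2 * sum(spec[sel])
}
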