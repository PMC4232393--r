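Package: ssvepr
Title: Quantification of Steady-State Visual Evoked Potentials from Multichannel EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify steady-state visual evoked potential (SSVEP)
    responses in multichannel EEG recorded under flickering visual stimulation.
    Implements the full analysis chain used in SSVEP brain-computer interface
    research: occipito-parietal channel selection, linked-mastoid re-referencing,
    anti-aliased decimation, per-frequency narrow-band elliptic filtering,
    Common Spatial Patterns (CSP) spatial filtering, Welch power spectra, the
    event-related spectral perturbation (ERSP) measure of response strength,
    and nonparametric repeated-measures inference (Friedman omnibus test with
    Wilcoxon signed-rank post-hoc comparisons under Bonferroni correction).
    Includes a synthetic session generator that emulates a 10-20 montage
    recording with known injected SSVEP amplitudes on a 1/f-plus-alpha
    background, so that every stage of the pipeline can be validated against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
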