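Package: ssmvep
Title: Bimodal Motion-Color SSMVEP Stimulus Synthesis and EEG Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Tools for steady-state motion visual evoked potential (SSMVEP)
    brain-computer interface research with bimodal motion-color stimuli.
    Synthesises Newton's-rings stimuli with equal-luminance red/green colour
    modulation (parametric ring geometry with a controlled band/background
    area ratio), generates synthetic multichannel EEG sessions from a
    configurable forward model (stimulus-locked harmonics, 1/f background,
    band-limited theta/alpha/beta components with task-wise drifts), and
    implements the downstream analyses: zero-phase Butterworth filter chains
    and epoching, Welch power spectral density and harmonic signal-to-noise
    ratio, FFT amplitude spectra of trial averages, bandpower-ratio
    workload and fatigue trends, and frequency recognition by canonical
    correlation analysis and by a compact depthwise-separable convolutional
    network, including segment-length accuracy sweeps and a seeded
    end-to-end pipeline.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
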