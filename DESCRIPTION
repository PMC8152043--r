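Package: texturestim
Title: Simulating Electrotactile Texture Feedback from Friction Sounds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulator of a sensory-feedback pipeline that converts
    friction sounds, recorded while stroking surface textures with a
    microphone, into frequency-modulated transcutaneous electrical
    stimulation. Provides mono 16-bit PCM WAV input/output, sliding-window
    FFT feature extraction (median frequency, mean frequency, total spectral
    magnitude with mains-notch and low-frequency exclusion), a linear
    median-frequency-to-stimulation-frequency transfer function with energy
    gating, a discrete-event model of a pulse stimulator with
    update-after-pulse and communication-latency constraints, a seeded
    synthetic friction-sound generator reproducing four canonical texture
    signatures, and a three-phase texture-discrimination experiment harness
    with a simulated template-matching observer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
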