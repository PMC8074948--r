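Package: fdlockin
Title: Fast Digital Lock-In Demodulation for Frequency-Multiplexed Image
    Stacks
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Simulation and demodulation toolkit for dual-channel
    (bright-field + fluorescence) imaging in which the two illumination
    sources are square-wave modulated at a 2:1 frequency ratio and a
    single camera stream carries both channels. Provides discrete
    square-wave modulation and reference generators, a multiplication-free
    digital lock-in demodulator (per-pixel correlation by frame addition
    and subtraction, with optional in-phase/quadrature amplitude and phase
    maps), a synthetic phantom and frame-stack simulator with additive
    Gaussian sensor noise, image signal-to-noise-ratio metrics based on
    mean squared error, an experiment driver that tabulates the SNR gain
    of lock-in acquisition over single-frame time-sharing acquisition,
    TIFF/PNG stack input/output, a fluorescence overlay renderer, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
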