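# fdlockin

Fast digital lock-in demodulation for frequency-multiplexed image stacks.

## The problem

Dual-channel fluorescence endoscopes need a bright-field (white light)
image and a near-infrared fluorescence image of dye-labelled tissue from a
single camera. Time-sharing the two light sources halves the frame rate
and leaves each channel with single-frame noise. The alternative is
frequency-division multiplexing: both sources are square-wave modulated at
a 2:1 frequency ratio (by default 12 Hz white and 6 Hz NIR under a 48 fps
camera) so every frame carries both channels, and each channel is
recovered digitally by lock-in detection.

`fdlockin` implements the whole simulation and analysis chain for this
scheme, for people developing or evaluating modulated-illumination imaging
systems:

* **waveforms** — discrete square-wave modulation/reference generators,
  quadrature shifts, and exact (integer-arithmetic) orthogonality checks;
* **lock-in demodulation** — the fast algorithm: because the reference is
  a ±1 square wave sampled at 4k times the signal frequency, the per-pixel
  correlation

  `f̂ = (2/n) Σ_t g_t r_t`,  `r_t ∈ {+1, −1}`

  reduces to adding and subtracting whole frames. Whole-period boxcar
  integration rejects constant ambient light exactly and the other
  channel exactly (orthogonal references at ratio 2); I/Q demodulation
  with the triangular square-on-square phase response recovers amplitude
  (`|I|+|Q|`) and phase for stacks of unknown phase;
* **simulator** — a deterministic phantom generator (bright-field scene
  with a fluorescent sub-region), modulated stack rendering, additive
  Gaussian sensor noise, and the single-frame time-sharing baseline;
* **metrics** — image SNR as `10·log10(I_original / MSE)` against the
  clean reference, with with/without-lock-in comparison reports;
* **experiment + CLI** — a driver that tabulates SNR with and without
  lock-in across noise levels, stack I/O (multi-page TIFF or PNG sequences
  with JSON sidecars), and a fluorescence overlay renderer.

The demodulated image's noise variance is `4σ²/n` for an `n`-frame window,
versus `σ²` for the one-frame baseline, so lock-in acquisition gains
`10·log10(n/4)` dB at every noise level — 6.99 dB for the standard
20-frame window. Reproducing that flat ~7 dB improvement is the package's
headline experiment.

## Worked example

```r
library(fdlockin)

scene <- make_phantom(c(128, 128), style = "letters", seed = 1)
cfg   <- modulation_config()            # 48 fps, 12 Hz white / 6 Hz fluor, 24 frames
stack <- add_noise(simulate_stack(scene, cfg), noise_sigma = 0.1, seed = 2)

res      <- demultiplex_dual(stack)     # both channels from one noisy stack
baseline <- time_sharing_baseline(scene, 0.1, seed = 3)

compare_snr(scene$white_image, res$channel_images$white, baseline$white_noisy)
#> snr_report (128 x 128): I_original = 0.3185
#>   with lock-in:    MSE = 0.001668, SNR = 22.81 dB
#>   without lock-in: MSE = 0.0101, SNR = 14.99 dB
#>   improvement: 7.82 dB
```

Reading the numbers: the baseline frame has error power `MSE ≈ σ² = 0.01`;
the 24-frame lock-in window suppresses it to `≈ 4σ²/24 = 0.00167`, a
`10·log10(6) = 7.78` dB gain (the 20-frame single-channel protocol used by
the SNR tables gives 6.99 dB). `I_original` is the clean image's mean
squared intensity, the numerator of both SNRs.

The same pipeline is scriptable from a shell via the thin front end in
`inst/cli/`:

```sh
fdlockin simulate --out stack.tif --noise-sigma 0.1 --seed 1
fdlockin demodulate --stack stack.tif --out-prefix out/demod
fdlockin reproduce-tables --out-prefix out/tables --verbose
fdlockin fuse --white out/demod_white.tif --fluor out/demod_fluor.tif --out fused.png
```

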