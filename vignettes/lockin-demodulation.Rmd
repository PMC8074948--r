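---
title: "Frequency-multiplexed image acquisition and fast lock-in demodulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-multiplexed image acquisition and fast lock-in demodulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdlockin)
```

## The acquisition model

Dual-channel fluorescence endoscopy wants two images from one camera at
once: a bright-field (white light) view and a near-infrared fluorescence
view of dye-labelled tissue. The conventional *time-sharing* scheme
alternates the two light sources frame by frame, which halves the usable
frame rate and leaves each channel with whatever noise a single frame
carries. The alternative modelled here is *frequency-division
multiplexing*: both sources stay on simultaneously but are switched on and
off as square waves at different frequencies — by default the white source
at 12 Hz and the NIR source at 6 Hz under a 48 fps camera, i.e. 4 and 8
frames per modulation period. Each recorded frame is then

$$ g_t \;=\; f_\mathrm{w}\, m_\mathrm{w}(t) \;+\; f_\mathrm{f}\, m_\mathrm{f}(t)
   \;+\; c \;+\; \varepsilon_t, $$

where $f_\mathrm{w}, f_\mathrm{f}$ are the clean channel images,
$m_\mathrm{w}, m_\mathrm{f} \in \{0,1\}$ the unipolar gating waveforms,
$c$ a constant ambient offset, and $\varepsilon_t$ zero-mean Gaussian
sensor noise of standard deviation $\sigma$ per pixel per frame.

## The fast digital lock-in demodulator

Each channel is recovered by correlating the frame sequence with a
*bipolar* ($\pm 1$) reference square wave at that channel's frequency and
integrating over the window (a boxcar filter):

$$ \hat f \;=\; \frac{2}{n} \sum_{t=1}^{n} g_t\, r_t , \qquad r_t \in \{+1, -1\}. $$

Because the reference only takes the values $\pm 1$, the sum is computed by
*adding* the frames where the reference is high and *subtracting* those
where it is low — no per-pixel multiplications, which is what makes the
algorithm fast on embedded hardware and is why the sampling rate must be
$4k$ times the modulation frequency ($k$ integer): the reference then flips
sign on exact frame boundaries. The test suite checks this addition/
subtraction path is bit-for-bit identical to the naive multiply-and-average
definition.

Three exact cancellation properties carry the method:

* a bipolar reference sums to zero over whole periods, so the ambient
  offset $c$ (and any constant background) correlates to exactly zero;
* two bipolar square waves at frequency ratio 2 are orthogonal over whole
  common periods, so the other channel correlates to exactly zero
  (`check_orthogonal()` verifies this in integer arithmetic). Ratios other
  than 2 share odd harmonics and are rejected for demultiplexing;
* the unipolar gating correlates with its own reference to $n/2$, so the
  $2/n$ normalization returns the channel at its true amplitude: a
  noiseless stack reproduces the scene to float tolerance.

### Phase

With signal and reference both square, the detector output as a function of
their phase difference $\varphi$ is triangular, not sinusoidal:
$WA(1 - 2\varphi/\pi)$ on $(0, \pi)$ and $WA(2\varphi/\pi - 3)$ on
$(\pi, 2\pi)$ (`phase_response()`; the open-interval branch ends agree, so
we take branch limits at $0$ and $\pi$). Phase offsets are whole-sample
cyclic advances — an offset of $d$ samples at $P$ samples per period is
$\varphi = 2\pi d / P$ — and the quadrature reference is the in-phase
reference advanced by exactly $P/4$ samples. For this triangular response
the exact amplitude estimator is $|I| + |Q|$, which is constant over all
phase offsets; the Euclidean $\sqrt{I^2+Q^2}$ is offered as an option but
dips between the axes. Phase is recovered by inverting the triangle
piecewise-linearly per quadrant and is defined as 0 where the amplitude is
0. The standard pipeline assumes the sources start high at frame 0 (the
hardware synchronization convention); `demodulate_iq()` handles stacks of
unknown phase.

### Noise

The demodulator passes noise through $\hat\varepsilon = (2/n)\sum \varepsilon_t r_t$,
so the recovered image's error variance is exactly

$$ \operatorname{Var}(\hat f - f) \;=\; \frac{4\sigma^2}{n}. $$

The one-frame time-sharing baseline has error variance $\sigma^2$, so the
SNR gain of lock-in acquisition is $10\log_{10}(n/4)$ dB — independent of
the noise level and of the scene. With the default 20-frame single-channel
window that is $10\log_{10} 5 = 6.99$ dB; with the 24-frame dual-channel
window, $7.78$ dB.

## Image SNR metric

Image quality is scored against the clean reference image $f$ by

$$ \mathrm{SNR} = 10 \log_{10} \frac{I_\mathrm{original}}{\mathrm{MSE}},
   \qquad I_\mathrm{original} = \frac{1}{MN}\sum f^2(i,j),
   \qquad \mathrm{MSE} = \frac{1}{MN}\sum \big(f(i,j)-g(i,j)\big)^2 . $$

A perfect reconstruction returns an explicit `Inf` sentinel (the ratio is
undefined at zero error) and an all-zero reference with zero error is an
error (0/0). Two structural consequences are worth noting because the
experiment tables inherit them: the *improvement*
$\mathrm{SNR}_\mathrm{with} - \mathrm{SNR}_\mathrm{without}$ depends only
on the MSE ratio ($I_\mathrm{original}$ cancels), and the baseline SNR
falls exactly 20 dB per decade of noise level because its MSE is
$\sigma^2$.

## The synthetic phantom and the experiment

No real endoscope frames ship with the package; the generator
`make_phantom()` emulates the kind of bench target used to validate such
systems: a textured, graded bright-field scene with the block letters
"TJPU", and a fluorescence channel lit on the "TJ" letters only (a dye
applied to a sub-region). Intensities are quantized to 4096 grey levels
(a 12-bit sensor's resolution). Scenes are deterministic in
`(shape, style, seed)`.

`reproduce_tables()` runs the full comparison: for each channel and each
noise level $\sigma \in \{0.01, 0.05, 0.1, 0.15, 0.2, 0.25, 0.3\}$ it
simulates `n_seeds = 20` independent acquisitions, demodulates a 20-frame
single-channel stack, scores it against the clean channel, and compares
with a single-frame baseline carrying an independent noise realization:

```{r tables, eval = FALSE}
tab <- reproduce_tables(experiment_config(seed = 1))
format_snr_table(tab, "white")
mean_improvement_db(tab)
```

The improvement column sits at $6.99 \pm$ Monte-Carlo noise at *every*
level — the flatness, not the absolute SNRs, is the informative output.
"Noise level" here means the Gaussian $\sigma$ on the $[0,1]$ intensity
scale: that reading is forced by the baseline's exact 20 dB-per-decade
structure. Noisy pixels are deliberately *not* clipped to $[0,1]$ (a
`clip` option exists): clipping truncates the noise distribution, breaks
the closed-form laws, and would erode the constant improvement at high
$\sigma$.

Design choices that were genuinely open, and how they were fixed:

* **Single-channel window of 20 frames** (5 periods at 4 frames/period)
  for the table protocol, each channel sampled at $f_s = 4f$. This is the
  smallest round window whose theoretical gain $10\log_{10}(20/4)$ matches
  the 7 dB regime the method is known for; the window length is exposed,
  and the noise-suppression law is asserted for $n \in \{8, 20, 40\}$.
* **Dual-channel window of 24 frames** (3 common periods of the 6 Hz
  channel at 48 fps), since 20 frames is not a whole number of slow-channel
  periods; dual-mode table runs are labelled with their own 7.78 dB gain.
* **Whole-period windows are enforced, never silently truncated** — a
  partial period leaks ambient and cross-channel signal; `trim` drops
  trailing frames explicitly.
* **Seeding**: every stochastic entry point takes a seed and restores the
  caller's RNG state; the experiment driver derives one scene seed and
  independent per-realization noise seeds (lock-in arm and baseline arm
  separately) from the master seed, so runs are exactly repeatable and
  arms are statistically independent.
* **Phantom glyphs are block bitmaps**, not font rasterizations, to keep
  generation dependency-free and deterministic across platforms.

## Problem sizes

The shipped protocol uses a $256 \times 256$ phantom, 20 noise seeds, 7
noise levels and both channels (280 acquisitions of 20 frames each); it
completes in well under a minute on a single core. The Monte-Carlo
variance checks use $\ge 100$ seeds on small ($12 \times 12$) constant
scenes, which pins the $4\sigma^2/n$ law to within a few percent.

## What the simulation does and does not show

The generator models copied clean frames plus i.i.d. Gaussian read noise —
the regime in which the $4\sigma^2/n$ law and the flat 7 dB improvement
are exact. Real endoscope stacks add effects deliberately out of scope:
photon (Poisson) noise, sensor saturation, motion between frames,
illumination flicker and drift, optics/PSF blur, and dye pharmacokinetics.
The demodulator can be *applied* to real stacks (`read_stack()` accepts
any TIFF/PNG dialect written by this package), but the closed-form gains
quoted here should not be expected to transfer quantitatively: passing the
acceptance suite shows the algorithm and its statistical laws are
implemented correctly, not that a particular instrument will gain 7 dB.
Hardware synchronization between the modulators and the camera is assumed
(both sources start high at frame 0); stacks with unknown phase must go
through the I/Q path.
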