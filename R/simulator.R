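#' Modulation configuration for frame-stack acquisition
#'
#' Describes how the two illumination sources are square-wave modulated
#' relative to the camera frame clock. Defaults follow a 48 fps camera with
#' the white source at 12 Hz and the near-infrared (fluorescence excitation)
#' source at 6 Hz, i.e. 4 and 8 frames per period. Each active channel must
#' satisfy the fast lock-in sampling constraint: `frame_rate / freq` an
#' integer multiple of 4.
#'
#' In `dual_channel` mode the white frequency must be exactly twice the
#' fluorescence frequency (square waves at other integer ratios share odd
#' harmonics and cannot be separated), and the integration window `n_frames`
#' must cover whole periods of the slower channel. The dual-channel default
#' window is 24 frames (three 6 Hz periods at 48 fps); the single-channel
#' default is 20 frames (five periods at 4 frames per period).
#'
#' @param frame_rate Camera frame rate in frames/s.
#' @param freq_white,freq_fluor Modulation frequencies in Hz.
#' @param n_frames Integration window in frames; `NULL` picks the mode
#'   default (20 single-channel, 24 dual-channel).
#' @param noise_sigma Standard deviation of additive Gaussian sensor noise
#'   on the `[0,1]` intensity scale.
#' @param mode `"dual_channel"` or `"single_channel"`.
#' @param channel Active channel in single-channel mode.
#' @param ambient Constant additive ambient offset applied to every frame.
#' @param phase_white,phase_fluor Modulation phase offsets in samples
#'   (cyclic advance; both sources start high at frame 0 by default).
#' @param seed Integer seed associated with noise realizations.
#' @return An object of class `modulation_config`.
#' @examples
#' modulation_config()                                   # dual-channel default
#' modulation_config(mode = "single_channel", channel = "white")
#' @export
modulation_config <- function(frame_rate = 48, freq_white = 12, freq_fluor = 6,
                              n_frames = NULL, noise_sigma = 0,
                              mode = c("dual_channel", "single_channel"),
                              channel = c("white", "fluor"),
                              ambient = 0, phase_white = 0L, phase_fluor = 0L,
                              seed = 1L) {
  mode <- match.arg(mode)
  channel <- match.arg(channel)
  if (noise_sigma < 0) stop("'noise_sigma' must be >= 0", call. = FALSE)
  active <- if (mode == "dual_channel") c("white", "fluor") else channel
  periods <- list()
  for (ch in active) {
    freq <- if (ch == "white") freq_white else freq_fluor
    if (freq <= 0 || frame_rate <= 0 || frame_rate %% freq != 0) {
      stop(sprintf("frame_rate (%g) must be an integer multiple of the %s frequency (%g)",
                   frame_rate, ch, freq), call. = FALSE)
    }
    p <- frame_rate / freq
    if (p %% 4 != 0) {
      stop(sprintf("%s channel: frame_rate/freq = %g frames per period must be a multiple of 4 (fs = 4k x f)",
                   ch, p), call. = FALSE)
    }
    periods[[ch]] <- as.integer(p)
  }
  if (mode == "dual_channel" && freq_white != 2 * freq_fluor) {
    stop("dual-channel mode requires freq_white = 2 * freq_fluor; ",
         "other ratios suffer odd-harmonic cross-talk", call. = FALSE)
  }
  if (is.null(n_frames)) {
    n_frames <- if (mode == "dual_channel") 3L * periods$fluor else 5L * periods[[channel]]
  }
  n_frames <- as.integer(n_frames)
  slow_period <- if (mode == "dual_channel") periods$fluor else periods[[channel]]
  if (n_frames < slow_period || n_frames %% slow_period != 0) {
    stop(sprintf("'n_frames' (%d) must be a whole multiple of the slowest active period (%d frames)",
                 n_frames, slow_period), call. = FALSE)
  }
  structure(
    list(
      frame_rate = frame_rate, freq_white = freq_white, freq_fluor = freq_fluor,
      n_frames = n_frames, noise_sigma = noise_sigma, mode = mode,
      channel = if (mode == "single_channel") channel else NULL,
      ambient = ambient,
      phase_white = as.integer(phase_white), phase_fluor = as.integer(phase_fluor),
      seed = as.integer(seed),
      periods = periods
    ),
    class = "modulation_config"
  )
}

#' @export
print.modulation_config <- function(x, ...) {
  chans <- if (x$mode == "dual_channel") "white + fluor" else x$channel
  cat(sprintf(
    "modulation_config: %s (%s), %g fps, white %g Hz / fluor %g Hz, %d frames, sigma = %g, ambient = %g\n",
    x$mode, chans, x$frame_rate, x$freq_white, x$freq_fluor, x$n_frames,
    x$noise_sigma, x$ambient
  ))
  invisible(x)
}

#' Build the square-wave spec of one channel of a configuration
#'
#' @param config A [modulation_config()].
#' @param channel `"white"` or `"fluor"`.
#' @param polarity `"unipolar"` for the source gating waveform, `"bipolar"`
#'   for the matching lock-in reference.
#' @return A [square_wave_spec()] with `n_samples = config$n_frames`.
#' @export
channel_spec <- function(config, channel = c("white", "fluor"),
                         polarity = c("bipolar", "unipolar")) {
  stopifnot(inherits(config, "modulation_config"))
  channel <- match.arg(channel)
  polarity <- match.arg(polarity)
  freq <- if (channel == "white") config$freq_white else config$freq_fluor
  phase <- if (channel == "white") config$phase_white else config$phase_fluor
  square_wave_spec(
    samples_per_period = config$frame_rate / freq,
    n_samples = config$n_frames,
    phase_offset_samples = phase,
    polarity = polarity,
    amplitude = 1
  )
}

#' Construct a frame stack
#'
#' A frame stack is an ordered sequence of equally sized grayscale frames
#' stored as a `rows x cols x n_frames` numeric array, carrying its
#' acquisition configuration as provenance.
#'
#' @param frames 3-D numeric array (`rows x cols x n_frames`).
#' @param config A [modulation_config()]; its `n_frames` must match.
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, config) {
  stopifnot(inherits(config, "modulation_config"))
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop("'frames' must be a rows x cols x n_frames array", call. = FALSE)
  }
  if (dim(frames)[3] != config$n_frames) {
    stop(sprintf("stack has %d frames but config expects %d",
                 dim(frames)[3], config$n_frames), call. = FALSE)
  }
  structure(list(frames = frames, config = config), class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("frame_stack: %d frames of %d x %d (%s)\n",
              d[3], d[1], d[2], x$config$mode))
  invisible(x)
}

#' @export
dim.frame_stack <- function(x) dim(x$frames)

#' Render a noiseless modulated frame stack from a phantom scene
#'
#' Frame `i` is `white_image * m_w[i] + fluor_image * m_f[i] + ambient`,
#' where `m_w` and `m_f` are the unipolar (on/off) source gating waveforms of
#' the configuration; single-channel mode uses only the active channel's
#' term. The output is noiseless — apply [add_noise()] to model the sensor.
#'
#' @param scene A [make_phantom()] scene.
#' @param config A [modulation_config()].
#' @return A [frame_stack()].
#' @examples
#' scene <- make_phantom(c(32, 32), seed = 1)
#' stack <- simulate_stack(scene, modulation_config())
#' dim(stack)
#' @export
simulate_stack <- function(scene, config = modulation_config()) {
  stopifnot(inherits(scene, "phantom_scene"), inherits(config, "modulation_config"))
  nr <- nrow(scene$white_image); nc <- ncol(scene$white_image)
  n <- config$n_frames
  frames <- array(config$ambient, dim = c(nr, nc, n))
  active <- if (config$mode == "dual_channel") c("white", "fluor") else config$channel
  for (ch in active) {
    m <- square_wave(channel_spec(config, ch, polarity = "unipolar"))
    img <- if (ch == "white") scene$white_image else scene$fluor_image
    for (i in which(m > 0)) frames[, , i] <- frames[, , i] + img * m[i]
  }
  frame_stack(frames, config)
}

#' Add Gaussian sensor noise to a frame stack
#'
#' Adds an independent zero-mean Gaussian draw of standard deviation
#' `noise_sigma` to every pixel of every frame. Pixels are *not* clipped to
#' `[0,1]` by default: clipping distorts the noise distribution and breaks
#' the closed-form SNR laws; enable it with `clip = TRUE` to emulate a
#' saturating sensor.
#'
#' @param stack A [frame_stack()].
#' @param noise_sigma Noise standard deviation on the `[0,1]` scale.
#' @param seed Integer seed; the result is deterministic given it.
#' @param clip Clip noisy pixels to `[0,1]`? Default `FALSE`.
#' @return A `frame_stack` with noisy frames; the embedded config records
#'   `noise_sigma` and `seed`.
#' @export
add_noise <- function(stack, noise_sigma, seed = stack$config$seed, clip = FALSE) {
  stopifnot(inherits(stack, "frame_stack"))
  if (length(noise_sigma) != 1L || !is.finite(noise_sigma) || noise_sigma < 0) {
    stop("'noise_sigma' must be a nonnegative number", call. = FALSE)
  }
  frames <- stack$frames
  if (noise_sigma > 0) {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(as.integer(seed))
    frames <- frames + array(stats::rnorm(length(frames), sd = noise_sigma),
                             dim = dim(frames))
    if (clip) frames[] <- pmin(pmax(frames, 0), 1)
  }
  config <- stack$config
  config$noise_sigma <- noise_sigma
  config$seed <- as.integer(seed)
  frame_stack(frames, config)
}

#' Single-frame time-sharing baseline acquisition
#'
#' The conventional comparator for lock-in acquisition: each channel is
#' imaged in its own dedicated frame under full (unmodulated) illumination,
#' with one Gaussian noise realization per channel and no frame averaging.
#' Its expected mean squared error against the clean scene is exactly
#' `noise_sigma^2`.
#'
#' @param scene A [make_phantom()] scene.
#' @param noise_sigma Noise standard deviation.
#' @param seed Integer seed (white and fluorescence draws are independent).
#' @return List with `white_noisy` and `fluor_noisy` matrices.
#' @export
time_sharing_baseline <- function(scene, noise_sigma, seed = scene$seed) {
  stopifnot(inherits(scene, "phantom_scene"))
  if (noise_sigma < 0) stop("'noise_sigma' must be >= 0", call. = FALSE)
  npix <- length(scene$white_image)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(seed))
  noise <- if (noise_sigma > 0) stats::rnorm(2 * npix, sd = noise_sigma) else numeric(2 * npix)
  list(
    white_noisy = scene$white_image + matrix(noise[seq_len(npix)],
                                             nrow(scene$white_image)),
    fluor_noisy = scene$fluor_image + matrix(noise[npix + seq_len(npix)],
                                             nrow(scene$fluor_image))
  )
}
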