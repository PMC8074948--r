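#' Fast in-phase lock-in demodulation of a frame stack
#'
#' Correlates the stack against a bipolar square-wave reference and applies
#' the boxcar (integrating) low-pass filter over the whole window:
#' `out = (2/n) * sum_i frame_i * r_i`. Because `r_i` is +1 or -1, the
#' correlation is computed purely by adding frames where the reference is
#' high and subtracting frames where it is low — no per-pixel
#' multiplications — followed by one final scaling. With the `2/n`
#' normalization a unipolar (on/off) modulated channel is recovered at its
#' true amplitude, so the output is directly comparable to the clean scene.
#'
#' The window must contain a whole number of reference periods; a partial
#' period would leak the DC (ambient) component and the other channel into
#' the output. Use `trim = TRUE` to drop trailing frames down to the largest
#' whole number of periods instead of erroring.
#'
#' @param stack A [frame_stack()] (or bare 3-D array).
#' @param channel_spec A bipolar [square_wave_spec()] with amplitude 1 whose
#'   `n_samples` matches the (possibly trimmed) stack length.
#' @param trim Drop trailing frames to a whole number of periods?
#' @return Demodulated image (matrix) of the stack's frame shape.
#' @examples
#' scene <- make_phantom(c(32, 32), seed = 1)
#' cfg <- modulation_config(mode = "single_channel", channel = "white")
#' stack <- simulate_stack(scene, cfg)
#' img <- demodulate_in_phase(stack, channel_spec(cfg, "white"))
#' max(abs(img - scene$white_image))
#' @export
demodulate_in_phase <- function(stack, channel_spec, trim = FALSE) {
  frames <- .stack_frames(stack)
  spec <- channel_spec
  stopifnot(inherits(spec, "square_wave_spec"))
  if (spec$polarity != "bipolar" || spec$amplitude != 1) {
    stop("the lock-in reference must be bipolar with amplitude 1", call. = FALSE)
  }
  n <- dim(frames)[3]
  p <- spec$samples_per_period
  if (n %% p != 0) {
    if (trim) {
      n <- (n %/% p) * p
      if (n == 0) stop("stack shorter than one reference period", call. = FALSE)
      frames <- frames[, , seq_len(n), drop = FALSE]
    } else {
      stop(sprintf(paste0("stack length (%d) is not a whole number of reference ",
                          "periods (%d); a partial period leaks ambient and ",
                          "cross-channel signal (use trim = TRUE to drop ",
                          "trailing frames)"), n, p), call. = FALSE)
    }
  }
  if (spec$n_samples != n) {
    stop(sprintf("reference length (%d) does not match stack length (%d)",
                 spec$n_samples, n), call. = FALSE)
  }
  r <- square_wave(.with_n(spec, n))
  out <- matrix(0, dim(frames)[1], dim(frames)[2])
  for (i in seq_len(n)) {
    if (r[i] > 0) out <- out + frames[, , i] else out <- out - frames[, , i]
  }
  out * (2 / n)
}

#' In-phase/quadrature lock-in demodulation
#'
#' Correlates the stack against the reference and its quarter-period-shifted
#' copy, yielding per-pixel in-phase (I) and quadrature (Q) images together
#' with amplitude and phase maps, so signals of unknown phase can be
#' recovered. For square-on-square correlation the phase response is
#' triangular (see [phase_response()]), so the exact amplitude estimator is
#' `|I| + |Q|` (the Euclidean `sqrt(I^2 + Q^2)` is available as an option
#' but underestimates away from the axes). Phase is the piecewise-linear
#' inversion of the triangular response, in `[0, 2*pi)`, defined as 0
#' where the amplitude is 0.
#'
#' @inheritParams demodulate_in_phase
#' @param amplitude_estimator `"manhattan"` (`|I|+|Q|`, exact for square
#'   references) or `"euclidean"`.
#' @return List with matrices `I`, `Q`, `amplitude`, `phase`.
#' @export
demodulate_iq <- function(stack, channel_spec, trim = FALSE,
                          amplitude_estimator = c("manhattan", "euclidean")) {
  amplitude_estimator <- match.arg(amplitude_estimator)
  I <- demodulate_in_phase(stack, channel_spec, trim = trim)
  Q <- demodulate_in_phase(stack, quadrature_reference(channel_spec), trim = trim)
  amp <- if (amplitude_estimator == "manhattan") abs(I) + abs(Q) else sqrt(I^2 + Q^2)
  phase <- .triangular_phase(I, Q, abs(I) + abs(Q))
  list(I = I, Q = Q, amplitude = amp, phase = phase)
}

# invert the triangular phase response: I = a*tri(phi), Q = a*tri(phi - pi/2)
# with tri the unit triangle wave of phase_response(); piecewise-linear in
# each quadrant, phi in [0, 2*pi), 0 where the amplitude is 0
.triangular_phase <- function(I, Q, a) {
  phase <- matrix(0, nrow(I), ncol(I))
  nz <- a > 0
  u <- I[nz] / a[nz]
  v <- Q[nz] / a[nz]
  ph <- ifelse(Q[nz] >= 0,
               ifelse(I[nz] >= 0, (pi / 2) * v, (pi / 2) * (1 - u)),
               (pi / 2) * (3 + u))
  phase[nz] <- ph %% (2 * pi)
  phase
}

#' Demultiplex both channels of a dual-channel stack
#'
#' Runs the fast in-phase demodulator once per channel with that channel's
#' bipolar reference. With the two sources modulated at a 2:1 frequency
#' ratio and a window of whole common periods the references are orthogonal,
#' so each channel's image is recovered with zero leakage from the other,
#' and any constant ambient offset is rejected exactly because both
#' references sum to zero over the window.
#'
#' @param stack A [frame_stack()].
#' @param config A [modulation_config()]; defaults to the stack's own.
#' @param iq Also compute quadrature/amplitude/phase maps per channel?
#' @param trim Passed to [demodulate_in_phase()].
#' @return An object of class `demodulation_result`: list with
#'   `channel_images` (named list of matrices), optional `iq`,
#'   `window_used`, and `config`.
#' @examples
#' scene <- make_phantom(c(32, 32), seed = 1)
#' stack <- simulate_stack(scene, modulation_config())
#' res <- demultiplex_dual(stack)
#' max(abs(res$channel_images$white - scene$white_image))
#' @export
demultiplex_dual <- function(stack, config = stack$config, iq = FALSE,
                             trim = FALSE) {
  stopifnot(inherits(stack, "frame_stack"), inherits(config, "modulation_config"))
  if (config$mode != "dual_channel") {
    stop("'config' must be a dual-channel configuration", call. = FALSE)
  }
  if (config$freq_white != 2 * config$freq_fluor) {
    stop("dual-channel demultiplexing requires a frequency ratio of exactly 2; ",
         "square references at other ratios share odd harmonics (cross-talk)",
         call. = FALSE)
  }
  n <- dim(stack$frames)[3]
  if (trim) {
    slow <- config$periods$fluor
    n <- (n %/% slow) * slow
  }
  channels <- c("white", "fluor")
  imgs <- list()
  iqs <- if (iq) list() else NULL
  for (ch in channels) {
    spec <- channel_spec(config, ch, polarity = "bipolar")
    spec <- .with_n(spec, n)
    sub <- stack$frames[, , seq_len(n), drop = FALSE]
    if (iq) {
      iqs[[ch]] <- demodulate_iq(sub, spec)
      imgs[[ch]] <- iqs[[ch]]$I
    } else {
      imgs[[ch]] <- demodulate_in_phase(sub, spec)
    }
  }
  structure(
    list(channel_images = imgs, iq = iqs, window_used = n, config = config),
    class = "demodulation_result"
  )
}

#' @export
print.demodulation_result <- function(x, ...) {
  d <- dim(x$channel_images[[1]])
  cat(sprintf("demodulation_result: channels [%s], %d x %d, window %d frames\n",
              paste(names(x$channel_images), collapse = ", "),
              d[1], d[2], x$window_used))
  invisible(x)
}

#' Triangular phase response of square-on-square lock-in detection
#'
#' Closed-form output of the phase-sensitive detector followed by the
#' integrator when both the signal (amplitude `W`) and the reference
#' (amplitude `A`) are square waves with phase difference `phi`:
#' `W*A*(1 - 2*phi/pi)` for `phi` in `[0, pi]` and `W*A*(2*phi/pi - 3)` for
#' `phi` in `[pi, 2*pi]`. The response is continuous, `2*pi`-periodic and
#' even; the open-interval branch ends coincide, so branch limits are used
#' at `phi = 0` and `phi = pi`.
#'
#' @param W Signal amplitude.
#' @param A Reference amplitude.
#' @param phi Phase difference in radians (vectorized; reduced mod `2*pi`).
#' @return Numeric vector of detector outputs.
#' @examples
#' phase_response(1, 1, c(0, pi / 2, pi)) # 1 0 -1
#' @export
phase_response <- function(W, A, phi) {
  phi <- phi %% (2 * pi)
  W * A * ifelse(phi <= pi, 1 - 2 * phi / pi, 2 * phi / pi - 3)
}

.stack_frames <- function(stack) {
  if (inherits(stack, "frame_stack")) return(stack$frames)
  if (is.array(stack) && length(dim(stack)) == 3L) return(stack)
  stop("'stack' must be a frame_stack or a rows x cols x n_frames array",
       call. = FALSE)
}
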