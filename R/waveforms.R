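#' Specify a discrete square wave
#'
#' Describes a 50%-duty-cycle square wave sampled at an integer number of
#' samples per period. The fast lock-in algorithm requires the sampling rate
#' to be `4k` times the modulation frequency for integer `k >= 1`, i.e.
#' `samples_per_period` must be a positive multiple of 4; that constraint is
#' enforced here, once, for every consumer.
#'
#' Within a period the wave is high first, low second. `phase_offset_samples`
#' advances the wave cyclically: sample `i` (0-based) is high iff
#' `(i + phase_offset_samples) %% samples_per_period < samples_per_period/2`.
#' An offset of `d` samples therefore corresponds to a phase of
#' `2*pi*d/samples_per_period` radians.
#'
#' @param samples_per_period Positive integer, a multiple of 4.
#' @param n_samples Positive integer; length of the generated sequence.
#' @param phase_offset_samples Integer cyclic advance in samples (default 0).
#' @param polarity `"bipolar"` (-A/+A, used for lock-in references) or
#'   `"unipolar"` (0/A, used for on/off source gating).
#' @param amplitude Nonnegative high level `A`.
#' @return An object of class `square_wave_spec`.
#' @seealso [square_wave()], [quadrature_reference()], [check_orthogonal()]
#' @examples
#' spec <- square_wave_spec(4, 8)
#' square_wave(spec)
#' @export
square_wave_spec <- function(samples_per_period, n_samples,
                             phase_offset_samples = 0L,
                             polarity = c("bipolar", "unipolar"),
                             amplitude = 1) {
  polarity <- match.arg(polarity)
  if (length(samples_per_period) != 1L || !is.finite(samples_per_period) ||
      samples_per_period != round(samples_per_period) || samples_per_period < 4 ||
      samples_per_period %% 4 != 0) {
    stop("'samples_per_period' must be a positive multiple of 4 ",
         "(sampling rate = 4k x modulation frequency)", call. = FALSE)
  }
  if (length(n_samples) != 1L || !is.finite(n_samples) ||
      n_samples != round(n_samples) || n_samples < 1) {
    stop("'n_samples' must be a positive integer", call. = FALSE)
  }
  if (length(phase_offset_samples) != 1L || !is.finite(phase_offset_samples) ||
      phase_offset_samples != round(phase_offset_samples)) {
    stop("'phase_offset_samples' must be an integer", call. = FALSE)
  }
  if (length(amplitude) != 1L || !is.finite(amplitude) || amplitude < 0) {
    stop("'amplitude' must be a nonnegative number", call. = FALSE)
  }
  structure(
    list(
      samples_per_period = as.integer(samples_per_period),
      n_samples = as.integer(n_samples),
      phase_offset_samples = as.integer(phase_offset_samples %% samples_per_period),
      polarity = polarity,
      amplitude = as.numeric(amplitude)
    ),
    class = "square_wave_spec"
  )
}

#' @export
print.square_wave_spec <- function(x, ...) {
  cat(sprintf(
    "square_wave_spec: period %d samples, n = %d, phase offset %d, %s, A = %g\n",
    x$samples_per_period, x$n_samples, x$phase_offset_samples, x$polarity,
    x$amplitude
  ))
  invisible(x)
}

#' Generate a discrete square wave
#'
#' Time-domain generator for the modulation and reference sequences. The wave
#' is high for the first half of each period and low for the second, with high
#' and low levels `(+A, -A)` for a bipolar wave and `(A, 0)` for a unipolar
#' one.
#'
#' @param spec A [square_wave_spec()].
#' @return Numeric vector of length `spec$n_samples`.
#' @examples
#' square_wave(square_wave_spec(4, 8))                        # 1 1 -1 -1 ...
#' square_wave(square_wave_spec(8, 8, polarity = "unipolar")) # 1 1 1 1 0 0 0 0
#' @export
square_wave <- function(spec) {
  stopifnot(inherits(spec, "square_wave_spec"))
  i <- seq_len(spec$n_samples) - 1L
  high <- ((i + spec$phase_offset_samples) %% spec$samples_per_period) <
    spec$samples_per_period %/% 2L
  low <- if (spec$polarity == "bipolar") -spec$amplitude else 0
  ifelse(high, spec$amplitude, low)
}

#' Quarter-period-shifted (quadrature) reference
#'
#' Returns the spec of the reference advanced by exactly a quarter period
#' (90 degrees) as a whole-sample cyclic shift; no interpolation is involved
#' because `samples_per_period` is a multiple of 4. Correlating a stack
#' against both the in-phase and the quadrature reference yields amplitude
#' and phase regardless of the signal's phase.
#'
#' @param spec A bipolar [square_wave_spec()].
#' @return A `square_wave_spec` with the shifted phase offset.
#' @examples
#' square_wave(quadrature_reference(square_wave_spec(4, 4))) # 1 -1 -1 1
#' @export
quadrature_reference <- function(spec) {
  stopifnot(inherits(spec, "square_wave_spec"))
  if (spec$polarity != "bipolar") {
    stop("quadrature reference is only defined for bipolar references",
         call. = FALSE)
  }
  square_wave_spec(
    samples_per_period = spec$samples_per_period,
    n_samples = spec$n_samples,
    phase_offset_samples = spec$phase_offset_samples +
      spec$samples_per_period %/% 4L,
    polarity = "bipolar",
    amplitude = spec$amplitude
  )
}

#' Check orthogonality of two references over a window
#'
#' Demultiplexing two frequency-multiplexed channels is exact only when the
#' two bipolar references are orthogonal over the integration window. For a
#' frequency ratio of 2 and a window that is a whole multiple of the longer
#' period the discrete inner product is exactly zero; odd frequency ratios
#' collide on shared odd harmonics and are not orthogonal.
#'
#' @param spec_a,spec_b Bipolar [square_wave_spec()] objects.
#' @param window Integer window length; must be at least the least common
#'   multiple of the two periods.
#' @return A list with `inner_product` (computed in integer arithmetic when
#'   both amplitudes are 1) and `orthogonal` (`TRUE` iff exactly 0).
#' @examples
#' check_orthogonal(square_wave_spec(4, 8), square_wave_spec(8, 8), 8)
#' @export
check_orthogonal <- function(spec_a, spec_b, window) {
  stopifnot(inherits(spec_a, "square_wave_spec"),
            inherits(spec_b, "square_wave_spec"))
  if (spec_a$polarity != "bipolar" || spec_b$polarity != "bipolar") {
    stop("orthogonality check is defined for bipolar references", call. = FALSE)
  }
  window <- as.integer(window)
  lcm_period <- .lcm(spec_a$samples_per_period, spec_b$samples_per_period)
  if (window < lcm_period) {
    stop(sprintf("'window' (%d) must cover at least one common period (%d)",
                 window, lcm_period), call. = FALSE)
  }
  a <- square_wave(.with_n(spec_a, window))
  b <- square_wave(.with_n(spec_b, window))
  ip <- if (spec_a$amplitude == 1 && spec_b$amplitude == 1) {
    sum(as.integer(a) * as.integer(b))
  } else {
    sum(a * b)
  }
  list(inner_product = ip, orthogonal = ip == 0)
}

.with_n <- function(spec, n) {
  spec$n_samples <- as.integer(n)
  spec
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

.lcm <- function(a, b) as.integer(a %/% .gcd(a, b) * b)
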