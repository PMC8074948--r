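# Independent oracles used to cross-check the fast implementation.

# naive lock-in: per-pixel multiply by the reference, accumulate in frame
# order, scale once — the textbook definition the add/subtract fast path
# must reproduce bit-for-bit
naive_demodulate <- function(frames, reference) {
  n <- dim(frames)[3]
  stopifnot(length(reference) == n)
  acc <- matrix(0, dim(frames)[1], dim(frames)[2])
  for (i in seq_len(n)) acc <- acc + frames[, , i] * reference[i]
  acc * (2 / n)
}

# brute-force discrete inner product of two sampled waveforms
brute_inner_product <- function(a, b) sum(a * b)

# closed-form SNR of a single noisy frame: 10*log10(mean(f^2)/sigma^2)
closed_form_snr0 <- function(f, sigma) 10 * log10(mean(f^2) / sigma^2)

# minimal constant-intensity scene for hand-computable stacks
constant_scene <- function(white = 0.5, fluor = 0, nr = 8, nc = 8) {
  structure(
    list(
      white_image = matrix(white, nr, nc),
      fluor_image = matrix(fluor, nr, nc),
      fluor_mask = matrix(fluor > 0, nr, nc),
      seed = 0L
    ),
    class = "phantom_scene"
  )
}
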