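test_that("in-phase demodulation recovers a unipolar channel at true amplitude", {
  scene <- constant_scene(white = 0.8, nr = 6, nc = 6)
  cfg <- modulation_config(freq_white = 12, freq_fluor = 12,
                           mode = "single_channel", channel = "white",
                           n_frames = 20)
  st <- simulate_stack(scene, cfg)
  out <- demodulate_in_phase(st, channel_spec(cfg, "white"))
  expect_equal(out, matrix(0.8, 6, 6), tolerance = 1e-12)
})

test_that("demodulation rejects the other channel, ambient, and constants", {
  scene <- make_phantom(c(32, 32), seed = 2)
  # stack carrying only the fluorescence channel, read with the white reference
  cfg <- modulation_config(mode = "single_channel", channel = "fluor",
                           n_frames = 24)
  st <- simulate_stack(scene, cfg)
  white_ref <- square_wave_spec(4, 24)   # 12 Hz at 48 fps
  leak <- demodulate_in_phase(st, white_ref)
  expect_lt(max(abs(leak)), 1e-12)

  # ambient-only stack demodulates to zero with any whole-period reference
  cfg2 <- modulation_config(ambient = 0.3)
  ambient_only <- frame_stack(array(0.3, c(8, 8, 24)), cfg2)
  for (p in c(4L, 8L)) {
    expect_lt(max(abs(demodulate_in_phase(ambient_only,
                                          square_wave_spec(p, 24)))), 1e-15)
  }
})

test_that("noiseless round trips are exact for single and dual channel", {
  scene <- make_phantom(c(48, 40), seed = 8)
  for (ch in c("white", "fluor")) {
    cfg <- modulation_config(mode = "single_channel", channel = ch,
                             n_frames = if (ch == "white") 20 else 40)
    out <- demodulate_in_phase(simulate_stack(scene, cfg),
                               channel_spec(cfg, ch))
    clean <- if (ch == "white") scene$white_image else scene$fluor_image
    expect_lt(max(abs(out - clean)), 1e-9)
  }
  res <- demultiplex_dual(simulate_stack(scene, modulation_config()))
  expect_lt(max(abs(res$channel_images$white - scene$white_image)), 1e-9)
  expect_lt(max(abs(res$channel_images$fluor - scene$fluor_image)), 1e-9)
  expect_identical(res$window_used, 24L)
})

test_that("demodulation output is invariant to constant frame offsets", {
  scene <- make_phantom(c(24, 24), seed = 6)
  base <- simulate_stack(scene, modulation_config())
  shifted <- simulate_stack(scene, modulation_config(ambient = 0.17))
  a <- demultiplex_dual(base)
  b <- demultiplex_dual(shifted)
  expect_lt(max(abs(a$channel_images$white - b$channel_images$white)), 1e-12)
  expect_lt(max(abs(a$channel_images$fluor - b$channel_images$fluor)), 1e-12)
})

test_that("demodulation is linear in the stack", {
  set.seed(42)
  f1 <- array(rnorm(8 * 8 * 16), c(8, 8, 16))
  f2 <- array(rnorm(8 * 8 * 16), c(8, 8, 16))
  spec <- square_wave_spec(4, 16)
  combo <- demodulate_in_phase(2.5 * f1 - 0.7 * f2, spec)
  parts <- 2.5 * demodulate_in_phase(f1, spec) -
    0.7 * demodulate_in_phase(f2, spec)
  expect_equal(combo, parts, tolerance = 1e-12)
})

test_that("fast add/subtract path equals the naive multiply-and-average oracle", {
  set.seed(7)
  for (p in c(4L, 8L)) {
    frames <- array(rnorm(8 * 8 * 24), c(8, 8, 24))
    for (offset in c(0L, 1L, 3L)) {
      spec <- square_wave_spec(p, 24, phase_offset_samples = offset)
      fast <- demodulate_in_phase(frames, spec)
      naive <- naive_demodulate(frames, square_wave(spec))
      expect_identical(fast, naive)    # bit-for-bit
    }
  }
})

test_that("I/Q demodulation recovers amplitude and phase at any offset", {
  scene <- make_phantom(c(16, 16), seed = 1)
  W <- scene$white_image
  for (d in c(0L, 2L, 5L, 8L, 13L, 16L, 27L, 31L)) {
    cfg <- modulation_config(frame_rate = 32, freq_white = 1, freq_fluor = 0.5,
                             mode = "single_channel", channel = "white",
                             n_frames = 32, phase_white = d)
    iq <- demodulate_iq(simulate_stack(scene, cfg), square_wave_spec(32, 32))
    phi <- 2 * pi * d / 32
    expect_equal(iq$I, phase_response(W, 1, phi), tolerance = 1e-12)
    expect_equal(iq$Q, phase_response(W, 1, phi - pi / 2), tolerance = 1e-12)
    # |I| + |Q| is flat in phase and equals the true amplitude
    expect_equal(iq$amplitude, W, tolerance = 1e-12)
    expect_equal(unique(round(iq$phase[W > 0], 9)), round(phi, 9))
    expect_true(all(iq$phase[iq$amplitude == 0] == 0))
  }
  # quarter-period shift moves the signal entirely into Q
  cfg <- modulation_config(freq_white = 12, freq_fluor = 12,
                           mode = "single_channel", channel = "white",
                           n_frames = 20, phase_white = 1L)
  iq <- demodulate_iq(simulate_stack(constant_scene(0.8, nr = 4, nc = 4), cfg),
                      square_wave_spec(4, 20))
  expect_equal(iq$I, matrix(0, 4, 4), tolerance = 1e-12)
  expect_equal(iq$Q, matrix(0.8, 4, 4), tolerance = 1e-12)
})

test_that("noise suppression follows the 4 sigma^2 / n law", {
  sigma <- 0.2; n <- 16L
  cfg <- modulation_config(freq_white = 12, freq_fluor = 12,
                           mode = "single_channel", channel = "white",
                           n_frames = n)
  scene <- constant_scene(0.5, nr = 24, nc = 24)
  clean <- simulate_stack(scene, cfg)
  spec <- channel_spec(cfg, "white")
  errs <- vapply(1:60, function(s) {
    out <- demodulate_in_phase(add_noise(clean, sigma, seed = s), spec)
    as.vector(out - scene$white_image)
  }, numeric(24 * 24))
  expect_equal(stats::var(as.vector(errs)), 4 * sigma^2 / n, tolerance = 0.05)
})

test_that("window and configuration violations are reported", {
  frames <- array(0.1, c(4, 4, 22))
  expect_error(demodulate_in_phase(frames, square_wave_spec(4, 22)),
               "whole number of reference periods")
  trimmed <- demodulate_in_phase(frames, square_wave_spec(4, 20), trim = TRUE)
  expect_identical(dim(trimmed), c(4L, 4L))
  expect_error(demodulate_in_phase(frames, square_wave_spec(4, 24, polarity = "unipolar")),
               "bipolar")
  expect_error(demodulate_in_phase(frames, square_wave_spec(4, 24, amplitude = 2)),
               "amplitude 1")
  # a 20-frame dual stack does not cover whole slow-channel periods
  scene <- make_phantom(c(16, 16), seed = 1)
  cfg24 <- modulation_config()
  st <- simulate_stack(scene, cfg24)
  short <- st
  short$frames <- st$frames[, , 1:20]
  short$config$n_frames <- 20L     # bypass the constructor's window check
  expect_error(demultiplex_dual(short), "whole number of reference periods")
  # single-channel config cannot be demultiplexed as dual
  cfg_single <- modulation_config(mode = "single_channel", channel = "white")
  st_single <- simulate_stack(scene, cfg_single)
  expect_error(demultiplex_dual(st_single), "dual-channel")
})

test_that("phase response is triangular, continuous, periodic and even", {
  expect_identical(phase_response(1, 1, 0), 1)
  expect_identical(phase_response(1, 1, pi / 2), 0)
  expect_identical(phase_response(1, 1, pi), -1)
  expect_equal(phase_response(2, 3, pi / 4), 3, tolerance = 1e-12)
  phi <- seq(0, 2 * pi, length.out = 201)
  expect_equal(phase_response(1, 1, phi + 2 * pi), phase_response(1, 1, phi),
               tolerance = 1e-12)
  expect_equal(phase_response(1, 1, -phi), phase_response(1, 1, phi),
               tolerance = 1e-12)
  expect_lt(max(abs(diff(phase_response(1, 1, phi)))), 2.1 * diff(phi[1:2]) / pi)
})
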