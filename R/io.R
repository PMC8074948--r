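#' Write a frame stack to disk
#'
#' Two dialects: a multi-page 32-bit TIFF (path ending in `.tif`/`.tiff`)
#' or a directory of zero-padded 8-bit PNG frames. Either way a JSON
#' sidecar (`<path>.json`, or `metadata.json` inside a PNG directory)
#' records the acquisition config, the pixel-scaling used, and a config
#' hash for provenance.
#'
#' Both containers store values in `[0,1]`; stacks whose pixels leave that
#' range (unclipped noisy stacks) are affinely mapped into it (integer
#' offset, power-of-two scale) and the `(pixel_offset, pixel_scale)` pair
#' needed to undo the mapping is stored in the sidecar. TIFF samples are
#' 32-bit, so the round trip quantizes at `2^-32` of the stored range —
#' absolute error below `1e-9` at typical dynamic ranges, which preserves
#' lock-in recovery to the pipeline's `1e-9` round-trip tolerance. PNG
#' frames quantize at about `2e-3` of the range — a preview dialect; use
#' the TIFF container for quantitative work.
#'
#' @param stack A [frame_stack()].
#' @param path Output `.tif`/`.tiff` file or directory (PNG dialect).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  frames <- stack$frames
  aff <- .affine_for_range(min(frames), max(frames))
  offset <- aff$offset; scale <- aff$scale
  scaled <- (frames - offset) / scale
  n <- dim(frames)[3]
  is_tiff <- grepl("\\.tiff?$", path, ignore.case = TRUE)
  meta <- .stack_metadata(stack, offset, scale,
                          format = if (is_tiff) "tiff" else "png")
  if (is_tiff) {
    pages <- lapply(seq_len(n), function(i) scaled[, , i])
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
    sidecar <- paste0(path, ".json")
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    for (i in seq_len(n)) {
      png::writePNG(scaled[, , i],
                    file.path(path, sprintf("frame_%04d.png", i)))
    }
    sidecar <- file.path(path, "metadata.json")
  }
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a frame stack written by [write_stack()]
#'
#' @param path A `.tif`/`.tiff` file or a PNG-sequence directory with its
#'   JSON sidecar.
#' @return A [frame_stack()] with the config restored from the sidecar.
#' @export
read_stack <- function(path) {
  is_tiff <- grepl("\\.tiff?$", path, ignore.case = TRUE)
  sidecar <- if (is_tiff) paste0(path, ".json") else file.path(path, "metadata.json")
  if (!file.exists(sidecar)) {
    stop(sprintf("missing stack sidecar '%s'", sidecar), call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is_tiff) {
    pages <- tiff::readTIFF(path, all = TRUE)
  } else {
    files <- sort(list.files(path, pattern = "^frame_\\d+\\.png$",
                             full.names = TRUE))
    if (length(files) == 0) stop("no PNG frames found in ", path, call. = FALSE)
    pages <- lapply(files, png::readPNG)
  }
  frames <- array(0, dim = c(dim(pages[[1]])[1], dim(pages[[1]])[2],
                             length(pages)))
  for (i in seq_along(pages)) frames[, , i] <- pages[[i]]
  frames <- frames * meta$pixel_scale + meta$pixel_offset
  frame_stack(frames, .config_from_meta(meta$config))
}

#' Write a single image as 32-bit TIFF with a JSON sidecar
#'
#' Same scaling convention as [write_stack()].
#'
#' @param img Numeric matrix.
#' @param path Output `.tif`/`.tiff` path.
#' @param extra Optional named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, extra = NULL) {
  aff <- .affine_for_range(min(img), max(img))
  offset <- aff$offset; scale <- aff$scale
  tiff::writeTIFF((img - offset) / scale, path, bits.per.sample = 32L,
                  reduce = FALSE)
  meta <- c(list(pixel_offset = offset, pixel_scale = scale,
                 n_rows = nrow(img), n_cols = ncol(img)), extra)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an image written by [write_image()]
#'
#' @param path A `.tif`/`.tiff` path; a `<path>.json` sidecar restores the
#'   pixel scaling if present.
#' @return Numeric matrix.
#' @export
read_image <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    img <- img * meta$pixel_scale + meta$pixel_offset
  }
  img
}

#' Render a fluorescence overlay on a bright-field image
#'
#' Display convention for dual-channel results: the white-light image is
#' the grayscale base, and the fluorescence channel is blended on top in a
#' pseudo-color with per-pixel alpha proportional to the fluorescence
#' intensity above a threshold. Zero fluorescence leaves pure grayscale; a
#' saturated fluorescence pixel becomes the pure overlay color.
#'
#' @param white Bright-field image (clamped to `[0,1]` for display).
#' @param fluor Fluorescence image, same shape.
#' @param color Length-3 RGB overlay color in `[0,1]` (default green).
#' @param threshold Fluorescence level below which nothing is overlaid.
#' @return `rows x cols x 3` RGB array in `[0,1]`.
#' @examples
#' scene <- make_phantom(c(64, 64), seed = 1)
#' rgb <- fuse_overlay(scene$white_image, scene$fluor_image)
#' dim(rgb)
#' @export
fuse_overlay <- function(white, fluor, color = c(0, 1, 0), threshold = 0.05) {
  .check_same_shape(white, fluor)
  if (length(color) != 3L || any(color < 0) || any(color > 1)) {
    stop("'color' must be an RGB triple in [0,1]", call. = FALSE)
  }
  if (threshold < 0 || threshold >= 1) {
    stop("'threshold' must be in [0, 1)", call. = FALSE)
  }
  base <- pmin(pmax(white, 0), 1)
  v <- pmin(pmax(fluor, 0), 1)
  alpha <- pmin(pmax((v - threshold) / (1 - threshold), 0), 1)
  out <- array(0, dim = c(nrow(white), ncol(white), 3L))
  for (k in 1:3) out[, , k] <- base * (1 - alpha) + color[k] * alpha
  out
}

# Affine map into the [0,1] range the TIFF/PNG containers require. The
# offset is an integer and the scale a power of two so the mapping itself
# is exact in floating point; only the container's sample quantization
# (2^-32 for TIFF, 2^-8 for PNG, times the scale) is lossy.
.affine_for_range <- function(lo, hi) {
  if (lo >= 0 && hi <= 1) return(list(offset = 0, scale = 1))
  offset <- floor(lo)
  range <- hi - offset
  scale <- 2^ceiling(log2(max(range, .Machine$double.eps)))
  list(offset = offset, scale = scale)
}

.stack_metadata <- function(stack, offset, scale, format) {
  cfg <- stack$config
  cfg_list <- unclass(cfg)
  list(
    format = format,
    n_frames = dim(stack$frames)[3],
    n_rows = dim(stack$frames)[1],
    n_cols = dim(stack$frames)[2],
    pixel_offset = offset,
    pixel_scale = scale,
    config = cfg_list,
    config_hash = config_hash(cfg)
  )
}

.config_from_meta <- function(cfg_list) {
  modulation_config(
    frame_rate = cfg_list$frame_rate,
    freq_white = cfg_list$freq_white,
    freq_fluor = cfg_list$freq_fluor,
    n_frames = cfg_list$n_frames,
    noise_sigma = cfg_list$noise_sigma,
    mode = cfg_list$mode,
    channel = if (length(cfg_list$channel) == 1L) cfg_list$channel else "white",
    ambient = cfg_list$ambient,
    phase_white = cfg_list$phase_white,
    phase_fluor = cfg_list$phase_fluor,
    seed = cfg_list$seed
  )
}

#' Short provenance hash of a configuration
#'
#' FNV-1a hash of the canonical JSON serialization; used to stamp written
#' artifacts so logs and sidecars can be matched to the configuration that
#' produced them.
#'
#' @param config Any jsonlite-serializable object.
#' @return 8-hex-digit string.
#' @export
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}
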