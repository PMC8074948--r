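# Block glyphs on a 5x7 grid, used to draw a deterministic test target
# without any font dependency. 1 = lit pixel.
.glyphs <- list(
  T = c("11111",
        "00100",
        "00100",
        "00100",
        "00100",
        "00100",
        "00100"),
  J = c("11111",
        "00010",
        "00010",
        "00010",
        "00010",
        "10010",
        "01100"),
  P = c("11110",
        "10001",
        "10001",
        "11110",
        "10000",
        "10000",
        "10000"),
  U = c("10001",
        "10001",
        "10001",
        "10001",
        "10001",
        "10001",
        "01110")
)

.glyph_matrix <- function(ch) {
  rows <- .glyphs[[ch]]
  m <- do.call(rbind, lapply(rows, function(r) as.integer(strsplit(r, "")[[1]])))
  storage.mode(m) <- "integer"
  m
}

# Quantize to multiples of 2^-12: the 4096 grey levels of a 12-bit camera,
# each an exact dyadic fraction.
.quantize <- function(x, bits = 12L) {
  q <- 2^bits
  pmin(pmax(round(x * q) / q, 0), 1)
}

#' Generate a synthetic dual-channel phantom scene
#'
#' Builds a clean bright-field reflectance image together with a clean
#' fluorescence emission image on the same pixel grid, emulating a test
#' target imaged under white light with a fluorescent dye applied to a
#' sub-region. The `"letters"` style draws the block letters "TJPU" on a
#' textured graded background and marks the letters "TJ" as fluorescent;
#' the `"geometric"` style uses a bright rectangle with a fluorescent disc.
#' Scenes are deterministic functions of `(shape, style, seed)`.
#'
#' Intensities are quantized to 4096 grey levels, emulating the discrete
#' output of a 12-bit sensor; every level is an exact dyadic fraction, so
#' scenes and the noiseless stacks rendered from them carry no hidden
#' floating-point residue.
#'
#' @param shape Integer vector `c(rows, cols)`, both at least 16.
#' @param style `"letters"` or `"geometric"`.
#' @param seed Integer seed for the background texture.
#' @return An object of class `phantom_scene`: a list with `white_image`
#'   (reflectance in `[0,1]`), `fluor_image` (emission in `[0,1]`, zero
#'   outside the fluorescent region), `fluor_mask` (logical), and `seed`.
#' @examples
#' scene <- make_phantom(c(64, 64), seed = 1)
#' range(scene$white_image)
#' mean(scene$fluor_mask)
#' @export
make_phantom <- function(shape = c(256L, 256L), style = c("letters", "geometric"),
                         seed = 1L) {
  style <- match.arg(style)
  if (length(shape) != 2L || any(!is.finite(shape)) ||
      any(shape != round(shape)) || any(shape < 16)) {
    stop("'shape' must be c(rows, cols) with both dimensions >= 16",
         call. = FALSE)
  }
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  seed <- as.integer(seed)

  # graded, lightly textured background (reflectance around 0.55)
  gx <- matrix(rep(seq(0, 1, length.out = nc), each = nr), nr, nc)
  gy <- matrix(rep(seq(0, 1, length.out = nr), times = nc), nr, nc)
  bg <- 0.45 + 0.15 * gx + 0.05 * gy
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  texture <- matrix(stats::runif(nr * nc, -0.02, 0.02), nr, nc)
  white <- bg + texture

  fluor <- matrix(0, nr, nc)
  if (style == "letters") {
    letters_all <- c("T", "J", "P", "U")
    # widest subset of glyphs (with 1-unit gaps) that fits the scene
    for (k in c(4L, 2L, 1L)) {
      width_units <- 5L * k + (k - 1L)
      s <- as.integer(min((nr * 3L) %/% (5L * 7L),     # height <= 60% of rows
                          (nc * 7L) %/% (10L * width_units)))
      if (s >= 1L) { n_letters <- k; break }
    }
    glyph_rows <- 7L * s; unit <- 5L * s; gap <- s
    total_w <- n_letters * unit + (n_letters - 1L) * gap
    r0 <- (nr - glyph_rows) %/% 2L
    c0 <- (nc - total_w) %/% 2L
    letter_mask <- matrix(FALSE, nr, nc)
    fluor_letters <- matrix(FALSE, nr, nc)
    n_fluor <- min(2L, n_letters)
    for (li in seq_len(n_letters)) {
      g <- kronecker(.glyph_matrix(letters_all[li]), matrix(1L, s, s))
      rows <- r0 + seq_len(glyph_rows)
      cols <- c0 + (li - 1L) * (unit + gap) + seq_len(unit)
      block <- letter_mask[rows, cols] | (g == 1L)
      letter_mask[rows, cols] <- block
      if (li <= n_fluor) fluor_letters[rows, cols] <- g == 1L
    }
    white[letter_mask] <- 0.875
    fluor[fluor_letters] <- 0.75
  } else {
    rr <- matrix(rep(seq_len(nr), times = nc), nr, nc)
    cc <- matrix(rep(seq_len(nc), each = nr), nr, nc)
    box <- rr > nr * 0.2 & rr < nr * 0.8 & cc > nc * 0.2 & cc < nc * 0.8
    white[box] <- 0.875
    rad2 <- (rr - nr / 2)^2 + (cc - nc / 2)^2
    disc <- rad2 < (min(nr, nc) * 0.18)^2
    fluor[disc] <- 0.75
  }

  white <- .quantize(white)
  fluor <- .quantize(fluor)
  structure(
    list(
      white_image = white,
      fluor_image = fluor,
      fluor_mask = fluor > 0,
      seed = seed
    ),
    class = "phantom_scene"
  )
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat(sprintf(
    "phantom_scene: %d x %d, white mean %.3f, fluorescent pixels %d (%.1f%%), seed %d\n",
    nrow(x$white_image), ncol(x$white_image), mean(x$white_image),
    sum(x$fluor_mask), 100 * mean(x$fluor_mask), x$seed
  ))
  invisible(x)
}

# save/restore the RNG state so seeded helpers do not perturb the caller's
# random stream
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
}

.Random.seed_set <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
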