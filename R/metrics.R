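#' Mean squared intensity (signal power) of an image
#'
#' `image_power(f) = mean(f^2)` over all `M x N` pixels — the signal-power
#' term of the image SNR.
#'
#' @param f Numeric matrix (or array) of pixel intensities.
#' @return Nonnegative scalar.
#' @examples
#' image_power(matrix(0.5, 4, 4)) # 0.25
#' @export
image_power <- function(f) {
  if (length(f) == 0) stop("'f' must be a nonempty image", call. = FALSE)
  mean(f^2)
}

#' Mean squared error between two images
#'
#' @param f,g Numeric matrices of identical shape.
#' @return Nonnegative scalar `mean((f - g)^2)`.
#' @examples
#' mse(matrix(1, 2, 2), matrix(0.9, 2, 2)) # 0.01
#' @export
mse <- function(f, g) {
  .check_same_shape(f, g)
  mean((f - g)^2)
}

#' Image signal-to-noise ratio in decibels
#'
#' `snr_db(f, g) = 10 * log10(image_power(f) / mse(f, g))`, the ratio of the
#' reference image's power to the reconstruction's error power. A perfect
#' reconstruction of a nonzero reference returns the explicit `Inf`
#' sentinel (the ratio is undefined at zero error); an all-zero reference
#' with zero error is rejected (0/0).
#'
#' @param f Reference (clean) image.
#' @param g Reconstructed image, same shape.
#' @return SNR in dB, possibly `Inf`.
#' @examples
#' snr_db(matrix(0.5, 8, 8), matrix(0.55, 8, 8)) # 20
#' @export
snr_db <- function(f, g) {
  .check_same_shape(f, g)
  p <- image_power(f)
  e <- mse(f, g)
  if (e == 0) {
    if (p == 0) stop("SNR undefined: both signal power and error are zero (0/0)",
                     call. = FALSE)
    return(Inf)
  }
  10 * log10(p / e)
}

#' Compare reconstructions with and without lock-in processing
#'
#' Computes the full with/without report for one reference image: signal
#' power, both mean squared errors, both SNRs, and the SNR improvement
#' `snr_with_db - snr_without_db`. The improvement depends only on the MSE
#' ratio — the signal-power term cancels — so it is comparable across scenes.
#'
#' @param f Clean reference image.
#' @param g_with Reconstruction with lock-in processing.
#' @param g_without Baseline reconstruction without lock-in processing.
#' @return An object of class `snr_report` (a list; see fields in
#'   `as.data.frame.snr_report`).
#' @examples
#' f <- matrix(0.5, 8, 8)
#' compare_snr(f, f + 0.01, f + 0.05)
#' @export
compare_snr <- function(f, g_with, g_without) {
  .check_same_shape(f, g_with)
  .check_same_shape(f, g_without)
  mse_w <- mse(f, g_with)
  mse_0 <- mse(f, g_without)
  snr_w <- snr_db(f, g_with)
  snr_0 <- snr_db(f, g_without)
  structure(
    list(
      i_original = image_power(f),
      mse_with = mse_w, mse_without = mse_0,
      snr_with_db = snr_w, snr_without_db = snr_0,
      improvement_db = snr_w - snr_0,
      n_rows = nrow(f), n_cols = ncol(f)
    ),
    class = "snr_report"
  )
}

#' @export
print.snr_report <- function(x, ...) {
  cat(sprintf(
    paste0("snr_report (%d x %d): I_original = %.4g\n",
           "  with lock-in:    MSE = %.4g, SNR = %.2f dB\n",
           "  without lock-in: MSE = %.4g, SNR = %.2f dB\n",
           "  improvement: %.2f dB\n"),
    x$n_rows, x$n_cols, x$i_original,
    x$mse_with, x$snr_with_db, x$mse_without, x$snr_without_db,
    x$improvement_db
  ))
  invisible(x)
}

#' @export
as.data.frame.snr_report <- function(x, ...) {
  data.frame(
    i_original = x$i_original,
    mse_with = x$mse_with, mse_without = x$mse_without,
    snr_with_db = x$snr_with_db, snr_without_db = x$snr_without_db,
    improvement_db = x$improvement_db,
    n_rows = x$n_rows, n_cols = x$n_cols
  )
}

.check_same_shape <- function(f, g) {
  if (length(f) == 0 || length(g) == 0) {
    stop("images must be nonempty", call. = FALSE)
  }
  if (!identical(dim(f), dim(g))) {
    stop(sprintf("image shapes differ: %s vs %s",
                 paste(dim(f), collapse = "x"), paste(dim(g), collapse = "x")),
         call. = FALSE)
  }
  invisible(TRUE)
}
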