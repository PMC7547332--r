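#' Image preprocessing for speckled ultrasound scans
#'
#' Images are plain numeric matrices with rows running down the image
#' (row = y, column = x) and intensities in `[0, 1]`. The conditioning
#' pipeline is fixed in order: border crop, speckle-reducing anisotropic
#' diffusion (SRAD), then global histogram equalization.
#'
#' @name preprocess
NULL

assert_image <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img)) {
    abort(sprintf("`%s` must be a numeric matrix", arg), class = "busfusion_type_error")
  }
  if (nrow(img) < 3 || ncol(img) < 3) {
    abort(sprintf("`%s` must be at least 3x3", arg), class = "busfusion_dim_error")
  }
  invisible(img)
}

#' Crop a fixed border from an image
#'
#' Removes `margin` pixels from every side, keeping the centered
#' sub-image. Ultrasound exports often carry burned-in annotation bands at
#' the frame edge; cropping removes them before filtering.
#'
#' @param img Numeric intensity matrix (row = y, column = x).
#' @param margin Border width in pixels to remove from each side.
#' @return The `(nrow - 2 margin) x (ncol - 2 margin)` sub-image.
#' @export
#' @examples
#' dim(crop_border(matrix(0, 256, 256), 16))
crop_border <- function(img, margin = 0L) {
  assert_image(img)
  margin <- as.integer(margin)
  if (margin < 0) abort("`margin` must be non-negative", class = "busfusion_param_error")
  if (2L * margin >= min(dim(img))) {
    abort(
      sprintf("margin %d too large for a %dx%d image", margin, nrow(img), ncol(img)),
      class = "busfusion_dim_error"
    )
  }
  if (margin == 0L) return(img)
  img[(margin + 1L):(nrow(img) - margin), (margin + 1L):(ncol(img) - margin), drop = FALSE]
}

# Pure-R reference SRAD update, kept for cross-checking the compiled kernel.
srad_reference <- function(img, n_iter, dt, q0_init, q0_decay) {
  I <- img
  nr <- nrow(I); nc <- ncol(I)
  up <- c(1L, seq_len(nr - 1L)); down <- c(seq_len(nr - 1L) + 1L, nr)
  left <- c(1L, seq_len(nc - 1L)); right <- c(seq_len(nc - 1L) + 1L, nc)
  for (it in seq_len(n_iter)) {
    q0 <- q0_init * exp(-q0_decay * (it - 1L) * dt)
    dN <- I[up, ] - I; dS <- I[down, ] - I
    dE <- I[, right] - I; dW <- I[, left] - I
    g2 <- (dN^2 + dS^2 + dE^2 + dW^2) / I^2
    lap <- (dN + dS + dE + dW) / I
    q2 <- pmax((0.5 * g2 - lap^2 / 16) / (1 + 0.25 * lap)^2, 0)
    cq <- pmin(pmax(1 / (1 + (q2 - q0^2) / (q0^2 * (1 + q0^2))), 0), 1)
    I <- I + 0.25 * dt * (cq[down, ] * dS + cq * dN + cq[, right] * dE + cq * dW)
  }
  I
}

# Estimate the reference coefficient of variation q0 from the darkest
# (typically most homogeneous, hypoechoic) block of the image.
estimate_q0 <- function(img, block = 32L) {
  nr <- nrow(img); nc <- ncol(img)
  block <- min(block, nr, nc)
  ris <- seq(1L, nr - block + 1L, by = block)
  cis <- seq(1L, nc - block + 1L, by = block)
  best <- NULL; best_mean <- Inf
  for (r in ris) for (cc in cis) {
    patch <- img[r:(r + block - 1L), cc:(cc + block - 1L)]
    m <- mean(patch)
    if (m < best_mean) { best_mean <- m; best <- patch }
  }
  q0 <- stats::sd(best) / max(mean(best), 1e-8)
  max(q0, 1e-3)
}

#' Speckle-reducing anisotropic diffusion (SRAD)
#'
#' Iterative PDE despeckling: the diffusion coefficient is driven by the
#' local instantaneous coefficient of variation, so fully developed speckle
#' (multiplicative noise) is smoothed while intensity edges, where the
#' coefficient of variation exceeds the speckle reference `q0`, block
#' diffusion and are preserved.
#'
#' `q0` starts at the coefficient of variation of a homogeneous reference
#' region (auto-estimated from the darkest 32x32 block when `q0_init` is
#' `NULL`) and decays exponentially with diffusion time, mirroring the
#' progressive cleaning of the image.
#'
#' @param img Numeric intensity matrix; values must be strictly positive
#'   (zeros are lifted by a small epsilon).
#' @param n_iter Number of diffusion iterations (>= 1).
#' @param dt Time step, in `(0, 0.25]` for stability.
#' @param q0_init Initial speckle scale; `NULL` to auto-estimate.
#' @param q0_decay Exponential decay rate of `q0` per unit diffusion time.
#' @return Filtered matrix, clipped to the input intensity range (within
#'   numerical tolerance).
#' @export
srad_filter <- function(img, n_iter = 100L, dt = 0.05, q0_init = NULL, q0_decay = 1 / 6) {
  assert_image(img)
  n_iter <- as.integer(n_iter)
  if (n_iter < 1L) abort("`n_iter` must be >= 1", class = "busfusion_param_error")
  if (!is.numeric(dt) || dt <= 0 || dt > 0.25) {
    abort("`dt` must be in (0, 0.25]", class = "busfusion_param_error")
  }
  eps <- 1e-6
  I <- pmax(img, eps)
  if (is.null(q0_init)) q0_init <- estimate_q0(I)
  out <- srad_cpp(I, n_iter, dt, q0_init, q0_decay)
  lo <- min(img); hi <- max(img)
  pmin(pmax(out, lo), hi)
}

#' Global histogram equalization
#'
#' Standard cumulative-distribution intensity remapping on the 8-bit grid:
#' `T(v) = max(0, floor(256 * cdf(v)) - 1)`. The mapping is monotone (pixel
#' ordering is preserved), it is the identity for an already-uniform
#' histogram, and it is idempotent up to rounding.
#'
#' @param img Numeric matrix in `[0, 1]` (quantized internally to 8 bits,
#'   round half up).
#' @return Equalized matrix in `[0, 1]` on the 8-bit grid.
#' @export
equalize_histogram <- function(img) {
  assert_image(img)
  if (min(img) < 0 || max(img) > 1) {
    abort("`img` intensities must lie in [0, 1]", class = "busfusion_range_error")
  }
  v8 <- floor(img * 255 + 0.5)
  counts <- tabulate(v8 + 1L, nbins = 256L)
  cdf <- cumsum(counts) / length(img)
  map <- pmax(0, floor(256 * cdf) - 1)
  out <- matrix(map[v8 + 1L], nrow(img), ncol(img))
  out / 255
}

#' Run the fixed preprocessing chain on one image
#'
#' Applies crop -> SRAD -> histogram equalization with the module defaults.
#'
#' @inheritParams crop_border
#' @inheritParams srad_filter
#' @return Preprocessed intensity matrix in `[0, 1]`.
#' @export
preprocess_image <- function(img, margin = 0L, n_iter = 100L, dt = 0.05,
                             q0_init = NULL, q0_decay = 1 / 6) {
  img <- crop_border(img, margin)
  img <- srad_filter(img, n_iter = n_iter, dt = dt, q0_init = q0_init, q0_decay = q0_decay)
  equalize_histogram(pmin(pmax(img, 0), 1))
}
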