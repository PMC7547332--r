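#' Texture descriptors for lesion regions
#'
#' Three descriptor families characterize the internal and marginal echo
#' texture of a lesion: 8-bit local binary patterns (LBP), histograms of
#' oriented gradients (HOG) on a fixed resized canvas, and Haralick
#' statistics of gray-level co-occurrence matrices (GLCM) over a grid of
#' pixel offsets.
#'
#' @name texture
NULL

# Neighbor offsets for the 3x3 LBP window, clockwise from top-left,
# p = 1..8 weighted 2^(p-1). Offsets are (dy, dx).
lbp_offsets <- function() {
  cbind(
    dy = c(-1L, -1L, -1L, 0L, 1L, 1L, 1L, 0L),
    dx = c(-1L, 0L, 1L, 1L, 1L, 0L, -1L, -1L)
  )
}

#' LBP code of a single 3x3 window
#'
#' Compares the eight neighbors against the center with the sign function
#' `s(x) = 1` if `x >= 0`, else 0, and packs the bits as
#' `sum(2^(p-1) s(i_p - i_c))`. Equal neighbor and center yields bit 1.
#' Neighbors are ordered clockwise from the top-left corner.
#'
#' @param center Center gray value.
#' @param neighbors The 8 neighbor gray values, in order p = 1..8.
#' @return Integer code in `[0, 255]`.
#' @export
#' @examples
#' lbp_code(5, c(6, 5, 4, 7, 2, 5, 3, 8)) # 171
lbp_code <- function(center, neighbors) {
  if (length(neighbors) != 8) abort("exactly 8 neighbors required", class = "busfusion_param_error")
  sum(2^(0:7) * (neighbors >= center))
}

shift_matrix <- function(m, dy, dx, fill = NA_real_) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ys <- seq_len(nr) + dy; xs <- seq_len(nc) + dx
  oky <- ys >= 1 & ys <= nr; okx <- xs >= 1 & xs <= nc
  out[which(oky), which(okx)] <- m[ys[oky], xs[okx]]
  out
}

#' Normalized 256-bin LBP histogram over a region of interest
#'
#' Computes the LBP code of every pixel whose full 3x3 window lies inside
#' the ROI mask and returns the normalized 256-bin code histogram. Codes
#' are invariant to adding a constant to all intensities.
#'
#' @param img Numeric intensity matrix.
#' @param mask Logical matrix of the same dimension (`NULL` = whole image).
#' @return Numeric vector of length 256 summing to 1, named
#'   `lbp_000`..`lbp_255`.
#' @export
lbp_histogram <- function(img, mask = NULL) {
  assert_image(img)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(img), ncol(img))
  if (!identical(dim(mask), dim(img))) abort("mask/image dimension mismatch", class = "busfusion_dim_error")
  off <- lbp_offsets()
  valid <- mask
  codes <- matrix(0, nrow(img), ncol(img))
  for (p in 1:8) {
    nb <- shift_matrix(img, off[p, 1], off[p, 2])
    mb <- shift_matrix(mask, off[p, 1], off[p, 2], fill = FALSE)
    valid <- valid & mb & !is.na(nb)
    codes <- codes + 2^(p - 1) * (!is.na(nb) & nb >= img)
  }
  idx <- which(valid)
  if (length(idx) < 1) abort("ROI too small for LBP (needs a full 3x3 window)", class = "busfusion_feature_error")
  h <- tabulate(codes[idx] + 1L, nbins = 256L)
  h <- h / sum(h)
  names(h) <- sprintf("lbp_%03d", 0:255)
  h
}

#' Histogram-of-oriented-gradients descriptor
#'
#' The input (typically a lesion bounding box resized to a fixed canvas so
#' descriptor length is constant across lesions) is gamma-corrected by
#' square-root compression; per-pixel gradients use central differences
#' with replicated edges; unsigned orientations in `[0, 180)` degrees vote
#' their gradient magnitude into `bins` per-cell histograms; blocks of
#' `block x block` cells (stride one cell) are L2-normalized and
#' concatenated.
#'
#' @param img Numeric matrix in `[0, 1]`.
#' @param cell Cell side in pixels (default 32).
#' @param block Block side in cells (default 2).
#' @param bins Orientation bins over `[0, 180)` (default 9).
#' @param canvas If non-`NULL`, resize `img` to `canvas x canvas` first.
#' @return Named numeric descriptor of fixed length
#'   `n_blocks * block^2 * bins`.
#' @export
hog_descriptor <- function(img, cell = 32L, block = 2L, bins = 9L, canvas = NULL) {
  assert_image(img)
  if (!is.null(canvas)) img <- resize_image(img, canvas, canvas)
  nr <- nrow(img); nc <- ncol(img)
  ncy <- nr %/% cell; ncx <- nc %/% cell
  if (ncy < block || ncx < block) {
    abort("image smaller than one HOG block", class = "busfusion_feature_error")
  }
  g <- sqrt(pmax(img, 0))
  up <- c(1L, seq_len(nr - 1L)); down <- c(seq_len(nr - 1L) + 1L, nr)
  left <- c(1L, seq_len(nc - 1L)); right <- c(seq_len(nc - 1L) + 1L, nc)
  gy <- (g[down, ] - g[up, ]) / 2
  gx <- (g[, right] - g[, left]) / 2
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) %% pi # unsigned orientation in [0, pi)
  obin <- pmin(floor(ang / pi * bins) + 1, bins)

  # accumulate magnitude per (cell, orientation bin); remainder pixels
  # beyond the last full cell are dropped
  ys <- (row(img) - 1L) %/% cell + 1L
  xs <- (col(img) - 1L) %/% cell + 1L
  keep <- ys <= ncy & xs <= ncx
  cellid <- (xs - 1L) * ncy + ys
  key <- (cellid - 1L) * bins + obin
  acc <- rep(0, ncy * ncx * bins)
  sums <- tapply(mag[keep], key[keep], sum)
  acc[as.integer(names(sums))] <- sums
  hist_arr <- array(acc, dim = c(bins, ncy, ncx))

  eps <- 1e-12
  out <- c()
  nms <- c()
  for (bx in seq_len(ncx - block + 1L)) {
    for (by in seq_len(ncy - block + 1L)) {
      v <- as.numeric(hist_arr[, by:(by + block - 1L), bx:(bx + block - 1L)])
      v <- v / sqrt(sum(v^2) + eps)
      out <- c(out, v)
      nms <- c(nms, sprintf("hog_b%02d_%02d_%03d", by, bx, seq_along(v)))
    }
  }
  names(out) <- nms
  out
}

# Bilinear resize via EBImage (which stores images as [x, y]).
resize_image <- function(img, w, h) {
  t(EBImage::resize(EBImage::Image(t(img)), w = w, h = h)@.Data)
}

glcm_offset <- function(d, angle) {
  switch(as.character(angle),
    "0" = c(dx = d, dy = 0L),
    "45" = c(dx = d, dy = -d),
    "90" = c(dx = 0L, dy = -d),
    "135" = c(dx = -d, dy = -d),
    abort("angle must be one of 0, 45, 90, 135", class = "busfusion_param_error")
  )
}

#' Gray-level co-occurrence matrix
#'
#' Intensities (in `[0, 1]`) are quantized to `levels` equal-width bins of
#' the full intensity range; ordered pixel pairs at offset `(d, angle)`
#' with both pixels inside the ROI are counted, the count matrix is
#' symmetrized and normalized to sum 1.
#'
#' @param img Numeric matrix in `[0, 1]`.
#' @param mask Logical ROI mask (`NULL` = whole image).
#' @param d Pixel distance (>= 1).
#' @param angle Direction in degrees: 0, 45, 90 or 135.
#' @param levels Number of gray levels (default 64).
#' @return `levels x levels` symmetric matrix summing to 1.
#' @export
glcm_matrix <- function(img, mask = NULL, d = 1L, angle = 0, levels = 64L) {
  assert_image(img)
  if (levels < 2L) abort("`levels` must be >= 2", class = "busfusion_param_error")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(img), ncol(img))
  q <- pmin(floor(pmin(pmax(img, 0), 1) * levels) + 1, levels)
  glcm_core(q, mask, d, angle, levels)
}

# Pair counting on an already-quantized matrix (shared across offsets).
glcm_core <- function(q, mask, d, angle, levels) {
  d <- as.integer(d)
  if (d < 1L) abort("`d` must be >= 1", class = "busfusion_param_error")
  off <- glcm_offset(d, angle)
  qs <- shift_matrix(q, off[["dy"]], off[["dx"]])
  ms <- shift_matrix(mask, off[["dy"]], off[["dx"]], fill = FALSE)
  ok <- mask & ms & !is.na(qs)
  if (!any(ok)) abort("no valid pixel pairs for this offset", class = "busfusion_feature_error")
  i <- q[ok]; j <- qs[ok]
  counts <- tabulate((i - 1L) * levels + j, nbins = levels * levels)
  P <- matrix(counts, levels, levels, byrow = TRUE)
  P <- P + t(P)
  P / sum(P)
}

#' Haralick statistics of a normalized co-occurrence matrix
#'
#' Energy `sum P^2`, contrast `sum P (i - j)^2`, correlation
#' `sum (i - mu_i)(j - mu_j) P / (sigma_i sigma_j)` (0 when either marginal
#' standard deviation is 0), and homogeneity `sum P / (1 + |i - j|)`.
#'
#' @param P Square matrix summing to 1.
#' @return Named numeric vector `c(energy, contrast, correlation,
#'   homogeneity)`.
#' @export
glcm_stats <- function(P) {
  if (!is.matrix(P) || nrow(P) != ncol(P)) abort("`P` must be square", class = "busfusion_type_error")
  if (abs(sum(P) - 1) > 1e-6) abort("`P` must be normalized to sum 1", class = "busfusion_contract_error")
  L <- nrow(P)
  i <- row(P); j <- col(P)
  energy <- sum(P^2)
  contrast <- sum(P * (i - j)^2)
  homogeneity <- sum(P / (1 + abs(i - j)))
  pi_ <- rowSums(P); pj <- colSums(P)
  mu_i <- sum(seq_len(L) * pi_); mu_j <- sum(seq_len(L) * pj)
  s_i <- sqrt(sum((seq_len(L) - mu_i)^2 * pi_))
  s_j <- sqrt(sum((seq_len(L) - mu_j)^2 * pj))
  correlation <- if (s_i * s_j < 1e-12) 0 else sum((i - mu_i) * (j - mu_j) * P) / (s_i * s_j)
  c(energy = energy, contrast = contrast, correlation = correlation, homogeneity = homogeneity)
}

#' Texture configuration
#'
#' Collects the tunable parameters of the texture channel. Defaults: LBP
#' over the dilated lesion ROI; HOG on the lesion bounding box resized to a
#' 128x128 canvas (32-px cells, 2x2-cell blocks, 9 orientation bins); GLCM
#' at 64 gray levels, distances 1..10 and four directions, giving 40
#' matrices and 160 Haralick statistics per image.
#'
#' @param glcm_levels Gray levels for GLCM quantization.
#' @param glcm_distances Integer vector of pixel distances.
#' @param glcm_angles Directions in degrees (subset of 0/45/90/135).
#' @param hog_cell,hog_block,hog_bins,hog_canvas HOG geometry.
#' @param roi_dilate ROI dilation radius in pixels around the contour.
#' @return A list of class `texture_config`.
#' @export
texture_config <- function(glcm_levels = 64L, glcm_distances = 1:10,
                           glcm_angles = c(0, 45, 90, 135),
                           hog_cell = 32L, hog_block = 2L, hog_bins = 9L,
                           hog_canvas = 128L, roi_dilate = 8L) {
  structure(
    list(
      glcm_levels = as.integer(glcm_levels),
      glcm_distances = as.integer(glcm_distances),
      glcm_angles = glcm_angles,
      hog_cell = as.integer(hog_cell), hog_block = as.integer(hog_block),
      hog_bins = as.integer(hog_bins), hog_canvas = as.integer(hog_canvas),
      roi_dilate = as.integer(roi_dilate)
    ),
    class = "texture_config"
  )
}

#' Rasterize a contour to a logical ROI mask
#'
#' Fills the contour polygon (even-odd test on pixel centers) and dilates
#' it by `dilate` pixels with a disc structuring element, so the mask
#' covers the lesion plus a marginal rim where boundary echo texture lives.
#'
#' @param contour Closed contour in pixel coordinates.
#' @param dim Image dimension `c(nrow, ncol)`.
#' @param dilate Dilation radius in pixels (0 = none).
#' @return Logical matrix.
#' @export
contour_mask <- function(contour, dim, dilate = 8L) {
  pts <- as_contour(contour)
  nr <- dim[1]; nc <- dim[2]
  # even-odd crossing test, vectorized per edge, restricted to the
  # contour bounding box (everything outside it is outside the polygon)
  x1 <- max(1L, floor(min(pts[, 1]))); x2 <- min(nc, ceiling(max(pts[, 1])))
  y1 <- max(1L, floor(min(pts[, 2]))); y2 <- min(nr, ceiling(max(pts[, 2])))
  px <- rep(x1:x2, each = y2 - y1 + 1L)
  py <- rep(y1:y2, times = x2 - x1 + 1L)
  cross <- integer(length(px))
  xs <- pts[, 1]; ys <- pts[, 2]
  xe <- c(xs[-1], xs[1]); ye <- c(ys[-1], ys[1])
  for (k in seq_along(xs)) {
    if (ys[k] == ye[k]) next
    hit <- ((ys[k] > py) != (ye[k] > py)) &
      (px < (xe[k] - xs[k]) * (py - ys[k]) / (ye[k] - ys[k]) + xs[k])
    cross <- cross + hit
  }
  mask <- matrix(FALSE, nr, nc)
  mask[cbind(py, px)] <- (cross %% 2L) == 1L
  if (dilate > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(dilate) + 1L, shape = "disc")
    mask <- t(EBImage::dilate(EBImage::Image(t(mask * 1)), brush)@.Data) > 0.5
  }
  mask
}

#' Full texture feature vector for one lesion
#'
#' Concatenates `[lbp | hog | glcm]`: the 256-bin LBP histogram and the
#' GLCM Haralick statistics are computed over the dilated lesion ROI; HOG
#' is computed on the lesion bounding box resized to the fixed canvas.
#' Feature names and length depend only on the configuration, never on
#' image content.
#'
#' @param img Preprocessed intensity matrix in `[0, 1]`.
#' @param contour Lesion contour in pixel coordinates of `img`.
#' @param config A [texture_config()].
#' @return Named numeric vector.
#' @export
texture_features <- function(img, contour, config = texture_config()) {
  assert_image(img)
  pts <- as_contour(contour)
  mask <- contour_mask(pts, dim(img), dilate = config$roi_dilate)

  lbp <- lbp_histogram(img, mask)

  # lesion bounding box, clamped to the frame, resized to the HOG canvas
  x1 <- max(1L, floor(min(pts[, 1]))); x2 <- min(ncol(img), ceiling(max(pts[, 1])))
  y1 <- max(1L, floor(min(pts[, 2]))); y2 <- min(nrow(img), ceiling(max(pts[, 2])))
  box <- img[y1:y2, x1:x2, drop = FALSE]
  hog <- hog_descriptor(box,
    cell = config$hog_cell, block = config$hog_block,
    bins = config$hog_bins, canvas = config$hog_canvas
  )

  q <- pmin(floor(pmin(pmax(img, 0), 1) * config$glcm_levels) + 1, config$glcm_levels)
  glcm <- numeric(0)
  for (d in config$glcm_distances) {
    for (ang in config$glcm_angles) {
      P <- glcm_core(q, mask, d = d, angle = ang, levels = config$glcm_levels)
      st <- glcm_stats(P)
      names(st) <- sprintf("glcm_d%02d_a%03d_%s", d, ang, names(st))
      glcm <- c(glcm, st)
    }
  }
  c(lbp, hog, glcm)
}
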