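#' Feature normalization and texture dimensionality reduction
#'
#' Feature blocks are kept separate end to end: the high-dimensional
#' texture block is min-max normalized then reduced by PCA; the 4-feature
#' morphological block is min-max normalized only. Both transforms are fit
#' on the training split alone and applied frozen to the test split.
#'
#' @name features
NULL

as_feature_matrix <- function(block) {
  if (is.data.frame(block)) block <- as.matrix(block)
  if (!is.matrix(block) || !is.numeric(block)) {
    abort("feature block must be a numeric matrix or data frame", class = "busfusion_type_error")
  }
  if (nrow(block) < 1 || ncol(block) < 1) {
    abort("empty feature block", class = "busfusion_contract_error")
  }
  block
}

#' Fit a min-max normalizer on a training block
#'
#' Per-feature scaling to `[0, 1]` using training minima and maxima.
#' Constant features map to 0; test values outside the training range are
#' clipped into `[0, 1]`.
#'
#' @param train_block Numeric matrix or data frame (>= 2 rows).
#' @return Object of class `feature_normalizer`.
#' @export
fit_normalizer <- function(train_block) {
  m <- as_feature_matrix(train_block)
  if (nrow(m) < 2) abort("normalizer needs >= 2 training samples", class = "busfusion_contract_error")
  structure(
    list(
      min = apply(m, 2, min), max = apply(m, 2, max),
      names = colnames(m)
    ),
    class = "feature_normalizer"
  )
}

#' Apply a fitted normalizer
#'
#' @param state A [fit_normalizer()] result.
#' @param block Block with the same columns as the training block.
#' @return Matrix scaled (and clipped) to `[0, 1]`.
#' @export
apply_normalizer <- function(state, block) {
  if (!inherits(state, "feature_normalizer")) abort("`state` must be a feature_normalizer", class = "busfusion_type_error")
  m <- as_feature_matrix(block)
  if (ncol(m) != length(state$min)) abort("column mismatch with fitted normalizer", class = "busfusion_contract_error")
  rng <- state$max - state$min
  out <- sweep(m, 2, state$min, "-")
  nz <- rng > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2, rng[nz], "/")
  out[, !nz] <- 0
  pmin(pmax(out, 0), 1)
}

#' Fit PCA on the (normalized) texture training block
#'
#' Mean-centered PCA retaining the smallest number of components whose
#' cumulative explained variance reaches `variance_retained`. Component
#' signs follow a fixed convention (largest-magnitude loading positive) so
#' the transform is deterministic given the training data.
#'
#' @param train_block Numeric matrix (>= 2 rows).
#' @param variance_retained Fraction in `(0, 1]` (default 0.95).
#' @return Object of class `pca_state` with loadings (`rotation`),
#'   `center`, per-component explained-variance fractions and the retained
#'   count `k`.
#' @export
fit_pca <- function(train_block, variance_retained = 0.95) {
  m <- as_feature_matrix(train_block)
  if (nrow(m) < 2) abort("PCA needs >= 2 training samples", class = "busfusion_contract_error")
  if (!is.numeric(variance_retained) || variance_retained <= 0 || variance_retained > 1) {
    abort("`variance_retained` must lie in (0, 1]", class = "busfusion_param_error")
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  frac <- ev / sum(ev)
  k <- which(cumsum(frac) >= variance_retained - 1e-12)[1]
  if (is.na(k)) k <- length(frac)
  rot <- pc$rotation
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  structure(
    list(rotation = rot[, seq_len(k), drop = FALSE], center = pc$center,
         explained = frac, k = k),
    class = "pca_state"
  )
}

#' Project a block onto retained principal components
#'
#' @param state A [fit_pca()] result.
#' @param block Block with the same columns as the training block.
#' @return `n x k` score matrix with columns `PC1..PCk`.
#' @export
apply_pca <- function(state, block) {
  if (!inherits(state, "pca_state")) abort("`state` must be a pca_state", class = "busfusion_type_error")
  m <- as_feature_matrix(block)
  if (ncol(m) != length(state$center)) abort("column mismatch with fitted PCA", class = "busfusion_contract_error")
  out <- sweep(m, 2, state$center, "-") %*% state$rotation
  colnames(out) <- paste0("PC", seq_len(ncol(out)))
  out
}

#' Extract the full feature table from a phantom (or image) dataset
#'
#' Runs preprocessing and both feature channels on every sample and
#' returns a wide tibble: `id`, `label`, texture columns (LBP, HOG, GLCM
#' names) and the 4 morphological columns (`morph_*`).
#'
#' @param data Tibble with columns `id`, `label`, `image`, `contour` (as
#'   returned by [phantom_dataset()] or [read_dataset()]).
#' @param config A [texture_config()].
#' @param preprocess Logical: run crop/SRAD/equalization first (default
#'   `TRUE`).
#' @param margin,srad_iters,srad_dt Preprocessing parameters.
#' @return Tibble, one row per sample.
#' @export
extract_features <- function(data, config = texture_config(), preprocess = TRUE,
                             margin = 0L, srad_iters = 100L, srad_dt = 0.05) {
  stopifnot(all(c("id", "label", "image", "contour") %in% names(data)))
  rows <- purrr::map(seq_len(nrow(data)), function(i) {
    img <- data$image[[i]]
    if (preprocess) {
      img <- preprocess_image(img, margin = margin, n_iter = srad_iters, dt = srad_dt)
    }
    tex <- texture_features(img, data$contour[[i]], config)
    mor <- morphology_features(data$contour[[i]])
    tibble::as_tibble(as.list(c(tex, mor)))
  })
  dplyr::bind_cols(data[, c("id", "label")], dplyr::bind_rows(rows))
}

texture_cols <- function(features) {
  grep("^(lbp|hog|glcm)_", names(features), value = TRUE)
}

morph_cols <- function(features) {
  grep("^morph_", names(features), value = TRUE)
}
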