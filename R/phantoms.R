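#' Synthetic breast-lesion ultrasound phantoms
#'
#' Seeded generator of ultrasound-like lesion images with ground-truth
#' contours, emulating the statistical structure the classifier assumes:
#' benign lesions are smooth and near-elliptical with well-defined margins
#' and homogeneous internal echoes; malignant lesions are lobulated and
#' irregular with blurred margins and heterogeneous internal echoes. Both
#' are hypoechoic (darker than background) and corrupted by multiplicative
#' Gamma-distributed speckle.
#'
#' The lesion boundary is the polar curve
#' `r(theta) = base_radius * (1 + sum_k alpha_k cos(k theta + phi_k))`
#' with seeded random phases `phi_k`; low-order, small-amplitude harmonics
#' produce benign ovals, high-order larger-amplitude harmonics produce
#' malignant lobulation.
#'
#' @name phantoms
NULL

#' Phantom specification
#'
#' Fixed parameter bands (shipped defaults): benign uses harmonic orders
#' `k <= 2` with relative amplitudes `<= 0.03`, margin blur sigma 1.5 px
#' and internal heterogeneity 0.05; malignant uses three harmonics drawn
#' from `k = 3..8` with amplitudes in `[0.08, 0.25]`, blur sigma 4 px and
#' heterogeneity 0.25. Radii, orders, amplitudes and phases are sampled
#' deterministically from `seed`.
#'
#' Stored contours additionally carry sub-pixel radial annotation jitter
#' (SD 0.05 px, both classes), emulating manual tracing.
#'
#' @param class_label `"benign"` or `"malignant"`.
#' @param seed Integer seed; the spec is a pure function of its arguments.
#' @param image_size Square frame side in pixels (default 256).
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(class_label = c("benign", "malignant"), seed = 1L,
                         image_size = 256L) {
  class_label <- match.arg(class_label)
  with_fixed_seed(as.integer(seed), {
    base_radius <- stats::runif(1, 34, 50)
    if (class_label == "benign") {
      orders <- 2L
      amps <- stats::runif(1, 0, 0.03)
      blur <- 1.5
      heterogeneity <- 0.05
    } else {
      orders <- sort(sample(3:8, 3))
      amps <- stats::runif(3, 0.08, 0.25)
      blur <- 4
      heterogeneity <- 0.25
    }
    spec <- structure(
      list(
        image_size = as.integer(image_size), class_label = class_label,
        base_radius = base_radius, lobulation_orders = orders,
        lobulation_amps = amps, boundary_blur_sigma = blur,
        lesion_intensity = 60, background_intensity = 150,
        heterogeneity = heterogeneity, speckle_shape = 4,
        contour_jitter_sd = 0.05, seed = as.integer(seed)
      ),
      class = "phantom_spec"
    )
    validate_phantom_spec(spec)
  })
}

validate_phantom_spec <- function(spec) {
  fail <- function(field, msg) {
    abort(sprintf("invalid phantom spec field `%s`: %s", field, msg),
      class = "busfusion_config_error"
    )
  }
  if (spec$image_size < 32) fail("image_size", "must be >= 32")
  if (spec$base_radius >= spec$image_size / 2 - spec$boundary_blur_sigma) {
    fail("base_radius", "lesion must fit fully inside the frame")
  }
  if (any(spec$lobulation_amps < 0)) fail("lobulation_amps", "must be >= 0")
  if (sum(spec$lobulation_amps) >= 1) fail("lobulation_amps", "sum must be < 1")
  if (length(spec$lobulation_amps) != length(spec$lobulation_orders)) {
    fail("lobulation_amps", "one amplitude per harmonic order")
  }
  if (spec$class_label == "benign" &&
    (any(spec$lobulation_amps > 0.03) || any(spec$lobulation_orders > 2))) {
    fail("lobulation_orders", "benign band requires amplitudes <= 0.03 and orders <= 2")
  }
  if (spec$class_label == "malignant" &&
    (any(spec$lobulation_amps < 0.08) || any(spec$lobulation_amps > 0.25) ||
      any(!spec$lobulation_orders %in% 3:8))) {
    fail("lobulation_orders", "malignant band requires amplitudes in [0.08, 0.25] and orders in 3..8")
  }
  if (spec$lesion_intensity < 0 || spec$lesion_intensity > 255 ||
    spec$background_intensity < 0 || spec$background_intensity > 255) {
    fail("lesion_intensity", "gray levels must lie in [0, 255]")
  }
  if (spec$speckle_shape <= 0) fail("speckle_shape", "must be > 0")
  if (spec$contour_jitter_sd < 0) fail("contour_jitter_sd", "must be >= 0")
  spec
}

gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  t(EBImage::gblur(EBImage::Image(t(img)), sigma = sigma)@.Data)
}

#' Generate one lesion phantom
#'
#' Renders the clean hypoechoic lesion over a brighter background, applies
#' intra-lesion heterogeneity (a smoothed multiplicative field), Gaussian
#' margin blur, and unit-mean multiplicative Gamma speckle, clipping to
#' `[0, 1]`. The returned contour is the analytic boundary curve sampled
#' at 256 ordered sub-pixel points.
#'
#' @param spec A [phantom_spec()].
#' @return List with `image` (matrix in `[0, 1]`, row = y) and `contour`
#'   (tibble with columns `x`, `y`).
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) abort("`spec` must be a phantom_spec", class = "busfusion_type_error")
  validate_phantom_spec(spec)
  s <- spec$image_size
  cx <- (s + 1) / 2; cy <- (s + 1) / 2

  with_fixed_seed(spec$seed + 1L, {
    k <- spec$lobulation_orders
    alpha <- spec$lobulation_amps
    phi <- stats::runif(length(k), 0, 2 * pi)

    radius_fn <- function(theta) {
      r <- rep(spec$base_radius, length(theta))
      for (m in seq_along(k)) r <- r + spec$base_radius * alpha[m] * cos(k[m] * theta + phi[m])
      r
    }

    # manual-annotation jitter: sub-pixel radial noise on the stored
    # contour (the rendered boundary stays analytic); sets a realistic
    # spectral floor for the radial-distance signature
    theta_c <- seq(0, 2 * pi, length.out = 257L)[1:256]
    rc <- radius_fn(theta_c) + stats::rnorm(256, 0, spec$contour_jitter_sd)
    contour <- tibble::tibble(x = cx + rc * cos(theta_c), y = cy + rc * sin(theta_c))

    xs <- matrix(rep(seq_len(s), each = s), s, s) # col index = x
    ys <- matrix(rep(seq_len(s), times = s), s, s) # row index = y
    dx <- xs - cx; dy <- ys - cy
    rpix <- sqrt(dx^2 + dy^2)
    tpix <- atan2(dy, dx)
    inside <- rpix <= radius_fn(tpix)

    clean <- matrix(spec$background_intensity / 255, s, s)
    clean[inside] <- spec$lesion_intensity / 255

    if (spec$heterogeneity > 0) {
      field <- matrix(stats::rnorm(s * s), s, s)
      field <- gaussian_blur(field, 8)
      field <- field / max(stats::sd(field), 1e-12)
      mult <- 1 + spec$heterogeneity * field
      clean[inside] <- clean[inside] * pmax(mult[inside], 0.1)
    }

    clean <- gaussian_blur(clean, spec$boundary_blur_sigma)
    speckle <- matrix(
      stats::rgamma(s * s, shape = spec$speckle_shape, rate = spec$speckle_shape), s, s
    )
    img <- pmin(pmax(clean * speckle, 0), 1)
    list(image = img, contour = contour)
  })
}

#' Generate an in-memory phantom dataset
#'
#' One row per phantom, with per-phantom seeds derived deterministically
#' from the master seed. Default class sizes follow the 184 benign / 264
#' malignant composition of the clinical collection the generator
#' emulates.
#'
#' @param n_benign,n_malignant Class counts (>= 1).
#' @param seed Master seed.
#' @param image_size Frame side in pixels.
#' @return Tibble with columns `id`, `label` (factor benign/malignant),
#'   `seed`, `image` (list of matrices) and `contour` (list of tibbles).
#' @export
phantom_dataset <- function(n_benign = 184L, n_malignant = 264L, seed = 1L,
                            image_size = 256L) {
  if (n_benign < 1 || n_malignant < 1) abort("class counts must be >= 1", class = "busfusion_param_error")
  n <- n_benign + n_malignant
  seeds <- derive_seeds(seed, n)
  labels <- c(rep("benign", n_benign), rep("malignant", n_malignant))
  ids <- sprintf("%s_%04d", substr(labels, 1, 1), seq_len(n))
  rows <- purrr::map(seq_len(n), function(i) {
    ph <- generate_phantom(phantom_spec(labels[i], seed = seeds[i], image_size = image_size))
    tibble::tibble(
      id = ids[i], label = labels[i], seed = seeds[i],
      image = list(ph$image), contour = list(ph$contour)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$label <- factor(out$label, levels = c("benign", "malignant"))
  out
}

#' Write a phantom dataset to disk
#'
#' Writes 8-bit grayscale PNG images, contour JSON files
#' (`{"points": [[x, y], ...]}` in pixel coordinates) and a manifest CSV
#' with header `file,label,seed`. Regeneration with the same master seed
#' is byte-identical.
#'
#' @inheritParams phantom_dataset
#' @param out_dir Output directory (created if missing).
#' @return The manifest as a tibble (invisibly returned paths in
#'   attributes).
#' @export
generate_dataset <- function(n_benign = 184L, n_malignant = 264L, seed = 1L,
                             out_dir, image_size = 256L) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create directory `%s`", out_dir), class = "busfusion_io_error")
  }
  data <- phantom_dataset(n_benign, n_malignant, seed, image_size)
  files <- sprintf("%s.png", data$id)
  for (i in seq_len(nrow(data))) {
    png::writePNG(data$image[[i]], file.path(out_dir, files[i]))
    ctr <- data$contour[[i]]
    jsonlite::write_json(
      list(points = unname(as.matrix(ctr))),
      file.path(out_dir, sprintf("%s.json", data$id[i])),
      digits = 6, auto_unbox = TRUE
    )
  }
  manifest <- tibble::tibble(file = files, label = as.character(data$label), seed = data$seed)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE, quote = FALSE)
  manifest
}

#' Read a phantom dataset written by [generate_dataset()]
#'
#' @param dir Directory containing `manifest.csv`, PNG images and contour
#'   JSON files.
#' @return Tibble in the same shape as [phantom_dataset()].
#' @export
read_dataset <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath)) abort(sprintf("no manifest.csv in `%s`", dir), class = "busfusion_io_error")
  manifest <- utils::read.csv(mpath, stringsAsFactors = FALSE)
  rows <- purrr::map(seq_len(nrow(manifest)), function(i) {
    img <- png::readPNG(file.path(dir, manifest$file[i]))
    if (length(dim(img)) == 3) img <- img[, , 1]
    id <- sub("\\.png$", "", manifest$file[i])
    cpath <- file.path(dir, paste0(id, ".json"))
    if (!file.exists(cpath)) {
      abort(sprintf("missing contour for sample `%s`", id), class = "busfusion_data_error")
    }
    pts <- jsonlite::fromJSON(cpath)$points
    tibble::tibble(
      id = id, label = manifest$label[i], seed = manifest$seed[i],
      image = list(img), contour = list(tibble::tibble(x = pts[, 1], y = pts[, 2]))
    )
  })
  out <- dplyr::bind_rows(rows)
  out$label <- factor(out$label, levels = c("benign", "malignant"))
  out
}
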