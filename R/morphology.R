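#' Morphological contour descriptors
#'
#' A tumor contour is an ordered, closed, simple polygon of sub-pixel
#' `(x, y)` coordinates (x rightwards, y downwards, origin top-left),
#' supplied either as a two-column matrix/data frame or a tibble with
#' columns `x` and `y`. The last vertex connects implicitly to the first.
#'
#' Four shape features summarize margin regularity: compactness (the
#' isoperimetric ratio, 1 for a circle), elliptic compactness (fitted
#' ellipse circumference over contour perimeter, near 1 for smooth oval
#' lesions), and the mean and variance of the log-amplitude Fourier
#' spectrum of the radial-distance signature (margin roughness).
#'
#' @name morphology
NULL

as_contour <- function(contour) {
  if (is.data.frame(contour)) {
    if (!all(c("x", "y") %in% names(contour))) {
      abort("contour data frame needs columns `x` and `y`", class = "busfusion_type_error")
    }
    pts <- cbind(contour$x, contour$y)
  } else if (is.matrix(contour) && ncol(contour) == 2) {
    pts <- contour
  } else {
    abort("contour must be an (x, y) matrix or data frame", class = "busfusion_type_error")
  }
  if (nrow(pts) >= 2 && all(pts[1, ] == pts[nrow(pts), ])) pts <- pts[-nrow(pts), , drop = FALSE]
  if (nrow(pts) < 3) abort("contour needs at least 3 distinct points", class = "busfusion_geometry_error")
  storage.mode(pts) <- "double"
  colnames(pts) <- c("x", "y")
  pts
}

#' Area, perimeter and centroid of a closed contour
#'
#' Area by the shoelace formula (absolute value), perimeter as closed
#' polyline length, centroid as the polygon area centroid.
#'
#' @param contour Closed contour; see [morphology].
#' @return A list with `area` (px^2), `perimeter` (px) and `centroid`
#'   (named numeric `c(x, y)`).
#' @export
#' @examples
#' contour_geometry(cbind(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1)))
contour_geometry <- function(contour) {
  pts <- as_contour(contour)
  x <- pts[, 1]; y <- pts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cross <- x * yn - xn * y
  a_signed <- sum(cross) / 2
  if (abs(a_signed) < 1e-12) {
    abort("degenerate contour: enclosed area is zero", class = "busfusion_geometry_error")
  }
  perim <- sum(sqrt((xn - x)^2 + (yn - y)^2))
  cx <- sum((x + xn) * cross) / (6 * a_signed)
  cy <- sum((y + yn) * cross) / (6 * a_signed)
  list(area = abs(a_signed), perimeter = perim, centroid = c(x = cx, y = cy))
}

#' Compactness (isoperimetric ratio)
#'
#' `C = 4 pi A / L^2`: exactly 1 for a continuous circle and strictly less
#' for any other shape, so smooth round lesions score near 1 and lobulated
#' margins score lower.
#'
#' @param area Enclosed area (px^2), > 0.
#' @param perimeter Contour perimeter (px), > 0.
#' @return Dimensionless compactness in `(0, 1]` for simple contours.
#' @export
#' @examples
#' compactness(pi * 25, 10 * pi) # circle of radius 5 -> 1
compactness <- function(area, perimeter) {
  if (!is.numeric(area) || !is.numeric(perimeter) || area <= 0 || perimeter <= 0) {
    abort("`area` and `perimeter` must be positive", class = "busfusion_param_error")
  }
  4 * pi * area / perimeter^2
}

#' Direct least-squares ellipse fit
#'
#' Fits a conic constrained to be an ellipse (`4AC - B^2 = 1`) to contour
#' points by the direct least-squares method of Fitzgibbon, Pilu and
#' Fisher, in the numerically stabilized partitioned form of Halir and
#' Flusser; points are centered and scaled before solving the reduced
#' eigenproblem.
#'
#' @param contour Contour points (>= 6 non-degenerate points).
#' @return An object of class `ellipse_fit`: list with `center` (named
#'   `c(x, y)`), semi-axes `a >= b > 0` and rotation `theta` of the major
#'   axis in radians, in `[0, pi)`.
#' @export
fit_ellipse <- function(contour) {
  pts <- as_contour(contour)
  if (nrow(pts) < 6) abort("ellipse fit needs at least 6 points", class = "busfusion_fit_error")
  mx <- mean(pts[, 1]); my <- mean(pts[, 2])
  sc <- max(stats::sd(pts[, 1]), stats::sd(pts[, 2]))
  if (!is.finite(sc) || sc < 1e-12) abort("degenerate point set", class = "busfusion_fit_error")
  x <- (pts[, 1] - mx) / sc; y <- (pts[, 2] - my) / sc

  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  T3 <- tryCatch(-solve(S3, t(S2)), error = function(e) {
    abort("singular scatter matrix (collinear points?)", class = "busfusion_fit_error")
  })
  M <- S1 + S2 %*% T3
  # inverse constraint matrix C1^-1 applied row-wise
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  eg <- eigen(M)
  evec <- Re(eg$vectors)
  cond <- 4 * evec[1, ] * evec[3, ] - evec[2, ]^2
  ok <- which(cond > 1e-12 & abs(Im(eg$values)) < 1e-8)
  if (length(ok) == 0) abort("no elliptical solution found", class = "busfusion_fit_error")
  a1 <- evec[, ok[1]]
  coef <- c(a1, as.numeric(T3 %*% a1)) # A B C D E F in scaled frame

  if (coef[1] + coef[3] < 0) coef <- -coef # fix conic sign so the form is positive
  A <- coef[1]; B <- coef[2]; C <- coef[3]; D <- coef[4]; E <- coef[5]; FF <- coef[6]
  den <- B^2 - 4 * A * C
  x0 <- (2 * C * D - B * E) / den
  y0 <- (2 * A * E - B * D) / den
  num0 <- 2 * (A * E^2 + C * D^2 - B * D * E + den * FF)
  root <- sqrt((A - C)^2 + B^2)
  aa <- -sqrt(num0 * ((A + C) + root)) / den
  bb <- -sqrt(num0 * ((A + C) - root)) / den
  semi <- sort(c(aa, bb), decreasing = TRUE)
  if (!all(is.finite(semi)) || semi[2] <= 0) {
    abort("ellipse fit produced non-finite axes", class = "busfusion_fit_error")
  }
  # major-axis direction: eigenvector of the quadratic form with the
  # smaller eigenvalue (larger extent along that axis)
  Q <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  eq <- eigen(Q, symmetric = TRUE)
  v <- eq$vectors[, which.min(eq$values)]
  theta <- atan2(v[2], v[1]) %% pi

  structure(
    list(
      center = c(x = x0 * sc + mx, y = y0 * sc + my),
      a = semi[1] * sc, b = semi[2] * sc, theta = theta
    ),
    class = "ellipse_fit"
  )
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf(
    "<ellipse_fit> center (%.3f, %.3f), a = %.3f, b = %.3f, theta = %.3f rad\n",
    x$center[["x"]], x$center[["y"]], x$a, x$b, x$theta
  ))
  invisible(x)
}

#' Elliptic compactness
#'
#' Ratio of the fitted-ellipse circumference, approximated as
#' `pi (a + b)`, to the contour perimeter. Near 1 for smooth oval lesions;
#' lobulated margins lengthen the contour relative to its fitted ellipse
#' and push the ratio below 1 (negatively correlated with malignancy).
#'
#' @param fit An [fit_ellipse()] result.
#' @param perimeter Contour perimeter (px), > 0.
#' @return Dimensionless elliptic compactness.
#' @export
elliptic_compactness <- function(fit, perimeter) {
  if (!inherits(fit, "ellipse_fit")) abort("`fit` must be an ellipse_fit", class = "busfusion_type_error")
  if (!is.numeric(perimeter) || perimeter <= 0) {
    abort("`perimeter` must be positive", class = "busfusion_param_error")
  }
  pi * (fit$a + fit$b) / perimeter
}

# Resample a closed polygon to n points equally spaced in arc length.
resample_contour <- function(pts, n) {
  closed <- rbind(pts, pts[1, ])
  seg <- sqrt(diff(closed[, 1])^2 + diff(closed[, 2])^2)
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) abort("zero-length contour", class = "busfusion_geometry_error")
  target <- (seq_len(n) - 1) * total / n
  x <- stats::approx(s, closed[, 1], xout = target, ties = "ordered")$y
  y <- stats::approx(s, closed[, 2], xout = target, ties = "ordered")$y
  cbind(x = x, y = y)
}

#' Radial-distance signature of a contour
#'
#' The contour is resampled to `n_samples` points equally spaced in arc
#' length; the signature is the Euclidean distance from each resampled
#' boundary point to the tumor center (the polygon area centroid).
#'
#' @param contour Closed contour.
#' @param n_samples Number of equal-arc-length samples (default 128).
#' @return An object of class `radial_profile`: list with `center`,
#'   `distances` (length `n_samples`) and the resampled `points`.
#' @export
radial_profile <- function(contour, n_samples = 128L) {
  pts <- as_contour(contour)
  n_samples <- as.integer(n_samples)
  if (n_samples < 8L) abort("`n_samples` must be >= 8", class = "busfusion_param_error")
  geo <- contour_geometry(pts)
  rp <- resample_contour(pts, n_samples)
  if (!isTRUE(mgcv::in.out(rbind(pts, pts[1, ]), matrix(geo$centroid, 1)) > 0)) {
    warning("contour centroid lies outside the polygon; radial distances remain defined")
  }
  d <- sqrt((rp[, 1] - geo$centroid[["x"]])^2 + (rp[, 2] - geo$centroid[["y"]])^2)
  structure(
    list(center = geo$centroid, distances = d, points = rp),
    class = "radial_profile"
  )
}

#' Log-amplitude spectrum statistics of a radial profile
#'
#' Discrete Fourier transform of the radial-distance signature; one-sided
#' harmonic amplitudes `2 |F_k| / N` for `k = 1..N/2` (DC excluded — it
#' encodes lesion size, not margin roughness); statistics are the mean and
#' variance of `log(amplitude + eps)`. Rough, lobulated margins put energy
#' into many harmonics and raise the variance.
#'
#' @param profile A [radial_profile()] object.
#' @param eps Guard added inside the logarithm (default 1e-8).
#' @return Named numeric vector `c(rds_mean, rds_var)`.
#' @export
radial_spectrum_features <- function(profile, eps = 1e-8) {
  if (!inherits(profile, "radial_profile")) {
    abort("`profile` must be a radial_profile", class = "busfusion_type_error")
  }
  d <- profile$distances
  n <- length(d)
  if (n < 8) abort("profile too short", class = "busfusion_param_error")
  amps <- 2 * Mod(stats::fft(d))[2:(n %/% 2 + 1)] / n
  la <- log(amps + eps)
  c(rds_mean = mean(la), rds_var = stats::var(la))
}

#' Morphological feature vector of a contour
#'
#' Computes the four contour descriptors: compactness `morph_C`, elliptic
#' compactness `morph_EC`, and radial-distance-spectrum statistics
#' `morph_RDSmean`, `morph_RDSvar`.
#'
#' @param contour Closed contour.
#' @param n_samples Radial-profile resampling length.
#' @return Named numeric vector of length 4.
#' @export
morphology_features <- function(contour, n_samples = 128L) {
  pts <- as_contour(contour)
  geo <- contour_geometry(pts)
  fit <- fit_ellipse(pts)
  rds <- radial_spectrum_features(radial_profile(pts, n_samples))
  c(
    morph_C = compactness(geo$area, geo$perimeter),
    morph_EC = elliptic_compactness(fit, geo$perimeter),
    morph_RDSmean = unname(rds["rds_mean"]),
    morph_RDSvar = unname(rds["rds_var"])
  )
}
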