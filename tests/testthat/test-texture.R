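test_that("lbp_code packs the sign comparisons with the s(0) = 1 branch", {
  expect_equal(lbp_code(5, rep(5, 8)), 255) # equality counts as 1
  expect_equal(lbp_code(9, rep(1, 8)), 0) # center strictly greater
  expect_equal(lbp_code(5, c(6, 5, 4, 7, 2, 5, 3, 8)), 171)
  expect_error(lbp_code(5, 1:7), class = "busfusion_param_error")
})

test_that("LBP histogram is normalized, gray-shift invariant, and matches window enumeration", {
  cst <- matrix(0.3, 9, 9)
  h <- lbp_histogram(cst)
  expect_equal(sum(h), 1, tolerance = 1e-9)
  expect_equal(unname(h[256]), 1) # all mass in code 255

  withr::with_seed(5, img <- matrix(runif(400), 20, 20))
  h1 <- lbp_histogram(img)
  expect_equal(sum(h1), 1, tolerance = 1e-9)
  expect_equal(lbp_histogram(img + 0.17), h1) # gray-shift invariance

  # 5x5 two-level checkerboard: enumerate the 9 interior windows by hand
  cb <- outer(1:5, 1:5, function(i, j) ifelse((i + j) %% 2 == 0, 1, 0))
  off <- busfusion:::lbp_offsets()
  codes <- c()
  for (y in 2:4) for (x in 2:4) {
    nb <- vapply(1:8, function(p) cb[y + off[p, 1], x + off[p, 2]], numeric(1))
    codes <- c(codes, lbp_code(cb[y, x], nb))
  }
  # centers equal to their diagonals can never win every comparison, so the
  # support is {85, 255}, not {0, 255}
  expect_setequal(unique(codes), c(85, 255))
  hcb <- lbp_histogram(cb)
  expect_equal(unname(hcb[c(85, 255) + 1]), as.vector(table(codes)) / 9)

  expect_error(lbp_histogram(matrix(1, 5, 5), matrix(FALSE, 5, 5)),
    class = "busfusion_feature_error"
  )
})

test_that("HOG descriptor has config-determined length and analytic edge response", {
  # constant image -> zero descriptor
  d0 <- hog_descriptor(matrix(0.5, 128, 128))
  expect_true(all(d0 == 0))
  expect_length(d0, 3 * 3 * 4 * 9) # (4-1)^2 blocks x 4 cells x 9 bins

  # vertical step edge -> horizontal gradient -> first orientation bin
  # dominates in every block crossing the edge (all blocks here)
  step <- cbind(matrix(0.2, 128, 64), matrix(0.8, 128, 64))
  ds <- hog_descriptor(step)
  blocks <- matrix(ds, nrow = 36) # one column per block
  expect_true(all(apply(blocks, 2, function(b) {
    bybin <- rowSums(matrix(b, nrow = 9))
    which.max(bybin) == 1
  })))

  # resize canvas keeps the length fixed for any input size
  withr::with_seed(2, odd <- matrix(runif(77 * 113), 77, 113))
  expect_length(hog_descriptor(odd, canvas = 128L), 324)
  expect_error(hog_descriptor(matrix(0.1, 40, 40)), class = "busfusion_feature_error")
})

test_that("GLCM matrices are symmetric, normalized, and counted per config", {
  cst <- matrix(0.7, 16, 16)
  P <- glcm_matrix(cst, d = 1, angle = 0)
  q <- floor(0.7 * 64) + 1
  expect_equal(P[q, q], 1) # single diagonal entry
  expect_equal(sum(P), 1)

  withr::with_seed(7, img <- matrix(runif(256), 16, 16))
  for (ang in c(0, 45, 90, 135)) {
    P <- glcm_matrix(img, d = 2, angle = ang)
    expect_equal(sum(P), 1, tolerance = 1e-9)
    expect_equal(P, t(P))
  }

  cfg <- texture_config()
  n_mat <- length(cfg$glcm_distances) * length(cfg$glcm_angles)
  expect_equal(n_mat, 40)
  expect_error(glcm_matrix(img, d = 40, angle = 0), class = "busfusion_feature_error")
})

test_that("Haralick statistics match brute-force double sums", {
  P1 <- diag(c(0.5, 0.5))
  s1 <- glcm_stats(P1)
  expect_equal(unname(s1), c(0.5, 0, 1, 1))

  P2 <- matrix(0, 3, 3); P2[2, 2] <- 1
  s2 <- glcm_stats(P2)
  expect_equal(unname(s2), c(1, 0, 0, 1)) # sigma = 0 convention for correlation

  P3 <- matrix(1 / 16, 4, 4)
  s3 <- glcm_stats(P3)
  expect_equal(s3, brute_glcm_stats(P3))
  expect_equal(unname(s3["energy"]), 1 / 16)
  expect_equal(unname(s3["contrast"]), 2.5) # sum of (i-j)^2 / 16 over all 16 cells

  withr::with_seed(11, {
    M <- matrix(rexp(36), 6, 6); M <- M + t(M); M <- M / sum(M)
  })
  expect_equal(glcm_stats(M), brute_glcm_stats(M), tolerance = 1e-12)
  expect_error(glcm_stats(M * 2), class = "busfusion_contract_error")
})

test_that("texture feature vector is deterministic with config-determined layout", {
  ph <- generate_phantom(phantom_spec("malignant", seed = 4, image_size = 128))
  img <- equalize_histogram(ph$image)
  v1 <- texture_features(img, ph$contour)
  v2 <- texture_features(img, ph$contour)
  expect_identical(v1, v2)
  expect_length(grep("^glcm_", names(v1)), 160) # 4 stats x 40 matrices
  expect_length(grep("^lbp_", names(v1)), 256)
  expect_length(grep("^hog_", names(v1)), 324)
  expect_false(anyNA(v1))

  # layout depends only on the config, not on image content
  ph2 <- generate_phantom(phantom_spec("benign", seed = 9, image_size = 128))
  v3 <- texture_features(equalize_histogram(ph2$image), ph2$contour)
  expect_identical(names(v1), names(v3))

  cfg <- texture_config(glcm_distances = 1:3, glcm_angles = c(0, 90))
  v4 <- texture_features(img, ph$contour, cfg)
  expect_length(grep("^glcm_", names(v4)), 4 * 3 * 2)
})
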