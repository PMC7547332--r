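test_that("stratified split reproduces the 448 -> 358/90 partition and is seed-stable", {
  df <- tibble::tibble(
    label = c(rep("benign", 184), rep("malignant", 264)),
    x = seq_len(448)
  )
  sp <- split_dataset(df, train_frac = 0.8, seed = 3)
  expect_equal(nrow(sp$train), 358)
  expect_equal(nrow(sp$test), 90)
  expect_equal(sum(sp$test$label == "malignant"), 53)
  expect_length(intersect(sp$train$x, sp$test$x), 0)

  sp2 <- split_dataset(df, train_frac = 0.8, seed = 3)
  expect_identical(sp, sp2)
  sp3 <- split_dataset(df, train_frac = 0.8, seed = 4)
  expect_false(identical(sp$train$x, sp3$train$x))
})

test_that("texture SVM separates well-separated blobs and is chance-level under label permutation", {
  withr::with_seed(41, {
    x <- rbind(
      matrix(rnorm(300, mean = 0), ncol = 2),
      matrix(rnorm(300, mean = 5), ncol = 2)
    )
    y <- rep(c("benign", "malignant"), each = 150)
    perm <- sample(y)
  })
  colnames(x) <- c("f1", "f2")
  m <- train_svm_texture(x, y, seed = 1)
  expect_equal(max(m$cv$cv_accuracy), 1)
  s <- channel_score(m, x)
  expect_true(all(s >= 0 & s <= 1))
  expect_equal(mean((s >= 0.5) == (y == "malignant")), 1)

  # permutation null: best CV accuracy near the class-prior rate
  mp <- train_svm_texture(x, perm,
    seed = 1,
    cost_grid = 2^c(-1, 3, 7), gamma_grid = 2^c(-7, -3, 1)
  )
  expect_lt(abs(max(mp$cv$cv_accuracy) - 0.5), 0.1)

  # deterministic given (data, seed, grid)
  m2 <- train_svm_texture(x, y, seed = 1)
  expect_identical(channel_score(m2, x), s)
})

test_that("Gaussian NB matches the hand Bayes-rule oracle and recovers priors", {
  # symmetric 1-D case: posterior exactly 0.5 at the midpoint
  xs <- matrix(c(-1.2, -1, -0.8, 0.8, 1, 1.2), ncol = 1)
  colnames(xs) <- "f"
  ys <- rep(c("benign", "malignant"), each = 3)
  nb <- train_nb_morph(xs, ys)
  expect_equal(channel_score(nb, matrix(0, 1, 1)), 0.5)

  # 10-sample toy set against brute-force Bayes rule
  withr::with_seed(6, {
    xt <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
    yt <- c(rep("benign", 4), rep("malignant", 6))
    xn <- matrix(rnorm(15), 5, 3, dimnames = list(NULL, c("a", "b", "c")))
  })
  nb2 <- train_nb_morph(xt, yt)
  expect_equal(channel_score(nb2, xn), unname(hand_nb_posterior(xt, yt, xn)),
    tolerance = 1e-12
  )

  # independent library cross-check
  df <- data.frame(xt, y = factor(yt))
  e <- e1071::naiveBayes(y ~ ., data = df)
  pe <- predict(e, data.frame(xn), type = "raw")[, "malignant"]
  expect_equal(channel_score(nb2, xn), unname(pe), tolerance = 1e-6)

  # class priors recovered from a 184/264 label vector
  withr::with_seed(2, xbig <- matrix(rnorm(448 * 2), 448, 2, dimnames = list(NULL, c("a", "b"))))
  nb3 <- train_nb_morph(xbig, c(rep("benign", 184), rep("malignant", 264)))
  expect_equal(nb3$prior, c(184, 264) / 448)

  # zero-variance feature: floored, never an error
  xz <- cbind(f1 = c(1, 1, 1, 1), f2 = c(0, 0.1, 1, 1.1))
  expect_silent(nbz <- train_nb_morph(xz, c("benign", "benign", "malignant", "malignant")))
  expect_true(all(is.finite(channel_score(nbz, xz))))
})

test_that("score fusion follows the weighted rule with the tie-to-malignant threshold", {
  expect_equal(fuse_scores(0.9, 0.3, lambda = 1)$s_c, 0.9)
  expect_equal(fuse_scores(0.9, 0.3, lambda = 0)$s_c, 0.3)
  f <- fuse_scores(0.9, 0.3, lambda = 0.8)
  expect_equal(f$s_c, 0.78)
  expect_equal(as.character(f$label), "malignant")
  expect_equal(as.character(fuse_scores(0.5, 0.5, 0.5)$label), "malignant") # tie
  expect_equal(as.character(fuse_scores(0.49, 0.49, 0.5)$label), "benign")
  expect_error(fuse_scores(1.2, 0.3, 0.5), class = "busfusion_contract_error")
  expect_error(fuse_scores(0.2, 0.3, 1.5), class = "busfusion_contract_error")

  # monotone in each channel score for fixed lambda
  withr::with_seed(14, {
    s1 <- sort(runif(20)); s2 <- runif(20)
  })
  expect_true(all(diff(fuse_scores(s1, s2[1], 0.7)$s_c) >= 0))
  expect_true(all(diff(fuse_scores(s1[1], sort(s2), 0.7)$s_c) >= 0))
})

test_that("baseline classifiers honor the [0, 1] score contract", {
  # KNN: query equal to 5 identical malignant duplicates scores 1
  xk <- matrix(c(rep(0, 5), rep(10, 5)), ncol = 1)
  colnames(xk) <- "f"
  yk <- c(rep("malignant", 5), rep("benign", 5))
  knn <- train_baseline("knn", xk, yk, k = 5)
  expect_equal(channel_score(knn, matrix(0, 1, 1)), 1)
  expect_error(train_baseline("knn", xk, yk, k = 50), class = "busfusion_param_error")

  # LDA on symmetric spherical Gaussians: midpoint posterior 0.5
  withr::with_seed(15, {
    xl <- rbind(matrix(rnorm(100), ncol = 2), matrix(rnorm(100, 4), ncol = 2))
  })
  colnames(xl) <- c("f1", "f2")
  yl <- rep(c("benign", "malignant"), each = 50)
  lda <- train_baseline("lda", xl, yl)
  mid <- matrix(colMeans(rbind(colMeans(xl[1:50, ]), colMeans(xl[51:100, ]))), 1)
  colnames(mid) <- c("f1", "f2")
  expect_equal(channel_score(lda, mid), 0.5, tolerance = 0.05)

  # depth-2 tree resolves an XOR-structured interaction (corner weights
  # unequal so each greedy split has positive gain)
  reps <- c(20, 15, 20, 10)
  xx <- cbind(f1 = c(0, 0, 1, 1), f2 = c(0, 1, 0, 1))
  yx <- c("benign", "malignant", "malignant", "benign")
  tr <- train_baseline("dtree", xx[rep(1:4, reps), ], rep(yx, reps))
  sx <- channel_score(tr, xx)
  expect_equal(as.numeric(sx >= 0.5), c(0, 1, 1, 0))
})
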