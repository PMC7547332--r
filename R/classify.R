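#' Channel classifiers and score fusion
#'
#' Two channel classifiers produce per-sample malignancy scores in
#' `[0, 1]`: an RBF-kernel SVM on the PCA-reduced texture block (Platt
#' probability calibration) and a Gaussian naive Bayes on the 4
#' morphological features (malignant posterior). The fused score is
#' `S_c(lambda) = lambda * S_SVM + (1 - lambda) * S_NB`; a tumor is called
#' malignant when `S_c >= 0.5` (ties go to malignant).
#'
#' @name classify
NULL

as_label_factor <- function(labels) {
  f <- factor(as.character(labels), levels = c("benign", "malignant"))
  if (any(is.na(f))) abort("labels must be 'benign' or 'malignant'", class = "busfusion_data_error")
  f
}

#' Stratified train/test split
#'
#' Seeded random split, stratified by class so both splits keep the class
#' prior; per class, `round(n_class * train_frac)` samples go to training.
#'
#' @param data Data frame with a `label` column.
#' @param train_frac Training fraction (default 0.8).
#' @param seed Integer seed.
#' @return List with tibbles `train` and `test` (disjoint).
#' @export
split_dataset <- function(data, train_frac = 0.8, seed = 1L) {
  labels <- as_label_factor(data$label)
  if (any(table(labels) < 2)) abort("need >= 2 samples per class", class = "busfusion_data_error")
  idx_train <- with_fixed_seed(as.integer(seed), {
    unlist(lapply(levels(labels), function(lv) {
      idx <- which(labels == lv)
      sample(idx, round(length(idx) * train_frac))
    }))
  })
  idx_train <- sort(idx_train)
  list(
    train = dplyr::as_tibble(data[idx_train, , drop = FALSE]),
    test = dplyr::as_tibble(data[-idx_train, , drop = FALSE])
  )
}

stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (lv in levels(labels)) {
    idx <- sample(which(labels == lv))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Train the texture-channel RBF SVM
#'
#' Grid search over `(cost, gamma)` (libsvm-conventional powers of two) by
#' seeded stratified 5-fold cross-validation; ties resolve to the smallest
#' cost, then the smallest gamma. The selected model is refit on the full
#' training block with Platt sigmoid probability calibration, so its
#' malignancy score lies in `[0, 1]`.
#'
#' @param x Numeric matrix of texture features (typically PCA scores).
#' @param labels benign/malignant labels.
#' @param seed Seed for fold assignment and calibration.
#' @param cost_grid,gamma_grid Candidate values.
#' @param folds Number of CV folds (default 5).
#' @return Object of class `channel_svm` with the fitted model, selected
#'   `(cost, gamma)` and the CV accuracy table.
#' @export
train_svm_texture <- function(x, labels, seed = 1L,
                              cost_grid = 2^seq(-5, 15, by = 2),
                              gamma_grid = 2^seq(-15, 3, by = 2),
                              folds = 5L) {
  x <- as_feature_matrix(x)
  y <- as_label_factor(labels)
  if (any(table(y) < folds)) abort("need >= `folds` samples per class for CV", class = "busfusion_data_error")

  fold <- with_fixed_seed(as.integer(seed), stratified_folds(y, folds))
  grid <- expand.grid(gamma = gamma_grid, cost = cost_grid)[, c("cost", "gamma")]
  cv_acc <- vapply(seq_len(nrow(grid)), function(g) {
    acc <- vapply(seq_len(folds), function(f) {
      tr <- fold != f
      fit <- e1071::svm(x[tr, , drop = FALSE], y[tr],
        kernel = "radial",
        cost = grid$cost[g], gamma = grid$gamma[g], scale = FALSE
      )
      mean(predict(fit, x[!tr, , drop = FALSE]) == y[!tr])
    }, numeric(1))
    mean(acc)
  }, numeric(1))

  ord <- order(-cv_acc, grid$cost, grid$gamma)
  best <- ord[1]

  # Platt sigmoid on cross-validated decision values (leakage-safe and
  # with a fixed sign orientation, unlike libsvm's internal estimates)
  dv_cv <- numeric(length(y))
  for (f in seq_len(folds)) {
    tr <- fold != f
    fit <- e1071::svm(x[tr, , drop = FALSE], y[tr],
      kernel = "radial",
      cost = grid$cost[best], gamma = grid$gamma[best], scale = FALSE
    )
    dv_cv[!tr] <- svm_decision(fit, x[!tr, , drop = FALSE])
  }
  platt <- suppressWarnings(stats::glm.fit(
    cbind(1, dv_cv), as.numeric(y == "malignant"),
    family = stats::binomial()
  )$coefficients)
  platt[is.na(platt)] <- 0 # degenerate (constant) decision values

  model <- e1071::svm(x, y,
    kernel = "radial", cost = grid$cost[best], gamma = grid$gamma[best],
    scale = FALSE
  )
  structure(
    list(
      model = model, cost = grid$cost[best], gamma = grid$gamma[best],
      platt = platt,
      cv = tibble::tibble(cost = grid$cost, gamma = grid$gamma, cv_accuracy = cv_acc)
    ),
    class = "channel_svm"
  )
}

# Decision values oriented so that positive always means "benign" side,
# regardless of libsvm's internal class ordering.
svm_decision <- function(fit, x) {
  dv <- attr(predict(fit, x, decision.values = TRUE), "decision.values")
  if (colnames(dv)[1] == "malignant/benign") dv <- -dv
  as.numeric(dv)
}

#' @export
print.channel_svm <- function(x, ...) {
  cat(sprintf(
    "<channel_svm> RBF SVM, cost = %g, gamma = %g, CV accuracy = %.4f\n",
    x$cost, x$gamma, max(x$cv$cv_accuracy)
  ))
  invisible(x)
}

#' Train the morphology-channel Gaussian naive Bayes
#'
#' Per-class, per-feature Gaussian class conditionals (variance floored at
#' `var_floor` so degenerate features never raise an error) with class
#' priors taken from training frequencies. The channel score is the
#' posterior probability of the malignant class.
#'
#' @param x Numeric matrix of morphological features.
#' @param labels benign/malignant labels.
#' @param var_floor Minimum class-conditional variance (default 1e-9).
#' @return Object of class `channel_nb`.
#' @export
train_nb_morph <- function(x, labels, var_floor = 1e-9) {
  x <- as_feature_matrix(x)
  y <- as_label_factor(labels)
  if (any(table(y) < 2)) abort("need >= 2 samples per class", class = "busfusion_data_error")
  stats_by <- lapply(levels(y), function(lv) {
    xc <- x[y == lv, , drop = FALSE]
    list(mean = colMeans(xc), var = pmax(apply(xc, 2, stats::var), var_floor))
  })
  names(stats_by) <- levels(y)
  structure(
    list(
      classes = levels(y),
      prior = as.numeric(table(y)) / length(y),
      params = stats_by, features = colnames(x)
    ),
    class = "channel_nb"
  )
}

#' @export
print.channel_nb <- function(x, ...) {
  cat(sprintf(
    "<channel_nb> Gaussian naive Bayes on %d features, priors %.3f/%.3f\n",
    length(x$features), x$prior[1], x$prior[2]
  ))
  invisible(x)
}

#' Malignancy score of a channel model
#'
#' Dispatches on the channel type and always returns scores in `[0, 1]`
#' (probability of the malignant class).
#'
#' @param model A channel model (`channel_svm`, `channel_nb`, or a
#'   baseline from [train_baseline()]).
#' @param x Feature matrix in the channel's feature space.
#' @return Numeric vector of malignancy scores.
#' @export
channel_score <- function(model, x) UseMethod("channel_score")

#' @export
channel_score.channel_svm <- function(model, x) {
  x <- as_feature_matrix(x)
  dv <- svm_decision(model$model, x)
  unname(stats::plogis(model$platt[1] + model$platt[2] * dv))
}

#' @export
channel_score.channel_nb <- function(model, x) {
  x <- as_feature_matrix(x)
  loglik <- sapply(model$classes, function(lv) {
    mu <- model$params[[lv]]$mean
    v <- model$params[[lv]]$var
    total <- log(rep(1, nrow(x)))
    for (j in seq_len(ncol(x))) {
      total <- total + stats::dnorm(x[, j], mu[j], sqrt(v[j]), log = TRUE)
    }
    total
  })
  loglik <- matrix(loglik, nrow = nrow(x))
  logpost <- sweep(loglik, 2, log(model$prior), "+")
  m <- apply(logpost, 1, max)
  post <- exp(logpost - m)
  post <- post / rowSums(post)
  unname(post[, which(model$classes == "malignant")])
}

#' Fuse channel scores into the final malignancy call
#'
#' `S_c = lambda * s_svm + (1 - lambda) * s_nb`, with the malignant call
#' at `S_c >= 0.5` (a tie scores malignant). `lambda = 1` reproduces the
#' texture channel exactly and `lambda = 0` the morphology channel.
#'
#' @param s_svm,s_nb Channel scores in `[0, 1]` (recycled to equal
#'   length).
#' @param lambda Fusion weight in `[0, 1]` (default 0.8).
#' @return Tibble with columns `s_svm`, `s_nb`, `lambda`, `s_c`, `label`.
#' @export
#' @examples
#' fuse_scores(0.9, 0.3, lambda = 0.8) # s_c = 0.78, malignant
fuse_scores <- function(s_svm, s_nb, lambda = 0.8) {
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda < 0 || lambda > 1) {
    abort("`lambda` must be a single value in [0, 1]", class = "busfusion_contract_error")
  }
  if (any(s_svm < 0 | s_svm > 1) || any(s_nb < 0 | s_nb > 1)) {
    abort("channel scores must lie in [0, 1]", class = "busfusion_contract_error")
  }
  s_c <- s_svm * lambda + s_nb * (1 - lambda)
  tibble::tibble(
    s_svm = s_svm, s_nb = s_nb, lambda = lambda, s_c = s_c,
    label = factor(ifelse(s_c >= 0.5, "malignant", "benign"),
      levels = c("benign", "malignant")
    )
  )
}

#' Baseline classifiers
#'
#' Comparison classifiers sharing the `[0, 1]` malignancy-score contract:
#' `knn` (k = 5; score is the malignant fraction among neighbors),
#' `dtree` (CART classification tree; leaf malignant probability) and
#' `lda` (linear discriminant; malignant posterior).
#'
#' @param kind One of `"knn"`, `"dtree"`, `"lda"`.
#' @param x Feature matrix.
#' @param labels benign/malignant labels.
#' @param k Neighbor count for `knn` (default 5).
#' @return A channel model usable with [channel_score()].
#' @export
train_baseline <- function(kind = c("knn", "dtree", "lda"), x, labels, k = 5L) {
  kind <- match.arg(kind)
  x <- as_feature_matrix(x)
  y <- as_label_factor(labels)
  obj <- switch(kind,
    knn = {
      if (k > nrow(x)) abort("`k` exceeds training size", class = "busfusion_param_error")
      list(train = x, y = y, k = as.integer(k))
    },
    dtree = {
      df <- data.frame(x, .label = y, check.names = FALSE)
      rpart::rpart(.label ~ ., data = df, method = "class")
    },
    lda = MASS::lda(x, grouping = y)
  )
  structure(list(kind = kind, fit = obj), class = c(paste0("channel_", kind), "channel_baseline"))
}

#' @export
channel_score.channel_knn <- function(model, x) {
  x <- as_feature_matrix(x)
  pred <- class::knn(model$fit$train, x, model$fit$y, k = model$fit$k, prob = TRUE)
  p <- attr(pred, "prob")
  ifelse(pred == "malignant", p, 1 - p)
}

#' @export
channel_score.channel_dtree <- function(model, x) {
  df <- data.frame(as_feature_matrix(x), check.names = FALSE)
  unname(predict(model$fit, df, type = "prob")[, "malignant"])
}

#' @export
channel_score.channel_lda <- function(model, x) {
  unname(predict(model$fit, as_feature_matrix(x))$posterior[, "malignant"])
}
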