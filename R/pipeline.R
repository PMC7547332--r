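#' End-to-end fusion pipeline
#'
#' One call runs the full experiment: phantom simulation (or a dataset
#' read from disk), preprocessing, two-channel feature extraction,
#' leakage-safe normalization/PCA fit on the training split, channel
#' training, score fusion, and evaluation. Every stage draws its
#' randomness from seeds derived from the single run seed, so a rerun with
#' the same configuration reproduces the report exactly.
#'
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' All tunable parameters of the pipeline in one validated object.
#' Unknown arguments are rejected.
#'
#' @param n_benign,n_malignant Phantom class counts (default 184/264, the
#'   benign:malignant composition of the clinical collection the phantom
#'   generator emulates).
#' @param image_size Phantom frame side (px).
#' @param margin Border crop (px).
#' @param srad_iters,srad_dt SRAD iteration count and time step.
#' @param texture A [texture_config()].
#' @param pca_variance Cumulative explained-variance fraction retained by
#'   texture PCA.
#' @param train_frac Training fraction of the stratified split.
#' @param lambda Fusion weight.
#' @param lambda_grid Grid for the fusion-weight sweep.
#' @param cost_grid,gamma_grid SVM grid-search candidates.
#' @return List of class `fusion_config`.
#' @export
fusion_config <- function(n_benign = 184L, n_malignant = 264L, image_size = 256L,
                          margin = 0L, srad_iters = 100L, srad_dt = 0.05,
                          texture = texture_config(), pca_variance = 0.95,
                          train_frac = 0.8, lambda = 0.8,
                          lambda_grid = seq(0, 1, by = 0.1),
                          cost_grid = 2^seq(-5, 15, by = 2),
                          gamma_grid = 2^seq(-15, 3, by = 2)) {
  cfg <- list(
    n_benign = as.integer(n_benign), n_malignant = as.integer(n_malignant),
    image_size = as.integer(image_size), margin = as.integer(margin),
    srad_iters = as.integer(srad_iters), srad_dt = srad_dt,
    texture = texture, pca_variance = pca_variance,
    train_frac = train_frac, lambda = lambda, lambda_grid = lambda_grid,
    cost_grid = cost_grid, gamma_grid = gamma_grid
  )
  if (!inherits(texture, "texture_config")) abort("`texture` must be a texture_config", class = "busfusion_config_error")
  if (cfg$train_frac <= 0 || cfg$train_frac >= 1) abort("`train_frac` must be in (0, 1)", class = "busfusion_config_error")
  if (cfg$lambda < 0 || cfg$lambda > 1) abort("`lambda` must be in [0, 1]", class = "busfusion_config_error")
  structure(cfg, class = "fusion_config")
}

#' Fit the two-channel fusion model on a training feature table
#'
#' Fits the frozen feature transforms (texture min-max + PCA, morphology
#' min-max) on the training block only, then trains the SVM and NB
#' channels.
#'
#' @param train Feature tibble (from [extract_features()]).
#' @param config A [fusion_config()].
#' @param seed Integer seed (SVM folds and calibration).
#' @return List of class `fusion_model`.
#' @export
fit_fusion_model <- function(train, config = fusion_config(), seed = 1L) {
  tex_cols <- texture_cols(train)
  mor_cols <- morph_cols(train)
  if (length(tex_cols) == 0 || length(mor_cols) == 0) {
    abort("feature table must contain texture and morphology blocks", class = "busfusion_data_error")
  }
  tex <- as.matrix(train[, tex_cols])
  mor <- as.matrix(train[, mor_cols])
  y <- as_label_factor(train$label)

  norm_tex <- fit_normalizer(tex)
  tex_n <- apply_normalizer(norm_tex, tex)
  pca <- fit_pca(tex_n, variance_retained = config$pca_variance)
  tex_p <- apply_pca(pca, tex_n)

  norm_mor <- fit_normalizer(mor)
  mor_n <- apply_normalizer(norm_mor, mor)

  svm <- train_svm_texture(tex_p, y,
    seed = seed,
    cost_grid = config$cost_grid, gamma_grid = config$gamma_grid
  )
  nb <- train_nb_morph(mor_n, y)

  structure(
    list(
      svm = svm, nb = nb, norm_tex = norm_tex, pca = pca, norm_mor = norm_mor,
      tex_cols = tex_cols, mor_cols = mor_cols, config = config, seed = seed
    ),
    class = "fusion_model"
  )
}

#' Channel scores of a fitted fusion model on new samples
#'
#' @param model A [fit_fusion_model()] result.
#' @param features Feature tibble with the same columns as training.
#' @return Tibble `id`, `label` (if present), `s_svm`, `s_nb`.
#' @export
predict_channels <- function(model, features) {
  if (!inherits(model, "fusion_model")) abort("`model` must be a fusion_model", class = "busfusion_type_error")
  tex <- apply_pca(model$pca, apply_normalizer(model$norm_tex, as.matrix(features[, model$tex_cols])))
  mor <- apply_normalizer(model$norm_mor, as.matrix(features[, model$mor_cols]))
  out <- tibble::tibble(
    s_svm = channel_score(model$svm, tex),
    s_nb = channel_score(model$nb, mor)
  )
  keep <- intersect(c("id", "label"), names(features))
  dplyr::bind_cols(features[, keep], out)
}

#' Run the full phantom-to-report fusion experiment
#'
#' Simulates (or accepts) a dataset, extracts features, splits, trains
#' both channels, fuses at `config$lambda`, and evaluates the test split:
#' confusion metrics for the fused rule and each single channel, the
#' fused-score ROC/AUC, and a fusion-weight sweep.
#'
#' @param config A [fusion_config()].
#' @param seed Master seed for the whole run.
#' @param data Optional pre-built dataset tibble (columns `id`, `label`,
#'   `image`, `contour`); when `NULL`, phantoms are simulated per config.
#' @param features Optional pre-extracted feature tibble (skips imaging
#'   stages).
#' @return Object of class `fusion_run`.
#' @export
run_fusion_pipeline <- function(config = fusion_config(), seed = 1L,
                                data = NULL, features = NULL) {
  seeds <- derive_seeds(seed, 3)
  if (is.null(features)) {
    if (is.null(data)) {
      data <- phantom_dataset(config$n_benign, config$n_malignant,
        seed = seeds[1], image_size = config$image_size
      )
    }
    features <- extract_features(data,
      config = config$texture,
      margin = config$margin, srad_iters = config$srad_iters, srad_dt = config$srad_dt
    )
  }
  split <- split_dataset(features, train_frac = config$train_frac, seed = seeds[2])
  model <- fit_fusion_model(split$train, config = config, seed = seeds[3])

  scores <- predict_channels(model, split$test)
  fused <- fuse_scores(scores$s_svm, scores$s_nb, lambda = config$lambda)
  test_scores <- dplyr::bind_cols(scores, fused[, c("s_c", "lambda")],
    predicted = fused$label
  )
  truth <- as_label_factor(split$test$label)

  metrics <- dplyr::bind_rows(
    dplyr::bind_cols(channel = "fused", confusion_metrics(confusion_counts(fused$label, truth))),
    dplyr::bind_cols(
      channel = "svm_texture",
      confusion_metrics(confusion_counts(fuse_scores(scores$s_svm, scores$s_nb, 1)$label, truth))
    ),
    dplyr::bind_cols(
      channel = "nb_morphology",
      confusion_metrics(confusion_counts(fuse_scores(scores$s_svm, scores$s_nb, 0)$label, truth))
    )
  )
  roc <- roc_curve(fused$s_c, truth)
  sweep <- lambda_sweep(scores$s_svm, scores$s_nb, truth, grid = config$lambda_grid)

  structure(
    list(
      config = config, seed = seed, features = features, model = model,
      test = test_scores, truth = truth, metrics = metrics, roc = roc,
      sweep = sweep,
      n_train = nrow(split$train), n_test = nrow(split$test)
    ),
    class = "fusion_run"
  )
}

#' @export
print.fusion_run <- function(x, ...) {
  g <- glance(x)
  cat("<fusion_run>\n")
  cat(sprintf("  samples: %d train / %d test, lambda = %.2f\n", x$n_train, x$n_test, x$config$lambda))
  cat(sprintf(
    "  fused: accuracy %.2f%%, sensitivity %.2f%%, specificity %.2f%%, AUC %.4f\n",
    g$accuracy, g$sensitivity, g$specificity, g$auc
  ))
  cat(sprintf(
    "  channels: SVM(texture) %.2f%%, NB(morphology) %.2f%%\n",
    g$accuracy_svm, g$accuracy_nb
  ))
  invisible(x)
}

#' @describeIn run_fusion_pipeline Per-sample test scores and calls.
#' @param x,object A `fusion_run`.
#' @param ... Unused.
#' @method tidy fusion_run
#' @export
tidy.fusion_run <- function(x, ...) {
  dplyr::as_tibble(x$test)
}

#' @describeIn run_fusion_pipeline One-row summary of the run.
#' @method glance fusion_run
#' @export
glance.fusion_run <- function(x, ...) {
  m <- x$metrics
  fused <- m[m$channel == "fused", ]
  tibble::tibble(
    accuracy = fused$accuracy, sensitivity = fused$sensitivity,
    specificity = fused$specificity, auc = attr(x$roc, "auc"),
    accuracy_svm = m$accuracy[m$channel == "svm_texture"],
    accuracy_nb = m$accuracy[m$channel == "nb_morphology"],
    lambda = x$config$lambda, n_train = x$n_train, n_test = x$n_test,
    seed = x$seed
  )
}

#' @method autoplot fusion_run
#' @export
autoplot.fusion_run <- function(object, which = c("roc", "sweep"), ...) {
  which <- match.arg(which)
  if (which == "roc") autoplot(object$roc) else autoplot(object$sweep)
}

#' Serialize the run report deterministically
#'
#' JSON text of the run's summary, per-sample test scores and
#' lambda-sweep, suitable for byte-for-byte reproducibility checks and for
#' the command-line `run` report.
#'
#' @param run A `fusion_run`.
#' @return A JSON string.
#' @export
report_json <- function(run) {
  if (!inherits(run, "fusion_run")) abort("`run` must be a fusion_run", class = "busfusion_type_error")
  as.character(jsonlite::toJSON(
    list(
      glance = glance(run),
      metrics = run$metrics,
      test = dplyr::mutate(tidy(run), dplyr::across(dplyr::where(is.factor), as.character)),
      sweep = dplyr::as_tibble(run$sweep)
    ),
    digits = NA, auto_unbox = TRUE, dataframe = "rows"
  ))
}
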