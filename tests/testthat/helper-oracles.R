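# Shape constructors and brute-force oracles used across tests.
# Oracles are deliberately written as direct enumerations / closed forms,
# independent of the package's own implementation paths.

circle_contour <- function(r = 10, n = 360, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  cbind(x = center[1] + r * cos(th), y = center[2] + r * sin(th))
}

ellipse_contour <- function(a, b, theta = 0, center = c(0, 0), n = 180) {
  t_ <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  cbind(
    x = center[1] + a * cos(t_) * cos(theta) - b * sin(t_) * sin(theta),
    y = center[2] + a * cos(t_) * sin(theta) + b * sin(t_) * cos(theta)
  )
}

# ellipse circumference by numerical quadrature of the arc-length integral
ellipse_perimeter_numeric <- function(a, b) {
  4 * stats::integrate(function(t) sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2),
    0, pi / 2, rel.tol = 1e-12
  )$value
}

# Haralick statistics by explicit double sums over matrix cells
brute_glcm_stats <- function(P) {
  L <- nrow(P)
  energy <- 0; contrast <- 0; homog <- 0
  mu_i <- 0; mu_j <- 0
  for (i in 1:L) for (j in 1:L) {
    energy <- energy + P[i, j]^2
    contrast <- contrast + P[i, j] * (i - j)^2
    homog <- homog + P[i, j] / (1 + abs(i - j))
    mu_i <- mu_i + i * P[i, j]
    mu_j <- mu_j + j * P[i, j]
  }
  s_i <- 0; s_j <- 0; cov <- 0
  for (i in 1:L) for (j in 1:L) {
    s_i <- s_i + (i - mu_i)^2 * P[i, j]
    s_j <- s_j + (j - mu_j)^2 * P[i, j]
    cov <- cov + (i - mu_i) * (j - mu_j) * P[i, j]
  }
  corr <- if (sqrt(s_i * s_j) < 1e-12) 0 else cov / sqrt(s_i * s_j)
  c(energy = energy, contrast = contrast, correlation = corr, homogeneity = homog)
}

# AUC as the fraction of concordant (malignant, benign) score pairs,
# ties counted one half
pairwise_auc <- function(scores, labels) {
  pos <- scores[labels == "malignant"]
  neg <- scores[labels == "benign"]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Gaussian naive Bayes malignant posterior by direct Bayes-rule evaluation
hand_nb_posterior <- function(x_train, y_train, x_new, var_floor = 1e-9) {
  lik <- function(lv, xrow) {
    xc <- x_train[y_train == lv, , drop = FALSE]
    prod(stats::dnorm(xrow, colMeans(xc), sqrt(pmax(apply(xc, 2, stats::var), var_floor))))
  }
  prior <- table(factor(y_train, levels = c("benign", "malignant"))) / length(y_train)
  apply(x_new, 1, function(xrow) {
    pb <- prior[["benign"]] * lik("benign", xrow)
    pm <- prior[["malignant"]] * lik("malignant", xrow)
    pm / (pb + pm)
  })
}
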