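# Binary linear classifier: regularised (shrinkage) linear discriminant
# analysis on the six standardised features, H = sign(w.x + b) with the
# tie decided in favour of "neural" (retain when in doubt).

new_classifier <- function(w, b, feature_means, feature_sds, alpha_band) {
  if (any(feature_sds <= 0))
    abort("feature standard deviations must be positive",
          "icaclean_training_error")
  structure(list(w = w, b = b, feature_means = feature_means,
                 feature_sds = feature_sds, alpha_band = alpha_band),
            class = "eeg_classifier")
}

#' @export
print.eeg_classifier <- function(x, ...) {
  cat(sprintf("<eeg_classifier> alpha band %g-%g Hz; |w| = %.3g, b = %.3g\n",
              x$alpha_band[1], x$alpha_band[2], sqrt(sum(x$w^2)), x$b))
  invisible(x)
}

feature_matrix <- function(features) {
  features <- as.data.frame(features)
  if ("flagged" %in% names(features) && any(features$flagged))
    features <- features[!features$flagged, , drop = FALSE]
  as.matrix(features[, .feature_cols, drop = FALSE])
}

# Ledoit-Wolf style analytic shrinkage intensity towards a scaled identity,
# computed from the pooled within-class centred data.
analytic_shrinkage <- function(Xc, S) {
  n <- nrow(Xc); p <- ncol(Xc)
  target <- diag(mean(diag(S)), p)
  var_s <- matrix(0, p, p)
  for (i in seq_len(p))
    for (j in seq_len(p)) {
      wij <- Xc[, i] * Xc[, j]
      var_s[i, j] <- n / (n - 1)^3 * sum((wij - mean(wij))^2)
    }
  num <- sum(var_s)
  den <- sum((S - target)^2)
  if (den <= 0) return(0)
  min(1, max(0, num / den))
}

#' Train the component classifier
#'
#' Features are z-scored by the training statistics; the weight vector and
#' bias are fitted by linear discriminant analysis with the pooled
#' covariance shrunk towards a scaled identity. The bias places the
#' decision boundary at equal Mahalanobis distance from the two class
#' means (equal priors).
#'
#' @param features data.frame of component features (from
#'   [extract_features()] or [read_feature_table()]).
#' @param labels a [label_set()] or +1/-1 vector (+1 = artifact).
#' @param reg shrinkage intensity in `[0, 1]`, or `"auto"` (default) for
#'   the analytic Ledoit-Wolf estimate.
#' @param alpha_band alpha band (Hz) the features were extracted with;
#'   stored on the classifier and checked at classification time.
#' @return an `eeg_classifier`.
#' @export
train_component_classifier <- function(features, labels, reg = "auto",
                                       alpha_band = c(6, 9)) {
  X <- feature_matrix(features)
  y <- as_label_vector(labels)
  if (length(y) != nrow(X))
    abort("labels length must match the number of feature rows",
          "icaclean_training_error")
  if (anyNA(X))
    abort("features contain NA", "icaclean_training_error")
  if (length(unique(y)) < 2)
    abort("training needs both classes", "icaclean_training_error")
  if (min(table(y)) < 2)
    abort("need at least 2 examples per class",
          "icaclean_training_error")
  mu <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    abort(paste("degenerate (constant) feature(s):",
                paste(colnames(X)[sds == 0], collapse = ", ")),
          "icaclean_training_error")
  Z <- scale(X, center = mu, scale = sds)

  m_pos <- colMeans(Z[y == 1L, , drop = FALSE])
  m_neg <- colMeans(Z[y == -1L, , drop = FALSE])
  Zc <- Z
  Zc[y == 1L, ] <- sweep(Z[y == 1L, , drop = FALSE], 2, m_pos)
  Zc[y == -1L, ] <- sweep(Z[y == -1L, , drop = FALSE], 2, m_neg)
  S <- crossprod(Zc) / (nrow(Zc) - 2)

  gamma <- if (identical(reg, "auto")) analytic_shrinkage(Zc, S)
           else as.numeric(reg)
  if (is.na(gamma) || gamma < 0 || gamma > 1)
    abort("reg must be in [0, 1] or \"auto\"", "icaclean_training_error")
  S_shrunk <- (1 - gamma) * S + gamma * diag(mean(diag(S)), ncol(S))

  w <- solve(S_shrunk, m_pos - m_neg)
  b <- -sum(w * (m_pos + m_neg)) / 2
  clf <- new_classifier(w = as.numeric(w), b = b, feature_means = mu,
                        feature_sds = sds, alpha_band = alpha_band)
  clf$shrinkage <- gamma
  clf
}

#' Classify components
#'
#' Returns `sign(w . z(x) + b)` per component, with z the stored training
#' standardisation. An exact zero maps to `-1` (neural): when in doubt the
#' component is retained.
#'
#' @param clf an `eeg_classifier`.
#' @param features data.frame (or matrix) of feature rows.
#' @return a [label_set()] with `source = "automatic"`; the decision values
#'   are attached as attribute `decision_values`.
#' @export
classify_components <- function(clf, features) {
  X <- if (is.matrix(features)) features else feature_matrix(features)
  if (anyNA(X))
    abort("features contain NA", "icaclean_input_error")
  Z <- scale(X, center = clf$feature_means, scale = clf$feature_sds)
  dv <- as.numeric(Z %*% clf$w + clf$b)
  lab <- ifelse(dv > 0, 1L, -1L)
  out <- label_set(lab, source = "automatic")
  attr(out, "decision_values") <- dv
  out
}

#' Disagreement (MSE) between two labelings
#'
#' The fraction of components on which two binary labelings disagree;
#' identical to the mean squared error of the 0/1-coded labels. 0.25 means
#' the two classifications differed on 25 % of components.
#'
#' @param auto,manual [label_set()] objects or +1/-1 vectors of equal
#'   length.
#' @return scalar in `[0, 1]`.
#' @export
evaluate_mse <- function(auto, manual) {
  a <- as_label_vector(auto)
  b <- as_label_vector(manual)
  if (length(a) != length(b) || length(a) < 1)
    abort("label vectors must have equal positive length",
          "icaclean_input_error")
  mean(a != b)
}

#' Stratified k-fold cross-validation of the classifier
#'
#' @param features data.frame of feature rows.
#' @param labels a [label_set()] or +1/-1 vector.
#' @param k_folds number of folds (default 10; `k = n` gives leave-one-out).
#' @param seed integer seed controlling the fold assignment.
#' @param reg shrinkage passed to [train_component_classifier()].
#' @return list with `fold_mse`, `mean_mse`, `sd_mse`.
#' @export
crossvalidate <- function(features, labels, k_folds = 10, seed = 1,
                          reg = "auto") {
  X <- feature_matrix(features)
  y <- as_label_vector(labels)
  if (k_folds < 2)
    abort("need at least 2 folds", "icaclean_input_error")
  folds <- integer(length(y))
  with_local_seed(seed, {
    start <- 0L
    for (cls in c(-1L, 1L)) {
      idx <- sample(which(y == cls))
      # continue the round-robin across classes so every fold is used
      folds[idx] <- ((start + seq_along(idx) - 1L) %% k_folds) + 1L
      start <- start + length(idx)
    }
  })
  df <- as.data.frame(X)
  fold_mse <- vapply(seq_len(k_folds), function(f) {
    tr <- folds != f
    te <- !tr
    if (!any(te)) return(NA_real_)
    if (length(unique(y[tr])) < 2)
      abort("a training fold lost one class; reduce k_folds",
            "icaclean_stratification_error")
    clf <- train_component_classifier(df[tr, , drop = FALSE], y[tr],
                                      reg = reg)
    evaluate_mse(classify_components(clf, df[te, , drop = FALSE]), y[te])
  }, numeric(1))
  fold_mse <- fold_mse[!is.na(fold_mse)]
  list(fold_mse = fold_mse, mean_mse = mean(fold_mse),
       sd_mse = stats::sd(fold_mse))
}
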