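#' Train a nearest-shrunken-centroids (PAM) classifier
#'
#' Diagonal-covariance classifier with soft-thresholded class centroids.
#' For feature i and class k with class centroid `xbar_ik`, overall centroid
#' `xbar_i`, pooled within-class SD `s_i`, fudge factor `s0` (the median of
#' the `s_i`), and `m_k = sqrt(1/n_k - 1/n)`:
#' `d_ik = (xbar_ik - xbar_i) / (m_k * (s_i + s0))`, soft-thresholded to
#' `d'_ik = sign(d_ik) * max(0, |d_ik| - delta)`, giving shrunken centroids
#' `xbar_i + m_k * (s_i + s0) * d'_ik`. Priors default to class frequencies.
#' At `delta = 0` this is plain nearest-centroid / diagonal LDA.
#'
#' Missing feature values are ignored in the centroid and SD computations
#' (features observed in at least one sample per class are required).
#'
#' @param X samples x features numeric matrix
#' @param y class labels (2 classes for the BRCA-like application, but any
#'   number is supported)
#' @param delta nonnegative shrinkage
#' @param priors optional class priors (default class frequencies)
#' @return an `nsc_model`
#' @export
train_nsc <- function(X, y, delta = 0, priors = NULL) {
  X <- as.matrix(X)
  y <- factor(y)
  if (delta < 0) stopf("delta must be >= 0")
  nk <- table(y)
  if (any(nk < 2)) stopf("each class needs >= 2 samples")
  if (any(colSums(!is.na(X)) == 0)) stopf("all-missing feature")
  n <- nrow(X); K <- nlevels(y); p <- ncol(X)
  xbar <- colMeans(X, na.rm = TRUE)
  cent <- do.call(rbind, lapply(levels(y), function(k)
    colMeans(X[y == k, , drop = FALSE], na.rm = TRUE)))  # K x p
  rownames(cent) <- levels(y)
  # pooled within-class SD per feature
  ss <- rep(0, p); dfree <- 0
  for (k in levels(y)) {
    Xi <- X[y == k, , drop = FALSE]
    dev <- sweep(Xi, 2, cent[k, ])
    ss <- ss + colSums(dev^2, na.rm = TRUE)
  }
  s_i <- sqrt(ss / (n - K))
  s0 <- stats::median(s_i)
  mk <- sqrt(1 / as.numeric(nk) - 1 / n)
  d <- sweep(cent, 2, xbar) / (outer(mk, s_i + s0))
  dprime <- sign(d) * pmax(0, abs(d) - delta)
  shrunken <- sweep(outer(mk, s_i + s0) * dprime, 2, xbar, "+")
  priors <- priors %||% as.numeric(nk) / n
  structure(list(feature_ids = colnames(X) %||% paste0("f", seq_len(p)),
                 class_labels = levels(y), overall_centroid = xbar,
                 centroids = cent, shrunken_centroids = shrunken,
                 offsets = dprime, pooled_sd = s_i, s0 = s0,
                 priors = priors, delta = delta,
                 posterior_threshold = 0.5),
            class = "nsc_model")
}

#' Posterior class probabilities under an NSC model
#'
#' Discriminant `delta_k(x) = sum_i (x_i - xbar'_ik)^2 / (s_i + s0)^2 -
#' 2 log pi_k`; posteriors are softmax of `-delta_k / 2`. Missing features
#' are imputed with the overall centroid (contributing equally to every
#' class up to the shrunken offset).
#'
#' @param model an `nsc_model`
#' @param X samples x features matrix (features matched by position)
#' @return samples x classes matrix of posteriors
#' @export
nsc_posterior <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$overall_centroid))
    stopf("feature mismatch: model has %d features, data %d",
          length(model$overall_centroid), ncol(X))
  denom <- (model$pooled_sd + model$s0)^2
  post <- matrix(NA_real_, nrow(X), length(model$class_labels),
                 dimnames = list(rownames(X), model$class_labels))
  for (s in seq_len(nrow(X))) {
    x <- X[s, ]
    x[is.na(x)] <- model$overall_centroid[is.na(x)]
    disc <- sapply(seq_along(model$class_labels), function(k)
      sum((x - model$shrunken_centroids[k, ])^2 / denom) -
        2 * log(model$priors[k]))
    w <- -0.5 * (disc - min(disc))
    post[s, ] <- exp(w) / sum(exp(w))
  }
  post
}

#' Classify 1 MB profiles as BRCA-like (non-BRCAmut HRD) or not
#'
#' Applies the posterior > 0.5 rule: a profile is called `nonBRCAmutHRD`
#' when the BRCA-like posterior exceeds 0.5 and QC passed; a posterior of
#' exactly 0.5 (or below) is non-BRCA-like. Samples with more than half of
#' the model features missing fail QC and get no label.
#'
#' @param model an `nsc_model` whose first class label is the BRCA-like
#'   class (`"BRCA_like"` by convention)
#' @param X samples x features matrix of calibrated 1 MB log2 ratios
#' @param brca_like_class which model class means BRCA-like
#' @return data.frame: sample_id, posterior_brca_like, label, qc_pass
#' @export
classify_hrd <- function(model, X, brca_like_class = "BRCA_like") {
  X <- as.matrix(X)
  stopifnot(brca_like_class %in% model$class_labels)
  frac_missing <- rowMeans(is.na(X))
  post <- nsc_posterior(model, X)
  pb <- post[, brca_like_class]
  qc <- frac_missing <= 0.5
  label <- ifelse(!qc, NA_character_,
                  ifelse(pb > model$posterior_threshold, "nonBRCAmutHRD",
                         "non_BRCA_like"))
  data.frame(sample_id = rownames(X) %||% seq_len(nrow(X)),
             posterior_brca_like = pb, label = label, qc_pass = qc,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Choose the NSC shrinkage by stratified cross-validation
#'
#' Stratified k-fold cross-validated misclassification error over a delta
#' grid; returns the largest delta whose CV error is within one standard
#' error of the minimum (the one-SE rule), favoring sparser models.
#'
#' @param X samples x features matrix
#' @param y class labels
#' @param folds number of folds (default 5)
#' @param delta_grid candidate shrinkage values
#' @param seed seed for the fold assignment
#' @return the chosen delta, with attributes `cv_error` and `cv_se`
#' @export
choose_delta <- function(X, y, folds = 5,
                         delta_grid = seq(0, 4, by = 0.25), seed = 1L) {
  if (!length(delta_grid)) stopf("empty delta grid")
  if (folds < 2) stopf("need >= 2 folds")
  X <- as.matrix(X); y <- factor(y)
  fold <- integer(nrow(X))
  with_seed(seed, for (k in levels(y)) {
    idx <- which(y == k)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  })
  err <- matrix(NA_real_, folds, length(delta_grid))
  for (f in seq_len(folds)) {
    tr <- fold != f
    m0 <- train_nsc(X[tr, , drop = FALSE], y[tr], delta = 0)
    for (j in seq_along(delta_grid)) {
      m <- train_nsc(X[tr, , drop = FALSE], y[tr], delta = delta_grid[j])
      post <- nsc_posterior(m, X[!tr, , drop = FALSE])
      pred <- m$class_labels[max.col(post, ties.method = "first")]
      err[f, j] <- mean(pred != as.character(y[!tr]))
    }
  }
  cv <- colMeans(err)
  se <- apply(err, 2, stats::sd) / sqrt(folds)
  best <- which.min(cv)
  ok <- which(cv <= cv[best] + se[best])
  chosen <- max(delta_grid[ok])
  structure(chosen, cv_error = cv, cv_se = se, delta_grid = delta_grid)
}

#' Save / load an NSC model as JSON
#'
#' @param model an `nsc_model`
#' @param path file path
#' @export
write_nsc_model <- function(model, path) {
  obj <- unclass(model)
  obj$format_version <- 1L
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_nsc_model
#' @export
read_nsc_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format_version)) stopf("not an nsc model file: %s", path)
  obj$format_version <- NULL
  K <- length(obj$class_labels)
  for (f in c("centroids", "shrunken_centroids", "offsets")) {
    m <- obj[[f]]
    if (!is.matrix(m)) m <- matrix(unlist(m), nrow = K, byrow = TRUE)
    dimnames(m) <- list(obj$class_labels, obj$feature_ids)
    obj[[f]] <- m
  }
  structure(obj, class = "nsc_model")
}
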