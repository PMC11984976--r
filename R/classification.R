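#' Fit a linear discriminant analysis classifier
#'
#' Gaussian classes with a shared covariance: class means are per-class
#' sample means, the pooled covariance is the within-class scatter divided
#' by `n - K`, and priors default to empirical class frequencies. A small
#' shrinkage `lambda` toward the scaled identity,
#' `S = (1 - lambda) * S + lambda * tr(S)/D * I`, keeps the pooled
#' covariance invertible when folds are small relative to the feature
#' dimension (the 160-class design trains folds with only two repetitions
#' per class).
#'
#' @param x Numeric matrix, samples in rows.
#' @param y Class labels; a factor's level order fixes the canonical label
#'   order (used for deterministic tie-breaking), otherwise labels are
#'   sorted.
#' @param lambda Shrinkage weight in \[0, 1\].
#' @param priors Optional named prior probabilities (must sum to 1);
#'   default: empirical frequencies.
#' @return An `lda_fit` with `labels`, `means` (K x D),
#'   `pooled_cov`, its inverse `pooled_cov_inv`, `priors`, `lambda` and the
#'   linear discriminant coefficients.
#' @export
fit_lda <- function(x, y, lambda = 1e-3, priors = NULL) {
  x <- as.matrix(x)
  if (!is.factor(y)) y <- factor(y)
  y <- droplevels(y)
  labels <- levels(y)
  k <- length(labels)
  if (k < 2L) stop("need at least 2 classes, got ", k, call. = FALSE)
  counts <- table(y)
  if (any(counts < 2L)) {
    stop("class(es) with < 2 samples: ",
         paste(names(counts)[counts < 2L], collapse = ", "), call. = FALSE)
  }
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]", call. = FALSE)
  n <- nrow(x)
  d <- ncol(x)
  means <- rowsum(x, y) / as.vector(counts)
  centred <- x - means[as.integer(y), , drop = FALSE]
  s_pooled <- crossprod(centred) / (n - k)
  s_shrunk <- (1 - lambda) * s_pooled +
    lambda * (sum(diag(s_pooled)) / d) * diag(d)
  s_inv <- chol2inv(chol(s_shrunk))
  if (is.null(priors)) {
    priors <- as.vector(counts) / n
    names(priors) <- labels
  } else {
    if (is.null(names(priors)) || !setequal(names(priors), labels) ||
        abs(sum(priors) - 1) > 1e-8) {
      stop("priors must be named over all classes and sum to 1",
           call. = FALSE)
    }
    priors <- priors[labels]
  }
  # discriminant delta_k(x) = x' S^-1 mu_k - mu_k' S^-1 mu_k / 2 + log pi_k
  w <- s_inv %*% t(means)                    # D x K
  b <- -0.5 * colSums(t(means) * w) + log(priors)
  structure(
    list(labels = labels, means = means, pooled_cov = s_shrunk,
         pooled_cov_inv = s_inv, priors = priors, lambda = lambda,
         coef = w, intercept = b, dim = d),
    class = "lda_fit"
  )
}

#' Predict classes from a fitted LDA model
#'
#' Returns `argmax_k delta_k(x)`; exact ties break deterministically to the
#' earliest label in the model's canonical label order.
#'
#' @param object An `lda_fit`.
#' @param newdata Numeric matrix (samples x features) or vector (one
#'   sample).
#' @param type `"class"` for labels, `"score"` for the K discriminant
#'   values per sample.
#' @param ... Unused.
#' @return Factor of predicted labels (or a score matrix).
#' @export
predict.lda_fit <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$dim) {
    stop("feature dimension ", ncol(newdata), " does not match model (",
         object$dim, ")", call. = FALSE)
  }
  scores <- newdata %*% object$coef +
    rep(object$intercept, each = nrow(newdata))
  colnames(scores) <- object$labels
  if (type == "score") return(scores)
  factor(object$labels[max.col(scores, ties.method = "first")],
         levels = object$labels)
}

#' Build a confusion matrix of counts
#'
#' @param truth,predicted Vectors of true and predicted labels.
#' @param labels Ordered label set for rows (truth) and columns
#'   (predictions).
#' @return K x K integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(truth, predicted, labels) {
  m <- table(factor(truth, levels = labels),
             factor(predicted, levels = labels))
  m <- unclass(as.matrix(m))
  dimnames(m) <- list(truth = labels, predicted = labels)
  class(m) <- c("confusion_matrix", class(m))
  m
}

#' Row-normalize a confusion matrix to percentages
#'
#' @param confusion A count `confusion_matrix`.
#' @return Matrix whose rows sum to 100.
#' @export
normalize_confusion <- function(confusion) {
  rs <- rowSums(confusion)
  if (any(rs == 0)) {
    stop("confusion matrix has empty row(s): ",
         paste(rownames(confusion)[rs == 0], collapse = ", "), call. = FALSE)
  }
  sweep(unclass(confusion), 1, rs, "/") * 100
}

#' Diagonal-mean classification accuracy
#'
#' Row-normalizes the confusion matrix and returns the mean of its diagonal
#' (macro-averaged per-class recall), in percent.
#'
#' @param confusion A count `confusion_matrix`.
#' @return Scalar percentage in \[0, 100\].
#' @export
accuracy <- function(confusion) {
  mean(diag(normalize_confusion(confusion)))
}

#' Leave-one-repetition-out cross-validation
#'
#' Repetitions are global fold keys: fold r trains on every window whose
#' repetition differs from r and tests on the windows of repetition r, for
#' each r in turn; window-level predictions from all folds accumulate into
#' a single confusion matrix.
#'
#' @param features Data.frame with a `repetition` column and the feature
#'   columns.
#' @param feature_cols Character vector naming the feature columns (e.g.
#'   [feature_names()]).
#' @param labels Vector/factor of class labels, one per row of `features`
#'   (or the name of a column of `features`).
#' @param label_levels Canonical label order; defaults to the factor levels
#'   or sorted unique labels.
#' @param lambda Shrinkage passed to [fit_lda()].
#' @return List with `confusion` (summed over folds) and `accuracy_pct`.
#' @export
loro_cv <- function(features, feature_cols, labels, label_levels = NULL,
                    lambda = 1e-3) {
  if (is.character(labels) && length(labels) == 1L &&
      labels %in% names(features)) {
    labels <- features[[labels]]
  }
  if (is.null(label_levels)) {
    label_levels <- if (is.factor(labels)) levels(labels)
                    else sort(unique(labels))
  }
  labels <- factor(labels, levels = label_levels)
  reps <- sort(unique(features$repetition))
  if (length(reps) < 2L) {
    stop("need at least 2 repetitions for leave-one-repetition-out CV",
         call. = FALSE)
  }
  x <- as.matrix(features[, feature_cols, drop = FALSE])
  conf <- matrix(0L, length(label_levels), length(label_levels),
                 dimnames = list(truth = label_levels,
                                 predicted = label_levels))
  for (r in reps) {
    test <- features$repetition == r
    y_train <- droplevels(labels[!test])
    missing <- setdiff(label_levels, levels(y_train))
    if (length(missing)) {
      stop("class(es) absent from training fold (repetition ", r,
           " held out): ", paste(missing, collapse = ", "), call. = FALSE)
    }
    fit <- fit_lda(x[!test, , drop = FALSE],
                   factor(labels[!test], levels = label_levels),
                   lambda = lambda)
    pred <- predict(fit, x[test, , drop = FALSE])
    conf <- conf + unclass(confusion_matrix(labels[test], pred, label_levels))
  }
  class(conf) <- c("confusion_matrix", class(conf))
  list(confusion = conf, accuracy_pct = accuracy(conf))
}
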