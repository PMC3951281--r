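#' Train a binary-relevance multi-label SVM (MLSVM)
#'
#' Decomposes the multi-label task into one soft-margin SVM per class.  The
#' hinge loss of each positive sample is amplified by
#' `lambda = N_neg / N_pos` (the inverse class frequency ratio) so that the
#' minority positive class is not swamped by negatives; negatives keep
#' weight 1.  Classes lacking a positive or a negative training sample are
#' skipped with a warning and produce sentinel scores.
#'
#' @param X numeric matrix, samples x features.
#' @param Y binary matrix, samples x classes (0/1), column names kept.
#' @param C soft-margin cost parameter.
#' @param kernel e1071 kernel name (`"radial"` default, or `"linear"`, ...).
#' @param gamma RBF bandwidth; default `1 / ncol(X)`.
#' @param amplify if `FALSE`, all loss weights are 1 (plain SVM).
#' @return object of class `mlsvm_model` holding one fitted discriminant per
#'   class plus the amplification coefficients used.
#' @export
train_mlsvm <- function(X, Y, C = 1, kernel = "radial",
                        gamma = 1 / ncol(X), amplify = TRUE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("class", seq_len(ncol(Y)))
  fits <- vector("list", ncol(Y))
  names(fits) <- colnames(Y)
  lambda <- stats::setNames(rep(NA_real_, ncol(Y)), colnames(Y))
  for (j in seq_len(ncol(Y))) {
    y <- Y[, j]
    n_pos <- sum(y == 1); n_neg <- sum(y == 0)
    if (n_pos == 0L || n_neg == 0L) {
      warning("class '", colnames(Y)[j],
              "' skipped: needs both positive and negative training samples")
      next
    }
    lambda[j] <- if (amplify) n_neg / n_pos else 1
    yf <- factor(ifelse(y == 1, "pos", "neg"), levels = c("pos", "neg"))
    fits[[j]] <- e1071::svm(X, yf, scale = FALSE, kernel = kernel,
                            cost = C, gamma = gamma,
                            class.weights = c(pos = lambda[[j]], neg = 1))
  }
  structure(list(fits = fits, C = C, kernel = kernel, gamma = gamma,
                 lambda = lambda, n_features = ncol(X),
                 class_ids = colnames(Y)),
            class = "mlsvm_model")
}

#' Continuous decision scores of an MLSVM model
#'
#' Signed decision values oriented so that positive scores favour class
#' membership; thresholding at zero gives binary labels.  Columns of skipped
#' classes are filled with `-Inf` and flagged in the `skipped` attribute.
#'
#' @param model a [train_mlsvm()] model.
#' @param X numeric matrix, samples x features (same feature count as
#'   training).
#' @return numeric matrix samples x classes of decision values.
#' @export
predict_scores <- function(model, X) {
  stopifnot(inherits(model, "mlsvm_model"))
  X <- as.matrix(X)
  if (nrow(X) && ncol(X) != model$n_features)
    stop("feature dimension mismatch: model expects ", model$n_features)
  scores <- matrix(-Inf, nrow(X), length(model$fits),
                   dimnames = list(rownames(X), model$class_ids))
  if (nrow(X) == 0L) return(scores)
  for (j in seq_along(model$fits)) {
    fit <- model$fits[[j]]
    if (is.null(fit)) next
    dv <- attr(stats::predict(fit, X, decision.values = TRUE),
               "decision.values")
    ## libsvm orients the decision value towards the first named class
    flip <- identical(colnames(dv)[1L], "neg/pos")
    scores[, j] <- if (flip) -dv[, 1L] else dv[, 1L]
  }
  attr(scores, "skipped") <- model$class_ids[vapply(model$fits, is.null,
                                                    logical(1))]
  scores
}

#' Train a similarity-sum multi-label KNN (MLKNN)
#'
#' Stores the training samples and labels for the lazy multi-label
#' k-nearest-neighbour classifier.  Neighbour search uses the correlation
#' distance `1 - pearson_r`; the similarity entering the likelihood scores is
#' the rescaled correlation `(1 + r) / 2` in `[0, 1]`.
#'
#' @param X numeric matrix, samples x features.
#' @param Y binary matrix, samples x classes.
#' @param k neighbour count, `1 <= k <= nrow(X)`.
#' @return object of class `mlknn_model`.
#' @export
train_mlknn <- function(X, Y, k = 5) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y), k >= 1, k <= nrow(X))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("class", seq_len(ncol(Y)))
  structure(list(X = X, Y = Y, k = k), class = "mlknn_model")
}

## indices of the k nearest training samples under 1 - r, ties by index
knn_neighbours <- function(x, model) {
  d <- apply(model$X, 1L, function(row) {
    if (stats::sd(row) == 0 || stats::sd(x) == 0) 2
    else 1 - stats::cor(x, row)
  })
  order(d)[seq_len(model$k)]
}

#' Candidate classes of a test sample
#'
#' The union of the label sets of the sample's k nearest training samples.
#'
#' @param x numeric feature vector.
#' @param model a [train_mlknn()] model.
#' @return character vector of candidate class ids.
#' @export
knn_candidates <- function(x, model) {
  nb <- knn_neighbours(x, model)
  colnames(model$Y)[colSums(model$Y[nb, , drop = FALSE]) > 0L]
}

#' Likelihood scores of the candidate classes
#'
#' For each class, the sum over the k nearest neighbours belonging to that
#' class of the similarity `(1 + pearson_r(x, neighbour)) / 2`.
#' Non-candidate classes score 0.  The total similarity mass over the k
#' neighbours is returned as attribute `total_mass` for the label decision.
#'
#' @param x numeric feature vector.
#' @param model a [train_mlknn()] model.
#' @return named numeric vector of per-class scores.
#' @export
knn_scores <- function(x, model) {
  nb <- knn_neighbours(x, model)
  sim <- vapply(nb, function(i) {
    row <- model$X[i, ]
    if (stats::sd(row) == 0 || stats::sd(x) == 0) 0
    else (1 + stats::cor(x, row)) / 2
  }, numeric(1))
  sc <- as.numeric(sim %*% model$Y[nb, , drop = FALSE])
  names(sc) <- colnames(model$Y)
  attr(sc, "total_mass") <- sum(sim)
  sc
}

#' Label decision from MLKNN scores
#'
#' A class is predicted iff it holds a strict majority of the similarity
#' mass of the k neighbours: `score(c) > total_mass / 2`.  An exact split
#' predicts neither class.
#'
#' @param scores named score vector from [knn_scores()].
#' @param total_mass total similarity mass over the k neighbours; defaults to
#'   the `total_mass` attribute of `scores`.
#' @return character vector of predicted class ids.
#' @export
knn_labels <- function(scores, total_mass = attr(scores, "total_mass")) {
  if (is.null(total_mass)) stop("total_mass is required")
  names(scores)[scores > total_mass / 2]
}

#' Score a sample matrix with an MLKNN model
#' @param model a [train_mlknn()] model.
#' @param X numeric matrix, samples x features.
#' @return numeric matrix samples x classes of similarity-sum scores.
#' @export
predict_knn_scores <- function(model, X) {
  X <- as.matrix(X)
  out <- matrix(0, nrow(X), ncol(model$Y),
                dimnames = list(rownames(X), colnames(model$Y)))
  for (i in seq_len(nrow(X))) out[i, ] <- knn_scores(X[i, ], model)
  out
}
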