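#' Balanced leave-a-percent-out split for one class
#'
#' Training positives are a random `n_percent` share of the class's positive
#' samples -- `floor(n_percent * P + 0.5)`, i.e. rounding halves up as in the
#' reference protocol -- clamped to `[1, P - 1]` so that small classes keep a
#' positive sample on each side of the split.  The same number of negatives
#' is drawn uniformly without replacement; everything else is the test set.
#'
#' @param Y binary label matrix (samples x classes) or a binary vector.
#' @param class class column index or name (ignored if `Y` is a vector).
#' @param n_percent training fraction in (0, 1).
#' @param seed integer seed making the split deterministic.
#' @return object of class `split_spec`: integer index vectors `train_pos`,
#'   `train_neg`, `test`, plus `n_percent` and `seed`.
#' @export
balanced_split <- function(Y, class = 1L, n_percent, seed) {
  y <- if (is.matrix(Y)) Y[, class] else Y
  stopifnot(n_percent > 0, n_percent < 1, all(y %in% 0:1))
  pos <- which(y == 1); neg <- which(y == 0)
  P <- length(pos)
  if (P < 2L) {
    warning("class has fewer than 2 positive samples; split skipped")
    return(NULL)
  }
  n_tr <- min(max(floor(n_percent * P + 0.5), 1L), P - 1L)
  if (length(neg) < n_tr)
    stop("not enough negative samples to balance ", n_tr, " positives")
  rng <- local_rng(seed)
  train_pos <- sort(rng$sample(pos, n_tr))
  train_neg <- sort(rng$sample(neg, n_tr))
  test <- setdiff(seq_along(y), c(train_pos, train_neg))
  structure(list(train_pos = train_pos, train_neg = train_neg, test = test,
                 n_percent = n_percent, seed = seed),
            class = "split_spec")
}

## deterministic RNG scoped away from the global stream
local_rng <- function(seed) {
  env <- new.env()
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    s
  }
  run <- function(expr_fun) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    expr_fun()
  }
  list(sample = function(x, size)
         run(function() x[sample.int(length(x), size)]),
       runif = function(n) run(function() stats::runif(n)),
       rnorm = function(n, mean = 0, sd = 1)
         run(function() stats::rnorm(n, mean, sd)))
}

## deterministic sub-seed derivation, kept within 32-bit integer range
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) h <- (h * 7919 + as.numeric(p) + 1) %% 2147483629
  as.integer(h) + 1L
}

#' Confusion counts
#'
#' @param y_true,y_pred binary vectors of equal length.
#' @return named integer vector `c(TP, FP, TN, FN)`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  c(TP = sum(y_true == 1 & y_pred == 1),
    FP = sum(y_true == 0 & y_pred == 1),
    TN = sum(y_true == 0 & y_pred == 0),
    FN = sum(y_true == 1 & y_pred == 0))
}

#' ROC curve and AUC for one class
#'
#' AUC uses the rank (Mann-Whitney) formulation -- the probability that a
#' random positive outscores a random negative, with ties counted one half.
#' The ROC points come from sweeping the unique score values as thresholds
#' (predict positive at `score >= threshold`); the trapezoidal area under
#' that sweep equals the rank AUC.
#'
#' @param scores numeric score vector (higher = more positive).
#' @param y_true binary truth vector; both classes must be present.
#' @return object of class `roc_result`: `auc`, `tpr`, `fpr`,
#'   `thresholds`.
#' @export
roc_auc <- function(scores, y_true) {
  stopifnot(length(scores) == length(y_true))
  P <- sum(y_true == 1); N <- sum(y_true == 0)
  if (P == 0L || N == 0L)
    stop("undefined AUC: y_true holds a single class")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y_true == 1]) - P * (P + 1) / 2) / (P * N)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & y_true == 1) / P,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & y_true == 0) / N,
                numeric(1))
  structure(list(auc = auc, tpr = tpr, fpr = fpr, thresholds = thr),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC = %.4f over %d thresholds\n", x$auc,
              length(x$thresholds)))
  invisible(x)
}

#' Balanced leave-a-percent-out evaluation protocol
#'
#' For each training fraction in `n_grid` and each repetition, every class of
#' the learning system gets a fresh balanced split ([balanced_split()]); a
#' binary-relevance classifier is trained on the split's balanced training
#' samples and scores the test samples; the per-class AUC, and the confusion
#' counts at the default operating point (score > 0 for the SVM, majority of
#' similarity mass for the KNN), are recorded.  Classes with fewer than two
#' positives are skipped.  Sub-seeds for each (class, n, repetition) cell are
#' derived deterministically from `seed`.
#'
#' @param system a [learning_system()].
#' @param expr preprocessed [tc_matrix()] containing the system's genes.
#' @param clf `"mlsvm"` or `"mlknn"`.
#' @param n_grid training fractions (default `seq(0.1, 0.9, by = 0.1)`).
#' @param reps repetitions per fraction (the reference protocol uses 20).
#' @param seed master seed.
#' @param C,kernel MLSVM cost and kernel.
#' @param k MLKNN neighbour count.
#' @return list with `summary` (data.frame: `n_percent`, `clf`, `mean_auc`,
#'   `mean_auc_pooled`, `mean_tpr`, `mean_fpr`) and `detail` (per class x
#'   repetition rows with AUC and confusion counts).
#' @export
run_protocol <- function(system, expr, clf = c("mlsvm", "mlknn"),
                         n_grid = seq(0.1, 0.9, by = 0.1), reps = 20,
                         seed = 1, C = 1, kernel = "radial", k = 5) {
  clf <- match.arg(clf)
  Y <- system$label_matrix
  X <- profiles(expr, rownames(Y))
  detail <- list()
  for (n in n_grid) for (rep_i in seq_len(reps)) {
    for (j in seq_len(ncol(Y))) {
      res <- evaluate_class(X, Y[, j], clf,
                            n_percent = n,
                            seed = derive_seed(seed, round(n * 100), rep_i, j),
                            C = C, kernel = kernel, k = k)
      if (is.null(res)) next
      detail[[length(detail) + 1L]] <-
        data.frame(n_percent = n, rep = rep_i, class = colnames(Y)[j],
                   auc = res$auc, TP = res$conf[["TP"]], FP = res$conf[["FP"]],
                   TN = res$conf[["TN"]], FN = res$conf[["FN"]])
    }
  }
  detail <- do.call(rbind, detail)
  if (is.null(detail)) stop("no class could be evaluated")
  summarise_n <- function(d) {
    per_class <- stats::aggregate(auc ~ class, d, mean)
    tpr <- d$TP / (d$TP + d$FN); fpr <- d$FP / (d$FP + d$TN)
    data.frame(mean_auc = mean(per_class$auc),     # class-then-repetition
               mean_auc_pooled = mean(d$auc),      # pooled class x repetition
               mean_tpr = mean(tpr, na.rm = TRUE),
               mean_fpr = mean(fpr, na.rm = TRUE))
  }
  summary <- do.call(rbind, lapply(split(detail, detail$n_percent),
                                   summarise_n))
  summary <- cbind(n_percent = as.numeric(rownames(summary)), clf = clf,
                   summary)
  rownames(summary) <- NULL
  list(summary = summary, detail = detail)
}

## one (class, split) evaluation; returns NULL if the class is unusable
evaluate_class <- function(X, y, clf, n_percent, seed, C = 1,
                           kernel = "radial", k = 5) {
  split <- withCallingHandlers(
    balanced_split(y, n_percent = n_percent, seed = seed),
    warning = function(w) invokeRestart("muffleWarning"))
  if (is.null(split)) return(NULL)
  tr <- c(split$train_pos, split$train_neg)
  if (!sum(y[split$test] == 1) || !sum(y[split$test] == 0)) return(NULL)
  Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
  Xte <- X[split$test, , drop = FALSE]; yte <- y[split$test]
  if (clf == "mlsvm") {
    model <- train_mlsvm(Xtr, matrix(ytr, ncol = 1L), C = C, kernel = kernel)
    sc <- predict_scores(model, Xte)[, 1L]
    pred <- as.integer(sc > 0)
  } else {
    k_eff <- min(k, nrow(Xtr))
    model <- train_mlknn(Xtr, matrix(ytr, ncol = 1L,
                                     dimnames = list(NULL, "pos")), k = k_eff)
    sc <- numeric(nrow(Xte)); pred <- integer(nrow(Xte))
    for (i in seq_len(nrow(Xte))) {
      s <- knn_scores(Xte[i, ], model)
      sc[i] <- s[["pos"]]
      pred[i] <- as.integer(s[["pos"]] > attr(s, "total_mass") / 2)
    }
  }
  list(auc = roc_auc(sc, yte)$auc, conf = confusion(yte, pred))
}
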