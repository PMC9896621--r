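#' Confusion counts from true and predicted labels
#'
#' @param truth,pred label vectors of equal length.
#' @param classes optional class ordering; defaults to the sorted union.
#' @return k x k contingency matrix (`confusion_counts`), rows = truth,
#'   columns = prediction.
#' @export
confusion_counts <- function(truth, pred, classes = NULL) {
  if (length(truth) != length(pred))
    stop("confusion_counts: length mismatch")
  classes <- classes %||% sort(union(unique(truth), unique(pred)))
  tab <- table(factor(truth, levels = classes),
               factor(pred, levels = classes))
  m <- unclass(as.matrix(tab))
  class(m) <- c("confusion_counts", class(m))
  m
}

.as_counts <- function(counts) {
  m <- unclass(as.matrix(counts))
  if (nrow(m) != ncol(m)) stop("confusion counts must be square")
  if (sum(m) == 0) stop("confusion counts: N = 0")
  m
}

#' Classification accuracy
#'
#' (TP + TN) / N for two classes; trace / N in the multi-class
#' generalization.
#'
#' @param counts square confusion matrix (truth in rows).
#' @return accuracy in `[0, 1]`.
#' @export
accuracy <- function(counts) {
  m <- .as_counts(counts)
  sum(diag(m)) / sum(m)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement (P0 - Pe) / (1 - Pe), with the chance
#' agreement Pe taken from the products of the row and column marginals.
#' Complete agreement gives 1; agreement at the level implied by the
#' marginals gives 0; negative values mean worse-than-chance agreement. In
#' the degenerate case Pe = 1 (all mass in one row and column) the function
#' returns 0 with a warning.
#'
#' @param counts square confusion matrix (truth in rows).
#' @return kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(counts) {
  m <- .as_counts(counts)
  n <- sum(m)
  p0 <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  if (abs(1 - pe) < 1e-12) {
    warning("cohens_kappa: degenerate marginals (Pe = 1); returning 0")
    return(0)
  }
  (p0 - pe) / (1 - pe)
}

#' ROC curve, AUC and best operating point
#'
#' AUC by the trapezoidal rule over all score thresholds (equivalently the
#' concordance probability with ties counted 1/2); the reported operating
#' point maximizes Youden's J = sensitivity + specificity - 1.
#'
#' @param scores numeric vector (higher = more positive), optionally named.
#' @param labels vector with exactly two kinds of entries; `positive` marks
#'   the positive class.
#' @param positive the positive label.
#' @return list with `auc`, `sensitivity`, `specificity`, `threshold` and the
#'   full `curve` data.frame (threshold, tpr, fpr).
#' @export
roc_curve <- function(scores, labels, positive = "active") {
  pos <- labels == positive
  if (!any(pos) || all(pos))
    stop("roc_curve: both classes must be present")
  np <- sum(pos); nn <- sum(!pos)
  # threshold sweep over unique scores, descending
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores[pos] >= t) / np, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores[!pos] >= t) / nn, numeric(1))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  j <- tpr - fpr
  best <- which.max(j)
  list(auc = auc, sensitivity = tpr[best], specificity = 1 - fpr[best],
       threshold = thr[best],
       curve = data.frame(threshold = thr, tpr = tpr, fpr = fpr))
}

#' Assemble the descriptor matrix for machine learning
#'
#' Columns are the binding-site atom ids (0/1 contact bits) followed by the
#' scoring-function values; rows are poses present in both blocks. Labels
#' and the pose-to-compound map ride along so splits can be applied with
#' pose integrity.
#'
#' @param fingerprints 0/1 matrix from [build_fingerprint_matrix()].
#' @param scores a [score_table()] (optional).
#' @param activities data.frame with `compound_id` and `activity_class`.
#' @param compound_of named vector pose_id -> compound_id.
#' @return A `feature_matrix`: list with `X`, `labels`, `compound_of`.
#' @export
feature_matrix <- function(fingerprints, scores = NULL, activities,
                           compound_of) {
  ids <- rownames(fingerprints)
  X <- fingerprints
  storage.mode(X) <- "double"
  if (!is.null(scores)) {
    keep <- intersect(ids, scores$pose_id)
    X <- X[keep, , drop = FALSE]
    sc <- as.matrix(scores[match(keep, scores$pose_id),
                           setdiff(names(scores), "pose_id"), drop = FALSE])
    rownames(sc) <- keep
    X <- cbind(X, sc)
    ids <- keep
  }
  compound_of <- compound_of[ids]
  labels <- activities$activity_class[match(compound_of,
                                            activities$compound_id)]
  names(labels) <- ids
  if (anyNA(labels)) stop("feature_matrix: unlabeled pose(s)")
  if (anyDuplicated(colnames(X))) stop("feature_matrix: duplicate columns")
  structure(list(X = X, labels = labels, compound_of = compound_of),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d poses x %d descriptors; classes: %s\n",
              nrow(x$X), ncol(x$X),
              paste(sprintf("%s=%d", names(table(x$labels)),
                            table(x$labels)), collapse = ", ")))
  invisible(x)
}

# Subset a feature matrix to the poses of the given compounds (and
# optionally to a label subset).
fm_subset <- function(fm, compounds, drop_intermediates = FALSE) {
  keep <- fm$compound_of %in% compounds
  if (drop_intermediates) keep <- keep & fm$labels != "intermediate"
  structure(list(X = fm$X[keep, , drop = FALSE], labels = fm$labels[keep],
                 compound_of = fm$compound_of[keep]),
            class = "feature_matrix")
}

# Pose-level leave-20%-out CV predicted classes for one learner.
.cv_predict <- function(name, X, y, seed, nfolds = 5L, params = list()) {
  n <- nrow(X)
  fold <- with_seed(child_seed(seed, 11L), sample(rep_len(seq_len(nfolds), n)))
  pred <- character(n)
  for (f in seq_len(nfolds)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2L)
      stop("cross-validation fold with a single training class")
    obj <- lrn_fit(name, X[tr, , drop = FALSE], y[tr],
                   seed = child_seed(seed, 100L + f), params = params)
    pred[!tr] <- lrn_predict_class(obj, X[!tr, , drop = FALSE])
  }
  pred
}

#' Scan the learner panel over a train/test split
#'
#' Every learner (with kNN expanded into neighbour-count and
#' distance-weighting variants) is evaluated by pose-level leave-20%-out
#' cross-validation on the training-partition poses and by external
#' prediction of the testing-partition poses. Intermediates are dropped by
#' default (binary task); retaining them switches accuracy/kappa to their
#' three-class forms.
#'
#' @param fm a [feature_matrix()].
#' @param split a [split_every_fifth()] assignment.
#' @param learners subset of `c("rf","xgb","nb","knn","pnn","mlp")`.
#' @param seed integer seed (folds, learner initialization).
#' @param drop_intermediates exclude the intermediate class.
#' @param knn_k neighbour counts scanned for kNN.
#' @param nfolds number of CV folds (5 = leave-20%-out).
#' @return data.frame of evaluation reports sorted by testing kappa.
#' @export
scan_learners <- function(fm, split,
                          learners = c("rf", "xgb", "nb", "knn", "pnn", "mlp"),
                          seed = 1L, drop_intermediates = TRUE,
                          knn_k = c(1L, 3L, 5L, 7L, 9L), nfolds = 5L) {
  train <- fm_subset(fm, split$training_compounds, drop_intermediates)
  test <- fm_subset(fm, split$testing_compounds, drop_intermediates)
  if (length(unique(train$labels)) < 2L)
    stop("scan_learners: training partition has a single class")
  classes <- sort(unique(c(train$labels, test$labels)))
  variants <- list()
  for (l in learners) {
    if (l == "knn") {
      for (k in knn_k) {
        variants[[sprintf("knn(k=%d)", k)]] <-
          list(name = "knn", params = list(k = k, weighted = FALSE))
        variants[[sprintf("knn_wd(k=%d)", k)]] <-
          list(name = "knn", params = list(k = k, weighted = TRUE))
      }
    } else variants[[l]] <- list(name = l, params = list())
  }
  rows <- lapply(names(variants), function(vn) {
    v <- variants[[vn]]
    cv_pred <- .cv_predict(v$name, train$X, train$labels, seed, nfolds,
                           v$params)
    cm_cv <- confusion_counts(train$labels, cv_pred, classes)
    obj <- lrn_fit(v$name, train$X, train$labels,
                   seed = child_seed(seed, 7L), params = v$params)
    test_pred <- lrn_predict_class(obj, test$X)
    cm_te <- confusion_counts(test$labels, test_pred, classes)
    data.frame(learner = vn,
               accuracy_cv = accuracy(cm_cv),
               kappa_cv = cohens_kappa(cm_cv),
               accuracy_test = accuracy(cm_te),
               kappa_test = cohens_kappa(cm_te),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$kappa_test), , drop = FALSE]
  rownames(out) <- NULL
  out
}
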