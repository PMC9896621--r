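# SHAP attribution on the model's class-probability output. Contributions
# are computed against a k-means-summarized background (feature sampling
# table): masked-out features are replaced by background values and the
# model's mean probability over the background is the coalition value.
# Exact subset enumeration is used for small models; otherwise an antithetic
# permutation-sampling estimator, which preserves the local-accuracy
# identity sum(phi) + baseline = predicted probability exactly (the
# telescoping sum over each permutation).

#' k-means background (feature sampling table) for SHAP
#'
#' @param X numeric matrix to summarize (typically the validation poses).
#' @param k number of centroids; clamped to the number of distinct rows.
#' @param seed integer seed for the k-means initialization.
#' @return matrix of centroids with the columns of `X`.
#' @export
shap_background <- function(X, k = 100L, seed = 1L) {
  X <- as.matrix(X)
  ux <- unique(X)
  if (k <= 1L) return(matrix(colMeans(X), 1L, ncol(X),
                             dimnames = list(NULL, colnames(X))))
  if (k >= nrow(ux)) {
    # as many clusters as distinct rows: the summary is the rows themselves
    rownames(ux) <- NULL
    return(ux)
  }
  km <- with_seed(seed,
                  suppressWarnings(kmeans(X, centers = k, iter.max = 100L,
                                          nstart = 1L)))
  centers <- km$centers
  colnames(centers) <- colnames(X)
  centers
}

.prob_active_fn <- function(model, positive = "active") {
  function(M) lrn_predict(model, M)[, positive]
}

#' Per-row, per-feature SHAP probability contributions
#'
#' Returns contributions toward the positive ("active") class probability;
#' for a binary model the contribution toward "inactive" is the negative.
#' For every row, `sum(contributions) + baseline` equals the model's
#' predicted probability (local accuracy), where the baseline is the mean
#' prediction over the background.
#'
#' @param model a [lrn_fit()] learner (binary).
#' @param X rows to explain (matrix with the model's columns).
#' @param background background matrix from [shap_background()].
#' @param method `"auto"` (exact below `exact_max` features), `"exact"`, or
#'   `"permutation"`.
#' @param n_perm permutations per row for the sampling estimator (rounded up
#'   to an even number; antithetic pairs).
#' @param exact_max feature-count limit for the exact path under "auto".
#' @param seed integer seed for the permutation draw.
#' @param positive the class whose probability is attributed.
#' @return matrix (rows of `X` x features) with attribute `baseline`.
#' @export
shap_values <- function(model, X, background,
                        method = c("auto", "exact", "permutation"),
                        n_perm = 20L, exact_max = 8L, seed = 1L,
                        positive = "active") {
  method <- match.arg(method)
  X <- as.matrix(X)
  background <- as.matrix(background)
  if (!identical(colnames(X), colnames(background)) &&
      !(is.null(colnames(X)) && is.null(colnames(background))))
    stop("shap_values: model/feature mismatch between X and background")
  f <- .prob_active_fn(model, positive)
  M <- ncol(X)
  if (method == "auto") method <- if (M <= exact_max) "exact" else "permutation"
  phi <- if (method == "exact") .shap_exact(f, X, background)
         else .shap_perm(f, X, background, n_perm, seed)
  dimnames(phi) <- dimnames(X)
  attr(phi, "baseline") <- mean(f(background))
  attr(phi, "method") <- method
  phi
}

# Exact Shapley by subset enumeration: phi_j = sum_S w(|S|) (v(S+j) - v(S)),
# with v(S) the mean model output when features S come from x and the rest
# from the background rows.
.shap_exact <- function(f, X, background) {
  M <- ncol(X)
  if (M > 20L) stop("exact SHAP limited to 20 features")
  B <- nrow(background)
  n <- nrow(X)
  subsets <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), M)))
  v <- matrix(0, n, nrow(subsets))  # coalition values per row
  for (s in seq_len(nrow(subsets))) {
    on <- subsets[s, ]
    big <- background[rep(seq_len(B), n), , drop = FALSE]
    if (any(on)) {
      xrep <- X[rep(seq_len(n), each = B), on, drop = FALSE]
      big[, on] <- xrep
    }
    v[, s] <- rowMeans(matrix(f(big), nrow = n, byrow = TRUE))
  }
  w <- function(k) factorial(k) * factorial(M - k - 1) / factorial(M)
  sizes <- rowSums(subsets)
  key <- subsets %*% 2^(seq_len(M) - 1)
  phi <- matrix(0, n, M)
  for (j in seq_len(M)) {
    without <- which(!subsets[, j])
    with_j <- match(key[without] + 2^(j - 1), key)
    ww <- w(sizes[without])
    phi[, j] <- (v[, with_j, drop = FALSE] - v[, without, drop = FALSE]) %*% ww
  }
  phi
}

# Antithetic permutation sampling; each permutation contributes a
# telescoping walk from the baseline to f(x).
.shap_perm <- function(f, X, background, n_perm, seed) {
  M <- ncol(X)
  B <- nrow(background)
  n <- nrow(X)
  half <- max(1L, ceiling(n_perm / 2))
  perms <- with_seed(seed, replicate(half, sample.int(M), simplify = FALSE))
  perms <- c(perms, lapply(perms, rev))
  phi <- matrix(0, n, M)
  base_rep <- background[rep(seq_len(B), M + 1L), , drop = FALSE]
  for (pi in perms) {
    # big matrix: (M+1) blocks of the background; block k has features
    # pi[1..k-1] replaced by x's values
    for (i in seq_len(n)) {
      big <- base_rep
      for (k in seq_len(M)) {
        rows <- (k * B + 1L):((M + 1L) * B)
        big[rows, pi[k]] <- X[i, pi[k]]
      }
      vals <- rowMeans(matrix(f(big), nrow = M + 1L, byrow = TRUE))
      phi[i, pi] <- phi[i, pi] + diff(vals)
    }
  }
  phi / length(perms)
}

#' Class-conditional SHAP summaries over the testing set
#'
#' For each feature: the mean contribution toward "active" over poses of
#' active testing compounds, the mean contribution toward "inactive" over
#' poses of inactive testing compounds (binary: the negated "active"
#' contribution), and the standard errors of those means (0 when a class
#' has a single pose).
#'
#' @param contributions matrix from [shap_values()] (rows = poses).
#' @param labels named vector pose_id -> class for the explained rows.
#' @return data.frame (`shap_summary`): feature, mean/stderr per class.
#' @export
summarize_by_class <- function(contributions, labels) {
  labels <- labels[rownames(contributions)]
  act <- contributions[labels == "active", , drop = FALSE]
  ina <- -contributions[labels == "inactive", , drop = FALSE]
  if (nrow(act) == 0L || nrow(ina) == 0L)
    stop("summarize_by_class: empty class")
  se <- function(m) if (nrow(m) < 2L) rep(0, ncol(m))
                    else apply(m, 2, sd) / sqrt(nrow(m))
  out <- data.frame(feature = colnames(contributions),
                    mean_contrib_active = colMeans(act),
                    stderr_active = se(act),
                    mean_contrib_inactive = colMeans(ina),
                    stderr_inactive = se(ina),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("shap_summary", "data.frame")
  out
}

#' Keep descriptors whose SHAP contributions are class-consistent
#'
#' A descriptor is consistent when its average contribution toward "active"
#' among active testing compounds and its average contribution toward
#' "inactive" among inactive testing compounds are both strictly positive.
#' Order is preserved; the filter is idempotent.
#'
#' @param summaries a [summarize_by_class()] result.
#' @return character vector of consistent feature names.
#' @export
filter_consistent <- function(summaries) {
  if (!nrow(summaries)) stop("filter_consistent: empty summary")
  keep <- summaries$mean_contrib_active > 0 &
    summaries$mean_contrib_inactive > 0
  summaries$feature[keep]
}

#' Select the pharmacophore template pose of a compound
#'
#' The pose maximizing the summed contribution toward "active" over the
#' SHAP-consistent descriptors; ties broken by the lexicographically
#' smaller pose id.
#'
#' @param compound_id the compound to pick a template for.
#' @param contributions matrix from [shap_values()] (rownames = pose ids).
#' @param compound_of named vector pose_id -> compound_id.
#' @param consistent_features features surviving [filter_consistent()].
#' @return the selected pose id.
#' @export
select_template_pose <- function(compound_id, contributions, compound_of,
                                 consistent_features) {
  rows <- rownames(contributions)[compound_of[rownames(contributions)] ==
                                    compound_id]
  if (!length(rows)) stop("select_template_pose: compound has no poses")
  sums <- rowSums(contributions[rows, intersect(consistent_features,
                                                colnames(contributions)),
                                drop = FALSE])
  rows <- sort(rows)
  sums <- sums[rows]
  rows[which.max(sums)]
}
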