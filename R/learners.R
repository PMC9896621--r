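# Learner panel. Each learner is fitted through lrn_fit() and queried with
# lrn_predict(), which always returns an n x K matrix of class probabilities
# with class names as colnames. Tree ensembles run in compiled code; the
# distance-based learners (knn, pnn, mlp) z-score features internally using
# training-fold statistics only.

.lrn_defaults <- list(
  rf  = list(ntree = 100L, max_depth = 20L, min_node = 2L),
  xgb = list(nrounds = 60L, max_depth = 3L, eta = 0.3, lambda = 1,
             nbins = 32L, min_hess = 1e-3),
  knn = list(k = 5L, weighted = FALSE),
  pnn = list(sigma_grid = c(0.5, 1, 2, 4)),
  mlp = list(hidden = 16L, epochs = 300L, lr = 0.05, momentum = 0.9),
  nb  = list(laplace = 1)
)

.zscale_fit <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  list(mu = mu, sd = sdv)
}
.zscale_apply <- function(X, z) sweep(sweep(X, 2, z$mu), 2, z$sd, "/")

#' Fit one learner of the panel
#'
#' @param name one of `"rf"`, `"xgb"`, `"nb"`, `"knn"`, `"pnn"`, `"mlp"`.
#' @param X numeric descriptor matrix (rows = poses).
#' @param y factor (or character) of class labels.
#' @param seed integer seed controlling any internal randomness.
#' @param params named list overriding the learner's defaults.
#' @return A `posevote_learner` object for [lrn_predict()].
#' @export
lrn_fit <- function(name, X, y, seed = 1L, params = list()) {
  name <- match.arg(name, c("rf", "xgb", "nb", "knn", "pnn", "mlp"))
  y <- factor(y)
  if (nlevels(y) < 2L) stop("lrn_fit: training data contains a single class")
  p <- utils::modifyList(.lrn_defaults[[name]], params)
  X <- as.matrix(X)
  classes <- levels(y)
  yi <- as.integer(y) - 1L
  K <- nlevels(y)
  fit <- switch(name,
    rf = {
      mtry <- max(1L, floor(sqrt(ncol(X))))
      cpp_rf_fit(X, yi, K, p$ntree, mtry, p$max_depth, p$min_node,
                 as.integer(seed %% 2147483647))
    },
    xgb = {
      if (K == 2L) {
        cpp_gbt_fit(X, as.numeric(yi), p$nrounds, p$max_depth, p$eta,
                    p$lambda, p$nbins, p$min_hess)
      } else {
        lapply(seq_len(K) - 1L, function(k)  # one-vs-rest
          cpp_gbt_fit(X, as.numeric(yi == k), p$nrounds, p$max_depth, p$eta,
                      p$lambda, p$nbins, p$min_hess))
      }
    },
    nb = .nb_fit(X, yi, K, p$laplace),
    knn = list(z = .zscale_fit(X), y = yi, k = p$k, weighted = p$weighted),
    pnn = .pnn_fit(X, yi, K, p$sigma_grid, seed),
    mlp = .mlp_fit(X, yi, K, p, seed)
  )
  if (name == "knn") fit$Xz <- .zscale_apply(X, fit$z)
  structure(list(name = name, fit = fit, classes = classes, params = p),
            class = "posevote_learner")
}

#' Class-probability predictions of a fitted learner
#' @param object a [lrn_fit()] result.
#' @param X descriptor matrix with the training column layout.
#' @return n x K matrix of class probabilities (columns named by class).
#' @export
lrn_predict <- function(object, X) {
  X <- as.matrix(X)
  K <- length(object$classes)
  fit <- object$fit
  pr <- switch(object$name,
    rf = cpp_rf_predict(fit, X),
    xgb = {
      if (K == 2L) {
        p1 <- cpp_gbt_predict(fit, X)
        cbind(1 - p1, p1)
      } else {
        raw <- vapply(fit, function(m) cpp_gbt_predict(m, X),
                      numeric(nrow(X)))
        raw <- matrix(raw, nrow = nrow(X))
        raw / pmax(rowSums(raw), 1e-12)
      }
    },
    nb = .nb_predict(fit, X),
    knn = .knn_predict(fit, X, K),
    pnn = .pnn_predict(fit, X, K),
    mlp = .mlp_predict(fit, X)
  )
  colnames(pr) <- object$classes
  pr
}

lrn_predict_class <- function(object, X) {
  pr <- lrn_predict(object, X)
  object$classes[max.col(pr, ties.method = "first")]
}

# ---- naive Bayes: Bernoulli for 0/1 columns, Gaussian otherwise ----

.nb_fit <- function(X, yi, K, laplace) {
  binary <- apply(X, 2, function(v) all(v %in% c(0, 1)))
  prior <- (tabulate(yi + 1L, K) + laplace) / (length(yi) + K * laplace)
  per_class <- lapply(seq_len(K) - 1L, function(k) {
    Xk <- X[yi == k, , drop = FALSE]
    nk <- nrow(Xk)
    theta <- (colSums(Xk[, binary, drop = FALSE]) + laplace) /
      (nk + 2 * laplace)
    mu <- colMeans(Xk[, !binary, drop = FALSE])
    sdv <- apply(Xk[, !binary, drop = FALSE], 2, sd)
    sdv[!is.finite(sdv) | sdv < 1e-6] <- 1e-6
    list(theta = theta, mu = mu, sd = sdv)
  })
  list(binary = binary, prior = prior, per_class = per_class)
}

.nb_predict <- function(fit, X) {
  K <- length(fit$per_class)
  n <- nrow(X)
  ll <- matrix(0, n, K)
  Xb <- X[, fit$binary, drop = FALSE]
  Xg <- X[, !fit$binary, drop = FALSE]
  for (k in seq_len(K)) {
    pc <- fit$per_class[[k]]
    ll[, k] <- log(fit$prior[k])
    if (ncol(Xb))
      ll[, k] <- ll[, k] + Xb %*% log(pc$theta) + (1 - Xb) %*% log(1 - pc$theta)
    if (ncol(Xg)) {
      lg <- -0.5 * sweep(sweep(Xg, 2, pc$mu), 2, pc$sd, "/")^2
      ll[, k] <- ll[, k] + rowSums(lg) - sum(log(pc$sd))
    }
  }
  ll <- ll - apply(ll, 1, max)
  e <- exp(ll)
  e / rowSums(e)
}

# ---- k-nearest neighbours (optionally distance-weighted voting) ----

.cross_dist <- function(A, B) {
  # Euclidean distances between rows of A (n) and rows of B (m): n x m
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

.knn_predict <- function(fit, X, K) {
  D <- .cross_dist(.zscale_apply(X, fit$z), fit$Xz)
  k <- min(fit$k, ncol(D))
  out <- matrix(0, nrow(X), K)
  for (i in seq_len(nrow(X))) {
    nn <- order(D[i, ])[seq_len(k)]
    w <- if (fit$weighted) 1 / (D[i, nn] + 1e-6) else rep(1, k)
    for (j in seq_len(k)) out[i, fit$y[nn[j]] + 1L] <- out[i, fit$y[nn[j]] + 1L] + w[j]
  }
  out / rowSums(out)
}

# ---- probabilistic neural network (Parzen/Gaussian-kernel classifier) ----

.pnn_fit <- function(X, yi, K, sigma_grid, seed) {
  z <- .zscale_fit(X)
  Xz <- .zscale_apply(X, z)
  # bandwidth by 3-fold CV accuracy over the grid
  fold <- with_seed(child_seed(seed, 31L),
                    sample(rep_len(1:3, nrow(Xz))))
  best <- sigma_grid[1]
  best_acc <- -1
  for (s in sigma_grid) {
    correct <- 0L
    for (f in 1:3) {
      tr <- fold != f
      if (!any(tr) || !any(!tr)) next
      pr <- .pnn_kernel(Xz[!tr, , drop = FALSE], Xz[tr, , drop = FALSE],
                        yi[tr], K, s)
      correct <- correct + sum(max.col(pr) - 1L == yi[!tr])
    }
    if (correct > best_acc) { best_acc <- correct; best <- s }
  }
  list(z = z, Xz = Xz, y = yi, sigma = best)
}

.pnn_kernel <- function(Xq, Xr, yr, K, sigma) {
  D <- .cross_dist(Xq, Xr)
  W <- exp(-D^2 / (2 * sigma^2))
  out <- matrix(1e-12, nrow(Xq), K)
  for (k in seq_len(K) - 1L) {
    idx <- yr == k
    if (any(idx)) out[, k + 1L] <- out[, k + 1L] + rowMeans(W[, idx, drop = FALSE])
  }
  out / rowSums(out)
}

.pnn_predict <- function(fit, X, K)
  .pnn_kernel(.zscale_apply(X, fit$z), fit$Xz, fit$y, K, fit$sigma)

# ---- multilayer perceptron: 1 tanh hidden layer, softmax output ----

.mlp_fit <- function(X, yi, K, p, seed) {
  z <- .zscale_fit(X)
  Xz <- .zscale_apply(X, z)
  n <- nrow(Xz); d <- ncol(Xz); h <- p$hidden
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), yi + 1L)] <- 1
  with_seed(child_seed(seed, 47L), {
    W1 <- matrix(runif(d * h, -0.5, 0.5) / sqrt(d), d, h)
    b1 <- rep(0, h)
    W2 <- matrix(runif(h * K, -0.5, 0.5) / sqrt(h), h, K)
    b2 <- rep(0, K)
    vW1 <- W1 * 0; vb1 <- b1 * 0; vW2 <- W2 * 0; vb2 <- b2 * 0
    for (ep in seq_len(p$epochs)) {
      H <- tanh(sweep(Xz %*% W1, 2, b1, "+"))
      L <- sweep(H %*% W2, 2, b2, "+")
      L <- L - apply(L, 1, max)
      P <- exp(L); P <- P / rowSums(P)
      dL <- (P - Y) / n
      gW2 <- crossprod(H, dL); gb2 <- colSums(dL)
      dH <- dL %*% t(W2) * (1 - H^2)
      gW1 <- crossprod(Xz, dH); gb1 <- colSums(dH)
      vW1 <- p$momentum * vW1 - p$lr * gW1; W1 <- W1 + vW1
      vb1 <- p$momentum * vb1 - p$lr * gb1; b1 <- b1 + vb1
      vW2 <- p$momentum * vW2 - p$lr * gW2; W2 <- W2 + vW2
      vb2 <- p$momentum * vb2 - p$lr * gb2; b2 <- b2 + vb2
    }
    list(z = z, W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  })
}

.mlp_predict <- function(fit, X) {
  H <- tanh(sweep(.zscale_apply(X, fit$z) %*% fit$W1, 2, fit$b1, "+"))
  L <- sweep(H %*% fit$W2, 2, fit$b2, "+")
  L <- L - apply(L, 1, max)
  P <- exp(L)
  P / rowSums(P)
}
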