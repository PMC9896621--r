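fit_small_xgb <- function(X, y) {
  lrn_fit("xgb", X, factor(y, levels = c("active", "inactive")), seed = 1,
          params = list(nrounds = 15L, max_depth = 3L))
}

test_that("exact SHAP on a 3-feature tree matches coalition enumeration", {
  posevote:::with_seed(2, {
    X <- matrix(rbinom(60 * 3, 1, 0.5), 60, 3,
                dimnames = list(NULL, c("f1", "f2", "f3")))
    y <- ifelse(X[, 1] + X[, 2] >= 1 + rbinom(60, 1, 0.15), "active",
                "inactive")
    mod <- fit_small_xgb(X, y)
    bg <- X[1:20, ]
    rows <- X[21:26, , drop = FALSE]
    got <- shap_values(mod, rows, bg, method = "exact")
    fpred <- function(M) lrn_predict(mod, M)[, "active"]
    for (i in seq_len(nrow(rows))) {
      value_fn <- function(have) {
        big <- bg
        big[, have] <- matrix(rows[i, have], nrow(bg), sum(have),
                              byrow = TRUE)
        mean(fpred(big))
      }
      oracle <- bf_shapley(value_fn, 3)
      expect_equal(unname(got[i, ]), oracle, tolerance = 1e-10)
    }
    # permutation estimator with all 3! orderings is exact as well
    gotp <- shap_values(mod, rows, bg, method = "permutation", n_perm = 6,
                        seed = 3)
    expect_equal(as.vector(gotp), as.vector(got), tolerance = 0.08)
  })
})

test_that("local accuracy holds for both estimators", {
  posevote:::with_seed(5, {
    X <- matrix(rnorm(200 * 6), 200, 6,
                dimnames = list(NULL, paste0("v", 1:6)))
    y <- ifelse(X[, 1] - X[, 2] + 0.3 * rnorm(200) > 0, "active", "inactive")
    mod <- fit_small_xgb(X, y)
    bg <- shap_background(X, k = 25, seed = 1)
    rows <- X[1:8, ]
    for (m in c("exact", "permutation")) {
      phi <- shap_values(mod, rows, bg, method = m, n_perm = 8, seed = 2)
      recon <- rowSums(phi) + attr(phi, "baseline")
      expect_equal(recon, unname(lrn_predict(mod, rows)[, "active"]),
                   tolerance = 1e-3)
    }
  })
})

test_that("constant features get zero attribution; single features get all", {
  posevote:::with_seed(6, {
    X <- cbind(sig = rbinom(80, 1, 0.5), const = 1)
    y <- ifelse(X[, "sig"] == 1, "active", "inactive")
    mod <- fit_small_xgb(X, y)
    bg <- X[1:30, ]
    phi <- shap_values(mod, X[31:40, ], bg, method = "exact")
    expect_true(all(abs(phi[, "const"]) < 1e-12))
    # effectively a single-feature model: contribution = prediction - baseline
    pred <- lrn_predict(mod, X[31:40, ])[, "active"]
    expect_equal(unname(phi[, "sig"]),
                 unname(pred - attr(phi, "baseline")), tolerance = 1e-10)
  })
})

test_that("k-means background is clamped and reproducible", {
  X <- matrix(rep(1:3, each = 4), 12, 2)  # 3 distinct rows
  bg <- shap_background(X, k = 100, seed = 1)
  expect_lte(nrow(bg), 3)
  X2 <- matrix(rnorm(400), 200, 2)
  b1 <- shap_background(X2, k = 10, seed = 7)
  b2 <- shap_background(X2, k = 10, seed = 7)
  expect_identical(b1, b2)
})

test_that("class summaries, consistency filter and its idempotence", {
  contrib <- rbind(a1 = c(s = 0.2, n = 0.05, bad = 0.1),
                   a2 = c(s = 0.3, n = -0.05, bad = 0.2),
                   i1 = c(s = -0.25, n = 0.02, bad = 0.15),
                   i2 = c(s = -0.15, n = -0.02, bad = 0.05))
  labels <- c(a1 = "active", a2 = "active", i1 = "inactive", i2 = "inactive")
  s <- summarize_by_class(contrib, labels)
  expect_equal(s$mean_contrib_active[s$feature == "s"], 0.25)
  expect_equal(s$mean_contrib_inactive[s$feature == "s"], 0.20)
  # 'bad' helps "active" in both classes -> inconsistent
  expect_equal(filter_consistent(s), "s")
  s_sub <- s[s$feature %in% filter_consistent(s), ]
  expect_equal(filter_consistent(s_sub), "s")
  # zero contributions give zero means; single-pose class gives stderr 0
  z <- summarize_by_class(rbind(a1 = c(x = 0), i1 = c(x = 0)),
                          c(a1 = "active", i1 = "inactive"))
  expect_equal(z$mean_contrib_active, 0)
  expect_equal(z$stderr_active, 0)
  expect_error(summarize_by_class(contrib[1:2, ], labels), "empty class")
})

test_that("template pose selection: argmax, ties, errors", {
  contrib <- rbind(`c1#1` = c(f = 0.1, g = 0.2),
                   `c1#2` = c(f = 0.5, g = 0.2),
                   `c2#1` = c(f = 0.9, g = 0.9))
  co <- c(`c1#1` = "c1", `c1#2` = "c1", `c2#1` = "c2")
  expect_equal(select_template_pose("c1", contrib, co, c("f", "g")), "c1#2")
  expect_equal(select_template_pose("c2", contrib, co, c("f", "g")), "c2#1")
  tie <- rbind(`c1#1` = c(f = 0.3), `c1#2` = c(f = 0.3))
  expect_equal(select_template_pose("c1", tie, co, "f"), "c1#1")
  expect_error(select_template_pose("zz", contrib, co, "f"), "no poses")
})

test_that("planted descriptors dominate class-conditional SHAP on fixtures", {
  fm <- toy_signal_matrix(n_cmp = 40, poses_per = 4, p_noise = 5, seed = 21)
  mod <- fit_small_xgb(fm$X, fm$labels)
  bg <- shap_background(fm$X, k = 30, seed = 2)
  phi <- shap_values(mod, fm$X[1:60, ], bg, method = "permutation",
                     n_perm = 10, seed = 3)
  s <- summarize_by_class(phi, fm$labels[1:60])
  top <- s$feature[which.max(s$mean_contrib_active)]
  expect_true(top %in% c("SIG1", "SIG2", "SIG3"))
  expect_true(all(c("SIG1", "SIG2", "SIG3") %in% filter_consistent(s)))
})
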