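test_that("accuracy from confusion counts", {
  cm <- matrix(c(10, 0, 0, 10), 2, 2)
  expect_equal(accuracy(cm), 1)
  expect_equal(accuracy(matrix(c(0, 10, 10, 0), 2, 2)), 0)
  # TP=40 TN=30 FP=20 FN=10 -> 0.7
  cm2 <- matrix(c(40, 20, 10, 30), 2, 2, byrow = TRUE)
  expect_equal(accuracy(cm2), 0.7)
  expect_error(accuracy(matrix(0, 2, 2)), "N = 0")
  # multi-class trace/N
  cm3 <- diag(c(3, 4, 5)); cm3[1, 2] <- 3
  expect_equal(accuracy(cm3), 12 / 15)
})

test_that("Cohen's kappa: limits, derived value, degenerate marginals", {
  expect_equal(cohens_kappa(matrix(c(10, 0, 0, 10), 2, 2)), 1)
  expect_equal(cohens_kappa(diag(c(2, 5, 9))), 1)
  expect_equal(cohens_kappa(matrix(25, 2, 2)), 0)
  # [[40,10],[20,30]]: P0 = 0.7, Pe = 0.5 -> 0.4
  expect_equal(cohens_kappa(matrix(c(40, 10, 20, 30), 2, 2, byrow = TRUE)),
               0.4)
  expect_warning(k <- cohens_kappa(matrix(c(7, 0, 0, 0), 2, 2)),
                 "degenerate")
  expect_equal(k, 0)
  # worse than chance is negative
  expect_lt(cohens_kappa(matrix(c(0, 10, 10, 0), 2, 2)), 0)
})

test_that("ROC: perfect, uninformative, and the 4-item derived toy", {
  r <- roc_curve(c(a = 3, b = 2, c = -1, d = -2),
                 c(a = "active", b = "active", c = "x", d = "x"))
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  flat <- roc_curve(rep(1, 6), rep(c("active", "x"), 3))
  expect_equal(flat$auc, 0.5)
  # {pos: 0.9, 0.6; neg: 0.7, 0.2}: 3 of 4 pos-neg pairs concordant
  toy <- roc_curve(c(0.9, 0.6, 0.7, 0.2),
                   c("active", "active", "x", "x"))
  expect_equal(toy$auc, 0.75)
  expect_error(roc_curve(1:3, rep("active", 3)), "both classes")
})

test_that("feature matrix assembles bits + scores with aligned labels", {
  fx <- generate_fixtures(fixture_config(n_compounds = 10, n_site_atoms = 30,
                                         poses_per_compound = c(2, 4),
                                         seed = 5))
  fp <- build_fingerprint_matrix(fx$poses, fx$site)
  co <- vapply(fx$poses, `[[`, "", "compound_id")
  names(co) <- vapply(fx$poses, `[[`, "", "pose_id")
  fm <- feature_matrix(fp, fx$scores, fx$activities, co)
  expect_equal(ncol(fm$X), 30 + 9)
  expect_identical(colnames(fm$X)[1:30], site_atom_ids(fx$site))
  expect_true(all(colnames(fm$X)[31:39] == paste0("SF", 1:9)))
  expect_false(anyNA(fm$X))
  pid <- rownames(fm$X)[5]
  expect_equal(unname(fm$labels[pid]),
               fx$activities$activity_class[fx$activities$compound_id ==
                                              co[pid]])
})

test_that("learner panel separates a planted signal and is reproducible", {
  fm <- toy_signal_matrix(n_cmp = 40, poses_per = 5, seed = 3)
  sp <- toy_split(fm)
  rep1 <- scan_learners(fm, sp, seed = 2, knn_k = c(3L, 5L))
  expect_true(all(c("rf", "xgb", "nb", "pnn", "mlp") %in% rep1$learner))
  expect_true(any(grepl("knn_wd", rep1$learner)))
  expect_equal(rep1$kappa_test, sort(rep1$kappa_test, decreasing = TRUE))
  expect_gt(max(rep1$kappa_test), 0.5)
  expect_true(all(rep1$accuracy_cv >= 0 & rep1$accuracy_cv <= 1))
  rep2 <- scan_learners(fm, sp, seed = 2, knn_k = c(3L, 5L))
  expect_identical(rep1, rep2)
})

test_that("single-class training partitions are rejected", {
  fm <- toy_signal_matrix(n_cmp = 20, poses_per = 3, seed = 4)
  keep <- fm$labels == "active"
  fm$X <- fm$X[keep, ]; fm$labels <- fm$labels[keep]
  fm$compound_of <- fm$compound_of[keep]
  sp <- toy_split(fm)
  expect_error(scan_learners(fm, sp, learners = "nb"), "single class")
})

test_that("permuted labels give chance-level kappa for every learner", {
  fm <- toy_signal_matrix(n_cmp = 100, poses_per = 20, p_noise = 15, seed = 6)
  fm$labels[] <- posevote:::with_seed(7, sample(unname(fm$labels)))
  sp <- toy_split(fm)
  rep <- scan_learners(fm, sp, seed = 8, knn_k = c(5L))
  expect_true(all(abs(rep$kappa_test) < 0.15))
})

test_that("three-class evaluation engages when intermediates are kept", {
  fm <- toy_signal_matrix(n_cmp = 45, poses_per = 4, seed = 9)
  third_cmp <- unique(fm$compound_of)[c(TRUE, FALSE, FALSE)]
  fm$labels[fm$compound_of %in% third_cmp] <- "intermediate"
  sp <- toy_split(fm)
  rep <- scan_learners(fm, sp, learners = c("nb", "xgb"), seed = 1,
                       drop_intermediates = FALSE)
  expect_true(all(is.finite(rep$kappa_cv)))
  expect_equal(nrow(rep), 2)
  # the intermediate class is noise here, so excluding it must not lower
  # the best test kappa
  rep_bin <- scan_learners(fm, sp, learners = c("nb", "xgb"), seed = 1,
                           drop_intermediates = TRUE)
  expect_gte(max(rep_bin$kappa_test), max(rep$kappa_test))
})
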